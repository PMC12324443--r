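#' Filter proteins by per-group quantification completeness
#'
#' Retains a protein when its observed fraction reaches \code{min_frac}
#' in at least one experimental group (the study convention: quantified
#' in >= 80\% of replicates of some group). Row order is preserved.
#'
#' @param x A \linkS4class{QuantMatrix}.
#' @param min_frac Minimum observed fraction (default from config, 0.8).
#' @return The filtered \linkS4class{QuantMatrix}.
#' @export
filterByCompleteness <- function(x, min_frac = 0.8) {
  m <- quantIntensities(x)
  if (nrow(m) == 0L) {
    warning("empty quantification matrix")
    return(x)
  }
  g <- quantGroups(x)
  frac <- sapply(unique(g), function(grp) {
    cols <- which(g == grp)
    rowMeans(!is.na(m[, cols, drop = FALSE]))
  })
  frac <- matrix(frac, nrow = nrow(m))
  keep <- apply(frac, 1L, max) >= min_frac
  x[keep, ]
}

#' Normalize a quantification matrix
#'
#' \code{log2_median} (default): log2-transform raw intensities
#' (non-positive values become missing) and subtract each sample's
#' median, removing multiplicative between-sample effects. \code{glog}:
#' a generalized-log (asinh-type) transform approximating
#' variance-stabilizing normalization; each sample is first scaled by a
#' moment-matching factor (its median over the mean of sample medians),
#' the glog offset is set to the mean lower-decile intensity, and sample
#' medians are centered afterwards.
#'
#' @param x A \linkS4class{QuantMatrix}.
#' @param method \code{"log2_median"} or \code{"glog"}.
#' @return A log2-scale \linkS4class{QuantMatrix}.
#' @export
normalizeQuant <- function(x, method = c("log2_median", "glog")) {
  method <- match.arg(method)
  m <- quantIntensities(x)
  if (quantScale(x) == "raw") {
    npos <- !is.na(m) & m <= 0
    if (any(npos)) {
      message(sum(npos), " non-positive intensities treated as missing")
      m[npos] <- NA
    }
  }
  if (method == "log2_median") {
    lm2 <- if (quantScale(x) == "raw") log2(m) else m
    med <- apply(lm2, 2L, stats::median, na.rm = TRUE)
    out <- sweep(lm2, 2L, med)
  } else {
    if (quantScale(x) != "raw")
      stop("glog normalization needs raw-scale intensities")
    med <- apply(m, 2L, stats::median, na.rm = TRUE)
    s <- med / mean(med)
    ms <- sweep(m, 2L, s, "/")
    c0 <- mean(apply(ms, 2L, stats::quantile, probs = 0.1, na.rm = TRUE))
    out <- log2((ms + sqrt(ms^2 + c0^2)) / 2)
    out <- sweep(out, 2L, apply(out, 2L, stats::median, na.rm = TRUE))
  }
  .replaceIntensities(x, out, scale = "log2")
}

#' Mixed MAR/MNAR imputation
#'
#' Missing cells whose protein has at least one observed replicate in
#' the same group are treated as missing-at-random (MAR) and replaced by
#' the mean of that group's observed replicates. Cells with no observed
#' value in their group are missing-not-at-random (MNAR) and drawn from
#' a down-shifted Gaussian, Normal(m_s - downshift*s_s,
#' (width*s_s)^2), where m_s and s_s are the mean and SD of the
#' observed values of that cell's sample. Draws are consumed in
#' protein-major order, so results are reproducible for a fixed seed and
#' independent of insertion order.
#'
#' @param x A log2-scale \linkS4class{QuantMatrix}.
#' @param downshift Down-shift in per-sample SD units (1.8).
#' @param width Width in per-sample SD units (0.3).
#' @param seed Integer seed for the MNAR draws.
#' @return A complete \linkS4class{QuantMatrix}.
#' @export
imputeMixed <- function(x, downshift = 1.8, width = 0.3, seed = 1L) {
  if (quantScale(x) != "log2")
    stop("imputation expects a log-scale matrix")
  m <- quantIntensities(x)
  if (!anyNA(m)) return(x)
  g <- quantGroups(x)
  nobs <- colSums(!is.na(m))
  if (any(nobs < 2L))
    stop("sample(s) with < 2 observed values (SD undefined): ",
         paste(colnames(m)[nobs < 2L], collapse = ", "))
  ms <- colMeans(m, na.rm = TRUE)
  ss <- apply(m, 2L, stats::sd, na.rm = TRUE)
  set.seed(seed)
  ord_rows <- order(rownames(m))
  ord_cols <- order(colnames(m))
  for (i in ord_rows) {
    for (j in ord_cols) {
      if (!is.na(m[i, j])) next
      grp_cols <- which(g == g[j])
      obs <- m[i, grp_cols]
      obs <- obs[!is.na(obs)]
      m[i, j] <- if (length(obs) > 0L) mean(obs)
        else stats::rnorm(1L, ms[j] - downshift * ss[j], width * ss[j])
    }
  }
  .replaceIntensities(x, m)
}

#' Per-protein Welch's t-test between two groups
#'
#' Two-sided Welch test (unequal variances, Welch-Satterthwaite degrees
#' of freedom) per protein; the fold change is the mean of the test
#' group minus the mean of the control group, in log2 units. Proteins
#' with zero variance in both groups get t = 0, p = 1 when the means are
#' equal, and infinite t with p = 0 otherwise.
#'
#' @param x A complete log2-scale \linkS4class{QuantMatrix}.
#' @param group_test,group_ctrl Group labels to contrast.
#' @return data.frame with columns \code{accession}, \code{log2_fc},
#'   \code{t_stat}, \code{p}.
#' @export
welchTest <- function(x, group_test, group_ctrl) {
  m <- quantIntensities(x)
  if (anyNA(m)) stop("matrix contains missing values; impute first")
  g <- quantGroups(x)
  it <- which(g == group_test)
  ic <- which(g == group_ctrl)
  if (length(it) < 2L || length(ic) < 2L)
    stop("both groups need >= 2 samples")
  res <- t(apply(m, 1L, function(v) {
    a <- v[it]; b <- v[ic]
    fc <- mean(a) - mean(b)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (fc == 0) c(fc, 0, 1) else c(fc, sign(fc) * Inf, 0)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      c(fc, unname(tt$statistic), tt$p.value)
    }
  }))
  data.frame(accession = rownames(m), log2_fc = res[, 1],
             t_stat = res[, 2], p = res[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (capped at 1, original order restored).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call enriched (and depleted) proteins
#'
#' A protein is enriched when its log2 fold change is at least
#' \code{lfc_min} and its adjusted p-value is strictly below
#' \code{alpha}; the symmetric depleted set uses \code{-lfc_min}.
#'
#' @param results data.frame from \code{\link{welchTest}} (columns
#'   \code{accession}, \code{log2_fc}, \code{p}); \code{p_adj} is added
#'   if absent.
#' @param lfc_min Minimum log2 fold change (2).
#' @param alpha Adjusted-p cutoff (0.05, strict).
#' @return The input with \code{p_adj}, \code{enriched} and
#'   \code{depleted} columns.
#' @export
callEnriched <- function(results, lfc_min = 2, alpha = 0.05) {
  if (is.null(results$p_adj)) results$p_adj <- bhAdjust(results$p)
  results$enriched <- results$log2_fc >= lfc_min & results$p_adj < alpha
  results$depleted <- results$log2_fc <= -lfc_min & results$p_adj < alpha
  results
}

#' Full AP-MS enrichment analysis
#'
#' Completeness filter, normalization, mixed imputation, per-protein
#' Welch tests, BH adjustment and threshold calls, in the study's order.
#'
#' @param x A \linkS4class{QuantMatrix} (raw or log2 scale).
#' @param group_test,group_ctrl Group labels to contrast.
#' @param config \code{\link{xlConfig}} supplying thresholds and the
#'   imputation parameters.
#' @param normalize_method Passed to \code{\link{normalizeQuant}}
#'   (skipped when the input is already log2 scale and method is glog).
#' @param seed Seed for the imputation draws (default from config).
#' @return data.frame of per-protein results (see
#'   \code{\link{callEnriched}}).
#' @export
runEnrichment <- function(x, group_test, group_ctrl, config = xlConfig(),
                          normalize_method = "log2_median",
                          seed = config$rng_seed) {
  x <- filterByCompleteness(x, config$completeness_min)
  x <- normalizeQuant(x, method = normalize_method)
  x <- imputeMixed(x, downshift = config$imputation_downshift,
                   width = config$imputation_width, seed = seed)
  res <- welchTest(x, group_test, group_ctrl)
  callEnriched(res, lfc_min = config$lfc_min, alpha = config$alpha)
}
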