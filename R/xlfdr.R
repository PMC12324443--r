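#' Prefilter candidate crosslink matches on fragment evidence
#'
#' Keeps candidates with more than two fragments matched with a
#' non-cleaved SDA and at least five matched fragments for each of the
#' two peptides.
#'
#' @param x An \linkS4class{XLinkSet} carrying the evidence columns
#'   \code{n_noncleaved_sda_fragments}, \code{n_matches_peptide_a},
#'   \code{n_matches_peptide_b}.
#' @return The filtered \linkS4class{XLinkSet}.
#' @export
prefilterCandidates <- function(x) {
  df <- xlRecords(x)
  need <- c("n_noncleaved_sda_fragments", "n_matches_peptide_a",
            "n_matches_peptide_b")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("candidate evidence column(s) missing: ",
         paste(miss, collapse = ", "))
  keep <- df$n_noncleaved_sda_fragments > 2L &
    pmin(df$n_matches_peptide_a, df$n_matches_peptide_b) >= 5L
  x[keep]
}

#' Collapse candidate matches to unique residue pairs
#'
#' One record per unique canonical (protein_a, residue_a, protein_b,
#' residue_b); the best-scoring member supplies the score and decoy
#' class, and dataset provenance is unioned.
#'
#' @param x An \linkS4class{XLinkSet}.
#' @return An \linkS4class{XLinkSet} of unique residue pairs.
#' @export
aggregateToResiduePairs <- function(x) {
  df <- as.data.frame(x)
  if (nrow(df) == 0L) return(x)
  key <- .pairKey(df)
  ord <- order(key, -df$score)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  ds <- vapply(split(df$dataset_id, key), function(d)
    paste(sort(unique(d)), collapse = ";"), character(1))
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$dataset_id <- unname(ds[key[first]])
  XLinkSet(out)
}

#' Target-decoy FDR estimate at a score threshold
#'
#' Counts TT/TD/DD records with score at or above the threshold and
#' estimates FDR as max(0, TD - DD) / TT (the reversed-decoy estimator;
#' a decoy-decoy match corrects for double counting). With no TT above
#' threshold the estimate is undefined (\code{NA}).
#'
#' @param x An \linkS4class{XLinkSet} or a data.frame with \code{score}
#'   and \code{decoy_class}.
#' @param threshold Score threshold (records with \code{score >=
#'   threshold} are counted). Default \code{-Inf}: the whole set.
#' @param level Label recorded in the report (\code{"residue_pair"} or
#'   \code{"ppi"}).
#' @return An \code{FDRReport}: list with \code{level},
#'   \code{threshold_score}, \code{counts} (named TT/TD/DD) and
#'   \code{fdr_est}.
#' @export
estimateFdr <- function(x, threshold = -Inf, level = "residue_pair") {
  df <- if (is(x, "XLinkSet")) as.data.frame(x) else as.data.frame(x)
  sel <- df$score >= threshold
  counts <- c(TT = sum(sel & df$decoy_class == "TT"),
              TD = sum(sel & df$decoy_class == "TD"),
              DD = sum(sel & df$decoy_class == "DD"))
  fdr <- if (counts["TT"] > 0L)
    max(0, counts["TD"] - counts["DD"]) / counts["TT"] else NA_real_
  structure(list(level = level, threshold_score = threshold,
                 counts = counts, fdr_est = unname(fdr)),
            class = "FDRReport")
}

#' @export
print.FDRReport <- function(x, ...) {
  cat("FDRReport [", x$level, "] threshold ", format(x$threshold_score),
      ": TT=", x$counts["TT"], " TD=", x$counts["TD"],
      " DD=", x$counts["DD"], " -> FDR ",
      if (is.na(x$fdr_est)) "undefined" else format(x$fdr_est, digits = 3),
      "\n", sep = "")
  invisible(x)
}

# For every candidate threshold (unique scores, descending acceptance),
# the estimated FDR; returns the lowest threshold meeting the target,
# i.e. the largest accepted set, or NULL when none qualifies.
.chooseThreshold <- function(score, decoy_class, target) {
  if (length(score) == 0L) return(NULL)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  cls <- decoy_class[ord]
  tt <- cumsum(cls == "TT")
  td <- cumsum(cls == "TD")
  dd <- cumsum(cls == "DD")
  # evaluate at the last tied record of each distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  fdr <- ifelse(tt[last] > 0, pmax(0, td[last] - dd[last]) / tt[last], NA)
  ok <- which(!is.na(fdr) & fdr <= target)
  if (length(ok) == 0L) return(NULL)
  s[last[max(ok)]]
}

#' Aggregate residue pairs into PPI edges
#'
#' Inter-protein records are grouped by unordered protein pair. The edge
#' score aggregates member residue-pair scores (sum by default); the
#' edge decoy class is the worst among members and dataset provenance is
#' unioned. Self links (same accession) are excluded, matching
#' inter-protein accounting.
#'
#' @param x An \linkS4class{XLinkSet}.
#' @param aggregate \code{"sum"} (default), \code{"max"} or
#'   \code{"topn_sum"}.
#' @param topn Number of members summed when \code{aggregate =
#'   "topn_sum"}.
#' @return data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{n_residue_pairs}, \code{aggregate_score}, \code{decoy_class},
#'   \code{datasets}.
#' @export
buildPPIEdges <- function(x, aggregate = c("sum", "max", "topn_sum"),
                          topn = 3L) {
  aggregate <- match.arg(aggregate)
  df <- as.data.frame(x)
  df <- df[df$is_inter_protein, , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(protein_a = character(), protein_b = character(),
                      n_residue_pairs = integer(),
                      aggregate_score = numeric(),
                      decoy_class = character(), datasets = character(),
                      stringsAsFactors = FALSE))
  f <- factor(.ppiKey(df))
  first <- match(levels(f), as.character(f))
  score <- switch(
    aggregate,
    sum = rowsum(df$score, f)[, 1L],
    max = vapply(split(df$score, f), max, numeric(1)),
    topn_sum = vapply(split(df$score, f), function(s)
      sum(sort(s, decreasing = TRUE)[seq_len(min(topn, length(s)))]),
      numeric(1)))
  # decoy class is a property of the accession pair, shared by members
  datasets <- vapply(split(df$dataset_id, f), function(d)
    paste(sort(unique(unlist(strsplit(d, ";", fixed = TRUE)))),
          collapse = ";"), character(1))
  out <- data.frame(protein_a = df$protein_a[first],
                    protein_b = df$protein_b[first],
                    n_residue_pairs = tabulate(f),
                    aggregate_score = unname(score[levels(f)]),
                    decoy_class = df$decoy_class[first],
                    datasets = unname(datasets[levels(f)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$protein_a, out$protein_b), , drop = FALSE]
}

#' Hierarchical target-decoy filtering at residue-pair and PPI level
#'
#' Chooses the most permissive residue-pair score threshold whose
#' estimated FDR does not exceed \code{rp_fdr}, aggregates survivors
#' into PPI edges, and applies a second threshold on aggregated edge
#' scores at \code{ppi_fdr}. With \code{boost = TRUE} the residue-pair
#' threshold is grid-searched over all observed scores to maximize the
#' number of accepted target PPIs, subject to both FDR constraints (the
#' PPI-boosting strategy). Decoy records are removed from the returned
#' sets but retained in the FDR reports.
#'
#' @param x An \linkS4class{XLinkSet} of (prefiltered) candidate matches
#'   or residue pairs; matches are collapsed to unique residue pairs
#'   first.
#' @param rp_fdr Residue-pair FDR target (0.02).
#' @param ppi_fdr PPI-level FDR target (0.05).
#' @param boost Grid-search the residue-pair threshold for maximal
#'   accepted target PPIs.
#' @param aggregate Edge score aggregation (see
#'   \code{\link{buildPPIEdges}}).
#' @return List of class \code{HierarchicalFDRResult}: accepted
#'   \code{residue_pairs} (targets only), \code{ppi_edges} (targets
#'   only), \code{reports} (residue-pair and PPI \code{FDRReport}s,
#'   decoys included in counts), and the chosen \code{thresholds}.
#' @export
hierarchicalFilter <- function(x, rp_fdr = 0.02, ppi_fdr = 0.05,
                               boost = FALSE, aggregate = "sum") {
  rp <- aggregateToResiduePairs(x)
  df <- as.data.frame(rp)

  eval_at <- function(thr) {
    keep <- df$score >= thr
    sub <- rp[keep]
    edges <- buildPPIEdges(sub, aggregate = aggregate)
    ppi_thr <- .chooseThreshold(edges$aggregate_score, edges$decoy_class,
                                ppi_fdr)
    acc_edges <- if (is.null(ppi_thr))
      edges[0L, , drop = FALSE]
    else edges[edges$aggregate_score >= ppi_thr, , drop = FALSE]
    list(sub = sub, edges = edges, ppi_thr = ppi_thr, acc = acc_edges)
  }

  rp_thr <- .chooseThreshold(df$score, df$decoy_class, rp_fdr)
  if (is.null(rp_thr)) {
    empty <- rp[0L]
    return(structure(list(
      residue_pairs = empty,
      ppi_edges = buildPPIEdges(empty, aggregate = aggregate),
      reports = list(residue_pair = estimateFdr(rp, Inf, "residue_pair"),
                     ppi = estimateFdr(
                       data.frame(score = numeric(),
                                  decoy_class = character()),
                       Inf, "ppi")),
      thresholds = list(residue_pair = NULL, ppi = NULL)),
      class = "HierarchicalFDRResult"))
  }

  if (boost) {
    # candidate grid: all thresholds meeting the residue-pair constraint
    ord <- order(df$score, decreasing = TRUE)
    s <- df$score[ord]
    cls <- df$decoy_class[ord]
    last <- which(!duplicated(s, fromLast = TRUE))
    tt <- cumsum(cls == "TT")[last]
    td <- cumsum(cls == "TD")[last]
    dd <- cumsum(cls == "DD")[last]
    fdr <- ifelse(tt > 0, pmax(0, td - dd) / tt, NA)
    cand <- s[last][!is.na(fdr) & fdr <= rp_fdr]
    # coarsen large grids, always retaining the unboosted threshold
    if (length(cand) > 64L)
      cand <- cand[unique(round(seq(1L, length(cand),
                                    length.out = 64L)))]
    cand <- unique(c(cand, rp_thr))
    n_tt <- vapply(cand, function(thr)
      sum(eval_at(thr)$acc$decoy_class == "TT"), numeric(1))
    if (length(cand) > 0L && max(n_tt) > 0)
      rp_thr <- min(cand[n_tt == max(n_tt)])
  }

  e <- eval_at(rp_thr)
  rp_report <- estimateFdr(e$sub, level = "residue_pair")
  rp_report$threshold_score <- rp_thr
  ppi_report <- estimateFdr(
    data.frame(score = e$edges$aggregate_score,
               decoy_class = e$edges$decoy_class),
    threshold = if (is.null(e$ppi_thr)) Inf else e$ppi_thr, level = "ppi")
  sub_df <- as.data.frame(e$sub)
  structure(list(
    residue_pairs = e$sub[sub_df$decoy_class == "TT"],
    ppi_edges = e$acc[e$acc$decoy_class == "TT", , drop = FALSE],
    reports = list(residue_pair = rp_report, ppi = ppi_report),
    thresholds = list(residue_pair = rp_thr, ppi = e$ppi_thr)),
    class = "HierarchicalFDRResult")
}

#' @export
print.HierarchicalFDRResult <- function(x, ...) {
  cat("Hierarchical FDR result:\n")
  cat("  residue pairs accepted (targets):", length(x$residue_pairs), "\n")
  cat("  PPI edges accepted (targets):", nrow(x$ppi_edges), "\n")
  print(x$reports$residue_pair)
  print(x$reports$ppi)
  invisible(x)
}

#' Merge residue-pair datasets with combined FDR accounting
#'
#' Takes the union of several residue-pair sets, collapsing redundancy
#' by canonical residue pair (best score kept, dataset provenance
#' unioned), and re-estimates the combined PPI-level FDR from the pooled
#' TT/TD/DD edge counts of the merged set.
#'
#' @param sets List of \linkS4class{XLinkSet} objects (each should carry
#'   its decoy accounting, i.e. include TD/DD records).
#' @param aggregate Edge score aggregation for the combined PPI report.
#' @return List with \code{merged} (an \linkS4class{XLinkSet}) and
#'   \code{ppi_report} (an \code{FDRReport} over all pooled edges).
#' @export
mergeDatasets <- function(sets, aggregate = "sum") {
  stopifnot(length(sets) >= 1L)
  merged <- aggregateToResiduePairs(do.call(c, sets))
  edges <- buildPPIEdges(merged, aggregate = aggregate)
  rep <- estimateFdr(data.frame(score = edges$aggregate_score,
                                decoy_class = edges$decoy_class),
                     level = "ppi")
  list(merged = merged, ppi_report = rep)
}

#' Filter a crosslink PPI network by AP-MS enrichment
#'
#' An edge whose partners include non-core proteins is kept only when
#' every non-core partner is in the enriched set from the matching
#' crosslinked AP-MS experiment; edges between core subunits are always
#' kept.
#'
#' @param edges data.frame of PPI edges (see
#'   \code{\link{buildPPIEdges}}).
#' @param enriched Character vector of enriched accessions.
#' @param core Character vector of canonical core-subunit accessions.
#' @return The filtered edge data.frame.
#' @export
enrichmentFilterPPIs <- function(edges, enriched, core) {
  if (length(enriched) == 0L)
    warning("empty enriched set: only core-core edges survive")
  ok_part <- function(p) p %in% core | p %in% enriched
  keep <- ok_part(edges$protein_a) & ok_part(edges$protein_b)
  edges[keep, , drop = FALSE]
}
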