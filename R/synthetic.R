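## Seeded generators with known ground truth. The score model is a
## right-skewed Gumbel null (location 4, scale 1) for false targets and
## decoys and a shifted Gaussian N(9, 1.5^2) for true links: overlapping
## distributions with targets higher, chosen for realistic overlap only.

.rgumbel <- function(n, loc = 4, scale = 1) {
  loc - scale * log(-log(stats::runif(n)))
}

.randomDir <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Generate a toy multi-chain complex
#'
#' Each chain is a 3D self-avoiding random walk with exact consecutive
#' Calpha spacing of 3.8 Angstrom (no two non-consecutive residues
#' closer than 3.5 A). Chains after the first are seeded 8 A from a
#' randomly chosen placed residue, so every pair of chains shares an
#' interface (minimal inter-chain distance <= 10 A by construction).
#' Random sequences are emitted alongside; chain k is assigned accession
#' \code{PROTk} and author numbering 1..n.
#'
#' @param n_chains Number of chains (>= 1).
#' @param n_res_per_chain Residues per chain (>= 5).
#' @param seed Integer seed; output is bit-reproducible.
#' @return List with \code{structure} (\linkS4class{StructureModel}) and
#'   \code{sequences} (\link[Biostrings]{AAStringSet}).
#' @export
generateToyComplex <- function(n_chains = 2L, n_res_per_chain = 50L,
                               seed = 1L) {
  if (n_chains < 1L || n_res_per_chain < 5L)
    stop("need n_chains >= 1 and n_res_per_chain >= 5")
  set.seed(seed)
  step <- 3.8
  min_sep <- 3.5
  placed <- matrix(numeric(0), ncol = 3L)
  coords <- vector("list", n_chains)
  grow_chain <- function(start) {
    pts <- matrix(NA_real_, nrow = n_res_per_chain, ncol = 3L)
    pts[1L, ] <- start
    for (i in seq(2L, n_res_per_chain)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        cand <- pts[i - 1L, ] + step * .randomDir()
        prev <- pts[seq_len(i - 2L), , drop = FALSE]
        all_pts <- rbind(placed, prev)
        if (nrow(all_pts) == 0L ||
            min(sqrt(rowSums(sweep(all_pts, 2L, cand)^2))) >= min_sep) {
          pts[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) return(NULL)
    }
    pts
  }
  for (k in seq_len(n_chains)) {
    pts <- NULL
    for (attempt in seq_len(100L)) {
      start <- if (k == 1L) c(0, 0, 0) else {
        anchor <- placed[sample.int(nrow(placed), 1L), ]
        s <- NULL
        for (try in seq_len(500L)) {
          cand <- anchor + 8 * .randomDir()
          if (min(sqrt(rowSums(sweep(placed, 2L, cand)^2))) >= 4) {
            s <- cand
            break
          }
        }
        if (is.null(s)) next
        s
      }
      pts <- grow_chain(start)
      if (!is.null(pts)) break
    }
    if (is.null(pts))
      stop("could not place chain ", k, " with the requested geometry")
    coords[[k]] <- pts
    placed <- rbind(placed, pts)
  }
  aa <- Biostrings::AA_STANDARD
  chains <- LETTERS[seq_len(n_chains)]
  seqs <- vapply(seq_len(n_chains), function(k)
    paste(sample(aa, n_res_per_chain, replace = TRUE), collapse = ""),
    character(1))
  atoms <- do.call(rbind, lapply(seq_len(n_chains), function(k)
    data.frame(chain = chains[k], resno = seq_len(n_res_per_chain),
               code = strsplit(seqs[k], "")[[1]],
               x = coords[[k]][, 1], y = coords[[k]][, 2],
               z = coords[[k]][, 3], stringsAsFactors = FALSE)))
  accs <- paste0("PROT", seq_len(n_chains))
  sequences <- Biostrings::AAStringSet(stats::setNames(seqs, accs))
  list(structure = StructureModel(paste0("toy_seed", seed), atoms,
                                  stats::setNames(accs, chains)),
       sequences = sequences)
}

# per-residue crosslink chemistry eligibility on a structure
.chemistryEligibility <- function(structure, config) {
  a <- as.data.frame(structure@atoms)
  c2p <- chainProteins(structure)
  a$protein <- unname(c2p[a$chain])
  nterm <- stats::ave(a$resno, a$chain, FUN = min) == a$resno
  cterm <- stats::ave(a$resno, a$chain, FUN = max) == a$resno
  a$nhs <- a$code %in% config$nhs_residues | nterm
  a$diaz <- a$code %in% config$diazirine_residues | nterm | cterm
  a
}

# all eligible residue pairs with their Calpha distances
.eligiblePairs <- function(structure, config) {
  a <- .chemistryEligibility(structure, config)
  xyz <- cbind(a$x, a$y, a$z)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  elig <- (a$nhs[i] & a$diaz[j]) | (a$nhs[j] & a$diaz[i])
  same <- a$chain[i] == a$chain[j] & a$resno[i] == a$resno[j]
  keep <- elig & !same
  data.frame(protein_a = a$protein[i][keep], residue_a = a$resno[i][keep],
             protein_b = a$protein[j][keep], residue_b = a$resno[j][keep],
             distance = d[idx][keep], stringsAsFactors = FALSE)
}

.pairsToRecords <- function(pairs, scores, dataset_id, truth_label) {
  n <- nrow(pairs)
  data.frame(protein_a = pairs$protein_a, residue_a = pairs$residue_a,
             protein_b = pairs$protein_b, residue_b = pairs$residue_b,
             score = scores, dataset_id = rep(dataset_id, n),
             truth = rep(truth_label, n), stringsAsFactors = FALSE)
}

#' Simulate crosslinks on a structure under SDA chemistry
#'
#' True links are drawn uniformly from residue pairs with one
#' NHS-eligible and one diazirine-eligible side and Calpha-Calpha
#' distance at or below the threshold; false links from eligible pairs
#' strictly beyond threshold + 5 A (avoiding boundary ambiguity in the
#' truth labels). True scores come from the shifted Gaussian signal
#' model, false scores from the Gumbel null. Decoy records (TD/DD) are
#' generated by relabeling eligible pairs to decoy accessions, with null
#' scores.
#'
#' @param structure A \linkS4class{StructureModel} with chain-protein
#'   assignments.
#' @param n_true,n_false Numbers of true and false target links.
#' @param n_td,n_dd Numbers of target-decoy and decoy-decoy records.
#' @param config \code{\link{xlConfig}} (chemistry sets, threshold,
#'   decoy prefix).
#' @param threshold Generating distance threshold (default the
#'   crosslinker maximum from config).
#' @param seed Integer seed.
#' @param dataset_id Dataset label stamped on the records.
#' @return List with \code{xlinks} (an \linkS4class{XLinkSet}) and
#'   \code{truth} (true/false canonical pair keys, threshold, seed).
#' @export
simulateCrosslinks <- function(structure, n_true, n_false, n_td = 0L,
                               n_dd = 0L, config = xlConfig(),
                               threshold = config$sda_max_ca_distance,
                               seed = 1L, dataset_id = "sim") {
  set.seed(seed)
  pairs <- .eligiblePairs(structure, config)
  true_pool <- pairs[pairs$distance <= threshold, , drop = FALSE]
  false_pool <- pairs[pairs$distance > threshold + 5, , drop = FALSE]
  if (nrow(true_pool) < n_true)
    stop("only ", nrow(true_pool), " eligible pairs within ", threshold,
         " A; ", n_true, " requested")
  if (nrow(false_pool) < n_false + n_td + n_dd)
    stop("only ", nrow(false_pool), " eligible pairs beyond ",
         threshold + 5, " A; ", n_false + n_td + n_dd, " requested")
  ti <- sample.int(nrow(true_pool), n_true)
  fi <- sample.int(nrow(false_pool), n_false + n_td + n_dd)
  df <- rbind(
    .pairsToRecords(true_pool[ti, ], stats::rnorm(n_true, 9, 1.5),
                    dataset_id, "true"),
    .pairsToRecords(false_pool[fi[seq_len(n_false)], , drop = FALSE],
                    .rgumbel(n_false), dataset_id, "false"))
  if (n_td + n_dd > 0L) {
    dec <- false_pool[fi[n_false + seq_len(n_td + n_dd)], , drop = FALSE]
    is_dd <- seq_len(nrow(dec)) > n_td
    dec$protein_a <- paste0(config$decoy_prefix, dec$protein_a)
    dec$protein_b[is_dd] <- paste0(config$decoy_prefix,
                                   dec$protein_b[is_dd])
    df <- rbind(df, .pairsToRecords(dec, .rgumbel(nrow(dec)), dataset_id,
                                    "decoy"))
  }
  df <- df[, setdiff(colnames(df), "distance"), drop = FALSE]
  xl <- XLinkSet(df, config = config)
  rec <- as.data.frame(xl)
  keys <- .pairKey(rec)
  truth <- list(true_links = sort(keys[rec$truth == "true"]),
                false_links = sort(keys[rec$truth == "false"]),
                generating_threshold = threshold, seed = seed)
  xl@records$truth <- NULL
  list(xlinks = xl, truth = truth)
}

#' Rigidly displace one chain of a structure
#'
#' Utility for constructing alternative conformational states: the named
#' chain is translated by \code{delta} (default: reflected through the
#' centroid of an anchor chain, carrying it to the opposite face of the
#' complex).
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param chain Chain id to move.
#' @param delta Numeric translation (length 3), or \code{NULL} to use
#'   the reflection default.
#' @param anchor Anchor chain for the default displacement.
#' @param model_id Identifier of the new state.
#' @return A \linkS4class{StructureModel}.
#' @export
displaceChain <- function(structure, chain, delta = NULL,
                          anchor = chainIds(structure)[1L],
                          model_id = paste0(modelId(structure), "_alt")) {
  a <- as.data.frame(structure@atoms)
  sel <- a$chain == chain
  if (!any(sel)) stop("no such chain: ", chain)
  if (is.null(delta)) {
    can <- colMeans(a[a$chain == anchor, c("x", "y", "z")])
    cm <- colMeans(a[sel, c("x", "y", "z")])
    delta <- 2 * (can - cm)
  }
  a$x[sel] <- a$x[sel] + delta[1]
  a$y[sel] <- a$y[sel] + delta[2]
  a$z[sel] <- a$z[sel] + delta[3]
  StructureModel(model_id, a, chainProteins(structure))
}

#' Simulate crosslinks explained by different conformers
#'
#' Draws \code{n_shared} links satisfied on conformer A and
#' \code{n_exclusive} links that are satisfied only on conformer B
#' (below threshold on B, beyond threshold + 5 A on A), all under the
#' crosslinker chemistry. The exclusive links are the planted signature
#' of the alternative state.
#'
#' @param structA,structB Two conformers of the same assembly
#'   (identical chains and numbering).
#' @param n_shared,n_exclusive Link counts.
#' @param config \code{\link{xlConfig}}.
#' @param threshold Generating threshold.
#' @param seed Integer seed.
#' @return List with \code{xlinks}, and \code{truth} carrying the
#'   shared/exclusive canonical keys.
#' @export
simulateEnsembleCrosslinks <- function(structA, structB, n_shared = 90L,
                                       n_exclusive = 10L,
                                       config = xlConfig(),
                                       threshold =
                                         config$sda_max_ca_distance,
                                       seed = 1L) {
  set.seed(seed)
  pa <- .eligiblePairs(structA, config)
  pb <- .eligiblePairs(structB, config)
  key <- function(p) paste(p$protein_a, p$residue_a, p$protein_b,
                           p$residue_b)
  stopifnot(identical(key(pa), key(pb)))
  shared_pool <- which(pa$distance <= threshold)
  excl_pool <- which(pb$distance <= threshold &
                       pa$distance > threshold + 5)
  if (length(shared_pool) < n_shared)
    stop("only ", length(shared_pool), " conformer-A pairs available; ",
         n_shared, " requested")
  if (length(excl_pool) < n_exclusive)
    stop("only ", length(excl_pool), " B-exclusive pairs available; ",
         n_exclusive, " requested")
  si <- sample(shared_pool, n_shared)
  ei <- sample(excl_pool, n_exclusive)
  df <- rbind(
    .pairsToRecords(pa[si, ], stats::rnorm(n_shared, 9, 1.5), "ensemble",
                    "shared"),
    .pairsToRecords(pa[ei, ], stats::rnorm(n_exclusive, 9, 1.5),
                    "ensemble", "exclusive"))
  df <- df[, setdiff(colnames(df), "distance"), drop = FALSE]
  xl <- XLinkSet(df, config = config)
  rec <- as.data.frame(xl)
  keys <- .pairKey(rec)
  truth <- list(shared_links = sort(keys[rec$truth == "shared"]),
                exclusive_links = sort(keys[rec$truth == "exclusive"]),
                generating_threshold = threshold, seed = seed)
  xl@records$truth <- NULL
  list(xlinks = xl, truth = truth)
}

#' Simulate a label-free quantification matrix with planted enrichment
#'
#' Per-protein baselines are drawn from Normal(25, 2) on the log2 scale,
#' replicate noise from Normal(0, sd); the first \code{n_enriched}
#' proteins are shifted by \code{effect_log2} in the test group. MNAR
#' missingness removes the lowest-intensity quantile of cells; MAR
#' missingness strikes uniformly at random among the rest.
#'
#' @param n_proteins Number of proteins.
#' @param n_enriched Number of planted enriched proteins.
#' @param n_per_group Replicates per group (two groups, \code{"ctrl"}
#'   and \code{"test"}).
#' @param effect_log2 Planted log2 effect size.
#' @param sd Replicate noise SD (log2 units).
#' @param missing_mar_rate,missing_mnar_rate Missingness rates in
#'   [0, 1); their sum must stay below 1.
#' @param seed Integer seed.
#' @return List with \code{quant} (a log2-scale
#'   \linkS4class{QuantMatrix}) and \code{truth} (planted accessions).
#' @export
simulateQuantMatrix <- function(n_proteins = 2000L, n_enriched = 0L,
                                n_per_group = 3L, effect_log2 = 3,
                                sd = 0.5, missing_mar_rate = 0,
                                missing_mnar_rate = 0, seed = 1L) {
  if (missing_mar_rate + missing_mnar_rate >= 1)
    stop("missingness rates must sum below 1")
  if (n_per_group < 2L) stop("need >= 2 samples per group")
  set.seed(seed)
  n_samp <- 2L * n_per_group
  groups <- rep(c("ctrl", "test"), each = n_per_group)
  mu <- stats::rnorm(n_proteins, 25, 2)
  m <- matrix(stats::rnorm(n_proteins * n_samp, 0, sd),
              nrow = n_proteins) + mu
  planted <- seq_len(n_enriched)
  if (n_enriched > 0L)
    m[planted, groups == "test"] <- m[planted, groups == "test"] +
      effect_log2
  rownames(m) <- sprintf("PROT%04d", seq_len(n_proteins))
  colnames(m) <- paste0(groups, rep(seq_len(n_per_group), 2L))
  if (missing_mnar_rate > 0) {
    thr <- stats::quantile(m, missing_mnar_rate)
    m[m < thr] <- NA
  }
  if (missing_mar_rate > 0) {
    mar <- matrix(stats::runif(length(m)) < missing_mar_rate,
                  nrow = nrow(m))
    m[mar & !is.na(m)] <- NA
  }
  list(quant = quantMatrix(m, stats::setNames(groups, colnames(m)),
                           scale = "log2"),
       truth = list(planted_enriched = rownames(m)[planted],
                    effect_log2 = effect_log2, seed = seed))
}

#' Simulate a candidate-match score set for FDR calibration
#'
#' True target links are distributed over \code{n_true_pairs} distinct
#' true protein pairs (multi-link edges); every false target, TD and DD
#' record gets its own protein pair, the reversed-decoy convention
#' populating TD:DD in 2:1 expectation when the defaults are used so
#' that E[TD - DD] matches the planted false-target count at any
#' threshold. False targets and decoys share the Gumbel null score
#' distribution; true targets are drawn from the shifted signal. All
#' records carry passing fragment evidence unless \code{n_weak} rows
#' failing the evidence prefilter are requested.
#'
#' @param n_true_targets,n_false_targets True/false target link counts.
#' @param n_td,n_dd Decoy record counts (defaults 2x and 1x the false
#'   target count).
#' @param n_true_pairs Number of distinct true protein pairs.
#' @param n_weak Extra null-score records with sub-threshold fragment
#'   evidence.
#' @param config \code{\link{xlConfig}}.
#' @param seed Integer seed.
#' @return List with \code{candidates} (an \linkS4class{XLinkSet} with
#'   evidence columns) and \code{truth} (false target keys/pairs, true
#'   pairs).
#' @export
simulateCandidateScores <- function(n_true_targets = 3000L,
                                    n_false_targets = 300L,
                                    n_td = 2L * n_false_targets,
                                    n_dd = n_false_targets,
                                    n_true_pairs =
                                      ceiling(n_true_targets / 2),
                                    n_weak = 0L,
                                    config = xlConfig(), seed = 1L) {
  set.seed(seed)
  true_pair_id <- sample.int(n_true_pairs, n_true_targets, replace = TRUE)
  mk <- function(pa, pb, score, truth) {
    n <- length(pa)
    data.frame(protein_a = pa, protein_b = pb,
               residue_a = sample.int(400L, n, replace = TRUE),
               residue_b = sample.int(400L, n, replace = TRUE),
               score = score,
               dataset_id = rep("simscores", n),
               n_noncleaved_sda_fragments = 3L + stats::rpois(n, 2),
               n_matches_peptide_a = 5L + stats::rpois(n, 3),
               n_matches_peptide_b = 5L + stats::rpois(n, 3),
               truth = rep(truth, n), stringsAsFactors = FALSE)
  }
  df <- rbind(
    mk(sprintf("TPA%04d", true_pair_id), sprintf("TPB%04d", true_pair_id),
       stats::rnorm(n_true_targets, 9, 1.5), "true"),
    mk(sprintf("FPA%04d", seq_len(n_false_targets)),
       sprintf("FPB%04d", seq_len(n_false_targets)),
       .rgumbel(n_false_targets), "false"),
    mk(sprintf("%sDXA%04d", config$decoy_prefix, seq_len(n_td)),
       sprintf("TDB%04d", seq_len(n_td)), .rgumbel(n_td), "decoy"),
    mk(sprintf("%sDDA%04d", config$decoy_prefix, seq_len(n_dd)),
       sprintf("%sDDB%04d", config$decoy_prefix, seq_len(n_dd)),
       .rgumbel(n_dd), "decoy"))
  if (n_weak > 0L) {
    w <- mk(sprintf("WPA%04d", seq_len(n_weak)),
            sprintf("WPB%04d", seq_len(n_weak)), .rgumbel(n_weak), "weak")
    w$n_noncleaved_sda_fragments <- 2L
    df <- rbind(df, w)
  }
  # de-duplicate residue pairs within a protein pair
  df <- df[!duplicated(paste(df$protein_a, df$protein_b, df$residue_a,
                             df$residue_b)), , drop = FALSE]
  xl <- XLinkSet(df, config = config)
  rec <- as.data.frame(xl)
  keys <- .pairKey(rec)
  truth <- list(
    false_target_keys = sort(keys[rec$truth == "false"]),
    true_target_keys = sort(keys[rec$truth == "true"]),
    true_pairs = sort(unique(.ppiKey(rec[rec$truth == "true", ]))),
    false_pairs = sort(unique(.ppiKey(rec[rec$truth == "false", ]))),
    seed = seed)
  xl@records$truth <- NULL
  list(candidates = xl, truth = truth)
}
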