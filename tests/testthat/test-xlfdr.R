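mkCandidates <- function(nsda, ma, mb, score = 10) {
  XLinkSet(data.frame(
    protein_a = "P1", protein_b = "P2",
    residue_a = seq_along(nsda), residue_b = seq_along(nsda) + 100L,
    score = score, n_noncleaved_sda_fragments = nsda,
    n_matches_peptide_a = ma, n_matches_peptide_b = mb))
}

test_that("candidate prefilter applies both evidence thresholds strictly", {
  x <- mkCandidates(nsda = c(3L, 2L, 4L), ma = c(5L, 8L, 5L),
                    mb = c(6L, 8L, 4L))
  kept <- as.data.frame(prefilterCandidates(x))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$residue_a, 1L)
})

test_that("residue-pair aggregation keeps the best member per pair", {
  df <- data.frame(
    protein_a = c("A", "B", "A"), residue_a = c(10L, 20L, 5L),
    protein_b = c("B", "A", "A"), residue_b = c(20L, 10L, 9L),
    score = c(10, 12, 3), dataset_id = c("d1", "d2", "d1"))
  agg <- aggregateToResiduePairs(XLinkSet(df))
  rec <- as.data.frame(agg)
  expect_equal(length(agg), 2L)
  inter <- rec[rec$is_inter_protein, ]
  expect_equal(inter$score, 12)
  expect_equal(inter$dataset_id, "d1;d2")
  empty <- XLinkSet(df[0, ])
  expect_equal(length(aggregateToResiduePairs(empty)), 0L)
})

test_that("FDR estimator is (TD - DD)/TT with clamping", {
  mk <- function(n_tt, n_td, n_dd) {
    n <- n_tt + n_td + n_dd
    XLinkSet(data.frame(
      protein_a = c(rep("P1", n_tt), rep("REV_X", n_td + n_dd)),
      protein_b = c(rep("P2", n_tt + n_td), rep("REV_Y", n_dd)),
      residue_a = seq_len(n), residue_b = seq_len(n) + 1000L,
      score = 5))
  }
  expect_equal(estimateFdr(mk(100, 0, 0))$fdr_est, 0)
  r <- estimateFdr(mk(100, 4, 1))
  expect_equal(r$fdr_est, 0.03)
  expect_equal(unname(r$counts), c(100, 4, 1))
  expect_equal(estimateFdr(mk(10, 5, 6))$fdr_est, 0)
  expect_true(is.na(estimateFdr(mk(0, 3, 1))$fdr_est))
})

test_that("all-target input passes both levels with zero FDR", {
  sim <- simulateCandidateScores(n_true_targets = 60, n_false_targets = 0,
                                 n_td = 0, n_dd = 0, seed = 2)
  res <- hierarchicalFilter(sim$candidates)
  expect_equal(length(res$residue_pairs), length(sim$candidates))
  expect_equal(res$reports$residue_pair$fdr_est, 0)
  expect_equal(res$reports$ppi$fdr_est, 0)
})

test_that("PPI boosting never accepts fewer target PPIs", {
  for (seed in 1:5) {
    sim <- simulateCandidateScores(seed = seed)
    plain <- hierarchicalFilter(sim$candidates, boost = FALSE)
    boosted <- hierarchicalFilter(sim$candidates, boost = TRUE)
    expect_gte(nrow(boosted$ppi_edges), nrow(plain$ppi_edges))
  }
})

test_that("hierarchical acceptance grows as the residue-pair FDR loosens", {
  sim <- simulateCandidateScores(seed = 13)
  sizes <- sapply(c(0.005, 0.01, 0.02, 0.05), function(f)
    nrow(hierarchicalFilter(sim$candidates, rp_fdr = f)$ppi_edges))
  expect_true(all(diff(sizes) >= 0))
})

test_that("edge aggregation sums member scores and takes worst decoy class", {
  df <- data.frame(
    protein_a = c("A", "A", "A"), residue_a = c(1L, 2L, 3L),
    protein_b = c("B", "B", "REV_C"), residue_b = c(5L, 6L, 7L),
    score = c(2, 3, 4))
  e <- buildPPIEdges(XLinkSet(df))
  expect_equal(nrow(e), 2L)
  ab <- e[e$protein_b == "B", ]
  expect_equal(ab$aggregate_score, 5)
  expect_equal(ab$n_residue_pairs, 2L)
  expect_equal(e$decoy_class[e$protein_b == "REV_C"], "TD")
  # self links never become edges
  self <- XLinkSet(data.frame(protein_a = "A", protein_b = "A",
                              residue_a = 1L, residue_b = 9L, score = 1))
  expect_equal(nrow(buildPPIEdges(self)), 0L)
})

test_that("dataset merging is a union with best-score redundancy collapse", {
  mk <- function(res, ds) XLinkSet(data.frame(
    protein_a = "A", protein_b = "B", residue_a = res,
    residue_b = res + 50L, score = res, dataset_id = ds))
  a <- mk(1:3, "d1"); b <- mk(4:7, "d2")
  expect_equal(length(mergeDatasets(list(a, b))$merged), 7L)
  expect_equal(length(mergeDatasets(list(a, a))$merged), 3L)
  overlap <- mk(2:5, "d3")
  m <- mergeDatasets(list(a, overlap))$merged
  # brute-force union oracle on canonical keys
  keys_union <- union(crosslinkR:::.pairKey(as.data.frame(a)),
                      crosslinkR:::.pairKey(as.data.frame(overlap)))
  expect_equal(length(m), length(keys_union))
  expect_setequal(crosslinkR:::.pairKey(as.data.frame(m)), keys_union)
  # provenance of an overlapping pair is unioned
  rec <- as.data.frame(m)
  expect_equal(rec$dataset_id[rec$residue_a == 2], "d1;d3")
})

test_that("merging is associative and commutative", {
  set.seed(3)
  mk <- function(seed) simulateCandidateScores(
    n_true_targets = 30, n_false_targets = 5, n_td = 5, n_dd = 2,
    seed = seed)$candidates
  a <- mk(1); b <- mk(2); c3 <- mk(3)
  key <- function(x) sort(crosslinkR:::.pairKey(as.data.frame(x)))
  m1 <- mergeDatasets(list(mergeDatasets(list(a, b))$merged, c3))$merged
  m2 <- mergeDatasets(list(a, mergeDatasets(list(b, c3))$merged))$merged
  m3 <- mergeDatasets(list(c3, b, a))$merged
  expect_equal(key(m1), key(m2))
  expect_equal(key(m1), key(m3))
})

test_that("combined PPI FDR is recomputed from pooled decoy edge counts", {
  mk <- function(pa, pb) data.frame(
    protein_a = pa, protein_b = pb,
    residue_a = sample.int(100L, length(pa)),
    residue_b = sample.int(100L, length(pa)) + 200L, score = 5)
  set.seed(4)
  s1 <- XLinkSet(mk(c("A", "A", "REV_B"), c("B", "C", "D")))
  s2 <- XLinkSet(mk(c("E", "REV_F"), c("F", "REV_G")))
  rep <- mergeDatasets(list(s1, s2))$ppi_report
  # pooled edges: 3 TT, 1 TD (REV_B-D), 1 TD (REV_F-F... both decoys?)
  expect_equal(sum(rep$counts), 5)
  expect_equal(rep$fdr_est,
               max(0, rep$counts[["TD"]] - rep$counts[["DD"]]) /
                 rep$counts[["TT"]])
})

test_that("AP-MS filter keeps core-core edges and enriched partners only", {
  edges <- data.frame(
    protein_a = c("RPN2", "RPN2", "RPN1"),
    protein_b = c("TXNL1", "UNSEEN", "RPN2"),
    n_residue_pairs = 1L, aggregate_score = 1,
    decoy_class = "TT", datasets = "d")
  core <- c("RPN1", "RPN2")
  kept <- enrichmentFilterPPIs(edges, enriched = "TXNL1", core = core)
  expect_setequal(kept$protein_b, c("TXNL1", "RPN2"))
  expect_warning(
    kept0 <- enrichmentFilterPPIs(edges, character(), core), "core-core")
  expect_equal(kept0$protein_b, "RPN2")
})
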