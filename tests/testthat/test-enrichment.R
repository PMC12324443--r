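mkQuant <- function(m, groups, scale = "log2") {
  quantMatrix(m, groups, scale = scale)
}

test_that("completeness filter keeps proteins complete in any one group", {
  m <- rbind(P1 = c(5, 6, 7, NA, NA, NA),    # 3/3 in A, 0/3 in B
             P2 = c(5, 6, NA, 5, 6, NA),     # 2/3 in both
             P3 = c(5, 6, 7, 5, 6, 7))
  colnames(m) <- paste0("s", 1:6)
  g <- rep(c("A", "B"), each = 3)
  qm <- mkQuant(m, g)
  kept <- rownames(quantIntensities(filterByCompleteness(qm, 0.8)))
  expect_setequal(kept, c("P1", "P3"))
  all_kept <- filterByCompleteness(qm, 0)
  expect_equal(nrow(quantIntensities(all_kept)), 3L)
})

test_that("median normalization removes per-sample scale and is idempotent", {
  set.seed(1)
  base <- matrix(2^rnorm(60, 20, 1), nrow = 10)
  m <- cbind(base[, 1:3], base[, 1:3] * 4)
  colnames(m) <- paste0("s", 1:6)
  qm <- mkQuant(m, rep(c("A", "B"), each = 3), scale = "raw")
  norm <- quantIntensities(normalizeQuant(qm))
  expect_equal(norm[, 1:3], norm[, 4:6], ignore_attr = TRUE)
  centered <- mkQuant(norm, rep(c("A", "B"), each = 3))
  expect_equal(quantIntensities(normalizeQuant(centered)), norm)
})

test_that("glog shrinks the variance-mean dependence of additive noise", {
  set.seed(7)
  mu <- 2^runif(300, 6, 16)
  m <- matrix(rep(mu, 6), ncol = 6) +
    matrix(rnorm(1800, 0, 50), ncol = 6)
  m[m <= 0] <- NA
  colnames(m) <- paste0("s", 1:6)
  qm <- mkQuant(m, rep(c("A", "B"), each = 3), scale = "raw")
  slope <- function(x) {
    v <- apply(x, 1, var, na.rm = TRUE)
    mn <- rowMeans(x, na.rm = TRUE)
    unname(coef(lm(v ~ mn))[2])
  }
  s_log <- slope(suppressMessages(quantIntensities(normalizeQuant(qm))))
  s_glog <- slope(suppressMessages(
    quantIntensities(normalizeQuant(qm, method = "glog"))))
  expect_lt(abs(s_glog), abs(s_log))
})

test_that("MAR cells get exact group means; complete matrices pass through", {
  m <- rbind(P1 = c(5, 7, NA, 9, 9, 9),
             P2 = c(4, 5, 6, 7, 8, 9),
             P3 = c(6, 6, 7, 8, 8, 9))
  colnames(m) <- paste0("s", 1:6)
  qm <- mkQuant(m, rep(c("A", "B"), each = 3))
  imp <- quantIntensities(imputeMixed(qm, seed = 1))
  expect_identical(imp["P1", "s3"], 6.0)
  full <- mkQuant(matrix(1:12 + 0.5, 2, dimnames = list(c("a", "b"),
                                                        paste0("s", 1:6))),
                  rep(c("A", "B"), each = 3))
  expect_identical(quantIntensities(imputeMixed(full, seed = 1)),
                   quantIntensities(full))
})

test_that("MNAR draws follow the down-shifted per-sample Gaussian", {
  # sample s1: anchors standardized to mean 25, sd 1; 20000 MNAR rows
  n_mnar <- 20000L
  anchors <- rnorm(500)
  anchors <- 25 + (anchors - mean(anchors)) / sd(anchors)
  m <- rbind(
    cbind(anchors, anchors, 25, 25),
    cbind(NA, NA, matrix(25, n_mnar, 2)))
  rownames(m) <- sprintf("P%05d", seq_len(nrow(m)))
  colnames(m) <- c("s1", "s2", "s3", "s4")
  qm <- mkQuant(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  imp <- quantIntensities(imputeMixed(qm, downshift = 1.8, width = 0.3,
                                      seed = 3))
  draws <- imp[-seq_len(500), "s1"]
  se_mean <- 0.3 / sqrt(n_mnar)
  se_sd <- 0.3 / sqrt(2 * n_mnar)
  expect_lt(abs(mean(draws) - (25 - 1.8)), 3 * se_mean)
  expect_lt(abs(sd(draws) - 0.3), 3 * se_sd)
  # reproducible for a fixed seed
  imp2 <- quantIntensities(imputeMixed(qm, seed = 3))
  expect_identical(imp, imp2)
})

test_that("imputation refuses samples with undefined SD", {
  m <- rbind(P1 = c(5, NA, 4, 5), P2 = c(6, NA, 5, 6))
  colnames(m) <- paste0("s", 1:4)
  qm <- mkQuant(m, rep(c("A", "B"), each = 2))
  expect_error(imputeMixed(qm, seed = 1), "s2")
})

test_that("Welch statistics match the textbook formula", {
  m <- rbind(P1 = c(10, 11, 12, 1, 2, 3),
             P2 = c(5, 5, 5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:6)
  qm <- mkQuant(m, rep(c("T", "C"), each = 3))
  res <- welchTest(qm, "T", "C")
  # oracle: explicit Welch-Satterthwaite computation
  a <- c(10, 11, 12); b <- c(1, 2, 3)
  se2 <- var(a) / 3 + var(b) / 3
  t_exp <- (mean(a) - mean(b)) / sqrt(se2)
  df_exp <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_exp <- 2 * pt(-abs(t_exp), df_exp)
  expect_equal(res$t_stat[1], t_exp, tolerance = 1e-12)
  expect_equal(res$p[1], p_exp, tolerance = 1e-12)
  expect_equal(res$log2_fc[1], 9)
  # null identity for the constant protein
  expect_equal(res$t_stat[2], 0)
  expect_equal(res$p[2], 1)
  # antisymmetry under group swap
  swap <- welchTest(qm, "C", "T")
  expect_equal(swap$t_stat[1], -res$t_stat[1])
  expect_equal(swap$p[1], res$p[1])
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.03, 0.04)
  # oracle: min over k >= rank(i) of m * p(k) / k, capped at 1
  m <- length(p)
  sp <- sort(p)
  oracle <- sapply(seq_len(m), function(i)
    min(pmin(1, m * sp[i:m] / (i:m))))[rank(p)]
  expect_equal(bhAdjust(p), oracle)
  expect_equal(oracle, rep(0.04, 4))
  set.seed(11)
  ps <- runif(100)
  adj <- bhAdjust(ps)
  expect_true(all(diff(adj[order(ps)]) >= -1e-12))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("enrichment calls respect both thresholds with strict alpha", {
  res <- data.frame(accession = c("a", "b", "c"),
                    log2_fc = c(3, 3, 1.9),
                    p = c(0.001, 0.001, 0.001),
                    p_adj = c(0.01, 0.05, 0.001))
  out <- callEnriched(res, lfc_min = 2, alpha = 0.05)
  expect_equal(out$enriched, c(TRUE, FALSE, FALSE))
})
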