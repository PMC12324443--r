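test_that("toy complexes are reproducible with the stated geometry", {
  a <- generateToyComplex(2L, 50L, seed = 7L)
  b <- generateToyComplex(2L, 50L, seed = 7L)
  expect_identical(caCoords(a$structure), caCoords(b$structure))
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  # consecutive Calpha spacing 3.8 +/- 0.01 within each chain
  for (ch in chainIds(a$structure)) {
    xyz <- caCoords(a$structure, ch)
    steps <- sqrt(rowSums(diff(xyz)^2))
    expect_true(all(abs(steps - 3.8) <= 0.01))
  }
  # chains share an interface: minimal inter-chain distance <= 10 A
  xa <- caCoords(a$structure, "A")
  xb <- caCoords(a$structure, "B")
  dd <- outer(seq_len(nrow(xa)), seq_len(nrow(xb)), function(i, j)
    sqrt(rowSums((xa[i, , drop = FALSE] - xb[j, , drop = FALSE])^2)))
  expect_lte(min(dd), 10)
  # self-avoidance: no two non-consecutive residues closer than 3.5 A
  all_xyz <- caCoords(a$structure)
  d <- as.matrix(dist(all_xyz))
  diag(d) <- Inf
  for (i in seq_len(nrow(d) - 1L)) d[i, i + 1L] <- d[i + 1L, i] <- Inf
  expect_gte(min(d), 3.5 - 1e-9)
  expect_error(generateToyComplex(0L, 50L), "n_chains")
})

test_that("simulated crosslinks respect chemistry and distance truth", {
  tc <- toyComplex(3L, 40L, seed = 61L)
  cfg <- xlConfig()
  sim <- simulateCrosslinks(tc$structure, n_true = 30, n_false = 8,
                            n_td = 4, n_dd = 2, seed = 5)
  rec <- as.data.frame(sim$xlinks)
  keys <- paste(rec$protein_a, rec$residue_a, rec$protein_b,
                rec$residue_b, sep = "|")
  expect_length(sim$truth$true_links, 30L)
  expect_length(intersect(sim$truth$true_links, sim$truth$false_links), 0L)
  codes <- setNames(strsplit(paste(as.character(tc$sequences),
                                   collapse = ""), "")[[1]],
                    paste(rep(names(tc$sequences), each = 40),
                          rep(1:40, 3)))
  is_nhs <- function(p, r) codes[paste(p, r)] %in% cfg$nhs_residues | r == 1
  is_dia <- function(p, r) codes[paste(p, r)] %in%
    cfg$diazirine_residues | r %in% c(1, 40)
  for (k in which(keys %in% sim$truth$true_links)) {
    ok <- (is_nhs(rec$protein_a[k], rec$residue_a[k]) &
             is_dia(rec$protein_b[k], rec$residue_b[k])) |
      (is_nhs(rec$protein_b[k], rec$residue_b[k]) &
         is_dia(rec$protein_a[k], rec$residue_a[k]))
    expect_true(ok)
    d <- bruteMinDistance(tc$structure, rec$protein_a[k], rec$residue_a[k],
                          rec$protein_b[k], rec$residue_b[k])
    expect_lte(d, 27)
  }
  # false links sit strictly beyond threshold + 5 on the generator
  for (k in which(keys %in% sim$truth$false_links)) {
    d <- bruteMinDistance(tc$structure, rec$protein_a[k], rec$residue_a[k],
                          rec$protein_b[k], rec$residue_b[k])
    expect_gt(d, 32)
  }
  # a perfect 27 A filter on the generating structure has zero FDR
  meas <- measureCrosslinks(sim$xlinks, tc$structure,
                            sequences = tc$sequences)
  mk <- paste(meas$protein_a, meas$residue_a, meas$protein_b,
              meas$residue_b, sep = "|")
  accepted <- mk[meas$status == "satisfied"]
  expect_equal(mean(accepted %in% sim$truth$false_links), 0)
  # shortfall errors name the problem
  expect_error(simulateCrosslinks(tc$structure, n_true = 1e6, n_false = 0,
                                  seed = 1), "eligible pairs")
})

test_that("quant generator hits requested missingness and stays seeded", {
  s1 <- simulateQuantMatrix(500, 10, missing_mar_rate = 0.08,
                            missing_mnar_rate = 0.05, seed = 17)
  s2 <- simulateQuantMatrix(500, 10, missing_mar_rate = 0.08,
                            missing_mnar_rate = 0.05, seed = 17)
  m <- quantIntensities(s1$quant)
  expect_identical(m, quantIntensities(s2$quant))
  n <- length(m)
  # MNAR: exactly the lowest 5% quantile of cells; MAR adds ~8% of the rest
  frac <- mean(is.na(m))
  expected <- 0.05 + 0.08 * 0.95
  expect_lt(abs(frac - expected),
            2.576 * sqrt(expected * (1 - expected) / n) + 1 / n)
  expect_error(simulateQuantMatrix(10, 0, missing_mar_rate = 0.6,
                                   missing_mnar_rate = 0.5, seed = 1),
               "below 1")
})

test_that("candidate score sets are seeded with null-calibrated decoys", {
  a <- simulateCandidateScores(seed = 23)
  b <- simulateCandidateScores(seed = 23)
  expect_identical(as.data.frame(a$candidates), as.data.frame(b$candidates))
  rec <- as.data.frame(a$candidates)
  # default decoy structure follows the 2:1 TD:DD expectation
  expect_equal(sum(rec$decoy_class == "TD"),
               2L * sum(rec$decoy_class == "DD"))
  # no decoys and no false targets: FDR is identically zero
  clean <- simulateCandidateScores(n_true_targets = 50,
                                   n_false_targets = 0, n_td = 0,
                                   n_dd = 0, seed = 1)
  expect_equal(estimateFdr(clean$candidates, threshold = 0)$fdr_est, 0)
})

test_that("generated artifacts survive a disk round trip into their readers", {
  tc <- toyComplex(2L, 30L, seed = 71L)
  dir <- withr::local_tempdir()
  pdb <- file.path(dir, "toy.pdb")
  fa <- file.path(dir, "toy.fasta")
  tsv <- file.path(dir, "xl.tsv")
  writeStructurePDB(tc$structure, pdb)
  Biostrings::writeXStringSet(tc$sequences, fa)
  sim <- simulateCrosslinks(tc$structure, n_true = 10, n_false = 2,
                            seed = 2)
  writeCrosslinkTable(sim$xlinks, tsv)
  expect_no_warning(s <- readStructure(pdb))
  expect_no_warning(seqs <- readProteinFasta(fa))
  expect_no_warning(xl <- readCrosslinkTable(
    tsv, dialect = crosslinkR:::.internalDialect()))
  expect_equal(as.data.frame(xl), as.data.frame(sim$xlinks))
  expect_equal(names(seqs), names(tc$sequences))
  expect_equal(nrow(s@atoms), 60L)
})
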