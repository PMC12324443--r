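test_that("chain maps recover author-numbering offsets for subsequences", {
  tc <- toyComplex(1L, 60L, seed = 5L)
  full <- as.character(tc$sequences[["PROT1"]])
  # chain covering canonical residues 5..60, renumbered from 1
  sub <- substring(full, 5, 60)
  atoms <- as.data.frame(tc$structure@atoms)[5:60, ]
  atoms$resno <- seq_len(nrow(atoms))
  s <- StructureModel("frag", atoms, c(A = "PROT1"))
  maps <- buildChainMaps(tc$sequences, s)
  expect_length(maps, 1L)
  expect_equal(maps[[1]]$identity, 1.0)
  # canonical position p maps to author number p - 4
  expect_equal(unname(maps[[1]]$map[as.character(10)]), 6L)
  expect_equal(unname(maps[[1]]$map[as.character(5)]), 1L)
})

test_that("near-identical chains pass and unrelated chains are rejected", {
  tc <- toyComplex(1L, 100L, seed = 6L)
  atoms <- as.data.frame(tc$structure@atoms)
  atoms$code[50] <- setdiff(Biostrings::AA_STANDARD, atoms$code[50])[1]
  s1 <- StructureModel("mut", atoms, c(A = "PROT1"))
  maps <- buildChainMaps(tc$sequences, s1)
  expect_length(maps, 1L)
  expect_equal(maps[[1]]$identity, 0.99)
  # a random unrelated sequence aligns far below the identity cutoff
  set.seed(8)
  atoms$code <- sample(Biostrings::AA_STANDARD, 100, replace = TRUE)
  s2 <- StructureModel("rand", atoms, c(A = "PROT1"))
  expect_warning(maps2 <- buildChainMaps(tc$sequences, s2), "below")
  expect_length(maps2, 0L)
})

test_that("distances follow Euclid and minimize over chain copies", {
  s <- twoCopyStructure()
  maps <- buildChainMaps(twoCopySequences(), s)
  xl <- function(pa, ra, pb, rb) list(protein_a = pa, residue_a = ra,
                                      protein_b = pb, residue_b = rb)
  # PARTNER res1 at (0,22,0); DUP copy A res1 at origin -> 22; copy B at 40
  m <- measureCrosslink(xl("DUP", 1L, "PARTNER", 1L), s, maps)
  expect_equal(m$min_distance, 22)
  expect_equal(nrow(m$per_copy), 2L)
  expect_setequal(m$per_copy$distance, c(22, sqrt(40^2 + 22^2)))
  # 3-4-5 triangle on hand-placed coordinates
  tri <- StructureModel("tri", data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), code = "K",
    x = c(0, 3), y = c(0, 4), z = 0), c(A = "PX", B = "PY"))
  tm <- buildChainMaps(Biostrings::AAStringSet(c(PX = "K", PY = "K")), tri)
  expect_equal(measureCrosslink(xl("PX", 1L, "PY", 1L), tri,
                                tm)$min_distance, 5)
  # self link on the duplicated protein: min over intra- and inter-copy
  sm <- measureCrosslink(xl("DUP", 1L, "DUP", 3L), s, maps)
  expect_equal(sm$min_distance, 7.6)   # intra-chain beats the 40 A copy gap
  # unmapped residue
  um <- measureCrosslink(xl("DUP", 99L, "PARTNER", 1L), s, maps)
  expect_equal(um$status, "unmapped")
  expect_true(is.na(um$min_distance))
})

test_that("measurement is symmetric in the two endpoints", {
  s <- twoCopyStructure()
  maps <- buildChainMaps(twoCopySequences(), s)
  a <- measureCrosslink(list(protein_a = "DUP", residue_a = 2L,
                             protein_b = "PARTNER", residue_b = 3L),
                        s, maps)
  b <- measureCrosslink(list(protein_a = "PARTNER", residue_a = 3L,
                             protein_b = "DUP", residue_b = 2L),
                        s, maps)
  expect_equal(a$min_distance, b$min_distance)
})

test_that("classification uses the inclusive threshold and band edges", {
  expect_equal(classifyDistance(26.9, 27), "satisfied")
  expect_equal(classifyDistance(27.0, 27), "satisfied")
  expect_equal(classifyDistance(27.0001, 27), "violated")
  expect_equal(distanceBand(c(10, 21.5, 25, 28.5, 30)),
               c("short", "mid", "mid", "mid", "long"))
})

test_that("module distances equal brute force on seeded toy complexes", {
  for (seed in 1:10) {
    tc <- toyComplex(2L + seed %% 3L, 30L, seed = 100L + seed)
    sim <- simulateCrosslinks(tc$structure, n_true = 4, n_false = 2,
                              seed = seed)
    maps <- buildChainMaps(tc$sequences, tc$structure)
    rec <- as.data.frame(sim$xlinks)
    for (i in seq_len(nrow(rec))) {
      m <- measureCrosslink(rec[i, ], tc$structure, maps)
      expect_equal(m$min_distance,
                   bruteMinDistance(tc$structure, rec$protein_a[i],
                                    rec$residue_a[i], rec$protein_b[i],
                                    rec$residue_b[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("links simulated under the threshold are all satisfied on origin", {
  tc <- toyComplex(3L, 40L, seed = 21L)
  sim <- simulateCrosslinks(tc$structure, n_true = 40, n_false = 0,
                            seed = 2)
  meas <- measureCrosslinks(sim$xlinks, tc$structure,
                            sequences = tc$sequences)
  expect_true(all(meas$status == "satisfied"))
})

test_that("ensemble satisfaction is order-invariant and monotone", {
  tc <- toyComplex(3L, 40L, seed = 31L)
  A <- tc$structure
  B <- displaceChain(A, "C", model_id = "B")
  sim <- simulateEnsembleCrosslinks(A, B, n_shared = 20, n_exclusive = 5,
                                    seed = 9)
  rA <- ensembleSatisfaction(sim$xlinks, list(A), tc$sequences)
  rAB <- ensembleSatisfaction(sim$xlinks, list(A, B), tc$sequences)
  rBA <- ensembleSatisfaction(sim$xlinks, list(B, A), tc$sequences)
  expect_equal(ensembleSummary(rA), 0.8)        # 20 of 25
  expect_equal(ensembleSummary(rAB), 1.0)
  expect_equal(ensembleSummary(rAB), ensembleSummary(rBA))
  expect_gte(ensembleSummary(rAB), ensembleSummary(rA))
  # per-link verdicts: exclusive links need B
  lv <- linkVerdicts(rAB)
  keys <- paste(lv$protein_a, lv$residue_a, lv$protein_b, lv$residue_b,
                sep = "|")
  excl <- keys %in% sim$truth$exclusive_links
  expect_true(all(lv$best_structure[excl] == "B"))
})

test_that("violation clusters follow the shared-pair window rule", {
  mk <- function(pa, ra, pb, rb, status = "violated")
    data.frame(protein_a = pa, residue_a = ra, protein_b = pb,
               residue_b = rb, status = status)
  meas <- rbind(mk("X", 10L, "Y", 200L), mk("X", 12L, "Y", 205L),
                mk("X", 15L, "Y", 198L))
  cl <- detectViolationClusters(meas, window = 10L, min_size = 3L)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 3L)
  # distant third link drops out; min_size 2 keeps the close pair
  meas2 <- rbind(meas[1:2, ], mk("X", 90L, "Y", 400L))
  expect_length(detectViolationClusters(meas2, 10L, 3L), 0L)
  cl2 <- detectViolationClusters(meas2, 10L, 2L)
  expect_length(cl2, 1L)
  expect_equal(cl2[[1]]$size, 2L)
  # violations scattered over distinct protein pairs never cluster
  meas3 <- do.call(rbind, lapply(1:5, function(i)
    mk(paste0("A", i), 10L, paste0("B", i), 20L)))
  expect_length(detectViolationClusters(meas3, 10L, 2L), 0L)
})
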