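# Shared fixtures, built in code. The toy complex is cached per session.

.fixture_env <- new.env(parent = emptyenv())

toyComplex <- function(n_chains = 3L, n_res = 40L, seed = 42L) {
  key <- paste("toy", n_chains, n_res, seed, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generateToyComplex(n_chains, n_res, seed = seed)
  .fixture_env[[key]]
}

# independent brute-force minimal Calpha-Calpha distance: enumerates all
# residue placements directly from the atom table, bypassing the
# alignment-based mapping machinery
bruteMinDistance <- function(structure, protein_a, residue_a,
                             protein_b, residue_b) {
  at <- as.data.frame(structure@atoms)
  c2p <- chainProteins(structure)
  at$protein <- unname(c2p[at$chain])
  ra <- at[at$protein == protein_a & at$resno == residue_a, , drop = FALSE]
  rb <- at[at$protein == protein_b & at$resno == residue_b, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(rb))) {
      if (ra$chain[i] == rb$chain[j] && ra$resno[i] == rb$resno[j]) next
      d <- sqrt((ra$x[i] - rb$x[j])^2 + (ra$y[i] - rb$y[j])^2 +
                  (ra$z[i] - rb$z[j])^2)
      if (d < best) best <- d
    }
  }
  if (is.infinite(best)) NA_real_ else best
}

# structure with two copies of one protein plus a partner, at controlled
# coordinates: used for min-over-copies and self-link tests
twoCopyStructure <- function() {
  atoms <- data.frame(
    chain = c(rep("A", 3), rep("B", 3), rep("C", 3)),
    resno = rep(1:3, 3),
    code = rep(c("K", "A", "S"), 3),
    x = c(0, 3.8, 7.6,   40, 43.8, 47.6,   0, 3.8, 7.6),
    y = c(0, 0, 0,        0, 0, 0,        22, 22, 22),
    z = 0, stringsAsFactors = FALSE)
  StructureModel("twocopy", atoms,
                 c(A = "DUP", B = "DUP", C = "PARTNER"))
}

twoCopySequences <- function() {
  Biostrings::AAStringSet(c(DUP = "KAS", PARTNER = "KAS"))
}
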