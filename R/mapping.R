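#' Align canonical sequences to structure chains
#'
#' For every chain with a protein assignment, the chain's observed
#' one-letter sequence is globally aligned to the canonical full-length
#' sequence (Needleman-Wunsch via Biostrings, chain global / canonical
#' local, so a construct covering part of the canonical sequence maps
#' with its offset recovered). The resulting map sends 1-based canonical
#' positions to author residue numbers. Maps whose aligned-position
#' identity falls below \code{min_identity} are discarded with a
#' warning; author numbering offsets are never assumed.
#'
#' @param sequences \link[Biostrings]{AAStringSet} of canonical
#'   sequences named by accession.
#' @param structure A \linkS4class{StructureModel} with chain-to-protein
#'   assignments.
#' @param min_identity Minimum fractional identity over aligned
#'   positions (0.95).
#' @return List of chain maps; each is a list with \code{accession},
#'   \code{chain_id}, \code{map} (named integer: canonical position ->
#'   author number) and \code{identity}.
#' @export
buildChainMaps <- function(sequences, structure, min_identity = 0.95) {
  c2p <- chainProteins(structure)
  maps <- list()
  for (chain in names(c2p)) {
    acc <- c2p[[chain]]
    if (!acc %in% names(sequences)) {
      message("no sequence for accession ", acc, "; chain ", chain,
              " skipped")
      next
    }
    obs <- .chainSequence(structure, chain)
    if (nchar(obs$codes) == 0L) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(obs$codes),
      subject = sequences[[acc]],
      type = "global-local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    sub_start <- Biostrings::start(Biostrings::subject(aln))
    pi <- 0L
    si <- sub_start - 1L
    seq_pos <- integer(0)
    auth_no <- integer(0)
    n_ident <- 0L
    n_alncol <- 0L
    for (k in seq_along(pat)) {
      if (pat[k] != "-") pi <- pi + 1L
      if (sub[k] != "-") si <- si + 1L
      if (pat[k] != "-" && sub[k] != "-") {
        n_alncol <- n_alncol + 1L
        if (pat[k] == sub[k]) n_ident <- n_ident + 1L
        seq_pos <- c(seq_pos, si)
        auth_no <- c(auth_no, obs$resno[pi])
      }
    }
    identity <- if (n_alncol > 0L) n_ident / n_alncol else 0
    if (identity < min_identity) {
      warning("chain ", chain, " vs ", acc, ": identity ",
              round(identity, 3), " below ", min_identity,
              "; map discarded")
      next
    }
    maps[[length(maps) + 1L]] <- list(accession = acc, chain_id = chain,
                                      map = stats::setNames(auth_no,
                                                            seq_pos),
                                      identity = identity)
  }
  maps
}

# author residue number for a canonical position, or NA
.mapResidue <- function(map, pos) {
  v <- map$map[as.character(pos)]
  if (length(v) == 0L) NA_integer_ else unname(v)
}

#' Measure one crosslink on a structure
#'
#' Computes the Euclidean Calpha-Calpha distance for every chain-copy
#' combination resolving both endpoints and takes the minimum (a
#' crosslink evidences proximity somewhere in the particle). Self links
#' on a multi-copy protein are evaluated over both intra-chain and
#' inter-copy placements. A crosslink is unmapped when no combination
#' resolves both residues.
#'
#' @param crosslink One-row data.frame (or list) with \code{protein_a},
#'   \code{residue_a}, \code{protein_b}, \code{residue_b}.
#' @param structure A \linkS4class{StructureModel}.
#' @param maps Chain maps from \code{\link{buildChainMaps}}.
#' @return List with \code{per_copy} (data.frame of chain_a, chain_b,
#'   resno_a, resno_b, distance), \code{min_distance} (\code{NA} when
#'   unmapped), \code{status} (\code{"mapped"} or \code{"unmapped"}) and
#'   the best combination's chains/author numbers.
#' @export
measureCrosslink <- function(crosslink, structure, maps) {
  acc <- vapply(maps, `[[`, character(1), "accession")
  ma <- maps[acc == crosslink$protein_a]
  mb <- maps[acc == crosslink$protein_b]
  per <- list()
  for (A in ma) {
    ra <- .mapResidue(A, crosslink$residue_a)
    if (is.na(ra)) next
    ca <- caCoords(structure, A$chain_id)
    pa <- ca[as.character(ra), ]
    for (B in mb) {
      rb <- .mapResidue(B, crosslink$residue_b)
      if (is.na(rb)) next
      if (A$chain_id == B$chain_id && ra == rb) next
      cb <- caCoords(structure, B$chain_id)
      pb <- cb[as.character(rb), ]
      per[[length(per) + 1L]] <- data.frame(
        chain_a = A$chain_id, chain_b = B$chain_id,
        resno_a = ra, resno_b = rb,
        distance = sqrt(sum((pa - pb)^2)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(per) == 0L)
    return(list(per_copy = data.frame(), min_distance = NA_real_,
                status = "unmapped", chain_a = NA_character_,
                chain_b = NA_character_, resno_a = NA_integer_,
                resno_b = NA_integer_))
  per <- do.call(rbind, per)
  i <- which.min(per$distance)
  list(per_copy = per, min_distance = per$distance[i], status = "mapped",
       chain_a = per$chain_a[i], chain_b = per$chain_b[i],
       resno_a = per$resno_a[i], resno_b = per$resno_b[i])
}

#' Measure a set of crosslinks on one structure
#'
#' @param x An \linkS4class{XLinkSet}.
#' @param structure A \linkS4class{StructureModel}.
#' @param maps Chain maps (built on demand when \code{NULL}).
#' @param sequences Needed to build maps when \code{maps} is
#'   \code{NULL}.
#' @param config \code{\link{xlConfig}} (identity cutoff, distance
#'   threshold for the status column).
#' @return data.frame, one row per crosslink: endpoints, the minimal
#'   distance, the chains/author numbers realizing it, and \code{status}
#'   (\code{satisfied}/\code{violated}/\code{unmapped}).
#' @export
measureCrosslinks <- function(x, structure, maps = NULL, sequences = NULL,
                              config = xlConfig()) {
  if (is.null(maps)) {
    if (is.null(sequences))
      stop("either maps or sequences must be given")
    maps <- buildChainMaps(sequences, structure, config$min_identity)
  }
  df <- as.data.frame(x)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    m <- measureCrosslink(df[i, ], structure, maps)
    data.frame(protein_a = df$protein_a[i], residue_a = df$residue_a[i],
               protein_b = df$protein_b[i], residue_b = df$residue_b[i],
               structure_id = modelId(structure),
               chain_a = m$chain_a, chain_b = m$chain_b,
               resno_a = m$resno_a, resno_b = m$resno_b,
               min_distance = m$min_distance,
               n_copies = nrow(m$per_copy),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$status <- ifelse(is.na(out$min_distance), "unmapped",
                       classifyDistance(out$min_distance,
                                        config$sda_max_ca_distance))
  out
}

#' Classify a crosslink distance against the crosslinker threshold
#'
#' Satisfied at or below the threshold (the inclusive convention of the
#' pseudobond coloring; configurable).
#'
#' @param distance Numeric distances in Angstrom.
#' @param threshold Distance threshold (27 for SDA).
#' @return Character vector: \code{"satisfied"} or \code{"violated"}.
#' @export
classifyDistance <- function(distance, threshold = 27) {
  ifelse(distance <= threshold, "satisfied", "violated")
}

#' Assign distances to short/mid/long bands
#'
#' Three classes split at the band edges; the middle band includes both
#' edges (a 21.5 A distance is mid, as is 28.5 A).
#'
#' @param distance Numeric distances in Angstrom.
#' @param edges Increasing pair of band edges, default
#'   \code{c(21.5, 28.5)}.
#' @return Character vector: \code{"short"}, \code{"mid"} or
#'   \code{"long"}.
#' @export
distanceBand <- function(distance, edges = c(21.5, 28.5)) {
  ifelse(distance < edges[1], "short",
         ifelse(distance <= edges[2], "mid", "long"))
}

#' Evaluate crosslink satisfaction across a structural ensemble
#'
#' Measures every crosslink on every ensemble member, records whether
#' each is satisfied in at least one state, and summarizes the fraction
#' of mappable crosslinks satisfied anywhere (\code{NA} when nothing
#' maps). Per-structure mapped/satisfied counts are tabulated for
#' ensemble bar plots.
#'
#' @param x An \linkS4class{XLinkSet}.
#' @param structures List of \linkS4class{StructureModel} objects.
#' @param sequences \link[Biostrings]{AAStringSet} of canonical
#'   sequences.
#' @param config \code{\link{xlConfig}}.
#' @return An \linkS4class{EnsembleReport}.
#' @export
ensembleSatisfaction <- function(x, structures, sequences,
                                 config = xlConfig()) {
  stopifnot(length(structures) >= 1L)
  meas <- lapply(structures, function(s)
    measureCrosslinks(x, s, sequences = sequences, config = config))
  all_meas <- do.call(rbind, meas)
  n <- length(x)
  sat <- sapply(meas, function(m) m$status == "satisfied")
  sat <- matrix(sat, nrow = n)
  mapped <- sapply(meas, function(m) m$status != "unmapped")
  mapped <- matrix(mapped, nrow = n)
  dmat <- sapply(meas, function(m) m$min_distance)
  dmat <- matrix(dmat, nrow = n)
  ids <- vapply(structures, modelId, character(1))
  best <- apply(dmat, 1L, function(d)
    if (all(is.na(d))) NA_integer_ else which.min(d))
  links <- DataFrame(
    as.data.frame(x)[, c("protein_a", "residue_a", "protein_b",
                         "residue_b")],
    mappable = rowSums(mapped) > 0L,
    satisfied_any = rowSums(sat) > 0L,
    best_structure = ifelse(is.na(best), NA_character_, ids[best]),
    best_distance = ifelse(is.na(best), NA_real_,
                           dmat[cbind(seq_len(n), best)]))
  per_structure <- DataFrame(structure_id = ids,
                             n_mapped = colSums(mapped),
                             n_satisfied = colSums(sat))
  n_map <- sum(links$mappable)
  summ <- if (n_map == 0L) NA_real_ else
    sum(links$satisfied_any & links$mappable) / n_map
  if (n_map == 0L) warning("no mappable crosslinks; summary undefined")
  new("EnsembleReport", measurements = DataFrame(all_meas),
      links = links, perStructure = per_structure, summary = summ)
}

#' Accessors for EnsembleReport
#'
#' @param x An \linkS4class{EnsembleReport}.
#' @return \code{ensembleSummary}: fraction of mappable crosslinks
#'   satisfied in at least one state; \code{linkVerdicts}: per-crosslink
#'   table; \code{measurements}: per-(crosslink, structure) table.
#' @name EnsembleReport-accessors
#' @aliases ensembleSummary linkVerdicts measurements
#'   ensembleSummary,EnsembleReport-method
#'   linkVerdicts,EnsembleReport-method measurements,EnsembleReport-method
#' @export
setMethod("ensembleSummary", "EnsembleReport", function(x) x@summary)

#' @rdname EnsembleReport-accessors
#' @export
setMethod("linkVerdicts", "EnsembleReport", function(x) x@links)

#' @rdname EnsembleReport-accessors
#' @export
setMethod("measurements", "EnsembleReport", function(x) x@measurements)

setMethod("show", "EnsembleReport", function(object) {
  cat("EnsembleReport:", nrow(object@links), "crosslink(s) on",
      nrow(object@perStructure), "structure(s)\n")
  cat("  satisfied in >= 1 state:",
      sum(object@links$satisfied_any), "/", sum(object@links$mappable),
      "mappable (summary ",
      if (is.na(object@summary)) "undefined"
      else sprintf("%.1f%%", 100 * object@summary), ")\n", sep = " ")
})

#' Per-structure satisfaction counts
#'
#' @param x An \linkS4class{EnsembleReport}.
#' @return DataFrame of mapped and satisfied counts per structure.
#' @export
perStructureCounts <- function(x) x@perStructure

#' Detect clusters of overlength (violated) crosslinks
#'
#' Violated crosslinks sharing the same unordered protein pair are
#' linked when both endpoint positions lie within \code{window} residues
#' of each other on their respective proteins; connected components of
#' at least \code{min_size} are reported, largest first. Co-located
#' violations between one protein pair indicate an unmodeled
#' conformational state.
#'
#' @param meas Measurement data.frame for one structure (from
#'   \code{\link{measureCrosslinks}}).
#' @param window Residue window on each protein (10).
#' @param min_size Minimum cluster size (3).
#' @return List of clusters; each is a list with \code{protein_a},
#'   \code{protein_b}, \code{members} (row indices into \code{meas}),
#'   \code{size}, and the sequence span on each protein.
#' @export
detectViolationClusters <- function(meas, window = 10L, min_size = 3L) {
  v <- which(meas$status == "violated")
  if (length(v) < min_size) return(list())
  sub <- meas[v, , drop = FALSE]
  pairkey <- paste(sub$protein_a, sub$protein_b, sep = "|")
  edges <- integer(0)
  for (grp in split(seq_along(v), pairkey)) {
    if (length(grp) < 2L) next
    for (i in seq_along(grp)[-length(grp)]) {
      for (j in seq((i + 1L), length(grp))) {
        a <- grp[i]; b <- grp[j]
        if (abs(sub$residue_a[a] - sub$residue_a[b]) <= window &&
            abs(sub$residue_b[a] - sub$residue_b[b]) <= window)
          edges <- c(edges, a, b)
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(v), directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_size)
  if (length(keep) == 0L) return(list())
  clusters <- lapply(keep, function(ci) {
    idx <- which(comp$membership == ci)
    list(protein_a = sub$protein_a[idx[1L]],
         protein_b = sub$protein_b[idx[1L]],
         members = v[idx],
         size = length(idx),
         span_a = range(sub$residue_a[idx]),
         span_b = range(sub$residue_b[idx]))
  })
  clusters[order(vapply(clusters, `[[`, numeric(1), "size"),
                 decreasing = TRUE)]
}
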