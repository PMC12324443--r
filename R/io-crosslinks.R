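#' Default column dialect for crosslink residue-pair tables
#'
#' Maps internal field names to the column names of the export being
#' read (the default follows xiFDR-style residue-pair exports). Override
#' entries to adapt to other layouts; set an entry to \code{NA} to mark
#' a field absent.
#'
#' @param ... Name-value overrides, e.g. \code{protein_a = "Protein1"}.
#' @export
xlDialect <- function(...) {
  d <- list(protein_a = "Protein1", protein_b = "Protein2",
            residue_a = "fromSite", residue_b = "ToSite",
            score = "Score", dataset_id = "run",
            n_noncleaved_sda_fragments = "nNonCleavedSDAFragments",
            n_matches_peptide_a = "nMatchesPeptide1",
            n_matches_peptide_b = "nMatchesPeptide2")
  ov <- list(...)
  d[names(ov)] <- ov
  d
}

#' Read a crosslink residue-pair / candidate-match table
#'
#' Reads a CSV/TSV export into an \linkS4class{XLinkSet}, deriving the
#' decoy class from the configured accession prefix and canonicalizing
#' endpoint order. Evidence columns (non-cleaved SDA fragment counts,
#' per-peptide match counts), when present under their dialect names,
#' are carried along for candidate prefiltering.
#'
#' @param path CSV or TSV file (separator chosen by extension, or by
#'   \code{sep}).
#' @param config \code{\link{xlConfig}} (decoy prefix).
#' @param dialect Column map from \code{\link{xlDialect}}.
#' @param sep Field separator; default guesses "," for .csv else tab.
#' @return An \linkS4class{XLinkSet}.
#' @export
readCrosslinkTable <- function(path, config = xlConfig(),
                               dialect = xlDialect(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  need <- c("protein_a", "protein_b", "residue_a", "residue_b", "score")
  for (f in need) {
    col <- dialect[[f]]
    if (is.null(col) || is.na(col) || !col %in% colnames(raw))
      stop("required column missing from ", path, ": ", f,
           " (expected header '", col, "')")
  }
  pick <- function(f) raw[[dialect[[f]]]]
  df <- data.frame(protein_a = as.character(pick("protein_a")),
                   protein_b = as.character(pick("protein_b")),
                   stringsAsFactors = FALSE)
  for (f in c("residue_a", "residue_b")) {
    v <- pick(f)
    iv <- suppressWarnings(as.integer(v))
    bad <- which(is.na(iv) & !is.na(v))
    if (length(bad) > 0L)
      stop("non-integer residue position in row ", bad[1L], " of ", path,
           " (column ", dialect[[f]], ", value '", v[bad[1L]], "')")
    df[[f]] <- iv
  }
  df$score <- as.numeric(pick("score"))
  ds <- dialect[["dataset_id"]]
  df$dataset_id <- if (!is.null(ds) && !is.na(ds) && ds %in% colnames(raw))
    as.character(raw[[ds]]) else "default"
  for (f in c("n_noncleaved_sda_fragments", "n_matches_peptide_a",
              "n_matches_peptide_b")) {
    col <- dialect[[f]]
    if (!is.null(col) && !is.na(col) && col %in% colnames(raw))
      df[[f]] <- as.integer(raw[[col]])
  }
  XLinkSet(df, config = config)
}

#' Write a crosslink table
#'
#' Writes the canonical record set as TSV; reading it back with the
#' default internal dialect reproduces the set exactly.
#'
#' @param x An \linkS4class{XLinkSet}.
#' @param path Output TSV path.
#' @export
writeCrosslinkTable <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal dialect matching writeCrosslinkTable output
.internalDialect <- function() {
  xlDialect(protein_a = "protein_a", protein_b = "protein_b",
            residue_a = "residue_a", residue_b = "residue_b",
            score = "score", dataset_id = "dataset_id",
            n_noncleaved_sda_fragments = "n_noncleaved_sda_fragments",
            n_matches_peptide_a = "n_matches_peptide_a",
            n_matches_peptide_b = "n_matches_peptide_b")
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @param config \code{\link{xlConfig}}; used to flag decoy accessions
#'   and canonical core subunits.
#' @return An \link[Biostrings]{AAStringSet} with per-sequence metadata
#'   columns \code{is_decoy} and \code{core_subunit}.
#' @export
readProteinFasta <- function(path, config = xlConfig()) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  S4Vectors::mcols(seqs) <- DataFrame(
    is_decoy = startsWith(names(seqs), config$decoy_prefix),
    core_subunit = names(seqs) %in% config$core_subunits)
  seqs
}

#' Write a PPI edge list as TSV
#'
#' @param edges data.frame of PPI edges (see
#'   \code{\link{buildPPIEdges}}).
#' @param path Output path.
#' @export
writePPIEdges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
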