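#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

#' XLinkSet: a set of crosslinked residue pairs
#'
#' Container for crosslink residue-pair records (and, optionally,
#' candidate spectrum matches carrying fragment-evidence columns).
#' Each record joins two (protein, 1-based residue) endpoints with a
#' match score, a target-decoy class and a dataset of origin.
#' Endpoints are stored in canonical order (lexicographic by accession,
#' then residue) so that (A,10)-(B,20) and (B,20)-(A,10) are the same
#' record.
#'
#' @slot records A \link[S4Vectors]{DataFrame} with columns
#'   \code{protein_a}, \code{protein_b}, \code{residue_a},
#'   \code{residue_b}, \code{score}, \code{decoy_class} (one of
#'   \code{"TT"}, \code{"TD"}, \code{"DD"}), \code{dataset_id},
#'   \code{is_inter_protein}. Candidate matches additionally carry
#'   \code{n_noncleaved_sda_fragments}, \code{n_matches_peptide_a},
#'   \code{n_matches_peptide_b}.
#' @exportClass XLinkSet
setClass("XLinkSet", representation(records = "DataFrame"))

.xlink_required_cols <- c("protein_a", "protein_b", "residue_a", "residue_b",
                          "score", "decoy_class", "dataset_id",
                          "is_inter_protein")

setValidity("XLinkSet", function(object) {
  df <- object@records
  miss <- setdiff(.xlink_required_cols, colnames(df))
  if (length(miss) > 0L)
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (!all(df$decoy_class %in% c("TT", "TD", "DD")))
    return("decoy_class must be one of TT, TD, DD")
  if (any(df$residue_a < 1L) || any(df$residue_b < 1L))
    return("residue positions must be >= 1")
  swap <- df$protein_a > df$protein_b |
    (df$protein_a == df$protein_b & df$residue_a > df$residue_b)
  if (any(swap))
    return("records are not in canonical endpoint order")
  if (!identical(df$is_inter_protein, df$protein_a != df$protein_b))
    return("is_inter_protein inconsistent with accessions")
  TRUE
})

#' StructureModel: Calpha trace of a (multi-chain) structure
#'
#' One structural state: per-chain ordered residues with author numbering,
#' one-letter residue codes and Calpha coordinates in Angstrom, plus the
#' assignment of chains to protein accessions (several chains may map to
#' one accession: copies in the assembly).
#'
#' @slot model_id Identifier, e.g. a PDB ID.
#' @slot atoms \link[S4Vectors]{DataFrame} with columns \code{chain},
#'   \code{resno} (author residue number), \code{code} (one-letter),
#'   \code{x}, \code{y}, \code{z}.
#' @slot chainToProtein Named character; names are chain ids, values are
#'   protein accessions.
#' @exportClass StructureModel
setClass("StructureModel",
         representation(model_id = "character",
                        atoms = "DataFrame",
                        chainToProtein = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "code", "x", "y", "z")
  miss <- setdiff(need, colnames(a))
  if (length(miss) > 0L)
    return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (nrow(a) > 0L) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite Calpha coordinate")
    inc <- vapply(split(a$resno, a$chain),
                  function(r) all(diff(r) > 0), logical(1))
    if (!all(inc))
      return("residue numbers must be strictly increasing within a chain")
  }
  bad <- setdiff(names(object@chainToProtein), unique(a$chain))
  if (length(bad) > 0L)
    return(paste("chainToProtein names absent from atoms:",
                 paste(bad, collapse = ", ")))
  TRUE
})

#' QuantMatrix: protein-by-sample label-free quantification matrix
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} subclass holding a
#' single \code{"intensity"} assay (proteins in rows, samples in columns),
#' a \code{group} column in \code{colData}, and a \code{scale} metadata
#' entry (\code{"raw"} or \code{"log2"}). Missing values are \code{NA};
#' zeros on the raw scale are treated as missing by the reader.
#'
#' @exportClass QuantMatrix
setClass("QuantMatrix", contains = "SummarizedExperiment")

setValidity("QuantMatrix", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is required")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData column 'group' is required")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("raw", "log2"))
    return("metadata scale must be 'raw' or 'log2'")
  m <- SummarizedExperiment::assay(object, "intensity")
  if (sc == "raw" && any(m <= 0, na.rm = TRUE))
    return("raw-scale intensities must be > 0 where present")
  TRUE
})

#' EnsembleReport: crosslink satisfaction across a structural ensemble
#'
#' Per-crosslink, per-structure minimal Calpha-Calpha distances with
#' satisfaction verdicts, the satisfied-in-any-state summary, and
#' per-structure satisfied counts.
#'
#' @slot measurements \link[S4Vectors]{DataFrame}: one row per
#'   (crosslink, structure) with the minimal distance over chain-copy
#'   combinations and its status.
#' @slot links \link[S4Vectors]{DataFrame}: one row per crosslink with
#'   \code{satisfied_any}, \code{best_structure}, \code{best_distance},
#'   \code{mappable}.
#' @slot perStructure \link[S4Vectors]{DataFrame}: mapped and satisfied
#'   counts per ensemble member.
#' @slot summary Fraction of mappable crosslinks satisfied in at least
#'   one state (\code{NA} if none mappable).
#' @exportClass EnsembleReport
setClass("EnsembleReport",
         representation(measurements = "DataFrame",
                        links = "DataFrame",
                        perStructure = "DataFrame",
                        summary = "numeric"))

setValidity("EnsembleReport", function(object) {
  s <- object@summary
  if (length(s) != 1L) return("summary must be length 1")
  if (!is.na(s) && (s < 0 || s > 1)) return("summary must lie in [0, 1]")
  if (nrow(object@links) > 0L &&
      !all(c("satisfied_any", "mappable") %in% colnames(object@links)))
    return("links must carry satisfied_any and mappable")
  TRUE
})
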