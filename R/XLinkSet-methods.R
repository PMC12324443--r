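#' Construct an XLinkSet from a data.frame of residue-pair records
#'
#' Endpoints are put in canonical order (lexicographic by accession, then
#' by residue, with the score-irrelevant side data swapped alongside) and
#' the decoy class is derived from the configured decoy accession prefix
#' when a \code{decoy_class} column is not supplied: neither accession
#' prefixed is \code{"TT"}, one is \code{"TD"}, both is \code{"DD"}.
#'
#' @param df data.frame with at least \code{protein_a}, \code{protein_b},
#'   \code{residue_a}, \code{residue_b}, \code{score}. Optional:
#'   \code{decoy_class}, \code{dataset_id}, candidate-evidence counts.
#' @param config An \code{\link{xlConfig}} list (used for the decoy
#'   prefix).
#' @return An \linkS4class{XLinkSet}.
#' @export
XLinkSet <- function(df, config = xlConfig()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "residue_a", "residue_b", "score")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$protein_a <- as.character(df$protein_a)
  df$protein_b <- as.character(df$protein_b)
  df$residue_a <- as.integer(df$residue_a)
  df$residue_b <- as.integer(df$residue_b)
  df$score <- as.numeric(df$score)
  if (is.null(df$dataset_id)) df$dataset_id <- "default"
  if (is.null(df$decoy_class)) {
    da <- startsWith(df$protein_a, config$decoy_prefix)
    db <- startsWith(df$protein_b, config$decoy_prefix)
    df$decoy_class <- c("TT", "TD", "DD")[1L + da + db]
  }
  swap <- df$protein_a > df$protein_b |
    (df$protein_a == df$protein_b & df$residue_a > df$residue_b)
  if (any(swap)) {
    pa <- df$protein_a; ra <- df$residue_a
    df$protein_a[swap] <- df$protein_b[swap]
    df$residue_a[swap] <- df$residue_b[swap]
    df$protein_b[swap] <- pa[swap]
    df$residue_b[swap] <- ra[swap]
    sw_a <- c("n_matches_peptide_a", "n_matches_peptide_b")
    if (all(sw_a %in% colnames(df))) {
      tmp <- df$n_matches_peptide_a
      df$n_matches_peptide_a[swap] <- df$n_matches_peptide_b[swap]
      df$n_matches_peptide_b[swap] <- tmp[swap]
    }
  }
  df$is_inter_protein <- df$protein_a != df$protein_b
  first <- .xlink_required_cols
  df <- df[, c(first, setdiff(colnames(df), first)), drop = FALSE]
  new("XLinkSet", records = DataFrame(df))
}

#' Accessors for XLinkSet
#'
#' @param x An \linkS4class{XLinkSet}.
#' @return \code{xlRecords} returns the record \code{DataFrame}.
#' @name XLinkSet-accessors
#' @aliases xlRecords xlRecords,XLinkSet-method
#' @export
setMethod("xlRecords", "XLinkSet", function(x) x@records)

#' @export
setMethod("length", "XLinkSet", function(x) nrow(x@records))

#' @export
setMethod("as.data.frame", "XLinkSet",
          function(x, ...) as.data.frame(x@records))

#' @export
setMethod("[", "XLinkSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, records = x@records[i, , drop = FALSE])
})

setMethod("show", "XLinkSet", function(object) {
  df <- object@records
  cat("XLinkSet with", nrow(df), "residue-pair record(s)\n")
  if (nrow(df) > 0L) {
    cat("  decoy classes:",
        paste(names(table(df$decoy_class)), table(df$decoy_class),
              sep = "=", collapse = " "), "\n")
    cat("  inter-protein:", sum(df$is_inter_protein),
        "| datasets:", length(unique(df$dataset_id)), "\n")
  }
})

# canonical keys used for uniqueness and set algebra
.pairKey <- function(df) {
  paste(df$protein_a, df$residue_a, df$protein_b, df$residue_b, sep = "|")
}

.ppiKey <- function(df) paste(df$protein_a, df$protein_b, sep = "|")

#' Combine crosslink sets
#'
#' @param x,... XLinkSet objects.
#' @export
setMethod("c", "XLinkSet", function(x, ...) {
  dfs <- lapply(c(list(x), list(...)), as.data.frame)
  common <- Reduce(intersect, lapply(dfs, colnames))
  XLinkSet(do.call(rbind, lapply(dfs, function(d) d[, common, drop = FALSE])))
})
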