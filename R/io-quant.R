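#' Construct a QuantMatrix
#'
#' @param intensities Numeric matrix, proteins in rows (rownames are
#'   accessions), samples in columns (colnames are sample ids). Missing
#'   values are \code{NA}; on the raw scale zeros are recoded to
#'   \code{NA} (LFQ convention).
#' @param groups Named character vector (or factor) of group labels per
#'   sample, or an unnamed vector in column order.
#' @param scale \code{"raw"} or \code{"log2"}.
#' @return A \linkS4class{QuantMatrix}.
#' @export
quantMatrix <- function(intensities, groups, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  m <- as.matrix(intensities)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("P", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("S", seq_len(ncol(m)))
  groups <- as.character(groups)
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m) || anyNA(groups))
    stop("every sample needs a group label")
  if (scale == "raw" && any(m == 0, na.rm = TRUE))
    m[!is.na(m) & m == 0] <- NA
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    colData = DataFrame(group = groups, row.names = colnames(m)),
    metadata = list(scale = scale))
  new("QuantMatrix", se)
}

#' Accessors for QuantMatrix
#'
#' @param x A \linkS4class{QuantMatrix}.
#' @return \code{quantIntensities}: the intensity matrix;
#'   \code{quantGroups}: named group labels; \code{quantScale}: the
#'   intensity scale.
#' @export
quantIntensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @rdname quantIntensities
#' @export
quantGroups <- function(x) {
  g <- SummarizedExperiment::colData(x)$group
  names(g) <- colnames(x)
  g
}

#' @rdname quantIntensities
#' @export
quantScale <- function(x) metadata(x)$scale

# rebuild preserving class/metadata after changing the matrix
.replaceIntensities <- function(x, m, scale = quantScale(x)) {
  quantMatrix(m, quantGroups(x), scale = scale)
}

#' Read a quantification matrix and its group labels
#'
#' @param path TSV/CSV of intensities: first column protein accession,
#'   remaining columns samples. Empty cells, \code{NA} and (on the raw
#'   scale) zeros are missing.
#' @param groups Either a named vector of group labels or the path of a
#'   two-column TSV (sample, group).
#' @param scale \code{"raw"} or \code{"log2"}.
#' @param sep Field separator (guessed from extension by default).
#' @return A \linkS4class{QuantMatrix}.
#' @export
readQuantTable <- function(path, groups, scale = c("raw", "log2"),
                           sep = NULL) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    g <- utils::read.table(groups, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    groups <- stats::setNames(as.character(g[[2]]), as.character(g[[1]]))
  }
  quantMatrix(m, groups, scale = scale)
}

#' Write a quantification matrix as TSV
#'
#' @param x A \linkS4class{QuantMatrix}.
#' @param path Output path.
#' @export
writeQuantTable <- function(x, path) {
  m <- quantIntensities(x)
  df <- data.frame(accession = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
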