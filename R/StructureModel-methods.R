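#' Construct a StructureModel from per-residue Calpha records
#'
#' @param model_id Identifier for the state (e.g. PDB ID).
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{code}, \code{x}, \code{y}, \code{z}; one row per residue
#'   possessing a Calpha atom.
#' @param chainToProtein Named character vector mapping chain ids to
#'   protein accessions. Chains left unmapped are ignored by the
#'   restraint-mapping stage.
#' @return A \linkS4class{StructureModel}.
#' @export
StructureModel <- function(model_id, atoms, chainToProtein = character()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  ord <- order(atoms$chain, atoms$resno)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  new("StructureModel", model_id = as.character(model_id),
      atoms = DataFrame(atoms),
      chainToProtein = chainToProtein)
}

#' Accessors for StructureModel
#'
#' @param x A \linkS4class{StructureModel}.
#' @param chain Optional chain id to restrict \code{caCoords}.
#' @param value Named character vector for the replacement method.
#' @return \code{modelId}: the identifier; \code{chainIds}: chain ids
#'   present; \code{chainProteins}: the chain-to-accession map;
#'   \code{caCoords}: a numeric matrix of Calpha coordinates with
#'   author residue numbers as rownames.
#' @name StructureModel-accessors
#' @aliases modelId chainIds chainProteins chainProteins<- caCoords
#'   modelId,StructureModel-method chainIds,StructureModel-method
#'   chainProteins,StructureModel-method
#'   chainProteins<-,StructureModel-method caCoords,StructureModel-method
#' @export
setMethod("modelId", "StructureModel", function(x) x@model_id)

#' @rdname StructureModel-accessors
#' @export
setMethod("chainIds", "StructureModel",
          function(x) unique(x@atoms$chain))

#' @rdname StructureModel-accessors
#' @export
setMethod("chainProteins", "StructureModel", function(x) x@chainToProtein)

#' @rdname StructureModel-accessors
#' @export
setReplaceMethod("chainProteins", "StructureModel", function(x, value) {
  x@chainToProtein <- value
  validObject(x)
  x
})

#' @rdname StructureModel-accessors
#' @export
setMethod("caCoords", "StructureModel", function(x, chain = NULL) {
  a <- x@atoms
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  m <- cbind(x = a$x, y = a$y, z = a$z)
  rownames(m) <- a$resno
  m
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel", object@model_id, "-", nrow(a), "Calpha residues in",
      length(unique(a$chain)), "chain(s)\n")
  if (length(object@chainToProtein) > 0L)
    cat("  chain map:",
        paste(names(object@chainToProtein), object@chainToProtein,
              sep = ":", collapse = " "), "\n")
})

# one-letter observed sequence of a chain, in residue order
.chainSequence <- function(structure, chain) {
  a <- structure@atoms
  a <- a[a$chain == chain, , drop = FALSE]
  list(codes = paste(a$code, collapse = ""), resno = a$resno)
}
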