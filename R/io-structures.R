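#' Read a structure into a Calpha trace
#'
#' Parses a PDB or mmCIF file (via bio3d) and keeps, for the first model
#' block only, one Calpha per residue. Alternate locations are resolved
#' to the highest-occupancy record, first-listed on ties. Chains without
#' any Calpha are dropped with a warning; a file with none at all (e.g.
#' HETATM-only) is an error.
#'
#' @param path Structure file.
#' @param fmt \code{"pdb"} or \code{"mmcif"}; guessed from the extension
#'   by default.
#' @param model_id Identifier for the returned model; defaults to the
#'   file name without extension.
#' @param chainToProtein Optional named character mapping chain ids to
#'   accessions.
#' @return A \linkS4class{StructureModel}.
#' @export
readStructure <- function(path, fmt = c("auto", "pdb", "mmcif"),
                          model_id = NULL, chainToProtein = character()) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto")
    fmt <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  pdb <- tryCatch(
    if (fmt == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                      verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", fmt, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  all_chains <- unique(at$chain[at$type == "ATOM"])
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no Calpha atoms in ", path)
  # resolve altlocs: highest occupancy, then first listed
  ca$o[is.na(ca$o)] <- 1
  key <- paste(ca$chain, ca$resno)
  ord <- order(key, -ca$o, seq_len(nrow(ca)))
  ca <- ca[ord, , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno)), , drop = FALSE]
  dropped <- setdiff(all_chains, unique(ca$chain))
  if (length(dropped) > 0L)
    warning("chain(s) without Calpha dropped: ",
            paste(dropped, collapse = ", "))
  code <- suppressWarnings(bio3d::aa321(ca$resid))
  code[is.na(code)] <- "X"
  if (is.null(model_id))
    model_id <- sub("\\.[^.]+$", "", basename(path))
  StructureModel(model_id,
                 data.frame(chain = ca$chain, resno = ca$resno,
                            code = code, x = ca$x, y = ca$y, z = ca$z,
                            stringsAsFactors = FALSE),
                 chainToProtein = chainToProtein)
}

# 1-letter -> 3-letter residue names for writing
.aa123 <- function(code) {
  out <- bio3d::aa123(code)
  out[is.na(out) | out == "X"] <- "UNK"
  out
}

#' Write a Calpha-trace structure as PDB
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param path Output path.
#' @export
writeStructurePDB <- function(structure, path) {
  a <- as.data.frame(structure@atoms)
  xyz <- as.numeric(t(cbind(a$x, a$y, a$z)))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno,
                   resid = .aa123(a$code), chain = a$chain,
                   elety = rep("CA", nrow(a)), eleno = seq_len(nrow(a)),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Write a Calpha-trace structure as mmCIF
#'
#' Emits a minimal atom_site loop (the standard category columns used by
#' structure readers). Intended for fixture generation and format
#' cross-checks; no installed R package writes mmCIF.
#'
#' @param structure A \linkS4class{StructureModel}.
#' @param path Output path.
#' @export
writeStructureCIF <- function(structure, path) {
  a <- as.data.frame(structure@atoms)
  res3 <- .aa123(a$code)
  hdr <- c(paste0("data_", gsub("[^A-Za-z0-9_]", "_",
                                structure@model_id)),
           "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id",
                    "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                    "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                    "auth_seq_id", "auth_comp_id", "auth_asym_id",
                    "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- sprintf(
    "ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s CA 1",
    seq_len(nrow(a)), res3, a$chain, a$resno, a$x, a$y, a$z,
    a$resno, res3, a$chain)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Write crosslink measurements as ChimeraX pseudobonds
#'
#' One line per mapped crosslink in ChimeraX pseudobond syntax,
#' \code{/<chain>:<resnum>@CA /<chain>:<resnum>@CA <color>}. The binary
#' scheme colors satisfied restraints blue and violated ones red; the
#' banded scheme colors blue below the lower band edge, yellow within
#' the band and red beyond it. Unmapped crosslinks are skipped and their
#' count reported in a message.
#'
#' @param meas data.frame of measurements on one structure, as returned
#'   by \code{\link{measureCrosslinks}} (columns \code{chain_a},
#'   \code{resno_a}, \code{chain_b}, \code{resno_b},
#'   \code{min_distance}, \code{status}).
#' @param path Output file.
#' @param color_scheme \code{"binary"} or \code{"banded"}.
#' @param config \code{\link{xlConfig}} providing the distance threshold
#'   and band edges.
#' @export
writePseudobonds <- function(meas, path, color_scheme = c("binary", "banded"),
                             config = xlConfig()) {
  color_scheme <- match.arg(color_scheme)
  meas <- as.data.frame(meas)
  unmapped <- is.na(meas$min_distance)
  if (any(unmapped))
    message(sum(unmapped), " unmapped crosslink(s) skipped")
  m <- meas[!unmapped, , drop = FALSE]
  color <- if (color_scheme == "binary") {
    ifelse(m$min_distance <= config$sda_max_ca_distance, "blue", "red")
  } else {
    band <- distanceBand(m$min_distance, config$band_edges)
    c(short = "blue", mid = "yellow", long = "red")[band]
  }
  lines <- sprintf("/%s:%d@CA /%s:%d@CA %s", m$chain_a, m$resno_a,
                   m$chain_b, m$resno_b, color)
  writeLines(lines, path)
  invisible(path)
}
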