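#' Combined model confidence from ipTM and pTM
#'
#' Weighted combination of the interface-predicted TM-score and the
#' global predicted TM-score, 0.8*ipTM + 0.2*pTM by default.
#'
#' @param iptm,ptm Numeric vectors in [0, 1].
#' @param weights Length-2 weights for (ipTM, pTM).
#' @return Numeric vector of confidence scores.
#' @export
modelConfidence <- function(iptm, ptm, weights = c(0.8, 0.2)) {
  if (any(iptm < 0 | iptm > 1, na.rm = FALSE) || anyNA(iptm))
    stop("ipTM out of [0, 1]")
  if (any(ptm < 0 | ptm > 1, na.rm = FALSE) || anyNA(ptm))
    stop("pTM out of [0, 1]")
  weights[1] * iptm + weights[2] * ptm
}

#' Score a predicted complex from its per-model ipTM/pTM
#'
#' Averages the per-model confidence over all supplied models (the
#' usual five); the prediction is high confidence when the mean strictly
#' exceeds the cutoff ("above 0.65").
#'
#' @param iptm,ptm Per-model scores in [0, 1] (equal length, >= 1).
#' @param pair_id Identifier of the protein pair (character).
#' @param cutoff Confidence cutoff (0.65; strict).
#' @param weights Weights for \code{\link{modelConfidence}}.
#' @return List of class \code{ModelConfidence}: \code{pair_id},
#'   \code{per_model_confidence}, \code{mean_confidence},
#'   \code{mean_iptm}, \code{high_confidence}, and crosslink tallies
#'   (\code{NA} until \code{\link{validatePrediction}} fills them).
#' @export
scorePrediction <- function(iptm, ptm, pair_id = "pair", cutoff = 0.65,
                            weights = c(0.8, 0.2)) {
  if (length(iptm) == 0L || length(iptm) != length(ptm))
    stop("need >= 1 model with matching ipTM and pTM")
  per <- modelConfidence(iptm, ptm, weights)
  structure(list(pair_id = pair_id,
                 per_model_confidence = per,
                 mean_confidence = mean(per),
                 mean_iptm = mean(iptm),
                 high_confidence = mean(per) > cutoff,
                 xl_satisfied = NA_integer_,
                 xl_mappable = NA_integer_,
                 xl_fraction = NA_real_),
            class = "ModelConfidence")
}

#' @export
print.ModelConfidence <- function(x, ...) {
  cat("ModelConfidence ", x$pair_id, ": mean ",
      sprintf("%.3f", x$mean_confidence),
      " over ", length(x$per_model_confidence), " model(s)",
      if (x$high_confidence) " [high confidence]" else "", "\n", sep = "")
  if (!is.na(x$xl_mappable))
    cat("  crosslinks satisfied: ", x$xl_satisfied, "/", x$xl_mappable,
        "\n", sep = "")
  invisible(x)
}

#' Read per-model prediction scores from JSON
#'
#' Schema: a list of \code{{pair: [accA, accB], models: [{iptm, ptm,
#' coords_path}]}} entries.
#'
#' @param path JSON file.
#' @return List of entries with \code{pair} (character(2)) and a
#'   data.frame \code{models}.
#' @export
readModelScores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(e) {
    models <- as.data.frame(e$models)
    if (!all(c("iptm", "ptm") %in% colnames(models)))
      stop("model score entries need iptm and ptm")
    list(pair = unlist(e$pair), models = models)
  })
}

#' Validate a predicted complex against crosslink restraints
#'
#' Measures the given crosslinks on the prediction's coordinates
#' (delegating to the restraint-mapping machinery) and tallies satisfied
#' versus mappable restraints; crosslinks with an unresolved endpoint
#' (e.g. in a trimmed disordered region) are excluded from the
#' denominator and reported separately.
#'
#' @param structure Predicted model as a \linkS4class{StructureModel}
#'   with chain-to-protein assignments.
#' @param x An \linkS4class{XLinkSet} of restraints involving the pair.
#' @param sequences Canonical sequences
#'   (\link[Biostrings]{AAStringSet}).
#' @param config \code{\link{xlConfig}}.
#' @return List with \code{xl_satisfied}, \code{xl_mappable},
#'   \code{xl_unmapped} and \code{fraction} (\code{NA} when nothing
#'   maps).
#' @export
validatePrediction <- function(structure, x, sequences,
                               config = xlConfig()) {
  meas <- measureCrosslinks(x, structure, sequences = sequences,
                            config = config)
  n_map <- sum(meas$status != "unmapped")
  n_sat <- sum(meas$status == "satisfied")
  list(xl_satisfied = n_sat, xl_mappable = n_map,
       xl_unmapped = sum(meas$status == "unmapped"),
       fraction = if (n_map == 0L) NA_real_ else n_sat / n_map,
       measurements = meas)
}

#' Rank predicted interfaces
#'
#' Orders predictions by high-confidence flag, then mean confidence,
#' then crosslink-satisfaction fraction (all descending), breaking full
#' ties lexicographically by pair id.
#'
#' @param confidences List of \code{ModelConfidence} objects (from
#'   \code{\link{scorePrediction}}, optionally with crosslink tallies
#'   filled in).
#' @return data.frame, best interface first.
#' @export
rankInterfaces <- function(confidences) {
  df <- do.call(rbind, lapply(confidences, function(m)
    data.frame(pair_id = m$pair_id,
               n_models = length(m$per_model_confidence),
               mean_confidence = m$mean_confidence,
               mean_iptm = m$mean_iptm,
               high_confidence = m$high_confidence,
               xl_satisfied = m$xl_satisfied,
               xl_mappable = m$xl_mappable,
               xl_fraction = m$xl_fraction,
               stringsAsFactors = FALSE)))
  frac <- ifelse(is.na(df$xl_fraction), -1, df$xl_fraction)
  ord <- order(-df$high_confidence, -df$mean_confidence, -frac,
               df$pair_id)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
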