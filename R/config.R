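#' Pipeline configuration
#'
#' Central parameter set for the crosslink analysis pipeline. Defaults
#' encode the SDA photo-crosslinker geometry and the thresholds of the
#' quantitative and FDR procedures.
#'
#' @param sda_max_ca_distance Maximum Calpha-Calpha distance (Angstrom)
#'   bridged by SDA; a restraint at or below it is satisfied. Default 27.
#' @param band_edges Two increasing distances (Angstrom) splitting
#'   distances into short/mid/long bands for banded coloring. Default
#'   \code{c(21.5, 28.5)}.
#' @param residue_pair_fdr Target FDR at the residue-pair level (0.02).
#' @param ppi_fdr Target FDR at the protein-protein interaction level
#'   (0.05).
#' @param completeness_min Minimum observed fraction per group for a
#'   protein to be retained in quantification (0.8).
#' @param imputation_downshift,imputation_width Down-shifted-Gaussian
#'   imputation parameters in units of per-sample SD (1.8 and 0.3).
#' @param lfc_min Minimum log2 fold change for an enrichment call (2).
#' @param alpha Adjusted-p cutoff for an enrichment call (0.05; strict
#'   \code{<}).
#' @param confidence_weights Weights of (ipTM, pTM) in the model
#'   confidence score, \code{c(0.8, 0.2)}.
#' @param confidence_cutoff Mean model confidence must strictly exceed
#'   this for a prediction to be called high confidence (0.65).
#' @param nhs_residues Residues reactive to the NHS-ester end of SDA
#'   (protein N-termini are always eligible in addition).
#' @param diazirine_residues Residues reactive to the photo-activated
#'   diazirine end (protein N- and C-termini also eligible).
#' @param decoy_prefix Accession prefix marking reversed-sequence decoys.
#' @param core_subunits Accessions of the canonical complex subunits
#'   (used by the AP-MS-based PPI filter).
#' @param min_identity Minimum sequence identity for a chain-to-protein
#'   alignment map to be used (0.95).
#' @param cluster_window Residue window for linking violated crosslinks
#'   into clusters (10).
#' @param cluster_min_size Minimum component size reported as a cluster
#'   (3).
#' @param rng_seed Seed from which all stochastic steps derive.
#' @return A classed list of validated parameters.
#' @export
xlConfig <- function(sda_max_ca_distance = 27,
                     band_edges = c(21.5, 28.5),
                     residue_pair_fdr = 0.02,
                     ppi_fdr = 0.05,
                     completeness_min = 0.8,
                     imputation_downshift = 1.8,
                     imputation_width = 0.3,
                     lfc_min = 2,
                     alpha = 0.05,
                     confidence_weights = c(0.8, 0.2),
                     confidence_cutoff = 0.65,
                     nhs_residues = c("K", "S", "T", "Y"),
                     diazirine_residues = c("A", "C", "D", "E", "G", "H",
                                            "I", "K", "L", "P", "S", "T",
                                            "V", "Y"),
                     decoy_prefix = "REV_",
                     core_subunits = character(),
                     min_identity = 0.95,
                     cluster_window = 10L,
                     cluster_min_size = 3L,
                     rng_seed = 1L) {
  stopifnot(sda_max_ca_distance > 0,
            length(band_edges) == 2L, band_edges[1] < band_edges[2],
            residue_pair_fdr >= 0, residue_pair_fdr <= 1,
            ppi_fdr >= 0, ppi_fdr <= 1,
            completeness_min >= 0, completeness_min <= 1,
            imputation_downshift >= 0, imputation_width >= 0,
            alpha > 0, alpha <= 1,
            length(confidence_weights) == 2L,
            all(confidence_weights >= 0),
            confidence_cutoff >= 0, confidence_cutoff <= 1,
            min_identity >= 0, min_identity <= 1,
            cluster_window >= 0, cluster_min_size >= 1)
  structure(list(sda_max_ca_distance = sda_max_ca_distance,
                 band_edges = band_edges,
                 residue_pair_fdr = residue_pair_fdr,
                 ppi_fdr = ppi_fdr,
                 completeness_min = completeness_min,
                 imputation_downshift = imputation_downshift,
                 imputation_width = imputation_width,
                 lfc_min = lfc_min,
                 alpha = alpha,
                 confidence_weights = confidence_weights,
                 confidence_cutoff = confidence_cutoff,
                 nhs_residues = nhs_residues,
                 diazirine_residues = diazirine_residues,
                 decoy_prefix = decoy_prefix,
                 core_subunits = core_subunits,
                 min_identity = min_identity,
                 cluster_window = as.integer(cluster_window),
                 cluster_min_size = as.integer(cluster_min_size),
                 rng_seed = as.integer(rng_seed)),
            class = "XLinkConfig")
}

#' @export
print.XLinkConfig <- function(x, ...) {
  cat("XLinkConfig:\n")
  cat("  distance threshold:", x$sda_max_ca_distance, "A; bands:",
      paste(x$band_edges, collapse = "-"), "A\n")
  cat("  FDR: residue-pair", x$residue_pair_fdr, "| PPI", x$ppi_fdr, "\n")
  cat("  enrichment: completeness >=", x$completeness_min,
      "| |log2FC| >=", x$lfc_min, "| adj. p <", x$alpha, "\n")
  cat("  imputation: downshift", x$imputation_downshift, "SD, width",
      x$imputation_width, "SD\n")
  cat("  model confidence:", paste(x$confidence_weights, collapse = "/"),
      "ipTM/pTM, cutoff >", x$confidence_cutoff, "\n")
  invisible(x)
}

#' Load a configuration from a YAML file
#'
#' Unknown keys raise an error naming them; missing keys fall back to the
#' \code{\link{xlConfig}} defaults. Keys that describe pipeline inputs
#' (paths, group labels) are returned alongside the parameter set.
#'
#' @param path YAML file.
#' @return List with elements \code{config} (an \code{XLinkConfig}) and
#'   \code{inputs} (everything else in the file).
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(xlConfig))
  input_keys <- setdiff(names(y), known)
  pars <- y[intersect(names(y), known)]
  cfg <- do.call(xlConfig, pars)
  list(config = cfg, inputs = y[input_keys])
}
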