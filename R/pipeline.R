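## End-to-end orchestration: enrich -> xlfdr -> ppi_filter -> map ->
## score_models, with a machine-readable manifest.

.pipeline_input_keys <- c("quant", "groups", "group_test", "group_ctrl",
                          "normalize_method", "candidates", "xl", "fasta",
                          "structures", "model_scores", "out_dir",
                          "boost", "aggregate")

#' Run the full crosslink analysis pipeline
#'
#' Stages are run in order, each persisting its outputs under
#' \code{out_dir} before the next starts; a failing stage aborts with
#' its name, leaving earlier outputs in place. Only stages whose inputs
#' are configured are run. A manifest (configuration snapshot, input
#' file digests, per-stage outputs and wall-clock) is written to
#' \code{out_dir/manifest.json} at start and finalized at the end.
#' Reruns with identical inputs and seed reproduce identical outputs.
#'
#' @param config_path YAML configuration: any \code{\link{xlConfig}}
#'   parameter plus the input keys \code{quant}, \code{groups},
#'   \code{group_test}, \code{group_ctrl}, \code{normalize_method},
#'   \code{candidates}, \code{xl}, \code{fasta}, \code{structures}
#'   (directory of PDB/mmCIF files), \code{model_scores},
#'   \code{out_dir}, \code{boost}, \code{aggregate}. Unknown keys are an
#'   error naming them.
#' @param out_dir Output directory (overrides the config entry).
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config_path, out_dir = NULL) {
  cf <- readConfig(config_path)
  config <- cf$config
  inputs <- cf$inputs
  bad <- setdiff(names(inputs), .pipeline_input_keys)
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(out_dir)) out_dir <- inputs$out_dir
  if (is.null(out_dir)) stop("out_dir must be configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  in_files <- unlist(inputs[intersect(names(inputs),
                                      c("quant", "groups", "candidates",
                                        "xl", "fasta", "model_scores"))])
  digests <- if (length(in_files) > 0L)
    as.list(tools::md5sum(in_files[file.exists(in_files)])) else list()
  manifest <- list(tool = "crosslinkR",
                   version = as.character(
                     utils::packageVersion("crosslinkR")),
                   config = unclass(config), inputs = inputs,
                   input_digests = digests, stages = list())
  man_path <- file.path(out_dir, "manifest.json")
  write_manifest <- function()
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  write_manifest()

  log_event <- function(stage, status)
    message(sprintf("[%s] stage %s: %s",
                    format(Sys.time(), "%H:%M:%S"), stage, status))
  run_stage <- function(name, fun) {
    log_event(name, "start")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      status = "complete", outputs = out,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    write_manifest()
    log_event(name, "complete")
    out
  }
  require_key <- function(keys, stage) {
    miss <- keys[vapply(keys, function(k) is.null(inputs[[k]]),
                        logical(1))]
    if (length(miss) > 0L)
      stop("stage '", stage, "' needs configuration key(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }

  enrichment <- NULL
  if (!is.null(inputs$quant)) {
    enrichment <- run_stage("enrich", function() {
      require_key(c("groups", "group_test", "group_ctrl"), "enrich")
      qm <- readQuantTable(inputs$quant, inputs$groups)
      res <- runEnrichment(
        qm, inputs$group_test, inputs$group_ctrl, config = config,
        normalize_method = inputs$normalize_method %||% "log2_median")
      p <- file.path(out_dir, "enrichment.tsv")
      utils::write.table(res, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    })
  }

  fdr_res <- NULL
  if (!is.null(inputs$candidates)) {
    fdr_out <- run_stage("xlfdr", function() {
      xl <- readCrosslinkTable(inputs$candidates, config = config,
                               dialect = .internalDialect())
      if ("n_noncleaved_sda_fragments" %in% colnames(xlRecords(xl)))
        xl <- prefilterCandidates(xl)
      res <- hierarchicalFilter(
        xl, rp_fdr = config$residue_pair_fdr, ppi_fdr = config$ppi_fdr,
        boost = isTRUE(inputs$boost),
        aggregate = inputs$aggregate %||% "sum")
      fdr_res <<- res
      p1 <- file.path(out_dir, "residue_pairs.tsv")
      writeCrosslinkTable(res$residue_pairs, p1)
      p2 <- file.path(out_dir, "ppi_edges.tsv")
      writePPIEdges(res$ppi_edges, p2)
      p3 <- file.path(out_dir, "fdr_report.json")
      jsonlite::write_json(
        lapply(res$reports, function(r)
          list(level = r$level, threshold = r$threshold_score,
               counts = as.list(r$counts), fdr_est = r$fdr_est)),
        p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(p1, p2, p3)
    })
  }

  if (!is.null(fdr_res) && !is.null(enrichment)) {
    run_stage("ppi_filter", function() {
      res <- utils::read.table(enrichment, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      enriched <- res$accession[res$enriched]
      kept <- enrichmentFilterPPIs(fdr_res$ppi_edges, enriched,
                                   config$core_subunits)
      p <- file.path(out_dir, "ppi_edges_filtered.tsv")
      writePPIEdges(kept, p)
      p
    })
  }

  xl_for_map <- if (!is.null(inputs$xl))
    readCrosslinkTable(inputs$xl, config = config,
                       dialect = .internalDialect())
  else if (!is.null(fdr_res)) fdr_res$residue_pairs else NULL

  if (!is.null(inputs$structures)) {
    run_stage("map", function() {
      require_key("fasta", "map")
      if (is.null(xl_for_map))
        stop("no crosslinks available (configure 'xl' or 'candidates')")
      seqs <- readProteinFasta(inputs$fasta, config = config)
      files <- if (dir.exists(inputs$structures))
        list.files(inputs$structures, pattern = "\\.(pdb|cif)$",
                   full.names = TRUE)
      else inputs$structures
      if (length(files) == 0L)
        stop("no structures found under ", inputs$structures)
      structs <- lapply(files, function(f) {
        s <- readStructure(f)
        # default chain->protein: chains named after accessions, or
        # 1:1 in order
        accs <- names(seqs)
        cp <- if (all(chainIds(s) %in% accs))
          stats::setNames(chainIds(s), chainIds(s))
        else stats::setNames(accs[seq_along(chainIds(s))], chainIds(s))
        chainProteins(s) <- cp
        s
      })
      rep <- ensembleSatisfaction(xl_for_map, structs, seqs,
                                  config = config)
      p1 <- file.path(out_dir, "ensemble_links.tsv")
      utils::write.table(as.data.frame(linkVerdicts(rep)), p1,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      p2 <- file.path(out_dir, "ensemble_structures.tsv")
      utils::write.table(as.data.frame(perStructureCounts(rep)), p2,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outs <- c(p1, p2)
      meas <- as.data.frame(measurements(rep))
      for (sid in unique(meas$structure_id)) {
        pp <- file.path(out_dir, paste0("pseudobonds_", sid, ".pb"))
        writePseudobonds(meas[meas$structure_id == sid, ], pp,
                         color_scheme = "binary", config = config)
        outs <- c(outs, pp)
        cl <- detectViolationClusters(
          meas[meas$structure_id == sid, ],
          window = config$cluster_window,
          min_size = config$cluster_min_size)
        if (length(cl) > 0L) {
          pc <- file.path(out_dir, paste0("clusters_", sid, ".tsv"))
          cdf <- do.call(rbind, lapply(cl, function(k)
            data.frame(protein_a = k$protein_a, protein_b = k$protein_b,
                       size = k$size,
                       span_a = paste(k$span_a, collapse = "-"),
                       span_b = paste(k$span_b, collapse = "-"))))
          utils::write.table(cdf, pc, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          outs <- c(outs, pc)
        }
      }
      outs
    })
  }

  if (!is.null(inputs$model_scores)) {
    run_stage("score_models", function() {
      entries <- readModelScores(inputs$model_scores)
      seqs <- if (!is.null(inputs$fasta))
        readProteinFasta(inputs$fasta, config = config) else NULL
      confs <- lapply(entries, function(e) {
        mc <- scorePrediction(e$models$iptm, e$models$ptm,
                              pair_id = paste(e$pair, collapse = "-"),
                              cutoff = config$confidence_cutoff,
                              weights = config$confidence_weights)
        cp <- e$models$coords_path
        if (!is.null(cp) && !is.null(seqs) && !is.null(xl_for_map) &&
            all(file.exists(cp))) {
          s <- readStructure(cp[1L])
          chainProteins(s) <- stats::setNames(
            e$pair[seq_along(chainIds(s))], chainIds(s))
          v <- validatePrediction(s, xl_for_map, seqs, config = config)
          mc$xl_satisfied <- v$xl_satisfied
          mc$xl_mappable <- v$xl_mappable
          mc$xl_fraction <- v$fraction
        }
        mc
      })
      p <- file.path(out_dir, "ranked_interfaces.tsv")
      utils::write.table(rankInterfaces(confs), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      p
    })
  }

  manifest$finished <- TRUE
  write_manifest()
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
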