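# End-to-end orchestration: read inputs -> RPM -> differential
# expression -> deltas -> (optional DE gating of the target map) ->
# apportionment/correlation/local influence -> PPI-weighted global
# ranking -> intervention calls -> written report + JSON manifest.
# The pipeline itself draws no random numbers, so a given input set
# always produces byte-identical outputs.

#' Pipeline configuration
#'
#' @param mirna_counts,gene_counts,pairing,target_map,ppi input file
#'   paths (formats as in [readExpression()], [readTargetMap()],
#'   [readPPI()]).
#' @param out_dir output directory.
#' @param de_method,de_alpha differential-expression test and FDR
#'   threshold (see [callDifferential()]).
#' @param gate_influence when `TRUE` (default), influence is computed
#'   only for target-map edges whose miRNA and gene are both flagged
#'   differentially expressed.
#' @param apportion_mode `"per_patient"` (default) or `"cohort_mean"`.
#' @param rho_threshold threshold for the correlation summary
#'   (default 0.3).
#' @param ppi_min_score strict PPI combined-score filter (default 150).
#' @param top_k rows of the ranked table kept in the top table
#'   (default 20).
#' @param n_top_intervention miRNAs summarized in the intervention
#'   table (default 5).
#' @return a list of class `mirinf_config`.
#' @export
pipelineConfig <- function(mirna_counts, gene_counts, pairing,
                           target_map, ppi, out_dir,
                           de_method = "nb_wald", de_alpha = 0.05,
                           gate_influence = TRUE,
                           apportion_mode = "per_patient",
                           rho_threshold = 0.3, ppi_min_score = 150,
                           top_k = 20, n_top_intervention = 5) {
  cfg <- list(mirna_counts = mirna_counts, gene_counts = gene_counts,
              pairing = pairing, target_map = target_map, ppi = ppi,
              out_dir = out_dir, de_method = de_method,
              de_alpha = de_alpha, gate_influence = gate_influence,
              apportion_mode = apportion_mode,
              rho_threshold = rho_threshold,
              ppi_min_score = ppi_min_score, top_k = top_k,
              n_top_intervention = n_top_intervention)
  class(cfg) <- "mirinf_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return a list of class `mirinf_config`.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

.checkInputsExist <- function(config) {
  for (key in c("mirna_counts", "gene_counts", "pairing", "target_map",
                "ppi")) {
    p <- config[[key]]
    if (is.null(p) || !file.exists(p))
      stop("input file for '", key, "' not found: ",
           if (is.null(p)) "<missing>" else p)
  }
}

#' Cross-file consistency report
#'
#' Reads all five inputs and reports how many miRNAs and genes are
#' shared between the expression matrices and the target map, how many
#' genes the filtered PPI covers, and the number of patients. Warns on
#' empty intersections and on PPI coverage below half of the expressed
#' target genes; an empty analyzable (miRNA, gene) set is a hard error.
#'
#' @param config a list from [pipelineConfig()].
#' @return list of counts (`n_patients`, `n_mirnas_shared`,
#'   `n_genes_shared`, `n_genes_in_ppi`, `ppi_coverage`).
#' @export
validateInputs <- function(config) {
  .checkInputsExist(config)
  mir <- readExpression(config$mirna_counts, config$pairing)
  gen <- readExpression(config$gene_counts, config$pairing)
  tm <- readTargetMap(config$target_map)
  ppi <- readPPI(config$ppi, min_score = config$ppi_min_score)
  ed <- targetEdges(tm)
  shared_m <- intersect(unique(ed$mirna), rownames(mir))
  shared_g <- intersect(unique(ed$gene), rownames(gen))
  if (length(shared_m) == 0L || length(shared_g) == 0L)
    stop("no analyzable (miRNA, gene) pair: the target map shares ",
         length(shared_m), " miRNA(s) and ", length(shared_g),
         " gene(s) with the expression data")
  in_ppi <- intersect(shared_g, names(ppi@degree))
  cov <- length(in_ppi) / length(shared_g)
  if (cov < 0.5)
    warning(sprintf("the filtered PPI covers only %.0f%% of the %d expressed target genes",
                    100 * cov, length(shared_g)))
  list(n_patients = nrow(pairing(mir)),
       n_mirnas_shared = length(shared_m),
       n_genes_shared = length(shared_g),
       n_genes_in_ppi = length(in_ppi),
       ppi_coverage = cov)
}

#' Run the full influence pipeline
#'
#' Executes every stage in order and writes all result tables (see
#' [writeReport()]) plus `manifest.json` (configuration echo, input
#' checksums, per-stage counts) into `out_dir`.
#'
#' @param config a list from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return invisibly, an [InfluenceReport-class].
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "mirinf_config"))
  .checkInputsExist(config)
  mir <- rpmNormalize(readExpression(config$mirna_counts,
                                     config$pairing))
  gen <- rpmNormalize(readExpression(config$gene_counts,
                                     config$pairing))
  tm <- readTargetMap(config$target_map)
  ppi <- readPPI(config$ppi, min_score = config$ppi_min_score)

  deM <- callDifferential(mir, alpha = config$de_alpha,
                          method = config$de_method)
  deG <- callDifferential(gen, alpha = config$de_alpha,
                          method = config$de_method)

  dM <- pairedDeltas(mir)
  dG <- pairedDeltas(gen)

  ed <- targetEdges(tm)
  if (isTRUE(config$gate_influence)) {
    keep <- ed$mirna %in% deM$feature[deM$flagged] &
      ed$gene %in% deG$feature[deG$flagged]
    ed <- ed[keep, , drop = FALSE]
  }
  edges <- if (nrow(ed)) {
    computeRegulationEdges(dM, dG, TargetMap(ed),
                           mode = config$apportion_mode)
  } else {
    warning("no target-map edge passes the DE gate; report is empty")
    computeRegulationEdges(dM, dG, TargetMap(ed[0, , drop = FALSE]))
  }

  gi <- globalInfluence(edges, ppi)
  ranked <- if (nrow(gi)) rankMirnas(gi, top_k = nrow(gi)) else
    data.frame(rank = integer(), mirna = character(),
               score = numeric(), n_targets_used = integer())
  calls <- interventionCalls(edges, deM, deG)
  btab <- interventionTable(calls, ranked$mirna,
                            n_top = config$n_top_intervention)
  rdist <- rhoDistribution(edges, threshold = config$rho_threshold)

  report <- new("InfluenceReport", edges = edges, global = ranked,
                calls = calls, binTable = btab, deMirna = deM,
                deGene = deG,
                meta = list(config = unclass(config),
                            rho_summary = rdist[c("n_positive",
                                                  "n_negative")],
                            n_edges = nrow(edges),
                            de_counts = as.list(deCounts(deM, deG))))
  writeReport(report, config$out_dir, top_k = config$top_k)
  manifest <- list(
    config = unclass(config),
    inputs = as.list(tools::md5sum(vapply(
      c("mirna_counts", "gene_counts", "pairing", "target_map", "ppi"),
      function(k) config[[k]], ""))),
    counts = list(
      n_patients = nrow(pairing(mir)),
      n_demir = unname(deCounts(deM, deG)[1L]),
      n_deg = unname(deCounts(deM, deG)[2L]),
      n_edges = nrow(edges),
      n_ranked = nrow(ranked),
      rho_positive = rdist$n_positive,
      rho_negative = rdist$n_negative))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
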