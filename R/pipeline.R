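#' Classify the driver-gene inactivation mechanism per tumor sample
#'
#' For each tumor sample of a driver cohort (see
#' [simulateDriverCohort()]): summarize the driver's exon log2 ratios to
#' a copy-number category, aggregate the per-site LOH calls over the gene,
#' call the candidate mutation with the somatic caller, combine the three
#' with [classifyInactivation()], and report the driver's expression
#' relative to the control group.
#'
#' @param driver list as returned by [simulateDriverCohort()].
#' @param rpkm RPKM matrix whose tumor columns match the cohort's sample
#'   names.
#' @param driver_gene the driver gene identifier (must be a row of
#'   `rpkm`).
#' @param controls character vector of control column names of `rpkm`.
#' @param seed seed forwarded to the somatic caller.
#' @return data.frame (sample, cna_category, loh_status, has_mutation,
#'   mechanism, biallelic, relative_expression).
#' @export
classifyDriver <- function(driver, rpkm, driver_gene, controls, seed = 1L) {
  if (!driver_gene %in% rownames(rpkm))
    stop("driver gene absent from the expression matrix: ", driver_gene)
  rows <- lapply(names(driver$samples), function(s) {
    ds <- driver$samples[[s]]
    cna <- geneLevelLog2(ds$exons)
    cat <- cna$category[cna$gene == driver_gene]
    loh <- aggregateLOH(callLOH(ds$loh_vafs))
    has_mut <- FALSE
    if (nSites(ds$mutation) > 0) {
      calls <- callSomatic(ds$mutation, seed = seed)
      kept <- filterVariants(calls, ds$annotation)
      has_mut <- nrow(somaticCalls(kept)) > 0
    }
    cls <- classifyInactivation(cat, loh, has_mut)
    data.frame(sample = s, cna_category = cat, loh_status = loh,
               has_mutation = has_mut, mechanism = cls$mechanism,
               biallelic = cls$biallelic,
               relative_expression =
                 relativeExpression(rpkm, driver_gene, s, controls),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a cohort under `config`, then runs every stage in order:
#' somatic calling with consequence/rarity filtering, gene-level
#' copy-number and LOH calling with the windowed Z-statistic, RPKM
#' quantification with the negative binomial DEG test and asymmetric
#' selection, gene-set over-representation with cancer-gene intersection
#' ranking and subgroup scoring, and the per-sample driver mechanism
#' table. All stage outputs are written as TSV under `out_dir` together
#' with a `manifest.json` (every threshold echoed) and a `report.json`
#' (per-stage record counts, truth-recovery metrics and the md5 hashes of
#' all outputs). Outputs are byte-identical across reruns of the same
#' configuration.
#'
#' @param config a [SimConfig-class].
#' @param out_dir output directory (created if needed).
#' @param min_depth,p_max,frac_min,n_perm somatic thresholds (see
#'   [callSomatic()]).
#' @param af_max rarity cut-off (see [filterVariants()]).
#' @param window_bp,z_threshold,min_probes window scan parameters (see
#'   [windowedZ()]).
#' @param up_p,down_p,lfc,rpkm_floor DEG thresholds (see [selectDEGs()]).
#' @param q_max enrichment q cut-off (see [hypergeomEnrich()]).
#' @return the report, invisibly (a named list mirroring `report.json`).
#' @export
runPipeline <- function(config = simConfig(), out_dir,
                        min_depth = 8, p_max = 0.05, frac_min = 0.9,
                        n_perm = 10000L, af_max = 0.01,
                        window_bp = 1e6, z_threshold = 4, min_probes = 10,
                        up_p = 0.05, down_p = 0.001, lfc = 1,
                        rpkm_floor = 0.5, q_max = 0.05) {
  stopifnot(is(config, "SimConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, ...)

  cohort <- simulateCohort(config)

  ## stage 1: somatic calling
  calls <- callSomatic(cohort$paired, min_depth = min_depth, p_max = p_max,
                       frac_min = frac_min, n_perm = n_perm,
                       seed = config@seed)
  filtered <- filterVariants(calls, cohort$annotations, af_max = af_max)
  writePairedSitesTsv(cohort$paired, path("paired_sites.tsv"))
  write_tsv(somaticCalls(calls), path("somatic_calls.tsv"))
  write_tsv(volcanoTable(calls), path("volcano.tsv"))
  write_tsv(somaticCalls(filtered), path("filtered_calls.tsv"))

  ## stage 2: copy number and LOH
  gene_cna <- geneLevelLog2(cohort$cnv$exons)
  loh_calls <- callLOH(cohort$cnv$loh_vafs)
  windows <- windowedZ(cohort$cnv$probes, window_bp = window_bp,
                       z_threshold = z_threshold, min_probes = min_probes)
  write_tsv(gene_cna, path("gene_cna.tsv"))
  write_tsv(loh_calls, path("loh_calls.tsv"))
  write_tsv(windows, path("windows.tsv"))

  ## stage 3: expression
  rpkm <- computeRPKM(cohort$counts)
  groups <- SummarizedExperiment::colData(cohort$counts)$group
  nb <- nbTest(cohort$counts)
  degs <- selectDEGs(nb, rpkm, groups, up_p = up_p, down_p = down_p,
                     lfc = lfc, rpkm_floor = rpkm_floor)
  writeCountsTsv(cohort$counts, path("rna"))
  write_tsv(degs, path("deg.tsv"))

  ## stage 4: enrichment, ranking, subgroups
  query <- degs$gene[degs$direction != "NONE"]
  enr <- hypergeomEnrich(query, cohort$sets, q_max = q_max)
  om <- overlapMatrix(enr, cohort$sets, genes = query)
  ranked <- cancerIntersectRank(om, cohort$cancer_genes, nb)
  meta <- S4Vectors::metadata(cohort$counts)
  tumors <- colnames(rpkm)[groups == "tumor"]
  controls <- colnames(rpkm)[groups == "control"]
  subgroups <- do.call(rbind, lapply(tumors, function(s) {
    sc <- subgroupScore(rpkm, s, meta$signatures, meta$reference_gene)
    data.frame(sample = s, label = sc$label,
               t(sc$scores), stringsAsFactors = FALSE)
  }))
  writeGMT(cohort$sets, path("gene_sets.gmt"))
  writeLines(cohort$cancer_genes, con = path("cancer_genes.txt"), sep = "\n")
  write_tsv(enr, path("enrichment.tsv"))
  write_tsv(data.frame(gene = rownames(om), om, check.names = FALSE),
            path("overlap_matrix.tsv"))
  write_tsv(ranked, path("ranked_candidates.tsv"))
  write_tsv(subgroups, path("subgroups.tsv"))

  ## stage 5: driver mechanism table
  driver_tab <- classifyDriver(cohort$driver, rpkm, config@driver_gene,
                               controls, seed = config@seed)
  write_tsv(driver_tab, path("driver_mechanisms.tsv"))

  ## truth recovery
  truth <- cohort$truth
  cd <- somaticCalls(calls)
  som_true <- truth@somatic_sites$site_id
  called <- cd$site_id[cd$verdict == "SOMATIC"]
  sens <- if (length(som_true)) mean(som_true %in% called) else NA_real_
  germ_fp <- if (length(truth@germline_sites))
    mean(truth@germline_sites %in% called) else NA_real_
  dirn <- stats::setNames(degs$direction, degs$gene)
  de_truth <- truth@de_genes
  de_recovered <- if (nrow(de_truth))
    mean(dirn[de_truth$gene] == de_truth$direction) else NA_real_
  label_truth <- truth@subgroup_labels
  sg <- stats::setNames(subgroups$label, subgroups$sample)
  sg_agree <- if (length(label_truth))
    mean(sg[names(label_truth)] == label_truth) else NA_real_

  manifest <- list(
    package_version = as.character(utils::packageVersion("PairedTumorKit")),
    config = .config_as_list(config),
    thresholds = list(min_depth = min_depth, p_max = p_max,
                      frac_min = frac_min, n_perm = n_perm,
                      af_max = af_max, window_bp = window_bp,
                      z_threshold = z_threshold, min_probes = min_probes,
                      up_p = up_p, down_p = down_p, lfc = lfc,
                      rpkm_floor = rpkm_floor, q_max = q_max))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  outputs <- sort(setdiff(list.files(out_dir), "report.json"))
  hashes <- tools::md5sum(file.path(out_dir, outputs))
  names(hashes) <- outputs
  report <- list(
    counts = list(
      sites_tested = nrow(cd),
      somatic_calls = sum(cd$verdict == "SOMATIC"),
      filtered_calls = nrow(somaticCalls(filtered)),
      genes_cna = nrow(gene_cna),
      loh_calls = sum(loh_calls$status == "LOH"),
      flagged_windows = sum(windows$flagged),
      deg_up = sum(degs$direction == "UP"),
      deg_down = sum(degs$direction == "DOWN"),
      enriched_sets = sum(enr$enriched),
      ranked_candidates = nrow(ranked),
      subgroup_calls = nrow(subgroups)),
    truth_recovery = list(
      somatic_sensitivity = sens,
      germline_false_positive_rate = germ_fp,
      de_direction_recovery = de_recovered,
      top_gene = if (nrow(ranked)) ranked$gene[1] else NA_character_,
      top_gene_is_truth = if (nrow(ranked))
        identical(ranked$gene[1], truth@top_gene) else FALSE,
      subgroup_agreement = sg_agree,
      driver_all_biallelic = all(driver_tab$biallelic |
                                 driver_tab$mechanism ==
                                 "NO_BIALLELIC_EVIDENCE"),
      driver_mechanisms = as.list(stats::setNames(driver_tab$mechanism,
                                                  driver_tab$sample)),
      driver_relative_expression =
        as.list(stats::setNames(driver_tab$relative_expression,
                                driver_tab$sample))),
    output_md5 = as.list(hashes))
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}

.config_as_list <- function(config) {
  nms <- slotNames("SimConfig")
  out <- lapply(nms, function(nm) {
    v <- slot(config, nm)
    if (is.data.frame(v)) as.list(v) else v
  })
  names(out) <- nms
  out
}
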