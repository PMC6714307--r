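#' @import methods
NULL

#' Simulation configuration for a synthetic paired tumor/normal cohort
#'
#' `SimConfig` bundles every parameter of the synthetic cohort generator:
#' the sequencing design (number of sites, mean depth, tumor purity), the
#' planted somatic/germline structure, the RNA-seq design (genes, samples,
#' negative binomial dispersion, planted differential expression), the
#' copy-number tracks, and the gene-set collection. A single integer seed
#' makes every generator deterministic.
#'
#' @slot n_sites total number of exome variant sites to simulate.
#' @slot n_somatic number of planted somatic sites (subset of `n_sites`).
#' @slot germline_het_rate fraction of the non-somatic sites that are
#'   germline heterozygous (VAF ~ 0.5 in both samples); the remainder are
#'   homozygous-reference sites carrying only sequencing error.
#' @slot depth_mean mean per-sample read depth; per-site depths are Poisson.
#' @slot purity tumor purity in (0, 1]; scales the observed somatic VAF.
#' @slot somatic_vaf cell-level variant allele fraction of planted somatic
#'   variants (observed tumor VAF is `purity * somatic_vaf`).
#' @slot error_rate per-base sequencing error rate used for the alternate
#'   allele at reference and (normal-sample) somatic sites.
#' @slot loh_regions data.frame (chrom, start, end) of planted regions of
#'   loss of heterozygosity: germline-het sites inside them drift to a
#'   homozygous tumor VAF while the normal stays heterozygous.
#' @slot n_genes,n_tumors,n_controls RNA-seq design: genes by samples.
#' @slot nb_dispersion negative binomial dispersion of the count generator.
#' @slot libsize_sd standard deviation (log scale) of the log-normal
#'   library-size factors.
#' @slot de_up_frac,de_down_frac fractions of genes planted up/down; their
#'   ratio is the planted up:down ratio (kept within 1.5--3 by default).
#' @slot lfc_magnitude absolute planted log2 fold change for DE genes.
#' @slot driver_gene identifier of the planted biallelically inactivated
#'   tumor-suppressor gene (SMARCB1 analog).
#' @slot driver_lfc planted expression log2 fold change of the driver gene
#'   in tumors (must be <= -2).
#' @slot n_gene_sets,n_enriched_sets,set_size gene-set collection design.
#' @slot n_cancer_genes size of the synthetic cancer-gene list.
#' @slot probe_spacing array probe spacing in bp for the copy-number track.
#' @slot noise_sd Gaussian noise sd of exon/probe log2 ratios.
#' @slot seed integer seed controlling all generators.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @export
setClass("SimConfig",
  representation(
    n_sites = "numeric", n_somatic = "numeric",
    germline_het_rate = "numeric", depth_mean = "numeric",
    purity = "numeric", somatic_vaf = "numeric", error_rate = "numeric",
    loh_regions = "data.frame",
    n_genes = "numeric", n_tumors = "numeric", n_controls = "numeric",
    nb_dispersion = "numeric", libsize_sd = "numeric",
    de_up_frac = "numeric", de_down_frac = "numeric",
    lfc_magnitude = "numeric",
    driver_gene = "character", driver_lfc = "numeric",
    n_gene_sets = "numeric", n_enriched_sets = "numeric",
    set_size = "numeric", n_cancer_genes = "numeric",
    probe_spacing = "numeric", noise_sd = "numeric",
    seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  for (nm in c("n_sites", "n_somatic", "germline_het_rate", "depth_mean",
               "purity", "somatic_vaf", "error_rate", "n_genes", "n_tumors",
               "n_controls", "nb_dispersion", "libsize_sd", "de_up_frac",
               "de_down_frac", "lfc_magnitude", "driver_lfc", "n_gene_sets",
               "n_enriched_sets", "set_size", "n_cancer_genes",
               "probe_spacing", "noise_sd", "seed")) {
    if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
      msg <- c(msg, sprintf("'%s' must be a single finite value", nm))
  }
  if (length(msg)) return(msg)
  if (object@depth_mean <= 0) msg <- c(msg, "depth_mean must be > 0")
  if (object@n_sites <= 0) msg <- c(msg, "n_sites must be > 0")
  if (object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "purity must be in (0, 1]")
  if (object@somatic_vaf < 0 || object@somatic_vaf > 1)
    msg <- c(msg, "somatic_vaf must be in [0, 1]")
  if (object@germline_het_rate < 0 || object@germline_het_rate > 1)
    msg <- c(msg, "germline_het_rate must be in [0, 1]")
  if (object@error_rate < 0 || object@error_rate > 0.5)
    msg <- c(msg, "error_rate must be in [0, 0.5]")
  if (object@n_somatic > object@n_sites)
    msg <- c(msg, "n_somatic cannot exceed n_sites")
  if (object@de_down_frac > 0) {
    r <- object@de_up_frac / object@de_down_frac
    if (r < 1 - 1e-9)
      msg <- c(msg, "de_up_frac must be >= de_down_frac (up:down ratio >= 1)")
  }
  if (object@driver_lfc > -2)
    msg <- c(msg, "driver_lfc must be <= -2 (biallelic inactivation analog)")
  if (abs(object@seed) >= 2^31)
    msg <- c(msg, "seed must fit in a 32-bit integer")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic cohort
#'
#' Container for everything the generators planted, used to score the
#' downstream stages: somatic/germline site labels, LOH sites, deleted
#' genes, DE genes, enriched gene sets, the designated top cancer gene,
#' the driver gene and the per-sample subgroup labels.
#'
#' @slot somatic_sites data.frame (site_id, true_vaf) of planted somatic sites.
#' @slot germline_sites character vector of germline heterozygous site ids.
#' @slot loh_sites character vector of site ids inside planted LOH regions.
#' @slot deleted_genes data.frame (gene, true_log2, class) of planted
#'   copy-number losses.
#' @slot cna_windows data.frame (chrom, start, end, shift) of planted
#'   aberrant 1-Mb probe windows.
#' @slot de_genes data.frame (gene, direction, true_lfc) of planted DE genes.
#' @slot enriched_sets names of the planted enriched gene sets.
#' @slot top_gene the planted top cancer gene (NPM1 analog).
#' @slot driver_gene the planted inactivated driver (SMARCB1 analog).
#' @slot subgroup_labels named character vector, tumor sample -> subgroup.
#' @export
setClass("TruthSet",
  representation(
    somatic_sites = "data.frame", germline_sites = "character",
    loh_sites = "character", deleted_genes = "data.frame",
    cna_windows = "data.frame", de_genes = "data.frame",
    enriched_sets = "character", top_gene = "character",
    driver_gene = "character", subgroup_labels = "character"
  ),
  prototype(
    somatic_sites = data.frame(site_id = character(), true_vaf = numeric()),
    germline_sites = character(), loh_sites = character(),
    deleted_genes = data.frame(gene = character(), true_log2 = numeric(),
                               class = character()),
    cna_windows = data.frame(chrom = character(), start = numeric(),
                             end = numeric(), shift = numeric()),
    de_genes = data.frame(gene = character(), direction = character(),
                          true_lfc = numeric()),
    enriched_sets = character(), top_gene = character(),
    driver_gene = character(), subgroup_labels = character()
  )
)

setValidity("TruthSet", function(object) {
  msg <- character()
  som <- object@somatic_sites$site_id
  if (anyDuplicated(som)) msg <- c(msg, "duplicated somatic site ids")
  if (length(intersect(som, object@germline_sites)))
    msg <- c(msg, "somatic and germline site labels must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Paired tumor/normal allele depths at variant sites
#'
#' One row per variant site with the high-quality read counts supporting
#' the reference and the alternate allele in the tumor and in the matched
#' normal sample. This is the unit of somatic testing.
#'
#' @slot data data.frame with columns `site_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `t_ref`, `t_alt`, `n_ref`, `n_alt`.
#' @seealso [PairedSites()], [callSomatic()]
#' @export
setClass("PairedSites", representation(data = "data.frame"))

.paired_cols <- c("site_id", "chrom", "pos", "ref", "alt",
                  "t_ref", "t_alt", "n_ref", "n_alt")

setValidity("PairedSites", function(object) {
  d <- object@data
  msg <- character()
  missing <- setdiff(.paired_cols, names(d))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (nrow(d)) {
    if (any(d$pos < 1)) msg <- c(msg, "pos must be >= 1")
    if (any(d$ref == d$alt)) msg <- c(msg, "ref and alt must differ")
    cnt <- as.matrix(d[, c("t_ref", "t_alt", "n_ref", "n_alt")])
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "read counts must be non-negative integers")
    if (anyDuplicated(d$site_id)) msg <- c(msg, "site_id must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Somatic call set
#'
#' Per-site result of the somatic selection: VAFs, permutation p-value,
#' VAF_frac, filter flags and the verdict, plus the thresholds used.
#' A site is `SOMATIC` if and only if its filter set is empty.
#'
#' @slot calls data.frame with one row per input site (input order kept):
#'   `site_id`, `chrom`, `pos`, `ref`, `alt`, `vaf_tumor`, `vaf_normal`,
#'   `p_perm`, `vaf_frac`, `neg_log10_p`, `filters` (semicolon-joined flags
#'   among LOW_DEPTH, GERMLINE_LIKE, FAIL_P, FAIL_FRAC; "" if none),
#'   `verdict` ("SOMATIC" or "REJECTED").
#' @slot params list of thresholds (min_depth, p_max, frac_min, n_perm,
#'   exact_cap, seed).
#' @seealso [callSomatic()], [volcanoTable()]
#' @export
setClass("SomaticCallSet",
         representation(calls = "data.frame", params = "list"))

setValidity("SomaticCallSet", function(object) {
  d <- object@calls
  need <- c("site_id", "vaf_tumor", "vaf_normal", "p_perm", "vaf_frac",
            "filters", "verdict")
  missing <- setdiff(need, names(d))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  bad <- d$verdict == "SOMATIC" & nzchar(d$filters)
  if (any(bad)) return("verdict SOMATIC requires an empty filter set")
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(d$p_perm) || !ok(d$vaf_tumor) || !ok(d$vaf_normal) ||
      !ok(d$vaf_frac))
    return("VAFs, p_perm and vaf_frac must lie in [0, 1]")
  TRUE
})

#' Named gene-set collection over a gene universe
#'
#' Sets are harmonized at construction: duplicate members are collapsed
#' and genes outside the universe are dropped.
#'
#' @slot sets named list of character vectors of gene identifiers.
#' @slot universe character vector: all genes considered (typically every
#'   gene tested for differential expression).
#' @seealso [GeneSetList()], [hypergeomEnrich()]
#' @export
setClass("GeneSetList",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetList", function(object) {
  if (length(object@sets) && is.null(names(object@sets)))
    return("sets must be named")
  if (anyDuplicated(names(object@sets))) return("set names must be unique")
  if (anyDuplicated(object@universe)) return("universe must be unique")
  out <- vapply(object@sets,
                function(s) any(!s %in% object@universe) || anyDuplicated(s) > 0,
                logical(1))
  if (any(out)) return("sets must be deduplicated subsets of the universe")
  TRUE
})

#' RNA-seq raw count container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `counts` assay of non-negative integers, per-gene transcript lengths in
#' `rowData()$gene_length` (bp), and per-sample metadata in `colData()`:
#' `group` ("tumor" or "control") and `total_mapped` (reads; defaults to
#' the column sums when not supplied).
#'
#' @seealso [RNACountSet()], [computeRPKM()], [nbTest()]
#' @export
#' @import SummarizedExperiment
setClass("RNACountSet", contains = "SummarizedExperiment")

setValidity("RNACountSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  k <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.finite(k)) || any(k < 0) || any(k != round(k)))
    msg <- c(msg, "counts must be non-negative integers")
  rd <- SummarizedExperiment::rowData(object)
  if (!"gene_length" %in% names(rd) || any(rd$gene_length <= 0))
    msg <- c(msg, "rowData()$gene_length must be present and > 0")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% names(cd) ||
      !all(cd$group %in% c("tumor", "control")))
    msg <- c(msg, "colData()$group must be 'tumor' or 'control'")
  if (!"total_mapped" %in% names(cd) || any(cd$total_mapped <= 0))
    msg <- c(msg, "colData()$total_mapped must be present and > 0")
  if (length(msg)) msg else TRUE
})
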