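#' @include AllClasses.R
NULL

#' Accessors for PairedTumorKit containers
#'
#' Small accessor generics for the S4 containers: `siteData()` returns the
#' per-site data.frame of a [PairedSites-class]; `nSites()` its row count;
#' `somaticCalls()` and `callParams()` the call table and thresholds of a
#' [SomaticCallSet-class]; `volcanoTable()` its (vaf_frac, -log10 p) table;
#' `geneSets()` and `geneUniverse()` the list of sets and the universe of a
#' [GeneSetList-class].
#'
#' @param x the object.
#' @return see details above; data.frames, vectors or lists.
#' @name accessors
#' @aliases siteData nSites somaticCalls callParams volcanoTable geneSets
#'   geneUniverse
NULL

#' @rdname accessors
#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))
#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("somaticCalls", function(x) standardGeneric("somaticCalls"))
#' @rdname accessors
#' @export
setGeneric("callParams", function(x) standardGeneric("callParams"))
#' @rdname accessors
#' @export
setGeneric("volcanoTable", function(x) standardGeneric("volcanoTable"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname accessors
setMethod("siteData", "PairedSites", function(x) x@data)
#' @rdname accessors
setMethod("nSites", "PairedSites", function(x) nrow(x@data))
#' @rdname accessors
setMethod("somaticCalls", "SomaticCallSet", function(x) x@calls)
#' @rdname accessors
setMethod("callParams", "SomaticCallSet", function(x) x@params)
#' @rdname accessors
setMethod("volcanoTable", "SomaticCallSet", function(x) {
  x@calls[, c("site_id", "vaf_frac", "neg_log10_p")]
})
#' @rdname accessors
setMethod("geneSets", "GeneSetList", function(x) x@sets)
#' @rdname accessors
setMethod("geneUniverse", "GeneSetList", function(x) x@universe)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  exome : %d sites (%d somatic), depth %g, purity %g, VAF %g\n",
              as.integer(object@n_sites), as.integer(object@n_somatic),
              object@depth_mean, object@purity, object@somatic_vaf))
  cat(sprintf("  rna   : %d genes, %d tumors vs %d controls, dispersion %g\n",
              as.integer(object@n_genes), as.integer(object@n_tumors),
              as.integer(object@n_controls), object@nb_dispersion))
  cat(sprintf("  de    : up %g / down %g (ratio %.2f), |lfc| %g, driver %s (%g)\n",
              object@de_up_frac, object@de_down_frac,
              if (object@de_down_frac > 0)
                object@de_up_frac / object@de_down_frac else NA_real_,
              object@lfc_magnitude, object@driver_gene, object@driver_lfc))
  cat(sprintf("  sets  : %d (of which %d enriched), size %d; seed %d\n",
              as.integer(object@n_gene_sets),
              as.integer(object@n_enriched_sets),
              as.integer(object@set_size), as.integer(object@seed)))
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet\n")
  cat(sprintf("  sites : %d somatic, %d germline, %d LOH\n",
              nrow(object@somatic_sites), length(object@germline_sites),
              length(object@loh_sites)))
  cat(sprintf("  cna   : %d deleted genes, %d aberrant windows\n",
              nrow(object@deleted_genes), nrow(object@cna_windows)))
  cat(sprintf("  de    : %d genes (%d up / %d down)\n",
              nrow(object@de_genes),
              sum(object@de_genes$direction == "UP"),
              sum(object@de_genes$direction == "DOWN")))
  cat(sprintf("  sets  : %d enriched; top gene %s; driver %s\n",
              length(object@enriched_sets),
              if (length(object@top_gene)) object@top_gene else "<none>",
              if (length(object@driver_gene)) object@driver_gene else "<none>"))
})

setMethod("show", "PairedSites", function(object) {
  cat(sprintf("PairedSites with %d sites\n", nrow(object@data)))
  if (nrow(object@data)) {
    print(utils::head(object@data, 5), row.names = FALSE)
    if (nrow(object@data) > 5) cat("  ...\n")
  }
})

setMethod("show", "SomaticCallSet", function(object) {
  d <- object@calls
  cat(sprintf("SomaticCallSet: %d sites, %d SOMATIC\n",
              nrow(d), sum(d$verdict == "SOMATIC")))
  p <- object@params
  cat(sprintf("  thresholds: min_depth %s, p_max %s, frac_min %s, n_perm %s\n",
              p$min_depth, p$p_max, p$frac_min, p$n_perm))
})

setMethod("show", "GeneSetList", function(object) {
  cat(sprintf("GeneSetList: %d sets over a universe of %d genes\n",
              length(object@sets), length(object@universe)))
})

#' Construct a PairedSites object
#'
#' @param data data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `t_ref`, `t_alt`, `n_ref`, `n_alt` and optionally `site_id`
#'   (generated as `chrom:pos` when absent).
#' @return a [PairedSites-class] object.
#' @examples
#' PairedSites(data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T",
#'                        t_ref = 60, t_alt = 40, n_ref = 99, n_alt = 1))
#' @export
PairedSites <- function(data) {
  data <- as.data.frame(data)
  if (!"site_id" %in% names(data) && all(c("chrom", "pos") %in% names(data)))
    data$site_id <- paste0(data$chrom, ":", data$pos)
  data <- data[, intersect(c(.paired_cols, setdiff(names(data), .paired_cols)),
                           names(data)), drop = FALSE]
  rownames(data) <- NULL
  new("PairedSites", data = data)
}

#' Construct a gene-set collection
#'
#' Genes outside the universe are dropped (with a warning) and duplicate
#' members within a set are collapsed.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of all genes under consideration.
#' @return a [GeneSetList-class] object.
#' @examples
#' GeneSetList(list(a = c("g1", "g2")), universe = paste0("g", 1:10))
#' @export
GeneSetList <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  n_out <- sum(vapply(sets, function(s) sum(!s %in% universe), numeric(1)))
  if (n_out > 0)
    warning(sprintf("%d set member(s) outside the universe were dropped",
                    n_out))
  sets <- lapply(sets, function(s) intersect(s, universe))
  new("GeneSetList", sets = sets, universe = universe)
}

#' Construct an RNA count container
#'
#' @param counts integer matrix, genes x samples (dimnames required).
#' @param gene_lengths numeric vector of transcript lengths in bp, one per
#'   gene (recycled by name when named).
#' @param groups character vector per sample, "tumor" or "control".
#' @param total_mapped optional per-sample total mapped reads; defaults to
#'   the column sums of `counts`.
#' @return an [RNACountSet-class] object.
#' @examples
#' m <- matrix(rpois(20, 50), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' RNACountSet(m, gene_lengths = rep(1000, 4),
#'             groups = c("tumor", "tumor", "control", "control", "control"))
#' @export
RNACountSet <- function(counts, gene_lengths, groups, total_mapped = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (gene) and column (sample) names")
  if (!is.null(names(gene_lengths)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths must match the number of genes")
  if (length(groups) != ncol(counts))
    stop("groups must match the number of samples")
  if (is.null(total_mapped)) total_mapped <- colSums(counts)
  if (all(is.finite(counts)) && all(counts == round(counts)) &&
      max(counts) < .Machine$integer.max)
    storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_length = as.numeric(gene_lengths)),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   total_mapped = as.numeric(total_mapped),
                                   row.names = colnames(counts))
  )
  new("RNACountSet", se)
}
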