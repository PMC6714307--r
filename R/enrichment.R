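#' Hypergeometric gene-set over-representation
#'
#' For each set of size K in a universe of size N, with a query of size n
#' overlapping the set in k genes, the enrichment p-value is the upper
#' hypergeometric tail `P(X >= k)`. p-values are BH-corrected across the
#' collection and records are returned sorted by p ascending with the set
#' name as a deterministic tie-break. Query genes outside the universe
#' are dropped with a warning.
#'
#' @param query character vector of query genes (e.g. the DEG list).
#' @param collection a [GeneSetList-class].
#' @param q_max records with BH q at or below this are flagged enriched
#'   (default 0.05).
#' @return data.frame (set, k, K, n, N, p, q, enriched).
#' @examples
#' gs <- GeneSetList(list(s1 = paste0("g", 1:5)),
#'                   universe = paste0("g", 1:20))
#' hypergeomEnrich(paste0("g", 1:5), gs)  # p = 1 / choose(20, 5)
#' @export
hypergeomEnrich <- function(query, collection, q_max = 0.05) {
  stopifnot(is(collection, "GeneSetList"))
  uni <- geneUniverse(collection)
  if (!length(uni)) stop("empty universe")
  query <- unique(query)
  out <- setdiff(query, uni)
  if (length(out)) {
    warning(length(out), " query gene(s) outside the universe were dropped")
    query <- intersect(query, uni)
  }
  if (!length(query)) stop("empty query after universe harmonization")
  sets <- geneSets(collection)
  N <- length(uni); n <- length(query)
  K <- vapply(sets, length, integer(1))
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(set = names(sets), k = k, K = K, n = n, N = N, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  res$enriched <- res$q <= q_max
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene-by-set overlap matrix of the enriched sets
#'
#' Binary matrix over the enriched sets; rows are restricted to genes
#' belonging to at least one enriched set. Column sums equal the sets'
#' sizes restricted to those genes; intersecting the rows with a query
#' reproduces the per-set overlap counts.
#'
#' @param enrichment data.frame from [hypergeomEnrich()].
#' @param collection the [GeneSetList-class] that was tested.
#' @param genes optional gene subset to which rows are further restricted
#'   (e.g. the DEG list, giving per-set column sums equal to `k`).
#' @return integer matrix, genes x enriched sets (possibly 0 rows).
#' @export
overlapMatrix <- function(enrichment, collection, genes = NULL) {
  stopifnot(is(collection, "GeneSetList"))
  enr <- enrichment$set[enrichment$enriched]
  sets <- geneSets(collection)[enr]
  if (!length(sets))
    return(matrix(integer(), nrow = 0, ncol = 0))
  members <- sort(unique(unlist(sets)))
  if (!is.null(genes)) members <- intersect(members, genes)
  mat <- vapply(sets, function(s) as.integer(members %in% s),
                integer(length(members)))
  mat <- matrix(mat, nrow = length(members),
                dimnames = list(members, names(sets)))
  mat[rowSums(mat) > 0, , drop = FALSE]
}

#' Rank cancer-list genes among the enriched-set members
#'
#' Intersects the genes of the enriched sets with a cancer-gene list and
#' ranks the intersection by differential expression significance: DEG p
#' ascending, then |log2fc| descending, then gene name. Rank 1 is the top
#' candidate.
#'
#' @param overlap overlap matrix from [overlapMatrix()] (its rownames are
#'   the enriched-set genes), or a character vector of genes.
#' @param cancer_genes character vector: the cancer-gene list.
#' @param deg data.frame with columns `gene`, `p`, `log2fc`, covering the
#'   overlap genes.
#' @return data.frame (gene, p, log2fc, in_cancer_list, rank), possibly
#'   empty when the intersection is empty.
#' @export
cancerIntersectRank <- function(overlap, cancer_genes, deg) {
  genes <- if (is.matrix(overlap)) rownames(overlap) else as.character(overlap)
  hit <- intersect(genes, cancer_genes)
  if (!length(hit)) {
    message("no enriched-set gene is on the cancer list")
    return(data.frame(gene = character(), p = numeric(),
                      log2fc = numeric(), in_cancer_list = logical(),
                      rank = integer()))
  }
  idx <- match(hit, deg$gene)
  if (anyNA(idx))
    stop("deg must cover the overlap genes; missing: ",
         paste(hit[is.na(idx)], collapse = ", "))
  res <- data.frame(gene = hit, p = deg$p[idx], log2fc = deg$log2fc[idx],
                    in_cancer_list = TRUE, stringsAsFactors = FALSE)
  res <- res[order(res$p, -abs(res$log2fc), res$gene), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Score a sample against subgroup signatures relative to a reference gene
#'
#' For each subgroup, the score is the mean over its signature genes of
#' `log2((rpkm(gene) + eps) / (rpkm(reference) + eps))` in the sample; the
#' sample is labelled with the arg-max subgroup, or `UNCLASSIFIED` on a
#' tie. The reference gene must be expressed in the sample and may not be
#' a member of any signature.
#'
#' @param rpkm RPKM matrix.
#' @param sample sample (column) identifier.
#' @param signatures named list, subgroup -> character vector of genes.
#' @param reference_gene the reference gene identifier.
#' @param eps pseudo-RPKM (default 0.25, matching the expression module).
#' @return list with `label` and `scores` (named numeric).
#' @export
subgroupScore <- function(rpkm, sample, signatures, reference_gene,
                          eps = 0.25) {
  if (!reference_gene %in% rownames(rpkm))
    stop("reference gene absent from the expression matrix: ",
         reference_gene)
  if (reference_gene %in% unlist(signatures))
    stop("reference gene may not belong to a signature")
  if (!sample %in% colnames(rpkm)) stop("unknown sample: ", sample)
  ref <- rpkm[reference_gene, sample]
  if (ref <= 0) stop("reference gene not expressed in ", sample)
  scores <- vapply(signatures, function(gs) {
    if (!all(gs %in% rownames(rpkm)))
      stop("signature gene absent from the expression matrix")
    mean(log2((rpkm[gs, sample] + eps) / (ref + eps)))
  }, numeric(1))
  top <- which(scores == max(scores))
  list(label = if (length(top) == 1L) names(scores)[top] else "UNCLASSIFIED",
       scores = scores)
}
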