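#' RPKM expression matrix
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm(g, s) = counts(g, s) * 1e9 / (gene_length(g) * total_mapped(s))`.
#' `total_mapped` is taken from `colData()` (column sums of the counts by
#' default, or externally supplied totals).
#'
#' @param m an [RNACountSet-class].
#' @return numeric matrix of RPKM values, genes x samples.
#' @examples
#' cnt <- matrix(c(10, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' rcs <- RNACountSet(cnt, gene_lengths = c(1000, 500), groups = "tumor",
#'                    total_mapped = 1e6)
#' computeRPKM(rcs)  # 10 and 0
#' @export
computeRPKM <- function(m) {
  stopifnot(is(m, "RNACountSet"))
  validObject(m)
  k <- SummarizedExperiment::assay(m, "counts")
  len <- SummarizedExperiment::rowData(m)$gene_length
  tot <- SummarizedExperiment::colData(m)$total_mapped
  if (any(tot <= 0)) stop("total_mapped must be positive")
  sweep(k / len, 2, tot, `/`) * 1e9
}

# Median-of-ratios size factors (computed over genes with no zero count).
.size_factors <- function(counts) {
  logs <- log(counts)
  ok <- apply(is.finite(logs), 1, all)
  if (sum(ok) < 10)
    stop("too few genes without zeros for size-factor estimation")
  geo <- rowMeans(logs[ok, , drop = FALSE])
  apply(logs[ok, , drop = FALSE], 2, function(x) exp(stats::median(x - geo)))
}

#' Two-group negative binomial differential expression test
#'
#' Per gene: median-of-ratios size-factor normalization, a pooled
#' method-of-moments dispersion estimate shrunk toward a fitted
#' `a0 + a1/mean` dispersion--mean trend (weight `df / (df + prior_df)` on
#' the per-gene estimate), and a two-sided exact conditional test of equal
#' group means under the NB model: conditional on the total count of a
#' gene, the probability of a split at least as extreme (in probability)
#' as the observed tumor/control split is accumulated over all splits.
#' For genes whose total count exceeds `wald_cap` a Wald test on the
#' difference of log normalized group means is used instead. The log2
#' fold change (tumor vs control) is computed from normalized group means
#' with a pseudocount.
#'
#' @param m an [RNACountSet-class] with at least two samples per group.
#' @param prior_df prior degrees of freedom of the dispersion shrinkage
#'   (default 10).
#' @param pseudocount added to normalized group means for the fold change
#'   (default 0.5).
#' @param wald_cap total-count bound above which the Wald approximation
#'   replaces the exact conditional sum (default 50000).
#' @return data.frame (gene, base_mean, log2fc, p, q, all_zero) with BH
#'   q-values reported for transparency; all-zero genes get `p = 1`,
#'   `log2fc = 0` and `all_zero = TRUE`.
#' @export
nbTest <- function(m, prior_df = 10, pseudocount = 0.5, wald_cap = 50000) {
  stopifnot(is(m, "RNACountSet"))
  validObject(m)
  k <- SummarizedExperiment::assay(m, "counts")
  grp <- SummarizedExperiment::colData(m)$group
  a_idx <- which(grp == "control")
  b_idx <- which(grp == "tumor")
  if (length(a_idx) < 2 || length(b_idx) < 2)
    stop("need at least two samples per group")
  sf <- .size_factors(k)
  norm <- sweep(k, 2, sf, `/`)

  base_mean <- rowMeans(norm)
  xim <- mean(1 / sf)
  n <- ncol(k)
  # pooled within-group variance of normalized counts
  v_a <- apply(norm[, a_idx, drop = FALSE], 1, stats::var)
  v_b <- apply(norm[, b_idx, drop = FALSE], 1, stats::var)
  dfa <- length(a_idx) - 1; dfb <- length(b_idx) - 1
  v_pool <- (v_a * dfa + v_b * dfb) / (dfa + dfb)
  raw_disp <- pmax((v_pool - xim * base_mean) / base_mean^2, 1e-8)

  use <- base_mean > 0
  fit <- stats::lm(raw_disp[use] ~ I(1 / base_mean[use]))
  cf <- pmax(stats::coef(fit), 0)
  fitted_disp <- pmax(cf[1] + cf[2] / pmax(base_mean, 1e-8), 1e-8)
  w <- (dfa + dfb - 0) / (dfa + dfb + prior_df)
  disp <- pmax(w * raw_disp + (1 - w) * fitted_disp, 1e-8)

  SA <- sum(sf[a_idx]); SB <- sum(sf[b_idx])
  SA2 <- sum(sf[a_idx]^2); SB2 <- sum(sf[b_idx]^2)
  kA <- rowSums(k[, a_idx, drop = FALSE])
  kB <- rowSums(k[, b_idx, drop = FALSE])
  kS <- kA + kB
  q0 <- kS / (SA + SB)

  p <- vapply(seq_len(nrow(k)), function(g) {
    if (kS[g] == 0) return(1)
    muA <- q0[g] * SA; muB <- q0[g] * SB
    vA <- pmax(muA + disp[g] * q0[g]^2 * SA2, muA * (1 + 1e-8))
    vB <- pmax(muB + disp[g] * q0[g]^2 * SB2, muB * (1 + 1e-8))
    if (kS[g] <= wald_cap) {
      szA <- muA^2 / (vA - muA); szB <- muB^2 / (vB - muB)
      a <- 0:kS[g]
      ps <- stats::dnbinom(a, mu = muA, size = szA) *
        stats::dnbinom(kS[g] - a, mu = muB, size = szB)
      tot <- sum(ps)
      if (tot == 0) return(NA_real_)
      min(1, sum(ps[ps <= ps[kA[g] + 1] * (1 + 1e-7)]) / tot)
    } else {
      la <- log(kA[g] / SA + 0.5); lb <- log(kB[g] / SB + 0.5)
      se <- sqrt(vA / muA^2 + vB / muB^2)
      2 * stats::pnorm(-abs(lb - la) / se)
    }
  }, numeric(1))
  all_zero <- kS == 0
  log2fc <- log2((kB / SB + pseudocount) / (kA / SA + pseudocount))
  log2fc[all_zero] <- 0
  res <- data.frame(gene = rownames(k), base_mean = base_mean,
                    log2fc = log2fc, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    all_zero = all_zero, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "size_factors") <- sf
  attr(res, "dispersion") <- disp
  res
}

#' Select differentially expressed genes with asymmetric thresholds
#'
#' Applies the expression floor and the asymmetric volcano rules: a gene
#' is kept only if the mean RPKM of its higher-expressed group exceeds
#' `rpkm_floor`; it is `UP` when `log2fc > lfc` and `p < up_p`, `DOWN`
#' when `log2fc < -lfc` and `p < down_p` (a deliberately stricter p
#' cut-off for downregulation), and `NONE` otherwise.
#'
#' @param results data.frame from [nbTest()] (columns `gene`, `log2fc`,
#'   `p`).
#' @param rpkm RPKM matrix from [computeRPKM()], same gene universe.
#' @param groups character vector per rpkm column, "tumor" or "control".
#' @param up_p,down_p p-value cut-offs (defaults 0.05 and 0.001).
#' @param lfc absolute log2 fold-change cut-off (default 1).
#' @param rpkm_floor expression floor on the higher group mean (default
#'   0.5).
#' @return data.frame (gene, mean_rpkm_tumor, mean_rpkm_control, log2fc,
#'   p, q, direction).
#' @export
selectDEGs <- function(results, rpkm, groups, up_p = 0.05, down_p = 0.001,
                       lfc = 1, rpkm_floor = 0.5) {
  if (!all(results$gene %in% rownames(rpkm)))
    stop("results and rpkm must share the gene universe")
  if (length(groups) != ncol(rpkm))
    stop("groups must match the rpkm columns")
  rpkm <- rpkm[results$gene, , drop = FALSE]
  mt <- rowMeans(rpkm[, groups == "tumor", drop = FALSE])
  mc <- rowMeans(rpkm[, groups == "control", drop = FALSE])
  floor_ok <- pmax(mt, mc) > rpkm_floor
  direction <- rep("NONE", nrow(results))
  direction[floor_ok & results$log2fc > lfc & results$p < up_p] <- "UP"
  direction[floor_ok & results$log2fc < -lfc & results$p < down_p] <- "DOWN"
  out <- data.frame(gene = results$gene, mean_rpkm_tumor = mt,
                    mean_rpkm_control = mc, log2fc = results$log2fc,
                    p = results$p,
                    q = results$q %||% stats::p.adjust(results$p, "BH"),
                    direction = direction, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-sample expression relative to the control group
#'
#' `log2((rpkm(gene, sample) + eps) / (mean control rpkm + eps))`; the
#' pseudo-RPKM `eps` guards zeros.
#'
#' @param rpkm RPKM matrix.
#' @param gene gene identifier (row of `rpkm`).
#' @param sample sample identifier (column of `rpkm`).
#' @param controls character vector of control column names.
#' @param eps pseudo-RPKM (default 0.25).
#' @return log2 ratio (single numeric).
#' @examples
#' r <- matrix(c(100, 800, 800, 800), 1, 4,
#'             dimnames = list("g", c("t", "c1", "c2", "c3")))
#' relativeExpression(r, "g", "t", c("c1", "c2", "c3"))  # ~ -3
#' @export
relativeExpression <- function(rpkm, gene, sample, controls, eps = 0.25) {
  if (!gene %in% rownames(rpkm)) stop("gene not present: ", gene)
  if (!length(controls)) stop("controls must be non-empty")
  if (!all(c(sample, controls) %in% colnames(rpkm)))
    stop("sample/control columns missing from rpkm")
  log2((rpkm[gene, sample] + eps) /
       (mean(rpkm[gene, controls]) + eps))
}
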