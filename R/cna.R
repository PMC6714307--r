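#' Summarize exon-level depth log2 ratios to gene level
#'
#' Per gene, the gene-level log2 ratio is the median of its exon log2
#' ratios (robust to single-exon artifacts), and a copy-number category is
#' assigned by cut-offs: `HOM_DEL` at or below `hom_cut`, `HET_DEL` at or
#' below `het_cut`, `GAIN` at or above `gain_cut`, otherwise `NEUTRAL`.
#'
#' @param exons data.frame with columns `gene`, `exon_index`, `log2_ratio`
#'   (finite).
#' @param hom_cut,het_cut,gain_cut category cut-offs (defaults -2, -0.5,
#'   0.5).
#' @return data.frame (gene, gene_log2, n_exons, category), one row per
#'   gene with at least one exon record, in first-appearance order.
#' @examples
#' geneLevelLog2(data.frame(gene = "g1", exon_index = 1:3,
#'                          log2_ratio = c(-1.2, -0.8, -1)))
#' @export
geneLevelLog2 <- function(exons, hom_cut = -2, het_cut = -0.5,
                          gain_cut = 0.5) {
  if (!all(c("gene", "log2_ratio") %in% names(exons)))
    stop("exons needs columns 'gene' and 'log2_ratio'")
  if (any(!is.finite(exons$log2_ratio)))
    stop("log2_ratio must be finite")
  if (!nrow(exons))
    return(data.frame(gene = character(), gene_log2 = numeric(),
                      n_exons = integer(), category = character()))
  genes <- unique(exons$gene)
  med <- vapply(split(exons$log2_ratio, factor(exons$gene, levels = genes)),
                stats::median, numeric(1))
  nex <- as.integer(table(factor(exons$gene, levels = genes)))
  category <- ifelse(med <= hom_cut, "HOM_DEL",
              ifelse(med <= het_cut, "HET_DEL",
              ifelse(med >= gain_cut, "GAIN", "NEUTRAL")))
  data.frame(gene = genes, gene_log2 = unname(med), n_exons = nex,
             category = unname(category), stringsAsFactors = FALSE)
}

#' Call loss of heterozygosity from paired VAFs
#'
#' A site is informative when the normal VAF lies in the heterozygous
#' interval `[het_lo, het_hi]`; an informative site is `LOH` when the
#' tumor VAF has drifted to within `hom_margin` of 0 or 1 (homozygous in
#' the tumor while heterozygous in the normal), `NO_LOH` otherwise, and
#' `UNINFORMATIVE` when the normal is not heterozygous. A pure function of
#' the two VAFs and the thresholds.
#'
#' @param vafs data.frame with columns `site_id`, `normal_vaf`,
#'   `tumor_vaf` (in \[0, 1\]).
#' @param het_lo,het_hi heterozygous interval for the normal (defaults
#'   0.4, 0.6).
#' @param hom_margin homozygosity margin for the tumor (default 0.1).
#' @return data.frame (site_id, normal_vaf, tumor_vaf, status).
#' @examples
#' callLOH(data.frame(site_id = "s1", normal_vaf = 0.5, tumor_vaf = 0.98))
#' @export
callLOH <- function(vafs, het_lo = 0.4, het_hi = 0.6, hom_margin = 0.1) {
  need <- c("site_id", "normal_vaf", "tumor_vaf")
  if (!all(need %in% names(vafs)))
    stop("vafs needs columns ", paste(need, collapse = ", "))
  v <- vafs[, need, drop = FALSE]
  if (any(v$normal_vaf < 0 | v$normal_vaf > 1 |
          v$tumor_vaf < 0 | v$tumor_vaf > 1, na.rm = TRUE))
    stop("VAFs must lie in [0, 1]")
  het <- v$normal_vaf >= het_lo & v$normal_vaf <= het_hi
  hom_t <- v$tumor_vaf <= hom_margin | v$tumor_vaf >= 1 - hom_margin
  v$status <- ifelse(!het, "UNINFORMATIVE",
                     ifelse(hom_t, "LOH", "NO_LOH"))
  rownames(v) <- NULL
  v
}

#' Aggregate per-site LOH calls to a regional status
#'
#' A region (or gene) is `LOH` when at least `min_frac` of its informative
#' sites are per-site LOH, `NO_LOH` when it has informative sites but too
#' few LOH ones, and `UNINFORMATIVE` with no informative site. The default
#' `min_frac = 0.3` tolerates purity-attenuated tumor VAFs straddling the
#' per-site homozygosity margin.
#'
#' @param loh_calls data.frame as returned by [callLOH()].
#' @param min_frac minimum fraction of informative sites called LOH.
#' @return single status string.
#' @export
aggregateLOH <- function(loh_calls, min_frac = 0.3) {
  inf <- loh_calls$status[loh_calls$status != "UNINFORMATIVE"]
  if (!length(inf)) return("UNINFORMATIVE")
  if (mean(inf == "LOH") >= min_frac) "LOH" else "NO_LOH"
}

#' Windowed Z-statistic over array probe log2 ratios
#'
#' Tiles each chromosome with non-overlapping windows of `window_bp`
#' anchored at position 1 and scores each window by
#' `z = mean(ratio) / (sd_global / sqrt(n_probes))`, where `sd_global` is
#' the robust global spread `1.4826 * MAD` of all probe ratios. A window
#' is flagged when `|z| >= z_threshold` and it contains at least
#' `min_probes` probes. With a degenerate zero global spread (noiseless
#' input) `z` is 0 for windows with mean 0 and infinite otherwise, so
#' recovery of planted aberrations is exact.
#'
#' @param probes data.frame with columns `chrom`, `pos`, `log2_ratio`,
#'   sorted by position within each chromosome.
#' @param window_bp window size in bp (default 1e6, a 1-Mb tiling).
#' @param z_threshold flagging threshold on |z| (default 4).
#' @param min_probes minimum probes per scored window (default 10).
#' @return data.frame (chrom, start, end, n_probes, mean_ratio, z,
#'   flagged), one row per non-empty window.
#' @export
windowedZ <- function(probes, window_bp = 1e6, z_threshold = 4,
                      min_probes = 10) {
  need <- c("chrom", "pos", "log2_ratio")
  if (!all(need %in% names(probes)))
    stop("probes needs columns ", paste(need, collapse = ", "))
  unsorted <- vapply(split(probes$pos, probes$chrom), is.unsorted,
                     logical(1))
  if (any(unsorted))
    stop("probes must be sorted by position within chromosome: ",
         paste(names(unsorted)[unsorted], collapse = ", "))
  sd_global <- 1.4826 * stats::mad(probes$log2_ratio, constant = 1)
  win_index <- (probes$pos - 1) %/% window_bp
  key <- paste(probes$chrom, win_index, sep = "\r")
  out <- lapply(split(seq_len(nrow(probes)), key), function(ii) {
    m <- mean(probes$log2_ratio[ii])
    n <- length(ii)
    z <- if (sd_global > 0) m / (sd_global / sqrt(n))
         else if (m == 0) 0 else sign(m) * Inf
    data.frame(chrom = probes$chrom[ii[1]],
               start = win_index[ii[1]] * window_bp + 1,
               end = (win_index[ii[1]] + 1) * window_bp,
               n_probes = n, mean_ratio = m, z = z,
               flagged = abs(z) >= z_threshold & n >= min_probes)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify the biallelic-inactivation mechanism of a gene
#'
#' Combines the gene-level copy-number category, the aggregated LOH status
#' and the presence of a somatic (truncating-class) mutation into one
#' mechanism label, mirroring the per-patient mechanism table of a
#' biallelically inactivated tumor suppressor:
#' `HOMOZYGOUS_DELETION` (both copies lost),
#' `HET_DELETION_PLUS_MUTATION` (one copy lost, the retained one mutated),
#' `COPY_NEUTRAL_LOH_PLUS_MUTATION` (copy neutral, mutated allele
#' homozygous by LOH) -- all three assert biallelic inactivation --
#' then `HET_DELETION_ONLY` and `NO_BIALLELIC_EVIDENCE`.
#'
#' @param cna_category one of `HOM_DEL`, `HET_DEL`, `NEUTRAL`, `GAIN`
#'   (see [geneLevelLog2()]).
#' @param loh_status one of `LOH`, `NO_LOH`, `UNINFORMATIVE`
#'   (see [aggregateLOH()]).
#' @param has_mutation logical: does the gene carry a somatic call of a
#'   damaging consequence class?
#' @return list with `mechanism` (label) and `biallelic` (logical).
#' @examples
#' classifyInactivation("HET_DEL", "LOH", TRUE)
#' @export
classifyInactivation <- function(cna_category, loh_status, has_mutation) {
  stopifnot(cna_category %in% c("HOM_DEL", "HET_DEL", "NEUTRAL", "GAIN"),
            loh_status %in% c("LOH", "NO_LOH", "UNINFORMATIVE"),
            is.logical(has_mutation), length(has_mutation) == 1L)
  mech <- if (cna_category == "HOM_DEL") {
    "HOMOZYGOUS_DELETION"
  } else if (cna_category == "HET_DEL" && has_mutation) {
    "HET_DELETION_PLUS_MUTATION"
  } else if (cna_category %in% c("NEUTRAL", "GAIN") &&
             loh_status == "LOH" && has_mutation) {
    "COPY_NEUTRAL_LOH_PLUS_MUTATION"
  } else if (cna_category == "HET_DEL") {
    "HET_DELETION_ONLY"
  } else {
    "NO_BIALLELIC_EVIDENCE"
  }
  list(mechanism = mech,
       biallelic = mech %in% c("HOMOZYGOUS_DELETION",
                               "HET_DELETION_PLUS_MUTATION",
                               "COPY_NEUTRAL_LOH_PLUS_MUTATION"))
}
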