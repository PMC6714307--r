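#' Variant allele fraction
#'
#' VAF = alt / (ref + alt). Zero total depth is an error: a depth-0 site
#' has no defined VAF and must be flagged (see `LOW_DEPTH` in
#' [callSomatic()]) rather than silently scored 0.
#'
#' @param ref_count,alt_count non-negative read counts (vectorized).
#' @return numeric vector of fractions in \[0, 1\].
#' @examples
#' computeVAF(10, 10)  # 0.5
#' @export
computeVAF <- function(ref_count, alt_count) {
  if (any(ref_count < 0) || any(alt_count < 0))
    stop("read counts must be non-negative")
  depth <- ref_count + alt_count
  if (any(depth == 0))
    stop("VAF undefined at zero total depth; flag the site as LOW_DEPTH")
  alt_count / depth
}

# Internal vectorized VAF that returns NA at zero depth instead of erroring.
.vaf_or_na <- function(ref_count, alt_count) {
  depth <- ref_count + alt_count
  ifelse(depth > 0, alt_count / depth, NA_real_)
}

#' VAF_frac: tumor share of the summed allele fractions
#'
#' `vaf_t / (vaf_t + vaf_c)`. Near 1 for tumor-specific (somatic) variants,
#' near 0.5 for shared (germline) variants. Undefined when both VAFs are 0;
#' such sites are flagged by the caller rather than scored.
#'
#' @param vaf_t,vaf_c tumor and control VAFs in \[0, 1\] (vectorized).
#' @return numeric vector in \[0, 1\] (`NA` where both inputs are 0).
#' @examples
#' vafFrac(0.5, 0)    # 1
#' vafFrac(0.3, 0.3)  # 0.5
#' @export
vafFrac <- function(vaf_t, vaf_c) {
  if (any(vaf_t < 0 | vaf_t > 1, na.rm = TRUE) ||
      any(vaf_c < 0 | vaf_c > 1, na.rm = TRUE))
    stop("VAFs must lie in [0, 1]")
  s <- vaf_t + vaf_c
  ifelse(is.na(s) | s == 0, NA_real_, vaf_t / s)
}

#' Permutation test for an elevated tumor VAF
#'
#' One-sided test of H1: VAF_tumor > VAF_normal at a single site. Under the
#' null the read labels (tumor/normal) carry no information, so all reads
#' are pooled and reassigned to the two samples keeping each sample's depth
#' fixed; the statistic is the VAF difference (well-defined at VAF 0). The
#' number of alt reads landing in the tumor slot is then hypergeometric,
#' and the VAF difference is monotone in it. When the total depth is at
#' most `exact_cap` the tail is computed exactly over that distribution;
#' above the cap a Monte Carlo estimate with add-one smoothing,
#' `p = (1 + #\{permuted diff >= observed\}) / (1 + n_perm)`, is used.
#' Ties count as exceedances (conservative).
#'
#' @param t_ref,t_alt,n_ref,n_alt read counts of the site (vectorized).
#' @param n_perm Monte Carlo permutations (default 10000).
#' @param seed integer seed for the Monte Carlo path; the draw for each
#'   site is additionally keyed on its read counts so results do not
#'   depend on input order.
#' @param exact_cap total-depth bound below which the exact enumeration is
#'   used (default 1000).
#' @return numeric vector of one-sided p-values.
#' @examples
#' permutationTestVAF(5, 5, 10, 0)   # hypergeometric tail P(X >= 5)
#' @export
permutationTestVAF <- function(t_ref, t_alt, n_ref, n_alt,
                               n_perm = 10000L, seed = 1L,
                               exact_cap = 1000L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  m <- max(length(t_ref), length(t_alt), length(n_ref), length(n_alt))
  t_ref <- rep_len(t_ref, m); t_alt <- rep_len(t_alt, m)
  n_ref <- rep_len(n_ref, m); n_alt <- rep_len(n_alt, m)
  dt <- t_ref + t_alt; dn <- n_ref + n_alt
  if (any(dt == 0 | dn == 0))
    stop("VAF undefined at zero total depth; flag the site as LOW_DEPTH")
  N <- dt + dn
  K <- t_alt + n_alt
  p <- numeric(m)
  exact <- N <= exact_cap
  # exact: P(X >= t_alt), X ~ Hypergeom(K alt among N reads, draw dt)
  p[exact] <- stats::phyper(t_alt[exact] - 1, K[exact],
                            N[exact] - K[exact], dt[exact],
                            lower.tail = FALSE)
  for (i in which(!exact)) {
    site_seed <- (abs(seed) + 7 * t_ref[i] + 13 * t_alt[i] +
                  31 * n_ref[i] + 57 * n_alt[i]) %% 2147483647
    obs <- t_alt[i] / dt[i] - n_alt[i] / dn[i]
    p[i] <- with_seed(site_seed, {
      x <- stats::rhyper(n_perm, K[i], N[i] - K[i], dt[i])
      perm <- x / dt[i] - (K[i] - x) / dn[i]
      (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
    })
  }
  p
}

#' Call somatic variants by permutation p-value and VAF_frac
#'
#' The three-step somatic selection over paired allele depths: compute each
#' sample's VAF, test for an elevated tumor VAF with
#' [permutationTestVAF()], and select sites jointly on the volcano axes
#' (VAF_frac vs -log10 p). A site is `SOMATIC` iff no filter fires:
#' \describe{
#'   \item{LOW_DEPTH}{tumor or normal depth below `min_depth`; the site is
#'     not scored further.}
#'   \item{FAIL_P}{permutation p-value >= `p_max`.}
#'   \item{FAIL_FRAC}{VAF_frac below `frac_min` (or undefined).}
#'   \item{GERMLINE_LIKE}{normal VAF >= 0.25, i.e. the variant is clearly
#'     present in the matched normal.}
#' }
#'
#' @param sites a [PairedSites-class] object.
#' @param min_depth minimum depth in both samples (default 8).
#' @param p_max permutation p-value cut-off (default 0.05).
#' @param frac_min VAF_frac cut-off in \[0.5, 1\] (default 0.9).
#' @param n_perm,seed,exact_cap passed to [permutationTestVAF()].
#' @return a [SomaticCallSet-class]; row order matches the input.
#' @examples
#' s <- PairedSites(data.frame(chrom = "chr1", pos = 1, ref = "A",
#'                             alt = "T", t_ref = 90, t_alt = 60,
#'                             n_ref = 149, n_alt = 1))
#' somaticCalls(callSomatic(s))
#' @export
callSomatic <- function(sites, min_depth = 8, p_max = 0.05, frac_min = 0.9,
                        n_perm = 10000L, seed = 1L, exact_cap = 1000L) {
  stopifnot(is(sites, "PairedSites"))
  if (p_max <= 0 || p_max >= 1) stop("p_max must be in (0, 1)")
  if (frac_min < 0.5 || frac_min > 1) stop("frac_min must be in [0.5, 1]")
  d <- siteData(sites)
  n <- nrow(d)
  params <- list(min_depth = min_depth, p_max = p_max, frac_min = frac_min,
                 n_perm = as.integer(n_perm), exact_cap = exact_cap,
                 seed = as.integer(seed))
  if (n == 0) {
    calls <- data.frame(site_id = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character(), vaf_tumor = numeric(),
                        vaf_normal = numeric(), p_perm = numeric(),
                        vaf_frac = numeric(), neg_log10_p = numeric(),
                        filters = character(), verdict = character())
    return(new("SomaticCallSet", calls = calls, params = params))
  }
  dt <- d$t_ref + d$t_alt
  dn <- d$n_ref + d$n_alt
  low <- dt < min_depth | dn < min_depth
  vaf_t <- .vaf_or_na(d$t_ref, d$t_alt)
  vaf_n <- .vaf_or_na(d$n_ref, d$n_alt)
  p <- rep(NA_real_, n)
  frac <- rep(NA_real_, n)
  sc <- !low
  if (any(sc)) {
    p[sc] <- permutationTestVAF(d$t_ref[sc], d$t_alt[sc], d$n_ref[sc],
                                d$n_alt[sc], n_perm = n_perm, seed = seed,
                                exact_cap = exact_cap)
    frac[sc] <- vafFrac(vaf_t[sc], vaf_n[sc])
  }
  flags <- lapply(seq_len(n), function(i) {
    if (low[i]) return("LOW_DEPTH")
    f <- character()
    if (!is.na(vaf_n[i]) && vaf_n[i] >= 0.25) f <- c(f, "GERMLINE_LIKE")
    if (is.na(p[i]) || p[i] >= p_max) f <- c(f, "FAIL_P")
    if (is.na(frac[i]) || frac[i] < frac_min) f <- c(f, "FAIL_FRAC")
    f
  })
  filters <- vapply(flags, paste, character(1), collapse = ";")
  calls <- data.frame(
    site_id = d$site_id, chrom = d$chrom, pos = d$pos, ref = d$ref,
    alt = d$alt, vaf_tumor = vaf_t, vaf_normal = vaf_n, p_perm = p,
    vaf_frac = frac, neg_log10_p = -log10(p),
    filters = filters,
    verdict = ifelse(nzchar(filters), "REJECTED", "SOMATIC"),
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  new("SomaticCallSet", calls = calls, params = params)
}

#' Filter somatic calls on consequence class and population rarity
#'
#' Keeps `SOMATIC` calls whose annotation is of a non-synonymous
#' consequence class (`nonsynonymous`, `stop_gain`, `splice`) and whose
#' population allele frequency is below `af_max` (default 1%, the rarity
#' cut-off against a population reference panel). Rejected calls pass
#' through unchanged; a `SOMATIC` call without an annotation is an error.
#'
#' @param calls a [SomaticCallSet-class].
#' @param annotations data.frame with columns `site_id`, `consequence`,
#'   `pop_af`.
#' @param af_max maximum population allele frequency (default 0.01).
#' @return a [SomaticCallSet-class] containing the surviving `SOMATIC`
#'   calls (input order preserved).
#' @export
filterVariants <- function(calls, annotations, af_max = 0.01) {
  stopifnot(is(calls, "SomaticCallSet"))
  d <- somaticCalls(calls)
  som <- d[d$verdict == "SOMATIC", , drop = FALSE]
  idx <- match(som$site_id, annotations$site_id)
  if (anyNA(idx))
    stop("missing annotation for SOMATIC site(s): ",
         paste(som$site_id[is.na(idx)], collapse = ", "))
  ann <- annotations[idx, , drop = FALSE]
  if (any(ann$pop_af < 0 | ann$pop_af > 1))
    stop("pop_af must lie in [0, 1]")
  keep <- ann$consequence %in% c("nonsynonymous", "stop_gain", "splice") &
    ann$pop_af < af_max
  som <- som[keep, , drop = FALSE]
  rownames(som) <- NULL
  new("SomaticCallSet", calls = som,
      params = c(callParams(calls), list(af_max = af_max)))
}
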