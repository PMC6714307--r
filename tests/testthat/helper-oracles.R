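# Independent oracles and small fixture builders shared across the suite.

# Upper hypergeometric tail P(X >= x_obs) by explicit enumeration of the
# pmf via log-binomial coefficients; independent of phyper().
hyper_tail_enum <- function(x_obs, K, N, n) {
  hi <- min(K, n)
  lo <- max(0L, n - (N - K))
  if (x_obs > hi) return(0)
  xs <- max(x_obs, lo):hi
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Exact central 99.73% prediction interval (the finite-sample analog of a
# +/- 3 SE band) for a Binomial(n, p) count. qbinom() in R 4.3 is unstable
# for p near 1, so the upper-half band is computed on the complement.
binom_band3 <- function(n, p) {
  p <- min(max(p, 0), 1)
  if (p > 0.5) {
    c(n - stats::qbinom(0.99865, n, 1 - p),
      n - stats::qbinom(0.00135, n, 1 - p))
  } else {
    c(stats::qbinom(0.00135, n, p), stats::qbinom(0.99865, n, p))
  }
}

# The fixed family of paired-depth configurations with total depth <= 30
# whose full alt-count grids enumerate 256 + 121 + 63 + 36 + 20 = 496 cases.
perm_test_grid <- function() {
  depth_pairs <- list(c(15, 15), c(10, 10), c(8, 6), c(5, 5), c(3, 4))
  do.call(rbind, lapply(depth_pairs, function(dp) {
    expand.grid(dt = dp[1], dn = dp[2], kt = 0:dp[1], kn = 0:dp[2])
  }))
}

# Minimal RNACountSet with given per-cell NB means (genes x 9 samples,
# 4 tumors vs 5 controls) and dispersion.
make_counts <- function(mu, dispersion = 0.1, seed = 1) {
  n_g <- nrow(mu)
  stopifnot(ncol(mu) == 9)
  withr::with_seed(seed, {
    k <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                               size = 1 / dispersion),
                n_g, 9,
                dimnames = list(sprintf("g%04d", seq_len(n_g)),
                                c(paste0("T", 1:4), paste0("C", 1:5))))
    RNACountSet(k, gene_lengths = rep(1000, n_g),
                groups = c(rep("tumor", 4), rep("control", 5)))
  })
}

# One-row PairedSites helper.
one_site <- function(t_ref, t_alt, n_ref, n_alt, pos = 1) {
  PairedSites(data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                         t_ref = t_ref, t_alt = t_alt,
                         n_ref = n_ref, n_alt = n_alt))
}

# Expected classifier label for each planted driver mechanism.
mechanism_label <- c(
  HOM_DEL = "HOMOZYGOUS_DELETION",
  HET_DEL_MUT = "HET_DELETION_PLUS_MUTATION",
  CN_LOH_MUT = "COPY_NEUTRAL_LOH_PLUS_MUTATION",
  HET_DEL_SPLICE = "HET_DELETION_PLUS_MUTATION",
  NONE = "NO_BIALLELIC_EVIDENCE")

no_loh_regions <- data.frame(chrom = character(), start = numeric(),
                             end = numeric())
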