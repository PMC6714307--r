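#' Build a simulation configuration
#'
#' Returns a validated [SimConfig-class] holding the study conditions of the
#' synthetic paired tumor/normal cohort. Defaults emulate a high-depth exome
#' design (~150x, Poisson per-site depth), tumor purity 0.9, planted somatic
#' variants at cell-level VAF 0.4, germline heterozygous sites at VAF 0.5,
#' one planted LOH region, a 4-tumor vs 5-control RNA-seq comparison with
#' negative binomial counts (dispersion 0.1, log-normal library sizes), a
#' planted up:down DE ratio of ~1.7 (within the 1.5--3 range such cohorts
#' show), a biallelically inactivated driver gene knocked down by 2^-4 in
#' tumors, and a gene-set collection with three enriched sets containing a
#' designated top cancer gene.
#'
#' @param n_sites,n_somatic,germline_het_rate,depth_mean,purity,somatic_vaf,error_rate,loh_regions
#'   exome design; see [SimConfig-class].
#' @param n_genes,n_tumors,n_controls,nb_dispersion,libsize_sd,de_up_frac,de_down_frac,lfc_magnitude,driver_gene,driver_lfc
#'   RNA-seq design; see [SimConfig-class].
#' @param n_gene_sets,n_enriched_sets,set_size,n_cancer_genes gene-set design.
#' @param probe_spacing,noise_sd copy-number track design.
#' @param seed master seed; every generator derives its own sub-seed from it.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_sites = 100, n_somatic = 10, seed = 1)
#' cfg
#' @export
simConfig <- function(n_sites = 5500, n_somatic = 500,
                      germline_het_rate = 0.6, depth_mean = 150,
                      purity = 0.9, somatic_vaf = 0.4, error_rate = 1e-3,
                      loh_regions = data.frame(chrom = "chr1",
                                               start = 2000001,
                                               end = 3000000),
                      n_genes = 5000, n_tumors = 4, n_controls = 5,
                      nb_dispersion = 0.1, libsize_sd = 0.2,
                      de_up_frac = 0.06, de_down_frac = 0.035,
                      lfc_magnitude = 2, driver_gene = "TSG1",
                      driver_lfc = -4,
                      n_gene_sets = 20, n_enriched_sets = 3, set_size = 50,
                      n_cancer_genes = 120,
                      probe_spacing = 10000, noise_sd = 0.1,
                      seed = 20190828) {
  new("SimConfig",
      n_sites = n_sites, n_somatic = n_somatic,
      germline_het_rate = germline_het_rate, depth_mean = depth_mean,
      purity = purity, somatic_vaf = somatic_vaf, error_rate = error_rate,
      loh_regions = as.data.frame(loh_regions),
      n_genes = n_genes, n_tumors = n_tumors, n_controls = n_controls,
      nb_dispersion = nb_dispersion, libsize_sd = libsize_sd,
      de_up_frac = de_up_frac, de_down_frac = de_down_frac,
      lfc_magnitude = lfc_magnitude, driver_gene = driver_gene,
      driver_lfc = driver_lfc,
      n_gene_sets = n_gene_sets, n_enriched_sets = n_enriched_sets,
      set_size = set_size, n_cancer_genes = n_cancer_genes,
      probe_spacing = probe_spacing, noise_sd = noise_sd, seed = seed)
}

# Gene identifiers of the expression universe; the first three slots are the
# driver (SMARCB1 analog), the designated top cancer gene (NPM1 analog) and
# the subgroup-scoring reference gene (EZH2 analog).
.gene_ids <- function(config) {
  ids <- sprintf("g%05d", seq_len(config@n_genes))
  ids[1] <- config@driver_gene
  if (config@n_genes >= 2) ids[2] <- "ONC1"
  if (config@n_genes >= 3) ids[3] <- "REFG1"
  ids
}

.subgroup_names <- c("TYR", "SHH", "MYC")

# Deterministic plan of the expression layer: baseline means, gene lengths,
# planted DE genes, top gene, subgroup signatures and sample labels. Both the
# count generator and the gene-set generator derive their truth from this, so
# a single SimConfig yields one consistent ground truth.
plan_expression <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@n_genes < 50) stop("n_genes must be >= 50")
  if (config@n_tumors < 2 || config@n_controls < 2)
    stop("n_tumors and n_controls must both be >= 2")
  ids <- .gene_ids(config)
  with_seed(sub_seed(config@seed, 2), {
    base <- stats::rlnorm(config@n_genes, meanlog = log(60), sdlog = 1.5)
    len <- round(stats::rlnorm(config@n_genes, meanlog = log(1500),
                               sdlog = 0.5))
    len <- pmax(len, 200)
    base[1] <- 1000   # driver: well expressed so the knock-down is measurable
    base[2] <- 600    # top gene
    base[3] <- 500    # reference gene
    names(base) <- names(len) <- ids

    # subgroup signature genes: moderately expressed, never DE
    sig_pool <- ids[-(1:3)][base[-(1:3)] >= 100 & base[-(1:3)] <= 400]
    sig_genes <- lapply(seq_along(.subgroup_names), function(i)
      sig_pool[((i - 1) * 8 + 1):(i * 8)])
    names(sig_genes) <- .subgroup_names
    base[unlist(sig_genes)] <- 200
    labels <- rep_len(c("SHH", "TYR", "MYC", "TYR"), config@n_tumors)
    names(labels) <- paste0("T", seq_len(config@n_tumors))

    n_up <- round(config@de_up_frac * config@n_genes)
    n_down <- round(config@de_down_frac * config@n_genes)
    de <- data.frame(gene = character(), direction = character(),
                     true_lfc = numeric())
    if (config@lfc_magnitude > 0 && (n_up + n_down) > 0) {
      # plant DE on adequately expressed genes so both the lenient up and the
      # strict down threshold are attainable at this design size
      pool <- setdiff(ids[base >= 50], c(ids[1:3], unlist(sig_genes)))
      if (length(pool) < n_up + n_down - 1)
        stop("not enough adequately expressed genes to plant DE")
      picked <- sample(pool, n_up + n_down - 1)
      up <- c(ids[2], picked[seq_len(max(n_up - 1, 0))])
      down <- picked[seq_len(n_down) + (n_up - 1)]
      de <- data.frame(
        gene = c(up, down),
        direction = c(rep("UP", length(up)), rep("DOWN", length(down))),
        true_lfc = c(config@lfc_magnitude + 2,
                     rep(config@lfc_magnitude, length(up) - 1),
                     rep(-config@lfc_magnitude, length(down))))
    }
    list(ids = ids, base = base, length = len, de = de,
         top_gene = ids[2], ref_gene = ids[3], sig_genes = sig_genes,
         subgroup_labels = labels)
  })
}

#' Simulate paired tumor/normal allele depths with ground truth
#'
#' Per-site depths are Poisson around `depth_mean` in each sample. Germline
#' heterozygous sites draw alt reads binomially at VAF 0.5 in both samples;
#' somatic sites at `purity * somatic_vaf` in the tumor and at the sequencing
#' error rate in the normal; homozygous-reference sites at the error rate in
#' both. Germline sites inside a planted LOH region keep the normal
#' heterozygous but push the tumor VAF toward 0 or 1 (purity-attenuated).
#' Site consequence/population-frequency annotations are also emitted.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `sites` ([PairedSites-class]), `annotations`
#'   (data.frame site_id, consequence, pop_af) and `truth`
#'   ([TruthSet-class]).
#' @examples
#' sim <- simulatePairedCounts(simConfig(n_sites = 200, n_somatic = 20,
#'                                       seed = 7))
#' sim$sites
#' @export
simulatePairedCounts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- as.integer(config@n_sites)
  with_seed(sub_seed(config@seed, 1), {
    pos <- seq_len(n) * 1000L
    chrom <- rep("chr1", n)
    site_id <- sprintf("s%06d", seq_len(n))
    in_loh <- rep(FALSE, n)
    lr <- config@loh_regions
    if (nrow(lr)) for (i in seq_len(nrow(lr)))
      in_loh <- in_loh | (chrom == lr$chrom[i] & pos >= lr$start[i] &
                          pos <= lr$end[i])

    status <- rep("reference", n)
    som_pool <- which(!in_loh)
    if (config@n_somatic > length(som_pool))
      stop("n_somatic exceeds the number of sites outside LOH regions")
    som_idx <- sort(sample(som_pool, config@n_somatic))
    status[som_idx] <- "somatic"
    rest <- setdiff(seq_len(n), som_idx)
    n_germ <- round(config@germline_het_rate * length(rest))
    germ_idx <- sort(sample(rest, n_germ))
    status[germ_idx] <- "germline"

    t_depth <- pmax(1L, stats::rpois(n, config@depth_mean))
    n_depth <- pmax(1L, stats::rpois(n, config@depth_mean))

    p_t <- rep(config@error_rate, n)
    p_n <- rep(config@error_rate, n)
    p_t[status == "germline"] <- 0.5
    p_n[status == "germline"] <- 0.5
    p_t[status == "somatic"] <- config@purity * config@somatic_vaf

    loh_site <- status == "germline" & in_loh
    keep_alt <- stats::runif(n) < 0.5
    p_t[loh_site] <- ifelse(keep_alt[loh_site],
                            config@purity + (1 - config@purity) * 0.5,
                            (1 - config@purity) * 0.5)

    t_alt <- stats::rbinom(n, t_depth, p_t)
    n_alt <- stats::rbinom(n, n_depth, p_n)

    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))

    cons <- rep("other", n)
    cons[status == "somatic"] <-
      sample(c("nonsynonymous", "stop_gain", "splice", "synonymous"),
             sum(status == "somatic"), replace = TRUE,
             prob = c(0.6, 0.15, 0.1, 0.15))
    cons[status == "germline"] <-
      sample(c("nonsynonymous", "synonymous", "other"),
             sum(status == "germline"), replace = TRUE,
             prob = c(0.3, 0.3, 0.4))
    pop_af <- rep(0, n)
    pop_af[status == "germline"] <- round(stats::runif(sum(status ==
      "germline"), 0.01, 0.5), 4)

    sites <- PairedSites(data.frame(
      site_id = site_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
      t_ref = t_depth - t_alt, t_alt = t_alt,
      n_ref = n_depth - n_alt, n_alt = n_alt,
      stringsAsFactors = FALSE))
    truth <- new("TruthSet",
      somatic_sites = data.frame(
        site_id = site_id[som_idx],
        true_vaf = rep(config@purity * config@somatic_vaf,
                       length(som_idx))),
      germline_sites = site_id[germ_idx],
      loh_sites = site_id[loh_site])
    list(sites = sites,
         annotations = data.frame(site_id = site_id, consequence = cons,
                                  pop_af = pop_af,
                                  stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate an RNA-seq count matrix with ground truth
#'
#' Counts are negative binomial with gene-specific log-normal baseline
#' means, a shared dispersion, and log-normal per-sample library-size
#' factors. Planted DE genes shift the tumor-group mean by
#' `2^(+/- lfc_magnitude)`; the driver gene's tumor mean is reduced by
#' `2^driver_lfc` (<= -2 log2 units, emulating biallelic inactivation);
#' subgroup signature genes are elevated 4-fold in tumors of the matching
#' subgroup so samples can be scored against a uniformly expressed
#' reference gene.
#'
#' @param config a [SimConfig-class]; requires `n_tumors >= 2` and
#'   `n_controls >= 2`.
#' @return list with elements `counts` ([RNACountSet-class]) and `truth`
#'   ([TruthSet-class]; DE genes, top gene, driver gene, subgroup labels).
#' @examples
#' sim <- simulateCountMatrix(simConfig(n_genes = 100, de_up_frac = 0.05,
#'                                      de_down_frac = 0.03, seed = 7))
#' dim(sim$counts)
#' @export
simulateCountMatrix <- function(config) {
  plan <- plan_expression(config)
  nt <- as.integer(config@n_tumors); nc <- as.integer(config@n_controls)
  samples <- c(paste0("T", seq_len(nt)), paste0("C", seq_len(nc)))
  groups <- c(rep("tumor", nt), rep("control", nc))
  with_seed(sub_seed(config@seed, 6), {
    mu <- matrix(plan$base, nrow = config@n_genes, ncol = nt + nc,
                 dimnames = list(plan$ids, samples))
    if (nrow(plan$de)) {
      fold <- 2^plan$de$true_lfc
      mu[plan$de$gene, seq_len(nt)] <-
        mu[plan$de$gene, seq_len(nt)] * fold
    }
    mu[config@driver_gene, seq_len(nt)] <-
      plan$base[config@driver_gene] * 2^config@driver_lfc
    for (sg in names(plan$sig_genes)) {
      hit <- which(plan$subgroup_labels == sg)
      if (length(hit))
        mu[plan$sig_genes[[sg]], hit] <- mu[plan$sig_genes[[sg]], hit] * 4
    }
    sf <- stats::rlnorm(nt + nc, 0, config@libsize_sd)
    mu_s <- sweep(mu, 2, sf, `*`)
    counts <- if (config@nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu_s), mu = mu_s,
                            size = 1 / config@nb_dispersion),
             nrow = nrow(mu_s), dimnames = dimnames(mu_s))
    } else {
      matrix(stats::rpois(length(mu_s), lambda = mu_s),
             nrow = nrow(mu_s), dimnames = dimnames(mu_s))
    }
    cs <- RNACountSet(counts, gene_lengths = plan$length, groups = groups)
    S4Vectors::metadata(cs)$size_factors_true <- stats::setNames(sf, samples)
    S4Vectors::metadata(cs)$base_means_true <- plan$base
    S4Vectors::metadata(cs)$signatures <- plan$sig_genes
    S4Vectors::metadata(cs)$reference_gene <- plan$ref_gene
    truth <- new("TruthSet", de_genes = plan$de, top_gene = plan$top_gene,
                 driver_gene = config@driver_gene,
                 subgroup_labels = plan$subgroup_labels)
    list(counts = cs, truth = truth)
  })
}

#' Simulate a gene-set collection and a cancer-gene list with ground truth
#'
#' Builds `n_gene_sets` sets of size `set_size` over the expression gene
#' universe. The first `n_enriched_sets` sets are stuffed with planted DE
#' genes well above chance (60% DE members; 80% for the first, most
#' enriched, set) and the designated top cancer gene is placed in the most
#' enriched set and on the cancer-gene list; the remaining sets are drawn
#' uniformly from the universe.
#'
#' @param config a [SimConfig-class] with `n_gene_sets >= 1`.
#' @return list with elements `sets` ([GeneSetList-class]), `cancer_genes`
#'   (character) and `truth` ([TruthSet-class]).
#' @examples
#' sim <- simulateGeneSets(simConfig(seed = 7))
#' sim$sets
#' @export
simulateGeneSets <- function(config) {
  if (config@n_gene_sets < 1) stop("n_gene_sets must be >= 1")
  plan <- plan_expression(config)
  de_genes <- plan$de$gene
  with_seed(sub_seed(config@seed, 3), {
    nset <- as.integer(config@n_gene_sets)
    nenr <- min(as.integer(config@n_enriched_sets), nset)
    set_names <- sprintf("SET%03d", seq_len(nset))
    sets <- vector("list", nset); names(sets) <- set_names
    for (i in seq_len(nset)) {
      if (i <= nenr && length(de_genes)) {
        frac_de <- if (i == 1) 0.8 else 0.6
        n_de <- min(round(frac_de * config@set_size), length(de_genes))
        memb <- sample(de_genes, n_de)
        if (i == 1) memb <- unique(c(plan$top_gene, memb))
        filler <- sample(setdiff(plan$ids, c(memb, de_genes)),
                         config@set_size - length(memb))
        sets[[i]] <- sample(c(memb, filler))
      } else {
        sets[[i]] <- sample(plan$ids, config@set_size)
      }
    }
    n_cancer_de <- min(round(config@n_cancer_genes / 3),
                       max(length(de_genes) - 1, 0))
    cancer <- unique(c(
      plan$top_gene,
      if (n_cancer_de) sample(setdiff(de_genes, plan$top_gene), n_cancer_de),
      sample(setdiff(plan$ids, c(de_genes, config@driver_gene,
                                 plan$ref_gene)),
             max(config@n_cancer_genes - n_cancer_de - 1, 0))))
    truth <- new("TruthSet",
                 enriched_sets = if (nenr) set_names[seq_len(nenr)]
                                 else character(),
                 top_gene = plan$top_gene,
                 de_genes = plan$de,
                 driver_gene = config@driver_gene)
    list(sets = GeneSetList(sets, universe = plan$ids),
         cancer_genes = cancer, truth = truth)
  })
}

#' Simulate exon-depth and array-probe log2-ratio tracks with ground truth
#'
#' The exon track covers the first 200 genes of the expression universe
#' (8 exons each); planted deleted genes get exon log2 ratios of -1
#' (heterozygous loss) or -3 (homozygous loss) plus Gaussian noise, and the
#' driver gene is always among the heterozygous losses. The probe track
#' tiles chr1 at `probe_spacing` with two planted aberrant 1-Mb windows
#' shifted by -1. A paired-VAF table for LOH calling is also produced:
#' sites inside the configured LOH regions are heterozygous in the normal
#' and (purity-attenuated) homozygous in the tumor.
#'
#' @param config a [SimConfig-class]; `noise_sd = 0` gives noiseless tracks.
#' @return list with elements `exons` (data.frame gene, exon_index,
#'   log2_ratio), `probes` (data.frame chrom, pos, log2_ratio), `loh_vafs`
#'   (data.frame site_id, chrom, pos, normal_vaf, tumor_vaf) and `truth`
#'   ([TruthSet-class]; deleted genes, aberrant windows, LOH sites).
#' @examples
#' sim <- simulateCopyNumberTracks(simConfig(noise_sd = 0, seed = 7))
#' head(sim$exons)
#' @export
simulateCopyNumberTracks <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  ids <- .gene_ids(config)
  genes <- ids[seq_len(min(200, length(ids)))]
  with_seed(sub_seed(config@seed, 4), {
    het_extra <- sample(genes[-(1:3)], 4)
    hom <- sample(setdiff(genes[-(1:3)], het_extra), 2)
    deleted <- data.frame(
      gene = c(config@driver_gene, het_extra, hom),
      true_log2 = c(rep(-1, 5), rep(-3, 2)),
      class = c(rep("HET_DEL", 5), rep("HOM_DEL", 2)),
      stringsAsFactors = FALSE)

    exons <- data.frame(gene = rep(genes, each = 8),
                        exon_index = rep(1:8, length(genes)))
    true_lr <- stats::setNames(rep(0, length(genes)), genes)
    true_lr[deleted$gene] <- deleted$true_log2
    exons$log2_ratio <- true_lr[exons$gene] +
      stats::rnorm(nrow(exons), 0, config@noise_sd)

    span <- 30e6
    pos <- seq(config@probe_spacing / 2, span, by = config@probe_spacing)
    win <- data.frame(chrom = "chr1",
                      start = c(5e6, 12e6) + 1, end = c(6e6, 13e6),
                      shift = c(-1, -1))
    shift <- rep(0, length(pos))
    for (i in seq_len(nrow(win)))
      shift[pos >= win$start[i] & pos <= win$end[i]] <- win$shift[i]
    probes <- data.frame(chrom = "chr1", pos = pos,
                         log2_ratio = shift +
                           stats::rnorm(length(pos), 0, config@noise_sd))

    vpos <- seq_len(as.integer(config@n_sites)) * 1000
    in_loh <- rep(FALSE, length(vpos))
    lr <- config@loh_regions
    if (nrow(lr)) for (i in seq_len(nrow(lr)))
      in_loh <- in_loh | (lr$chrom[i] == "chr1" & vpos >= lr$start[i] &
                          vpos <= lr$end[i])
    keep_alt <- stats::runif(length(vpos)) < 0.5
    tumor_true <- ifelse(in_loh,
                         ifelse(keep_alt,
                                config@purity + (1 - config@purity) * 0.5,
                                (1 - config@purity) * 0.5),
                         0.5)
    clamp <- function(x) pmin(1, pmax(0, x))
    loh_vafs <- data.frame(
      site_id = sprintf("v%06d", seq_along(vpos)), chrom = "chr1",
      pos = vpos,
      normal_vaf = clamp(0.5 + stats::rnorm(length(vpos), 0,
                                            config@noise_sd / 4)),
      tumor_vaf = clamp(tumor_true + stats::rnorm(length(vpos), 0,
                                                  config@noise_sd / 4)),
      stringsAsFactors = FALSE)

    truth <- new("TruthSet", deleted_genes = deleted, cna_windows = win,
                 loh_sites = loh_vafs$site_id[in_loh],
                 driver_gene = config@driver_gene)
    list(exons = exons, probes = probes, loh_vafs = loh_vafs, truth = truth)
  })
}

#' Simulate a per-tumor driver-inactivation cohort
#'
#' Emulates the mechanism table of a biallelically inactivated driver:
#' each tumor sample is planted with one inactivation mechanism among
#' homozygous deletion, heterozygous deletion plus truncating mutation,
#' copy-neutral LOH plus truncating mutation, and heterozygous deletion
#' plus splice-site mutation (or none). Exon log2 ratios, germline-het VAF
#' pairs over the driver, and the mutation's paired read counts follow the
#' purity model: with purity p a heterozygously deleted germline-het site
#' drifts to VAF 1/(2-p) (retained allele) or (1-p)/(2-p) (lost allele), a
#' copy-neutral LOH site to (1+p)/2 or (1-p)/2, a truncating mutation on
#' the retained allele is observed at VAF p/(2-p), and a homozygous
#' mutation under copy-neutral LOH at VAF p.
#'
#' @param config a [SimConfig-class].
#' @param mechanisms character vector recycled over tumors, from
#'   `c("HOM_DEL", "HET_DEL_MUT", "CN_LOH_MUT", "HET_DEL_SPLICE", "NONE")`.
#' @return list with `samples` (named list; per tumor: `exons`, `loh_vafs`,
#'   `mutation` ([PairedSites-class], 0/1 rows), `annotation`, and
#'   `mechanism_truth`) and `mechanisms` (named character vector).
#' @examples
#' drv <- simulateDriverCohort(simConfig(n_tumors = 4, seed = 7))
#' drv$mechanisms
#' @export
simulateDriverCohort <- function(config,
                                 mechanisms = c("HOM_DEL", "HET_DEL_MUT",
                                                "CN_LOH_MUT",
                                                "HET_DEL_SPLICE")) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  ok <- c("HOM_DEL", "HET_DEL_MUT", "CN_LOH_MUT", "HET_DEL_SPLICE", "NONE")
  if (!all(mechanisms %in% ok))
    stop("unknown mechanism; use ", paste(ok, collapse = ", "))
  nt <- as.integer(config@n_tumors)
  mech <- stats::setNames(rep_len(mechanisms, nt),
                          paste0("T", seq_len(nt)))
  p <- config@purity
  d <- round(config@depth_mean)
  # observed VAFs under the purity model (tumor cells + contaminating normal)
  loh_het_del <- 1 / (2 - p)        # germline het, deleted other allele
  loh_cn <- (1 + p) / 2             # germline het, copy-neutral LOH
  mut_het_del <- p / (2 - p)        # somatic mutation on the retained allele
  mut_cn <- p                       # homozygous mutation, copy-neutral LOH
  with_seed(sub_seed(config@seed, 5), {
    out <- lapply(names(mech), function(s) {
      m <- mech[[s]]
      exon_true <- switch(m, HOM_DEL = -3, HET_DEL_MUT = -1,
                          HET_DEL_SPLICE = -1, CN_LOH_MUT = 0, NONE = 0)
      exons <- data.frame(gene = config@driver_gene, exon_index = 1:8,
                          log2_ratio = exon_true +
                            stats::rnorm(8, 0, config@noise_sd))
      n_het <- 12
      loh_p <- switch(m,
        HOM_DEL = 0.5,                 # reads come from contaminating normal
        HET_DEL_MUT = , HET_DEL_SPLICE =
          ifelse(stats::runif(n_het) < 0.5, loh_het_del, 1 - loh_het_del),
        CN_LOH_MUT = ifelse(stats::runif(n_het) < 0.5, loh_cn, 1 - loh_cn),
        NONE = 0.5)
      loh_vafs <- data.frame(
        site_id = sprintf("%s_h%02d", s, seq_len(n_het)),
        normal_vaf = stats::rbinom(n_het, d, 0.5) / d,
        tumor_vaf = stats::rbinom(n_het, d, loh_p) / d)
      mut_vaf <- switch(m, HET_DEL_MUT = , HET_DEL_SPLICE = mut_het_del,
                        CN_LOH_MUT = mut_cn, NA_real_)
      cons <- switch(m, HET_DEL_MUT = "stop_gain", CN_LOH_MUT = "stop_gain",
                     HET_DEL_SPLICE = "splice", NA_character_)
      if (!is.na(mut_vaf)) {
        td <- pmax(1L, stats::rpois(1, d)); nd <- pmax(1L, stats::rpois(1, d))
        ta <- stats::rbinom(1, td, mut_vaf)
        na_ <- stats::rbinom(1, nd, config@error_rate)
        mutation <- PairedSites(data.frame(
          site_id = paste0(s, "_mut"), chrom = "chr22", pos = 24129150,
          ref = "G", alt = "T", t_ref = td - ta, t_alt = ta,
          n_ref = nd - na_, n_alt = na_))
        annotation <- data.frame(site_id = paste0(s, "_mut"),
                                 consequence = cons, pop_af = 0)
      } else {
        mutation <- PairedSites(data.frame(
          site_id = character(), chrom = character(), pos = integer(),
          ref = character(), alt = character(), t_ref = integer(),
          t_alt = integer(), n_ref = integer(), n_alt = integer()))
        annotation <- data.frame(site_id = character(),
                                 consequence = character(),
                                 pop_af = numeric())
      }
      list(exons = exons, loh_vafs = loh_vafs, mutation = mutation,
           annotation = annotation, mechanism_truth = m)
    })
    names(out) <- names(mech)
    list(samples = out, mechanisms = mech)
  })
}

#' Simulate the full cohort in one call
#'
#' Runs every generator under one configuration and merges the ground
#' truth. This is the entry point used by [runPipeline()].
#'
#' @param config a [SimConfig-class].
#' @return list with `paired`, `annotations`, `counts`, `sets`,
#'   `cancer_genes`, `cnv`, `driver` and a merged `truth`
#'   ([TruthSet-class]).
#' @export
simulateCohort <- function(config) {
  paired <- simulatePairedCounts(config)
  rna <- simulateCountMatrix(config)
  gs <- simulateGeneSets(config)
  cnv <- simulateCopyNumberTracks(config)
  drv <- simulateDriverCohort(config)
  truth <- new("TruthSet",
               somatic_sites = paired$truth@somatic_sites,
               germline_sites = paired$truth@germline_sites,
               loh_sites = paired$truth@loh_sites,
               deleted_genes = cnv$truth@deleted_genes,
               cna_windows = cnv$truth@cna_windows,
               de_genes = rna$truth@de_genes,
               enriched_sets = gs$truth@enriched_sets,
               top_gene = rna$truth@top_gene,
               driver_gene = config@driver_gene,
               subgroup_labels = rna$truth@subgroup_labels)
  list(paired = paired$sites, annotations = paired$annotations,
       counts = rna$counts, sets = gs$sets, cancer_genes = gs$cancer_genes,
       cnv = cnv, driver = drv, truth = truth)
}
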