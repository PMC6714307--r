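test_that("configuration invariants are enforced", {
  expect_error(simConfig(depth_mean = 0), "depth_mean")
  expect_error(simConfig(purity = 0), "purity")
  expect_error(simConfig(n_sites = 10, n_somatic = 20), "n_somatic")
  expect_error(simConfig(driver_lfc = -1), "driver_lfc")
  expect_error(simConfig(de_up_frac = 0.01, de_down_frac = 0.03),
               "up:down")
  expect_s4_class(simConfig(), "SimConfig")
})

test_that("paired-count generator is seeded and honours its contracts", {
  cfg <- simConfig(n_sites = 400, n_somatic = 40, seed = 11)
  a <- simulatePairedCounts(cfg)
  b <- simulatePairedCounts(cfg)
  expect_identical(siteData(a$sites), siteData(b$sites))
  expect_identical(a$truth@somatic_sites, b$truth@somatic_sites)
  # truth labels partition the sites
  d <- siteData(a$sites)
  som <- a$truth@somatic_sites$site_id
  expect_length(intersect(som, a$truth@germline_sites), 0)
  expect_true(all(c(som, a$truth@germline_sites) %in% d$site_id))
  # zero error rate and full purity: somatic sites carry no normal alt read
  clean <- simulatePairedCounts(simConfig(n_sites = 300, n_somatic = 50,
                                          purity = 1, somatic_vaf = 0.5,
                                          error_rate = 0, seed = 3))
  dc <- siteData(clean$sites)
  expect_true(all(dc$n_alt[dc$site_id %in%
                           clean$truth@somatic_sites$site_id] == 0))
  none <- simulatePairedCounts(simConfig(n_sites = 100, n_somatic = 0,
                                         seed = 3))
  expect_identical(nrow(none$truth@somatic_sites), 0L)
})

test_that("empirical depth matches the configured mean", {
  sim <- simulatePairedCounts(simConfig(n_sites = 10000, n_somatic = 0,
                                        depth_mean = 150, seed = 2))
  d <- siteData(sim$sites)
  depth <- (d$t_ref + d$t_alt + d$n_ref + d$n_alt) / 2
  expect_lt(abs(mean(depth) - 150) / 150, 0.02)
})

test_that("count generator determinism, planted ratio and marginal means", {
  cfg <- simConfig(n_genes = 5000, de_up_frac = 0.034, de_down_frac = 0.02,
                   seed = 13)
  a <- simulateCountMatrix(cfg)
  b <- simulateCountMatrix(cfg)
  expect_identical(SummarizedExperiment::assay(a$counts, "counts"),
                   SummarizedExperiment::assay(b$counts, "counts"))
  de <- a$truth@de_genes
  # planted counts are specified, not sampled: 170 up / 100 down = 1.7
  expect_identical(sum(de$direction == "UP") / sum(de$direction == "DOWN"),
                   1.7)
  # control columns carry the baseline means: normalized marginal mean
  # within 2% of the configured baseline average
  k <- SummarizedExperiment::assay(a$counts, "counts")
  meta <- S4Vectors::metadata(a$counts)
  ctrl <- paste0("C", 1:5)
  norm <- sweep(k[, ctrl], 2, meta$size_factors_true[ctrl], `/`)
  expect_lt(abs(mean(norm) - mean(meta$base_means_true)) /
            mean(meta$base_means_true), 0.02)
  # no fold change requested -> no DE truth
  flat <- simulateCountMatrix(simConfig(lfc_magnitude = 0, de_up_frac = 0,
                                        de_down_frac = 0, seed = 13))
  expect_identical(nrow(flat$truth@de_genes), 0L)
  expect_error(simulateCountMatrix(simConfig(n_tumors = 1)), "n_tumors")
})

test_that("gene-set generator plants enrichment and the top gene", {
  cfg <- simConfig(seed = 17)
  gs <- simulateGeneSets(cfg)
  sets <- geneSets(gs$sets)
  expect_length(sets, 20)
  expect_true(all(lengths(sets) == 50))
  expect_true(all(unlist(sets) %in% geneUniverse(gs$sets)))
  expect_identical(gs$truth@enriched_sets, c("SET001", "SET002", "SET003"))
  # top gene sits in the most enriched set and on the cancer list
  expect_true(gs$truth@top_gene %in% sets[["SET001"]])
  expect_true(gs$truth@top_gene %in% gs$cancer_genes)
  de <- gs$truth@de_genes$gene
  frac_de <- vapply(sets, function(s) mean(s %in% de), numeric(1))
  expect_true(all(frac_de[gs$truth@enriched_sets] >= 0.5))
  expect_true(all(frac_de[setdiff(names(sets), gs$truth@enriched_sets)]
                  < 0.3))
  expect_error(simulateGeneSets(simConfig(n_gene_sets = 0)), "n_gene_sets")
})

test_that("noiseless copy-number tracks are exact", {
  cnv <- simulateCopyNumberTracks(simConfig(noise_sd = 0, seed = 19))
  tr <- cnv$truth@deleted_genes
  ex <- cnv$exons
  for (i in seq_len(nrow(tr)))
    expect_true(all(ex$log2_ratio[ex$gene == tr$gene[i]] == tr$true_log2[i]))
  expect_true(all(ex$log2_ratio[!ex$gene %in% tr$gene] == 0))
  # probe shifts exactly inside planted windows
  pr <- cnv$probes
  win <- cnv$truth@cna_windows
  inside <- rep(FALSE, nrow(pr))
  for (i in seq_len(nrow(win)))
    inside <- inside | (pr$pos >= win$start[i] & pr$pos <= win$end[i])
  expect_true(all(pr$log2_ratio[inside] == -1))
  expect_true(all(pr$log2_ratio[!inside] == 0))
})

test_that("null cohort p-values are calibrated at the 5% level", {
  cfg <- simConfig(n_sites = 4000, n_somatic = 0, germline_het_rate = 1,
                   loh_regions = no_loh_regions, seed = 23)
  sim <- simulatePairedCounts(cfg)
  cd <- somaticCalls(callSomatic(sim$sites, seed = 23))
  rate <- mean(cd$p_perm < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(cd))
  expect_lte(rate, 0.05 + 3 * se)
})
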