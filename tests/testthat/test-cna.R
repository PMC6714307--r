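test_that("gene-level summary is the exon median with category cut-offs", {
  g0 <- geneLevelLog2(data.frame(gene = "g", exon_index = 1:3,
                                 log2_ratio = c(0, 0, 0)))
  expect_identical(g0$gene_log2, 0)
  expect_identical(g0$category, "NEUTRAL")
  g1 <- geneLevelLog2(data.frame(gene = "g", exon_index = 1:3,
                                 log2_ratio = c(-1, -1, -1)))
  expect_identical(g1$gene_log2, -1)
  expect_identical(g1$category, "HET_DEL")
  # median is robust to a single outlying exon
  g2 <- geneLevelLog2(data.frame(gene = "g", exon_index = 1:4,
                                 log2_ratio = c(-1.2, -0.8, -1.0, 3.0)))
  expect_equal(g2$gene_log2, -0.9, tolerance = 1e-12)
  expect_identical(g2$category, "HET_DEL")
  expect_identical(
    geneLevelLog2(data.frame(gene = "g", exon_index = 1,
                             log2_ratio = -2.5))$category, "HOM_DEL")
  expect_error(geneLevelLog2(data.frame(gene = "g", exon_index = 1,
                                        log2_ratio = Inf)), "finite")
})

test_that("gene summary is invariant to record order and duplication", {
  ex <- data.frame(gene = rep(c("a", "b"), each = 4), exon_index = 1:4,
                   log2_ratio = c(-1.1, -0.9, -1, -3, 0.1, -0.1, 0, 0.2))
  ref <- geneLevelLog2(ex)
  shuf <- geneLevelLog2(ex[sample(nrow(ex)), ])
  expect_equal(shuf[match(ref$gene, shuf$gene), "gene_log2"],
               ref$gene_log2)
  dup <- geneLevelLog2(rbind(ex, ex))
  expect_equal(dup[match(ref$gene, dup$gene), "gene_log2"], ref$gene_log2)
  expect_identical(dup[match(ref$gene, dup$gene), "category"],
                   ref$category)
})

test_that("LOH status depends only on the two VAFs and thresholds", {
  v <- data.frame(site_id = c("a", "b", "c"),
                  normal_vaf = c(0.50, 0.50, 0.97),
                  tumor_vaf = c(0.98, 0.50, 1.00))
  out <- callLOH(v)
  expect_identical(out$status, c("LOH", "NO_LOH", "UNINFORMATIVE"))
  expect_identical(callLOH(v), out)  # pure function
  low <- callLOH(data.frame(site_id = "d", normal_vaf = 0.45,
                            tumor_vaf = 0.05))
  expect_identical(low$status, "LOH")
  expect_error(callLOH(data.frame(site_id = "e", normal_vaf = 1.2,
                                  tumor_vaf = 0.5)), "\\[0, 1\\]")
})

test_that("regional LOH aggregation tolerates margin-straddling sites", {
  calls <- data.frame(site_id = 1:10, normal_vaf = 0.5, tumor_vaf = 0.9,
                      status = c(rep("LOH", 4), rep("NO_LOH", 4),
                                 rep("UNINFORMATIVE", 2)))
  expect_identical(aggregateLOH(calls), "LOH")       # 4/8 informative
  calls$status[1:3] <- "NO_LOH"
  expect_identical(aggregateLOH(calls), "NO_LOH")    # 1/8 informative
  expect_identical(aggregateLOH(calls[calls$status == "UNINFORMATIVE", ]),
                   "UNINFORMATIVE")
})

test_that("windowed Z flags exactly the aberrant windows", {
  # flat track: nothing to flag
  flat <- data.frame(chrom = "chr1", pos = seq(5000, 3e6, by = 1e4),
                     log2_ratio = 0)
  wf <- windowedZ(flat)
  expect_true(all(wf$z == 0) && !any(wf$flagged))
  # one window shifted to -1 (50 probes); background alternates +/- 0.2 so
  # the global robust spread is known; expected z from direct arithmetic
  pos <- seq(10000, 5e6, by = 2e4)
  lr <- rep(c(0.2, -0.2), length.out = length(pos))
  shift <- pos > 2e6 & pos <= 3e6
  lr[shift] <- -1
  pr <- data.frame(chrom = "chr1", pos = pos, log2_ratio = lr)
  w <- windowedZ(pr)
  sd_g <- 1.4826 * stats::mad(lr, constant = 1)
  z_exp <- -1 / (sd_g / sqrt(sum(shift)))
  hit <- w[w$start == 2e6 + 1, ]
  expect_equal(hit$z, z_exp, tolerance = 1e-12)
  expect_true(hit$flagged)
  expect_identical(w$start[w$flagged], 2e6 + 1)
  # sparse window: never flagged regardless of mean
  sparse <- data.frame(chrom = "chr1",
                       pos = c(seq(5000, 1e6, by = 1e4), 1.5e6, 1.6e6),
                       log2_ratio = c(rep(c(0.1, -0.1), 50), -5, -5))
  ws <- windowedZ(sparse, min_probes = 10)
  expect_false(ws$flagged[ws$start == 1e6 + 1])
  expect_error(windowedZ(pr[rev(seq_len(nrow(pr))), ]), "sorted")
})

test_that("inactivation mechanisms combine deletion, LOH and mutation", {
  expect_identical(classifyInactivation("HET_DEL", "LOH", TRUE)$mechanism,
                   "HET_DELETION_PLUS_MUTATION")
  expect_identical(classifyInactivation("HOM_DEL", "NO_LOH",
                                        FALSE)$mechanism,
                   "HOMOZYGOUS_DELETION")
  expect_identical(classifyInactivation("NEUTRAL", "LOH", TRUE)$mechanism,
                   "COPY_NEUTRAL_LOH_PLUS_MUTATION")
  expect_identical(classifyInactivation("HET_DEL", "LOH", FALSE)$mechanism,
                   "HET_DELETION_ONLY")
  expect_identical(classifyInactivation("NEUTRAL", "NO_LOH",
                                        FALSE)$mechanism,
                   "NO_BIALLELIC_EVIDENCE")
  expect_true(classifyInactivation("HOM_DEL", "NO_LOH", FALSE)$biallelic)
  expect_false(classifyInactivation("HET_DEL", "LOH", FALSE)$biallelic)
})
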