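test_that("RPKM follows the closed-form definition", {
  cnt <- matrix(c(10, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  rcs <- RNACountSet(cnt, gene_lengths = c(1000, 500), groups = "tumor",
                     total_mapped = 1e6)
  r <- computeRPKM(rcs)
  expect_identical(r["a", "s1"], 10)
  expect_identical(r["b", "s1"], 0)
  # doubling the mapped total halves every RPKM in that sample
  rcs2 <- RNACountSet(cnt, gene_lengths = c(1000, 500), groups = "tumor",
                      total_mapped = 2e6)
  expect_equal(computeRPKM(rcs2), r / 2)
  expect_error(RNACountSet(cnt, gene_lengths = c(1000, 500),
                           groups = "tumor", total_mapped = 0),
               "total_mapped")
})

test_that("NB test: symmetric groups, all-zero genes, label swap", {
  mu <- matrix(100, 50, 9)
  rcs <- make_counts(mu, seed = 4)
  k <- SummarizedExperiment::assay(rcs, "counts")
  # a gene with a constant count has identical normalized group means
  k["g0001", ] <- 80L
  k["g0002", ] <- 0L
  rcs2 <- RNACountSet(k, gene_lengths = rep(1000, nrow(k)),
                      groups = c(rep("tumor", 4), rep("control", 5)))
  nb <- nbTest(rcs2)
  expect_lt(abs(nb$log2fc[nb$gene == "g0001"]), 0.05)
  expect_identical(nb$p[nb$gene == "g0002"], 1)
  expect_identical(nb$log2fc[nb$gene == "g0002"], 0)
  expect_true(nb$all_zero[nb$gene == "g0002"])
  expect_true(all(nb$p >= 0 & nb$p <= 1))
  # swapping the group labels negates the fold change, p unchanged
  swapped <- RNACountSet(k, gene_lengths = rep(1000, nrow(k)),
                         groups = c(rep("control", 4), rep("tumor", 5)))
  nb_sw <- nbTest(swapped)
  expect_equal(nb_sw$p, nb$p, tolerance = 1e-9)
  live <- !nb$all_zero
  expect_equal(nb_sw$log2fc[live], -nb$log2fc[live], tolerance = 1e-9)
  one <- RNACountSet(k[, c(1, 5:8)], gene_lengths = rep(1000, nrow(k)),
                     groups = c("tumor", rep("control", 4)))
  expect_error(nbTest(one), "two samples per group")
})

test_that("NB test recovers a planted fold change with sane significance", {
  mu <- matrix(100, 400, 9)
  mu[1:40, 1:4] <- 400
  rcs <- make_counts(mu, seed = 8)
  nb <- nbTest(rcs)
  expect_gte(mean(nb$p[1:40] < 0.05 & nb$log2fc[1:40] > 1), 0.9)
  expect_lte(mean(nb$p[-(1:40)] < 0.05), 0.12)
  expect_equal(mean(nb$log2fc[1:40]), 2, tolerance = 0.15)
})

test_that("DEG selection applies the asymmetric volcano thresholds", {
  res <- data.frame(gene = c("up", "down_weak", "floored", "down_strong"),
                    log2fc = c(1.5, -1.5, 2.0, -1.5),
                    p = c(0.01, 0.01, 0.001, 1e-5),
                    q = c(0.02, 0.02, 0.004, 1e-4))
  rpkm <- matrix(rep(c(2, 2, 0.3, 4), 9), 4, 9,
                 dimnames = list(res$gene,
                                 c(paste0("T", 1:4), paste0("C", 1:5))))
  rpkm["floored", ] <- 0.3
  groups <- c(rep("tumor", 4), rep("control", 5))
  out <- selectDEGs(res, rpkm, groups)
  expect_identical(out$direction[out$gene == "up"], "UP")
  # downregulation demands the stricter p < 0.001
  expect_identical(out$direction[out$gene == "down_weak"], "NONE")
  expect_identical(out$direction[out$gene == "down_strong"], "DOWN")
  # expression floor: higher group mean must exceed 0.5 RPKM
  expect_identical(out$direction[out$gene == "floored"], "NONE")
})

test_that("raising p cut-offs never removes a selected gene", {
  withr::with_seed(31, {
    res <- data.frame(gene = sprintf("g%03d", 1:200),
                      log2fc = rnorm(200, 0, 1.5),
                      p = runif(200)^2, q = NA)
    res$q <- p.adjust(res$p, "BH")
    rpkm <- matrix(rexp(200 * 9, 0.2), 200, 9,
                   dimnames = list(res$gene,
                                   c(paste0("T", 1:4), paste0("C", 1:5))))
    groups <- c(rep("tumor", 4), rep("control", 5))
    strict <- selectDEGs(res, rpkm, groups)
    loose <- selectDEGs(res, rpkm, groups, up_p = 0.2, down_p = 0.05)
    sel_s <- strict$gene[strict$direction != "NONE"]
    sel_l <- loose$gene[loose$direction != "NONE"]
    expect_true(all(sel_s %in% sel_l))
  })
})

test_that("relative expression is a guarded log2 ratio to controls", {
  r <- matrix(c(100, 800, 800, 800), 1, 4,
              dimnames = list("g", c("t", "c1", "c2", "c3")))
  expect_equal(relativeExpression(r, "g", "t", c("c1", "c2", "c3")),
               log2(100.25 / 800.25))
  r2 <- r; r2[1, 1] <- 800
  expect_identical(relativeExpression(r2, "g", "t", c("c1", "c2", "c3")), 0)
  expect_error(relativeExpression(r, "x", "t", "c1"), "not present")
  expect_error(relativeExpression(r, "g", "t", character()), "non-empty")
})

test_that("size factors agree with the reference median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  rna <- simulateCountMatrix(simConfig(n_genes = 500, de_up_frac = 0.04,
                                       de_down_frac = 0.02, seed = 29))
  k <- SummarizedExperiment::assay(rna$counts, "counts")
  sf_pkg <- attr(nbTest(rna$counts), "size_factors")
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  expect_equal(unname(sf_pkg), unname(sf_ref), tolerance = 0.02)
})
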