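test_that("hypergeometric enrichment matches closed forms and enumeration", {
  uni <- paste0("g", 1:20)
  gs <- GeneSetList(list(s1 = paste0("g", 1:5)), universe = uni)
  res <- hypergeomEnrich(paste0("g", 1:5), gs)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(res$q, res$p)  # BH with a single set
  # zero overlap: every assignment is at least as extreme, p = 1
  res0 <- hypergeomEnrich(paste0("g", 6:10), gs)
  expect_identical(res0$k, 0L)
  expect_equal(res0$p, 1, tolerance = 1e-12)
  # enumeration oracle over a parameter sweep
  withr::with_seed(41, {
    for (i in 1:25) {
      N <- sample(10:60, 1)
      K <- sample(2:(N - 2), 1)
      n <- sample(2:(N - 2), 1)
      u <- paste0("x", seq_len(N))
      set <- sample(u, K)
      query <- sample(u, n)
      k <- length(intersect(set, query))
      p <- hypergeomEnrich(query,
                           GeneSetList(list(s = set), universe = u))$p
      expect_equal(p, hyper_tail_enum(k, K, N, n), tolerance = 1e-12)
    }
  })
  expect_error(hypergeomEnrich(character(), gs), "empty query")
  expect_warning(hypergeomEnrich(c("g1", "zzz"), gs), "outside")
})

test_that("BH q-values are monotone and ordering is deterministic", {
  withr::with_seed(43, {
    uni <- paste0("g", 1:200)
    sets <- lapply(1:30, function(i) sample(uni, 25))
    names(sets) <- sprintf("S%02d", 1:30)
    res <- hypergeomEnrich(sample(uni, 40),
                           GeneSetList(sets, universe = uni), q_max = 0.05)
    expect_false(is.unsorted(res$p))
    expect_false(is.unsorted(res$q))            # monotone in p-rank
    expect_true(all(res$q >= res$p - 1e-15))
    # ties broken by set name
    tied <- res[duplicated(res$p) | duplicated(res$p, fromLast = TRUE), ]
    for (pv in unique(tied$p))
      expect_false(is.unsorted(tied$set[tied$p == pv]))
  })
})

test_that("random queries yield super-uniform enrichment p-values", {
  withr::with_seed(47, {
    uni <- paste0("g", 1:500)
    sets <- lapply(1:200, function(i) sample(uni, 20))
    names(sets) <- sprintf("R%03d", 1:200)
    res <- hypergeomEnrich(sample(uni, 50),
                           GeneSetList(sets, universe = uni))
    for (alpha in c(0.05, 0.1, 0.25)) {
      se <- sqrt(alpha * (1 - alpha) / 200)
      expect_lte(mean(res$p <= alpha), alpha + 3 * se)
    }
  })
})

test_that("overlap matrix is consistent with the per-set overlap counts", {
  uni <- paste0("g", 1:40)
  sets <- list(A = paste0("g", 1:10), B = paste0("g", 11:20),
               C = paste0("g", 5:14))
  gsl <- GeneSetList(sets, universe = uni)
  query <- paste0("g", c(1:8, 12, 30))
  enr <- hypergeomEnrich(query, gsl, q_max = 1)   # flag all for the matrix
  om <- overlapMatrix(enr, gsl, genes = query)
  expect_identical(colSums(om)[enr$set], setNames(as.double(enr$k),
                                                  enr$set))
  expect_true(all(rowSums(om) >= 1))
  # disjoint sets: no gene can sit in two of them
  om2 <- overlapMatrix(enr, GeneSetList(sets[c("A", "B")], universe = uni))
  expect_true(all(rowSums(om2) <= 1))
  # a gene present in all enriched sets has a full row
  expect_identical(sum(om["g5", c("A", "C")]), 2L)
})

test_that("cancer-gene ranking uses p, then effect size, then name", {
  deg <- data.frame(gene = c("a", "b", "c", "d"),
                    p = c(1e-5, 1e-5, 1e-3, 0.5),
                    log2fc = c(2, 2, -3, 1))
  rk <- cancerIntersectRank(c("a", "b", "c", "d"),
                            cancer_genes = c("a", "b", "c"), deg = deg)
  expect_identical(rk$gene, c("a", "b", "c"))    # name breaks the a/b tie
  expect_identical(rk$rank, 1:3)
  expect_message(
    empty <- cancerIntersectRank(c("a", "b"), cancer_genes = "z",
                                 deg = deg),
    "cancer list")
  expect_identical(nrow(empty), 0L)
  expect_error(cancerIntersectRank("zz", cancer_genes = "zz", deg = deg),
               "cover")
})

test_that("subgroup scoring labels by reference-relative signatures", {
  r <- matrix(1000, 5, 1, dimnames = list(c("ref", "a1", "a2", "b1", "b2"),
                                          "s"))
  r[c("a1", "a2"), 1] <- 2000
  r[c("b1", "b2"), 1] <- 500
  sig <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  sc <- subgroupScore(r, "s", sig, "ref")
  expect_identical(sc$label, "A")
  expect_equal(unname(sc$scores["A"]), 1, tolerance = 0.01)
  expect_equal(unname(sc$scores["B"]), -1, tolerance = 0.01)
  # perfect tie is not forced into a label
  r2 <- r; r2[c("b1", "b2"), 1] <- 2000
  expect_identical(subgroupScore(r2, "s", sig, "ref")$label,
                   "UNCLASSIFIED")
  expect_error(subgroupScore(r, "s", sig, "missing"), "absent")
  expect_error(subgroupScore(r, "s", list(A = c("a1", "ref")), "ref"),
               "signature")
})
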