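test_that("mean normal expression is the per-gene arithmetic mean", {
  m <- matrix(c(2, 4, 1, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("n1", "n2")))
  expect_equal(mean_normal_expression(m, c("n1", "n2")),
               c(g1 = 1.5, g2 = 3.5))
  expect_equal(mean_normal_expression(m, "n1"), c(g1 = 2, g2 = 4))
  expect_error(mean_normal_expression(m, character(0)), "at least one")

  set.seed(1)
  big <- matrix(rexp(50), 10, 5,
                dimnames = list(paste0("g", 1:10), paste0("n", 1:5)))
  oracle <- apply(big, 1, function(r) sum(r) / length(r))
  expect_equal(mean_normal_expression(big, colnames(big)), oracle,
               tolerance = 1e-12)
})

test_that("DEG calling applies strict fold-change thresholds", {
  nm <- c(a = 1, b = 1, c = 1)
  # FC exactly 1 / exactly 2 excluded; just above 2 included
  x1 <- c(a = 1.01, b = 2.02, c = 2.0301)   # FCs 1, 2, 2.01 with pc 0.01
  degs <- call_degs(x1, nm, pseudocount = 0.01)
  expect_identical(degs$gene, "c")
  expect_identical(degs$direction, "up")

  fcs <- c(3, 2, 1, 0.5, 0.4, 0.1)
  x2 <- setNames(fcs * 1.01, paste0("g", 1:6))
  nm2 <- setNames(rep(1, 6), paste0("g", 1:6))
  degs2 <- call_degs(x2, nm2, pseudocount = 0.01)
  expect_setequal(degs2$gene, c("g1", "g5", "g6"))
  expect_identical(degs2$direction[degs2$gene == "g1"], "up")
  expect_identical(degs2$direction[degs2$gene == "g6"], "down")

  expect_error(call_degs(x2[1:5], nm2, 0.01), "aligned")
})

test_that("hypergeometric pmf and tail match exhaustive enumeration", {
  expect_equal(hypergeom_pmf(10, 0, 5, 0), 1)
  expect_equal(hypergeom_pmf(10, 4, 3, 4), 0)       # k > n
  expect_equal(hypergeom_pmf(10, 4, 5, 2), 120 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 4, 5, 0), 1)
  expect_error(hypergeom_pmf(10, 11, 5, 2), "M")

  for (N in c(5, 8)) for (M in 0:N) for (n in 0:N) {
    for (k in 0:min(M, n)) {
      oracle <- enum_hyper(N, M, n, k)
      expect_equal(hypergeom_pmf(N, M, n, k), oracle$pmf, tolerance = 1e-12)
      expect_equal(hypergeom_tail(N, M, n, k), oracle$tail, tolerance = 1e-12)
    }
  }
})

test_that("tail normalises against the pmf and is monotone in k", {
  set.seed(2)
  for (rep in 1:20) {
    N <- sample(5:60, 1); M <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(M, n), 1)
    below <- if (k > 0) sum(vapply(0:(k - 1), function(j)
      hypergeom_pmf(N, M, n, j), numeric(1))) else 0
    expect_equal(hypergeom_tail(N, M, n, k) + below, 1, tolerance = 1e-12)
    tails <- vapply(0:min(M, n), function(j)
      hypergeom_tail(N, M, n, j), numeric(1))
    expect_true(all(diff(tails) <= 1e-15))
  }
})

test_that("the TCD profile encodes per-sample enrichment correctly", {
  genes <- paste0("g", 1:10)
  normal <- matrix(1, 10, 2, dimnames = list(genes, c("n1", "n2")))
  # tumour sample tt: genes g1..g4 at FC ~3 (DEGs), rest at FC ~1
  tumour <- matrix(1, 10, 1, dimnames = list(genes, "tt"))
  tumour[1:4, 1] <- 3
  expr <- cbind(normal, tumour)
  sigs <- list(stateA = c("g1", "g2", "g3", "g7", "g8"))
  pr <- build_tcd_profile(expr, sigs, c("n1", "n2"))
  expect_equal(unname(pr$p["stateA", "tt"]), 66 / 252, tolerance = 1e-12)
  expect_equal(pr$universe_size, 10)
  expect_equal(unname(pr$n_deg[["tt"]]), 4)

  # tumour equal to the normal mean: no DEGs, all p = 1
  flat <- cbind(normal, matrix(1, 10, 1, dimnames = list(genes, "t2")))
  pr2 <- build_tcd_profile(flat, list(s1 = genes[1:3], s2 = genes[4:9]),
                           c("n1", "n2"))
  expect_true(all(pr2$p == 1))

  # zero-overlap signature: warning and p = 1
  expect_warning(
    pr3 <- build_tcd_profile(expr, list(empty = c("zz1", "zz2")), c("n1", "n2")),
    "no overlap")
  expect_true(all(pr3$p["empty", ] == 1))

  expect_error(build_tcd_profile(expr, sigs, colnames(expr)), "tumour")
})

test_that("profile entries are probabilities and the transform is monotone", {
  co <- small_cohort(seed = 13)
  pr <- build_tcd_profile(co$expression, co$signatures, normal_ids_of(co))
  expect_true(all(pr$p >= 0 & pr$p <= 1))
  expect_true(all(pr$neglog10 >= 0))
  o <- order(pr$p)
  expect_true(all(diff(pr$neglog10[o]) <= 1e-12))
})

test_that("planted severity raises enrichment monotonically", {
  co <- small_cohort(seed = 17)
  pr <- build_tcd_profile(co$expression, co$signatures, normal_ids_of(co))
  truth <- co$truth$subtype
  med <- sapply(1:4, function(s)
    median(pr$neglog10["exhaustion", names(truth)[truth == s]]))
  expect_true(all(diff(med) > 0))
})
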