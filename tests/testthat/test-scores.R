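test_that("mean-z scores are population z-scores averaged over set members", {
  m <- matrix(c(1, 3), 1, 2, dimnames = list("g1", c("s1", "s2")))
  sc <- signature_score(m, list(set = "g1"))
  # population sd of (1, 3) is 1, so the z-scores are -1 and +1
  expect_equal(unname(sc["set", ]), c(-1, 1))
  expect_lt(abs(mean(sc)), 1e-8)

  const <- matrix(1, 2, 3, dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  expect_error(suppressWarnings(signature_score(const, list(bad = c("g1", "g2")))),
               "bad")
})

test_that("mean-z is affine-invariant per gene; rank-z is monotone-invariant per sample", {
  set.seed(6)
  X <- matrix(rexp(5 * 12), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  sets <- list(a = c("g1", "g3"), b = c("g2", "g4", "g5"))
  base <- signature_score(X, sets)
  Y <- X
  Y["g3", ] <- 7 * X["g3", ] + 2       # affine rescale of one gene row
  expect_equal(signature_score(Y, sets), base, tolerance = 1e-12)

  rbase <- signature_score(X, sets, method = "rank-z")
  Z <- X^3                              # strictly monotone per-sample transform
  expect_equal(signature_score(Z, sets, method = "rank-z"), rbase,
               tolerance = 1e-12)
})

test_that("planted severity shows up as increasing exhaustion scores", {
  co <- small_cohort(seed = 23)
  tum <- names(co$truth$subtype)
  sc <- signature_score(log2(co$expression[, tum] + 1), co$signatures)
  means <- sapply(1:4, function(s)
    mean(sc["exhaustion", names(co$truth$subtype)[co$truth$subtype == s]]))
  expect_true(all(diff(means) > 0))
})

test_that("group summaries compute the requested statistic and reference proportions", {
  v <- setNames(c(1, 2, 3, 10), paste0("s", 1:4))
  lab <- c("A", "A", "A", "B")
  gs <- group_summary(v, lab, stat = "median", reference = "B")
  expect_equal(unname(gs$summary[, 1]), c(2, 10))
  expect_equal(unname(gs$relative["A", 1]), 0.2)
  expect_error(group_summary(v, lab, reference = "Z"), "unknown reference")

  one <- group_summary(v, rep("A", 4), stat = "mean")
  expect_equal(unname(one$summary[1, 1]), 4)
})

test_that("pearson matrix matches the textbook formula", {
  set.seed(4)
  X <- matrix(rnorm(5 * 50), 5, 50, dimnames = list(paste0("f", 1:5), NULL))
  C <- pearson_matrix(X)
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    xi <- X[i, ]; xj <- X[j, ]
    oracle[i, j] <- mean((xi - mean(xi)) * (xj - mean(xj))) /
      (sqrt(mean((xi - mean(xi))^2)) * sqrt(mean((xj - mean(xj))^2)))
  }
  expect_equal(unname(C), oracle, tolerance = 1e-10)
  expect_equal(unname(diag(C)), rep(1, 5))
  expect_equal(unname(pearson_matrix(rbind(X[1, , drop = FALSE],
                                           -X[1, , drop = FALSE]))[1, 2]), -1)
  Xz <- rbind(X, zero = rep(2, 50))
  expect_warning(Cz <- pearson_matrix(Xz), "zero-variance")
  expect_true(all(is.na(Cz["zero", -6])))
})

test_that("anti-correlated target selection filters on both criteria", {
  set.seed(19)
  n <- 60
  lab <- rep(c("T-low", "T-high"), each = n / 2)
  names(lab) <- paste0("s", 1:n)
  m <- setNames(rnorm(n, ifelse(lab == "T-high", 8, 2)), names(lab))
  genes <- rbind(
    self = m,                                   # r = 1, excluded
    anti = -m + 20,                             # r = -1, higher in T-low
    anti_low = -m + 2                           # r = -1 but equal group means? no: higher T-low too
  )
  genes["anti_low", ] <- -m + rnorm(n, 0, 0.01) # still higher in T-low
  colnames(genes) <- names(lab)
  hits <- anticorrelated_targets(m, genes, lab)
  expect_true("anti" %in% hits)
  expect_false("self" %in% hits)
})

test_that("planted miRNA targets are recovered from the cohort", {
  co <- generate_cohort(cohort_config(seed = 29))
  tum <- names(co$truth$subtype)
  lab <- setNames(ifelse(co$truth$subtype == 4, "T-high",
                         ifelse(co$truth$subtype == 1, "T-low", "mid")), tum)
  mir <- co$mirna[co$truth$up_panel[1], tum]
  cand <- unique(co$mirna_targets$gene)
  hits <- anticorrelated_targets(mir, log2(co$expression[cand, tum] + 1), lab)
  expect_setequal(hits, co$truth$target_genes)
})

test_that("over-representation reuses the hypergeometric tail and BH", {
  universe <- paste0("g", 1:10)
  hits <- paste0("g", 1:4)
  res <- overrepresentation(hits, universe,
                            list(pw = c("g1", "g2", "g3", "g7", "g8"),
                                 disjoint = c("g9", "g10")))
  expect_equal(res$p[res$pathway == "pw"], 66 / 252, tolerance = 1e-12)
  expect_equal(res$p[res$pathway == "disjoint"], 1)
  expect_error(overrepresentation(c("g1", "zz"), universe, list(a = "g1")),
               "zz")

  ps <- c(0.01, 0.02, 0.03)
  expect_equal(bh_adjust(ps), rep(0.03, 3))
})
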