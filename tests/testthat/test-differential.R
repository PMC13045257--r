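test_that("duplicated data across disjoint groups gives zero log2FC; overlap errors", {
  X <- matrix(rexp(10 * 4), 10, 4,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
  X[, 3:4] <- X[, 1:2]
  de <- two_group_de(X, c("s1", "s2"), c("s3", "s4"))
  expect_equal(de$log2FC, rep(0, 10))
  expect_equal(de$p, rep(1, 10))
  expect_error(two_group_de(X, c("s1", "s2"), c("s2", "s3")), "overlap")
})

test_that("separated constant groups hit the floor p with the forced sign", {
  X <- matrix(c(rep(2^8 - 1, 3), rep(2^2 - 1, 3)), 1, 6,
              dimnames = list("f1", paste0("s", 1:6)))
  de <- two_group_de(X, paste0("s", 1:3), paste0("s", 4:6), log_transform = TRUE)
  expect_equal(de$log2FC, 6)
  expect_lte(de$p, 1e-300)
  expect_gt(de$p, 0)
})

test_that("welch t matches stats::t.test row by row", {
  set.seed(12)
  X <- matrix(rnorm(20 * 14, 5), 20, 14,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:14)))
  A <- paste0("s", 1:6); B <- paste0("s", 7:14)
  de <- two_group_de(X, A, B, log_transform = FALSE)
  for (i in c(1, 7, 20)) {
    tt <- t.test(X[i, A], X[i, B])
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2FC[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("group swap negates the effect and preserves p", {
  set.seed(13)
  X <- matrix(rexp(50 * 10), 50, 10,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:10)))
  A <- paste0("s", 1:5); B <- paste0("s", 6:10)
  d1 <- two_group_de(X, A, B)
  d2 <- two_group_de(X, B, A)
  expect_equal(d1$log2FC, -d2$log2FC)
  expect_equal(d1$p, d2$p)
})

test_that("the null rejection rate is calibrated", {
  set.seed(71)
  X <- matrix(2^rnorm(2000 * 40, 5, 1), 2000, 40,
              dimnames = list(paste0("f", 1:2000), paste0("s", 1:40)))
  de <- two_group_de(X, paste0("s", 1:20), paste0("s", 21:40))
  rate <- mean(de$p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("BH adjustment equals the independent step-up oracle", {
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  p <- runif(1000)
  q <- bh_adjust(p)
  expect_equal(q, bh_step_up(p), tolerance = 1e-12)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(bh_adjust(q) >= q - 1e-15))      # re-adjusting never decreases
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))           # nondecreasing in p order
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DE selection uses strict thresholds on both criteria", {
  rec <- data.frame(feature = c("a", "b", "c"),
                    log2FC = c(1.0, -2, 3), p = c(0.005, 0.001, 0.02))
  sel <- select_de_features(rec)
  expect_setequal(sel$feature, "b")   # a fails strict |log2FC| > 1, c fails p
})

test_that("planted miRNAs are recovered exactly, one-vs-rest", {
  for (seed in c(2, 5, 8)) {
    co <- generate_cohort(cohort_config(samples_per_subtype = 100,
                                        n_normal = 10, n_genes = 600,
                                        seed = seed))
    tum <- names(co$truth$subtype)
    A <- tum[co$truth$subtype == 4]
    B <- setdiff(tum, A)
    de <- two_group_de(co$mirna[, tum], A, B)
    sel <- select_de_features(de)
    expect_setequal(sel$feature, co$truth$informative_mirnas)
  }
})

test_that("DMP detection gates on delta and q", {
  set.seed(33)
  n <- 50
  mkprobe <- function(m) pmin(pmax(rnorm(2 * n, m, 0.05), 0), 1)
  beta <- rbind(
    strong = c(rnorm(n, 0.80, 0.05), rnorm(n, 0.60, 0.05)),
    weak = c(rnorm(n, 0.50, 0.05), rnorm(n, 0.40, 0.05))
  )
  beta <- pmin(pmax(beta, 0), 1)
  colnames(beta) <- paste0("s", 1:(2 * n))
  A <- paste0("s", 1:n); B <- paste0("s", (n + 1):(2 * n))
  rec <- find_dmps(beta, A, B)
  expect_true(rec$selected[rec$feature == "strong"])
  expect_false(rec$selected[rec$feature == "weak"])   # delta 0.10 < 0.15
  expect_error(find_dmps(beta * 2, A, B), "\\[0, 1\\]")
})

test_that("the null beta matrix yields no DMPs", {
  total <- 0
  for (seed in 1:10) {
    set.seed(seed)
    beta <- matrix(plogis(rnorm(500 * 40, 1, 0.5)), 500, 40,
                   dimnames = list(paste0("cg", 1:500), paste0("s", 1:40)))
    rec <- find_dmps(beta, paste0("s", 1:20), paste0("s", 21:40))
    total <- total + sum(rec$selected)
  }
  expect_lte(total, 1)
})

test_that("planted DMP probes separate the extreme subtypes", {
  co <- small_cohort(seed = 37)
  tum <- names(co$truth$subtype)
  A <- tum[co$truth$subtype == 4]; B <- tum[co$truth$subtype == 1]
  rec <- find_dmps(co$beta[, c(A, B)], A, B)
  found <- rec$feature[rec$selected]
  expect_setequal(found, co$truth$dmp_probes)
})
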