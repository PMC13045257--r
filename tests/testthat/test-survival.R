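test_that("KM estimates equal the hand product-limit", {
  # all censored: survival never drops
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km0), 0)

  km1 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km1$surv, c(2 / 3, 0))
  expect_equal(km1$n_risk, c(3, 1))

  set.seed(10)
  time <- rexp(100); event <- rbinom(100, 1, 0.7)
  km <- km_estimate(time, event)
  oracle <- km_hand(time, event)
  expect_equal(km$time, oracle$time)
  expect_equal(km$surv, oracle$surv, tolerance = 1e-12)

  perm <- sample(100)
  expect_equal(km_estimate(time[perm], event[perm]), km)  # order invariance
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank detects planted effects and is silent on duplicates", {
  time <- rexp(30); event <- rbinom(30, 1, 0.8)
  lr0 <- logrank_test(c(time, time), c(event, event), rep(1:2, each = 30))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  expect_error(logrank_test(time, event, rep(1, 30)), "two nonempty")

  cfg <- cohort_config(seed = 1, surv_base_hazard = 0.1,
                       surv_log_hr_per_severity = 1.0, censor_fraction = 0.2)
  for (seed in c(3, 14, 25)) {
    set.seed(seed)
    clin <- generate_survival(rep(1:2, each = 200), cfg)
    lr <- logrank_test(clin$os_time, clin$os_event, clin$group)
    expect_lt(lr$p, 0.001)
  }
})

test_that("cox fit maximises the Breslow partial likelihood on a toy dataset", {
  toy <- data.frame(time = c(1, 2, 2, 4, 5, 6),
                    event = c(1, 1, 0, 1, 0, 1),
                    x = c(2, 1, 3, 0, 2, 1))
  fit <- cox_fit(toy, "x")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, breslow_loglik_1d, numeric(1),
               time = toy$time, event = toy$event, x = toy$x)
  expect_lt(abs(unname(fit$coef) - grid[which.max(ll)]), 1e-4)
  # the fitted maximum dominates every grid point
  expect_gte(breslow_loglik_1d(unname(fit$coef), toy$time, toy$event, toy$x),
             max(ll) - 1e-10)
})

test_that("cox fit agrees with survival::coxph under Breslow ties", {
  set.seed(20)
  n <- 150
  df <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  df$time <- round(rexp(n, exp(0.6 * df$x1 - 0.4 * df$x2) * 0.2), 1) + 0.1
  df$event <- rbinom(n, 1, 0.8)
  fit <- cox_fit(df, c("x1", "x2"))
  ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = df,
                         ties = "breslow")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(unname(fit$hr), unname(exp(coef(ref))), tolerance = 1e-6)
})

test_that("cox fit is scale-equivariant and covers the null", {
  set.seed(30)
  n <- 200
  df <- data.frame(x = rnorm(n), time = rexp(n), event = rbinom(n, 1, 0.8))
  f1 <- cox_fit(df, "x")
  df2 <- df; df2$x <- df$x * 10
  f2 <- cox_fit(df2, "x")
  expect_equal(unname(f1$coef), unname(f2$coef) * 10, tolerance = 1e-6)

  covered <- 0
  for (seed in 1:10) {
    set.seed(seed)
    d <- data.frame(x = rnorm(100), time = rexp(100), event = 1)
    f <- cox_fit(d, "x")
    covered <- covered + (abs(f$coef) < 3 * f$se)
  }
  expect_gte(covered, 9)
  expect_error(cox_fit(data.frame(time = 1:5, event = rep(1, 5), x = 1), "x"),
               "constant")
})

test_that("univariate screening keeps planted prognostic features", {
  set.seed(44)
  n <- 800
  X <- matrix(rnorm(6 * n), 6, n, dimnames = list(paste0("m", 1:6),
                                                  paste0("s", 1:n)))
  lp <- 0.8 * (X[1, ] - X[2, ] + X[3, ] + X[4, ] - X[5, ]) / sqrt(5)
  rec <- data.frame(sample_id = colnames(X),
                    os_time = rexp(n, exp(lp) * 0.1),
                    os_event = 1)
  sel <- univariate_screen(X, rec)
  expect_setequal(sel, paste0("m", 1:5))        # m6 carries no effect
  scr <- attr(sel, "screen")
  expect_true(all(scr$p[match(paste0("m", 1:5), scr$feature)] < 0.05))
})

test_that("risk scores follow x'beta and the median split is balanced", {
  model <- structure(list(coef = c(a = 1, b = -1), covariates = c("a", "b")),
                     class = "cox_risk_model")
  X <- matrix(c(2, 3), 1, 2, dimnames = list("s1", c("a", "b")))
  expect_error(risk_scores(model, X), "identical")  # single sample: degenerate
  X4 <- matrix(c(2, 0, 1, 5, 3, 0, 0, 1), 4, 2,
               dimnames = list(paste0("s", 1:4), c("a", "b")))
  rs <- risk_scores(model, X4)
  expect_equal(rs$score, c(-1, 0, 1, 4))
  expect_equal(sum(rs$group == "high"), 2)
  expect_equal(rs$group[rs$score >= attr(rs, "threshold")],
               rep("high", 2))

  model0 <- structure(list(coef = c(a = 0, b = 0), covariates = c("a", "b")),
                      class = "cox_risk_model")
  expect_error(risk_scores(model0, X4), "identical")

  # single positive coefficient: high-risk group has the higher covariate median
  modp <- structure(list(coef = c(a = 2), covariates = "a"),
                    class = "cox_risk_model")
  set.seed(3)
  Xp <- matrix(rnorm(40), 40, 1, dimnames = list(paste0("s", 1:40), "a"))
  rp <- risk_scores(modp, Xp)
  expect_gt(median(Xp[rp$group == "high", 1]),
            median(Xp[rp$group == "low", 1]))
})

test_that("a frozen model transfers to an external cohort", {
  set.seed(55)
  gen <- function(n, effect = 1) {
    x <- rnorm(n)
    data.frame(sample_id = paste0("s", seq_len(n)), x = x,
               os_time = rexp(n, exp(effect * x) * 0.1),
               os_event = rbinom(n, 1, 0.85))
  }
  train <- gen(300)
  model <- cox_fit(train, "x")
  Xtr <- matrix(train$x, dimnames = list(train$sample_id, "x"))
  internal <- risk_scores(model, Xtr)
  val_same <- validate_model(model, train, Xtr)
  expect_identical(val_same$stratification$group, internal$group)

  external <- gen(300)
  Xex <- matrix(external$x, dimnames = list(external$sample_id, "x"))
  val <- validate_model(model, external, Xex)
  expect_lt(val$logrank$p, 0.01)
  expect_named(val$km, c("high", "low"))
})
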