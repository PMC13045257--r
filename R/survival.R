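#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator over distinct event times; samples
#' censored exactly at an event time are counted at risk at that time.
#' Estimation is delegated to \pkg{survival}'s `survfit`.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 event, 0 censored).
#' @return An object of class `km_curve`: data.frame with `time`, `n_risk`,
#'   `n_event` and `surv` at the distinct event times.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) .stop_input("at least one record is required")
  if (any(!is.finite(time)) || any(time <= 0))
    .stop_input("all times must be positive")
  if (!all(event %in% c(0, 1))) .stop_input("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], surv = fit$surv[keep])
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test for survival differences between groups
#'
#' Observed-versus-expected chi-square statistic across pooled event times
#' (via \pkg{survival}'s `survdiff`), with `g - 1` degrees of freedom.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 event, 0 censored).
#' @param group Group label per sample (at least two nonempty groups).
#' @return List with `chisq`, `df` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) .stop_input("at least two nonempty groups are required")
  if (any(table(group) == 0)) .stop_input("a group has zero samples")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

# Breslow partial log-likelihood, score and observed information at beta.
# X rows sorted by ascending time; ties share the full risk-set sums.
.cox_breslow <- function(beta, time, event, X) {
  n <- nrow(X); p <- ncol(X)
  eta <- as.vector(X %*% beta)
  w <- exp(eta)
  if (any(!is.finite(w))) return(list(loglik = -Inf))
  S0 <- rev(cumsum(rev(w)))
  S1 <- apply(X * w, 2, function(cc) rev(cumsum(rev(cc))))
  S1 <- matrix(S1, n, p)
  first <- match(time, time)           # first index of each tie block
  S0b <- S0[first]
  S1b <- S1[first, , drop = FALSE]
  ev <- which(event == 1)
  loglik <- sum(eta[ev]) - sum(log(S0b[ev]))
  U <- colSums(X[ev, , drop = FALSE]) - colSums(S1b[ev, , drop = FALSE] / S0b[ev])
  # S2 risk-set sums per covariate pair
  I <- matrix(0, p, p)
  S2b <- vector("list", p)
  for (a in seq_len(p)) {
    Sa <- apply(X * (X[, a] * w), 2, function(cc) rev(cumsum(rev(cc))))
    Sa <- matrix(Sa, n, p)
    S2b[[a]] <- Sa[first, , drop = FALSE]
  }
  for (i in ev) {
    m <- S1b[i, ] / S0b[i]
    S2i <- t(vapply(seq_len(p), function(a) S2b[[a]][i, ], numeric(p)))
    I <- I + S2i / S0b[i] - tcrossprod(m)
  }
  list(loglik = loglik, U = U, I = I)
}

#' Fit a Cox proportional-hazards model by partial likelihood
#'
#' Maximises the Breslow partial likelihood by Newton-Raphson with
#' step-halving, starting from zero coefficients; convergence is declared
#' when the largest absolute score component falls below `1e-8` (or after 50
#' iterations). Standard errors come from the inverse observed information;
#' per-covariate Wald p-values are reported. The baseline hazard is not
#' estimated: risk ranking needs only the linear predictor.
#'
#' @param records Data.frame with columns `time` (or `os_time`), `event` (or
#'   `os_event`) and the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return An object of class `cox_risk_model`: `coef`, `se`, `z`, `p`, `hr`,
#'   `loglik`, `iter`, `converged`, `covariates`, `n`, `n_events`.
#' @export
cox_fit <- function(records, covariates) {
  time <- records[["time"]] %||% records[["os_time"]]
  event <- records[["event"]] %||% records[["os_event"]]
  if (is.null(time) || is.null(event))
    .stop_input("records must contain time/os_time and event/os_event columns")
  missing <- setdiff(covariates, names(records))
  if (length(missing)) .stop_input("missing covariate: '%s'", missing[1L])
  X <- as.matrix(records[, covariates, drop = FALSE])
  if (any(!is.finite(X))) .stop_input("covariates must be finite")
  if (sum(event) < 2) .stop_input("at least 2 events are required")
  const <- apply(X, 2, function(cc) max(cc) == min(cc))
  if (any(const))
    .stop_input("constant covariate: '%s'", covariates[const][1L])

  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  # centre covariates for numerical stability (shift-invariant likelihood)
  centre <- colMeans(X)
  Xc <- sweep(X, 2, centre)

  beta <- rep(0, ncol(Xc))
  fit <- .cox_breslow(beta, time, event, Xc)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(50L)) {
    if (max(abs(fit$U)) < 1e-8) { converged <- TRUE; break }
    delta <- tryCatch(solve(fit$I, fit$U), error = function(e)
      .stop_input("singular information matrix; covariates may be collinear or separated"))
    step <- 1
    repeat {
      cand <- beta + step * delta
      newfit <- .cox_breslow(cand, time, event, Xc)
      if (is.finite(newfit$loglik) && newfit$loglik >= fit$loglik - 1e-12) break
      step <- step / 2
      if (step < 1e-10)
        .stop_input("Cox fit failed to improve the partial likelihood; possible complete separation")
    }
    beta <- cand
    fit <- newfit
  }
  if (!converged && max(abs(fit$U)) < 1e-8) converged <- TRUE
  if (!is.finite(fit$loglik) || any(!is.finite(beta)))
    .stop_input("Cox fit diverged; possible complete separation")
  vcov <- tryCatch(solve(fit$I), error = function(e)
    .stop_input("singular information matrix at the optimum"))
  se <- sqrt(diag(vcov))
  z <- beta / se
  structure(list(
    coef = stats::setNames(beta, covariates),
    se = stats::setNames(se, covariates),
    z = stats::setNames(z, covariates),
    p = stats::setNames(2 * stats::pnorm(-abs(z)), covariates),
    hr = stats::setNames(exp(beta), covariates),
    loglik = fit$loglik,
    iter = iter,
    converged = converged,
    covariates = covariates,
    n = nrow(Xc),
    n_events = sum(event)
  ), class = "cox_risk_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Univariate Cox screen over a feature panel
#'
#' One single-covariate [cox_fit()] per feature; features whose Wald p-value
#' is strictly below `alpha` are selected. Features whose fit fails are
#' skipped with a warning.
#'
#' @param features Numeric features x samples matrix, columns aligned with
#'   `records` rows (by `sample_id` when present).
#' @param records Survival data.frame (`sample_id`, time and event columns).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of selected feature names, with attribute
#'   `screen`: a data.frame of per-feature coefficients and p-values.
#' @export
univariate_screen <- function(features, records, alpha = 0.05) {
  if (!is.null(records$sample_id)) {
    if (!all(records$sample_id %in% colnames(features)))
      .stop_input("features do not cover all records")
    features <- features[, records$sample_id, drop = FALSE]
  } else if (ncol(features) != nrow(records)) {
    .stop_input("features are not aligned with records")
  }
  rows <- lapply(rownames(features), function(f) {
    rec <- records
    rec[[".x"]] <- as.numeric(features[f, ])
    fit <- tryCatch(cox_fit(rec, ".x"), error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("univariate fit skipped for '%s': %s", f,
                      conditionMessage(fit)), call. = FALSE)
      return(data.frame(feature = f, coef = NA_real_, hr = NA_real_,
                        se = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(feature = f, coef = unname(fit$coef), hr = unname(fit$hr),
               se = unname(fit$se), p = unname(fit$p), stringsAsFactors = FALSE)
  })
  screen <- do.call(rbind, rows)
  selected <- screen$feature[!is.na(screen$p) & screen$p < alpha]
  attr(selected, "screen") <- screen
  selected
}

#' Linear risk scores and median-split stratification
#'
#' `f(X) = x'beta` per sample from a fitted Cox model; samples at or above
#' the median score form the high-risk group, samples below it the low-risk
#' group.
#'
#' @param model A `cox_risk_model`.
#' @param X Samples x covariates matrix (columns matching the model).
#' @param threshold Optional score threshold; defaults to the median of the
#'   computed scores.
#' @return An object of class `risk_stratification`: data.frame `sample`,
#'   `score`, `group` with attribute `threshold`.
#' @export
risk_scores <- function(model, X, threshold = NULL) {
  if (!inherits(model, "cox_risk_model")) .stop_input("not a cox_risk_model")
  missing <- setdiff(model$covariates, colnames(X))
  if (length(missing)) .stop_input("missing covariate: '%s'", missing[1L])
  score <- as.vector(as.matrix(X[, model$covariates, drop = FALSE]) %*% model$coef)
  if (max(score) == min(score))
    .stop_input("all risk scores identical; median split degenerate - supply an explicit threshold policy")
  if (is.null(threshold)) threshold <- stats::median(score)
  group <- ifelse(score >= threshold, "high", "low")
  if (length(unique(group)) < 2)
    .stop_input("degenerate stratification: all samples on one side of the threshold")
  out <- data.frame(sample = rownames(X) %||% seq_along(score),
                    score = score, group = group, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("risk_stratification", "data.frame")
  out
}

#' Validate a frozen Cox risk model on an external cohort
#'
#' Applies the fitted coefficients without refitting, median-splits the
#' external risk scores, and compares the two groups by Kaplan-Meier curves
#' and the log-rank test.
#'
#' @param model A `cox_risk_model`.
#' @param records External survival data.frame (time/event columns).
#' @param X External samples x covariates matrix, rows aligned with
#'   `records`.
#' @return List with `stratification`, `logrank` and `km` (per-group
#'   [km_estimate()] curves).
#' @export
validate_model <- function(model, records, X) {
  strat <- risk_scores(model, X)
  time <- records[["time"]] %||% records[["os_time"]]
  event <- records[["event"]] %||% records[["os_event"]]
  lr <- logrank_test(time, event, strat$group)
  km <- lapply(split(seq_len(nrow(strat)), strat$group), function(i)
    km_estimate(time[i], event[i]))
  list(stratification = strat, logrank = lr, km = km)
}

#' @export
print.cox_risk_model <- function(x, ...) {
  cat(sprintf("Cox risk model (%d samples, %d events, %s in %d iterations)\n",
              x$n, x$n_events,
              if (x$converged) "converged" else "NOT converged", x$iter))
  print(data.frame(coef = x$coef, HR = x$hr, se = x$se, p = x$p))
  invisible(x)
}
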