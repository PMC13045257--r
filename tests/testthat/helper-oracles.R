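# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# exhaustive hypergeometric: enumerate every size-n subset of a universe with
# the first M elements marked; returns the probability of overlap exactly k
# and of overlap >= k.
enum_hyper <- function(N, M, n, k) {
  if (n == 0) {
    pmf <- as.numeric(k == 0)
    return(list(pmf = pmf, tail = as.numeric(k <= 0)))
  }
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= M)
  list(pmf = mean(overlaps == k), tail = mean(overlaps >= k))
}

naive_manhattan <- function(X) {
  n <- ncol(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(abs(X[, i] - X[, j]))
  D
}

# exhaustive k-medoids: minimum assignment cost over every medoid subset
exhaustive_pam_cost <- function(D, k) {
  n <- nrow(D)
  sets <- utils::combn(n, k)
  min(apply(sets, 2, function(med)
    sum(apply(D[, med, drop = FALSE], 1, min))))
}

# textbook BH step-up, written independently of stats::p.adjust
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# hand product-limit estimator
km_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# AUC by explicit pair counting, ties half-counted
auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# explicit Breslow partial log-likelihood for a single covariate
breslow_loglik_1d <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    d <- time == t & event == 1
    ll <- ll + sum(beta * x[d]) - sum(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# small fast cohort for module-level recovery checks
small_cohort <- function(seed = 7, ...) {
  generate_cohort(cohort_config(samples_per_subtype = 25, n_normal = 20,
                                n_genes = 800, seed = seed, ...))
}

normal_ids_of <- function(cohort)
  names(cohort$sample_role)[cohort$sample_role == "normal"]
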