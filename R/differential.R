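# vectorised Welch two-sample t across rows; returns diff of means (A - B),
# t, df and two-sided p. Zero pooled SE: p = 1 when the means agree, else
# 1e-300 (below any resolvable threshold).
.row_welch <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  se2 <- vA / nA + vB / nB
  diff <- mA - mB
  t <- diff / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  p[zero] <- ifelse(diff[zero] == 0, 1, 1e-300)
  t[zero] <- ifelse(diff[zero] == 0, 0, sign(diff[zero]) * Inf)
  list(diff = diff, t = t, df = df, p = p)
}

#' Two-group differential expression by Welch's t-test
#'
#' Per-feature Welch two-sample t-test between groups A and B, on
#' `log2(x + 1)` when `log_transform` is set (the default, matching FPKM-like
#' input) or on the raw values otherwise. The reported `log2FC` is the
#' difference of group means on the tested scale (A minus B). Benjamini-
#' Hochberg q-values are attached across features.
#'
#' @param X Numeric features x samples matrix.
#' @param groupA,groupB Disjoint character vectors of sample ids.
#' @param log_transform Test on `log2(x + 1)` (default `TRUE`).
#' @return A data.frame: `feature`, `log2FC`, `t`, `p`, `q`.
#' @export
two_group_de <- function(X, groupA, groupB, log_transform = TRUE) {
  if (length(intersect(groupA, groupB)))
    .stop_input("groups overlap: %s", paste(intersect(groupA, groupB), collapse = ", "))
  if (length(groupA) < 2 || length(groupB) < 2)
    .stop_input("both groups need at least 2 samples")
  missing <- setdiff(c(groupA, groupB), colnames(X))
  if (length(missing)) .stop_input("unknown sample id: '%s'", missing[1L])
  V <- if (log_transform) log2(X + 1) else X
  w <- .row_welch(V[, groupA, drop = FALSE], V[, groupB, drop = FALSE])
  data.frame(feature = rownames(X), log2FC = unname(w$diff), t = unname(w$t),
             p = unname(w$p), q = bh_adjust(unname(w$p)),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return The BH-adjusted q-values, order-preserving and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    .stop_input("p-values must all lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter differential records on effect size and significance
#'
#' Strict thresholds on both criteria: `|log2FC| > min_abs_log2fc` and
#' `p < max_p`.
#'
#' @param records A data.frame from [two_group_de()] (columns `log2FC`, `p`).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @param max_p Maximum p-value (default 0.01).
#' @return The selected subset, with attribute `n_selected`.
#' @export
select_de_features <- function(records, min_abs_log2fc = 1, max_p = 0.01) {
  keep <- abs(records$log2FC) > min_abs_log2fc & records$p < max_p
  out <- records[keep, , drop = FALSE]
  attr(out, "n_selected") <- sum(keep)
  out
}

#' Differentially methylated probes between two groups
#'
#' Per probe, `delta` is the difference of group mean beta values on the raw
#' beta scale (A minus B); p-values come from Welch's t on the raw betas, with
#' Benjamini-Hochberg adjustment across probes. A probe is a DMP when
#' `|delta| > min_delta` and `q < max_q` (both strict).
#'
#' @param beta Probes x samples matrix of beta values in `[0, 1]`.
#' @param groupA,groupB Disjoint sample id vectors.
#' @param min_delta Minimum absolute mean beta difference (default 0.15).
#' @param max_q Maximum BH q-value (default 0.05).
#' @return A data.frame `feature`, `delta`, `p`, `q`, `selected` covering all
#'   probes, with attribute `n_selected`.
#' @export
find_dmps <- function(beta, groupA, groupB, min_delta = 0.15, max_q = 0.05) {
  if (any(beta < 0 | beta > 1))
    .stop_input("beta values must lie in [0, 1]")
  if (length(intersect(groupA, groupB)))
    .stop_input("groups overlap")
  w <- .row_welch(beta[, groupA, drop = FALSE], beta[, groupB, drop = FALSE])
  q <- bh_adjust(unname(w$p))
  selected <- abs(w$diff) > min_delta & q < max_q
  out <- data.frame(feature = rownames(beta), delta = unname(w$diff),
                    p = unname(w$p), q = q, selected = unname(selected),
                    stringsAsFactors = FALSE)
  attr(out, "n_selected") <- sum(selected)
  out
}
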