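#' Mean expression of the normal reference samples
#'
#' Per-gene arithmetic mean over the named normal samples; the denominator of
#' the per-sample fold change used for DEG calling.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @param normal_ids Character vector of normal sample ids (columns of `expr`).
#' @return Named numeric vector, one mean per gene.
#' @export
mean_normal_expression <- function(expr, normal_ids) {
  .check_expression_matrix(expr)
  if (length(normal_ids) == 0)
    .stop_input("at least one normal sample id is required")
  missing <- setdiff(normal_ids, colnames(expr))
  if (length(missing))
    .stop_input("normal sample id not in matrix: '%s'", missing[1L])
  rowMeans(expr[, normal_ids, drop = FALSE])
}

#' Call per-sample differentially expressed genes by fold change
#'
#' A gene is a DEG for a tumour sample when its fold change against the mean
#' normal expression is strictly above `up` (up-regulated) or strictly below
#' `down` (down-regulated). Fold change is
#' `tumour / (mean normal + pseudocount)`; the pseudocount guards against
#' zero FPKM in the reference.
#'
#' @param sample_col Numeric vector of one tumour sample, named by gene.
#' @param normal_mean Numeric vector from [mean_normal_expression()], same
#'   gene universe.
#' @param pseudocount Nonnegative value added to the normal mean denominator.
#' @param up,down Strict fold-change thresholds (defaults 2 and 0.5).
#' @return A data.frame with columns `gene`, `fc`, `direction` ("up"/"down"),
#'   one row per DEG.
#' @export
call_degs <- function(sample_col, normal_mean, pseudocount = 0.01,
                      up = 2, down = 0.5) {
  if (is.null(names(sample_col)) || is.null(names(normal_mean)))
    .stop_input("sample_col and normal_mean must be named by gene")
  if (length(sample_col) != length(normal_mean) ||
      !all(names(sample_col) == names(normal_mean)))
    .stop_input("sample_col and normal_mean are not aligned on the same gene universe")
  if (pseudocount < 0) .stop_input("pseudocount must be nonnegative")
  fc <- sample_col / (normal_mean + pseudocount)
  if (any(!is.finite(fc)) || any(fc <= 0 & (sample_col > 0)))
    .stop_input("fold change undefined for some genes; check normal means and pseudocount")
  keep <- fc > up | fc < down
  data.frame(
    gene = names(sample_col)[keep],
    fc = unname(fc[keep]),
    direction = ifelse(fc[keep] > up, "up", "down"),
    stringsAsFactors = FALSE
  )
}

.check_hyper_params <- function(N, M, n, k) {
  for (v in list(N = N, M = M, n = n, k = k)) {
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v))
      .stop_input("hypergeometric parameters must be single nonnegative integers")
  }
  if (M > N) .stop_input("hypergeometric parameters invalid: M (%d) > N (%d)", M, N)
  if (n > N) .stop_input("hypergeometric parameters invalid: n (%d) > N (%d)", n, N)
  invisible(NULL)
}

#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `k` marked genes when `n` genes are drawn
#' without replacement from a universe of `N` genes of which `M` are marked:
#' `C(M,k) C(N-M,n-k) / C(N,n)`, evaluated in log space. Returns 0 for
#' impossible overlaps (`k > min(M, n)` or `n - k > N - M`).
#'
#' @param N Universe size.
#' @param M Number of marked genes (DEGs).
#' @param n Draw size (signature size within the universe).
#' @param k Overlap (DEGs within the signature).
#' @return A single probability.
#' @export
hypergeom_pmf <- function(N, M, n, k) {
  .check_hyper_params(N, M, n, k)
  if (k > min(M, n) || n - k > N - M) return(0)
  exp(lchoose(M, k) + lchoose(N - M, n - k) - lchoose(N, n))
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)`, the probability of an overlap at least as large as observed;
#' the per-state entry of the TCD profile. Equals 1 when `k = 0`.
#'
#' @inheritParams hypergeom_pmf
#' @return A p-value in `[0, 1]`.
#' @export
hypergeom_tail <- function(N, M, n, k) {
  .check_hyper_params(N, M, n, k)
  hi <- min(M, n)
  if (k <= 0) return(1)
  if (k > hi) return(0)
  j <- k:hi
  lp <- lchoose(M, j) + lchoose(N - M, n - j) - lchoose(N, n)
  lp <- lp[is.finite(lp)]
  if (!length(lp)) return(0)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Build the per-sample T cell dysfunction profile
#'
#' For every tumour sample, genes are called differentially expressed by fold
#' change against the mean normal reference, and each TCD state signature is
#' tested for over-representation of those DEGs with the upper-tail
#' hypergeometric test. The result is a states x tumour-samples matrix of
#' enrichment p-values with a `-log10` companion view.
#'
#' The gene universe is the set of genes whose normal mean plus pseudocount is
#' positive (all genes for any positive pseudocount); signature members absent
#' from the universe are dropped from the signature size `n`. A signature with
#' no overlap with the universe yields p = 1 for that state with a warning.
#'
#' @param expr Numeric matrix, genes x samples, containing both normal and
#'   tumour columns.
#' @param signatures Named list of character vectors (gene sets); for the TCD
#'   use-case the four states exhaustion, senescence, exclusion, dysfunction.
#' @param normal_ids Character vector naming the normal reference columns;
#'   all remaining columns are profiled as tumour samples.
#' @param pseudocount Added to the normal-mean denominator of the fold change.
#' @param up,down Strict fold-change thresholds for DEG calling.
#' @return An object of class `tcd_profile`: list with `p` (states x samples
#'   p-value matrix), `neglog10` (capped at 300), `universe_size`, `n_deg`
#'   (per-sample DEG count `M`), and `sig_sizes` (per-state `n`).
#' @export
build_tcd_profile <- function(expr, signatures, normal_ids, pseudocount = 0.01,
                              up = 2, down = 0.5) {
  .check_expression_matrix(expr)
  if (!is.list(signatures) || is.null(names(signatures)) || !length(signatures))
    .stop_input("signatures must be a non-empty named list of gene id vectors")
  tumour_ids <- setdiff(colnames(expr), normal_ids)
  if (!length(normal_ids)) .stop_input("at least one normal sample is required")
  if (!length(tumour_ids)) .stop_input("at least one tumour sample is required")
  nm <- mean_normal_expression(expr, normal_ids)
  universe <- names(nm)[(nm + pseudocount) > 0]
  N <- length(universe)
  if (N == 0) .stop_input("empty gene universe after the normal-mean filter")

  fc <- expr[universe, tumour_ids, drop = FALSE] /
    (nm[universe] + pseudocount)
  deg <- fc > up | fc < down
  M <- colSums(deg)

  states <- names(signatures)
  p <- matrix(NA_real_, length(states), length(tumour_ids),
              dimnames = list(states, tumour_ids))
  sig_sizes <- integer(length(states)); names(sig_sizes) <- states
  for (s in states) {
    members <- intersect(unique(signatures[[s]]), universe)
    n_s <- length(members)
    sig_sizes[s] <- n_s
    if (n_s == 0) {
      warning(sprintf("signature '%s' has no overlap with the gene universe; p set to 1", s),
              call. = FALSE)
      p[s, ] <- 1
      next
    }
    k <- colSums(deg[members, , drop = FALSE])
    p[s, ] <- vapply(seq_along(tumour_ids), function(j)
      hypergeom_tail(N, M[[j]], n_s, k[[j]]), numeric(1))
  }
  structure(list(
    p = p,
    neglog10 = pmin(-log10(pmax(p, 1e-300)), 300),
    universe_size = N,
    n_deg = M,
    sig_sizes = sig_sizes
  ), class = "tcd_profile")
}

#' Extract the clustering view of a TCD profile
#'
#' @param profile A `tcd_profile`.
#' @param transform `"neglog10"` (default) for `-log10(p)` capped at 300, or
#'   `"p"` for raw p-values.
#' @return A states x samples numeric matrix.
#' @export
profile_matrix <- function(profile, transform = c("neglog10", "p")) {
  if (!inherits(profile, "tcd_profile")) .stop_input("not a tcd_profile")
  transform <- match.arg(transform)
  if (transform == "p") profile$p else profile$neglog10
}

#' @export
print.tcd_profile <- function(x, ...) {
  cat(sprintf("TCD profile: %d states x %d tumour samples (universe %d genes)\n",
              nrow(x$p), ncol(x$p), x$universe_size))
  cat("median -log10(p) per state:\n")
  print(round(apply(x$neglog10, 1, stats::median), 3))
  invisible(x)
}
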