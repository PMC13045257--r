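#' Per-sample signature scores
#'
#' Summarises each gene set into one score per sample. `mean-z` z-scores every
#' gene across samples (population standard deviation, ddof 0) and averages
#' the z-scores of the set members; `rank-z` first replaces each sample column
#' by within-sample gene ranks scaled to `(0, 1]` (making the score invariant
#' to any monotone per-sample transform), then z-scores and averages the same
#' way. Zero-variance genes are excluded with a warning; a set with no usable
#' member is an error.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param sets Named list of gene sets.
#' @param method `"mean-z"` (default) or `"rank-z"`.
#' @return A sets x samples score matrix with attribute `method`.
#' @export
signature_score <- function(expr, sets, method = c("mean-z", "rank-z")) {
  method <- match.arg(method)
  if (!is.matrix(expr) || !is.numeric(expr))
    .stop_input("expr must be a numeric matrix")
  if (!is.list(sets) || is.null(names(sets)))
    .stop_input("sets must be a named list")
  X <- if (method == "rank-z")
    apply(expr, 2, function(col) rank(col, ties.method = "average") / length(col))
  else expr
  if (method == "rank-z") rownames(X) <- rownames(expr)
  sd0 <- .row_sd_pop(X)
  degenerate <- sd0 == 0
  if (any(degenerate))
    warning(sprintf("%d zero-variance genes excluded from z-scoring", sum(degenerate)),
            call. = FALSE)
  Z <- (X[!degenerate, , drop = FALSE] - rowMeans(X[!degenerate, , drop = FALSE])) /
    sd0[!degenerate]
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (s in names(sets)) {
    members <- intersect(unique(sets[[s]]), rownames(Z))
    if (!length(members))
      .stop_input("signature score undefined for set '%s': no gene with nonzero variance", s)
    scores[s, ] <- colMeans(Z[members, , drop = FALSE])
  }
  attr(scores, "method") <- method
  scores
}

#' Group-wise summaries of features
#'
#' The requested statistic (median or mean) per group per feature, optionally
#' with each group expressed as a proportion of a named reference group.
#'
#' @param values Numeric vector (one feature) or features x samples matrix.
#' @param labels Group label per sample.
#' @param stat `"median"` or `"mean"`.
#' @param reference Optional group name; when given, `relative` holds each
#'   group's statistic divided by the reference group's.
#' @return List with `summary` (groups x features matrix) and `relative`
#'   (same shape, or `NULL`).
#' @export
group_summary <- function(values, labels, stat = c("median", "mean"),
                          reference = NULL) {
  stat <- match.arg(stat)
  if (is.vector(values)) values <- matrix(values, nrow = 1,
                                          dimnames = list("feature", names(values)))
  if (ncol(values) != length(labels))
    .stop_input("every sample must be labelled")
  labels <- as.character(labels)
  groups <- unique(labels)
  f <- if (stat == "median") stats::median else mean
  out <- matrix(NA_real_, length(groups), nrow(values),
                dimnames = list(groups, rownames(values)))
  for (g in groups)
    out[g, ] <- apply(values[, labels == g, drop = FALSE], 1, f)
  rel <- NULL
  if (!is.null(reference)) {
    if (!reference %in% groups)
      .stop_input("unknown reference group '%s'", reference)
    rel <- sweep(out, 2, out[reference, ], "/")
  }
  list(summary = out, relative = rel)
}

#' Pearson correlation matrix between features
#'
#' @param X Numeric features x samples matrix with at least 3 samples.
#' @return Symmetric features x features correlation matrix; zero-variance
#'   features give `NA` rows/columns with a warning.
#' @export
pearson_matrix <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) .stop_input("X must be a numeric matrix")
  if (ncol(X) < 3) .stop_input("at least 3 samples are required")
  if (any(!is.finite(X))) .stop_input("X contains non-finite values")
  sd0 <- .row_sd_pop(X)
  if (any(sd0 == 0))
    warning(sprintf("zero-variance feature(s): %s; correlations reported as NA",
                    paste(rownames(X)[sd0 == 0], collapse = ", ")), call. = FALSE)
  suppressWarnings(stats::cor(t(X)))
}

#' Select anti-correlated, T-low-elevated candidate target genes
#'
#' Among candidate target genes of one miRNA, keeps those whose expression is
#' negatively Pearson-correlated with the miRNA (pooled over all samples,
#' strict `r < 0`) and whose mean expression is higher in the T-low subtype
#' than in the T-high subtype.
#'
#' @param mirna_row Named numeric vector: the miRNA's expression per sample.
#' @param gene_rows Candidate genes x samples matrix (same samples).
#' @param labels A `subtype_assignment`, or a character/factor vector of
#'   subtype names per sample containing `low` and `high` groups.
#' @param low,high Names of the extreme subtypes (defaults "T-low"/"T-high").
#' @return Character vector of selected gene ids.
#' @export
anticorrelated_targets <- function(mirna_row, gene_rows, labels,
                                   low = "T-low", high = "T-high") {
  if (inherits(labels, "subtype_assignment")) labels <- labels$subtype
  labels <- stats::setNames(as.character(labels), names(labels))
  samples <- colnames(gene_rows)
  if (is.null(samples) || is.null(names(mirna_row)))
    .stop_input("mirna_row and gene_rows must be named by sample")
  if (!all(samples %in% names(mirna_row)) || !all(samples %in% names(labels)))
    .stop_input("mirna_row and labels must cover all gene_rows samples")
  labels <- labels[samples]
  if (!any(labels == low) || !any(labels == high))
    .stop_input("labels must contain both '%s' and '%s' groups", low, high)
  m <- mirna_row[samples]
  r <- suppressWarnings(as.vector(stats::cor(t(gene_rows), m)))
  mean_low <- rowMeans(gene_rows[, labels == low, drop = FALSE])
  mean_high <- rowMeans(gene_rows[, labels == high, drop = FALSE])
  keep <- !is.na(r) & r < 0 & mean_low > mean_high
  rownames(gene_rows)[keep]
}

#' Over-representation of a hit list in pathway gene sets
#'
#' Upper-tail hypergeometric test per pathway (`N` = universe size, `M` =
#' hits, `n` = pathway within universe, `k` = hits within pathway) with
#' Benjamini-Hochberg adjustment across pathways. Shares the
#' [hypergeom_tail()] code path with the TCD profile.
#'
#' @param hits Character vector of hit gene ids, a subset of `universe`.
#' @param universe Character vector of background gene ids.
#' @param pathways Named list of pathway gene sets.
#' @return A data.frame with columns `pathway`, `N`, `M`, `n`, `k`, `p`, `q`.
#' @export
overrepresentation <- function(hits, universe, pathways) {
  hits <- unique(hits); universe <- unique(universe)
  bad <- setdiff(hits, universe)
  if (length(bad))
    .stop_input("hits not in universe: %s", paste(bad, collapse = ", "))
  N <- length(universe); M <- length(hits)
  res <- lapply(names(pathways), function(pw) {
    members <- intersect(unique(pathways[[pw]]), universe)
    n <- length(members)
    k <- length(intersect(hits, members))
    data.frame(pathway = pw, N = N, M = M, n = n, k = k,
               p = hypergeom_tail(N, M, n, k), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}
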