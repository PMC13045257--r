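#' Manhattan distances between profile columns
#'
#' @param X Numeric matrix, features x samples; distances are between sample
#'   columns: `d(i,j) = sum_f |x_fi - x_fj|`.
#' @return Symmetric sample x sample distance matrix with zero diagonal.
#' @export
manhattan_distances <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) .stop_input("X must be a numeric matrix")
  if (any(!is.finite(X))) .stop_input("X contains missing or non-finite values")
  D <- as.matrix(stats::dist(t(X), method = "manhattan"))
  dimnames(D) <- list(colnames(X), colnames(X))
  D
}

#' Partitioning around medoids (exact on tiny instances, BUILD + SWAP at scale)
#'
#' Deterministic k-medoids on a precomputed dissimilarity matrix, minimising
#' the total cost `sum_i d(i, medoid(i))`. When the medoid search space is
#' small (`choose(n, k) <= exact_limit`) every medoid set is enumerated and
#' the optimum returned, so single-swap local optima cannot occur on small
#' problems; beyond that, the classic BUILD phase seeds the medoids greedily
#' and SWAP applies steepest-descent single swaps until none lowers the cost.
#' All ties are broken by the lowest index (lexicographically smallest medoid
#' set on the exact path), so the result is a pure function of `D` and `k`.
#'
#' @param D Symmetric dissimilarity matrix (or `dist`).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Ignored (the algorithm is deterministic); accepted so callers
#'   can treat all clusterers uniformly.
#' @param exact_limit Maximum number of medoid sets enumerated exhaustively
#'   before falling back to BUILD + SWAP (default 2000).
#' @return List with `labels` (cluster index per sample, numbered by sorted
#'   medoid position), `medoids` (indices), `medoid_ids`, and `cost`.
#' @export
pam_cluster <- function(D, k, seed = NULL, exact_limit = 2000) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n == 0 || ncol(D) != n) .stop_input("D must be a square matrix")
  if (k < 1 || k > n) .stop_input("k must be between 1 and n = %d", n)

  if (choose(n, k) <= exact_limit) {
    sets <- utils::combn(n, k)
    costs <- apply(sets, 2, function(med)
      sum(do.call(pmin, lapply(med, function(m) D[, m]))))
    med <- sets[, which.min(costs)]
    return(.pam_result(D, med))
  }

  # BUILD
  med <- integer(0)
  d_near <- rep(Inf, n)
  for (i in seq_len(k)) {
    if (i == 1L) {
      h <- which.min(colSums(D))
    } else {
      cand <- setdiff(seq_len(n), med)
      gain <- colSums(pmax(d_near - D[, cand, drop = FALSE], 0))
      h <- cand[which.max(gain)]
    }
    med <- c(med, h)
    d_near <- pmin(d_near, D[, h])
  }

  # SWAP: best single swap per pass, lowest-index tie-break
  repeat {
    Dm <- D[, med, drop = FALSE]
    nearest <- max.col(-Dm, ties.method = "first")
    d1 <- Dm[cbind(seq_len(n), nearest)]
    cost <- sum(d1)
    if (k == n) break
    Dm2 <- Dm
    Dm2[cbind(seq_len(n), nearest)] <- Inf
    d2 <- if (k == 1L) rep(Inf, n) else do.call(pmin, lapply(seq_len(k), function(j) Dm2[, j]))
    cand <- setdiff(seq_len(n), med)
    best_cost <- cost
    best_m <- best_h <- NA_integer_
    for (mi in seq_len(k)) {
      f <- ifelse(nearest == mi, d2, d1)
      new_costs <- colSums(pmin(D[, cand, drop = FALSE], f))
      j <- which.min(new_costs)
      if (new_costs[j] < best_cost - 1e-12) {
        best_cost <- new_costs[j]
        best_m <- mi
        best_h <- cand[j]
      }
    }
    if (is.na(best_m)) break
    med[best_m] <- best_h
  }

  .pam_result(D, med)
}

.pam_result <- function(D, med) {
  n <- nrow(D)
  med <- sort(med)
  Dm <- D[, med, drop = FALSE]
  nearest <- max.col(-Dm, ties.method = "first")
  list(labels = stats::setNames(nearest, rownames(D)),
       medoids = med,
       medoid_ids = rownames(D)[med],
       cost = sum(Dm[cbind(seq_len(n), nearest)]))
}

#' Consensus clustering of a TCD profile
#'
#' Subsampled PAM clustering with Manhattan distances over a range of cluster
#' numbers, in the spirit of consensus clustering for tumour subtype
#' discovery. For each of `n_resamples` draws, `ceiling(item_fraction * n)`
#' samples are clustered; the consensus entry for a sample pair is the
#' fraction of co-draws in which they co-clustered. Final per-k labels come
#' from PAM on `1 - consensus` as a dissimilarity. The area under the
#' empirical CDF of consensus values (`A_k`, computed exactly as
#' `1 - mean(consensus)` over sample pairs) yields the relative delta-area
#' sequence used by [select_k()].
#'
#' @param X Profile matrix, features x samples (e.g.
#'   `profile_matrix(profile)`).
#' @param k_min,k_max Cluster-number range (defaults 2..8).
#' @param n_resamples Number of subsampling draws (default 100).
#' @param item_fraction Fraction of samples per draw, in `(0, 1]`.
#' @param seed Integer seed for the subsampling.
#' @param select_threshold Relative delta-area threshold passed to
#'   [select_k()].
#' @return An object of class `consensus_result`: `k_range`, per-k `consensus`
#'   matrices and `labels`, `areas`, `delta_areas`, and `chosen_k`.
#' @export
consensus_cluster <- function(X, k_min = 2, k_max = 8, n_resamples = 100,
                              item_fraction = 0.8, seed = 1,
                              select_threshold = 0.1) {
  if (n_resamples < 2) .stop_input("n_resamples must be at least 2")
  if (item_fraction <= 0 || item_fraction > 1)
    .stop_input("item_fraction must be in (0, 1]")
  D <- manhattan_distances(X)
  n <- ncol(X)
  if (k_max > n) .stop_input("k_max exceeds the number of samples")
  ids <- colnames(X)

  set.seed(seed)
  m <- ceiling(item_fraction * n)
  draws <- lapply(seq_len(n_resamples), function(r) sort(sample.int(n, m)))

  tot <- matrix(0, n, n)
  for (s in draws) tot[s, s] <- tot[s, s] + 1
  never <- sum(tot[upper.tri(tot)] == 0)
  if (never > 0)
    warning(sprintf("%d sample pairs were never co-sampled; consensus imputed as 0", never),
            call. = FALSE)

  k_range <- k_min:k_max
  consensus <- labels <- vector("list", length(k_range))
  names(consensus) <- names(labels) <- paste0("k", k_range)
  areas <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    co <- matrix(0, n, n)
    for (s in draws) {
      cl <- pam_cluster(D[s, s, drop = FALSE], k)$labels
      co[s, s] <- co[s, s] + outer(cl, cl, "==")
    }
    cons <- ifelse(tot > 0, co / pmax(tot, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    v <- cons[upper.tri(cons)]
    areas[i] <- 1 - mean(v)          # exact integral of the empirical CDF on [0,1]
    labels[[i]] <- pam_cluster(1 - cons, k)$labels
    consensus[[i]] <- cons
  }
  delta <- c(areas[1L],
             if (length(areas) > 1) diff(areas) / areas[-length(areas)])
  res <- structure(list(
    k_range = k_range,
    consensus = consensus,
    labels = labels,
    areas = stats::setNames(areas, paste0("k", k_range)),
    delta_areas = stats::setNames(delta, paste0("k", k_range)),
    chosen_k = NA_integer_,
    seed = seed, n_resamples = n_resamples, item_fraction = item_fraction
  ), class = "consensus_result")
  res$chosen_k <- if (length(k_range) < 2) k_range
  else select_k(res, threshold = select_threshold)
  res
}

#' Choose the number of clusters from the delta-area sequence
#'
#' The relative delta-area for k is `(A_k - A_{k-1}) / A_{k-1}` (and `A_2`
#' itself for k = 2). The chosen k is the smallest k whose successor's
#' relative delta-area first falls below `threshold`; if none falls below,
#' the largest k in the range is returned.
#'
#' @param result A `consensus_result`, or a numeric delta-area vector for the
#'   consecutive k values starting at the smallest.
#' @param threshold Relative delta-area cut-off (default 0.1).
#' @param k_range Integer vector of k values when `result` is a bare numeric
#'   vector.
#' @return The chosen k.
#' @export
select_k <- function(result, threshold = 0.1, k_range = NULL) {
  if (inherits(result, "consensus_result")) {
    delta <- result$delta_areas
    k_range <- result$k_range
  } else {
    delta <- result
    if (is.null(k_range)) k_range <- seq_along(delta) + 1L
  }
  if (length(delta) < 2) .stop_input("delta-area selection needs at least two k values")
  if (length(delta) != length(k_range)) .stop_input("delta/k length mismatch")
  for (i in seq_len(length(delta) - 1L))
    if (delta[i + 1L] < threshold) return(k_range[i])
  k_range[length(k_range)]
}

#' Order clusters by TCD severity and name the subtypes
#'
#' Clusters are ranked by their mean `-log10(p)` averaged over the four TCD
#' states: the least enriched cluster is T-low, the most enriched T-high.
#' With k = 4 the display names are T-low, T-middle, T-middle2, T-high;
#' other k use the same low/middle.../high scheme.
#'
#' @param profile A `tcd_profile` (or a states x samples `-log10(p)` matrix).
#' @param labels Named integer cluster labels covering the profile samples.
#' @return An object of class `subtype_assignment`: `cluster` (input labels),
#'   `severity_rank` (rank per cluster index, 1 = least severe), `subtype`
#'   (named factor of display names, levels in severity order) and
#'   `subtype_names`.
#' @export
order_subtypes <- function(profile, labels) {
  L <- if (inherits(profile, "tcd_profile")) profile$neglog10 else profile
  if (is.null(names(labels))) .stop_input("labels must be named by sample")
  if (!all(colnames(L) %in% names(labels)))
    .stop_input("labels do not cover all profile samples")
  labels <- labels[colnames(L)]
  ks <- sort(unique(labels))
  sizes <- table(labels)
  if (any(sizes == 0)) .stop_input("empty cluster")
  enrich <- vapply(ks, function(k) mean(L[, labels == k, drop = FALSE]),
                   numeric(1))
  severity_rank <- stats::setNames(rank(enrich, ties.method = "first"), ks)
  k <- length(ks)
  nm <- if (k == 1) "T-low"
  else if (k == 2) c("T-low", "T-high")
  else c("T-low",
         paste0("T-middle", c("", if (k > 3) seq_len(k - 3) + 1)),
         "T-high")
  subtype_names <- stats::setNames(nm[severity_rank], ks)
  subtype <- factor(subtype_names[as.character(labels)], levels = nm)
  names(subtype) <- names(labels)
  structure(list(cluster = labels,
                 severity_rank = severity_rank,
                 subtype = subtype,
                 subtype_names = subtype_names,
                 mean_enrichment = stats::setNames(enrich, ks)),
            class = "subtype_assignment")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering over k = %d..%d (%d resamples, item fraction %.2f)\n",
              min(x$k_range), max(x$k_range), x$n_resamples, x$item_fraction))
  cat("relative delta-areas:\n")
  print(round(x$delta_areas, 3))
  cat(sprintf("chosen k: %d\n", x$chosen_k))
  invisible(x)
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat("Subtype assignment (severity-ordered):\n")
  print(table(x$subtype))
  invisible(x)
}
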