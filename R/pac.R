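#' Cluster labeling container
#'
#' Per-event integer cluster labels plus per-cluster summaries (mean,
#' sample covariance, size), consistent with and recomputable from the
#' labels.
#'
#' @param labels Integer vector of labels in `1..n_clusters`.
#' @param summaries List of per-cluster summaries as built by
#'   [cluster_summaries()].
#' @param sample_id Sample identifier.
#' @return An object of class `cluster_labeling`.
#' @export
cluster_labeling <- function(labels, summaries, sample_id = "sample") {
  labels <- as.integer(labels)
  if (length(summaries) < max(labels)) {
    stop("every label needs a summary")
  }
  sizes <- vapply(summaries, `[[`, numeric(1L), "size")
  if (sum(sizes) != length(labels)) {
    stop("summary sizes must sum to the number of events")
  }
  structure(list(labels = labels, summaries = summaries,
                 sample_id = sample_id),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  sizes <- vapply(x$summaries, `[[`, numeric(1L), "size")
  cat(sprintf("cluster_labeling '%s': %d events in %d clusters\n",
              x$sample_id, length(x$labels), length(x$summaries)))
  cat("sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster summaries
#'
#' Mean vector, sample covariance matrix and size for each cluster of a
#' labeling.
#'
#' @param values Numeric event matrix.
#' @param labels Integer labels in `1..k`.
#' @return A list of `k` summaries, each `list(mean, cov, size)`.
#' @export
cluster_summaries <- function(values, labels) {
  k <- max(labels)
  lapply(seq_len(k), function(j) {
    sel <- labels == j
    x <- values[sel, , drop = FALSE]
    list(mean = colMeans(x),
         cov = if (nrow(x) > 1L) stats::cov(x) else
           matrix(0, ncol(x), ncol(x)),
         size = nrow(x))
  })
}

# Nearest-center assignment by Euclidean distance (BLAS-backed).
assign_nearest <- function(values, centers) {
  cross <- values %*% t(centers)
  d2 <- matrix(rowSums(centers^2), nrow(values), nrow(centers), byrow = TRUE) -
    2 * cross
  max.col(-d2, ties.method = "first")
}

#' k-means refinement from given centers
#'
#' Standard Lloyd updates (assign each event to its nearest center by
#' Euclidean distance, recompute the means) run for exactly `iterations`
#' steps, or fewer if the assignment stops changing. With `iterations = 0`
#' the result is the plain nearest-center assignment. Clusters emptied
#' during iteration are dropped, so the final cluster count can be smaller
#' than the number of starting centers. A small number of iterations from
#' partition-derived centers is the intended use: the rectangles anchor the
#' centers near density modes and convergence is fast.
#'
#' @param m An [event_matrix()].
#' @param centers Numeric matrix of starting centers (one per row), with
#'   the same number of columns as `m`.
#' @param iterations Number of Lloyd iterations (>= 0, default 50).
#' @return A [cluster_labeling()]; its `"iterations_used"` attribute counts
#'   the update steps actually performed.
#' @export
kmeans_refine <- function(m, centers, iterations = 50L) {
  stopifnot(inherits(m, "event_matrix"))
  centers <- as.matrix(centers)
  if (nrow(centers) < 1L) stop("need at least one center")
  if (ncol(centers) != ncol(m$values)) {
    stop("center dimension mismatch: centers have ", ncol(centers),
         " columns, events have ", ncol(m$values))
  }
  if (iterations < 0L) stop("iterations must be >= 0")
  values <- m$values
  labels <- assign_nearest(values, centers)
  used <- 0L
  for (it in seq_len(iterations)) {
    keep <- sort(unique(labels))
    if (length(keep) < nrow(centers)) {
      labels <- match(labels, keep)       # drop emptied clusters
      centers <- centers[keep, , drop = FALSE]
    }
    centers <- rowsum(values, labels) /
      as.vector(table(factor(labels, levels = seq_len(nrow(centers)))))
    new_labels <- assign_nearest(values, centers)
    used <- it
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  keep <- sort(unique(labels))
  labels <- match(labels, keep)
  out <- cluster_labeling(labels, cluster_summaries(values, labels),
                          sample_id = m$sample_id)
  attr(out, "iterations_used") <- used
  out
}

# Regularised inverse-covariance quadratic form used by the merge
# distance. Clusters too small for a stable full covariance (size below
# n_markers + 1) fall back to their diagonal; a small ridge proportional to
# the mean variance guards invertibility.
precision_of <- function(s, label, epsilon = 1e-6) {
  p <- ncol(s$cov)
  S <- s$cov
  if (s$size < p + 1L) {
    S <- diag(diag(S), p)
  }
  S <- S + diag(epsilon * (sum(diag(S)) / p), p)
  inv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(inv)) {
    stop("singular covariance for cluster ", label,
         " (size ", s$size, ") even after regularization")
  }
  inv
}

#' Minimum squared-Mahalanobis distance between two clusters
#'
#' The merging distance
#' `D(X, Y) = min{ (xbar - ybar)' Sx^-1 (xbar - ybar),
#'                 (xbar - ybar)' Sy^-1 (xbar - ybar) }`,
#' i.e. the squared Mahalanobis separation of the two means measured in
#' whichever cluster's covariance makes them look closer. The squared form
#' is used as-is (no square root). Covariances receive a relative ridge
#' `1e-6 * trace(S)/p * I` before inversion, and clusters smaller than
#' `n_markers + 1` events use their diagonal covariance only.
#'
#' @param x,y Cluster summaries (`list(mean, cov, size)`).
#' @param label_x,label_y Cluster names used in error messages.
#' @return A non-negative scalar distance.
#' @export
merge_distance <- function(x, y, label_x = "x", label_y = "y") {
  d <- x$mean - y$mean
  qx <- drop(d %*% precision_of(x, label_x) %*% d)
  qy <- drop(d %*% precision_of(y, label_y) %*% d)
  min(qx, qy)
}

#' Hierarchically merge clusters down to K
#'
#' Repeatedly merges the pair of clusters with the smallest
#' [merge_distance()] (ties broken by the lowest index pair), recomputing
#' the merged cluster's summary from its member events, until `K` clusters
#' remain. Event counts are conserved; surviving clusters are relabelled
#' `1..K` in order of their original indices.
#'
#' @param m The [event_matrix()] the labeling refers to.
#' @param labeling A [cluster_labeling()].
#' @param K Target number of clusters, `1 <= K <=` current count.
#' @return A [cluster_labeling()] with `K` clusters.
#' @export
merge_to_k <- function(m, labeling, K) {
  stopifnot(inherits(m, "event_matrix"), inherits(labeling, "cluster_labeling"))
  if (K < 1L) stop("K must be >= 1")
  k0 <- length(labeling$summaries)
  if (K > k0) stop("K exceeds the current cluster count (", k0, ")")
  if (K == k0) return(labeling)
  values <- m$values
  labels <- labeling$labels
  summ <- labeling$summaries
  active <- seq_len(k0)

  D <- matrix(Inf, k0, k0)
  for (i in seq_len(k0 - 1L)) {
    for (j in seq.int(i + 1L, k0)) {
      D[i, j] <- merge_distance(summ[[i]], summ[[j]], i, j)
    }
  }

  while (length(active) > K) {
    sub <- D[active, active, drop = FALSE]
    flat <- which(sub == min(sub), arr.ind = TRUE)
    # lowest (i, j) pair among ties
    flat <- flat[order(flat[, 1L], flat[, 2L]), , drop = FALSE]
    i <- active[flat[1L, 1L]]
    j <- active[flat[1L, 2L]]
    labels[labels == j] <- i
    sel <- labels == i
    x <- values[sel, , drop = FALSE]
    summ[[i]] <- list(mean = colMeans(x),
                      cov = if (nrow(x) > 1L) stats::cov(x) else
                        matrix(0, ncol(x), ncol(x)),
                      size = nrow(x))
    active <- setdiff(active, j)
    for (o in setdiff(active, i)) {
      a <- min(i, o); b <- max(i, o)
      D[a, b] <- merge_distance(summ[[a]], summ[[b]], a, b)
    }
  }
  labels <- match(labels, active)
  cluster_labeling(labels, cluster_summaries(values, labels),
                   sample_id = labeling$sample_id)
}

#' Partition-assisted clustering
#'
#' The full clustering pipeline for one sample: partition the marker space
#' into `n_init` hyper-rectangles ([dsp_partition()] or
#' [bsp_ll_partition()]), take leaf means as rational initial centers,
#' refine with a small number of Lloyd iterations ([kmeans_refine()]) and
#' hierarchically merge to `k` final clusters under the minimum
#' squared-Mahalanobis distance ([merge_to_k()]). Deterministic given the
#' data and configuration. Picking `n_init` at 2-3 times the number of
#' subpopulations expected works well in practice.
#'
#' @param m A transformed [event_matrix()].
#' @param k Desired number of final clusters.
#' @param n_init Number of initial partitions (default `2 * k`).
#' @param method `"dsp"` (discrepancy-guided, the faster default) or
#'   `"bsp"` (midpoint cuts with one-step look-ahead).
#' @param iterations Lloyd iterations in the refinement step (default 50).
#' @param theta,min_leaf_size Passed to [dsp_partition()].
#' @param lambda Passed to [bsp_ll_partition()].
#' @return A [cluster_labeling()] with attributes `"method"`,
#'   `"n_init"` and `"partition_leaves"`.
#' @examples
#' sim <- gmm_sample(sim_spec(a = 4, b = 2, c = 30, d = 2000, seed = 1))
#' cl <- pac(sim$events, k = 2)
#' f_measure(sim$labels, cl$labels)
#' @export
pac <- function(m, k, n_init = 2L * k, method = c("dsp", "bsp"),
                iterations = 50L, theta = NULL, min_leaf_size = 10L,
                lambda = NULL) {
  stopifnot(inherits(m, "event_matrix"))
  method <- match.arg(method)
  if (!isTRUE(m$transformed)) {
    stop("pac expects transformed intensities; run arcsinh_transform() first")
  }
  if (k < 1L || n_init < k) stop("need 1 <= k <= n_init")
  part <- if (method == "dsp") {
    dsp_partition(m, leaf_budget = n_init, theta = theta,
                  min_leaf_size = min_leaf_size)
  } else {
    bsp_ll_partition(m, leaf_budget = n_init, lambda = lambda)
  }
  centers <- initial_centers(part, m)
  refined <- kmeans_refine(m, centers, iterations = iterations)
  k_eff <- min(k, length(refined$summaries))
  if (k_eff < k) {
    warning("only ", length(refined$summaries),
            " clusters survived refinement; returning ", k_eff)
  }
  out <- merge_to_k(m, refined, k_eff)
  attr(out, "method") <- method
  attr(out, "n_init") <- n_init
  attr(out, "partition_leaves") <- length(part$leaves)
  out
}

#' Total within-cluster sum of squares
#'
#' @param values Numeric event matrix.
#' @param labels Integer cluster labels.
#' @return Total squared Euclidean distance of events to their cluster
#'   means.
#' @export
total_sse <- function(values, labels) {
  centers <- rowsum(values, labels) / as.vector(table(labels))
  sum((values - centers[match(labels, sort(unique(labels))), ])^2)
}
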