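#' Uniformity gap of a one-dimensional point set
#'
#' Kolmogorov-style discrepancy between the empirical distribution of points
#' inside a half-open interval and the uniform distribution on that
#' interval, together with the coordinate at which the deviation is
#' attained. This is the statistic that drives discrepancy-guided
#' partitioning: a large gap means the points are far from uniform and the
#' interval is worth cutting at the gap location.
#'
#' @param x Numeric vector of at least two points inside `[lo, hi)`.
#' @param lo,hi Interval bounds, `lo < hi`.
#' @return A list with `score` (discrepancy in `[0, 1]`) and `cut` (the
#'   coordinate attaining the maximal deviation, clamped strictly inside
#'   the interval).
#' @export
leaf_uniformity_gap <- function(x, lo, hi) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("need at least 2 points")
  }
  if (!(hi > lo)) {
    stop("degenerate interval: lo must be < hi")
  }
  u <- sort((x - lo) / (hi - lo))
  n <- length(u)
  d_hi <- seq_len(n) / n - u          # F_hat just after each point
  d_lo <- u - (seq_len(n) - 1L) / n   # F_hat just before each point
  score <- max(pmax(d_hi, d_lo), 0)
  # candidate cuts between adjacent order statistics, scored by the summed
  # positive deviations on both sides of the flat CDF stretch: at a CDF
  # crossing this equals the point spacing, so a wide empty gap between
  # modes is cut at its middle, while skewed leaves fall back to the
  # one-sided deviation maximum
  if (n >= 2L) {
    i <- seq_len(n - 1L)
    dev_cut <- pmax(i / n - u[i], 0) + pmax(u[i + 1L] - i / n, 0)
    j <- which.max(dev_cut)
    cut <- lo + (u[j] + u[j + 1L]) / 2 * (hi - lo)
  } else {
    cut <- (lo + hi) / 2
  }
  eps <- 1e-9 * (hi - lo)
  cut <- min(max(cut, lo + eps), hi - eps)
  list(score = score, cut = cut)
}

# Best discrepancy cut of one leaf dimension subject to a minimum child
# size. Uniformity is judged on the span of the member points themselves
# (not the inherited rectangle bounds): empty margins left behind by cuts
# in other dimensions would otherwise dominate the deviation and attract
# degenerate edge cuts. Candidate cuts sit at the sorted sample points; a
# cut c sends x < c to the left child. Returns score -Inf when no
# admissible cut exists (e.g. the column is constant within the leaf).
best_dim_cut <- function(x, lo, hi, min_leaf_size) {
  n <- length(x)
  u <- sort(x)
  lo <- u[1L]
  hi <- u[n] + 1e-9 * max(u[n] - u[1L], 1)
  s <- (u - lo) / (hi - lo)
  raw <- max(pmax(seq_len(n) / n - s, s - (seq_len(n) - 1L) / n), 0)
  # candidate cuts halfway between adjacent distinct order statistics;
  # cutting after point i leaves exactly i points in the left child. The
  # summed positive deviations around the cut equal the spacing at a CDF
  # crossing, favouring a cut through the middle of an empty gap
  i <- seq_len(n - 1L)
  dev_cut <- pmax(i / n - s[i], 0) + pmax(s[i + 1L] - i / n, 0)
  ok <- i >= min_leaf_size & (n - i) >= min_leaf_size & u[i + 1L] > u[i]
  if (!any(ok)) {
    return(list(score = -Inf, cut = NA_real_, raw = raw))
  }
  j <- which(ok)[which.max(dev_cut[ok])]
  list(score = raw, cut = (u[j] + u[j + 1L]) / 2, raw = raw)
}

new_leaf <- function(lower, upper, idx, depth, created) {
  list(lower = lower, upper = upper, idx = idx, depth = depth,
       created = created)
}

# Shared bounding box: [min, max] per dimension expanded by a small
# relative margin, with half-open ownership [lo, hi).
bounding_box <- function(values) {
  lo <- apply(values, 2L, min)
  hi <- apply(values, 2L, max)
  margin <- 1e-6 * pmax(hi - lo, 1)
  list(lower = lo - margin, upper = hi + margin)
}

partition_result <- function(leaves, method, n_events, box) {
  structure(list(leaves = leaves, method = method, n_events = n_events,
                 box = box),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  sizes <- vapply(x$leaves, function(l) length(l$idx), integer(1L))
  cat(sprintf("partition_result (%s): %d leaves over %d events\n",
              x$method, length(x$leaves), x$n_events))
  cat("leaf sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Discrepancy-guided sequential partition
#'
#' Recursively splits the data bounding box into half-open hyper-rectangles.
#' At every step the leaf whose most non-uniform dimension has the largest
#' uniformity gap (Kolmogorov discrepancy, [leaf_uniformity_gap()]) is cut
#' at the location of that gap. Splitting stops once every leaf is
#' sufficiently uniform (gap below the threshold), the leaf budget is
#' reached, or leaves become too small to split.
#'
#' @param m An [event_matrix()].
#' @param leaf_budget Maximum number of leaves (>= 1). A useful default in
#'   practice is 2-3 times the number of subpopulations expected.
#' @param theta Uniformity threshold; a leaf with gap below it is final.
#'   `NULL` (default) uses the 5% Kolmogorov-Smirnov critical value
#'   `1.36 / sqrt(n_leaf)` per leaf.
#' @param min_leaf_size Minimum events per child (default 10); cuts are
#'   clamped so both children respect it.
#' @return A `partition_result` with leaves carrying bounds and member
#'   event indices.
#' @export
dsp_partition <- function(m, leaf_budget, theta = NULL, min_leaf_size = 10L) {
  stopifnot(inherits(m, "event_matrix"))
  if (leaf_budget < 1L) stop("leaf_budget must be >= 1")
  if (min_leaf_size < 2L) stop("min_leaf_size must be >= 2")
  values <- m$values
  n <- nrow(values)
  box <- bounding_box(values)
  root <- new_leaf(box$lower, box$upper, seq_len(n), 0L, 1L)
  if (n < min_leaf_size) {
    warning("fewer events than min_leaf_size; returning a single leaf")
    return(partition_result(list(root), "dsp", n, box))
  }

  threshold <- function(n_leaf) {
    if (is.null(theta)) 1.36 / sqrt(n_leaf) else theta
  }

  score_leaf <- function(leaf) {
    nl <- length(leaf$idx)
    if (nl < 2L * min_leaf_size) {
      leaf$gap <- -Inf
      leaf$priority <- -Inf
      return(leaf)
    }
    best <- -Inf; best_dim <- NA_integer_; best_cut <- NA_real_
    for (j in seq_len(ncol(values))) {
      cand <- best_dim_cut(values[leaf$idx, j], leaf$lower[j], leaf$upper[j],
                           min_leaf_size)
      if (is.finite(cand$score) && cand$score > best) {
        best <- cand$score
        best_dim <- j
        best_cut <- cand$cut
      }
    }
    leaf$gap <- best
    # evidence of non-uniformity on the KS scale: sqrt(n) * D, so dense
    # structured leaves outrank small slivers whose raw gap is inflated
    leaf$priority <- sqrt(nl) * best
    leaf$dim <- best_dim
    leaf$cut <- best_cut
    leaf
  }

  leaves <- list(score_leaf(root))
  created <- 1L
  while (length(leaves) < leaf_budget) {
    gaps <- vapply(leaves, function(l) l$gap, numeric(1L))
    prio <- vapply(leaves, function(l) l$priority, numeric(1L))
    sizes <- vapply(leaves, function(l) length(l$idx), numeric(1L))
    eligible <- which(is.finite(gaps) & gaps >= threshold(sizes))
    if (length(eligible) == 0L) break
    # strongest standardized gap first, ties by leaf creation index
    ord <- eligible[order(-prio[eligible],
                          vapply(leaves[eligible], `[[`, integer(1L), "created"))]
    pick <- ord[1L]
    leaf <- leaves[[pick]]
    left_sel <- values[leaf$idx, leaf$dim] < leaf$cut
    lo_l <- leaf$lower; hi_l <- leaf$upper; hi_l[leaf$dim] <- leaf$cut
    lo_r <- leaf$lower; lo_r[leaf$dim] <- leaf$cut
    left <- score_leaf(new_leaf(lo_l, hi_l, leaf$idx[left_sel],
                                leaf$depth + 1L, created + 1L))
    right <- score_leaf(new_leaf(lo_r, leaf$upper, leaf$idx[!left_sel],
                                 leaf$depth + 1L, created + 2L))
    created <- created + 2L
    leaves[[pick]] <- left
    leaves[[length(leaves) + 1L]] <- right
  }
  partition_result(leaves, "dsp", n, box)
}

# Piecewise-constant log-likelihood contribution of one leaf:
# n_l * log(n_l / (n * V_l)) with V_l the volume fraction of the bounding
# box; zero for an empty leaf.
ll_term <- function(nl, log_relvol, n_total) {
  if (nl == 0) 0 else nl * (log(nl) - log(n_total) - log_relvol)
}

# Evaluate the best one-step look-ahead midpoint cut of a leaf: immediate
# penalised gain plus the best single follow-up midpoint cut inside either
# child (taken as 0 when every follow-up is unprofitable).
bsp_candidate <- function(X, log_relvol, n_total, lambda) {
  nl <- nrow(X)
  p <- ncol(X)
  if (nl < 2L) {
    return(list(dim = NA_integer_, combined = -Inf, immediate = -Inf))
  }
  lower <- attr(X, "lower"); upper <- attr(X, "upper")
  mids <- (lower + upper) / 2
  B <- X < rep(mids, each = nl)          # n x p: below-midpoint indicator
  storage.mode(B) <- "double"
  n_left <- .colSums(B, nl, p)
  n_right <- nl - n_left
  lv_child <- log_relvol - log(2)
  lv_grand <- log_relvol - 2 * log(2)
  term_leaf <- ll_term(nl, log_relvol, n_total)
  t_left <- vapply(n_left, ll_term, numeric(1L), lv_child, n_total)
  t_right <- vapply(n_right, ll_term, numeric(1L), lv_child, n_total)
  immediate <- t_left + t_right - term_leaf - lambda

  # Follow-up counts for a second cut along j2 != j reuse the same
  # midpoints, so M[j, j2] = #(below mid_j & below mid_j2) gives them all.
  M <- crossprod(B)
  q1 <- (lower + mids) / 2
  q3 <- (mids + upper) / 2
  nq1 <- .colSums(X < rep(q1, each = nl), nl, p)   # counts in [lo, q1)
  nq3 <- .colSums(X < rep(q3, each = nl), nl, p)   # counts in [lo, q3)

  followup <- numeric(p)
  for (j in seq_len(p)) {
    best <- 0
    for (j2 in seq_len(p)) {
      if (j2 == j) {
        a <- nq1[j]                       # left child split at its midpoint
        g1 <- ll_term(a, lv_grand, n_total) +
          ll_term(n_left[j] - a, lv_grand, n_total) -
          ll_term(n_left[j], lv_child, n_total) - lambda
        b <- nq3[j] - n_left[j]           # right child split at its midpoint
        g2 <- ll_term(b, lv_grand, n_total) +
          ll_term(n_right[j] - b, lv_grand, n_total) -
          ll_term(n_right[j], lv_child, n_total) - lambda
      } else {
        a <- M[j, j2]
        g1 <- ll_term(a, lv_grand, n_total) +
          ll_term(n_left[j] - a, lv_grand, n_total) -
          ll_term(n_left[j], lv_child, n_total) - lambda
        b <- n_left[j2] - a
        g2 <- ll_term(b, lv_grand, n_total) +
          ll_term(n_right[j] - b, lv_grand, n_total) -
          ll_term(n_right[j], lv_child, n_total) - lambda
      }
      best <- max(best, g1, g2)
    }
    followup[j] <- best
  }
  combined <- immediate + followup
  j <- which.max(combined)
  list(dim = j, combined = combined[j], immediate = immediate[j])
}

#' Bayesian sequential partition with one-step look-ahead
#'
#' Greedy sequence of midpoint binary cuts scored by the penalised
#' piecewise-constant log-likelihood
#' `sum_l n_l log(n_l / (n V_l)) - lambda * #leaves`.
#' Each step evaluates, for every (leaf, dimension) pair, the gain of the
#' midpoint cut plus the best single follow-up midpoint cut inside either
#' child, and executes the cut with the largest combined gain. The
#' procedure stops at the leaf budget or when no candidate has a positive
#' combined gain.
#'
#' @param m An [event_matrix()].
#' @param leaf_budget Maximum number of leaves (>= 1).
#' @param lookahead Look-ahead depth; only the one-step scheme (`1`) is
#'   implemented.
#' @param lambda Complexity penalty per leaf; default `log(n) / 2`.
#' @return A `partition_result`; its `score_trace` attribute records the
#'   penalised score after each accepted cut.
#' @export
bsp_ll_partition <- function(m, leaf_budget, lookahead = 1L, lambda = NULL) {
  stopifnot(inherits(m, "event_matrix"))
  if (leaf_budget < 1L) stop("leaf_budget must be >= 1")
  if (!identical(as.integer(lookahead), 1L)) {
    stop("only one-step look-ahead is implemented")
  }
  values <- m$values
  n <- nrow(values)
  box <- bounding_box(values)
  lambda <- if (is.null(lambda)) log(n) / 2 else lambda

  make <- function(lower, upper, idx, depth, created, log_relvol) {
    leaf <- new_leaf(lower, upper, idx, depth, created)
    leaf$log_relvol <- log_relvol
    X <- values[idx, , drop = FALSE]
    attr(X, "lower") <- lower
    attr(X, "upper") <- upper
    leaf$cand <- bsp_candidate(X, log_relvol, n, lambda)
    leaf
  }

  leaves <- list(make(box$lower, box$upper, seq_len(n), 0L, 1L, 0))
  created <- 1L
  score <- ll_term(n, 0, n) - lambda
  trace <- score
  while (length(leaves) < leaf_budget) {
    combined <- vapply(leaves, function(l) l$cand$combined, numeric(1L))
    if (max(combined) <= 0) break
    ord <- order(-combined,
                 vapply(leaves, `[[`, integer(1L), "created"))
    pick <- ord[1L]
    leaf <- leaves[[pick]]
    j <- leaf$cand$dim
    mid <- (leaf$lower[j] + leaf$upper[j]) / 2
    left_sel <- values[leaf$idx, j] < mid
    hi_l <- leaf$upper; hi_l[j] <- mid
    lo_r <- leaf$lower; lo_r[j] <- mid
    lv <- leaf$log_relvol - log(2)
    left <- make(leaf$lower, hi_l, leaf$idx[left_sel], leaf$depth + 1L,
                 created + 1L, lv)
    right <- make(lo_r, leaf$upper, leaf$idx[!left_sel], leaf$depth + 1L,
                  created + 2L, lv)
    created <- created + 2L
    score <- score + leaf$cand$immediate
    trace <- c(trace, score)
    leaves[[pick]] <- left
    leaves[[length(leaves) + 1L]] <- right
  }
  out <- partition_result(leaves, "bsp_ll", n, box)
  attr(out, "score_trace") <- trace
  attr(out, "lambda") <- lambda
  out
}

#' Penalised log-likelihood score of a partition
#'
#' Direct evaluation of
#' `sum_l n_l log(n_l / (n V_l)) - lambda * #leaves`,
#' with `V_l` the leaf volume as a fraction of the bounding box. Useful for
#' inspecting or verifying a partition independently of the incremental
#' bookkeeping done during construction.
#'
#' @param p A `partition_result`.
#' @param lambda Penalty per leaf; default `log(n) / 2`.
#' @return The penalised score (a scalar).
#' @export
partition_score <- function(p, lambda = NULL) {
  stopifnot(inherits(p, "partition_result"))
  n <- p$n_events
  lambda <- if (is.null(lambda)) log(n) / 2 else lambda
  box_log_vol <- sum(log(p$box$upper - p$box$lower))
  s <- 0
  for (leaf in p$leaves) {
    nl <- length(leaf$idx)
    lv <- sum(log(leaf$upper - leaf$lower)) - box_log_vol
    s <- s + ll_term(nl, lv, n)
  }
  s - lambda * length(p$leaves)
}

#' Initial cluster centers from a partition
#'
#' One center per non-empty leaf, the mean of the leaf's member events, in
#' leaf creation order.
#'
#' @param p A `partition_result` built on `m`.
#' @param m The [event_matrix()] the partition was built on.
#' @return A numeric matrix, one center per row.
#' @export
initial_centers <- function(p, m) {
  stopifnot(inherits(p, "partition_result"), inherits(m, "event_matrix"))
  keep <- Filter(function(l) length(l$idx) > 0L, p$leaves)
  ord <- order(vapply(keep, `[[`, integer(1L), "created"))
  centers <- t(vapply(keep[ord], function(l) {
    colMeans(m$values[l$idx, , drop = FALSE])
  }, numeric(ncol(m$values))))
  colnames(centers) <- m$marker_names
  centers
}
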