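test_that("uniformity gap matches the exhaustive discrepancy scan", {
  set.seed(11)
  x <- rbeta(200, 2, 2)
  got <- leaf_uniformity_gap(x, 0, 1)
  u <- sort(x)
  n <- length(u)
  oracle <- max(pmax(abs(seq_len(n) / n - u), abs((seq_len(n) - 1) / n - u)))
  expect_equal(got$score, oracle, tolerance = 1e-12)
  expect_gt(got$cut, 0)
  expect_lt(got$cut, 1)
})

test_that("uniformity gap hits its extremes", {
  k <- 200
  expect_lt(leaf_uniformity_gap(seq_len(k) / (k + 1), 0, 1)$score, 0.01)
  expect_equal(leaf_uniformity_gap(rep(0, 50), 0, 1)$score, 1)
  expect_error(leaf_uniformity_gap(c(1, 2), 3, 3), "degenerate")
  expect_error(leaf_uniformity_gap(1, 0, 1), "at least 2")
})

test_that("uniform data yields a single leaf under a loose threshold", {
  set.seed(2)
  ev <- as_events(matrix(runif(2000), 1000, 2))
  p <- dsp_partition(ev, leaf_budget = 10, theta = 0.5)
  expect_equal(length(p$leaves), 1L)
  b <- bsp_ll_partition(ev, leaf_budget = 10)
  expect_equal(length(b$leaves), 1L)
})

test_that("two separated modes are cut between them", {
  set.seed(3)
  x <- c(rnorm(500), rnorm(500, 10))
  ev <- as_events(cbind(x, runif(1000)))
  p <- dsp_partition(ev, leaf_budget = 2)
  expect_equal(length(p$leaves), 2L)
  cut <- p$leaves[[1L]]$upper[1L]
  expect_gt(cut, 2); expect_lt(cut, 8)
  sizes <- vapply(p$leaves, function(l) length(l$idx), integer(1L))
  expect_true(all(sizes >= 0.49 * 1000))
})

test_that("a five-mode mixture gets each mode its own leaf", {
  set.seed(4)
  centers <- cbind(c(0, 0, 20, 20, 10), c(0, 20, 0, 20, 10))
  values <- do.call(rbind, lapply(1:5, function(i) {
    matrix(rnorm(2 * 400), 400, 2) + rep(centers[i, ], each = 400)
  }))
  p <- dsp_partition(as_events(values), leaf_budget = 10)
  owner <- vapply(1:5, function(i) {
    for (j in seq_along(p$leaves)) {
      l <- p$leaves[[j]]
      if (all(centers[i, ] >= l$lower & centers[i, ] < l$upper)) return(j)
    }
    NA_integer_
  }, integer(1L))
  expect_equal(length(unique(owner)), 5L)
})

test_that("partitions cover every event exactly once", {
  for (seed in 1:3) {
    sim <- gmm_sample(sim_spec(a = 3, b = 3, c = 30, d = 3000, seed = seed))
    for (p in list(dsp_partition(sim$events, 8),
                   bsp_ll_partition(sim$events, 8))) {
      idx <- sort(unlist(lapply(p$leaves, `[[`, "idx")))
      expect_equal(idx, seq_len(3000))
      # every member lies inside its leaf's half-open box
      for (l in p$leaves) {
        if (length(l$idx) == 0L) next
        v <- sim$events$values[l$idx, , drop = FALSE]
        expect_true(all(t(v) >= l$lower & t(v) < l$upper))
      }
      # leaf volumes tile the bounding box
      box_vol <- prod(p$box$upper - p$box$lower)
      leaf_vol <- sum(vapply(p$leaves, function(l) prod(l$upper - l$lower),
                             numeric(1L)))
      expect_equal(leaf_vol, box_vol, tolerance = 1e-9)
    }
  }
})

test_that("well-separated components are captured by distinct leaf centers", {
  hits <- vapply(1:20, function(seed) {
    sim <- gmm_sample(sim_spec(a = 3, b = 4, c = 60, d = 4000, seed = seed))
    p <- dsp_partition(sim$events, leaf_budget = 8)
    centers <- initial_centers(p, sim$events)
    nearest <- apply(sim$means, 1L, function(mu) {
      which.min(colSums((t(centers) - mu)^2))
    })
    length(unique(nearest)) == 4L
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("the BSP score equals its direct evaluation", {
  sim <- gmm_sample(sim_spec(a = 3, b = 3, c = 30, d = 4000, seed = 5))
  p <- bsp_ll_partition(sim$events, leaf_budget = 8)
  lambda <- attr(p, "lambda")
  trace <- attr(p, "score_trace")
  direct <- brute_partition_score(p, lambda)
  expect_equal(trace[length(trace)], direct, tolerance = 1e-8)
  expect_equal(partition_score(p, lambda), direct, tolerance = 1e-8)
  # each accepted cut improved the penalised score
  expect_true(all(diff(trace) > 0))
})

test_that("the first BSP cut maximises the look-ahead gain over all dimensions", {
  # three clusters with one offset: the look-ahead score of each candidate
  # dimension is recomputed by direct enumeration of cut + best follow-up
  set.seed(6)
  values <- rbind(matrix(rnorm(600, sd = 0.5), 300, 2) + rep(c(1, 1), each = 300),
                  matrix(rnorm(600, sd = 0.5), 300, 2) + rep(c(1, 9), each = 300),
                  matrix(rnorm(600, sd = 0.5), 300, 2) + rep(c(9, 6), each = 300))
  ev <- as_events(values)
  p <- bsp_ll_partition(ev, leaf_budget = 2)
  first_cut_dim <- unname(which(p$leaves[[1L]]$upper != p$leaves[[2L]]$upper))

  n <- nrow(values)
  lambda <- log(n) / 2
  lo <- apply(values, 2, min) - 1e-6 * pmax(apply(values, 2, range)[2, ] - apply(values, 2, min), 1)
  hi <- apply(values, 2, max) + 1e-6 * pmax(apply(values, 2, max) - apply(values, 2, min), 1)
  term <- function(nl, v) if (nl == 0) 0 else nl * log(nl / (n * v))
  gain_of <- function(sel_lo, sel_hi, vol, dim) {
    inside <- values[, 1] >= sel_lo[1] & values[, 1] < sel_hi[1] &
      values[, 2] >= sel_lo[2] & values[, 2] < sel_hi[2]
    nl <- sum(inside)
    mid <- (sel_lo[dim] + sel_hi[dim]) / 2
    nlft <- sum(inside & values[, dim] < mid)
    term(nlft, vol / 2) + term(nl - nlft, vol / 2) - term(nl, vol) - lambda
  }
  combined <- vapply(1:2, function(j) {
    g1 <- gain_of(lo, hi, 1, j)
    best_follow <- 0
    for (side in 1:2) {
      child_lo <- lo; child_hi <- hi
      mid <- (lo[j] + hi[j]) / 2
      if (side == 1) child_hi[j] <- mid else child_lo[j] <- mid
      for (j2 in 1:2) {
        best_follow <- max(best_follow, gain_of(child_lo, child_hi, 0.5, j2))
      }
    }
    g1 + best_follow
  }, numeric(1L))
  expect_equal(first_cut_dim, which.max(combined))
})

test_that("initial centers are leaf means in creation order", {
  set.seed(8)
  ev <- as_events(matrix(runif(600), 300, 2))
  p <- dsp_partition(ev, leaf_budget = 5, theta = 0.9)
  centers <- initial_centers(p, ev)
  expect_equal(nrow(centers),
               sum(vapply(p$leaves, function(l) length(l$idx) > 0, logical(1L))))
  expect_equal(unname(centers[1L, ]), unname(colMeans(ev$values[p$leaves[[1L]]$idx, ])))
  # single leaf: the global mean
  p1 <- dsp_partition(ev, leaf_budget = 1)
  expect_equal(unname(initial_centers(p1, ev)[1L, ]), unname(colMeans(ev$values)))
})

test_that("degenerate partition inputs error or warn as contracted", {
  ev <- as_events(matrix(rnorm(40), 20, 2))
  expect_error(dsp_partition(ev, leaf_budget = 0), ">= 1")
  expect_error(bsp_ll_partition(ev, leaf_budget = 0), ">= 1")
  tiny <- as_events(matrix(rnorm(8), 4, 2))
  expect_warning(p <- dsp_partition(tiny, leaf_budget = 4, min_leaf_size = 10),
                 "single leaf")
  expect_equal(length(p$leaves), 1L)
})
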