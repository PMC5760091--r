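test_that("k-means refinement reproduces a reference Lloyd run", {
  set.seed(21)
  values <- matrix(rnorm(200), 100, 2)
  ev <- as_events(values)
  centers <- values[c(5, 40, 80), ]
  for (iters in c(0L, 1L, 2L, 5L)) {
    got <- kmeans_refine(ev, centers, iterations = iters)
    want <- reference_lloyd(values, centers, iters)
    expect_equal(got$labels, want, info = paste("iterations", iters))
  }
  # SSE is non-increasing in the iteration count
  sse <- vapply(0:6, function(it) {
    total_sse(values, kmeans_refine(ev, centers, iterations = it)$labels)
  }, numeric(1L))
  expect_true(all(diff(sse) <= 1e-9))
})

test_that("true centers are a fixed point of the refinement", {
  clouds <- two_clouds(n = 150, gap = 12, seed = 22)
  ev <- as_events(clouds$values)
  centers <- rowsum(clouds$values, clouds$labels) / 150
  a <- kmeans_refine(ev, centers, iterations = 0L)
  b <- kmeans_refine(ev, centers, iterations = 25L)
  expect_equal(a$labels, b$labels)
  expect_equal(total_sse(clouds$values, a$labels),
               total_sse(clouds$values, b$labels))
})

test_that("refinement validates inputs and drops emptied clusters", {
  ev <- as_events(matrix(rnorm(60), 30, 2))
  expect_error(kmeans_refine(ev, matrix(0, 2, 3)), "dimension mismatch")
  # a far-away center captures nothing and is dropped
  centers <- rbind(colMeans(ev$values), c(1e6, 1e6))
  out <- kmeans_refine(ev, centers, iterations = 3L)
  expect_equal(length(out$summaries), 1L)
  expect_equal(sum(vapply(out$summaries, `[[`, numeric(1L), "size")), 30)
})

test_that("merge distance matches its closed forms", {
  mk <- function(mean, cov, size = 10) list(mean = mean, cov = cov, size = size)
  eye <- diag(2)
  expect_equal(merge_distance(mk(c(0, 0), eye), mk(c(0, 0), eye)), 0)
  expect_equal(merge_distance(mk(c(3, 0), eye), mk(c(0, 0), eye)), 9,
               tolerance = 1e-4)
  expect_equal(merge_distance(mk(c(3, 0), eye), mk(c(0, 0), 9 * eye)),
               1, tolerance = 1e-4)
  # symmetric in its arguments
  expect_equal(merge_distance(mk(c(1, 2), eye), mk(c(4, 0), 3 * eye)),
               merge_distance(mk(c(4, 0), 3 * eye), mk(c(1, 2), eye)))
  bad <- mk(c(0, 0), matrix(0, 2, 2), size = 1)
  expect_error(merge_distance(bad, mk(c(1, 1), eye), "tiny", "ok"), "tiny")
})

test_that("greedy merging picks the exhaustive argmin pair", {
  set.seed(23)
  for (k0 in c(3L, 6L, 10L)) {
    centers <- matrix(runif(k0 * 3, 0, 20), k0, 3)
    values <- do.call(rbind, lapply(seq_len(k0), function(i) {
      matrix(rnorm(60 * 3), 60, 3) + rep(centers[i, ], each = 60)
    }))
    labels <- rep(seq_len(k0), each = 60)
    ev <- as_events(values)
    lab <- cluster_labeling(labels, cluster_summaries(values, labels))
    merged <- merge_to_k(ev, lab, k0 - 1L)
    # oracle: evaluate every pair's distance, find the argmin
    s <- lab$summaries
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k0 - 1L)) {
      for (j in seq.int(i + 1L, k0)) {
        d <- merge_distance(s[[i]], s[[j]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    expect_true(all(merged$labels[labels == best[1L]] ==
                      merged$labels[labels == best[2L]]))
    expect_equal(length(merged$summaries), k0 - 1L)
    expect_equal(sum(vapply(merged$summaries, `[[`, numeric(1L), "size")),
                 length(labels))
  }
})

test_that("merging is a no-op at K = current and total at K = 1", {
  clouds <- two_clouds(n = 100, seed = 24)
  ev <- as_events(clouds$values)
  lab <- cluster_labeling(clouds$labels,
                          cluster_summaries(clouds$values, clouds$labels))
  expect_identical(merge_to_k(ev, lab, 2L)$labels, lab$labels)
  one <- merge_to_k(ev, lab, 1L)
  expect_equal(unique(one$labels), 1L)
  expect_error(merge_to_k(ev, lab, 0L), ">= 1")
  expect_error(merge_to_k(ev, lab, 3L), "exceeds")
})

test_that("staged merging equals direct merging", {
  sim <- gmm_sample(sim_spec(a = 3, b = 6, c = 40, d = 3000, seed = 25))
  km <- kmeans_refine(sim$events, sim$means, iterations = 10L)
  direct <- merge_to_k(sim$events, km, 3L)
  staged <- merge_to_k(sim$events, merge_to_k(sim$events, km, 5L), 3L)
  expect_equal(f_measure(direct$labels, staged$labels), 1)
})

test_that("pac recovers two disjoint Gaussians exactly", {
  clouds <- two_clouds(n = 500, p = 3, gap = 15, seed = 26)
  ev <- as_events(clouds$values)
  cl <- pac(ev, k = 2, n_init = 4)
  # oracle: exhaustive 2-means on two well-separated clouds is the true split
  expect_equal(f_measure(clouds$labels, cl$labels), 1)
  expect_equal(sum(vapply(cl$summaries, `[[`, numeric(1L), "size")), 1000)
})

test_that("pac with K = N leaves merging a no-op", {
  sim <- gmm_sample(sim_spec(a = 3, b = 2, c = 40, d = 2000, seed = 27))
  p <- dsp_partition(sim$events, leaf_budget = 4)
  refined <- kmeans_refine(sim$events, initial_centers(p, sim$events))
  k_eff <- length(refined$summaries)
  via_pac <- pac(sim$events, k = k_eff, n_init = 4)
  expect_equal(via_pac$labels, refined$labels)
})

test_that("pac refuses untransformed input and bad configurations", {
  raw <- event_matrix(matrix(abs(rnorm(100)), 50, 2))
  expect_error(pac(raw, k = 2), "transformed")
  ev <- as_events(matrix(rnorm(100), 50, 2))
  expect_error(pac(ev, k = 5, n_init = 3), "k <= n_init")
})
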