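test_that("identical networks collapse to one clade", {
  nets <- list(a = fake_network(c("ab", "bc")), b = fake_network(c("ab", "bc")),
               c = fake_network(c("ab", "bc")))
  tree <- network_dendrogram(nets)
  expect_equal(unname(cut_to_clades(tree, 1L)), rep(1L, 3))
  expect_true(all(tree$height == 0))
})

test_that("two identical pairs split cleanly at k = 2", {
  nets <- list(p1 = fake_network(c("ab", "bc", "cd")),
               q1 = fake_network(c("ae", "de", "ce")),
               p2 = fake_network(c("ab", "bc", "cd")),
               q2 = fake_network(c("ae", "de", "ce")))
  cl <- cut_to_clades(network_dendrogram(nets), 2L)
  expect_equal(cl[["p1"]], cl[["p2"]])
  expect_equal(cl[["q1"]], cl[["q2"]])
  expect_true(cl[["p1"]] != cl[["q1"]])
  # exhaustive check: no other 2-partition has zero within-clade distance
  expect_equal(unname(cut_to_clades(network_dendrogram(nets), 4L)), 1:4)
})

test_that("clade cuts validate their range", {
  nets <- list(a = fake_network("ab"), b = fake_network("cd"))
  tree <- network_dendrogram(nets)
  expect_equal(unname(cut_to_clades(tree, 1L)), c(1L, 1L))
  expect_error(cut_to_clades(tree, 3L), "out of range")
  expect_error(cut_to_clades(tree, 0L), "out of range")
  single <- network_dendrogram(nets[1])
  expect_equal(unname(cut_to_clades(single, 1L)), 1L)
  expect_error(cut_to_clades(single, 2L), "out of range")
})

test_that("within-sample co-clade subpopulations merge, others do not", {
  assignment <- data.frame(sample = c("s1", "s1", "s1", "s2"),
                           subpop = c(1L, 2L, 3L, 1L),
                           clade = c(1L, 1L, 2L, 1L),
                           size = c(10L, 5L, 7L, 9L))
  labelings <- list(s1 = rep(c(1L, 2L, 3L), c(10, 5, 7)), s2 = rep(1L, 9))
  out <- merge_within_sample(assignment, labelings)
  expect_equal(nrow(out$assignment), 3L)
  merged_row <- out$assignment[out$assignment$sample == "s1" &
                                 out$assignment$clade == 1L, ]
  expect_equal(merged_row$subpop, 1L)
  expect_equal(merged_row$size, 15L)
  expect_equal(sum(out$labelings$s1 == 1L), 15)
  expect_equal(length(out$labelings$s1), 22L)      # conservation
  expect_equal(out$labelings$s2, labelings$s2)     # cross-sample untouched

  # identity when nothing shares a clade within a sample
  lone <- data.frame(sample = c("s1", "s1"), subpop = 1:2, clade = 1:2,
                     size = c(3L, 4L))
  out2 <- merge_within_sample(lone, list(s1 = rep(1:2, 3:4)))
  expect_equal(out2$assignment, lone)
})

test_that("small subpopulations join their group's aligned anchor", {
  centroids <- rbind(c(0, 0), c(0.2, 0), c(10, 10), c(100, 100))
  sample_of <- rep("s1", 4)
  clade_of <- c(1L, NA, 2L, NA)
  out <- rescue_small_subpopulations(centroids, sample_of, clade_of, k = 2L,
                                     expression_groups = 3L)
  expect_equal(out$clade[2L], 1L)       # grouped with, and nearest to, clade 1
  expect_equal(out$kind[2L], "aligned")
  # the far singleton group is beyond reach and becomes sample-specific
  expect_equal(out$clade[4L], 3L)
  expect_equal(out$kind[4L], "minor")
})

test_that("with no aligned subpopulations everything becomes sample-specific", {
  centroids <- rbind(c(0, 0), c(5, 5))
  expect_warning(
    out <- rescue_small_subpopulations(centroids, c("s1", "s1"),
                                       c(NA_integer_, NA_integer_), k = 0L,
                                       expression_groups = 2L),
    "no large")
  expect_true(all(out$kind == "minor"))
  expect_equal(sort(unique(out$clade)), c(1L, 2L))
})

test_that("tiny clades are discarded from the assignment", {
  set.seed(51)
  base <- two_clouds(n = 1500, p = 4, gap = 12, seed = 51)
  spike <- matrix(rnorm(90 * 4), 90, 4) + 60   # 90 events, far away
  values <- rbind(base$values, spike)
  labels <- c(base$labels, rep(3L, 90))
  samples <- list(
    s1 = list(events = as_events(values, "s1"),
              labeling = cluster_labeling(labels, cluster_summaries(values, labels), "s1")),
    s2 = list(events = as_events(base$values, "s2"),
              labeling = cluster_labeling(base$labels,
                                          cluster_summaries(base$values, base$labels), "s2")))
  a <- man(samples, k = 2, mode = "sequential", expression_groups = 3)
  spike_row <- a$assignment[a$assignment$sample == "s1" & a$assignment$subpop == 3L, ]
  expect_equal(spike_row$kind, "discarded")
  expect_true(is.na(spike_row$clade))
  expect_true(all(is.na(a$event_clades$s1[labels == 3L])))
  # discarded events are excluded from, and proportions normalised over,
  # the retained events
  expect_equal(unname(colSums(a$proportions)), c(1, 1))
})

test_that("a single sample with k = #subpopulations is an identity assignment", {
  sim <- gmm_sample(sim_spec(a = 4, b = 3, c = 40, d = 4500, seed = 52))
  lab <- cluster_labeling(sim$labels, cluster_summaries(sim$events$values, sim$labels))
  samples <- list(s1 = list(events = sim$events, labeling = lab))
  a <- man(samples, k = 3, mode = "network")
  expect_equal(nrow(a$assignment), 3L)
  expect_equal(sort(unique(a$assignment$clade)), 1:3)
  expect_equal(a$event_subpops$s1, sim$labels)
})

test_that("alignment is invariant to a constant shift of one sample", {
  sc <- batch_scenario(n_per_subpop = 1500, seed = 53)
  mk <- function(s) {
    lab <- cluster_labeling(s$labels,
                            cluster_summaries(s$events$values, s$labels),
                            s$events$sample_id)
    list(events = s$events, labeling = lab)
  }
  samples <- lapply(sc$samples, mk)
  a1 <- man(samples, k = 2, mode = "network")
  shifted <- samples
  shifted$instrument2$events$values <- shifted$instrument2$events$values + 7.3
  a2 <- man(shifted, k = 2, mode = "network")
  expect_equal(a1$assignment, a2$assignment)
  expect_equal(a1$event_clades, a2$event_clades)
})

test_that("no clade ever holds two unmerged subpopulations of one sample", {
  for (seed in 1:2) {
    sc <- batch_scenario(n_per_subpop = 1200, seed = seed)
    ps <- lapply(sc$samples, function(s) {
      list(events = s$events, labeling = pac(s$events, k = 3, n_init = 6))
    })
    a <- man(ps, k = 3, mode = "network")
    non_na <- a$assignment[!is.na(a$assignment$clade), ]
    expect_false(anyDuplicated(non_na[, c("sample", "clade")]) > 0)
    # event conservation: every event is labelled or explicitly discarded
    for (s in names(ps)) {
      expect_equal(length(a$event_clades[[s]]), nrow(ps[[s]]$events$values))
    }
  }
})

test_that("pairing score is 1 exactly on a correct linkage", {
  sc <- batch_scenario(n_per_subpop = 800, seed = 54)
  mk <- function(s) {
    lab <- cluster_labeling(s$labels,
                            cluster_summaries(s$events$values, s$labels),
                            s$events$sample_id)
    list(events = s$events, labeling = lab)
  }
  a <- man(lapply(sc$samples, mk), k = 2, mode = "network",
           large_threshold = 500)
  expect_equal(pairing_ari(a, sc$truth), 1)
  expect_true(tracks_subpopulations(a, sc$truth))
  # breaking the cross-sample identity must break the score
  bad_truth <- sc$truth
  bad_truth$instrument2 <- 3 - bad_truth$instrument2
  expect_lt(pairing_ari(a, bad_truth), 1)
  half <- sc$truth
  half$instrument2[] <- 1L
  expect_lt(pairing_ari(a, half), 1)
})

test_that("the elbow finder locates a knee and flags flat curves", {
  k <- 1:11
  kinked <- ifelse(k <= 5, 100 - 15 * k, 25 - 1 * (k - 5))
  out <- elbow_knee(k, kinked, span = 0.5)
  expect_equal(out$suggested_k, 5L)
  expect_true(out$confident)
  flat <- elbow_knee(k, 100 - 3 * k)
  expect_false(flat$confident)
  short <- elbow_knee(1:2, c(3, 2))
  expect_true(is.na(short$suggested_k))
})

test_that("the elbow curve decreases with k on separable data", {
  sim1 <- gmm_sample(sim_spec(a = 4, b = 3, c = 40, d = 3000, seed = 55))
  sim2 <- gmm_sample(sim_spec(a = 4, b = 3, c = 40, d = 3000, seed = 56))
  mk <- function(sim, id) {
    ev <- sim$events; ev$sample_id <- id
    list(events = ev, labeling = pac(ev, k = 4, n_init = 8))
  }
  samples <- list(s1 = mk(sim1, "s1"), s2 = mk(sim2, "s2"))
  out <- elbow_curve(samples, k_range = 2:5, mode = "means")
  expect_equal(out$k, 2:5)
  expect_true(all(is.finite(out$error)))
  expect_lt(out$error[4], out$error[1])
})
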