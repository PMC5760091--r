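# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths: pair counts by explicit double loop,
# MRMR by a literal forward-selection transcription, Lloyd by a naive
# reference, the partition score by direct evaluation of its formula.

brute_pair_confusion <- function(truth, pred) {
  n <- length(truth)
  tp <- fp <- fn <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      same_class <- truth[i] == truth[j]
      same_cluster <- pred[i] == pred[j]
      if (same_class && same_cluster) tp <- tp + 1
      if (!same_class && same_cluster) fp <- fp + 1
      if (same_class && !same_cluster) fn <- fn + 1
    }
  }
  list(TP = tp, FP = fp, FN = fn)
}

brute_p_measure <- function(truth, pred) {
  classes <- sort(unique(truth))
  clusters <- sort(unique(pred))
  out <- NULL
  for (ck in classes) {
    best <- -1; best_cluster <- NA
    for (l in clusters) {
      ov <- sum(truth == ck & pred == l)
      if (ov > best) { best <- ov; best_cluster <- l }
    }
    s1 <- best / sum(pred == best_cluster)
    s2 <- best / sum(truth == ck)
    out <- rbind(out, data.frame(class = as.character(ck), S1 = s1, S2 = s2,
                                 P = 2 * s1 * s2 / (s1 + s2)))
  }
  out
}

# Literal MRMR forward selection over an MI matrix, one target at a time.
brute_mrmr_ranking <- function(mi) {
  p <- ncol(mi)
  score <- matrix(NA_real_, p, p)
  for (target in seq_len(p)) {
    selected <- c()
    remaining <- setdiff(seq_len(p), target)
    while (length(remaining) > 0L) {
      vals <- sapply(remaining, function(cand) {
        red <- if (length(selected) == 0L) 0 else
          mean(mi[cand, selected])
        mi[target, cand] - red
      })
      best <- remaining[which.max(vals)]
      score[target, best] <- max(vals)
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
    }
  }
  nm <- colnames(mi)
  out <- NULL
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      w <- max(score[i, j], score[j, i])
      if (w > 0) {
        a <- sort(c(nm[i], nm[j]))
        out <- rbind(out, data.frame(marker_a = a[1L], marker_b = a[2L],
                                     score = w))
      }
    }
  }
  out[order(-out$score, out$marker_a, out$marker_b), , drop = FALSE]
}

# Naive Lloyd reference: same semantics as the package contract (initial
# nearest-center assignment, then `iterations` update/assign rounds with
# empty clusters dropped, stopping early when labels stabilise).
reference_lloyd <- function(values, centers, iterations) {
  assign_step <- function(cent) {
    apply(values, 1L, function(x) {
      which.min(colSums((t(cent) - x)^2))
    })
  }
  labels <- assign_step(centers)
  for (it in seq_len(iterations)) {
    keep <- sort(unique(labels))
    labels <- match(labels, keep)
    centers <- centers[keep, , drop = FALSE]
    for (j in seq_len(nrow(centers))) {
      centers[j, ] <- colMeans(values[labels == j, , drop = FALSE])
    }
    new_labels <- assign_step(centers)
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  match(labels, sort(unique(labels)))
}

# Direct evaluation of the penalised piecewise-constant log-likelihood of
# a partition, from its leaves alone.
brute_partition_score <- function(p, lambda) {
  n <- p$n_events
  box_vol <- prod(p$box$upper - p$box$lower)
  s <- 0
  for (leaf in p$leaves) {
    nl <- length(leaf$idx)
    if (nl == 0L) next
    v <- prod(leaf$upper - leaf$lower) / box_vol
    s <- s + nl * log(nl / (n * v))
  }
  s - lambda * length(p$leaves)
}

# Histogram mutual information computed through an unrelated code path
# (explicit table + p log p loop) for the bin-for-bin comparison.
brute_histogram_mi <- function(x, y, bins) {
  n <- length(x)
  bx <- pmin(bins, ceiling(rank(x, ties.method = "first") * bins / n))
  by <- pmin(bins, ceiling(rank(y, ties.method = "first") * bins / n))
  joint <- table(bx, by) / n
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
      }
    }
  }
  max(mi, 0)
}

# Small helper: a marker_network built directly from an edge list.
fake_network <- function(edges, markers = NULL) {
  if (length(edges) == 0L) {
    df <- data.frame(marker_a = character(0), marker_b = character(0),
                     score = numeric(0))
  } else {
    a <- substr(edges, 1L, 1L)
    b <- substr(edges, 2L, 2L)
    df <- data.frame(marker_a = pmin(a, b), marker_b = pmax(a, b),
                     score = seq(1, 0.5, length.out = length(edges)))
  }
  if (is.null(markers)) markers <- sort(unique(c(df$marker_a, df$marker_b)))
  top_d_network(df, d = max(1L, nrow(df)), markers = markers)
}

# Two well-separated Gaussian clouds in `p` dimensions.
two_clouds <- function(n = 200L, p = 2L, gap = 10, seed = 1L) {
  set.seed(seed)
  values <- rbind(matrix(rnorm(n * p), n, p),
                  matrix(rnorm(n * p) + gap, n, p))
  colnames(values) <- paste0("V", seq_len(p))
  list(values = values, labels = rep(1:2, each = n))
}

as_events <- function(values, sample_id = "test") {
  event_matrix(values, sample_id = sample_id, transformed = TRUE)
}
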