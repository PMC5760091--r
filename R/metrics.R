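#' Pair-counting confusion of two labelings
#'
#' Views a clustering as one decision per pair of events: a true positive
#' pair shares both its true class and its predicted cluster, a false
#' positive shares the cluster but not the class, a false negative shares
#' the class but not the cluster. Computed from the class x cluster
#' contingency table in linear time; counts are returned as doubles since
#' pair counts overflow 32-bit integers beyond ~65k events.
#'
#' @param truth,pred Equal-length label vectors (any atomic type), length
#'   >= 2.
#' @return A list with elements `TP`, `FP`, `FN` and `n`.
#' @export
pair_confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length")
  }
  n <- length(truth)
  if (n < 2L) stop("need at least 2 events")
  tab <- table(factor(truth), factor(pred))
  choose2 <- function(x) x * (x - 1) / 2
  tp <- sum(choose2(as.numeric(tab)))
  same_cluster <- sum(choose2(as.numeric(colSums(tab))))
  same_class <- sum(choose2(as.numeric(rowSums(tab))))
  list(TP = tp, FP = same_cluster - tp, FN = same_class - tp, n = n)
}

#' Pair-counting F-measure
#'
#' Harmonic mean of pairwise precision `P = TP / (TP + FP)` and recall
#' `R = TP / (TP + FN)` over all event-pair co-assignment decisions
#' (see [pair_confusion()]). Equals 1 exactly when the two labelings induce
#' identical partitions. Conventions for empty denominators: `P` (or `R`)
#' is 1 when no same-cluster (same-class) pair exists, and `F` is 0 when
#' `TP = 0` with `FN > 0`.
#'
#' @inheritParams pair_confusion
#' @return F-measure in `[0, 1]`.
#' @export
f_measure <- function(truth, pred) {
  pc <- pair_confusion(truth, pred)
  precision <- if (pc$TP + pc$FP == 0) 1 else pc$TP / (pc$TP + pc$FP)
  recall <- if (pc$TP + pc$FN == 0) 1 else pc$TP / (pc$TP + pc$FN)
  if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
}

#' Class-specific purity measure
#'
#' For every true class `C_k`, finds the predicted cluster `L` with the
#' largest overlap (ties broken by the lowest cluster id), and reports
#' `S1 = |C_k ∩ L| / |L|` (how pure the matched cluster is),
#' `S2 = |C_k ∩ L| / |C_k|` (how much of the class it recovers) and their
#' harmonic mean `P = 2 S1 S2 / (S1 + S2)`.
#'
#' @inheritParams pair_confusion
#' @return A data frame with one row per true class: `class`, `cluster`,
#'   `overlap`, `S1`, `S2`, `P`.
#' @export
p_measure <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length")
  }
  tab <- table(factor(truth), factor(pred))
  if (any(rowSums(tab) == 0)) stop("empty class in truth labels")
  cluster_sizes <- colSums(tab)
  out <- lapply(seq_len(nrow(tab)), function(k) {
    overlaps <- tab[k, ]
    i <- which.max(overlaps)       # which.max takes the first (lowest id) tie
    ov <- as.numeric(overlaps[i])
    s1 <- ov / as.numeric(cluster_sizes[i])
    s2 <- ov / as.numeric(sum(tab[k, ]))
    data.frame(class = rownames(tab)[k],
               cluster = colnames(tab)[i],
               overlap = ov, S1 = s1, S2 = s2,
               P = if (s1 + s2 > 0) 2 * s1 * s2 / (s1 + s2) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected for chance.
#' Used to score recovered cross-sample pairings against generator truth.
#'
#' @inheritParams pair_confusion
#' @return ARI (1 for identical partitions, ~0 for random agreement).
#' @export
adjusted_rand <- function(truth, pred) {
  pc <- pair_confusion(truth, pred)
  total <- pc$n * (pc$n - 1) / 2
  tn <- total - pc$TP - pc$FP - pc$FN
  num <- 2 * (pc$TP * tn - pc$FP * pc$FN)
  den <- (pc$TP + pc$FP) * (pc$FP + tn) + (pc$TP + pc$FN) * (pc$FN + tn)
  if (den == 0) 1 else num / den
}
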