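#' Pairwise mutual-information matrix of markers
#'
#' Plug-in (histogram) mutual information in nats between every pair of
#' markers after equal-frequency discretization of each column into
#' `bins` bins. The diagonal holds the marginal bin entropies. Because the
#' binning depends only on ranks, the matrix is invariant under strictly
#' monotone per-marker transforms — the property that makes downstream
#' network alignment robust to batch-effect shifts. Constant columns carry
#' no information; their entries are set to 0 with a warning.
#'
#' @param values Numeric matrix (events x markers), at least 2 markers.
#' @param bins Number of bins per marker; default `ceiling(n^(1/3))`.
#' @param min_events Minimum rows required for a usable estimate
#'   (default 50).
#' @return A symmetric non-negative matrix with marker dimnames.
#' @export
mutual_information_matrix <- function(values, bins = NULL, min_events = 50L) {
  values <- as.matrix(values)
  p <- ncol(values)
  n <- nrow(values)
  if (p < 2L) stop("need at least 2 markers")
  if (n < min_events) {
    stop("too few events (", n, ") for mutual information; need >= ",
         min_events)
  }
  if (is.null(bins)) bins <- ceiling(n^(1 / 3))
  bins <- max(2L, as.integer(bins))

  constant <- apply(values, 2L, function(x) max(x) == min(x))
  if (any(constant)) {
    warning("constant marker column(s): ",
            paste(colnames(values)[constant], collapse = ", "),
            "; their mutual information is 0")
  }
  # equal-frequency bins from ranks; ties resolved by original row order so
  # any strictly monotone transform yields identical bins
  disc <- apply(values, 2L, function(x) {
    r <- rank(x, ties.method = "first")
    pmin(bins, ceiling(r * bins / n))
  })

  entropy <- function(counts) {
    pr <- counts[counts > 0] / sum(counts)
    -sum(pr * log(pr))
  }
  marg <- lapply(seq_len(p), function(j) tabulate(disc[, j], nbins = bins))

  mi <- matrix(0, p, p, dimnames = list(colnames(values), colnames(values)))
  for (j in seq_len(p)) {
    mi[j, j] <- if (constant[j]) 0 else entropy(marg[[j]])
  }
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      if (constant[i] || constant[j]) next
      joint <- tabulate(disc[, i] + bins * (disc[, j] - 1L),
                        nbins = bins * bins)
      hij <- entropy(joint)
      v <- entropy(marg[[i]]) + entropy(marg[[j]]) - hij
      mi[i, j] <- mi[j, i] <- max(v, 0)
    }
  }
  mi
}

# MRMR forward selection for one target: repeatedly add the candidate with
# the largest (relevance - redundancy) = MI(target, c) - mean MI(c, selected),
# recording each candidate's score at its selection time.
mrmr_scores <- function(mi, target) {
  p <- ncol(mi)
  candidates <- setdiff(seq_len(p), target)
  selected <- integer(0)
  scores <- rep(NA_real_, p)
  red_sum <- numeric(p)
  while (length(candidates) > 0L) {
    red <- if (length(selected) == 0L) 0 else
      red_sum[candidates] / length(selected)
    val <- mi[target, candidates] - red
    pick <- candidates[which.max(val)]   # first max = lowest index on ties
    scores[pick] <- max(val)
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
    if (length(candidates) > 0L) {
      red_sum[candidates] <- red_sum[candidates] + mi[pick, candidates]
    }
  }
  scores
}

#' Maximum-relevance/minimum-redundancy edge ranking
#'
#' Network inference by mutual-information ranking: an MRMR forward
#' selection is run with every marker as the target (relevance =
#' MI(target, candidate); redundancy = mean MI(candidate, already
#' selected)), and the score of edge `{i, j}` is the larger of `j`'s score
#' when `i` is the target and vice versa. Only edges with positive score —
#' markers that carry non-redundant information about each other — are
#' returned, ranked by score (ties by lexicographic marker pair). With
#' fewer than 3 markers the ranking degenerates to raw mutual information.
#'
#' @param mi Symmetric mutual-information matrix from
#'   [mutual_information_matrix()].
#' @return A data frame `marker_a`, `marker_b`, `score`, sorted by
#'   decreasing score.
#' @export
mrnet_edges <- function(mi) {
  mi <- as.matrix(mi)
  p <- ncol(mi)
  if (p < 2L || nrow(mi) != p) stop("mi must be a square matrix of >= 2 markers")
  if (is.null(colnames(mi))) {
    colnames(mi) <- rownames(mi) <- paste0("V", seq_len(p))
  }
  nm <- colnames(mi)
  pairs <- which(upper.tri(mi), arr.ind = TRUE)
  if (p < 3L) {
    w <- mi[pairs]
  } else {
    sc <- t(vapply(seq_len(p), function(t) mrmr_scores(mi, t), numeric(p)))
    w <- pmax(sc[cbind(pairs[, 1L], pairs[, 2L])],
              sc[cbind(pairs[, 2L], pairs[, 1L])])
  }
  keep <- w > 0
  edges <- data.frame(marker_a = nm[pairs[keep, 1L]],
                      marker_b = nm[pairs[keep, 2L]],
                      score = w[keep], stringsAsFactors = FALSE)
  swap <- edges$marker_a > edges$marker_b
  tmp <- edges$marker_a[swap]
  edges$marker_a[swap] <- edges$marker_b[swap]
  edges$marker_b[swap] <- tmp
  edges <- edges[order(-edges$score, edges$marker_a, edges$marker_b), ]
  rownames(edges) <- NULL
  edges
}

#' Marker network of the top-d edges
#'
#' Keeps the `d` highest-scoring edges of a ranking (ties at the boundary
#' resolved by lexicographic marker pair, which the ranking already
#' encodes). The conventional budget is one edge per marker
#' (`d = n_markers`): enough to capture the dependence structure that
#' defines a cellular state while discarding noisy edges that would blur
#' the graph distance.
#'
#' @param ranking Edge ranking from [mrnet_edges()].
#' @param d Edge budget (>= 1).
#' @param markers Character vector of the node namespace; defaults to the
#'   markers present in the ranking.
#' @param source Optional list tagging the network's origin
#'   (sample / subpopulation / size).
#' @return An object of class `marker_network` with fields `markers`,
#'   `edges`, `d`, `source`.
#' @export
top_d_network <- function(ranking, d, markers = NULL, source = NULL) {
  if (d < 1L) stop("d must be >= 1")
  if (is.null(markers)) {
    markers <- sort(unique(c(ranking$marker_a, ranking$marker_b)))
  }
  edges <- utils::head(ranking, d)
  structure(list(markers = markers, edges = edges, d = d, source = source),
            class = "marker_network")
}

#' @export
print.marker_network <- function(x, ...) {
  cat(sprintf("marker_network: %d markers, %d/%d edges\n",
              length(x$markers), nrow(x$edges), x$d))
  if (!is.null(x$source)) {
    cat("source:", paste(unlist(x$source), collapse = " / "), "\n")
  }
  invisible(x)
}

edge_keys <- function(g) {
  if (nrow(g$edges) == 0L) character(0) else
    paste(g$edges$marker_a, g$edges$marker_b, sep = "\r")
}

#' Jaccard distance between two marker networks
#'
#' `1 - |shared edges| / |union of edges|`, ignoring edge weights. Zero for
#' identical edge sets, one for disjoint ones. Two empty networks are at
#' distance 0 (with a warning). Because the edge sets come from
#' rank-invariant mutual information, this distance is unaffected by
#' per-sample shifts in marker intensity.
#'
#' @param g1,g2 `marker_network` objects over a shared marker namespace.
#' @return A distance in `[0, 1]`.
#' @export
jaccard_distance <- function(g1, g2) {
  e1 <- edge_keys(g1)
  e2 <- edge_keys(g2)
  union_n <- length(union(e1, e2))
  if (union_n == 0L) {
    warning("both edge sets are empty; distance 0")
    return(0)
  }
  1 - length(intersect(e1, e2)) / union_n
}

#' Hub markers of a network
#'
#' The `h` most connected nodes (degree ties broken lexicographically),
#' used to annotate the cellular state a subpopulation represents: markers
#' central to the dependence structure constrain the state much as hub
#' genes constrain a regulatory network.
#'
#' @param g A `marker_network` with at least one edge.
#' @param h Number of hubs to report (default 3).
#' @return Character vector of marker names, most connected first.
#' @export
hub_markers <- function(g, h = 3L) {
  stopifnot(inherits(g, "marker_network"))
  if (nrow(g$edges) == 0L) stop("network has no edges")
  deg <- table(factor(c(g$edges$marker_a, g$edges$marker_b),
                      levels = sort(g$markers)))
  ord <- order(-as.numeric(deg), names(deg))
  utils::head(names(deg)[ord], h)
}

#' Infer the marker network of one subpopulation
#'
#' Convenience composition for one cluster: mutual-information matrix,
#' MRMR edge ranking, top-d filtering.
#'
#' @param values Event rows of the subpopulation.
#' @param d Edge budget; default one edge per marker.
#' @param bins Passed to [mutual_information_matrix()].
#' @param source Origin tag stored in the network.
#' @return A `marker_network`.
#' @export
subpopulation_network <- function(values, d = ncol(values), bins = NULL,
                                  source = NULL) {
  mi <- mutual_information_matrix(values, bins = bins)
  top_d_network(mrnet_edges(mi), d = d, markers = colnames(mi),
                source = source)
}
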