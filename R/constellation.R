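#' Embed subpopulation centroids in 2-D
#'
#' Barnes-Hut t-SNE of the clade-subpopulation centroids (perplexity 30,
#' 1000 iterations by default), seeded for reproducibility. With fewer
#' than 3 centroids, or a perplexity too large for the number of points,
#' the method falls back to (or auto-reduces towards) what the data
#' supports: below 3 points the first two principal directions are used,
#' and an infeasible perplexity is reduced with a warning.
#'
#' @param centroids Numeric matrix, one subpopulation centroid per row.
#' @param perplexity t-SNE perplexity (default 30).
#' @param iterations t-SNE iterations (default 1000).
#' @param seed Integer seed; fixed seeds give identical layouts.
#' @return Numeric n x 2 coordinate matrix.
#' @export
embed_centroids <- function(centroids, perplexity = 30, iterations = 1000L,
                            seed = 1L) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 3L || floor((n - 1) / 3) < 1L) {
    pc <- stats::prcomp(centroids, center = TRUE, scale. = FALSE)
    coords <- matrix(0, n, 2L)
    take <- seq_len(min(2L, ncol(pc$x)))
    coords[, take] <- pc$x[, take, drop = FALSE]
    colnames(coords) <- c("x", "y")
    return(coords)
  }
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    warning("perplexity ", perplexity, " too large for ", n,
            " centroids; reduced to ", max_perp)
    perplexity <- max_perp
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(centroids, dims = 2L, perplexity = perplexity,
                      max_iter = iterations, theta = 0.5,
                      check_duplicates = FALSE, pca = FALSE, verbose = FALSE)
  coords <- fit$Y
  colnames(coords) <- c("x", "y")
  coords
}

#' Constellation connections within clades
#'
#' Within every clade of two or more members, connects each member to its
#' nearest same-clade neighbour on the 2-D plane; undirected duplicates are
#' removed. Singleton clades contribute no edges.
#'
#' @param coords n x 2 coordinate matrix from [embed_centroids()].
#' @param clades Integer/character clade id per row of `coords`.
#' @return Data frame `from`, `to` (row indices, `from < to`).
#' @export
constellation_edges <- function(coords, clades) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(clades))
  from <- integer(0); to <- integer(0)
  for (cl in unique(clades[!is.na(clades)])) {
    members <- which(!is.na(clades) & clades == cl)
    if (length(members) < 2L) next
    D <- as.matrix(stats::dist(coords[members, , drop = FALSE]))
    diag(D) <- Inf
    for (a in seq_along(members)) {
      b <- which.min(D[a, ])
      e <- sort(c(members[a], members[b]))
      from <- c(from, e[1L]); to <- c(to, e[2L])
    }
  }
  unique(data.frame(from = from, to = to))
}

#' Prune distant clade members on the constellation plane
#'
#' Members far from their clade's 2-D centre are split off into fresh
#' clades. For clades of three or more members, the threshold is
#' `multiplier` times the clade's average member distance to its 2-D
#' centroid. For two-member clades a global rule applies: the mean
#' separation over all two-member clades is computed, and pairs separated
#' by more than `multiplier` times that mean are dissolved. A researcher-
#' controlled `global_cap` (in embedding units) bounds every threshold from
#' above; it is disabled (`Inf`) by default. Pruning only ever splits
#' clades; the number of subpopulations is conserved.
#'
#' @param coords n x 2 coordinate matrix.
#' @param clades Clade id per row.
#' @param multiplier Threshold constant multiplier (default 2).
#' @param global_cap Absolute upper bound on thresholds (default `Inf`).
#' @return `list(clades, log)`: updated clade ids and a data frame of
#'   pruned members (`index`, `old_clade`, `new_clade`, `distance`,
#'   `threshold`).
#' @export
prune_clades <- function(coords, clades, multiplier = 2, global_cap = Inf) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(clades))
  clades <- as.integer(factor(clades, levels = unique(clades)))
  out <- clades
  next_id <- max(clades, na.rm = TRUE)
  log_rows <- list()

  prune <- function(idx, old, dist, thr) {
    next_id <<- next_id + 1L
    out[idx] <<- next_id
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      index = idx, old_clade = old, new_clade = next_id,
      distance = dist, threshold = thr)
  }

  sizes <- table(clades)
  big <- as.integer(names(sizes)[sizes >= 3L])
  twos <- as.integer(names(sizes)[sizes == 2L])

  for (cl in big) {
    members <- which(clades == cl)
    centre <- colMeans(coords[members, , drop = FALSE])
    dists <- sqrt(colSums((t(coords[members, , drop = FALSE]) - centre)^2))
    thr <- min(multiplier * mean(dists), global_cap)
    for (i in which(dists > thr)) {
      prune(members[i], cl, dists[i], thr)
    }
  }

  if (length(twos) > 0L) {
    seps <- vapply(twos, function(cl) {
      members <- which(clades == cl)
      sqrt(sum((coords[members[1L], ] - coords[members[2L], ])^2))
    }, numeric(1L))
    thr <- min(multiplier * mean(seps), global_cap)
    for (i in which(seps > thr)) {
      members <- which(clades == twos[i])
      # the pair is dissolved: the later member moves to a fresh clade
      prune(members[2L], twos[i], seps[i], thr)
    }
  }

  log <- if (length(log_rows) == 0L) {
    data.frame(index = integer(0), old_clade = integer(0),
               new_clade = integer(0), distance = numeric(0),
               threshold = numeric(0))
  } else do.call(rbind, log_rows)
  list(clades = out, log = log)
}

#' Constellation layout of a clade assignment
#'
#' Composes [embed_centroids()], [prune_clades()] and
#' [constellation_edges()] for the final (sample, subpopulation) units of a
#' [man()] result, and classifies each clade as sample-specific (drawn
#' grey) or multi-sample (coloured).
#'
#' @param x A `clade_assignment`.
#' @param samples The sample list the assignment was computed from.
#' @param multiplier,global_cap Passed to [prune_clades()].
#' @param perplexity,iterations,seed Passed to [embed_centroids()].
#' @return A data frame layout (sample, subpop, clade, x, y, color_class)
#'   with the edge list and pruning log as attributes.
#' @export
constellation_layout <- function(x, samples, multiplier = 2,
                                 global_cap = Inf, perplexity = 30,
                                 iterations = 1000L, seed = 1L) {
  stopifnot(inherits(x, "clade_assignment"))
  tab <- x$assignment[!is.na(x$assignment$clade), , drop = FALSE]
  centroids <- t(vapply(seq_len(nrow(tab)), function(i) {
    s <- tab$sample[i]
    labs <- x$event_subpops[[s]]
    colMeans(samples[[s]]$events$values[labs == tab$subpop[i], , drop = FALSE])
  }, numeric(ncol(samples[[1L]]$events$values))))
  coords <- embed_centroids(centroids, perplexity = perplexity,
                            iterations = iterations, seed = seed)
  pruned <- prune_clades(coords, tab$clade, multiplier = multiplier,
                         global_cap = global_cap)
  clade <- pruned$clades
  multi <- tapply(tab$sample, clade, function(s) length(unique(s)) > 1L)
  layout <- data.frame(sample = tab$sample, subpop = tab$subpop,
                       clade = clade, x = coords[, 1L], y = coords[, 2L],
                       color_class = ifelse(multi[as.character(clade)],
                                            "multi-sample", "sample-specific"))
  attr(layout, "edges") <- constellation_edges(coords, clade)
  attr(layout, "pruning") <- pruned$log
  layout
}
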