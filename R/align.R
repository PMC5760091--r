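#' Dendrogram over subpopulation networks
#'
#' Agglomerative clustering of a pool of subpopulation marker networks
#' under the pairwise [jaccard_distance()]. Deterministic given the inputs.
#'
#' @param networks List of >= 2 `marker_network` objects.
#' @param linkage Agglomeration criterion: `"average"` (default),
#'   `"single"` or `"complete"`.
#' @param sample_of Optional character vector naming each network's
#'   sample. When given, exactly tied distances are broken in favour of
#'   cross-sample links: a vanishing penalty (1e-9) is added to
#'   same-sample pairs, so that among equally similar networks the
#'   dendrogram links subpopulations across samples first — which is the
#'   purpose of the alignment.
#' @return An [stats::hclust] tree (or a degenerate single-leaf stub when
#'   only one network is supplied).
#' @export
network_dendrogram <- function(networks, linkage = "average",
                               sample_of = NULL) {
  linkage <- match.arg(linkage, c("average", "single", "complete"))
  m <- length(networks)
  if (m < 1L) stop("need at least one network")
  if (m == 1L) {
    return(structure(list(n = 1L, labels = names(networks)),
                     class = "single_leaf_tree"))
  }
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      d <- jaccard_distance(networks[[i]], networks[[j]])
      if (!is.null(sample_of) && sample_of[i] == sample_of[j]) {
        d <- d + 1e-9
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  dimnames(D) <- list(names(networks), names(networks))
  stats::hclust(stats::as.dist(D), method = linkage)
}

#' Cut a dendrogram into k clades
#'
#' @param tree An [stats::hclust] tree (or the single-leaf stub from
#'   [network_dendrogram()]).
#' @param k Number of clades, `1 <= k <=` number of leaves.
#' @return Integer clade ids, one per leaf, numbered in cut order.
#' @export
cut_to_clades <- function(tree, k) {
  if (inherits(tree, "single_leaf_tree")) {
    if (k != 1L) stop("k out of range: tree has a single leaf")
    out <- 1L
    names(out) <- tree$labels
    return(out)
  }
  n_leaves <- length(tree$order)
  if (k < 1L || k > n_leaves) {
    stop("k out of range: must be in [1, ", n_leaves, "]")
  }
  stats::cutree(tree, k = k)
}

#' Merge same-sample subpopulations that share a clade
#'
#' Subpopulations from one sample falling into the same clade are unioned
#' into a single subpopulation (relabelled to the lowest involved
#' subpopulation id); subpopulations from different samples are never
#' merged. Event counts per sample are conserved.
#'
#' @param assignment Data frame with columns `sample`, `subpop`, `clade`
#'   (NA clades are left untouched).
#' @param labelings Named list of per-sample integer label vectors (values
#'   are subpopulation ids).
#' @return `list(assignment, labelings)` with merged subpopulations.
#' @export
merge_within_sample <- function(assignment, labelings) {
  stopifnot(all(c("sample", "subpop", "clade") %in% names(assignment)))
  drop <- logical(nrow(assignment))
  for (s in unique(assignment$sample)) {
    rows <- which(assignment$sample == s & !is.na(assignment$clade))
    if (length(rows) < 2L) next
    for (cl in unique(assignment$clade[rows])) {
      grp <- rows[assignment$clade[rows] == cl]
      if (length(grp) < 2L) next
      target <- min(assignment$subpop[grp])
      victims <- setdiff(assignment$subpop[grp], target)
      labelings[[s]][labelings[[s]] %in% victims] <- target
      keep_row <- grp[assignment$subpop[grp] == target]
      if ("size" %in% names(assignment)) {
        assignment$size[keep_row] <- sum(assignment$size[grp])
      }
      drop[setdiff(grp, keep_row)] <- TRUE
    }
  }
  assignment <- assignment[!drop, , drop = FALSE]
  rownames(assignment) <- NULL
  list(assignment = assignment, labelings = labelings)
}

#' Attach small subpopulations to clades by expression
#'
#' Subpopulations too small for stable network inference join the clade
#' whose (large, aligned) member centroid is nearest in Euclidean marker
#' space — unless a within-sample expression grouping of subpopulation
#' centroids (hierarchical, cut into `expression_groups` groups) isolates
#' them in a group without any large member, in which case each such group
#' becomes one sample-specific minor clade (so at most
#' `expression_groups - 1` minor clades can arise per sample).
#'
#' @param centroids Numeric matrix of subpopulation centroids, one row per
#'   unit.
#' @param sample_of Character vector: the sample of each unit.
#' @param clade_of Integer vector: clade ids for large/aligned units, `NA`
#'   for the small units to be rescued.
#' @param k Number of network clades already assigned (minor clades are
#'   numbered from `k + 1`).
#' @param expression_groups Within-sample expression clusters (default 5).
#' @param linkage Linkage for the within-sample grouping (default
#'   `"average"`, matching the main dendrogram).
#' @param reach Distance multiplier defining "close enough" for groups
#'   without an aligned member: such a group joins its globally nearest
#'   aligned subpopulation only if that one lies within `reach` times the
#'   median nearest-neighbour distance among aligned subpopulations;
#'   otherwise the group is genuinely distant and becomes sample-specific.
#' @return `list(clade, kind)`: completed clade ids and a per-unit kind
#'   (`"aligned"` or `"minor"`).
#' @export
rescue_small_subpopulations <- function(centroids, sample_of, clade_of, k,
                                        expression_groups = 5L,
                                        linkage = "average", reach = 3) {
  centroids <- as.matrix(centroids)
  n_units <- nrow(centroids)
  stopifnot(length(sample_of) == n_units, length(clade_of) == n_units)
  clade <- clade_of
  kind <- ifelse(is.na(clade_of), NA_character_, "aligned")
  large_idx <- which(!is.na(clade_of))
  if (length(large_idx) == 0L) {
    warning("no large subpopulations: every small one becomes sample-specific")
  }
  next_minor <- k

  # spacing of the aligned landscape: how far aligned subpopulations
  # typically sit from their nearest aligned neighbour
  spacing <- Inf
  if (length(large_idx) >= 2L) {
    DL <- as.matrix(stats::dist(centroids[large_idx, , drop = FALSE]))
    diag(DL) <- Inf
    spacing <- stats::median(apply(DL, 1L, min))
  }

  for (s in unique(sample_of)) {
    in_s <- which(sample_of == s)
    small_s <- in_s[is.na(clade_of[in_s])]
    if (length(small_s) == 0L) next
    g <- min(expression_groups, length(in_s))
    groups <- if (length(in_s) == 1L) 1L else
      stats::cutree(stats::hclust(stats::dist(centroids[in_s, , drop = FALSE]),
                                  method = linkage), k = g)
    names(groups) <- as.character(in_s)
    for (u in small_s) {
      mates <- in_s[groups == groups[[as.character(u)]]]
      anchors <- mates[!is.na(clade_of[mates])]
      if (length(anchors) > 0L) {
        # join the nearest aligned subpopulation of the same expression
        # group: small fragments re-attach to the large subpopulation they
        # were split from, rather than chasing drifting centroids globally
        d2 <- colSums((t(centroids[anchors, , drop = FALSE]) -
                         centroids[u, ])^2)
        clade[u] <- clade_of[anchors[which.min(d2)]]
        kind[u] <- "aligned"
      }
    }
    # groups without any aligned member join the globally nearest aligned
    # subpopulation when one is within reach; genuinely distant groups
    # become sample-specific minor clades, one clade per group
    for (gid in sort(unique(groups))) {
      members <- in_s[groups == gid]
      pending <- members[is.na(clade[members])]
      if (length(pending) == 0L) next
      rescued <- FALSE
      if (length(large_idx) > 0L && is.finite(spacing)) {
        centre <- colMeans(centroids[pending, , drop = FALSE])
        d2 <- colSums((t(centroids[large_idx, , drop = FALSE]) - centre)^2)
        if (sqrt(min(d2)) <= reach * spacing) {
          clade[pending] <- clade_of[large_idx[which.min(d2)]]
          kind[pending] <- "aligned"
          rescued <- TRUE
        }
      }
      if (!rescued) {
        next_minor <- next_minor + 1L
        clade[pending] <- next_minor
        kind[pending] <- "minor"
      }
    }
  }
  list(clade = clade, kind = kind)
}

# Build the flat unit table (one row per (sample, subpopulation)) that the
# alignment steps operate on.
subpop_units <- function(samples) {
  stopifnot(length(samples) >= 1L, !is.null(names(samples)))
  rows <- list()
  centroids <- list()
  for (s in names(samples)) {
    lab <- samples[[s]]$labeling
    stopifnot(inherits(samples[[s]]$events, "event_matrix"),
              inherits(lab, "cluster_labeling"))
    for (j in seq_along(lab$summaries)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, subpop = j, size = lab$summaries[[j]]$size,
        stringsAsFactors = FALSE)
      centroids[[length(centroids) + 1L]] <- lab$summaries[[j]]$mean
    }
  }
  list(table = do.call(rbind, rows), centroids = do.call(rbind, centroids))
}

#' Multiple alignment of networks across samples
#'
#' Links the subpopulations discovered per sample (by [pac()]) into
#' dataset-level clades. In the default `"sequential"` mode, subpopulations
#' with more than `large_threshold` events — the ones whose covariance, and
#' hence mutual-information network, is stable — are aligned by
#' agglomerative clustering of their pairwise network Jaccard distances;
#' the dendrogram is cut into `k` clades; same-sample subpopulations
#' sharing a clade are merged (consolidating any over-partitioning from the
#' clustering step); the remaining small subpopulations are attached to the
#' nearest clade by mean marker profile or spun off as sample-specific
#' minor clades ([rescue_small_subpopulations()]); finally clades with
#' fewer than `discard_threshold` events are discarded. `"network"` mode
#' aligns every subpopulation's network regardless of size, and `"means"`
#' mode replaces the network distance with the Euclidean distance between
#' subpopulation centroids — both provided for comparison, since mean
#' shifts across batches defeat centroid alignment while noisy small-cluster
#' networks defeat pure network alignment.
#'
#' @param samples Named list; each element is
#'   `list(events = event_matrix, labeling = cluster_labeling)`.
#' @param k Number of clades to cut the dendrogram into.
#' @param mode `"sequential"` (default), `"network"` or `"means"`.
#' @param large_threshold Events above which a subpopulation's network is
#'   considered stable (default 1000).
#' @param discard_threshold Minimum clade size in events (default 100).
#' @param expression_groups Within-sample expression clusters used by the
#'   rescue step (default 5).
#' @param linkage Agglomeration criterion for all dendrograms.
#' @param d Edge budget per network; default one edge per marker.
#' @param bins Bin count for mutual information; default `n^(1/3)`.
#' @param reach Proximity multiplier for the rescue step; see
#'   [rescue_small_subpopulations()].
#' @return An object of class `clade_assignment`: `assignment` (one row
#'   per final (sample, subpopulation) unit: sample, subpop, clade, size,
#'   kind), `event_clades` / `event_subpops` (per-sample per-event vectors,
#'   `NA` for discarded events), `proportions` (clade x sample matrix),
#'   `tree`, `networks`, `config`.
#' @export
man <- function(samples, k, mode = c("sequential", "network", "means"),
                large_threshold = 1000L, discard_threshold = 100L,
                expression_groups = 5L, linkage = "average",
                d = NULL, bins = NULL, reach = 3) {
  mode <- match.arg(mode)
  if (k < 1L) stop("k must be >= 1")
  units <- subpop_units(samples)
  tab <- units$table
  centroids <- units$centroids
  n_units <- nrow(tab)
  n_markers <- ncol(samples[[1L]]$events$values)
  if (is.null(d)) d <- n_markers

  net_for <- function(i) {
    s <- tab$sample[i]
    lab <- samples[[s]]$labeling$labels
    subpopulation_network(
      samples[[s]]$events$values[lab == tab$subpop[i], , drop = FALSE],
      d = d, bins = bins,
      source = list(sample_id = s, subpopulation = tab$subpop[i],
                    size = tab$size[i]))
  }

  tree <- NULL
  networks <- NULL
  clade <- rep(NA_integer_, n_units)
  kind <- rep(NA_character_, n_units)

  if (mode == "means") {
    tree <- stats::hclust(stats::dist(centroids), method = linkage)
    clade <- unname(cut_to_clades(tree, k))
    kind <- rep("aligned", n_units)
  } else {
    min_mi <- 50L
    idx <- if (mode == "network") which(tab$size >= min_mi) else
      which(tab$size > large_threshold)
    if (mode == "network" && length(idx) < n_units) {
      warning("subpopulations below ", min_mi,
              " events cannot support network inference and are left",
              " unaligned")
    }
    if (length(idx) < 2L) {
      if (length(idx) <= 0L && mode == "sequential") {
        res <- rescue_small_subpopulations(centroids, tab$sample, clade,
                                           k = 0L,
                                           expression_groups = expression_groups,
                                           linkage = linkage, reach = reach)
        clade <- res$clade
        kind <- res$kind
      } else stop("need at least 2 subpopulations eligible for network alignment")
    } else {
      networks <- lapply(idx, net_for)
      names(networks) <- paste(tab$sample[idx], tab$subpop[idx], sep = ".")
      tree <- network_dendrogram(networks, linkage = linkage,
                                 sample_of = tab$sample[idx])
      clade[idx] <- unname(cut_to_clades(tree, k))
      kind[idx] <- "aligned"
      if (mode == "sequential" && any(is.na(clade))) {
        # merge aligned units within sample first so the rescue sees
        # consolidated clade members
        merged_centroid <- centroids
        res <- rescue_small_subpopulations(merged_centroid, tab$sample, clade,
                                           k = k,
                                           expression_groups = expression_groups,
                                           linkage = linkage, reach = reach)
        clade <- res$clade
        kind <- res$kind
      }
    }
  }

  tab$clade <- clade
  tab$kind <- kind

  # union same-sample co-clade subpopulations into one (merged) unit
  lab_list <- lapply(samples, function(x) x$labeling$labels)
  merged <- merge_within_sample(tab[, c("sample", "subpop", "clade", "size")],
                                lab_list)
  kind_keep <- tab$kind[match(paste(merged$assignment$sample,
                                    merged$assignment$subpop),
                              paste(tab$sample, tab$subpop))]
  tab <- merged$assignment
  tab$kind <- kind_keep
  lab_list <- merged$labelings

  # discard clades that end up with too few events
  clade_sizes <- tapply(tab$size, tab$clade, sum)
  bad <- as.integer(names(clade_sizes)[clade_sizes < discard_threshold])
  if (length(bad) > 0L) {
    sel <- tab$clade %in% bad
    tab$clade[sel] <- NA_integer_
    tab$kind[sel] <- "discarded"
  }

  dup <- stats::na.omit(tab[, c("sample", "clade")])
  if (anyDuplicated(dup)) {
    stop("internal error: a clade holds two unmerged subpopulations of one sample")
  }

  event_clades <- list()
  event_subpops <- list()
  for (s in names(samples)) {
    labs <- lab_list[[s]]
    rows <- tab[tab$sample == s, , drop = FALSE]
    cl <- rows$clade[match(labs, rows$subpop)]
    event_clades[[s]] <- cl
    event_subpops[[s]] <- labs
  }

  out <- structure(list(assignment = tab, event_clades = event_clades,
                        event_subpops = event_subpops,
                        tree = tree, networks = networks,
                        config = list(k = k, mode = mode,
                                      large_threshold = large_threshold,
                                      discard_threshold = discard_threshold,
                                      expression_groups = expression_groups,
                                      linkage = linkage, d = d, bins = bins)),
                   class = "clade_assignment")
  out$proportions <- clade_proportions(out)
  out
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("clade_assignment (%s): %d units, %d clades over %d samples\n",
              x$config$mode, nrow(x$assignment),
              length(unique(stats::na.omit(x$assignment$clade))),
              length(x$event_clades)))
  print(x$assignment)
  invisible(x)
}

#' Clade x sample proportion matrix
#'
#' Entry (clade, sample) is the fraction of the sample's retained (i.e.
#' non-discarded) events that fall in the clade; columns therefore sum
#' to 1 for samples with nothing discarded and to at most 1 otherwise.
#' A sample-specific clade shows a single non-zero column.
#'
#' @param x A `clade_assignment` from [man()].
#' @return Numeric matrix, rows labelled by clade id.
#' @export
clade_proportions <- function(x) {
  stopifnot(inherits(x, "clade_assignment"))
  clades <- sort(unique(stats::na.omit(x$assignment$clade)))
  samples <- names(x$event_clades)
  m <- matrix(0, length(clades), length(samples),
              dimnames = list(as.character(clades), samples))
  for (s in samples) {
    cl <- x$event_clades[[s]]
    n_retained <- sum(!is.na(cl))
    if (n_retained == 0L) next
    counts <- table(factor(cl, levels = clades))
    m[, s] <- as.numeric(counts) / n_retained
  }
  m
}

#' Cross-sample pairing recovery score
#'
#' Scores how well a clade assignment recovers the true cross-sample
#' linkage of subpopulations. The events of each (sample, true class)
#' block vote inside every clade: a clade links the blocks that form the
#' within-sample majority of its member events in each sample it spans.
#' Blocks connected through shared clades form the recovered linkage
#' components, which are compared with the partition by true class via
#' the adjusted Rand index. A score of 1 means every true subpopulation
#' is linked across all samples and no clade links different true
#' subpopulations.
#'
#' @param x A `clade_assignment` from [man()].
#' @param truth Named list (same sample names) of per-event true labels.
#' @return Adjusted Rand index of the recovered block linkage.
#' @export
pairing_ari <- function(x, truth) {
  stopifnot(inherits(x, "clade_assignment"),
            setequal(names(truth), names(x$event_clades)))
  blocks <- character(0)
  for (s in names(x$event_clades)) {
    blocks <- c(blocks, paste(s, sort(unique(truth[[s]])), sep = "\r"))
  }
  comp <- seq_along(blocks)          # union-find over blocks
  names(comp) <- blocks
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  clades <- sort(unique(stats::na.omit(unlist(x$event_clades))))
  for (cl in clades) {
    linked <- character(0)
    for (s in names(x$event_clades)) {
      sel <- which(x$event_clades[[s]] == cl)
      if (length(sel) == 0L) next
      tab <- table(truth[[s]][sel])
      major <- names(tab)[which.max(tab)]
      linked <- c(linked, paste(s, major, sep = "\r"))
    }
    if (length(linked) > 1L) {
      roots <- vapply(match(linked, blocks), find, integer(1L))
      comp[roots] <- roots[1L]
    }
  }
  membership <- vapply(seq_along(blocks), find, integer(1L))
  block_class <- sub("^.*\r", "", blocks)
  adjusted_rand(block_class, membership)
}

#' Does the assignment track every true subpopulation?
#'
#' Boolean summary of a scenario run: `TRUE` when the recovered
#' cross-sample linkage is exact ([pairing_ari()] equal to 1) and every
#' per-sample cell of every clade is composed essentially of the clade's
#' own subpopulation. The purity floor separates benign assignment noise
#' at cluster boundaries (a few percent of events) from a structurally
#' misplaced fragment, which contaminates a cell by the fragment's whole
#' share (typically 20% or more).
#'
#' @param x A `clade_assignment` from [man()].
#' @param truth Named list of per-event true labels.
#' @param min_purity Minimum within-cell share of the clade's majority
#'   class (default 0.85).
#' @return `TRUE` or `FALSE`.
#' @export
tracks_subpopulations <- function(x, truth, min_purity = 0.85) {
  if (pairing_ari(x, truth) != 1) return(FALSE)
  for (cl in sort(unique(stats::na.omit(unlist(x$event_clades))))) {
    counts <- list()
    for (s in names(x$event_clades)) {
      sel <- which(x$event_clades[[s]] == cl)
      if (length(sel) == 0L) next
      counts[[s]] <- table(factor(truth[[s]][sel],
                                  levels = sort(unique(unlist(truth)))))
    }
    total <- Reduce(`+`, counts)
    major <- which.max(total)
    purity <- vapply(counts, function(tab) tab[major] / sum(tab), numeric(1L))
    if (any(purity < min_purity)) return(FALSE)
  }
  TRUE
}

#' Elbow-point analysis of the number of clades
#'
#' Runs the alignment for every `k` in `k_range`, computes the average
#' within-clade error (mean squared Euclidean distance of events to their
#' sample-level clade centroid, averaged over samples), smooths the curve
#' with local regression and suggests the `k` of maximum curvature
#' (largest second difference of the smoothed curve). The researcher makes
#' the final call; when the curve has no pronounced knee the suggestion is
#' flagged as low-confidence.
#'
#' @param samples As in [man()].
#' @param k_range Integer vector of candidate clade counts.
#' @param span Local-regression span (default 0.75).
#' @param ... Further arguments passed to [man()].
#' @return A list with `k`, `error`, `smoothed`, `suggested_k`,
#'   `confident`.
#' @export
elbow_curve <- function(samples, k_range, span = 0.75, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  errors <- vapply(k_range, function(k) {
    a <- man(samples, k = k, ...)
    per_sample <- vapply(names(samples), function(s) {
      cl <- a$event_clades[[s]]
      vals <- samples[[s]]$events$values
      keep <- !is.na(cl)
      if (!any(keep)) return(NA_real_)
      v <- vals[keep, , drop = FALSE]
      f <- factor(cl[keep])
      centers <- rowsum(v, f) / as.vector(table(f))
      mean(rowSums((v - centers[as.integer(f), , drop = FALSE])^2))
    }, numeric(1L))
    mean(per_sample, na.rm = TRUE)
  }, numeric(1L))

  knee <- elbow_knee(k_range, errors, span = span)
  list(k = k_range, error = errors, smoothed = knee$smoothed,
       suggested_k = knee$suggested_k, confident = knee$confident)
}

#' Locate the knee of a within-clade error curve
#'
#' Smooths the error-versus-k curve with local regression and suggests the
#' `k` of maximum curvature (largest second difference of the smoothed
#' values). A curve without a pronounced knee — e.g. a straight line —
#' yields a low-confidence suggestion.
#'
#' @param k Integer vector of clade counts (sorted).
#' @param error Average within-clade errors at each `k`.
#' @param span Local-regression span (default 0.75); curves shorter than 7
#'   points are used unsmoothed.
#' @return A list with `smoothed`, `suggested_k` and `confident`.
#' @export
elbow_knee <- function(k, error, span = 0.75) {
  stopifnot(length(k) == length(error))
  smoothed <- error
  if (length(k) >= 7L) {
    fit <- stats::loess(error ~ k, span = span, degree = 2L,
                        surface = "direct")
    smoothed <- as.numeric(stats::predict(fit, k))
  }
  suggested <- NA_integer_
  confident <- FALSE
  if (length(k) >= 3L) {
    d2 <- diff(smoothed, differences = 2L)
    i <- which.max(d2)
    suggested <- k[i + 1L]
    spread <- diff(range(smoothed))
    confident <- is.finite(spread) && spread > 0 && max(d2) > 0.01 * spread
  }
  list(smoothed = smoothed, suggested_k = suggested, confident = confident)
}
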