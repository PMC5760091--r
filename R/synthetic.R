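#' Specification of a Gaussian-mixture benchmark
#'
#' The benchmark family is indexed by a four-part name `a_b_c_d`: `a`
#' marker dimensions, `b` mixture components (subpopulations), hypercube
#' edge length `c` for the component means, and `d` events (the suffixes
#' `k`/`M` denote thousands/millions, so `40_10_20_100k` is 40 dimensions,
#' 10 components, edge 20, 100,000 events).
#'
#' @param name Optional benchmark name `"a_b_c_d"`; parsed when given.
#' @param a,b,c,d Dimensions, components, hypercube edge, events.
#' @param weights Mixing weights (default equal), recycled to length `b`
#'   and normalised.
#' @param seed Integer seed; generation is a pure function of it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(name = NULL, a = NULL, b = NULL, c = NULL, d = NULL,
                     weights = NULL, seed = 1L) {
  if (!is.null(name)) {
    parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
    if (length(parts) != 4L) stop("benchmark name must look like 'a_b_c_d'")
    num <- function(x) {
      mult <- 1
      if (grepl("k$", x, ignore.case = TRUE)) mult <- 1e3
      if (grepl("m$", x, ignore.case = TRUE)) mult <- 1e6
      as.numeric(sub("[kKmM]$", "", x)) * mult
    }
    a <- num(parts[1L]); b <- num(parts[2L])
    c <- num(parts[3L]); d <- num(parts[4L])
  }
  if (any(vapply(list(a, b, c, d), is.null, logical(1L)))) {
    stop("either a name or all of a, b, c, d must be given")
  }
  a <- as.integer(a); b <- as.integer(b); d <- as.integer(d)
  if (a < 2L) stop("need a >= 2 dimensions")
  if (b < 1L) stop("need b >= 1 components")
  if (c <= 0) stop("need edge length c > 0")
  if (d < b) stop("need at least one event per component")
  if (is.null(weights)) weights <- rep(1, b)
  weights <- rep_len(weights, b)
  weights <- weights / sum(weights)
  structure(list(a = a, b = b, c = c, d = d, weights = weights,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("sim_spec %s (seed %d)\n", format(x), x$seed))
  invisible(x)
}

#' @export
format.sim_spec <- function(x, ...) {
  d_txt <- if (x$d %% 1000L == 0L) paste0(x$d / 1000L, "k") else
    as.character(x$d)
  sprintf("%d_%d_%g_%s", x$a, x$b, x$c, d_txt)
}

#' Sample a Gaussian-mixture benchmark
#'
#' Component means are drawn uniformly from the hypercube `[0, c]^a`;
#' component covariances are `A A'` with `A` an `a x a` matrix of standard
#' normal entries (a Wishart draw, giving realistically elongated,
#' correlated clusters); events are assigned to components by the mixing
#' weights. The generating means and covariances are returned alongside
#' the data so that distributional checks need no re-derivation. Fully
#' reproducible from the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @return A list with `events` (an [event_matrix()], already on the
#'   analysis scale), `labels` (component of each event, `1..b`),
#'   `means` (b x a), `covariances` (list of b matrices) and `spec`.
#' @export
gmm_sample <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  means <- matrix(stats::runif(spec$b * spec$a, 0, spec$c), spec$b, spec$a)
  covs <- lapply(seq_len(spec$b), function(i) {
    A <- matrix(stats::rnorm(spec$a * spec$a), spec$a, spec$a)
    A %*% t(A)
  })
  labels <- sample.int(spec$b, spec$d, replace = TRUE, prob = spec$weights)
  values <- matrix(0, spec$d, spec$a)
  for (i in seq_len(spec$b)) {
    sel <- labels == i
    n_i <- sum(sel)
    if (n_i == 0L) next
    z <- matrix(stats::rnorm(n_i * spec$a), n_i, spec$a)
    values[sel, ] <- z %*% chol(covs[[i]]) +
      matrix(means[i, ], n_i, spec$a, byrow = TRUE)
  }
  colnames(values) <- paste0("V", seq_len(spec$a))
  list(events = event_matrix(values, sample_id = format(spec),
                             transformed = TRUE),
       labels = labels, means = means, covariances = covs, spec = spec)
}

# Unit-variance covariance of a Gaussian graphical model: the precision
# matrix carries -w on the requested edges, is inverted and rescaled to
# unit marginal variances. Positive definite whenever the precision is.
ggm_cov <- function(edges, w) {
  p <- max(unlist(edges))
  omega <- diag(p)
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    omega[e[1L], e[2L]] <- omega[e[2L], e[1L]] <- -w[i]
  }
  S <- solve(omega)
  D <- diag(1 / sqrt(diag(S)))
  D %*% S %*% D
}

#' Scenario subpopulation covariance presets
#'
#' The fixed dependence structures of the two subpopulations used by
#' [batch_scenario()] and [dynamic_scenario()]. Both share a strong
#' two-link backbone (V1-V2-V3) — related cellular states share their core
#' dependencies — while identity is carried by three weaker, disjoint
#' peripheral links. Large subpopulations recover the peripheral links
#' reliably; small fragments lose them, which is exactly the
#' noisy-network regime that motivates size-thresholded alignment.
#'
#' @return A list of two unit-variance 5 x 5 covariance matrices, `A` and
#'   `B`.
#' @export
scenario_covariances <- function() {
  backbone <- 0.42
  peripheral <- 0.33
  w <- c(backbone, backbone, peripheral, peripheral, peripheral)
  list(
    A = ggm_cov(list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(1L, 3L)), w),
    B = ggm_cov(list(c(1L, 2L), c(2L, 3L), c(3L, 5L), c(1L, 4L), c(1L, 5L)), w)
  )
}

scenario_sample <- function(n_per_subpop, mean_a, mean_b, covs, sample_id) {
  n <- 2L * n_per_subpop
  labels <- rep(c(1L, 2L), each = n_per_subpop)
  za <- matrix(stats::rnorm(n_per_subpop * 5L), n_per_subpop, 5L)
  zb <- matrix(stats::rnorm(n_per_subpop * 5L), n_per_subpop, 5L)
  values <- rbind(
    za %*% chol(covs$A) + matrix(mean_a, n_per_subpop, 5L, byrow = TRUE),
    zb %*% chol(covs$B) + matrix(mean_b, n_per_subpop, 5L, byrow = TRUE))
  perm <- sample.int(n)   # interleave so event order carries no label hint
  colnames(values) <- paste0("V", 1:5)
  list(events = event_matrix(values[perm, ], sample_id = sample_id,
                             transformed = TRUE),
       labels = labels[perm])
}

#' Two-sample batch-effect scenario
#'
#' Five-dimensional data with two subpopulations per sample measured on
#' two instruments: sample 2's mean marker levels are shifted up by
#' `shift` on the two informative dimensions (V1, V2) relative to sample 1,
#' emulating a more sensitive instrument. With the default geometry the
#' right subpopulation of sample 1 sits exactly on top of the left
#' subpopulation of sample 2, so pooled clustering cannot distinguish
#' them — while each subpopulation keeps its own fixed covariance (and
#' hence marker-network) structure across both samples. Truth labels
#' carry cross-sample identity (1 = left/low subpopulation, 2 = right).
#'
#' @param n_per_subpop Events per subpopulation per sample (>= 100;
#'   default 10000).
#' @param shift Batch shift on the informative dimensions (default 5, the
#'   within-sample separation, producing the overlap).
#' @param seed Integer seed.
#' @return A list with `samples` (named list of two
#'   `list(events, labels)`), `truth` (per-sample true label vectors),
#'   `means` and `covariances`.
#' @export
batch_scenario <- function(n_per_subpop = 10000L, shift = 5, seed = 1L) {
  if (n_per_subpop < 100L) stop("n_per_subpop must be >= 100")
  set.seed(seed)
  covs <- scenario_covariances()
  base_a <- c(1, 1, 0, 0, 0)
  base_b <- c(6, 6, 0, 0, 0)
  sh <- c(shift, shift, 0, 0, 0)
  s1 <- scenario_sample(n_per_subpop, base_a, base_b, covs, "instrument1")
  s2 <- scenario_sample(n_per_subpop, base_a + sh, base_b + sh, covs,
                        "instrument2")
  list(samples = list(instrument1 = s1, instrument2 = s2),
       truth = list(instrument1 = s1$labels, instrument2 = s2$labels),
       means = list(instrument1 = rbind(base_a, base_b),
                    instrument2 = rbind(base_a + sh, base_b + sh)),
       covariances = covs)
}

#' Five-sample dynamic (perturbation time-course) scenario
#'
#' Five-dimensional data with two subpopulations whose mean expression
#' profiles nearly converge over the time course without ever meeting:
#' subpopulation 1 drifts upward along the informative dimensions (V1, V2)
#' while the gap to subpopulation 2 shrinks strictly from sample to
#' sample. Covariances are fixed over time (the default structures of
#' [batch_scenario()]), so network structure — unlike mean position — keeps
#' identifying each subpopulation. By design the late positions of
#' subpopulation 1 coincide with the early positions of subpopulation 2,
#' which is what defeats centroid-based alignment.
#'
#' @param n_per_subpop Events per subpopulation per sample (default 2600,
#'   sized so that moderate over-partitioning fragments a subpopulation
#'   into pieces whose covariance — and hence network — is unstable).
#' @param n_samples Number of time points (>= 2, default 5; gaps are
#'   interpolated for other values).
#' @param seed Integer seed.
#' @return As [batch_scenario()], with one entry per time point `t1..tn`;
#'   `gaps` records the per-dimension mean gap at each time point.
#' @export
dynamic_scenario <- function(n_per_subpop = 2600L, n_samples = 5L,
                             seed = 1L) {
  if (n_samples < 2L) stop("need at least 2 samples")
  set.seed(seed)
  covs <- scenario_covariances()
  gaps <- seq(6, 3.25, length.out = n_samples)
  drift <- 1.5 * (seq_len(n_samples) - 1L)
  samples <- list()
  truth <- list()
  means <- list()
  for (t in seq_len(n_samples)) {
    mean_a <- c(drift[t], drift[t], 0, 0, 0)
    mean_b <- mean_a + c(gaps[t], gaps[t], 0, 0, 0)
    s <- scenario_sample(n_per_subpop, mean_a, mean_b, covs,
                         sprintf("t%d", t))
    nm <- sprintf("t%d", t)
    samples[[nm]] <- s
    truth[[nm]] <- s$labels
    means[[nm]] <- rbind(mean_a, mean_b)
  }
  list(samples = samples, truth = truth, means = means,
       covariances = covs, gaps = gaps)
}
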