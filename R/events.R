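#' Event matrix container
#'
#' The universal input of the pipeline: an events x markers numeric matrix
#' together with marker names, a sample identifier and a flag recording
#' whether the variance-stabilising arcsinh transform has been applied.
#'
#' @param values Numeric matrix, events in rows, markers in columns. No
#'   missing values are allowed and at least two markers are required.
#' @param marker_names Character vector of unique marker names, one per
#'   column. Defaults to `colnames(values)`.
#' @param sample_id Single string identifying the sample.
#' @param transformed Logical flag; `TRUE` once intensities are on the
#'   arcsinh scale (or were simulated directly on the analysis scale).
#'
#' @return An object of class `event_matrix`: a list with elements
#'   `values`, `marker_names`, `sample_id` and `transformed`.
#' @seealso [read_events()], [arcsinh_transform()], [viability_filter()]
#' @export
event_matrix <- function(values, marker_names = colnames(values),
                         sample_id = "sample", transformed = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("event values must be numeric")
  }
  if (anyNA(values)) {
    stop("event values must not contain missing values")
  }
  if (ncol(values) < 2L) {
    stop("an event matrix needs at least 2 markers")
  }
  if (is.null(marker_names)) {
    marker_names <- paste0("V", seq_len(ncol(values)))
  }
  marker_names <- as.character(marker_names)
  if (length(marker_names) != ncol(values)) {
    stop("marker_names length must equal the number of columns")
  }
  if (anyDuplicated(marker_names)) {
    stop("duplicate marker names: ",
         paste(unique(marker_names[duplicated(marker_names)]), collapse = ", "))
  }
  dimnames(values) <- list(NULL, marker_names)
  structure(
    list(values = values, marker_names = marker_names,
         sample_id = as.character(sample_id)[1L],
         transformed = isTRUE(transformed)),
    class = "event_matrix"
  )
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix '%s': %d events x %d markers (%s)\n",
              x$sample_id, nrow(x$values), ncol(x$values),
              if (x$transformed) "transformed" else "raw"))
  cat("markers:", paste(utils::head(x$marker_names, 8L), collapse = ", "),
      if (length(x$marker_names) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$values)

#' Read cytometry events from file
#'
#' Reads an FCS 3.0/3.1 list-mode file or a delimited text table (header row
#' of marker names; comma by default, tab accepted) into an [event_matrix()].
#' Intensities are returned untransformed and channel order is preserved.
#' For FCS input the marker names come from the $PnS keyword, falling back
#' to $PnN when $PnS is absent.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by file extension), `"fcs"` or `"delimited"`.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return An untransformed [event_matrix()].
#' @export
read_events <- function(path, format = c("auto", "fcs", "delimited"),
                        sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "delimited"
  }
  if (file.size(path) == 0L) {
    stop("empty file: ", path)
  }
  if (format == "fcs") {
    parsed <- read_fcs(path)
    return(event_matrix(parsed$values, marker_names = parsed$marker_names,
                        sample_id = sample_id, transformed = FALSE))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "")
  if (nrow(tab) == 0L) {
    stop("no data rows in ", path)
  }
  event_matrix(as.matrix(tab), marker_names = colnames(tab),
               sample_id = sample_id, transformed = FALSE)
}

#' Arcsinh transform of raw intensities
#'
#' Applies the standard cytometry variance-stabilising transform
#' `asinh(x / cofactor)` to every value. The conventional cofactor for mass
#' cytometry is 5. Double transformation is refused.
#'
#' @param m An [event_matrix()] with `transformed = FALSE`.
#' @param cofactor Positive scaling constant (default 5).
#' @return The transformed [event_matrix()] (`transformed = TRUE`).
#' @export
arcsinh_transform <- function(m, cofactor = 5) {
  stopifnot(inherits(m, "event_matrix"))
  if (isTRUE(m$transformed)) {
    stop("event matrix is already transformed")
  }
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    stop("cofactor must be a positive number")
  }
  out <- m
  out$values <- asinh(m$values / cofactor)
  dimnames(out$values) <- list(NULL, m$marker_names)
  out$transformed <- TRUE
  out
}

#' Sequential DNA / viability event filter
#'
#' Reproduces the usual two-step quality gate for mass cytometry: keep the
#' top `keep_fraction` of events by DNA content (good-quality cells carry
#' high DNA signal), then, among the survivors, the `keep_fraction` with the
#' lowest viability-stain signal (live cells carry low cisplatin). Overall
#' retention is approximately `keep_fraction^2` (the classical "top 90%").
#' Either direction can be flipped per channel. Ties at a quantile boundary
#' are broken by original row order, so the retained count is exactly
#' `ceiling(f * ceiling(f * n))` for any input.
#'
#' @param m An [event_matrix()].
#' @param dna_channel,viability_channel Marker names of the two channels.
#' @param keep_fraction Fraction kept at each step (default 0.95).
#' @param dna_keep,viability_keep `"high"` or `"low"`: which end of each
#'   channel is retained. Defaults: high DNA, low viability stain.
#' @return The filtered [event_matrix()] (row order preserved).
#' @export
viability_filter <- function(m, dna_channel, viability_channel,
                             keep_fraction = 0.95,
                             dna_keep = "high", viability_keep = "low") {
  stopifnot(inherits(m, "event_matrix"))
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]")
  }
  for (ch in c(dna_channel, viability_channel)) {
    if (!ch %in% m$marker_names) {
      stop("channel not present: ", ch)
    }
  }
  dna_keep <- match.arg(dna_keep, c("high", "low"))
  viability_keep <- match.arg(viability_keep, c("high", "low"))

  keep_top <- function(idx, values, direction) {
    k <- ceiling(keep_fraction * length(idx))
    v <- values[idx]
    # order() with radix is stable, so ties fall back to original row order
    ord <- if (direction == "high") order(-v) else order(v)
    sort(idx[ord[seq_len(k)]])
  }

  idx <- seq_len(nrow(m$values))
  idx <- keep_top(idx, m$values[, dna_channel], dna_keep)
  idx <- keep_top(idx, m$values[, viability_channel], viability_keep)
  out <- m
  out$values <- m$values[idx, , drop = FALSE]
  out
}

#' Write per-event subpopulation / clade assignments
#'
#' Writes a delimited table with columns `event_index`, `sample_id`,
#' `subpopulation` and `clade` in deterministic (sample, event) order.
#' Events without a clade (e.g. discarded ones) are written as `NA`.
#'
#' @param x A [cluster_labeling()] or a [man()] clade assignment.
#' @param path Output path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return Invisibly, the written data frame.
#' @export
write_assignments <- function(x, path) {
  if (inherits(x, "cluster_labeling")) {
    tab <- data.frame(event_index = seq_along(x$labels),
                      sample_id = x$sample_id,
                      subpopulation = x$labels,
                      clade = NA_integer_)
  } else if (inherits(x, "clade_assignment")) {
    tabs <- lapply(names(x$event_clades), function(s) {
      data.frame(event_index = seq_along(x$event_clades[[s]]),
                 sample_id = s,
                 subpopulation = x$event_subpops[[s]],
                 clade = x$event_clades[[s]])
    })
    tab <- do.call(rbind, tabs[order(names(x$event_clades))])
    rownames(tab) <- NULL
  } else {
    stop("cannot write assignments for class ", paste(class(x), collapse = "/"))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  ok <- tryCatch({
    utils::write.table(tab, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("could not write ", path, ": ", conditionMessage(ok))
  }
  invisible(tab)
}
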