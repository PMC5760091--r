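# Minimal FCS 3.0 / 3.1 list-mode reader.
#
# Only what automated gating needs: the TEXT segment keywords and the DATA
# segment for $MODE L with $DATATYPE F (float), D (double) or I (unsigned
# integer, uniform $PnB of 8/16/32 bits). Analysis segments, compensation
# and multi-dataset files are out of scope.

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!grepl("^FCS3\\.", version)) {
    stop("unsupported FCS version '", version, "' in ", path)
  }
  off <- function(a, b) {
    v <- suppressWarnings(as.integer(trimws(substr(header, a, b))))
    if (is.na(v)) stop("malformed FCS header offsets in ", path)
    v
  }
  text_start <- off(11L, 18L)
  text_end <- off(19L, 26L)
  data_start <- off(27L, 34L)
  data_end <- off(35L, 42L)

  seek(con, text_start)
  text_raw <- readBin(con, "raw", text_end - text_start + 1L)
  text <- rawToChar(text_raw)
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1L]]
  if (length(parts) < 2L) stop("empty FCS TEXT segment in ", path)
  keys <- toupper(trimws(parts[seq(1L, length(parts) - 1L, by = 2L)]))
  vals <- parts[seq(2L, length(parts), by = 2L)]
  kw <- function(name, default = NA_character_) {
    i <- match(toupper(name), keys)
    if (is.na(i)) default else vals[i]
  }

  n_par <- as.integer(kw("$PAR"))
  n_tot <- as.integer(kw("$TOT"))
  if (is.na(n_par) || is.na(n_tot)) stop("FCS file lacks $PAR/$TOT: ", path)
  if (!identical(toupper(kw("$MODE", "L")), "L")) {
    stop("only list-mode ($MODE L) FCS files are supported")
  }
  dtype <- toupper(kw("$DATATYPE", "F"))
  byte_ord <- kw("$BYTEORD", "1,2,3,4")
  endian <- if (identical(byte_ord, "4,3,2,1")) "big" else "little"

  if (data_start == 0L) data_start <- as.integer(kw("$BEGINDATA"))
  if (data_end == 0L) data_end <- as.integer(kw("$ENDDATA"))
  if (is.na(data_start) || data_start <= 0L) {
    stop("cannot locate FCS DATA segment in ", path)
  }
  seek(con, data_start)

  n_values <- n_par * n_tot
  if (dtype == "F") {
    x <- readBin(con, "numeric", n = n_values, size = 4L, endian = endian)
  } else if (dtype == "D") {
    x <- readBin(con, "numeric", n = n_values, size = 8L, endian = endian)
  } else if (dtype == "I") {
    bits <- unique(vapply(seq_len(n_par), function(i) {
      as.integer(kw(sprintf("$P%dB", i), "32"))
    }, integer(1L)))
    if (length(bits) != 1L || !bits %in% c(8L, 16L, 32L)) {
      stop("integer FCS data requires a uniform $PnB of 8, 16 or 32 bits")
    }
    size <- bits / 8L
    x <- readBin(con, "integer", n = n_values, size = size,
                 signed = size == 4L, endian = endian)
    x <- as.numeric(x)
    # 32-bit values read as signed; fold negatives back to unsigned range
    if (size == 4L && any(x < 0)) x[x < 0] <- x[x < 0] + 2^32
  } else {
    stop("unsupported $DATATYPE '", dtype, "'")
  }
  if (length(x) < n_values) {
    stop("truncated FCS DATA segment in ", path)
  }
  values <- matrix(x, nrow = n_tot, ncol = n_par, byrow = TRUE)

  marker_names <- vapply(seq_len(n_par), function(i) {
    s <- kw(sprintf("$P%dS", i))
    if (is.na(s) || !nzchar(trimws(s))) s <- kw(sprintf("$P%dN", i))
    if (is.na(s) || !nzchar(trimws(s))) s <- sprintf("P%d", i)
    trimws(s)
  }, character(1L))

  list(values = values, marker_names = marker_names)
}
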