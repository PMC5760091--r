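# Writes a minimal FCS 3.0 list-mode file for round-trip tests. Fixtures
# are generated at test time; nothing binary is stored in the repository.
write_test_fcs <- function(path, values, short_names = NULL,
                           stain_names = NULL, datatype = "F",
                           endian = "little", bits = 32L) {
  n <- nrow(values); p <- ncol(values)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$MODE", "L", "$DATATYPE", datatype,
          "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1",
          "$PAR", as.character(p), "$TOT", as.character(n),
          "$NEXTDATA", "0")
  for (i in seq_len(p)) {
    nm <- if (is.null(short_names)) sprintf("P%d", i) else short_names[i]
    kw <- c(kw, sprintf("$P%dN", i), nm,
            sprintf("$P%dB", i), as.character(bits),
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144")
    if (!is.null(stain_names) && !is.na(stain_names[i])) {
      kw <- c(kw, sprintf("$P%dS", i), stain_names[i])
    }
  }
  size <- if (datatype == "D") 8L else bits / 8L
  data_len <- n * p * size
  header_len <- 58L

  # iterate because $BEGINDATA/$ENDDATA values change the TEXT length
  text_start <- header_len
  data_start <- 1000L
  for (rep in 1:5) {
    full_kw <- c(kw, "$BEGINDATA", as.character(data_start),
                 "$ENDDATA", as.character(data_start + data_len - 1L))
    text <- paste0("/", paste(full_kw, collapse = "/"), "/")
    new_start <- text_start + nchar(text)
    if (new_start == data_start) break
    data_start <- new_start
  }
  text_end <- text_start + nchar(text) - 1L

  field <- function(x) formatC(x, width = 8L)
  header <- paste0("FCS3.0    ", field(text_start), field(text_end),
                   field(data_start), field(data_start + data_len - 1L),
                   field(0L), field(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  flat <- as.vector(t(values))
  if (datatype == "I") {
    writeBin(as.integer(flat), con, size = size, endian = endian)
  } else {
    writeBin(as.numeric(flat), con, size = size, endian = endian)
  }
  invisible(path)
}
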