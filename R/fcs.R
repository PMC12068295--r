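# Minimal FCS 3.1 codec: list-mode, single data set, 32-bit float data.
# Covers what the pipeline needs (write synthetic wells, read them and any
# conformant float FCS 3.0/3.1 file back); it is not a general-purpose
# cytometry library.

#' Write events to an FCS 3.1 file
#'
#' List mode, 32-bit little-endian floats, one parameter per channel. Hidden
#' ground-truth labels are never written to FCS; use [write_csv_events()] for
#' a labelled sidecar.
#'
#' @param events EventTable (tibble of channel intensities; a `.truth_class`
#'   column is dropped).
#' @param path Output path.
#' @param channel_map Named character vector mapping logical channel names to
#'   the `$PnN` names written to the file (default [default_channel_map()]).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, channel_map = default_channel_map()) {
  mat <- as.matrix(events[, intersect(BH3_CHANNELS, names(events)), drop = FALSE])
  if (nrow(mat) == 0) stop("cannot write an empty event table", call. = FALSE)
  storage.mode(mat) <- "double"
  pnn <- unname(channel_map[colnames(mat)])
  if (anyNA(pnn)) pnn <- colnames(mat)
  p <- ncol(mat); n <- nrow(mat)

  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%010d", "$ENDDATA", "%010d",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
  for (i in seq_len(p)) {
    rng <- format(max(262144, 2^ceiling(log2(max(mat[, i], 1)))), scientific = FALSE)
    kw <- c(kw, sprintf("$P%dN", i), pnn[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), rng)
  }
  delim <- "/"
  text_tpl <- paste0(delim, paste(kw, collapse = delim), delim)
  text_begin <- 58L
  # measure with the offsets expanded to their final 10-char width
  text_end <- text_begin + nchar(sprintf(text_tpl, 0L, 0L)) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * p * n - 1L
  text <- sprintf(text_tpl, data_begin, data_end)

  hdr8 <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ", hdr8(text_begin), hdr8(text_end),
                   hdr8(if (data_end <= 99999999) data_begin else 0),
                   hdr8(if (data_end <= 99999999) data_end else 0),
                   hdr8(0), hdr8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS file
#'
#' Parses the HEADER and primary TEXT segment and reads list-mode float data
#' (`$DATATYPE F`, or `D` for doubles), honouring `$BYTEORD`.
#'
#' @param path FCS 3.0/3.1 file.
#' @return Tibble with one column per `$PnN` parameter name; attribute
#'   `"keywords"` holds the TEXT keyword list.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  if (!grepl("^FCS3\\.[01]", header)) {
    stop("not an FCS 3.0/3.1 file: ", path, call. = FALSE)
  }
  off <- function(i) {
    v <- suppressWarnings(as.integer(trimws(substr(header, 11 + (i - 1) * 8, 10 + i * 8))))
    if (is.na(v)) stop("corrupt FCS header in ", path, call. = FALSE)
    v
  }
  text_begin <- off(1); text_end <- off(2)
  seek(con, text_begin)
  text <- rawToChar(readBin(con, "raw", text_end - text_begin + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)], toupper(parts[seq(1, length(parts), 2)]))

  need <- function(k) {
    if (!k %in% names(kw)) stop("FCS file missing required keyword ", k, call. = FALSE)
    kw[[k]]
  }
  p <- as.integer(need("$PAR")); n <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D")) {
    stop("unsupported FCS $DATATYPE '", dtype, "' (float data expected)", call. = FALSE)
  }
  endian <- if (startsWith(need("$BYTEORD"), "1")) "little" else "big"
  data_begin <- as.integer(kw[["$BEGINDATA"]] %||% off(3))
  size <- if (dtype == "F") 4L else 8L
  seek(con, data_begin)
  vals <- readBin(con, "numeric", n * p, size = size, endian = endian)
  mat <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(p), function(i) kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i), "")
  out <- tibble::as_tibble(mat)
  attr(out, "keywords") <- kw
  out
}

#' Default logical-to-physical channel map
#'
#' Maps the pipeline's five logical channels (fsc, ssc, annexin,
#' viability_dye, bead) to conventional cytometer parameter names.
#' @return Named character vector.
#' @export
default_channel_map <- function() {
  c(fsc = "FSC-A", ssc = "SSC-A", annexin = "Annexin V-APC-A",
    viability_dye = "7-AAD-A", bead = "Bead-Count-A")
}
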