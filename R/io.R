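#' Read / write a single spectrum as CSV
#'
#' Dialect: comma separator, dot decimal, UTF-8, mandatory header
#' `wavelength_nm,intensity`, one row per grid point. Values survive a
#' write/read round trip bit-for-bit (shortest round-trippable decimal
#' representation). Wavelengths must be strictly increasing on read.
#'
#' @param path File path.
#' @param delta_lambda Optional scan offset (nm) to attach to the spectrum
#'   on read.
#' @return `read_spectrum_csv()` returns a `sync_spectrum` tibble;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, delta_lambda = NA_real_) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(df), c("wavelength_nm", "intensity"))) {
    stop("Spectrum CSV must have exactly the columns ",
         "`wavelength_nm,intensity` (got: ",
         paste(names(df), collapse = ","), ").", call. = FALSE)
  }
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  bad <- which(is.na(df$wavelength_nm) | is.na(df$intensity))
  if (length(bad)) {
    stop(sprintf("Malformed spectrum CSV at line %d of %s.",
                 bad[1] + 1L, path), call. = FALSE)
  }
  if (anyNA(df$wavelength_nm) || any(diff(df$wavelength_nm) <= 0)) {
    stop("Spectrum wavelengths must be strictly increasing.", call. = FALSE)
  }
  new_sync_spectrum(df$wavelength_nm, df$intensity, delta_lambda)
}

#' @rdname read_spectrum_csv
#' @param spec Spectrum tibble with columns `wavelength_nm`, `intensity`.
#' @export
write_spectrum_csv <- function(spec, path) {
  fmt <- function(v) vapply(v, function(z) format(z, digits = 17), "")
  writeLines(c("wavelength_nm,intensity",
               paste(fmt(spec$wavelength_nm), fmt(spec$intensity), sep = ",")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read / write an excitation-emission matrix as CSV
#'
#' Layout: the first row carries the emission grid (first cell empty), the
#' first column the excitation grid, the body the intensities. Every row must
#' have the same number of fields; ragged rows are rejected with the row
#' number.
#'
#' @param path File path.
#' @return `read_eem_csv()` returns an [eem]; `write_eem_csv()` returns
#'   `path` invisibly.
#' @export
read_eem_csv <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  fields <- strsplit(lines, ",", fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged)) {
    stop(sprintf("Ragged EEM CSV: row %d has %d fields, expected %d.",
                 ragged[1], lengths(fields)[ragged[1]], width),
         call. = FALSE)
  }
  em <- suppressWarnings(as.numeric(fields[[1]][-1]))
  body <- fields[-1]
  ex <- suppressWarnings(as.numeric(vapply(body, `[`, "", 1L)))
  if (anyNA(em) || anyNA(ex)) {
    stop("Non-numeric wavelengths in the EEM CSV header row/column.",
         call. = FALSE)
  }
  intensity <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(body, `[`, -1L)))),
    nrow = length(ex), ncol = length(em), byrow = TRUE)
  if (anyNA(intensity)) {
    stop("Non-numeric intensity values in the EEM CSV body.", call. = FALSE)
  }
  eem(ex, em, intensity)
}

#' @rdname read_eem_csv
#' @param x An [eem].
#' @export
write_eem_csv <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  fmt <- function(v) vapply(v, function(z) format(z, digits = 17), "")
  header <- paste(c("", fmt(x$em_nm)), collapse = ",")
  rows <- vapply(seq_along(x$ex_nm), function(i) {
    paste(c(fmt(x$ex_nm[i]), fmt(x$intensity[i, ])), collapse = ",")
  }, "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a simple JCAMP-DX spectrum
#'
#' Minimal reader for single-spectrum JCAMP-DX files with an uncompressed
#' (AFFN) `##XYDATA=(X++(Y..Y))` block, honouring `XFACTOR`, `YFACTOR`,
#' `FIRSTX` and `DELTAX`. Compressed encodings (SQZ/DIF/DUP), PEAK TABLE
#' records and multi-block files are rejected loudly rather than silently
#' misread.
#'
#' @param path File path.
#' @param delta_lambda Optional scan offset (nm) to attach.
#' @return A `sync_spectrum` tibble.
#' @export
read_jcamp <- function(path, delta_lambda = NA_real_) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^##", key, "="), "", hit[1])
  }
  if (length(grep("^##TITLE=", lines)) > 1L) {
    stop("Multi-block JCAMP-DX files are not supported.", call. = FALSE)
  }
  if (any(grepl("^##(PEAK TABLE|PEAKTABLE|DATA TABLE)=", lines))) {
    stop("Only ##XYDATA=(X++(Y..Y)) JCAMP-DX records are supported.",
         call. = FALSE)
  }
  xy_at <- grep("^##XYDATA=", lines)
  if (!length(xy_at)) stop("No ##XYDATA record found.", call. = FALSE)
  form <- gsub("\\s", "", sub("^##XYDATA=", "", lines[xy_at[1]]))
  if (form != "(X++(Y..Y))") {
    stop("Unsupported XYDATA form: ", form, call. = FALSE)
  }
  xfac <- as.numeric(get_field("XFACTOR") %||% "1")
  yfac <- as.numeric(get_field("YFACTOR") %||% "1")
  end_at <- grep("^##END", lines)
  end_at <- if (length(end_at)) min(end_at[end_at > xy_at[1]]) else
    length(lines) + 1L
  data_lines <- lines[(xy_at[1] + 1L):(end_at - 1L)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (any(grepl("[A-DF-Za-df-z%@]", data_lines))) {
    stop("Compressed (non-AFFN) JCAMP-DX data are not supported.",
         call. = FALSE)
  }
  wl <- c(); y <- c()
  for (ln in data_lines) {
    vals <- as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1]])
    if (anyNA(vals) || length(vals) < 2L) {
      stop("Malformed XYDATA line: ", ln, call. = FALSE)
    }
    x0 <- vals[1] * xfac
    ys <- vals[-1] * yfac
    dx <- as.numeric(get_field("DELTAX") %||% NA)
    if (is.na(dx)) {
      npt <- as.numeric(get_field("NPOINTS"))
      lastx <- as.numeric(get_field("LASTX")) * xfac
      firstx <- as.numeric(get_field("FIRSTX")) * xfac
      dx <- (lastx - firstx) / (npt - 1)
    } else {
      dx <- dx * xfac
    }
    wl <- c(wl, x0 + dx * (seq_along(ys) - 1L))
    y <- c(y, ys)
  }
  if (any(diff(wl) <= 0)) {
    stop("JCAMP-DX wavelengths are not strictly increasing.", call. = FALSE)
  }
  new_sync_spectrum(wl, y, delta_lambda)
}
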