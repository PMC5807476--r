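#' Read a voltammogram from delimited text
#'
#' Two dialects are supported.  `two_column_csv`: an optional block of
#' comment lines (`# key=value`) followed by two delimited numeric columns
#' (potential, current).  `instrument_text`: a plain `key=value` header block
#' (no comment marker) terminated by a `[data]` line or the first line that
#' parses as two numbers, then the data block.  The delimiter is
#' auto-detected among comma, tab and semicolon unless given.
#'
#' Rows with non-numeric entries are dropped with a message reporting the
#' count; a file whose first data line cannot be parsed at all is rejected
#' naming that line.  Cycle boundaries are always re-detected from
#' potential-direction reversals.
#'
#' @param path File path.
#' @param dialect `"two_column_csv"` or `"instrument_text"`.
#' @param scan_rate Scan rate in V/s; if `NULL`, taken from the file header
#'   (key `scan_rate_V_per_s`), which must then be present.
#' @param reference Reference spec as in [voltammogram()]; if `NULL`, taken
#'   from header keys `reference` / `reference_offset_V`, defaulting to NHE.
#' @param delimiter Optional explicit delimiter (`","`, `"\t"`, `";"`).
#' @param potential_unit,current_unit Units used in the file: `"V"` or
#'   `"mV"`; `"A"`, `"mA"` or `"uA"`.  Values are converted to V and A.
#' @param flip_current If `TRUE`, negate the current column (for instruments
#'   that record cathodic current as positive).  The flip is recorded in
#'   `meta$sign_flipped`.
#' @return A validated [voltammogram()].
#' @export
read_voltammogram <- function(path, dialect = c("two_column_csv", "instrument_text"),
                              scan_rate = NULL, reference = NULL,
                              delimiter = NULL,
                              potential_unit = "V", current_unit = "A",
                              flip_current = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)

  header <- character()
  if (dialect == "two_column_csv") {
    is_com <- startsWith(trimws(lines), "#")
    header <- sub("^\\s*#\\s*", "", lines[is_com])
    data_lines <- lines[!is_com]
  } else {
    kv <- grepl("=", lines, fixed = TRUE) & !grepl("^\\s*[-+0-9.]", lines)
    first_data <- which(!kv & !grepl("^\\s*\\[", lines))[1]
    if (is.na(first_data)) stop("no data block found in ", path, call. = FALSE)
    header <- lines[seq_len(first_data - 1)]
    header <- header[grepl("=", header, fixed = TRUE)]
    data_lines <- lines[first_data:length(lines)]
  }
  meta <- parse_header_kv(header)

  if (length(data_lines) == 0) stop("no data rows in ", path, call. = FALSE)
  if (is.null(delimiter)) delimiter <- sniff_delimiter(data_lines[1])
  # drop a column-name line if present
  first_fields <- strsplit(data_lines[1], delimiter, fixed = TRUE)[[1]]
  if (all(is.na(suppressWarnings(as.numeric(first_fields)))) &&
      length(data_lines) > 1) {
    data_lines <- data_lines[-1]
  }

  parts <- strsplit(data_lines, delimiter, fixed = TRUE)
  ncols <- vapply(parts, length, integer(1))
  bad_shape <- ncols < 2
  pot <- rep(NA_real_, length(parts))
  cur <- rep(NA_real_, length(parts))
  ok <- !bad_shape
  pot[ok] <- suppressWarnings(as.numeric(vapply(parts[ok], `[[`, "", 1)))
  cur[ok] <- suppressWarnings(as.numeric(vapply(parts[ok], `[[`, "", 2)))
  bad <- bad_shape | is.na(pot) | is.na(cur)
  if (bad[1] && all(bad)) {
    stop("cannot parse '", path, "': first bad line: ", data_lines[1],
         call. = FALSE)
  }
  if (any(bad)) {
    message(sum(bad), " non-numeric row(s) dropped while reading ", path)
  }
  pot <- pot[!bad]; cur <- cur[!bad]
  if (length(pot) < 2) stop("fewer than 2 samples in ", path, call. = FALSE)

  pot <- pot * switch(potential_unit, V = 1, mV = 1e-3,
                      stop("unknown potential unit: ", potential_unit))
  cur <- cur * switch(current_unit, A = 1, mA = 1e-3, uA = 1e-6,
                      stop("unknown current unit: ", current_unit))
  if (flip_current) cur <- -cur

  if (is.null(scan_rate)) {
    scan_rate <- as.numeric(meta[["scan_rate_V_per_s"]] %||% NA)
    if (!is.finite(scan_rate)) {
      stop("scan_rate not given and not found in header of ", path,
           call. = FALSE)
    }
  }
  if (is.null(reference)) {
    ref_name <- meta[["reference"]] %||% "NHE"
    ref_off <- suppressWarnings(as.numeric(meta[["reference_offset_V"]] %||% NA))
    reference <- if (is.finite(ref_off)) {
      list(name = ref_name, offset_V = ref_off)
    } else ref_name
  }

  keep <- setdiff(names(meta),
                  c("scan_rate_V_per_s", "reference", "reference_offset_V",
                    "cycles"))
  v <- voltammogram(pot, cur, scan_rate, reference = reference,
                    meta = as.list(meta[keep]))
  if (flip_current) v$meta$sign_flipped <- TRUE
  v
}

parse_header_kv <- function(header) {
  kv <- strsplit(header, "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, integer(1)) >= 2]
  vals <- lapply(kv, function(x) trimws(paste(x[-1], collapse = "=")))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  vals
}

sniff_delimiter <- function(line) {
  cands <- c(",", "\t", ";")
  counts <- vapply(cands, function(d) {
    length(strsplit(line, d, fixed = TRUE)[[1]])
  }, integer(1))
  if (all(counts < 2)) {
    stop("cannot detect delimiter (auto-detection covers comma, tab and ",
         "semicolon; declare anything else explicitly) in: ", line,
         call. = FALSE)
  }
  cands[which.max(counts)]
}

#' Write a voltammogram to two-column delimited text
#'
#' Writes a commented header carrying the scan rate, reference, cycle
#' boundaries and free-form metadata, followed by `potential_V,current_A`
#' data at full double precision (`%.10e`).  [read_voltammogram()] inverts
#' the format.
#'
#' @param v A valid [voltammogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_voltammogram <- function(v, path) {
  stopifnot(inherits(v, "voltammogram"))
  if (anyNA(v$current) || anyNA(v$potential)) {
    stop("refusing to write voltammogram containing NA samples", call. = FALSE)
  }
  cyc <- vapply(v$cycles, function(cc) paste0(cc[1], ":", cc[2]), "")
  hdr <- c(
    sprintf("# scan_rate_V_per_s=%.10g", v$scan_rate),
    sprintf("# reference=%s", v$reference$name),
    sprintf("# reference_offset_V=%.10g", v$reference$offset_V),
    sprintf("# cycles=%s", paste(cyc, collapse = ","))
  )
  if (length(v$meta)) {
    hdr <- c(hdr, sprintf("# %s=%s", names(v$meta),
                          vapply(v$meta, function(x) paste(format(x), collapse = " "), "")))
  }
  body <- sprintf("%.10e,%.10e", v$potential, v$current)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "potential_V,current_A", body), con)
  invisible(path)
}
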