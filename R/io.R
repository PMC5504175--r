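# canonical plain-text formats: two-column (re, im) FID files with
# '#'-comments and an optional "# n=<N>" header, and "nuslist"-style
# schedule files with one zero-based index per line

#' Read a complex time-domain vector from delimited text
#'
#' One sample per line, two whitespace- (or comma-) separated columns
#' (real, imaginary); lines starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @return A `nus_fid`.
#' @export
read_fid <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop_data("no data lines in ", path)
  nums <- lapply(which(keep), function(i) {
    parts <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2L || any(!is.finite(vals)))
      stop_data("malformed FID line ", i, " in ", path, ": '", lines[i], "'")
    vals
  })
  mat <- do.call(rbind, nums)
  fid(complex(real = mat[, 1], imaginary = mat[, 2]), label = basename(path))
}

#' Write a complex time-domain vector as delimited text
#'
#' Full double precision; round-trips through [read_fid()] bit-exactly.
#'
#' @param fid a [fid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fid <- function(fid, path) {
  fid <- as_fid(fid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d", fid$n), con)
  writeLines(sprintf("%.17g %.17g", Re(fid$samples), Im(fid$samples)), con)
  invisible(path)
}

#' Read a NUS schedule file
#'
#' "nuslist" style: one zero-based grid index per line. Unsorted input is
#' accepted (and stored sorted); duplicates and out-of-range indices are
#' rejected.
#'
#' @param path file path.
#' @param n full grid size; defaults to `max(index) + 1` if omitted.
#' @return A [schedule()].
#' @export
read_schedule <- function(path, n = NULL) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop_data("no index lines in ", path)
  idx <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(!is.finite(idx) | idx != round(idx))
  if (length(bad))
    stop_data("malformed schedule line ", which(keep)[bad[1]], " in ", path)
  if (is.null(n)) n <- max(idx) + 1
  schedule(idx, n)
}

#' Write a NUS schedule file
#'
#' @param sched a [schedule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(sched, path) {
  stopifnot(inherits(sched, "nus_schedule"))
  writeLines(as.character(sched$indices), path)
  invisible(path)
}

#' Read a peak list from a YAML/JSON config
#'
#' The file holds a `peaks` sequence, each entry with keys `frequency`,
#' `amplitude` and optional `phase`, `decay`.
#'
#' @param path file path (YAML; JSON is valid YAML).
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_data("cannot parse ", path, ": ",
                                                conditionMessage(e)))
  peaks <- if (!is.null(doc$peaks)) doc$peaks else doc
  if (!is.list(peaks) || !length(peaks)) stop_data("no peaks in ", path)
  get <- function(field, default = NULL) vapply(peaks, function(p) {
    v <- p[[field]]
    if (is.null(v)) {
      if (is.null(default)) stop_data("peak missing field '", field, "' in ", path)
      v <- default
    }
    as.numeric(v)
  }, 0)
  peak_list(frequency = get("frequency"), amplitude = get("amplitude"),
            phase = get("phase", 0), decay = get("decay", 0))
}
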