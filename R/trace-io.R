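#' Read and write trace CSV files
#'
#' Traces are stored as comma-separated text with `#`-prefixed metadata
#' header lines (`# key: value`) followed by the columns
#' `time_s,capacitance_fF` and optionally `temperature_C`. Writing then
#' reading restores all fields, including metadata, to within 1e-9 fF.
#'
#' @param trace A trace tibble (see [generate_trace()]).
#' @param path File path.
#' @return `read_trace_csv()` returns the trace tibble with its `meta`
#'   attribute; `write_trace_csv()` returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is.data.frame(trace), all(c("time_s", "capacitance_fF") %in% names(trace)))
  meta <- trace_meta(trace)
  hdr <- c("# irritrace trace v1",
           vapply(names(meta), function(k) {
             v <- meta[[k]]
             v <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
             sprintf("# %s: %s", k, v)
           }, character(1)))
  cols <- intersect(c("time_s", "capacitance_fF", "temperature_C"), names(trace))
  body <- do.call(paste, c(lapply(trace[cols], function(x) sprintf("%.12f", x)),
                           list(sep = ",")))
  writeLines(c(hdr, paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta]
  meta <- list()
  for (ln in grep("^# .+: ", meta_lines, value = TRUE)) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]+: ?", "", kv)
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else if (val == "NA") NA_real_ else val
  }
  body <- lines[!is_meta]
  if (!length(body)) {
    abort("No data rows found.", class = "irritrace_format_error")
  }
  cols <- strsplit(body[1], ",")[[1]]
  if (!all(c("time_s", "capacitance_fF") %in% cols)) {
    abort(sprintf("Header line %d must name time_s and capacitance_fF columns: '%s'",
                  which(!is_meta)[1], body[1]),
          class = "irritrace_format_error")
  }
  cells <- strsplit(body[-1], ",")
  bad_shape <- which(lengths(cells) != length(cols))
  if (length(bad_shape)) {
    abort(sprintf("Line %d has %d fields, expected %d.",
                  which(!is_meta)[bad_shape[1] + 1], lengths(cells)[bad_shape[1]],
                  length(cols)),
          class = "irritrace_format_error")
  }
  mat <- suppressWarnings(vapply(cells, as.numeric, numeric(length(cols))))
  mat <- matrix(mat, ncol = length(cols), byrow = TRUE,
                dimnames = list(NULL, cols))
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1, any))[1]
    abort(sprintf("Non-numeric cell on line %d: '%s'",
                  which(!is_meta)[bad + 1], body[bad + 1]),
          class = "irritrace_format_error")
  }
  tr <- tibble::as_tibble(as.data.frame(mat))
  dt <- diff(tr$time_s)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * max(dt[1], 1e-12))) {
    abort("Time grid in file is not strictly increasing and uniform.",
          class = "irritrace_format_error")
  }
  attr(tr, "meta") <- meta
  tr
}
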