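# Dotted key-value parameter files ("RPDock.grid_step = 1" dialect).

#' Parse a `.par` parameter file
#'
#' Each non-empty line is split on the first `=`; both sides are
#' whitespace-trimmed and a trailing comma on the value is stripped.
#' Lines starting with `#` are ignored. Duplicate keys keep the last value
#' (with a warning). Values stay raw strings until typed by their consumer.
#'
#' @param path Path to the parameter file.
#' @return Named list of class `par_file`, in file order.
#' @export
parse_par <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    eq <- regexpr("=", raw, fixed = TRUE)
    if (eq < 0) stop("line ", ln, " of ", path, " has no '=': ", raw)
    key <- trimws(substr(raw, 1, eq - 1))
    val <- trimws(substr(raw, eq + 1, nchar(raw)))
    val <- sub(",+$", "", val)
    val <- trimws(val)
    if (!nzchar(key)) stop("line ", ln, " of ", path, " has an empty key")
    if (key %in% names(out)) {
      warning("duplicate key '", key, "' at line ", ln, "; last value wins")
    }
    out[[key]] <- val
  }
  structure(out, class = "par_file")
}

#' Write a parameter list to a `.par` file
#' @param par Named list (or `par_file`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_par <- function(par, path) {
  writeLines(sprintf("%s = %s", names(par), unlist(par)), path)
  invisible(path)
}
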