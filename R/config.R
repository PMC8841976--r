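#' Read and write flat key=value configuration files
#'
#' One `key=value` pair per line; vectors are comma-separated; logical
#' values are `true`/`false`. Lines starting with `#` are ignored.
#'
#' @param x Named list of scalar or vector values.
#' @param path File path.
#' @return `path` (write) or a named list (read).
#' @export
write_config <- function(x, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(paste(ifelse(v, "true", "false"), collapse = ","))
    if (is.numeric(v)) return(paste(format(v, digits = 15, scientific = FALSE,
                                           trim = TRUE), collapse = ","))
    paste(as.character(v), collapse = ",")
  }
  keep <- vapply(x, function(v) is.atomic(v) && length(v) > 0, logical(1))
  lines <- vapply(names(x)[keep],
                  function(k) paste0(k, "=", fmt(x[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (all(tolower(parts) %in% c("true", "false"))) {
      out[[key]] <- tolower(parts) == "true"
    } else {
      num <- suppressWarnings(as.numeric(parts))
      out[[key]] <- if (all(!is.na(num))) num else parts
    }
  }
  out
}
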