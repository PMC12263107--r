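`%||%` <- function(x, y) if (is.null(x)) y else x

pm3_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "pm3_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# escape regex metacharacters for literal matching (PCRE)
regex_escape <- function(x) {
  gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", x, perl = TRUE)
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
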