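PM3_TIERS <- c("T0_full", "T1_digits", "T2_tolerant")

# A "standalone digit run" is a maximal run of digits not immediately
# preceded by a digit or by "<digit>." and not immediately followed by a
# digit. This accepts the 274 in "c.274G>T" but rejects 388 inside
# "0.93884" (preceded by a digit) or "0.388..." (preceded by "<digit>."),
# and 388 inside "rs3885" (followed by a digit).
standalone_digit_regex <- function(n) {
  sprintf("(?<![0-9])(?<![0-9]\\.)%d(?![0-9])", as.integer(n))
}

#' Test whether a number occurs as a standalone digit run in a text
#'
#' @param text Character vector of texts.
#' @param n A single integer.
#' @return Logical vector: does `n` occur in each text outside of longer
#'   digit runs and decimal fractions?
#' @export
has_standalone_digits <- function(text, n) {
  grepl(standalone_digit_regex(n), text, perl = TRUE)
}

# build one T0 pattern from a literal representation: optional whitespace
# between tokens, optional parentheses, X/* interchange; "Ter" also
# matches the symbolic stop spellings
t0_pattern <- function(form, case_insensitive) {
  form2 <- gsub("Ter", "\x01", form, fixed = TRUE)
  chars <- strsplit(form2, "", fixed = TRUE)[[1]]
  parts <- vapply(chars, function(ch) {
    if (ch == "\x01") "(?:Ter|[X*])"
    else if (ch == "(") "\\(?"
    else if (ch == ")") "\\)?"
    else if (ch %in% c("*", "X")) "[X*]"
    else if (ch == " ") ""
    else regex_escape(ch)
  }, character(1), USE.NAMES = FALSE)
  pat <- paste(parts[nzchar(parts)], collapse = "\\s*")
  if (grepl("^[0-9]", form)) pat <- paste0("(?<![0-9.])", pat)
  if (case_insensitive) pat <- paste0("(?i)", pat)
  pat
}

# one-letter protein shorthand such as D92Y: matched case-sensitively and
# guarded against occurring inside a longer alphanumeric token
is_shorthand <- function(form) grepl("^[A-Z*X][0-9]+[A-Z*X]$", form)

#' Compile a representation set into one tier of match patterns
#'
#' Three relaxation tiers are supported. `T0_full` compiles every textual
#' representation with optional whitespace between tokens, optional
#' parentheses and `X`/`*` interchange; DNA notation and three-letter
#' protein forms are case-insensitive while one-letter shorthand stays
#' case-sensitive. `T1_digits` matches each coordinate of the variant as a
#' standalone digit run. `T2_tolerant` additionally accepts every integer
#' within `tolerance` of each coordinate, absorbing small coordinate
#' shifts between reference sequences.
#'
#' @param r A `pm3_repset` from [augment_variant()].
#' @param tier `"T0_full"`, `"T1_digits"` or `"T2_tolerant"`.
#' @param tolerance Numeric tolerance for `T2_tolerant` (default 2).
#' @return An object of class `pm3_patterns`: list with `tier`,
#'   `patterns` (PCRE strings), `representation` (what each pattern
#'   stands for) and `tolerance` (0 for T0/T1).
#' @export
compile_patterns <- function(r, tier = "T0_full", tolerance = 2L) {
  stopifnot(inherits(r, "pm3_repset"))
  tier <- match.arg(tier, PM3_TIERS)
  tolerance <- as.integer(tolerance)
  if (tolerance < 0L) pm3_abort("tolerance must be non-negative", "pm3_domain_error")

  if (tier == "T0_full") {
    forms <- all_forms(r)
    pats <- vapply(forms, function(f) {
      if (is_shorthand(f))
        paste0("(?<![A-Za-z0-9])", t0_pattern(f, case_insensitive = FALSE), "(?![A-Za-z0-9])")
      else
        t0_pattern(f, case_insensitive = TRUE)
    }, character(1), USE.NAMES = FALSE)
    reps <- forms
    tol <- 0L
  } else if (tier == "T1_digits") {
    pats <- vapply(r$positions, standalone_digit_regex, character(1))
    reps <- paste0("pos:", r$positions)
    tol <- 0L
  } else {
    vals <- unique(unlist(lapply(r$positions, function(p)
      seq.int(max(1L, p - tolerance), p + tolerance))))
    pats <- vapply(vals, standalone_digit_regex, character(1))
    reps <- paste0("pos~", vals)
    tol <- tolerance
  }

  structure(list(tier = tier, patterns = pats, representation = reps,
                 tolerance = if (tier == "T2_tolerant") tol else 0L),
            class = "pm3_patterns")
}

#' @export
print.pm3_patterns <- function(x, ...) {
  cat("<pm3_patterns> tier ", x$tier, ", ", length(x$patterns), " patterns",
      if (x$tolerance > 0) sprintf(", tolerance %d", x$tolerance), "\n", sep = "")
  invisible(x)
}

#' Scan a text with a compiled pattern set
#'
#' @param text A single string.
#' @param patset A `pm3_patterns` object.
#' @return A data.frame with 0-based half-open character offsets
#'   (`start`, `end`), the matched text (`match`) and the representation
#'   that matched (`representation`), ordered by `start`; zero rows if
#'   nothing matches.
#' @export
pm3_scan <- function(text, patset) {
  stopifnot(inherits(patset, "pm3_patterns"), is_scalar_string(text))
  out <- list()
  for (i in seq_along(patset$patterns)) {
    m <- gregexpr(patset$patterns[i], text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    out[[length(out) + 1L]] <- data.frame(
      start = as.integer(m) - 1L,
      end = as.integer(m) - 1L + len,
      match = substring(text, m, m + len - 1L),
      representation = patset$representation[i],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0), representation = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("start", "end")]), , drop = FALSE]
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

pm3_matches_any <- function(text, patset) {
  for (p in patset$patterns)
    if (grepl(p, text, perl = TRUE)) return(TRUE)
  FALSE
}
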