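# generic HGVS-like mention pattern used by the mock extractor: coding DNA
# changes plus three-letter and one-letter protein changes
HGVS_MENTION_PATTERNS <- c(
  dna = "(?i)c\\.[0-9]+(?:_[0-9]+)?(?:[ACGT]>[ACGT]|delins[ACGT]+|del[ACGT]*|dup[ACGT]*|ins[ACGT]+)",
  protein3 = "p\\.\\(?[A-Z][a-z]{2}[0-9]+(?:[A-Z][a-z]{2}|Ter|\\*|X)\\)?",
  protein3_bare = "(?<![A-Za-z.(])[A-Z][a-z]{2}[0-9]+(?:[A-Z][a-z]{2}|Ter)(?![A-Za-z])",
  shorthand = "(?<![A-Za-z0-9])[A-Z][0-9]+[A-Z*X](?![A-Za-z0-9])"
)

scan_variant_mentions <- function(text) {
  found <- list()
  for (pat in HGVS_MENTION_PATTERNS) {
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    found[[length(found) + 1L]] <- data.frame(
      start = as.integer(m), text = substring(text, m, m + len - 1L),
      stringsAsFactors = FALSE)
  }
  if (!length(found)) return(character(0))
  all <- do.call(rbind, found)
  all <- all[order(all$start), , drop = FALSE]
  unique(all$text)
}

#' Construct a completion-backend request
#'
#' @param task One of `"variant_hit"`, `"in_trans"`, `"sql_generation"`,
#'   `"summarize"`.
#' @param context The retrieved chunks or fetched table rows, as text.
#' @param variant_forms A `pm3_repset` for the query variant (or `NULL`
#'   for tasks that do not need one).
#' @param extra Optional task-specific fields (e.g. the SQL template).
#' @return A list of class `pm3_request`.
#' @export
backend_request <- function(task, context, variant_forms = NULL, extra = list()) {
  task <- match.arg(task, c("variant_hit", "in_trans", "sql_generation", "summarize"))
  structure(c(list(task = task, context = context,
                   variant_forms = variant_forms,
                   prompt_template_id = paste0(task, "/1")), extra),
            class = "pm3_request")
}

backend_answer <- function(verdict = "n/a", extracted_variants = character(0),
                           rationale_span = "", text = "") {
  structure(list(verdict = verdict, extracted_variants = extracted_variants,
                 rationale_span = rationale_span, text = text),
            class = "pm3_answer")
}

#' Read a versioned prompt template shipped with the package
#'
#' @param id Template identifier such as `"variant_hit/1"`.
#' @return The template text.
#' @export
prompt_template <- function(id) {
  parts <- strsplit(id, "/", fixed = TRUE)[[1]]
  path <- system.file("prompts", paste0(parts[1], "-v", parts[2] %||% "1", ".txt"),
                      package = "pm3miner")
  if (!nzchar(path)) pm3_abort(sprintf("unknown prompt template '%s'", id), "pm3_domain_error")
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' Complete a backend request
#'
#' Generic dispatched on the backend object. Every backend is total: it
#' returns a `pm3_answer` or signals a typed `pm3_backend_unavailable`
#' error (HTTP adapter only; the mock never fails).
#'
#' @param backend A backend object.
#' @param request A `pm3_request`.
#' @return A `pm3_answer` with `verdict` (`"yes"`, `"no"`, `"n/a"`),
#'   `extracted_variants`, `rationale_span` (verbatim substring of the
#'   request context, or empty) and free-text `text`.
#' @export
complete <- function(backend, request) UseMethod("complete")

#' Deterministic mock completion backend
#'
#' A rule-based stand-in for the completion model that encodes the
#' behavioural contract the pipeline relies on — short answers with
#' verbatim evidence — so the full pipeline runs offline and
#' reproducibly. For `variant_hit` it answers yes iff the context
#' contains a full-notation match of the query; for `in_trans` it
#' extracts every HGVS-like mention that is not the query itself, in
#' order of first occurrence; for `sql_generation` it returns the
#' supplied template; for `summarize` it produces a one-line digest of
#' the mentions in the context.
#'
#' @return A backend object of class `pm3_backend_mock`.
#' @export
pm3_backend_mock <- function() {
  structure(list(), class = c("pm3_backend_mock", "pm3_backend"))
}

#' @export
complete.pm3_backend_mock <- function(backend, request) {
  stopifnot(inherits(request, "pm3_request"))
  ctx <- request$context
  switch(request$task,
    variant_hit = {
      t0 <- compile_patterns(request$variant_forms, "T0_full")
      m <- pm3_scan(ctx, t0)
      if (nrow(m))
        backend_answer("yes", rationale_span = m$match[1],
                       text = sprintf("The query variant is reported (matched '%s').", m$match[1]))
      else
        backend_answer("no", text = "The query variant is not reported in the context.")
    },
    in_trans = mock_in_trans(request),
    sql_generation = backend_answer(text = request$template %||% ""),
    summarize = {
      mentions <- scan_variant_mentions(ctx)
      backend_answer(text = if (length(mentions))
        paste0("Variants mentioned: ", paste(mentions, collapse = ", "), ".")
      else "No variant mentions in context.")
    }
  )
}

#' Mock in trans extraction
#'
#' Scans the request context with generic HGVS-like mention patterns
#' (coding DNA changes, three-letter protein changes, one-letter
#' shorthand), removes every mention that matches the query variant's
#' own representation set, and returns the remainder deduplicated in
#' order of first occurrence.
#'
#' @param request A `pm3_request` with `task = "in_trans"`.
#' @return A `pm3_answer`; `extracted_variants` holds the candidates.
#' @export
mock_in_trans <- function(request) {
  stopifnot(identical(request$task, "in_trans"))
  mentions <- scan_variant_mentions(request$context)
  if (!is.null(request$variant_forms)) {
    t0 <- compile_patterns(request$variant_forms, "T0_full")
    own <- vapply(mentions, function(s) {
      m <- pm3_scan(s, t0)
      nrow(m) > 0 && any(m$start == 0L & m$end == nchar(s))
    }, logical(1))
    mentions <- mentions[!own]
  }
  first <- if (length(mentions)) mentions[1] else ""
  backend_answer(
    verdict = if (length(mentions)) "yes" else "no",
    extracted_variants = mentions,
    rationale_span = first,
    text = if (length(mentions))
      paste0("Candidate in trans variants: ", paste(mentions, collapse = ", "), ".")
    else "No in trans candidate found."
  )
}

#' HTTP adapter for a local model server
#'
#' Sends the request (rendered prompt template plus context) to an
#' Ollama-style generate endpoint and parses the JSON response. The
#' request/response pair is appended as JSON lines to `log_file` when
#' given. An unreachable or failing server raises a typed
#' `pm3_backend_unavailable` error.
#'
#' @param url Base URL of the server (e.g. `"http://localhost:11434"`).
#' @param model Model tag to request.
#' @param log_file Optional path for JSON-lines request logging.
#' @param timeout Request timeout in seconds.
#' @return A backend object of class `pm3_backend_http`.
#' @export
pm3_backend_http <- function(url, model, log_file = NULL, timeout = 60) {
  structure(list(url = sub("/$", "", url), model = model,
                 log_file = log_file, timeout = timeout),
            class = c("pm3_backend_http", "pm3_backend"))
}

#' @export
complete.pm3_backend_http <- function(backend, request) {
  stopifnot(inherits(request, "pm3_request"))
  prompt <- paste0(prompt_template(request$prompt_template_id),
                   "\n\nContext:\n", request$context)
  body <- jsonlite::toJSON(list(model = backend$model, prompt = prompt,
                                stream = FALSE,
                                options = list(temperature = 0)),
                           auto_unbox = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  status <- suppressWarnings(system2(
    "curl",
    c("-sS", "--max-time", as.character(backend$timeout),
      "-H", shQuote("Content-Type: application/json"),
      "-d", shQuote(body), shQuote(paste0(backend$url, "/api/generate"))),
    stdout = tmp, stderr = FALSE
  ))
  if (!identical(status, 0L) || !file.exists(tmp) || !file.size(tmp))
    pm3_abort(sprintf("model server unreachable at %s", backend$url),
              "pm3_backend_unavailable")
  resp <- tryCatch(jsonlite::fromJSON(tmp), error = function(e)
    pm3_abort("model server returned unparseable output", "pm3_backend_unavailable"))
  text <- resp$response %||% ""
  if (!is.null(backend$log_file)) {
    line <- jsonlite::toJSON(list(task = request$task, model = backend$model,
                                  prompt_chars = nchar(prompt), response = text),
                             auto_unbox = TRUE)
    cat(line, "\n", file = backend$log_file, append = TRUE, sep = "")
  }
  verdict <- if (grepl("^\\s*yes\\b", text, ignore.case = TRUE)) "yes"
             else if (grepl("^\\s*no\\b", text, ignore.case = TRUE)) "no"
             else "n/a"
  span <- scan_variant_mentions(text)
  span <- span[vapply(span, function(s) grepl(s, request$context, fixed = TRUE), logical(1))]
  backend_answer(verdict,
                 extracted_variants = scan_variant_mentions(text),
                 rationale_span = if (length(span)) span[1] else "",
                 text = text)
}
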