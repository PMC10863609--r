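#' Completion backends
#'
#' A backend wraps a text-completion model behind a uniform contract: given a
#' rendered prompt string it returns a completion string. Backends flagged
#' deterministic return identical completions for identical prompts.
#'
#' Built-in deterministic backends (no model weights, no network):
#' \describe{
#'   \item{noop}{echoes the choices in the given (retrieval) order — the
#'     re-ranker becomes the identity, so downstream metrics equal the
#'     retrieval-only metrics.}
#'   \item{oracle}{needs gold links; answers with the gold name first, then
#'     the remaining choices in given order. Entities absent from gold fall
#'     back to noop behaviour (recorded on the result). Downstream Hits@1
#'     equals the retriever's recall@K — the re-ranking upper bound.}
#'   \item{token_overlap}{orders choices by Jaccard similarity between the
#'     tokenized query and each tokenized choice name, ties broken by given
#'     order — a cheap lexical re-ranker.}
#' }
#'
#' @param name backend label.
#' @param complete function(prompt_string) -> completion string. It may read
#'   `attr(prompt, "bundle")`, the `bkf_prompt`, which [rerank()] attaches.
#' @param deterministic logical flag.
#' @return object of class `bkf_backend`.
#' @export
completion_backend <- function(name, complete, deterministic = TRUE) {
  structure(list(name = name, complete = complete,
                 deterministic = isTRUE(deterministic)),
            class = "bkf_backend")
}

prompt_bundle_of <- function(prompt) {
  b <- attr(prompt, "bundle")
  if (is.null(b))
    abort_bkf("this built-in backend requires the prompt bundle; call it via rerank()",
              "bkf_config_error")
  b
}

#' @rdname completion_backend
#' @param gold a `bkf_alignment` (required by the oracle backend).
#' @param h the hierarchy, used by the oracle to resolve gold term names.
#' @export
backend_noop <- function() {
  completion_backend("noop", function(prompt) {
    b <- prompt_bundle_of(prompt)
    paste0("Answer: ", paste(b$test_choices, collapse = "; "))
  })
}

#' @rdname completion_backend
#' @export
backend_oracle <- function(gold, h) {
  gold_term <- stats::setNames(gold$pairs$term_id, gold$pairs$entity_id)
  completion_backend("oracle", function(prompt) {
    b <- prompt_bundle_of(prompt)
    choices <- b$test_choices
    tid <- if (b$entity_id %in% names(gold_term))
      gold_term[[b$entity_id]] else NA_character_
    if (!is.na(tid) && tid %in% names(h$terms)) {
      gname <- h$terms[[tid]]$name
      i <- match(gname, choices)
      if (!is.na(i)) choices <- c(gname, choices[-i])
    } else {
      message(sprintf("oracle backend: entity '%s' absent from gold; using given order",
                      b$entity_id))
    }
    paste0("Answer: ", paste(choices, collapse = "; "))
  })
}

#' @rdname completion_backend
#' @export
backend_token_overlap <- function() {
  completion_backend("token-overlap", function(prompt) {
    b <- prompt_bundle_of(prompt)
    q <- unique(tokenize(b$test_query))
    jac <- vapply(b$test_choices, function(ch) {
      c_tok <- unique(tokenize(ch))
      u <- length(union(q, c_tok))
      if (u == 0L) 0 else length(intersect(q, c_tok)) / u
    }, 0, USE.NAMES = FALSE)
    ord <- order(-jac, seq_along(jac))  # stable: ties keep given order
    paste0("Answer: ", paste(b$test_choices[ord], collapse = "; "))
  })
}

#' @rdname completion_backend
#' @param backend_name one of "noop", "oracle", "token-overlap".
#' @export
builtin_backends <- function(gold = NULL, h = NULL) {
  out <- list(noop = backend_noop(), token_overlap = backend_token_overlap())
  if (!is.null(gold)) out$oracle <- backend_oracle(gold, h)
  out
}

#' Parse a completion into a re-ranked candidate permutation
#'
#' The mapping from the backend's free-text output to a ranking. Takes the
#' text after the first `Answer:` (or the whole completion if absent), splits
#' on `;` and newlines, normalizes each fragment (casefold, trim, collapse
#' whitespace) and matches fragments to candidate names by exact normalized
#' equality. First occurrence of each candidate wins; fragments matching no
#' candidate are dropped (hallucinations are never guessed at); candidates the
#' completion missed are backfilled in retrieval order. The result is always a
#' permutation of the candidate ids — worst case the retrieval order itself
#' with a parse report showing 0 matches.
#'
#' @param completion the raw completion string.
#' @param candidates a `bkf_candidates`.
#' @param name_of function(term id) -> display name (or a named character
#'   vector).
#' @return object of class `bkf_rerank`: `entity_id`, `ranked_terms`
#'   (permutation of the candidate ids), `raw_completion`, and `parse_report`
#'   with counts `matched`, `dropped`, `backfilled`.
#' @export
parse_answer <- function(completion, candidates, name_of) {
  if (nrow(candidates$ranked) == 0L)
    abort_bkf("empty candidate list", "bkf_validation_error")
  if (!is.function(name_of)) {
    tbl <- name_of
    name_of <- function(id) tbl[[id]]
  }
  ids <- candidates$ranked$term_id
  cand_names <- normalize_name(vapply(ids, name_of, ""))
  body <- sub("(?s)^.*?Answer:", "", completion, perl = TRUE)
  frags <- unlist(strsplit(body, "[;\n]"), use.names = FALSE)
  frags <- normalize_name(frags)
  frags <- frags[nzchar(frags)]
  hit <- match(frags, cand_names)
  dropped <- sum(is.na(hit))
  hit <- hit[!is.na(hit)]
  hit <- hit[!duplicated(hit)]
  backfill <- setdiff(seq_along(ids), hit)
  structure(list(entity_id = candidates$entity_id,
                 ranked_terms = ids[c(hit, backfill)],
                 raw_completion = completion,
                 parse_report = c(matched = length(hit), dropped = dropped,
                                  backfilled = length(backfill))),
            class = "bkf_rerank")
}

#' Re-rank a candidate list via a completion backend
#'
#' Sends the rendered prompt to the backend and parses the completion with
#' [parse_answer()]. Backend failures propagate as errors carrying the entity
#' id so callers can retry; they are never silently converted to a fallback
#' ranking.
#'
#' @param prompt a `bkf_prompt` built from `candidates`.
#' @param candidates the `bkf_candidates` behind the prompt.
#' @param backend a [completion_backend()].
#' @param h hierarchy for candidate names (may be omitted if `name_of` given).
#' @param name_of optional explicit id -> name mapping.
#' @return a `bkf_rerank`.
#' @export
rerank <- function(prompt, candidates, backend, h = NULL, name_of = NULL) {
  if (!identical(prompt$term_ids, candidates$ranked$term_id))
    abort_bkf("prompt was not built from these candidates", "bkf_config_error")
  if (is.null(name_of)) {
    if (is.null(h)) abort_bkf("need h or name_of", "bkf_config_error")
    name_of <- function(id) h$terms[[id]]$name
  }
  rendered <- prompt$rendered
  attr(rendered, "bundle") <- prompt
  completion <- tryCatch(backend$complete(rendered), error = function(e) {
    abort_bkf(sprintf("backend '%s' failed for entity '%s': %s",
                      backend$name, prompt$entity_id, conditionMessage(e)),
              "bkf_backend_error")
  })
  parse_answer(completion, candidates, name_of)
}

#' HTTP completion backend for a generic text-completion endpoint
#'
#' Posts `{"prompt": ..., "temperature": ..., "max_tokens": ...}` as JSON to
#' the configured URL and expects a JSON response whose completion text sits
#' at `choices[[1]]$text` (or top-level `text`). Temperature defaults to 0 so
#' completions are as deterministic as the provider allows. Transient failures
#' are retried with exponential backoff; persistent failure raises a
#' structured error — the backend never degrades to another ranking strategy.
#'
#' @param url endpoint URL.
#' @param auth_env name of the environment variable holding the bearer token
#'   (the token itself is never stored in the config).
#' @param temperature sampling temperature, default 0.
#' @param max_tokens completion length cap.
#' @param retries number of attempts on retriable (5xx / transport) failures.
#' @param backoff base seconds between attempts (doubled each retry).
#' @param transport function(body_list) -> list(status, text); injectable for
#'   testing. The default posts via the `httr` package.
#' @return a [completion_backend()] (flagged non-deterministic).
#' @export
http_backend <- function(url, auth_env = NULL, temperature = 0,
                         max_tokens = 512L, retries = 3L, backoff = 1,
                         transport = NULL) {
  if (is.null(transport)) {
    transport <- function(body) {
      if (!requireNamespace("httr", quietly = TRUE))
        abort_bkf("the httr package is required for the default HTTP transport",
                  "bkf_config_error")
      headers <- c("Content-Type" = "application/json")
      if (!is.null(auth_env) && nzchar(Sys.getenv(auth_env)))
        headers <- c(headers,
                     Authorization = paste("Bearer", Sys.getenv(auth_env)))
      resp <- httr::POST(url, httr::add_headers(.headers = headers),
                         body = jsonlite::toJSON(body, auto_unbox = TRUE))
      list(status = httr::status_code(resp),
           text = httr::content(resp, as = "text", encoding = "UTF-8"))
    }
  }
  completion_backend(
    name = paste0("http:", url), deterministic = FALSE,
    complete = function(prompt) {
      body <- list(prompt = as.character(prompt), temperature = temperature,
                   max_tokens = max_tokens)
      last <- NULL
      for (attempt in seq_len(retries)) {
        res <- tryCatch(transport(body), error = function(e)
          list(status = -1L, text = conditionMessage(e)))
        if (res$status >= 200 && res$status < 300) {
          parsed <- tryCatch(jsonlite::fromJSON(res$text,
                                                simplifyVector = FALSE),
                             error = function(e) NULL)
          out <- parsed$choices[[1]]$text %||% parsed$text %||% NULL
          if (is.null(out))
            abort_bkf("completion endpoint returned no text field",
                      "bkf_backend_error")
          return(out)
        }
        last <- res
        if (attempt < retries) Sys.sleep(backoff * 2^(attempt - 1))
      }
      abort_bkf(sprintf("completion endpoint failed after %d attempts (status %s)",
                        retries, last$status), "bkf_backend_error")
    })
}
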