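# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize free text for lexical retrieval
#'
#' Casefolds and splits on maximal runs of non-alphanumeric characters.
#' No stemming and no stopword removal; empty fragments are dropped.
#'
#' @param text a character scalar (or vector; vectors are collapsed with a
#'   space before splitting).
#' @return character vector of tokens; `character(0)` for empty input.
#' @examples
#' tokenize("Typhus, Epidemic Louse-Borne")
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) return(character(0))
  text <- paste(text, collapse = " ")
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# C-locale lexicographic sort: platform-independent tie-breaking everywhere.
lex_sort <- function(x) {
  if (length(x) == 0L) return(x)
  sort(x, method = "radix")
}

lex_order <- function(...) order(..., method = "radix")

# Normalize a generated name fragment for exact matching in parse_answer().
normalize_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Short stable hash used to stamp run artifacts with their configuration.
config_hash <- function(cfg) {
  digest::digest(cfg, algo = "xxhash64")
}

abort_bkf <- function(msg, class) {
  stop(structure(class = c(class, "bkfuse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
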