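#' Normalize a protein name for keyword matching
#'
#' Protein descriptions in sequence databases mix punctuation styles
#' (unicode dashes, primes, irregular whitespace, case). Keyword matching is
#' performed on a normal form so that, e.g., `"Glutathione S-Transferase"`
#' and `"glutathione S-transferase"` compare equal. Brackets and ASCII
#' hyphens are retained: hyphenated and space-separated spellings are
#' deliberately kept distinct (the accept list carries both spellings where
#' both occur in databases).
#'
#' @param x character vector of raw names.
#' @return character vector of normalized names: lower-cased, unicode
#'   dashes/minus mapped to `-`, primes mapped to `'`, whitespace runs
#'   collapsed to single spaces, leading/trailing whitespace removed.
#' @examples
#' normalize_name("Cytochrome  P450 1A2")
#' @export
normalize_name <- function(x) {
  x <- tolower(x)
  # unicode hyphen/dash/minus variants -> ASCII hyphen
  x <- gsub("[‐‑‒–—−]", "-", x)
  # prime / acute / right single quote -> ASCII apostrophe
  x <- gsub("[′ʹ´’]", "'", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

read_keyword_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("^#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Build a keyword configuration for XME selection
#'
#' @param accept character vector of accept-list name fragments (non-empty).
#' @param reject character vector of reject-list name fragments.
#' @param filter_words character vector of whole words that disqualify a
#'   name outright (default `"hypothetical"`, `"like"`).
#' @return an object of class `keyword_config` holding the normalized lists
#'   (original order preserved; first hit in list order is reported).
#' @seealso [default_keyword_config()] for the packaged lists.
#' @export
keyword_config <- function(accept, reject = character(),
                           filter_words = c("hypothetical", "like")) {
  accept <- normalize_name(as.character(accept))
  reject <- normalize_name(as.character(reject))
  filter_words <- normalize_name(as.character(filter_words))
  if (length(accept) == 0L || any(!nzchar(accept)))
    stop("accept list must be non-empty with no blank entries")
  if (any(!nzchar(reject)) || any(!nzchar(filter_words)))
    stop("keyword lists must not contain blank entries")
  structure(list(accept = accept, reject = reject,
                 filter_words = filter_words),
            class = "keyword_config")
}

#' Load the packaged XME accept/reject keyword configuration
#'
#' The packaged lists are the enzyme accept list (52 fragments covering the
#' classical XME families: alcohol/aldehyde dehydrogenases, cytochrome P450,
#' glutathione transferase, sulfotransferase, ...), a short reject list for
#' names that would otherwise be caught by a broad fragment (e.g.
#' glucose-6-phosphate dehydrogenase), and the word filters
#' `hypothetical`/`like`.
#'
#' @return a [keyword_config()] object.
#' @export
default_keyword_config <- function() {
  ext <- function(f) system.file("extdata", f, package = "xmeprofiler",
                                 mustWork = TRUE)
  keyword_config(
    accept = read_keyword_list(ext("xme_accept_keywords.txt")),
    reject = read_keyword_list(ext("xme_reject_keywords.txt")),
    filter_words = read_keyword_list(ext("xme_filter_words.txt"))
  )
}

#' Classify one protein name against the keyword configuration
#'
#' Evaluation order is fixed: (1) whole-word filter words (matched on word
#' boundaries, so `"ligase"` is never hit by `"like"` but
#' `"...C3-like protein"` is); (2) reject-list fragments (substring
#' containment); (3) accept-list fragments; (4) otherwise no match. The
#' first matching fragment in list order is recorded. Rejects deliberately
#' override accepts: a name such as "protein-glutamine
#' gamma-glutamyltransferase" must not survive via a transferase fragment.
#'
#' @param name a single protein name (raw; normalized internally).
#' @param config a [keyword_config()].
#' @return a list with elements `name`, `outcome` (one of `"accepted"`,
#'   `"rejected-by-reject-list"`, `"filtered-by-word"`,
#'   `"no-keyword-match"`) and `fragment` (the normalized matched fragment,
#'   or `""`).
#' @export
classify_name <- function(name, config) {
  stopifnot(inherits(config, "keyword_config"), length(name) == 1L)
  norm <- normalize_name(name)
  for (w in config$filter_words) {
    if (grepl(paste0("\\b", w, "\\b"), norm))
      return(list(name = name, outcome = "filtered-by-word", fragment = w))
  }
  for (frag in config$reject) {
    if (grepl(frag, norm, fixed = TRUE))
      return(list(name = name, outcome = "rejected-by-reject-list",
                  fragment = frag))
  }
  for (frag in config$accept) {
    if (grepl(frag, norm, fixed = TRUE))
      return(list(name = name, outcome = "accepted", fragment = frag))
  }
  list(name = name, outcome = "no-keyword-match", fragment = "")
}

#' Select putative XMEs from a vector of protein names
#'
#' Applies [classify_name()] to every name and returns the accepted set plus
#' a complete audit table (one row per input name) so the selection is
#' transparent and re-runnable under different lists.
#'
#' @param names character vector of protein names.
#' @param config a [keyword_config()]; defaults to the packaged lists.
#' @return a list with `accepted` (character vector of accepted names),
#'   `audit` (data.frame: `name`, `outcome`, `matched_fragment`) and
#'   `counts` (table of outcomes).
#' @export
select_xmes <- function(names, config = default_keyword_config()) {
  if (length(names) == 0L) {
    audit <- data.frame(name = character(), outcome = character(),
                        matched_fragment = character(),
                        stringsAsFactors = FALSE)
    return(list(accepted = character(), audit = audit,
                counts = table(factor(character(), levels = OUTCOME_LEVELS))))
  }
  rows <- lapply(names, classify_name, config = config)
  audit <- data.frame(
    name = vapply(rows, `[[`, "", "name"),
    outcome = vapply(rows, `[[`, "", "outcome"),
    matched_fragment = vapply(rows, `[[`, "", "fragment"),
    stringsAsFactors = FALSE
  )
  counts <- table(factor(audit$outcome, levels = OUTCOME_LEVELS))
  list(accepted = audit$name[audit$outcome == "accepted"],
       audit = audit, counts = counts)
}

OUTCOME_LEVELS <- c("accepted", "rejected-by-reject-list",
                    "filtered-by-word", "no-keyword-match")
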