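# Ontology mapping: reduce MeSH subject headings to a filtered single-word
# dictionary that parameterizes the latent-semantic engine.

#' Create a MeSH heading object
#'
#' A heading is one subject-heading label from a controlled vocabulary such
#' as MeSH, optionally carrying the tree numbers (hierarchy codes) attached
#' to the descriptor.
#'
#' @param label Heading text, e.g. `"Reproductive and Urinary Physiological
#'   Phenomena"`.  Must be non-empty after whitespace trimming.
#' @param tree_numbers Optional character vector of hierarchy codes.
#' @return An object of class `hgf_mesh_heading`.
#' @export
#' @examples
#' mesh_heading("Stroke", tree_numbers = "C10.228.140.300.775")
mesh_heading <- function(label, tree_numbers = character()) {
  if (!is_string(label)) {
    hgf_stop("heading label must be a single character string", "hgf_invalid_input")
  }
  label <- trimws(label)
  if (!nzchar(label)) {
    hgf_stop("heading label is empty", "hgf_invalid_input")
  }
  structure(
    list(label = label, tree_numbers = as.character(tree_numbers)),
    class = "hgf_mesh_heading"
  )
}

#' @export
print.hgf_mesh_heading <- function(x, ...) {
  cat("<MeSH heading> ", x$label, "\n", sep = "")
  if (length(x$tree_numbers)) {
    cat("  tree numbers: ", paste(x$tree_numbers, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Shared tokenizer: NFKD-normalize, strip diacritics, lowercase, then split
# on any run of non-alphanumeric characters (hyphens, commas, slashes all
# delimit).  Returns a list of token vectors, one per input string.
tokenize_text <- function(x) {
  x <- as.character(x)
  x <- stringi::stri_trans_general(x, "NFKD; [:Nonspacing Mark:] Remove; NFC")
  x <- stringi::stri_trans_tolower(x)
  lapply(stringi::stri_split_regex(x, "[^a-z0-9]+"), function(t) t[nzchar(t)])
}

#' Reduce a heading to single-word tokens
#'
#' Splits a heading label on every run of non-alphanumeric characters
#' (whitespace, hyphens, commas, ...) after lowercasing and stripping
#' diacritics.  All tokens are returned in their original order; filtering
#' (stop words, minimum length, de-duplication) happens later in
#' [filter_vocabulary()].
#'
#' @param heading An [mesh_heading()] object or a single character string.
#' @return Character vector of lowercase tokens.
#' @export
#' @examples
#' tokenize_heading("Reproductive and Urinary Physiological Phenomena")
#' tokenize_heading("Heart-Assist Devices")
tokenize_heading <- function(heading) {
  label <- if (inherits(heading, "hgf_mesh_heading")) heading$label else heading
  if (!is_string(label) || !nzchar(trimws(label))) {
    hgf_stop("heading label must be a single non-empty string", "hgf_invalid_input")
  }
  tokenize_text(label)[[1L]]
}

#' Collect the raw token multiset of a heading set
#'
#' Concatenates [tokenize_heading()] over all headings.  Duplicates are
#' deliberately retained at this stage; [filter_vocabulary()] performs the
#' de-duplication and filtering.
#'
#' @param headings List of [mesh_heading()] objects (or character strings).
#' @return Character vector of tokens (with duplicates).
#' @export
build_vocabulary <- function(headings) {
  if (length(headings) == 0L) {
    hgf_stop("heading list is empty", "hgf_invalid_input")
  }
  if (is.character(headings)) headings <- as.list(headings)
  unlist(lapply(headings, tokenize_heading), use.names = FALSE)
}

#' Filter a token multiset into a dictionary
#'
#' Removes duplicates, stop words, and words shorter than `min_length`
#' characters, then sorts the remaining words lexicographically (byte order,
#' locale-independent).  The result is the ordered dictionary over which all
#' term-document matrices are built.
#'
#' @param tokens Character vector of word tokens (duplicates allowed).
#' @param stoplist Character vector of stop words; defaults to the packaged
#'   English list ([default_stopwords()]).
#' @param min_length Minimum word length in characters (default 3): words
#'   with fewer characters are removed.
#' @param provenance Optional free-text description of the token source,
#'   recorded in the dictionary object and its serialized sidecar.
#' @return An object of class `hgf_dictionary` with elements `words`
#'   (ordered unique character vector) and `provenance`.
#' @export
#' @examples
#' filter_vocabulary(tokenize_heading("Reproductive and Urinary Physiological Phenomena"))
filter_vocabulary <- function(tokens,
                              stoplist = default_stopwords(),
                              min_length = 3L,
                              provenance = NULL) {
  if (!is.numeric(min_length) || length(min_length) != 1L || min_length < 1) {
    hgf_stop("min_length must be a single integer >= 1", "hgf_invalid_input")
  }
  min_length <- as.integer(min_length)
  tokens <- as.character(tokens)
  words <- unique(tokens)
  words <- words[nchar(words) >= min_length]
  words <- setdiff(words, stoplist)
  if (length(words) == 0L) {
    hgf_stop("no words survive filtering: dictionary would be empty", "hgf_empty_result")
  }
  words <- sort(words, method = "radix")
  structure(
    list(
      words = words,
      provenance = list(
        source = provenance %||% "token list",
        n_input_tokens = length(tokens),
        stoplist_size = length(stoplist),
        min_length = min_length
      )
    ),
    class = "hgf_dictionary"
  )
}

#' @export
print.hgf_dictionary <- function(x, ...) {
  cat("<hgf dictionary> ", length(x$words), " words (min length ",
    x$provenance$min_length, ", ", x$provenance$stoplist_size,
    " stop words)\n",
    sep = ""
  )
  shown <- head(x$words, 8L)
  cat("  ", paste(shown, collapse = ", "),
    if (length(x$words) > 8L) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Positions of words in a dictionary
#'
#' @param dictionary An `hgf_dictionary`.
#' @param words Character vector of words to look up.
#' @return Integer positions (1-based, `NA` for absent words).
#' @export
dictionary_index <- function(dictionary, words) {
  stopifnot(inherits(dictionary, "hgf_dictionary"))
  match(words, dictionary$words)
}

#' Packaged English stop-word list
#'
#' A fixed, versioned stop-word list shipped with the package (function
#' words such as "and", "the", "of").  Used by default in
#' [filter_vocabulary()]; supply your own list to override.
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  load_stopwords(system.file("extdata", "stopwords_en.txt", package = "hgf", mustWork = TRUE))
}

#' Read a stop-word list from file
#'
#' @param path Plain-text file, one stop word per line; blank lines and
#'   lines starting with `#` are ignored.
#' @return Character vector of stop words (lowercased).
#' @export
load_stopwords <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tolower(lines)
}

#' Read MeSH headings from a file
#'
#' Two dialects are supported: `flat_list` (one heading per line) and
#' `descriptor_export` (the ASCII descriptor export format in which each
#' record carries an `MH = <heading>` line followed by zero or more
#' `MN = <tree number>` lines; records are introduced by `*NEWRECORD`).
#'
#' @param source File path, connection, or character vector of lines.
#' @param dialect `"flat_list"` or `"descriptor_export"`.
#' @return List of [mesh_heading()] objects, input order preserved.
#' @export
load_mesh_headings <- function(source, dialect = c("flat_list", "descriptor_export")) {
  dialect <- match.arg(dialect)
  lines <- source_lines(source)
  if (dialect == "flat_list") {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      hgf_stop("no headings found in flat_list source", "hgf_invalid_input")
    }
    return(lapply(lines, mesh_heading))
  }
  # descriptor_export
  headings <- list()
  current_label <- NULL
  current_trees <- character()
  flush <- function() {
    if (!is.null(current_label)) {
      headings[[length(headings) + 1L]] <<- mesh_heading(current_label, current_trees)
    }
    current_label <<- NULL
    current_trees <<- character()
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\*NEWRECORD\\s*$", line)) {
      flush()
    } else if (grepl("^MH = ", line)) {
      if (!is.null(current_label)) {
        hgf_stop(
          sprintf("malformed descriptor export at line %d: second MH field in one record", i),
          "hgf_parse_error"
        )
      }
      current_label <- sub("^MH = ", "", line)
    } else if (grepl("^MN = ", line)) {
      if (is.null(current_label)) {
        hgf_stop(
          sprintf("malformed descriptor export at line %d: MN field before MH", i),
          "hgf_parse_error"
        )
      }
      current_trees <- c(current_trees, sub("^MN = ", "", line))
    }
  }
  flush()
  if (length(headings) == 0L) {
    hgf_stop("no descriptor records found in source", "hgf_invalid_input")
  }
  headings
}

#' Serialize a dictionary to a directory
#'
#' Writes `dictionary.txt` (one word per line, lexicographic order, UTF-8)
#' and `dictionary.json` (provenance and filter settings sidecar).
#'
#' @param dictionary An `hgf_dictionary`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_dictionary <- function(dictionary, dir) {
  stopifnot(inherits(dictionary, "hgf_dictionary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(dictionary$words, file.path(dir, "dictionary.txt"), useBytes = TRUE)
  jsonlite::write_json(
    c(dictionary$provenance, list(n_words = length(dictionary$words))),
    file.path(dir, "dictionary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Read a dictionary written by [write_dictionary()]
#'
#' @param dir Directory containing `dictionary.txt` (+ optional sidecar).
#' @return An `hgf_dictionary`.
#' @export
read_dictionary <- function(dir) {
  words <- readLines(file.path(dir, "dictionary.txt"), encoding = "UTF-8", warn = FALSE)
  if (length(words) == 0L) {
    hgf_stop("dictionary file is empty", "hgf_invalid_input")
  }
  side <- file.path(dir, "dictionary.json")
  prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  structure(
    list(
      words = words,
      provenance = list(
        source = prov$source %||% dir,
        n_input_tokens = prov$n_input_tokens %||% NA_integer_,
        stoplist_size = prov$stoplist_size %||% NA_integer_,
        min_length = prov$min_length %||% 3L
      )
    ),
    class = "hgf_dictionary"
  )
}
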