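# Corpus I/O: MEDLINE-format citation parsing and per-factor document
# collections that together form the knowledge space.

#' Create a citation record
#'
#' One PubMed-style citation: identifier, title, abstract, optional year.
#' At least one of title/abstract must be non-empty.
#'
#' @param pmid Identifier string (non-empty).
#' @param title Title text (may be empty if `abstract` is not).
#' @param abstract Abstract text (may be empty if `title` is not).
#' @param year Optional publication year (integer).
#' @return An object of class `hgf_citation`.
#' @export
citation_record <- function(pmid, title = "", abstract = "", year = NULL) {
  if (!is_string(pmid) || !nzchar(trimws(pmid))) {
    hgf_stop("pmid must be a non-empty string", "hgf_invalid_input")
  }
  title <- if (is.null(title) || is.na(title)) "" else as.character(title)
  abstract <- if (is.null(abstract) || is.na(abstract)) "" else as.character(abstract)
  if (!nzchar(title) && !nzchar(abstract)) {
    hgf_stop(
      sprintf("citation %s has neither title nor abstract", pmid),
      "hgf_invalid_input"
    )
  }
  structure(
    list(
      pmid = trimws(pmid), title = title, abstract = abstract,
      year = if (is.null(year) || is.na(year)) NA_integer_ else as.integer(year)
    ),
    class = "hgf_citation"
  )
}

#' Text of a citation
#'
#' Title and abstract concatenated with a single space; no other
#' normalization (tokenization happens downstream against the dictionary).
#'
#' @param record An [citation_record()].
#' @return Character scalar.
#' @export
document_text <- function(record) {
  stopifnot(inherits(record, "hgf_citation"))
  if (!nzchar(record$abstract)) {
    record$title
  } else if (!nzchar(record$title)) {
    record$abstract
  } else {
    paste(record$title, record$abstract)
  }
}

#' Parse MEDLINE tagged-format citations
#'
#' Reads the tagged plain-text export used by PubMed: fields look like
#' `PMID- 123`, `TI  - Title text`, `AB  - Abstract text`; continuation
#' lines are indented with spaces and are joined with single spaces.
#' Records are separated by blank lines.  Records lacking both a title and
#' an abstract are dropped with a warning.
#'
#' @param source File path, connection, or character vector of lines.
#' @return List of [citation_record()] objects.
#' @export
parse_medline <- function(source) {
  lines <- source_lines(source)
  records <- list()
  dropped <- 0L
  fields <- list()
  tag <- NULL
  flush <- function() {
    if (length(fields) == 0L) {
      return(invisible())
    }
    pmid <- fields[["PMID"]]
    ti <- fields[["TI"]] %||% ""
    ab <- fields[["AB"]] %||% ""
    yr <- NULL
    if (!is.null(fields[["DP"]])) {
      m <- regmatches(fields[["DP"]], regexpr("\\d{4}", fields[["DP"]]))
      if (length(m)) yr <- as.integer(m)
    }
    if (is.null(pmid) || (!nzchar(ti) && !nzchar(ab))) {
      dropped <<- dropped + 1L
    } else {
      records[[length(records) + 1L]] <<- citation_record(pmid, ti, ab, yr)
    }
    fields <<- list()
    tag <<- NULL
  }
  for (line in lines) {
    if (!nzchar(trimws(line))) {
      flush()
      next
    }
    m <- regmatches(line, regexec("^([A-Z]{1,4})\\s*- (.*)$", line))[[1L]]
    if (length(m) == 3L) {
      tag <- m[[2L]]
      value <- m[[3L]]
      fields[[tag]] <- if (is.null(fields[[tag]])) value else paste(fields[[tag]], value)
    } else if (grepl("^\\s+\\S", line) && !is.null(tag)) {
      fields[[tag]] <- paste(fields[[tag]], trimws(line))
    }
    # other lines (headers etc.) are ignored
  }
  flush()
  if (dropped > 0L) {
    hgf_warn(
      sprintf("dropped %d citation(s) lacking both title and abstract", dropped),
      "hgf_dropped_records"
    )
  }
  if (length(records) == 0L) {
    hgf_stop("no parseable MEDLINE records in source", "hgf_parse_error")
  }
  records
}

#' Write citations in MEDLINE tagged format
#'
#' @param records List of [citation_record()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_medline <- function(records, path) {
  out <- character(0)
  for (r in records) {
    stopifnot(inherits(r, "hgf_citation"))
    block <- c(sprintf("PMID- %s", r$pmid))
    if (nzchar(r$title)) block <- c(block, sprintf("TI  - %s", r$title))
    if (nzchar(r$abstract)) block <- c(block, sprintf("AB  - %s", r$abstract))
    if (!is.na(r$year)) block <- c(block, sprintf("DP  - %d", r$year))
    out <- c(out, block, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Create a factor specification
#'
#' A candidate factor (disease, sign/symptom, chemical compound, or
#' environmental/lifestyle factor) with the query synonyms used to retrieve
#' its literature.
#'
#' @param name Canonical factor label (unique within a factor set).
#' @param query_terms Character vector of retrieval synonyms (non-empty);
#'   defaults to `name`.
#' @param category One of `"disease/medical condition"`, `"sign/symptom"`,
#'   `"chemical compound"`, `"environmental/lifestyle"`.
#' @return An object of class `hgf_factor`.
#' @export
factor_spec <- function(name,
                        query_terms = name,
                        category = c(
                          "disease/medical condition", "sign/symptom",
                          "chemical compound", "environmental/lifestyle"
                        )) {
  if (!is_string(name) || !nzchar(trimws(name))) {
    hgf_stop("factor name must be a non-empty string", "hgf_invalid_input")
  }
  category <- match.arg(category)
  query_terms <- as.character(query_terms)
  query_terms <- query_terms[nzchar(trimws(query_terms))]
  if (length(query_terms) == 0L) {
    hgf_stop(sprintf("factor '%s' has no query terms", name), "hgf_invalid_input")
  }
  structure(
    list(name = trimws(name), query_terms = query_terms, category = category),
    class = "hgf_factor"
  )
}

#' Read a factor table
#'
#' Tab-separated file with columns `name`, `category`, `query_terms`
#' (semicolon-joined synonyms).
#'
#' @param path TSV file path.
#' @return List of [factor_spec()] objects.
#' @export
read_factor_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("name", "category", "query_terms")
  if (!all(required %in% names(df))) {
    hgf_stop(
      sprintf(
        "factor table must have columns %s",
        paste(required, collapse = ", ")
      ),
      "hgf_invalid_input"
    )
  }
  if (anyDuplicated(df$name)) {
    hgf_stop("factor names must be unique", "hgf_invalid_input")
  }
  lapply(seq_len(nrow(df)), function(i) {
    factor_spec(
      df$name[[i]],
      query_terms = strsplit(df$query_terms[[i]], ";", fixed = TRUE)[[1L]],
      category = df$category[[i]]
    )
  })
}

#' Packaged reference factor list
#'
#' The curated set of candidate contributing factors (diseases and medical
#' conditions, signs and symptoms, chemical compounds including the mineral
#' deficiency/overdose pairs and vitamins, and environmental/lifestyle
#' factors) used as the default factor universe for disease queries.
#'
#' @return List of [factor_spec()] objects.
#' @export
reference_factors <- function() {
  read_factor_table(
    system.file("extdata", "reference_factors.tsv", package = "hgf", mustWork = TRUE)
  )
}

new_collection <- function(factors, documents) {
  names(factors) <- vapply(factors, `[[`, character(1), "name")
  stopifnot(identical(sort(names(documents)), sort(names(factors))))
  documents <- documents[names(factors)]
  structure(
    list(factors = factors, documents = documents),
    class = "hgf_collection"
  )
}

#' Assemble a per-factor document collection
#'
#' Reads one MEDLINE file per factor (or accepts pre-parsed record lists)
#' and builds the collection whose union of documents forms the knowledge
#' space.  Per-factor document counts with a min/mean/max summary are
#' reported via `message()`.
#'
#' @param factors List of [factor_spec()] objects.
#' @param files Named character vector/list mapping factor name to a
#'   MEDLINE file path, or a named list of pre-parsed citation-record
#'   lists.  Every factor must be covered.
#' @param min_year,max_year Optional publication-year window; records with
#'   a known year outside the window are dropped (records without a year
#'   are kept).
#' @return An object of class `hgf_collection` with elements `factors`
#'   (named list) and `documents` (named list of citation-record lists).
#' @export
assemble_collection <- function(factors, files, min_year = NULL, max_year = NULL) {
  if (inherits(factors, "hgf_factor")) factors <- list(factors)
  fnames <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(fnames)) {
    hgf_stop("factor names must be unique", "hgf_invalid_input")
  }
  missing <- setdiff(fnames, names(files))
  if (length(missing)) {
    hgf_stop(
      sprintf("no document source for factor(s): %s", paste(missing, collapse = ", ")),
      "hgf_invalid_input"
    )
  }
  documents <- lapply(fnames, function(fn) {
    src <- files[[fn]]
    recs <- tryCatch(
      if (is.character(src)) parse_medline(src) else src,
      hgf_error = function(e) list()
    )
    if (!is.null(min_year) || !is.null(max_year)) {
      keep <- vapply(recs, function(r) {
        is.na(r$year) ||
          ((is.null(min_year) || r$year >= min_year) &&
            (is.null(max_year) || r$year <= max_year))
      }, logical(1))
      recs <- recs[keep]
    }
    recs
  })
  names(documents) <- fnames
  counts <- lengths(documents)
  if (any(counts == 0L)) {
    hgf_stop(
      sprintf(
        "factor(s) with zero usable documents: %s",
        paste(fnames[counts == 0L], collapse = ", ")
      ),
      "hgf_empty_factor"
    )
  }
  message(sprintf(
    "assembled %d factors, %d documents (per-factor min %d / mean %.1f / max %d)",
    length(fnames), sum(counts), min(counts), mean(counts), max(counts)
  ))
  new_collection(factors, documents)
}

#' @export
print.hgf_collection <- function(x, ...) {
  counts <- lengths(x$documents)
  cat("<hgf collection> ", length(x$factors), " factors, ",
    sum(counts), " documents\n",
    sep = ""
  )
  cat(sprintf(
    "  documents per factor: min %d / mean %.1f / max %d\n",
    min(counts), mean(counts), max(counts)
  ))
  invisible(x)
}

#' Per-factor document counts
#'
#' @param collection An `hgf_collection`.
#' @return Named integer vector of document counts.
#' @export
collection_counts <- function(collection) {
  stopifnot(inherits(collection, "hgf_collection"))
  lengths(collection$documents)
}
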