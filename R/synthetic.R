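# Synthetic-data generators: a MeSH-like heading fixture, planted-topic
# document collections with known ground truth, and samples from the
# tri-modal score model.  Everything is deterministic under a fixed seed.

#' Configuration for a planted-topic corpus
#'
#' Each factor is assigned a topic; its documents draw `1 - background_noise`
#' of their tokens uniformly from the topic's vocabulary and the rest from a
#' shared background vocabulary.  The defaults describe the standard
#' evaluation corpus used throughout the package: 6 topics with 4 factors
#' each, 50 documents per factor, 80 tokens per document, 30% background
#' noise.
#'
#' @param n_topics Number of planted topics.
#' @param words_per_topic Vocabulary size of each topic.
#' @param n_factors Number of factors (assigned to topics in blocks:
#'   factors `1..n_factors/n_topics` get topic 1, and so on).
#' @param docs_per_factor Documents generated per factor.
#' @param doc_length Tokens per document.
#' @param topic_of_factor Optional integer vector (length `n_factors`)
#'   overriding the block assignment.
#' @param background_noise Fraction of tokens drawn from the shared
#'   background vocabulary, in `[0, 1)`.
#' @param n_background_words Size of the background vocabulary.
#' @param seed Integer seed.
#' @return An object of class `hgf_corpus_config`.
#' @export
planted_corpus_config <- function(n_topics = 6L, words_per_topic = 12L,
                                  n_factors = 24L, docs_per_factor = 50L,
                                  doc_length = 80L, topic_of_factor = NULL,
                                  background_noise = 0.3,
                                  n_background_words = 40L, seed = 1L) {
  counts <- c(n_topics, words_per_topic, n_factors, docs_per_factor, doc_length, n_background_words)
  if (any(counts < 1)) hgf_stop("all counts must be positive", "hgf_invalid_input")
  if (background_noise < 0 || background_noise >= 1) {
    hgf_stop("background_noise must lie in [0, 1)", "hgf_invalid_input")
  }
  if (is.null(topic_of_factor)) {
    topic_of_factor <- rep(seq_len(n_topics), length.out = n_factors)
    topic_of_factor <- sort(topic_of_factor)
  }
  if (length(topic_of_factor) != n_factors ||
    any(topic_of_factor < 1 | topic_of_factor > n_topics)) {
    hgf_stop("topic_of_factor must map every factor to a valid topic", "hgf_invalid_input")
  }
  structure(
    list(
      n_topics = as.integer(n_topics), words_per_topic = as.integer(words_per_topic),
      n_factors = as.integer(n_factors), docs_per_factor = as.integer(docs_per_factor),
      doc_length = as.integer(doc_length),
      topic_of_factor = as.integer(topic_of_factor),
      background_noise = background_noise,
      n_background_words = as.integer(n_background_words),
      seed = as.integer(seed)
    ),
    class = "hgf_corpus_config"
  )
}

#' Topic and background vocabularies of a corpus configuration
#'
#' Word forms are deterministic functions of the configuration sizes
#' (`t<topic>w<index>` and `bg<index>`), all alphanumeric and at least
#' three characters, so they survive dictionary filtering.
#'
#' @param config An [planted_corpus_config()].
#' @return List with `topics` (list of character vectors, one per topic)
#'   and `background` (character vector).
#' @export
topic_vocabulary <- function(config) {
  stopifnot(inherits(config, "hgf_corpus_config"))
  topics <- lapply(seq_len(config$n_topics), function(t) {
    sprintf("t%02dw%02d", t, seq_len(config$words_per_topic))
  })
  list(
    topics = topics,
    background = sprintf("bg%03d", seq_len(config$n_background_words))
  )
}

#' Generate a MeSH-like heading fixture
#'
#' Produces multiword headings drawn from the synthetic topic and
#' background vocabularies, guaranteeing that the union of heading tokens
#' covers every vocabulary word (so a dictionary built from the fixture
#' indexes the whole corpus).  Some headings join their words with the
#' stop word "and", exercising the filtering step.
#'
#' @param n_headings Number of headings (>= 1).
#' @param config Corpus configuration whose vocabularies to cover.
#' @param seed Integer seed (defaults to the configuration's).
#' @return List of [mesh_heading()] objects.
#' @export
generate_mesh_fixture <- function(n_headings, config = planted_corpus_config(),
                                  seed = config$seed) {
  if (n_headings < 1L) hgf_stop("n_headings must be >= 1", "hgf_invalid_input")
  vocab <- topic_vocabulary(config)
  words <- c(unlist(vocab$topics, use.names = FALSE), vocab$background)
  withr::with_seed(seed, {
    slot <- rep(seq_len(n_headings), length.out = length(words))
    groups <- split(words, slot)
    labels <- vapply(seq_len(n_headings), function(i) {
      grp <- groups[[as.character(i)]]
      if (is.null(grp)) grp <- sample(words, 3L)
      sep <- if (i %% 2L == 0L) " and " else " "
      paste(sample(grp), collapse = sep)
    }, character(1))
    lapply(labels, mesh_heading)
  })
}

#' Generate a planted-topic document collection
#'
#' @param config An [planted_corpus_config()].
#' @return List with `collection` (an `hgf_collection`) and `truth`
#'   (list: `topic_of_factor` named by factor, `topic_words`,
#'   `background_words`).
#' @export
generate_planted_corpus <- function(config = planted_corpus_config()) {
  stopifnot(inherits(config, "hgf_corpus_config"))
  vocab <- topic_vocabulary(config)
  fnames <- sprintf("factor%02d", seq_len(config$n_factors))
  withr::with_seed(config$seed, {
    documents <- lapply(seq_len(config$n_factors), function(fi) {
      topic_words <- vocab$topics[[config$topic_of_factor[[fi]]]]
      lapply(seq_len(config$docs_per_factor), function(di) {
        n_bg <- rbinom(1L, config$doc_length, config$background_noise)
        toks <- c(
          sample(topic_words, config$doc_length - n_bg, replace = TRUE),
          sample(vocab$background, n_bg, replace = TRUE)
        )
        toks <- sample(toks)
        n_title <- min(5L, length(toks))
        citation_record(
          pmid = sprintf("9%02d%05d", fi, di),
          title = paste(toks[seq_len(n_title)], collapse = " "),
          abstract = paste(toks[-seq_len(n_title)], collapse = " "),
          year = sample(1992:2012, 1L)
        )
      })
    })
    names(documents) <- fnames
    factors <- lapply(seq_len(config$n_factors), function(fi) {
      factor_spec(fnames[[fi]],
        query_terms = fnames[[fi]],
        category = "disease/medical condition"
      )
    })
    truth <- list(
      topic_of_factor = setNames(config$topic_of_factor, fnames),
      topic_words = vocab$topics,
      background_words = vocab$background
    )
    list(collection = new_collection(factors, documents), truth = truth)
  })
}

#' Sample association scores from the tri-modal model
#'
#' Component `i` is chosen with probability proportional to
#' `alpha_i * sigma_i` (each unnormalized component integrates to
#' `alpha_i * sigma_i * sqrt(pi)`), and the value is drawn from a Gaussian
#' with mean `mu_i` and standard deviation `sigma_i / sqrt(2)` — the
#' distribution whose density is proportional to the fitted component
#' curve `exp(-((x - mu_i)/sigma_i)^2)`.  Samples are clipped to
#' `[-1, 1]`; for the narrow, well-inside-range components used in
#' practice the clipped boundary mass is negligible.
#'
#' @param params An [trimodal_params()].
#' @param n Number of samples (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` within `[-1, 1]`.
#' @export
sample_trimodal <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "hgf_trimodal_params"))
  if (n < 1L) hgf_stop("n must be >= 1", "hgf_invalid_input")
  w <- params$alpha * params$sigma
  if (sum(w) <= 0) {
    hgf_stop("all component weights are zero; nothing to sample", "hgf_invalid_input")
  }
  draw <- function() {
    comp <- sample.int(3L, n, replace = TRUE, prob = w / sum(w))
    x <- rnorm(n, mean = params$mu[comp], sd = params$sigma[comp] / sqrt(2))
    pmin(pmax(x, -1), 1)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Write a synthetic corpus to disk
#'
#' Emits one MEDLINE-format file per factor, a `factors.tsv` table, and a
#' `truth.json` ground-truth sidecar, so the on-disk pipeline entry points
#' can run against generated data.
#'
#' @param corpus Result of [generate_planted_corpus()].
#' @param dir Output directory (created if absent).
#' @return Named character vector mapping factor name to its MEDLINE file.
#' @export
write_corpus_files <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  collection <- corpus$collection
  files <- vapply(names(collection$documents), function(fn) {
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9]+", "_", fn), ".medline"))
    write_medline(collection$documents[[fn]], path)
    path
  }, character(1))
  df <- data.frame(
    name = names(collection$factors),
    category = vapply(collection$factors, `[[`, character(1), "category"),
    query_terms = vapply(
      collection$factors,
      function(f) paste(f$query_terms, collapse = ";"), character(1)
    ),
    stringsAsFactors = FALSE
  )
  write.table(df, file.path(dir, "factors.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(corpus$truth)) {
    jsonlite::write_json(corpus$truth, file.path(dir, "truth.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  files
}
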