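# Shared fixtures, all built in code.

# Dictionary over an explicit word list (no stop-word or length filtering,
# so tests control the vocabulary exactly).
tiny_dictionary <- function(words) {
  filter_vocabulary(words, stoplist = character(0), min_length = 1L)
}

medline_fixture_lines <- function() {
  c(
    "PMID- 1001",
    "TI  - Stroke risk and blood pressure",
    "AB  - Elevated blood pressure raises stroke",
    "      risk in older adults and is treatable",
    "      with common medication regimes",
    "      according to several cohort studies.",
    "DP  - 2001 Mar",
    "",
    "PMID- 1002",
    "TI  - Title only citation",
    "DP  - 1999",
    "",
    "PMID- 1003",
    "AB  - Abstract only citation about magnesium.",
    ""
  )
}

# A 3-factor collection with hand-written documents.
tiny_collection <- function() {
  recs <- function(...) lapply(list(...), function(x) do.call(citation_record, x))
  factors <- list(
    factor_spec("stroke", category = "disease/medical condition"),
    factor_spec("migraine", category = "disease/medical condition"),
    factor_spec("magnesium", category = "chemical compound")
  )
  documents <- list(
    stroke = recs(
      list(pmid = "s1", title = "stroke risk", abstract = "blood pressure stroke"),
      list(pmid = "s2", title = "stroke outcome", abstract = "stroke treatment pressure")
    ),
    migraine = recs(
      list(pmid = "m1", title = "migraine headache", abstract = "magnesium migraine relief"),
      list(pmid = "m2", title = "migraine trigger", abstract = "headache stress migraine")
    ),
    magnesium = recs(
      list(pmid = "g1", title = "magnesium deficiency", abstract = "magnesium supplement relief"),
      list(pmid = "g2", title = "magnesium intake", abstract = "dietary magnesium deficiency")
    )
  )
  hgf:::new_collection(factors, documents)
}

# Small planted corpus for engine tests.
small_corpus_config <- function(seed = 11L) {
  planted_corpus_config(
    n_topics = 3L, words_per_topic = 6L, n_factors = 6L,
    docs_per_factor = 8L, doc_length = 30L,
    background_noise = 0.2, n_background_words = 12L, seed = seed
  )
}

# Dictionary covering everything a planted corpus can emit.
corpus_dictionary <- function(config) {
  vocab <- topic_vocabulary(config)
  tiny_dictionary(c(unlist(vocab$topics), vocab$background))
}

# Independent naive token-count oracle (dictionary words only).
naive_count_oracle <- function(text, words) {
  toks <- hgf:::tokenize_text(text)[[1L]]
  vapply(words, function(w) sum(toks == w), numeric(1))
}

well_separated_params <- function() {
  trimodal_params(c(5, 10, 5), c(-0.4, 0.05, 0.45), c(0.1, 0.12, 0.1))
}
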