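test_that("headings reduce to lowercase single words in original order", {
  expect_identical(
    tokenize_heading("Reproductive and Urinary Physiological Phenomena"),
    c("reproductive", "and", "urinary", "physiological", "phenomena")
  )
  expect_identical(tokenize_heading("Stroke"), "stroke")
  # hyphens, commas, slashes all delimit
  expect_identical(tokenize_heading("Heart-Assist Devices"), c("heart", "assist", "devices"))
  expect_identical(tokenize_heading("Abnormalities, Drug-Induced"), c("abnormalities", "drug", "induced"))
  # diacritics are stripped before tokenizing
  expect_identical(tokenize_heading("Café au Lait Spots"), c("cafe", "au", "lait", "spots"))
  expect_error(tokenize_heading("   "), class = "hgf_invalid_input")
})

test_that("vocabulary collection concatenates tokens and retains duplicates", {
  expect_identical(build_vocabulary(c("A B", "B C")), c("a", "b", "b", "c"))
  expect_length(build_vocabulary(list(mesh_heading("Reproductive and Urinary Physiological Phenomena"))), 5L)
  headings <- replicate(100, "alpha beta gamma")
  expect_length(build_vocabulary(headings), 300L)
  expect_error(build_vocabulary(list()), class = "hgf_invalid_input")
})

test_that("filtering removes duplicates, stop words and short words, and sorts", {
  d <- filter_vocabulary(tokenize_heading("Reproductive and Urinary Physiological Phenomena"))
  expect_identical(d$words, c("phenomena", "physiological", "reproductive", "urinary"))
  expect_identical(
    filter_vocabulary(c("aa", "abc"), stoplist = character(0), min_length = 3)$words,
    "abc"
  )
  # alphanumeric tokens such as vitamin names are kept
  expect_true("b12" %in% filter_vocabulary(c("vitamin", "b12"), stoplist = character(0))$words)
  expect_error(filter_vocabulary(c("a", "an")), class = "hgf_empty_result")
  expect_error(filter_vocabulary("word", min_length = 0), class = "hgf_invalid_input")
})

test_that("filtering matches brute-force set arithmetic on a synthetic heading set", {
  words_pool <- c(
    "and", "the", "of", "ab", "xy", "stroke", "risk", "pressure",
    "magnesium", "vitamin", "b12", "disease", "factor", "cohort"
  )
  withr::with_seed(99, {
    headings <- replicate(1000, paste(sample(words_pool, sample(2:5, 1), replace = TRUE), collapse = " "))
  })
  tokens <- build_vocabulary(headings)
  stoplist <- default_stopwords()
  d <- filter_vocabulary(tokens, stoplist = stoplist, min_length = 3)
  oracle <- sort(setdiff(unique(tokens)[nchar(unique(tokens)) >= 3], stoplist), method = "radix")
  expect_identical(d$words, oracle)
})

test_that("dictionary invariants hold and filtering is idempotent", {
  headings <- generate_mesh_fixture(20, small_corpus_config(), seed = 3)
  d <- filter_vocabulary(build_vocabulary(headings))
  expect_false(anyDuplicated(d$words) > 0)
  expect_true(all(nchar(d$words) >= 3))
  expect_length(intersect(d$words, default_stopwords()), 0L)
  expect_lte(length(d$words), length(unique(build_vocabulary(headings))))
  d2 <- filter_vocabulary(d$words)
  expect_identical(d2$words, d$words)
})

test_that("serialized dictionaries are byte-identical across identical runs", {
  headings <- generate_mesh_fixture(15, small_corpus_config(), seed = 5)
  d <- filter_vocabulary(build_vocabulary(headings), provenance = "fixture")
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_dictionary(d, dir1)
  write_dictionary(d, dir2)
  expect_identical(
    readBin(file.path(dir1, "dictionary.txt"), "raw", 1e6),
    readBin(file.path(dir2, "dictionary.txt"), "raw", 1e6)
  )
  d_back <- read_dictionary(dir1)
  expect_identical(d_back$words, d$words)
})

test_that("heading files load in both dialects", {
  flat <- withr::local_tempfile(lines = c("Stroke", "Migraine Disorders", "Magnesium"))
  h <- load_mesh_headings(flat, "flat_list")
  expect_length(h, 3L)
  expect_identical(h[[2L]]$label, "Migraine Disorders")

  export <- c(
    "*NEWRECORD",
    "MH = Stroke",
    "MN = C10.228.140.300.775",
    "MN = C14.907.253.855",
    "*NEWRECORD",
    "MH = Magnesium",
    "MN = D01.268.549"
  )
  h2 <- load_mesh_headings(export, "descriptor_export")
  expect_length(h2, 2L)
  expect_identical(h2[[1L]]$tree_numbers, c("C10.228.140.300.775", "C14.907.253.855"))
  expect_error(load_mesh_headings(character(0), "flat_list"), class = "hgf_invalid_input")
  expect_error(
    load_mesh_headings(c("MN = C10.1", "MH = Stroke"), "descriptor_export"),
    class = "hgf_parse_error"
  )
})
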