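test_that("term counting matches a naive scan and ignores out-of-dictionary words", {
  d <- tiny_dictionary(c("risk", "stroke"))
  counts <- count_terms("stroke stroke risk", d)
  expect_equal(counts[dictionary_index(d, c("stroke", "risk"))], c(2, 1))
  expect_equal(count_terms("completely unrelated words", d), c(0, 0))
  cfg <- small_corpus_config()
  dict <- corpus_dictionary(cfg)
  withr::with_seed(21, {
    text <- paste(sample(c(dict$words, "outside", "vocab"), 200, replace = TRUE), collapse = " ")
  })
  expect_equal(count_terms(text, dict), unname(naive_count_oracle(text, dict$words)))
})

test_that("identity weighting reproduces raw counts and log-entropy matches hand computation", {
  d <- tiny_dictionary(c("alpha", "beta"))
  col <- hgf:::new_collection(
    list(factor_spec("f1"), factor_spec("f2")),
    list(
      f1 = list(citation_record("1", title = "alpha")),
      f2 = list(citation_record("2", title = "beta beta"))
    )
  )
  tdm <- build_matrix(col, d, weighting = "none")
  expect_equal(as.matrix(tdm$values), matrix(c(1, 0, 0, 2), 2), ignore_attr = TRUE)

  # hand-computed log-entropy on a denser 2x2: global weight
  # g_i = 1 + sum_j p_ij log(p_ij) / log(n); local weight log(1 + tf)
  col2 <- hgf:::new_collection(
    list(factor_spec("f1"), factor_spec("f2")),
    list(
      f1 = list(citation_record("1", title = "alpha alpha beta")),
      f2 = list(citation_record("2", title = "alpha beta beta beta"))
    )
  )
  tdm2 <- build_matrix(col2, d, weighting = "log-entropy")
  counts <- matrix(c(2, 1, 1, 3), 2) # rows alpha, beta; cols doc1, doc2
  g <- vapply(1:2, function(i) {
    p <- counts[i, ] / sum(counts[i, ])
    1 + sum(p * log(p)) / log(2)
  }, numeric(1))
  expect_equal(as.matrix(tdm2$values), diag(g) %*% log1p(counts), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("nonzero pattern of the matrix matches the per-document count oracle", {
  cfg <- small_corpus_config()
  corp <- generate_planted_corpus(cfg)
  dict <- corpus_dictionary(cfg)
  tdm <- build_matrix(corp$collection, dict, weighting = "none")
  texts <- unlist(lapply(corp$collection$documents, function(rs) vapply(rs, document_text, character(1))))
  oracle <- vapply(texts, naive_count_oracle, numeric(length(dict$words)), words = dict$words)
  expect_equal(unname(as.matrix(tdm$values)), unname(oracle))
  expect_error(
    build_matrix(corp$collection, tiny_dictionary("absentword")),
    class = "hgf_empty_result"
  )
})

test_that("decomposition recovers singular structure and enforces the rank cap", {
  d <- tiny_dictionary(c("aaa", "bbb"))
  col <- hgf:::new_collection(
    list(factor_spec("f1"), factor_spec("f2")),
    list(
      f1 = list(citation_record("1", title = paste(rep("aaa", 3), collapse = " "))),
      f2 = list(citation_record("2", title = "bbb"))
    )
  )
  tdm <- build_matrix(col, d, weighting = "none") # diag(3, 1)
  sp <- decompose_space(tdm, k = 2)
  expect_equal(sp$singular_values, c(3, 1))
  expect_error(decompose_space(tdm, k = 3), regexp = "rank", class = "hgf_invalid_input")

  cfg <- small_corpus_config()
  tdm2 <- build_matrix(generate_planted_corpus(cfg)$collection, corpus_dictionary(cfg))
  full <- decompose_space(tdm2, variance = 1)
  sp2 <- if (full$k < full$rank) decompose_space(tdm2, k = full$rank) else full
  dense <- as.matrix(tdm2$values)
  recon <- sp2$term_basis %*% t(sp2$doc_vectors)
  expect_lt(max(abs(recon - dense)) / max(abs(dense)), 1e-8)
  # rank-k truncation error equals the dense full-SVD oracle
  k <- 5L
  spk <- decompose_space(tdm2, k = k)
  sv <- svd(dense)
  oracle_recon <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
  my_recon <- spk$term_basis %*% t(spk$doc_vectors)
  expect_equal(
    norm(dense - my_recon, "F"), norm(dense - oracle_recon, "F"),
    tolerance = 1e-10
  )
  # orthonormal basis, non-increasing singular values
  expect_lt(max(abs(crossprod(sp2$term_basis) - diag(sp2$k))), 1e-8)
  expect_true(all(diff(sp2$singular_values) <= 1e-12))
  expect_true(all(sp2$singular_values > 0))
})

test_that("query fold-in is consistent with indexed documents and linear", {
  cfg <- small_corpus_config()
  corp <- generate_planted_corpus(cfg)
  dict <- corpus_dictionary(cfg)
  tdm <- build_matrix(corp$collection, dict, weighting = "none")
  full <- decompose_space(tdm, variance = 1)
  sp <- if (full$k < full$rank) decompose_space(tdm, k = full$rank) else full
  # a document's own text folds onto its (inverse-singular-value scaled) coordinates
  text <- document_text(corp$collection$documents[[1L]][[1L]])
  folded <- fold_in(text, sp)
  expect_equal(folded, sp$doc_vectors[1L, ] / sp$singular_values, tolerance = 1e-6)
  # single-word query is the term's basis row scaled by inverse singular values
  w <- dict$words[[1L]]
  expect_equal(fold_in(w, sp), sp$term_basis[1L, ] / sp$singular_values, tolerance = 1e-10)
  # multiword fold-in equals the sum of single-word fold-ins
  w2 <- dict$words[[2L]]
  expect_equal(
    fold_in(paste(w, w2), sp),
    fold_in(w, sp) + fold_in(w2, sp),
    tolerance = 1e-10
  )
  expect_error(fold_in("nodictionaryword", sp), regexp = "nodictionaryword", class = "hgf_unknown_query")
})

test_that("cosine similarity satisfies its closed forms and degenerate contract", {
  v <- c(0.3, -1.2, 4)
  expect_equal(cosine_similarity(v, v), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), sqrt(2) / 2, tolerance = 1e-4)
  # scale invariance
  expect_equal(cosine_similarity(3.7 * v, 0.2 * c(1, 5, -2)), cosine_similarity(v, c(1, 5, -2)))
  expect_warning(s <- cosine_similarity(c(0, 0), c(1, 1)), class = "hgf_zero_vector")
  expect_true(is.na(s))
})

test_that("rankings cover every factor once, match a brute-force loop, and are order-stable", {
  cfg <- small_corpus_config()
  corp <- generate_planted_corpus(cfg)
  dict <- corpus_dictionary(cfg)
  sp <- decompose_space(build_matrix(corp$collection, dict))
  res <- rank_factors("t01w01 t01w03", sp)
  expect_setequal(res$factor, names(corp$collection$documents))
  expect_false(anyDuplicated(res$factor) > 0)
  expect_true(all(diff(res$score) <= 1e-15))
  expect_true(all(res$score >= -1 & res$score <= 1))
  # brute-force loop oracle over factor vectors
  q <- fold_in("t01w01 t01w03", sp) * sp$singular_values
  oracle <- vapply(rownames(sp$factor_vectors), function(f) {
    u <- sp$factor_vectors[f, ]
    sum(q * u) / (sqrt(sum(q^2)) * sqrt(sum(u^2)))
  }, numeric(1))
  expect_equal(
    res$score[match(names(oracle), res$factor)],
    unname(oracle),
    tolerance = 1e-10
  )
  # the planted same-topic factors outrank the rest
  same <- names(which(corp$truth$topic_of_factor == 1L))
  expect_lt(
    median(match(same, res$factor)),
    median(match(setdiff(res$factor, same), res$factor))
  )
})

test_that("document input order does not change factor scores", {
  cfg <- small_corpus_config()
  corp <- generate_planted_corpus(cfg)
  dict <- corpus_dictionary(cfg)
  sp1 <- decompose_space(build_matrix(corp$collection, dict), k = 10)
  shuffled <- corp$collection
  withr::with_seed(4, {
    shuffled$documents <- lapply(shuffled$documents, function(recs) recs[sample(seq_along(recs))])
  })
  sp2 <- decompose_space(build_matrix(shuffled, dict), k = 10)
  r1 <- rank_factors("t02w01", sp1)
  r2 <- rank_factors("t02w01", sp2)
  expect_equal(
    r1$score[match(r2$factor, r1$factor)], r2$score,
    tolerance = 1e-10
  )
})

test_that("model bundles round-trip through disk", {
  cfg <- small_corpus_config()
  corp <- generate_planted_corpus(cfg)
  sp <- decompose_space(build_matrix(corp$collection, corpus_dictionary(cfg)), k = 6)
  dir <- withr::local_tempdir()
  save_space(sp, dir)
  sp2 <- load_space(dir)
  r1 <- rank_factors("t03w02", sp)
  r2 <- rank_factors("t03w02", sp2)
  expect_identical(r1$factor, r2$factor)
  expect_equal(r1$score, r2$score, tolerance = 1e-9)
})
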