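# Latent-semantic engine: weighted term-document matrix over the dictionary,
# truncated singular value decomposition (the reduced eigen space), query
# fold-in, and cosine ranking of factors.

#' Count dictionary terms in a text
#'
#' Bag-of-words counts using the same tokenizer as the dictionary builder;
#' out-of-dictionary tokens are ignored.  An all-zero vector is a valid
#' result.
#'
#' @param text Character scalar.
#' @param dictionary An `hgf_dictionary`.
#' @return Numeric vector of counts, one per dictionary word (unnamed, in
#'   dictionary order).
#' @export
count_terms <- function(text, dictionary) {
  stopifnot(inherits(dictionary, "hgf_dictionary"))
  n <- length(dictionary$words)
  if (n == 0L) hgf_stop("dictionary is empty", "hgf_invalid_input")
  toks <- tokenize_text(text)[[1L]]
  idx <- match(toks, dictionary$words)
  tabulate(idx[!is.na(idx)], nbins = n)
}

# Global term weights for a raw count matrix (terms x documents).
# log-entropy: g_i = 1 + sum_j p_ij log p_ij / log n  (p_ij = tf_ij / gf_i);
# tf-idf: g_i = log(n / df_i).  Terms absent from the corpus get weight 1
# (log-entropy) or 0 (tf-idf); their rows are zero either way.
global_weights <- function(counts, weighting) {
  n_docs <- ncol(counts)
  if (weighting == "none") {
    return(rep(1, nrow(counts)))
  }
  if (weighting == "tf-idf") {
    df <- Matrix::rowSums(counts > 0)
    w <- ifelse(df > 0, log(n_docs / df), 0)
    return(as.numeric(w))
  }
  # log-entropy
  gf <- Matrix::rowSums(counts)
  if (n_docs <= 1L) {
    return(rep(1, nrow(counts)))
  }
  tc <- as(counts, "TsparseMatrix")
  p <- tc@x / gf[tc@i + 1L]
  contrib <- p * log(p)
  ent <- rep(0, nrow(counts))
  agg <- tapply(contrib, tc@i, sum)
  ent[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  w <- 1 + ent / log(n_docs)
  w[gf == 0] <- 1
  w
}

# Apply local log(1 + tf) (log-entropy) or raw tf (none, tf-idf) and the
# global weight vector to a sparse count matrix.
apply_weighting <- function(counts, gw, weighting) {
  m <- as(counts, "CsparseMatrix")
  if (weighting == "log-entropy") m@x <- log1p(m@x)
  Matrix::Diagonal(x = gw) %*% m
}

#' Build the weighted term-document matrix
#'
#' One column per citation (title+abstract), one row per dictionary word.
#' Raw counts are transformed by the chosen weighting scheme:
#' `"log-entropy"` (default; `log(1+tf)` local weight times a global
#' entropy weight), `"tf-idf"`, or `"none"` (raw counts).
#'
#' @param collection An `hgf_collection`.
#' @param dictionary An `hgf_dictionary`.
#' @param weighting Weighting scheme name.
#' @return An object of class `hgf_tdm` with elements `dictionary`,
#'   `doc_ids` (data frame: factor, index), `values` (sparse weighted
#'   matrix), `counts` (sparse raw counts), `weighting`, `global_weights`.
#' @export
build_matrix <- function(collection, dictionary,
                         weighting = c("log-entropy", "none", "tf-idf")) {
  stopifnot(inherits(collection, "hgf_collection"))
  weighting <- match.arg(weighting)
  texts <- unlist(lapply(collection$documents, function(recs) {
    vapply(recs, document_text, character(1))
  }), use.names = FALSE)
  doc_ids <- data.frame(
    factor = rep(names(collection$documents), lengths(collection$documents)),
    index = unlist(lapply(lengths(collection$documents), seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  n_terms <- length(dictionary$words)
  tok_lists <- tokenize_text(texts)
  triplets <- lapply(seq_along(tok_lists), function(j) {
    idx <- match(tok_lists[[j]], dictionary$words)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) {
      return(NULL)
    }
    tab <- table(idx)
    list(i = as.integer(names(tab)), j = rep.int(j, length(tab)), x = as.numeric(tab))
  })
  triplets <- triplets[!vapply(triplets, is.null, logical(1))]
  if (length(triplets) == 0L) {
    hgf_stop(
      "corpus shares no vocabulary with the dictionary",
      "hgf_empty_result"
    )
  }
  counts <- Matrix::sparseMatrix(
    i = unlist(lapply(triplets, `[[`, "i")),
    j = unlist(lapply(triplets, `[[`, "j")),
    x = unlist(lapply(triplets, `[[`, "x")),
    dims = c(n_terms, length(texts))
  )
  gw <- global_weights(counts, weighting)
  structure(
    list(
      dictionary = dictionary,
      doc_ids = doc_ids,
      values = apply_weighting(counts, gw, weighting),
      counts = counts,
      weighting = weighting,
      global_weights = gw
    ),
    class = "hgf_tdm"
  )
}

#' @export
print.hgf_tdm <- function(x, ...) {
  cat("<hgf term-document matrix> ", nrow(x$values), " terms x ",
    ncol(x$values), " documents (", x$weighting, " weighting, ",
    length(x$values@x), " nonzeros)\n",
    sep = ""
  )
  invisible(x)
}

# Weight a raw count vector consistently with a matrix's stored scheme.
weight_vector <- function(counts, gw, weighting) {
  local <- if (weighting == "log-entropy") log1p(counts) else counts
  gw * local
}

#' Decompose the matrix into a reduced eigen space
#'
#' Computes the best rank-`k` approximation of the weighted term-document
#' matrix by truncated singular value decomposition.  Document coordinates
#' are the right singular vectors scaled by the singular values; each
#' factor is represented by one vector derived from its documents'
#' coordinates.
#'
#' @param matrix An `hgf_tdm` from [build_matrix()].
#' @param k Retained dimension count, or `NULL` (default) to choose the
#'   smallest `k` capturing `variance` of the squared singular-value mass.
#' @param variance Fraction of squared singular-value mass for automatic
#'   `k` selection (default 0.8).
#' @param k_max Cap on automatic `k` (default 300).
#' @param factor_mode `"centroid"` (default): a factor's vector is the
#'   mean of its documents' coordinates, re-normalized to unit length;
#'   `"pseudo_doc"`: the factor's raw counts are pooled, re-weighted, and
#'   projected through the term basis.
#' @return An object of class `hgf_space` with elements `k`, `term_basis`
#'   (terms x k, orthonormal), `singular_values`, `doc_vectors` (documents
#'   x k), `factor_vectors` (factors x k, named rows), plus the dictionary
#'   and weighting metadata needed for query fold-in.
#' @export
decompose_space <- function(matrix, k = NULL, variance = 0.8, k_max = 300L,
                            factor_mode = c("centroid", "pseudo_doc")) {
  stopifnot(inherits(matrix, "hgf_tdm"))
  factor_mode <- match.arg(factor_mode)
  dense <- as.matrix(matrix$values)
  sv <- svd(dense)
  tol <- max(dim(dense)) * .Machine$double.eps * sv$d[[1L]]
  rank <- sum(sv$d > tol)
  if (rank == 0L) hgf_stop("matrix is numerically zero", "hgf_invalid_input")
  if (is.null(k)) {
    mass <- cumsum(sv$d[seq_len(rank)]^2) / sum(sv$d[seq_len(rank)]^2)
    k <- which(mass >= variance)[[1L]]
    k <- min(k, k_max, rank)
  } else {
    k <- as.integer(k)
    if (k < 1L || k > rank) {
      hgf_stop(
        sprintf("k = %d outside achievable range [1, %d] (matrix rank)", k, rank),
        "hgf_invalid_input"
      )
    }
  }
  term_basis <- sv$u[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  doc_vectors <- sv$v[, seq_len(k), drop = FALSE] %*% diag(d, nrow = k)
  fnames <- unique(matrix$doc_ids$factor)
  factor_vectors <- if (factor_mode == "centroid") {
    grp <- base::factor(matrix$doc_ids$factor, levels = fnames)
    cent <- rowsum(doc_vectors, grp) / as.vector(table(grp))
    norms <- sqrt(rowSums(cent^2))
    cent * ifelse(norms < HGF_NORM_FLOOR, 0, 1 / norms)
  } else {
    mats <- vapply(fnames, function(fn) {
      cols <- which(matrix$doc_ids$factor == fn)
      pooled <- Matrix::rowSums(matrix$counts[, cols, drop = FALSE])
      w <- weight_vector(as.numeric(pooled), matrix$global_weights, matrix$weighting)
      v <- as.numeric(crossprod(term_basis, w))
      nv <- vec_norm(v)
      if (nv < HGF_NORM_FLOOR) v * 0 else v / nv
    }, numeric(k))
    if (is.matrix(mats)) t(mats) else matrix(mats, ncol = 1L)
  }
  rownames(factor_vectors) <- fnames
  structure(
    list(
      k = k,
      term_basis = term_basis,
      singular_values = d,
      doc_vectors = doc_vectors,
      factor_vectors = factor_vectors,
      doc_ids = matrix$doc_ids,
      dictionary = matrix$dictionary,
      weighting = matrix$weighting,
      global_weights = matrix$global_weights,
      factor_mode = factor_mode,
      rank = rank
    ),
    class = "hgf_space"
  )
}

#' @export
print.hgf_space <- function(x, ...) {
  cat("<hgf eigen space> k = ", x$k, " (rank ", x$rank, "), ",
    nrow(x$term_basis), " terms, ", nrow(x$doc_vectors), " documents, ",
    nrow(x$factor_vectors), " factors (", x$factor_mode, " representation, ",
    x$weighting, " weighting)\n",
    sep = ""
  )
  invisible(x)
}

#' Fold a query text into an eigen space
#'
#' The query's weighted term counts are projected through the term basis
#' and the inverse singular values (standard pseudo-document fold-in):
#' `q_hat = Sigma^{-1} U' w(q)`.  Multiplying the result by the singular
#' values places it in the same coordinate scale as `doc_vectors` /
#' `factor_vectors` (that is what [rank_factors()] does before computing
#' cosines).
#'
#' @param text Query text; must contain at least one dictionary word.
#' @param space An `hgf_space`.
#' @param dictionary Dictionary to tokenize against (defaults to the one
#'   stored in the space).
#' @return Numeric vector of length `k`.
#' @export
fold_in <- function(text, space, dictionary = space$dictionary) {
  stopifnot(inherits(space, "hgf_space"))
  counts <- count_terms(text, dictionary)
  if (sum(counts) == 0) {
    toks <- unique(tokenize_text(text)[[1L]])
    hgf_stop(
      sprintf(
        "query contains no dictionary words (unrecognized: %s)",
        paste(toks, collapse = ", ")
      ),
      "hgf_unknown_query"
    )
  }
  w <- weight_vector(counts, space$global_weights, space$weighting)
  as.numeric(crossprod(space$term_basis, w)) / space$singular_values
}

#' Cosine similarity of two vectors
#'
#' Inner product over the product of Euclidean norms, in `[-1, 1]`.
#' Vectors with norm below the numerical floor (1e-12) are degenerate: the
#' score is undefined and reported as `NA` with a warning, never as 0.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Numeric scalar in `[-1, 1]`, or `NA` for a degenerate input.
#' @export
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0)) # sqrt(2)/2
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    hgf_stop("vectors must have equal length", "hgf_invalid_input")
  }
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu < HGF_NORM_FLOOR || nv < HGF_NORM_FLOOR) {
    hgf_warn("cosine undefined for a zero vector; returning NA", "hgf_zero_vector")
    return(NA_real_)
  }
  s <- sum(u * v) / (nu * nv)
  min(1, max(-1, s))
}

#' Rank factors by association with a query
#'
#' Folds the query into the space and scores every factor by cosine
#' similarity between the query's coordinates and the factor's vector.
#' Factors are returned in descending score order; ties are broken
#' lexicographically by factor name.  Degenerate (zero-vector) factors
#' receive `NA` scores and sort last.
#'
#' @param query Query text (any word(s) in the dictionary).
#' @param space An `hgf_space`.
#' @param dictionary Dictionary override (defaults to the space's).
#' @return A data frame of class `hgf_query_result` with columns `rank`,
#'   `factor`, `score`, and the query stored in `attr(, "query")`.
#' @export
rank_factors <- function(query, space, dictionary = space$dictionary) {
  q <- fold_in(query, space, dictionary) * space$singular_values
  fv <- space$factor_vectors
  scores <- vapply(seq_len(nrow(fv)), function(i) {
    suppressWarnings(cosine_similarity(q, fv[i, ]))
  }, numeric(1))
  names(scores) <- rownames(fv)
  ord <- order(-scores, rownames(fv), method = "radix", na.last = TRUE)
  out <- data.frame(
    rank = seq_along(scores),
    factor = rownames(fv)[ord],
    score = unname(scores[ord]),
    stringsAsFactors = FALSE
  )
  attr(out, "query") <- query
  class(out) <- c("hgf_query_result", "data.frame")
  out
}

#' @export
print.hgf_query_result <- function(x, n = 10L, ...) {
  cat("<hgf ranking> query: \"", attr(x, "query"), "\" (",
    nrow(x), " factors)\n",
    sep = ""
  )
  print.data.frame(head(as.data.frame(x), n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more\n", sep = "")
  invisible(x)
}

#' Save an eigen-space model bundle
#'
#' Writes a directory with the dictionary, JSON metadata, and
#' tab-separated numeric tables for the term basis, singular values,
#' document coordinates, factor vectors, and global term weights.
#'
#' @param space An `hgf_space`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_space <- function(space, dir) {
  stopifnot(inherits(space, "hgf_space"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dictionary(space$dictionary, dir)
  write_mat <- function(m, file) {
    write.table(m,
      file.path(dir, file),
      sep = "\t", row.names = FALSE,
      col.names = FALSE, quote = FALSE
    )
  }
  write_mat(space$term_basis, "term_basis.tsv")
  write_mat(space$doc_vectors, "doc_vectors.tsv")
  write_mat(cbind(rownames(space$factor_vectors), round(space$factor_vectors, 12)),
    "factor_vectors.tsv"
  )
  writeLines(format(space$singular_values, digits = 17), file.path(dir, "singular_values.tsv"))
  writeLines(format(space$global_weights, digits = 17), file.path(dir, "global_weights.tsv"))
  write.table(space$doc_ids, file.path(dir, "doc_ids.tsv"),
    sep = "\t",
    row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(
      k = space$k, rank = space$rank, weighting = space$weighting,
      factor_mode = space$factor_mode,
      n_terms = nrow(space$term_basis), n_documents = nrow(space$doc_vectors)
    ),
    file.path(dir, "model.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Load an eigen-space model bundle written by [save_space()]
#'
#' @param dir Model directory.
#' @return An `hgf_space`.
#' @export
load_space <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  read_mat <- function(file) {
    as.matrix(read.delim(file.path(dir, file), header = FALSE))
  }
  fv_raw <- read.delim(file.path(dir, "factor_vectors.tsv"),
    header = FALSE,
    stringsAsFactors = FALSE
  )
  fv <- as.matrix(fv_raw[, -1, drop = FALSE])
  dimnames(fv) <- list(fv_raw[[1L]], NULL)
  structure(
    list(
      k = meta$k,
      term_basis = unname(read_mat("term_basis.tsv")),
      singular_values = as.numeric(readLines(file.path(dir, "singular_values.tsv"))),
      doc_vectors = unname(read_mat("doc_vectors.tsv")),
      factor_vectors = fv,
      doc_ids = read.delim(file.path(dir, "doc_ids.tsv"), stringsAsFactors = FALSE),
      dictionary = read_dictionary(dir),
      weighting = meta$weighting,
      global_weights = as.numeric(readLines(file.path(dir, "global_weights.tsv"))),
      factor_mode = meta$factor_mode,
      rank = meta$rank
    ),
    class = "hgf_space"
  )
}
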