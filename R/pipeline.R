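# Pipeline orchestration: dictionary -> index -> model -> query -> fit ->
# categorize -> network, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects the paths and settings of a full run.  All paths must exist at
#' run time; `out_dir` is created.
#'
#' @param mesh_file MeSH heading source file.
#' @param corpus_dir Directory of per-factor MEDLINE files (file stem =
#'   factor name with non-alphanumeric runs replaced by `_`).
#' @param factor_file Factor table TSV (name, category, query_terms).
#' @param out_dir Output directory.
#' @param mesh_dialect `"flat_list"` or `"descriptor_export"`.
#' @param stoplist_file Optional stop-word list path (default: packaged list).
#' @param min_length Minimum dictionary word length.
#' @param min_year,max_year Optional publication-year window.
#' @param weighting Term weighting scheme (see [build_matrix()]).
#' @param k `"auto"` or an integer dimension (see [decompose_space()]).
#' @param factor_mode Factor representation (see [decompose_space()]).
#' @param bins Histogram bins for the tri-modal fit.
#' @param restarts Randomized fit restarts.
#' @param seed Integer seed recorded in all outputs.
#' @param thresholds Optional numeric cutoffs overriding the fitted
#'   thresholds (length 2 or 3).
#' @param network_rule Edge rule (see [edge_weight()]).
#' @param min_weight Minimum network edge weight.
#' @return An object of class `hgf_pipeline_config`.
#' @export
pipeline_config <- function(mesh_file, corpus_dir, factor_file, out_dir,
                            mesh_dialect = "flat_list", stoplist_file = NULL,
                            min_length = 3L, min_year = NULL, max_year = NULL,
                            weighting = "log-entropy", k = "auto",
                            factor_mode = "centroid", bins = 20L,
                            restarts = 20L, seed = 1L, thresholds = NULL,
                            network_rule = "jaccard_assoc", min_weight = 0) {
  cfg <- list(
    mesh_file = mesh_file, corpus_dir = corpus_dir, factor_file = factor_file,
    out_dir = out_dir, mesh_dialect = mesh_dialect, stoplist_file = stoplist_file,
    min_length = as.integer(min_length), min_year = min_year, max_year = max_year,
    weighting = weighting, k = k, factor_mode = factor_mode,
    bins = as.integer(bins), restarts = as.integer(restarts),
    seed = as.integer(seed), thresholds = thresholds,
    network_rule = network_rule, min_weight = min_weight
  )
  structure(cfg, class = "hgf_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return An `hgf_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

checksum_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) {
    return(list())
  }
  sums <- tools::md5sum(paths)
  as.list(setNames(unname(sums), basename(names(sums))))
}

run_stage <- function(name, manifest, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(expr, error = function(e) {
    hgf_stop(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      "hgf_stage_failure"
    )
  })
  manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(result = result, manifest = manifest)
}

#' Run the full hypothesis-generation pipeline
#'
#' Executes dictionary building, corpus indexing, eigen-space
#' construction, per-query ranking, tri-modal fitting with threshold
#' derivation (or the configured manual thresholds), categorization, and
#' (with two or more queries) network assembly.  Every intermediate
#' artifact is written under `config$out_dir`, and a `manifest.json`
#' records settings, input checksums, per-stage timings, and output
#' paths, so a rerun with the same configuration and seed reproduces
#' identical rankings and fits.
#'
#' @param config An [pipeline_config()] (or path to a YAML file).
#' @param queries Character vector of query texts (at least one).
#' @return List with `manifest` (also written to disk) and the in-memory
#'   stage results (`dictionary`, `collection`, `space`, `rankings`,
#'   `fits`, `bands`, `network`).
#' @export
run_pipeline <- function(config, queries) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "hgf_pipeline_config"))
  if (length(queries) < 1L) hgf_stop("need at least one query", "hgf_invalid_input")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "hgf",
    settings = unclass(config),
    seed = config$seed,
    queries = as.character(queries),
    timings = list(),
    outputs = list(),
    stats = list()
  )

  # 1. dictionary
  st <- run_stage("dictionary", manifest, {
    headings <- load_mesh_headings(config$mesh_file, config$mesh_dialect)
    stoplist <- if (is.null(config$stoplist_file)) {
      default_stopwords()
    } else {
      load_stopwords(config$stoplist_file)
    }
    dict <- filter_vocabulary(build_vocabulary(headings),
      stoplist = stoplist,
      min_length = config$min_length,
      provenance = config$mesh_file
    )
    dict_dir <- file.path(config$out_dir, "dictionary")
    write_dictionary(dict, dict_dir)
    list(dict = dict, dir = dict_dir)
  })
  manifest <- st$manifest
  dictionary <- st$result$dict
  manifest$outputs$dictionary <- st$result$dir
  manifest$stats$dictionary_size <- length(dictionary$words)

  # 2. index
  st <- run_stage("index", manifest, {
    factors <- read_factor_table(config$factor_file)
    fnames <- vapply(factors, `[[`, character(1), "name")
    files <- setNames(
      file.path(config$corpus_dir, paste0(gsub("[^A-Za-z0-9]+", "_", fnames), ".medline")),
      fnames
    )
    suppressMessages(
      assemble_collection(factors, files,
        min_year = config$min_year,
        max_year = config$max_year
      )
    )
  })
  manifest <- st$manifest
  collection <- st$result
  counts <- collection_counts(collection)
  manifest$stats$documents <- list(
    total = sum(counts), min = min(counts),
    mean = round(mean(counts), 1), max = max(counts)
  )
  manifest$inputs <- c(
    checksum_files(c(config$mesh_file, config$factor_file)),
    checksum_files(list.files(config$corpus_dir, full.names = TRUE))
  )

  # 3. model
  st <- run_stage("model", manifest, {
    tdm <- build_matrix(collection, dictionary, weighting = config$weighting)
    k <- if (identical(config$k, "auto")) NULL else as.integer(config$k)
    space <- decompose_space(tdm, k = k, factor_mode = config$factor_mode)
    model_dir <- file.path(config$out_dir, "model")
    save_space(space, model_dir)
    list(space = space, dir = model_dir)
  })
  manifest <- st$manifest
  space <- st$result$space
  manifest$outputs$model <- st$result$dir
  manifest$stats$k <- space$k

  # 4. query
  safe <- function(q) gsub("[^A-Za-z0-9]+", "_", q)
  st <- run_stage("query", manifest, {
    rankings <- lapply(queries, function(q) rank_factors(q, space))
    names(rankings) <- queries
    paths <- vapply(queries, function(q) {
      p <- file.path(config$out_dir, sprintf("scores_%s.tsv", safe(q)))
      write.table(as.data.frame(rankings[[q]]), p,
        sep = "\t",
        row.names = FALSE, quote = FALSE
      )
      p
    }, character(1))
    list(rankings = rankings, paths = paths)
  })
  manifest <- st$manifest
  rankings <- st$result$rankings
  manifest$outputs$scores <- as.list(st$result$paths)

  # 5. fit (skipped when manual thresholds are configured)
  fits <- list()
  thresholds_of <- list()
  if (is.null(config$thresholds)) {
    st <- run_stage("fit", manifest, {
      lapply(queries, function(q) {
        h <- score_histogram(rankings[[q]]$score, n_bins = config$bins)
        fit <- fit_trimodal(h, restarts = config$restarts, seed = config$seed)
        thr <- derive_thresholds(fit)
        p <- file.path(config$out_dir, sprintf("fit_%s.json", safe(q)))
        jsonlite::write_json(
          list(
            query = q, alpha = fit$params$alpha, mu = fit$params$mu,
            sigma = fit$params$sigma, r_square = fit$r_square,
            bin_edges = fit$bins, heights = fit$heights,
            cutoffs = thr$cutoffs, source = thr$source, seed = config$seed
          ),
          p,
          auto_unbox = TRUE, digits = NA, pretty = TRUE
        )
        list(fit = fit, thresholds = thr, path = p)
      })
    })
    manifest <- st$manifest
    names(st$result) <- queries
    fits <- lapply(st$result, `[[`, "fit")
    thresholds_of <- lapply(st$result, `[[`, "thresholds")
    manifest$outputs$fits <- lapply(st$result, `[[`, "path")
    manifest$stats$r_square <- lapply(fits, `[[`, "r_square")
  } else {
    thr <- manual_thresholds(config$thresholds)
    thresholds_of <- setNames(rep(list(thr), length(queries)), queries)
    manifest$timings$fit <- 0
    manifest$stats$thresholds <- "manual override; tri-modal fit skipped"
  }

  # 6. categorize
  st <- run_stage("categorize", manifest, {
    lapply(queries, function(q) {
      bands <- categorize(rankings[[q]], thresholds_of[[q]])
      p <- file.path(config$out_dir, sprintf("bands_%s.tsv", safe(q)))
      write.table(bands$table, p, sep = "\t", row.names = FALSE, quote = FALSE)
      list(bands = bands, path = p)
    })
  })
  manifest <- st$manifest
  names(st$result) <- queries
  bands <- lapply(st$result, `[[`, "bands")
  manifest$outputs$bands <- lapply(st$result, `[[`, "path")

  # 7. network
  network <- NULL
  if (length(queries) >= 2L) {
    st <- run_stage("network", manifest, {
      net <- build_network(bands, rule = config$network_rule, min_weight = config$min_weight)
      gp <- file.path(config$out_dir, "network.graphml")
      tp <- file.path(config$out_dir, "network_edges.tsv")
      write_network_graphml(net, gp)
      write_network_edgelist(net, tp)
      list(net = net, paths = c(gp, tp))
    })
    manifest <- st$manifest
    network <- st$result$net
    manifest$outputs$network <- as.list(st$result$paths)
  } else {
    message("network stage skipped: need at least 2 queries")
    manifest$stats$network <- "skipped (single query)"
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null"
  )
  list(
    manifest = manifest, manifest_path = manifest_path,
    dictionary = dictionary, collection = collection, space = space,
    rankings = rankings, fits = fits, bands = bands, network = network
  )
}
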