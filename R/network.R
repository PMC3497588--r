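# Disease-disease networks assembled from the categorized factor sets of
# multiple queries.  Edges are weighted by shared-factor overlap (Jaccard).

band_set <- function(bands, rule) {
  if (rule == "jaccard_established") {
    bands$established
  } else {
    union(bands$established, bands$potential)
  }
}

#' Overlap weight between two categorized queries
#'
#' Jaccard index of the two queries' associated-factor sets:
#' `jaccard_established` uses the established sets only;
#' `jaccard_assoc` (default elsewhere) uses established plus potential,
#' on the reasoning that hidden knowledge sits in the weakly-positive
#' band.  When both sets are empty the weight is undefined and reported
#' as `NA` (such edges are omitted by [build_network()]).
#'
#' @param bands_a,bands_b `hgf_association_categories` over the same
#'   factor universe.
#' @param rule `"jaccard_assoc"` or `"jaccard_established"`.
#' @return List with `weight` (numeric or `NA`) and `shared` (character
#'   vector of shared factor names).
#' @export
edge_weight <- function(bands_a, bands_b, rule = c("jaccard_assoc", "jaccard_established")) {
  rule <- match.arg(rule)
  stopifnot(
    inherits(bands_a, "hgf_association_categories"),
    inherits(bands_b, "hgf_association_categories")
  )
  if (!setequal(bands_a$table$factor, bands_b$table$factor)) {
    hgf_stop("categorizations cover different factor universes", "hgf_invalid_input")
  }
  sa <- band_set(bands_a, rule)
  sb <- band_set(bands_b, rule)
  shared <- sort(intersect(sa, sb))
  uni <- union(sa, sb)
  if (length(uni) == 0L) {
    return(list(weight = NA_real_, shared = character(0)))
  }
  list(weight = length(shared) / length(uni), shared = shared)
}

#' Build a disease-disease network
#'
#' All pairwise edges between categorized queries with overlap weight at
#' least `min_weight`.  Isolated nodes are retained (absence of overlap is
#' itself a finding); node and edge ordering is deterministic
#' (lexicographic).
#'
#' @param categorized Named list (query name -> `hgf_association_categories`),
#'   at least two entries.
#' @param rule Overlap rule, see [edge_weight()].
#' @param min_weight Minimum edge weight kept (default 0).
#' @return An object of class `hgf_network`: list with `nodes` (character)
#'   and `edges` (data frame: from, to, weight, shared — semicolon-joined
#'   factor names).
#' @export
build_network <- function(categorized, rule = c("jaccard_assoc", "jaccard_established"),
                          min_weight = 0) {
  rule <- match.arg(rule)
  if (length(categorized) < 2L) {
    hgf_stop("need at least 2 categorized queries to build a network", "hgf_invalid_input")
  }
  if (is.null(names(categorized)) || any(!nzchar(names(categorized)))) {
    hgf_stop("categorized list must be named by query", "hgf_invalid_input")
  }
  nodes <- sort(names(categorized), method = "radix")
  edges <- data.frame(
    from = character(0), to = character(0), weight = numeric(0),
    shared = character(0), stringsAsFactors = FALSE
  )
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      ew <- edge_weight(categorized[[nodes[i]]], categorized[[nodes[j]]], rule)
      if (is.na(ew$weight) || ew$weight < min_weight) next
      edges <- rbind(edges, data.frame(
        from = nodes[i], to = nodes[j], weight = ew$weight,
        shared = paste(ew$shared, collapse = ";"),
        stringsAsFactors = FALSE
      ))
    }
  }
  structure(
    list(nodes = nodes, edges = edges, rule = rule, min_weight = min_weight),
    class = "hgf_network"
  )
}

#' @export
print.hgf_network <- function(x, ...) {
  cat("<hgf network> ", length(x$nodes), " nodes, ", nrow(x$edges),
    " edges (rule ", x$rule, ", min weight ", x$min_weight, ")\n",
    sep = ""
  )
  if (nrow(x$edges)) print.data.frame(x$edges, row.names = FALSE, digits = 3)
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges,
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
  )
}

#' Export a network as GraphML
#'
#' @param network An `hgf_network`.
#' @param path Output `.graphml` file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "hgf_network"))
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export a network as an edge-list TSV
#'
#' Columns: node_a, node_b, weight, shared_factors (semicolon-joined).
#'
#' @param network An `hgf_network`.
#' @param path Output `.tsv` file.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(network, path) {
  stopifnot(inherits(network, "hgf_network"))
  out <- network$edges
  names(out) <- c("node_a", "node_b", "weight", "shared_factors")
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
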