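# Metabolite synergy network ---------------------------------------------------

#' Build the synergy network from top co-occurring pairs
#'
#' Keeps the `n_keep = ceiling(top_fraction * denominator)` most frequent
#' pairs (all ties at the cutoff count retained) and builds an undirected
#' simple graph whose vertices are the endpoints of the kept edges, with
#' vertex weight = individual occurrence frequency and edge weight =
#' co-occurrence frequency.  Only pairs with nonzero count are eligible.
#'
#' The denominator of the top-fraction cutoff is a policy: `"n_squared"`
#' (all n^2 ordered feature combinations, the default), `"n_choose_2"`
#' (unordered pairs), or `"nonzero"` (observed nonzero pairs).
#'
#' @param table An `lgp_occurrence` from [count_occurrences()].
#' @param top_fraction Fraction of pairs to keep (default 0.01).
#' @param denominator Cutoff denominator policy, see above.
#' @return An object of class `synergy_network`: list with `graph` (igraph),
#'   `vertices` (tibble `feature`, `occurrence_frequency`), `edges` (tibble
#'   `feature_a`, `feature_b`, `count`, `cooccurrence_frequency`), `n_keep`
#'   and `cutoff_count`.
#' @export
build_network <- function(table, top_fraction = 0.01,
                          denominator = c("n_squared", "n_choose_2",
                                          "nonzero")) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  denominator <- match.arg(denominator)
  nf <- length(table$feature_names)
  pairs <- dplyr::filter(table$pairs, .data$count > 0)
  denom <- switch(denominator,
    n_squared = nf^2,
    n_choose_2 = nf * (nf - 1) / 2,
    nonzero = nrow(pairs)
  )
  if (nrow(pairs) == 0) {
    warn("all pair counts are zero: empty synergy network")
    return(new_synergy_network(
      tibble(feature = character(), occurrence_frequency = numeric()),
      tibble(feature_a = character(), feature_b = character(),
             count = integer(), cooccurrence_frequency = numeric()),
      n_keep = 0L, cutoff_count = NA_integer_))
  }
  n_keep <- min(ceiling(top_fraction * denom), nrow(pairs))
  pairs <- dplyr::arrange(pairs, dplyr::desc(.data$count), .data$feature_a,
                          .data$feature_b)
  cutoff <- pairs$count[n_keep]
  kept <- dplyr::filter(pairs, .data$count >= cutoff)
  verts <- sort(unique(c(kept$feature_a, kept$feature_b)))
  vtb <- tibble(
    feature = verts,
    occurrence_frequency = table$features$frequency[
      match(verts, table$features$feature)]
  )
  etb <- dplyr::select(kept, "feature_a", "feature_b", "count",
                       cooccurrence_frequency = "frequency")
  new_synergy_network(vtb, etb, n_keep = as.integer(n_keep),
                      cutoff_count = cutoff)
}

new_synergy_network <- function(vertices, edges, n_keep, cutoff_count) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$feature_a, to = edges$feature_b,
                   weight = edges$cooccurrence_frequency,
                   count = edges$count),
    directed = FALSE,
    vertices = data.frame(name = vertices$feature,
                          occurrence_frequency =
                            vertices$occurrence_frequency)
  )
  structure(list(graph = g, vertices = vertices, edges = edges,
                 n_keep = n_keep, cutoff_count = cutoff_count),
            class = "synergy_network")
}

#' @export
print.synergy_network <- function(x, ...) {
  cat(sprintf(
    "<synergy_network: %d vertices, %d edges (cutoff count %s), mean degree %.2f>\n",
    nrow(x$vertices), nrow(x$edges),
    format(x$cutoff_count), mean_degree(x)))
  invisible(x)
}

mean_degree <- function(net) {
  nv <- nrow(net$vertices)
  if (nv == 0) return(NaN)
  2 * nrow(net$edges) / nv
}

#' Vertex degrees and the degree histogram
#'
#' @param net A `synergy_network`.
#' @return List with `degrees` (tibble `feature`, `degree`) and `histogram`
#'   (tibble `degree`, `n_vertices` over observed degrees).
#' @export
degree_distribution_net <- function(net) {
  deg <- igraph::degree(net$graph)
  degrees <- tibble(feature = names(deg), degree = as.integer(deg))
  hist <- dplyr::count(degrees, .data$degree, name = "n_vertices")
  list(degrees = dplyr::arrange(degrees, dplyr::desc(.data$degree),
                                .data$feature),
       histogram = hist)
}

#' Closeness and betweenness centralities
#'
#' Unweighted shortest-path centralities computed per connected component:
#' closeness is `(n_c - 1) / sum(d)` over the vertex's component (0 for
#' singletons), betweenness is the fraction of shortest paths between
#' same-component vertex pairs passing through the vertex (0 when the
#' component has fewer than 3 vertices).
#'
#' @param net A `synergy_network`.
#' @return Tibble `feature`, `degree`, `closeness`, `betweenness`,
#'   `component`.
#' @export
centralities <- function(net) {
  g <- net$graph
  nv <- igraph::vcount(g)
  if (nv == 0) {
    return(tibble(feature = character(), degree = integer(),
                  closeness = numeric(), betweenness = numeric(),
                  component = integer()))
  }
  comp <- igraph::components(g)
  close <- numeric(nv)
  btw <- numeric(nv)
  for (c_id in seq_len(comp$no)) {
    members <- which(comp$membership == c_id)
    nc <- length(members)
    if (nc == 1) next
    sub <- igraph::induced_subgraph(g, members)
    d <- igraph::distances(sub, weights = NA)   # topological, not weighted
    close[members] <- (nc - 1) / rowSums(d)
    if (nc >= 3) {
      btw[members] <- igraph::betweenness(sub, directed = FALSE,
                                          weights = NA) /
        ((nc - 1) * (nc - 2) / 2)
    }
  }
  tibble(feature = igraph::V(g)$name,
         degree = as.integer(igraph::degree(g)),
         closeness = close, betweenness = btw,
         component = as.integer(comp$membership))
}

#' Hub and bottleneck report
#'
#' Ranks vertices by degree, closeness and betweenness and lists the
#' vertices whose degree exceeds a threshold.
#'
#' @param net A `synergy_network`.
#' @param top_n Number of top vertices to report per criterion.
#' @param degree_threshold Degree cutoff for the threshold listing
#'   (default > 10).
#' @return List with `ranking` (centrality tibble plus `rank_degree`,
#'   `rank_closeness`, `rank_betweenness`, ties broken by name) and
#'   `high_degree` (vertices with degree > threshold).
#' @export
hubs_and_bottlenecks <- function(net, top_n = 10, degree_threshold = 10) {
  ct <- centralities(net)
  if (nrow(ct) == 0) {
    return(list(ranking = ct, high_degree = ct))
  }
  rank_by <- function(v) {
    ord <- order(-v, ct$feature)
    r <- integer(length(v))
    r[ord] <- seq_along(v)
    r
  }
  ranking <- dplyr::mutate(
    ct,
    rank_degree = rank_by(.data$degree),
    rank_closeness = rank_by(.data$closeness),
    rank_betweenness = rank_by(.data$betweenness)
  )
  ranking <- dplyr::arrange(ranking, .data$rank_degree)
  list(
    ranking = utils::head(ranking, max(top_n, 0)),
    high_degree = dplyr::filter(ranking, .data$degree > degree_threshold)
  )
}

#' @method tidy synergy_network
#' @export
tidy.synergy_network <- function(x, ...) x$edges

#' @method glance synergy_network
#' @export
glance.synergy_network <- function(x, ...) {
  comp <- if (igraph::vcount(x$graph) > 0) {
    igraph::components(x$graph)$no
  } else {
    0L
  }
  tibble(n_vertices = nrow(x$vertices), n_edges = nrow(x$edges),
         mean_degree = mean_degree(x), n_components = comp,
         cutoff_count = x$cutoff_count)
}

#' Export a synergy network
#'
#' Writes GraphML (vertex attribute `occurrence_frequency`, edge attribute
#' `weight` = co-occurrence frequency; loadable by Cytoscape) and/or a TSV
#' weighted edge list.
#'
#' @param net A `synergy_network`.
#' @param graphml,edgelist Output paths (skipped when `NULL`).
#' @return Written paths, invisibly.
#' @export
write_network <- function(net, graphml = NULL, edgelist = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(net$graph, graphml, format = "graphml")
  }
  if (!is.null(edgelist)) {
    readr::write_tsv(net$edges, edgelist)
  }
  invisible(c(graphml, edgelist))
}
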