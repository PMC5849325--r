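# occurrence table built directly from feature/pair counts
occ_fixture <- function(pair_counts, n_models = 20, universe = NULL) {
  feats <- sort(unique(c(pair_counts$feature_a, pair_counts$feature_b)))
  if (is.null(universe)) universe <- feats
  structure(list(
    features = tibble::tibble(
      feature = universe,
      count = as.integer(round(n_models * 0.5)),
      frequency = 0.5
    ),
    pairs = dplyr::arrange(
      dplyr::mutate(pair_counts, frequency = count / n_models),
      dplyr::desc(count), feature_a, feature_b),
    n_models = n_models,
    feature_names = universe
  ), class = "lgp_occurrence")
}

test_that("the cutoff keeps the top fraction of pairs with ties included", {
  # 10-feature universe, distinct counts: top 1% of 10^2 = 1 pair kept
  pc <- tibble::tibble(feature_a = paste0("f", 1:5),
                       feature_b = paste0("g", 1:5),
                       count = c(9L, 7L, 5L, 3L, 1L))
  occ <- occ_fixture(pc, universe = c(paste0("f", 1:5), paste0("g", 1:5)))
  net <- build_network(occ, top_fraction = 0.01)
  expect_equal(net$n_keep, 1L)
  expect_equal(nrow(net$edges), 1)
  expect_equal(nrow(net$vertices), 2)
  expect_equal(net$edges$count, 9L)

  # kept edge weights dominate every dropped pair
  expect_true(min(net$edges$count) >= max(setdiff(pc$count, net$edges$count)))

  # ties at the cutoff are all retained
  pc_tie <- dplyr::mutate(pc, count = c(9L, 5L, 5L, 5L, 1L))
  net_tie <- build_network(occ_fixture(pc_tie,
                                       universe = occ$feature_names),
                           top_fraction = 0.02)  # n_keep = 2
  expect_equal(nrow(net_tie$edges), 4)  # 9 plus the three tied 5s

  # top_fraction = 1 keeps every nonzero pair
  net_all <- build_network(occ, top_fraction = 1)
  expect_equal(nrow(net_all$edges), 5)

  # alternative denominators change n_keep only
  net_c2 <- build_network(occ, top_fraction = 0.1,
                          denominator = "n_choose_2")  # ceil(4.5) = 5
  expect_equal(net_c2$n_keep, 5L)
})

test_that("an all-zero pair table gives an empty network with a warning", {
  pc <- tibble::tibble(feature_a = "a", feature_b = "b", count = 0L)
  expect_warning(net <- build_network(occ_fixture(pc)), "zero")
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$vertices), 0)
  expect_equal(glance(net)$n_components, 0L)
})

test_that("degrees satisfy the handshake lemma on canonical graphs", {
  triangle <- occ_fixture(tibble::tibble(
    feature_a = c("a", "a", "b"), feature_b = c("b", "c", "c"),
    count = c(5L, 4L, 3L)))
  net <- build_network(triangle, top_fraction = 1)
  dd <- degree_distribution_net(net)
  expect_true(all(dd$degrees$degree == 2))
  expect_equal(sum(dd$degrees$degree), 2 * nrow(net$edges))

  star <- occ_fixture(tibble::tibble(
    feature_a = rep("hub", 5), feature_b = paste0("leaf", 1:5),
    count = 5:1))
  nets <- build_network(star, top_fraction = 1)
  dds <- degree_distribution_net(nets)
  expect_equal(dds$degrees$degree[dds$degrees$feature == "hub"], 5L)
  expect_true(all(dds$degrees$degree[dds$degrees$feature != "hub"] == 1L))
  expect_equal(sum(dds$degrees$degree), 2 * nrow(nets$edges))
  # histogram covers the observed degrees
  expect_setequal(dds$histogram$degree, c(1L, 5L))
})

test_that("closeness and betweenness match hand values on path and triangle", {
  path3 <- occ_fixture(tibble::tibble(
    feature_a = c("a", "b"), feature_b = c("b", "c"), count = c(3L, 2L)))
  ct <- centralities(build_network(path3, top_fraction = 1))
  get <- function(f, col) ct[[col]][ct$feature == f]
  expect_equal(get("b", "betweenness"), 1)
  expect_equal(get("a", "betweenness"), 0)
  expect_equal(get("c", "betweenness"), 0)
  expect_equal(get("b", "closeness"), 1)
  expect_equal(get("a", "closeness"), 2 / 3)

  triangle <- occ_fixture(tibble::tibble(
    feature_a = c("a", "a", "b"), feature_b = c("b", "c", "c"),
    count = c(3L, 3L, 3L)))
  ctt <- centralities(build_network(triangle, top_fraction = 1))
  expect_true(all(ctt$betweenness == 0))
  expect_true(all(ctt$closeness == 1))
})

test_that("centralities are computed per component and invariant to labels", {
  # two components: a path of 3 and an isolated edge
  two <- occ_fixture(tibble::tibble(
    feature_a = c("a", "b", "x"), feature_b = c("b", "c", "y"),
    count = c(3L, 3L, 3L)))
  ct <- centralities(build_network(two, top_fraction = 1))
  expect_equal(length(unique(ct$component)), 2)
  expect_equal(ct$closeness[ct$feature == "x"], 1)  # (2-1)/1 in its component
  expect_equal(ct$betweenness[ct$feature == "x"], 0)

  # relabeling the path vertices permutes but does not change values
  relab <- occ_fixture(tibble::tibble(
    feature_a = c("p", "q"), feature_b = c("q", "r"), count = c(3L, 2L)))
  path3 <- occ_fixture(tibble::tibble(
    feature_a = c("a", "b"), feature_b = c("b", "c"), count = c(3L, 2L)))
  v1 <- sort(centralities(build_network(path3, top_fraction = 1))$closeness)
  v2 <- sort(centralities(build_network(relab, top_fraction = 1))$closeness)
  expect_equal(v1, v2)
})

test_that("hub/bottleneck report ranks the star center first", {
  star <- occ_fixture(tibble::tibble(
    feature_a = rep("hub", 5), feature_b = paste0("leaf", 1:5), count = 5:1))
  hb <- hubs_and_bottlenecks(build_network(star, top_fraction = 1),
                             top_n = 3, degree_threshold = 4)
  expect_equal(hb$ranking$feature[1], "hub")
  expect_equal(hb$ranking$rank_betweenness[1], 1)
  expect_equal(hb$ranking$rank_closeness[1], 1)
  expect_equal(hb$high_degree$feature, "hub")

  # low-degree graphs yield an empty threshold listing
  tri <- occ_fixture(tibble::tibble(
    feature_a = c("a", "a", "b"), feature_b = c("b", "c", "c"),
    count = c(3L, 3L, 3L)))
  hb2 <- hubs_and_bottlenecks(build_network(tri, top_fraction = 1))
  expect_equal(nrow(hb2$high_degree), 0)
  # deterministic tie-break by name
  expect_equal(hb2$ranking$feature, sort(hb2$ranking$feature))
})

test_that("GraphML and edge-list exports are loadable and faithful", {
  tri <- occ_fixture(tibble::tibble(
    feature_a = c("a", "a", "b"), feature_b = c("b", "c", "c"),
    count = c(6L, 5L, 4L)))
  net <- build_network(tri, top_fraction = 1)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, graphml = gml, edgelist = tsv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::V(g)$occurrence_frequency,
                  net$vertices$occurrence_frequency)
  el <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(el), 3)
  expect_equal(sort(el$cooccurrence_frequency),
               sort(net$edges$cooccurrence_frequency))
})
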