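# Effective-feature occurrence / co-occurrence analysis ------------------------

#' Count feature occurrences and pairwise co-occurrences across models
#'
#' Membership is per model and binary: a model contributes at most one count
#' to any feature and any unordered pair, no matter how often the feature
#' appears inside the model, and only *effective* features count (introns
#' never create occurrences).
#'
#' @param models An `lgp_models` tibble (from [run_batch()] / [run_cv()]).
#' @return An object of class `lgp_occurrence`: a list with `features`
#'   (tibble `feature`, `count`, `frequency` over all features of the
#'   universe, zero rows included), `pairs` (tibble `feature_a`, `feature_b`,
#'   `count`, `frequency` for observed pairs, `feature_a < feature_b`),
#'   `n_models` and `feature_names`.
#' @export
count_occurrences <- function(models) {
  if (nrow(models) == 0) abort("empty model collection")
  sets <- if ("features" %in% names(models)) {
    models$features
  } else {
    lapply(models$program, effective_features, names = TRUE)
  }
  universe <- models$program[[1]]$feature_names
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  }
  n_models <- length(sets)
  feat_counts <- table(factor(unlist(lapply(sets, unique)),
                              levels = universe))
  pair_list <- lapply(sets, function(s) {
    s <- sort(unique(s))
    if (length(s) < 2) return(NULL)
    cmb <- combn(s, 2)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  })
  pair_counts <- table(unlist(pair_list))
  pairs <- if (length(pair_counts) == 0) {
    tibble(feature_a = character(), feature_b = character(),
           count = integer(), frequency = numeric())
  } else {
    parts <- strsplit(names(pair_counts), "\r", fixed = TRUE)
    tibble(
      feature_a = vapply(parts, `[`, character(1), 1),
      feature_b = vapply(parts, `[`, character(1), 2),
      count = as.integer(pair_counts),
      frequency = as.integer(pair_counts) / n_models
    )
  }
  structure(
    list(
      features = tibble(feature = universe,
                        count = as.integer(feat_counts),
                        frequency = as.integer(feat_counts) / n_models),
      pairs = dplyr::arrange(pairs, dplyr::desc(.data$count),
                             .data$feature_a, .data$feature_b),
      n_models = n_models,
      feature_names = universe
    ),
    class = "lgp_occurrence"
  )
}

#' @export
print.lgp_occurrence <- function(x, ...) {
  cat(sprintf("<lgp_occurrence: %d models, %d features, %d observed pairs>\n",
              x$n_models, length(x$feature_names), nrow(x$pairs)))
  print(top_k(x, 5))
  invisible(x)
}

#' @method tidy lgp_occurrence
#' @export
tidy.lgp_occurrence <- function(x, which = c("features", "pairs"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' Top-k most frequent features or pairs
#'
#' Ranked by descending frequency; ties broken lexicographically by feature
#' name so the ordering is deterministic.
#'
#' @param table An `lgp_occurrence`.
#' @param k Number of entries (the whole ranked table if larger).
#' @param which `"features"` or `"pairs"`.
#' @return Ranked tibble with a `rank` column.
#' @export
top_k <- function(table, k = 20, which = c("features", "pairs")) {
  which <- match.arg(which)
  tb <- table[[which]]
  tb <- if (which == "features") {
    dplyr::arrange(tb, dplyr::desc(.data$count), .data$feature)
  } else {
    dplyr::arrange(tb, dplyr::desc(.data$count), .data$feature_a,
                   .data$feature_b)
  }
  tb <- utils::head(tb, k)
  dplyr::mutate(tb, rank = dplyr::row_number(), .before = 1)
}

#' Correlation between fitness and number of effective features
#'
#' Pearson correlation of per-model training MCE against effective-feature
#' count, with the two-sided t-test p-value.
#'
#' @param models An `lgp_models` tibble.
#' @param use_train Correlate against training MCE (default) or held-out MCE.
#' @return One-row tibble: `estimate`, `p.value`, `n`.
#' @export
fitness_feature_correlation <- function(models, use_train = TRUE) {
  x <- if (use_train) models$train_mce else models$mce
  y <- models$n_features_effective
  if (nrow(models) < 3) abort("need at least 3 models")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble(estimate = NA_real_, p.value = NA_real_, n = nrow(models)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
         n = nrow(models))
}

#' Intersection of two top-k rankings
#'
#' @param discovery,replication Ranked tibbles from [top_k()] (or
#'   `lgp_occurrence` objects, ranked internally).
#' @param k Depth of each list.
#' @return Character vector of features in both top-k sets, ordered by
#'   discovery rank.
#' @export
intersect_top <- function(discovery, replication, k = 20) {
  d <- ranked_names(discovery, k)
  r <- ranked_names(replication, k)
  d[d %in% r]
}

ranked_names <- function(x, k) {
  if (inherits(x, "lgp_occurrence")) x <- top_k(x, k)
  utils::head(x$feature, k)
}

#' Export occurrence tables to CSV
#'
#' Writes `<prefix>_features.csv` (feature, count, frequency) and
#' `<prefix>_pairs.csv` (feature_a, feature_b, count, frequency).
#'
#' @param table An `lgp_occurrence`.
#' @param prefix Output path prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_occurrence <- function(table, prefix) {
  pf <- paste0(prefix, "_features.csv")
  pp <- paste0(prefix, "_pairs.csv")
  readr::write_csv(table$features, pf)
  readr::write_csv(table$pairs, pp)
  invisible(c(pf, pp))
}
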