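# Two-round evolutionary pipeline ----------------------------------------------
#
# Round 1: multi-seed cross-validated evolution on the discovery dataset's
# full feature set; count effective-feature occurrences; build the synergy
# network; its vertex set becomes the reduced feature set.  Round 2: repeat
# the batch on the reduced feature set for both discovery and replication;
# the intersection of the two top-20 occurrence lists is the key-feature
# report.  A fold-matched logistic regression serves as the linear baseline.

#' Round 1: full-feature evolution and synergy network
#'
#' @param discovery Preprocessed discovery dataset tibble.
#' @param config An [evolution_config()].
#' @param n_seeds Number of run seeds (seeds `1..n_seeds` by default).
#' @param seeds Optional explicit seed vector.
#' @param top_fraction,denominator Passed to [build_network()].
#' @param k Folds per run.
#' @param k_top Depth of the top-feature/pair listings.
#' @return A list of class `lgp_round`: `models`, `summary`, `occurrence`,
#'   `network`, `top_features`, `top_pairs`, `reduced_features` (the
#'   network's vertex set), `correlation`.
#' @export
round_one <- function(discovery, config, n_seeds, seeds = seq_len(n_seeds),
                      top_fraction = 0.01,
                      denominator = "n_squared", k = 5, k_top = 20) {
  models <- run_batch(discovery, config, n_seeds, seeds = seeds, k = k)
  occ <- count_occurrences(models)
  net <- build_network(occ, top_fraction = top_fraction,
                       denominator = denominator)
  structure(list(
    models = models,
    summary = summarize_metrics(models),
    occurrence = occ,
    network = net,
    top_features = top_k(occ, k_top, "features"),
    top_pairs = top_k(occ, k_top, "pairs"),
    reduced_features = net$vertices$feature,
    correlation = fitness_feature_correlation(models)
  ), class = "lgp_round")
}

#' @export
print.lgp_round <- function(x, ...) {
  cat(sprintf("<lgp_round: %d models, %d reduced features>\n",
              nrow(x$models), length(x$reduced_features)))
  print(x$summary)
  invisible(x)
}

#' Round 2: reduced-feature evolution on discovery and replication
#'
#' @param discovery,replication Preprocessed dataset tibbles.
#' @param reduced_features Character vector of features to restrict to
#'   (typically `round_one(...)$reduced_features`).
#' @param config,n_seeds,seeds,k,k_top As in [round_one()].
#' @return A list of class `lgp_round2`: per-dataset `models`, `summary`,
#'   `occurrence` and `top_features`, plus `key_features` (intersection of
#'   the two top-`k_top` lists, ordered by discovery rank).
#' @export
round_two <- function(discovery, replication, reduced_features, config,
                      n_seeds, seeds = seq_len(n_seeds), k = 5, k_top = 20) {
  if (length(reduced_features) < 2) {
    abort("reduced feature set must contain at least two features")
  }
  for (d in list(discovery, replication)) {
    if (!all(reduced_features %in% feature_names(d))) {
      abort("reduced features missing from a dataset")
    }
  }
  restrict <- function(d) {
    d[, c(intersect(.reserved_cols, names(d)), reduced_features)]
  }
  res <- lapply(list(discovery = restrict(discovery),
                     replication = restrict(replication)), function(d) {
    models <- run_batch(d, config, n_seeds, seeds = seeds, k = k)
    occ <- count_occurrences(models)
    list(models = models, summary = summarize_metrics(models),
         occurrence = occ, top_features = top_k(occ, k_top, "features"))
  })
  structure(list(
    discovery = res$discovery,
    replication = res$replication,
    key_features = intersect_top(res$discovery$occurrence,
                                 res$replication$occurrence, k_top),
    reduced_features = reduced_features
  ), class = "lgp_round2")
}

#' @export
print.lgp_round2 <- function(x, ...) {
  cat(sprintf("<lgp_round2: %d + %d models, %d key features>\n",
              nrow(x$discovery$models), nrow(x$replication$models),
              length(x$key_features)))
  cat("key features:", paste(x$key_features, collapse = ", "), "\n")
  invisible(x)
}

#' Fold-matched logistic-regression baseline
#'
#' For every run seed, rebuilds the exact fold assignment the evolutionary
#' runs used (same seed schedule), fits a logistic regression on each set of
#' four training folds over the reduced feature set, and evaluates on the
#' held-out fold.  Non-converged fits are flagged and skipped with a
#' warning.
#'
#' @param data Preprocessed dataset tibble.
#' @param reduced_features Feature subset to use.
#' @param n_seeds,seeds,k Fold/seed scheme, as in [run_batch()].
#' @param ridge If `TRUE`, fit a weakly ridge-penalized model via glmnet
#'   (lambda = 1e-3) instead of plain [stats::glm()].
#' @return Tibble with one row per (seed, fold): `mce`, `sensitivity`,
#'   `specificity`, `auc`, `roc`, `converged`.
#' @export
logistic_baseline <- function(data, reduced_features, n_seeds,
                              seeds = seq_len(n_seeds), k = 5,
                              ridge = FALSE) {
  rows <- list()
  for (s in seeds) {
    sch <- derive_seeds(s, k + 1)
    fold <- stratified_kfold(data, k, seed = sch[1])
    for (f in seq_len(k)) {
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      scores <- fit_logistic(train, test, reduced_features, ridge)
      if (is.null(scores)) {
        warn(sprintf("logistic fit did not converge (seed %d fold %d); skipped",
                     s, f))
        next
      }
      met <- metrics_from_scores(scores, test$label)
      rows[[length(rows) + 1]] <-
        dplyr::bind_cols(tibble(seed = s, fold = f), met,
                         tibble(converged = TRUE))
    }
  }
  dplyr::bind_rows(rows)
}

fit_logistic <- function(train, test, features, ridge) {
  Xtr <- as.matrix(train[, features, drop = FALSE])
  Xte <- as.matrix(test[, features, drop = FALSE])
  if (ridge) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      abort("ridge baseline requires the glmnet package")
    }
    fit <- glmnet::glmnet(Xtr, factor(train$label), family = "binomial",
                          alpha = 0, lambda = 1e-3)
    return(as.numeric(predict(fit, Xte, type = "response")))
  }
  df_tr <- data.frame(label = train$label, Xtr, check.names = TRUE)
  df_te <- data.frame(Xte, check.names = TRUE)
  fit <- suppressWarnings(glm(label ~ ., data = df_tr, family = binomial()))
  if (!fit$converged) return(NULL)
  suppressWarnings(as.numeric(predict(fit, newdata = df_te,
                                      type = "response")))
}

#' Run the full two-round pipeline
#'
#' Preprocesses a raw dataset (batch correction, covariate adjustment,
#' stratified discovery/replication split, per-half normalization), runs
#' round 1 on discovery, round 2 on both halves with the network-reduced
#' feature set, and the fold-matched logistic baseline on both halves.  All
#' per-stage seeds derive deterministically from `seed`.
#'
#' @param data Raw dataset tibble (e.g. from [generate_dataset()] or
#'   [read_dataset()]).
#' @param config An [evolution_config()].
#' @param n_seeds Run seeds per batch.
#' @param seed Master seed.
#' @param top_fraction,denominator Network cutoff policy.
#' @param k Folds.
#' @param k_top Top-list depth.
#' @param baseline_ridge Use the ridge baseline.
#' @return A list of class `lgp_pipeline`: `discovery`, `replication`
#'   (preprocessed halves), `round1`, `round2`, `baseline` (per-half
#'   tibbles), `key_features`, `seed`.
#' @export
run_pipeline <- function(data, config, n_seeds = 200, seed = 1,
                         top_fraction = 0.01, denominator = "n_squared",
                         k = 5, k_top = 20, baseline_ridge = FALSE) {
  sch <- derive_seeds(seed, 4)
  halves <- preprocess(data, seed = sch[1])
  batch_seeds <- function(stage_seed) derive_seeds(stage_seed, n_seeds)
  r1 <- round_one(halves$discovery, config, n_seeds,
                  seeds = batch_seeds(sch[2]),
                  top_fraction = top_fraction, denominator = denominator,
                  k = k, k_top = k_top)
  r2 <- round_two(halves$discovery, halves$replication,
                  r1$reduced_features, config, n_seeds,
                  seeds = batch_seeds(sch[3]), k = k, k_top = k_top)
  baseline <- list(
    discovery = logistic_baseline(halves$discovery, r1$reduced_features,
                                  n_seeds, seeds = batch_seeds(sch[3]),
                                  k = k, ridge = baseline_ridge),
    replication = logistic_baseline(halves$replication, r1$reduced_features,
                                    n_seeds, seeds = batch_seeds(sch[3]),
                                    k = k, ridge = baseline_ridge)
  )
  structure(list(
    discovery = halves$discovery, replication = halves$replication,
    round1 = r1, round2 = r2, baseline = baseline,
    key_features = r2$key_features, seed = seed
  ), class = "lgp_pipeline")
}

#' @export
print.lgp_pipeline <- function(x, ...) {
  cat(sprintf("<lgp_pipeline: seed %s>\n", format(x$seed)))
  cat(sprintf("round 1: %d models, %d reduced features\n",
              nrow(x$round1$models), length(x$round1$reduced_features)))
  cat(sprintf("round 2: key features: %s\n",
              paste(x$key_features, collapse = ", ")))
  cat(sprintf("mean test AUC: evolved %.3f (disc) / %.3f (repl), logistic %.3f / %.3f\n",
              mean(x$round2$discovery$models$auc, na.rm = TRUE),
              mean(x$round2$replication$models$auc, na.rm = TRUE),
              mean(x$baseline$discovery$auc, na.rm = TRUE),
              mean(x$baseline$replication$auc, na.rm = TRUE)))
  invisible(x)
}

#' @method glance lgp_pipeline
#' @export
glance.lgp_pipeline <- function(x, ...) {
  tibble(
    n_models_round1 = nrow(x$round1$models),
    n_reduced = length(x$round1$reduced_features),
    n_key = length(x$key_features),
    auc_round2_discovery = mean(x$round2$discovery$models$auc, na.rm = TRUE),
    auc_round2_replication = mean(x$round2$replication$models$auc,
                                  na.rm = TRUE),
    auc_baseline_discovery = mean(x$baseline$discovery$auc, na.rm = TRUE),
    auc_baseline_replication = mean(x$baseline$replication$auc, na.rm = TRUE)
  )
}

#' Write a round report to a directory
#'
#' Summary-table CSV (metric statistics), top-20 feature/pair CSVs, network
#' GraphML + edge-list TSV, and ROC points of the best model by AUC.
#'
#' @param round An `lgp_round` (round 1) result.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_round_report <- function(round, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    summary = file.path(dir, "summary.csv"),
    top_features = file.path(dir, "top_features.csv"),
    top_pairs = file.path(dir, "top_pairs.csv"),
    graphml = file.path(dir, "network.graphml"),
    edges = file.path(dir, "network_edges.tsv"),
    roc = file.path(dir, "best_model_roc.csv"),
    models = file.path(dir, "models.jsonl")
  )
  readr::write_csv(round$summary, paths["summary"])
  readr::write_csv(round$top_features, paths["top_features"])
  readr::write_csv(round$top_pairs, paths["top_pairs"])
  write_network(round$network, graphml = paths["graphml"],
                edgelist = paths["edges"])
  best <- which.max(round$models$auc)
  readr::write_csv(round$models$roc[[best]], paths["roc"])
  write_models(round$models, paths["models"])
  invisible(paths)
}

# Planted-synergy recovery study ----------------------------------------------

#' Study conditions for the XOR-pair recovery experiment
#'
#' A deliberately compact version of the two-round procedure used to check
#' that the framework recovers a purely synergistic feature pair: 200 cases +
#' 200 controls over 30 features, a single XOR-threshold pair
#' (`met_006`/`met_007`) with log-odds coefficient 4.5 (generative Bayes AUC
#' about 0.90) and no main effects, population 200 / 200 parents / 250
#' generations / tournament 8 / max length 15 / 10 calculation registers,
#' 4 run seeds per batch.  Short programs keep the per-model effective
#' feature sets small, which sharpens the occurrence ranking that the
#' recovery check reads.
#'
#' @return List with `data_config` ([synthetic_config()]) and `evo_config`
#'   ([evolution_config()]), `n_seeds`, `top_fraction`, `k_top`.
#' @export
recovery_study_conditions <- function() {
  list(
    data_config = synthetic_config(
      n_cases = 200, n_controls = 200, n_features = 30, n_batches = 2,
      batch_sd = 0.2, covariate_sd = 0.1,
      main_effects = NULL,
      synergies = list(list(features = c("met_006", "met_007"),
                            form = "xor", beta = 4.5)),
      noise_sdlog = 0.5
    ),
    evo_config = evolution_config(
      population_size = 200, n_parents = 200, n_generations = 250,
      tournament_size = 8, max_program_length = 15, n_calc_registers = 10
    ),
    n_seeds = 4,
    top_fraction = 0.01,
    k_top = 20
  )
}

#' One replicate of the planted-XOR recovery experiment
#'
#' Generates a dataset under [recovery_study_conditions()], runs the full
#' two-round pipeline, and reports whether both members of the planted pair
#' rank in the round-1 top-5 occurrence list and survive the round-2
#' top-20 intersection, together with the evolved and baseline mean test
#' AUCs.
#'
#' @param seed Master seed for the replicate.
#' @param conditions Study conditions (default
#'   [recovery_study_conditions()]).
#' @return One-row tibble: `seed`, `pair_in_top5`, `pair_in_intersection`,
#'   `evolved_auc`, `baseline_auc`.
#' @export
recovery_replicate <- function(seed, conditions = recovery_study_conditions()) {
  data <- generate_dataset(conditions$data_config, seed = seed)
  pair <- conditions$data_config$synergies[[1]]$features
  pipe <- run_pipeline(data, conditions$evo_config,
                       n_seeds = conditions$n_seeds, seed = seed,
                       top_fraction = conditions$top_fraction,
                       k_top = conditions$k_top)
  top5 <- utils::head(pipe$round1$top_features$feature, 5)
  tibble(
    seed = seed,
    pair_in_top5 = all(pair %in% top5),
    pair_in_intersection = all(pair %in% pipe$key_features),
    evolved_auc = mean(c(pipe$round2$discovery$models$auc,
                         pipe$round2$replication$models$auc), na.rm = TRUE),
    baseline_auc = mean(c(pipe$baseline$discovery$auc,
                          pipe$baseline$replication$auc), na.rm = TRUE)
  )
}
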