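# Multi-seed cross-validated experiment ---------------------------------------

#' Class-stratified k-fold assignment
#'
#' Cases and controls are shuffled separately and dealt round-robin into `k`
#' folds, so per-class fold sizes differ by at most one.
#'
#' @param data Dataset tibble with a 0/1 `label` column.
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @return Integer vector of fold indices in `1..k`, one per row of `data`.
#' @export
stratified_kfold <- function(data, k = 5, seed = NULL) {
  labels <- data$label
  if (sum(labels == 1) < k || sum(labels == 0) < k) {
    abort("need at least k samples of each class for stratified k-fold")
  }
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in c(0, 1)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the observed scores (descending, with
#' sentinels at the ends) and records one (FPR, TPR) point per threshold.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels 0/1 labels.
#' @return A tibble with `threshold`, `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1).
#' @export
roc_points <- function(scores, labels) {
  pos <- labels == 1
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  tibble(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' @param roc A tibble from [roc_points()], or numeric scores (then pass
#'   `labels`).
#' @param labels 0/1 labels when `roc` is a score vector.
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc, labels = NULL) {
  if (!is.data.frame(roc)) roc <- roc_points(roc, labels)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Held-out test metrics of a program
#'
#' MCE, sensitivity, specificity at the 0.5 score threshold, plus the ROC
#' curve and its trapezoidal AUC.  A single-class test fold leaves
#' sensitivity or specificity `NA`.
#'
#' @param program An `lgp_program` (or any object with a `program` element).
#' @param test Test dataset tibble with `label`.
#' @return One-row tibble: `mce`, `sensitivity`, `specificity`, `auc`, and a
#'   `roc` list-column.
#' @export
test_metrics <- function(program, test) {
  if (!is.null(program$program)) program <- program$program
  if (nrow(test) == 0) abort("empty test set")
  sc <- program_scores(program, test)
  metrics_from_scores(sc$score, test$label)
}

metrics_from_scores <- function(scores, labels) {
  pred <- as.integer(scores >= 0.5)
  pos <- labels == 1
  tp <- sum(pred == 1 & pos)
  fn <- sum(pred == 0 & pos)
  tn <- sum(pred == 0 & !pos)
  fp <- sum(pred == 1 & !pos)
  roc <- roc_points(scores, labels)
  tibble(
    mce = mean(pred != labels),
    sensitivity = if (sum(pos) == 0) NA_real_ else tp / (tp + fn),
    specificity = if (sum(!pos) == 0) NA_real_ else tn / (tn + fp),
    auc = if (sum(pos) == 0 || sum(!pos) == 0) NA_real_ else
      auc_trapezoid(roc),
    roc = list(roc)
  )
}

#' One cross-validated run: five best models from one seed
#'
#' Derives the fold assignment and five per-fold evolution seeds
#' deterministically from `seed`, evolves a population on each set of four
#' training folds, and evaluates the best-of-run model on the held-out fold.
#'
#' @param data Preprocessed dataset tibble.
#' @param config An [evolution_config()].
#' @param seed Integer run seed.
#' @param k Number of folds (default 5).
#' @return A tibble of class `lgp_models` with one row per fold: `seed`,
#'   `fold`, `program` (list-column), `train_mce`, `n_features_effective`,
#'   `features` (list-column of effective feature names), and the held-out
#'   `mce`, `sensitivity`, `specificity`, `auc`, `roc`.
#' @export
run_cv <- function(data, config, seed, k = 5) {
  seeds <- derive_seeds(seed, k + 1)
  fold <- stratified_kfold(data, k, seed = seeds[1])
  rows <- lapply(seq_len(k), function(f) {
    best <- evolve_lgp(data[fold != f, , drop = FALSE], config,
                       seed = seeds[f + 1])
    met <- test_metrics(best$program, data[fold == f, , drop = FALSE])
    dplyr::bind_cols(
      tibble(seed = seed, fold = f, program = list(best$program),
             train_mce = best$fitness,
             n_features_effective = length(
               effective_features(best$program, names = FALSE)),
             features = list(effective_features(best$program, names = TRUE))),
      met
    )
  })
  new_lgp_models(dplyr::bind_rows(rows))
}

new_lgp_models <- function(x) {
  class(x) <- c("lgp_models", class(x))
  x
}

#' Multi-seed batch of cross-validated runs
#'
#' Runs [run_cv()] once per seed; with `k = 5` folds, `n_seeds` seeds yield
#' `5 * n_seeds` best models.
#'
#' @param data Preprocessed dataset tibble.
#' @param config An [evolution_config()].
#' @param n_seeds Number of independent run seeds (used as seeds
#'   `1..n_seeds` unless `seeds` is given).
#' @param seeds Optional explicit integer seed vector.
#' @param k Number of folds.
#' @param progress Print one line per completed seed.
#' @return An `lgp_models` tibble with `k * length(seeds)` rows.
#' @export
run_batch <- function(data, config, n_seeds, seeds = seq_len(n_seeds), k = 5,
                      progress = FALSE) {
  rows <- lapply(seeds, function(s) {
    res <- run_cv(data, config, s, k = k)
    if (progress) message(sprintf("seed %d: mean test MCE %.3f", s,
                                  mean(res$mce)))
    res
  })
  new_lgp_models(dplyr::bind_rows(rows))
}

#' Summary statistics of collection metrics
#'
#' Mean, median, min, max, sample standard deviation and the normal-interval
#' bounds mean +/- 1.96 sd (reported as the 5%/95% confidence rows) for each
#' held-out metric.
#'
#' @param models An `lgp_models` tibble (or any tibble with `mce`,
#'   `sensitivity`, `specificity`, `auc` columns).
#' @return A tibble with a `statistic` column and one column per metric.
#' @export
summarize_metrics <- function(models) {
  metrics <- c("mce", "sensitivity", "specificity", "auc")
  metrics <- intersect(metrics, names(models))
  stats <- list(
    mean = function(x) mean(x, na.rm = TRUE),
    median = function(x) median(x, na.rm = TRUE),
    min = function(x) min(x, na.rm = TRUE),
    max = function(x) max(x, na.rm = TRUE),
    std_dev = function(x) sd(x, na.rm = TRUE),
    conf_5 = function(x) mean(x, na.rm = TRUE) - 1.96 * sd_or_zero(x),
    conf_95 = function(x) mean(x, na.rm = TRUE) + 1.96 * sd_or_zero(x)
  )
  out <- lapply(names(stats), function(s) {
    row <- lapply(metrics, function(m) stats[[s]](models[[m]]))
    names(row) <- metrics
    dplyr::bind_cols(tibble(statistic = s), tibble::as_tibble(row))
  })
  dplyr::bind_rows(out)
}

sd_or_zero <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) 0 else sd(x)
}

#' @method tidy lgp_models
#' @export
tidy.lgp_models <- function(x, ...) {
  dplyr::select(as_tibble(x), -dplyr::any_of(c("program", "roc", "features")))
}

#' @method glance lgp_models
#' @export
glance.lgp_models <- function(x, ...) {
  tibble(n_models = nrow(x), n_seeds = length(unique(x$seed)),
         mean_mce = mean(x$mce, na.rm = TRUE),
         mean_auc = mean(x$auc, na.rm = TRUE),
         best_auc = max(x$auc, na.rm = TRUE),
         mean_n_features = mean(x$n_features_effective))
}

#' Persist / load a model collection as JSON lines
#'
#' One JSON object per line: seed, fold, metrics, effective features and the
#' serialized program.
#'
#' @param models An `lgp_models` tibble.
#' @param path Output file.
#' @return `read_models` returns the `lgp_models` tibble (without ROC
#'   curves, which are not persisted).
#' @export
write_models <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    jsonlite::toJSON(list(
      seed = models$seed[i], fold = models$fold[i],
      train_mce = models$train_mce[i], mce = models$mce[i],
      sensitivity = models$sensitivity[i],
      specificity = models$specificity[i], auc = models$auc[i],
      features = models$features[[i]],
      program = jsonlite::fromJSON(program_to_json(models$program[[i]]),
                                   simplifyVector = FALSE)
    ), auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  rows <- lapply(readLines(path), function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    prog <- program_from_json(jsonlite::toJSON(obj$program,
                                               auto_unbox = TRUE,
                                               digits = NA, null = "null"))
    tibble(seed = obj$seed, fold = obj$fold, program = list(prog),
           train_mce = obj$train_mce,
           n_features_effective = length(obj$features),
           features = list(unlist(obj$features) %||% character()),
           mce = obj$mce,
           sensitivity = obj$sensitivity %||% NA_real_,
           specificity = obj$specificity %||% NA_real_,
           auc = obj$auc %||% NA_real_)
  })
  new_lgp_models(dplyr::bind_rows(rows))
}
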