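# Synthetic case-control metabolomics data -------------------------------------
#
# Emulates a Biocrates-style targeted metabolomics case-control matrix:
# log-normal per-feature concentrations, multiplicative batch factors,
# additive covariate (age/sex/BMI) contributions, and disease labels drawn
# from a logistic model over the standardized latent signal of a few planted
# features — main effects plus purely synergistic interactions (product, or
# XOR-threshold: elevated log-odds iff exactly one member of a pair exceeds
# its median) whose members carry negligible marginal effect.

#' Synthetic data configuration
#'
#' Defaults mirror the structure of a typical targeted metabolomics
#' case-control study: 153 cases, 236 controls, 167 measured metabolites,
#' three analysis batches.  Planted signal defaults to three main-effect
#' features, one product pair, one XOR-threshold pair and one product
#' triple; set `main_effects = NULL` / `synergies = NULL` for pure noise.
#'
#' @param n_cases,n_controls Sample counts per class.
#' @param n_features Number of metabolite features.
#' @param n_batches Number of batches (1 disables batch structure).
#' @param batch_sd SD of per-(batch, feature) log-scale multiplicative batch
#'   factors.
#' @param covariate_sd SD (in units of feature SD) of per-feature covariate
#'   coefficients; 0 disables covariate structure.
#' @param main_effects Named numeric: log-odds per SD of latent signal,
#'   names are feature names (or a bare numeric with default names
#'   `met_001...`).
#' @param synergies List of `list(features = c(...), form = "product" |
#'   "xor", beta = log-odds)` interaction groups; `"xor"` requires a pair.
#' @param noise_sdlog Log-scale SD of the concentrations.
#' @param feature_names Optional feature names (default `met_001`, ...).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 153, n_controls = 236,
                             n_features = 167, n_batches = 3,
                             batch_sd = 0.3, covariate_sd = 0.2,
                             main_effects = c(met_001 = 0.8, met_002 = 0.5,
                                              met_003 = 0.4),
                             synergies = list(
                               list(features = c("met_004", "met_005"),
                                    form = "product", beta = 1.0),
                               list(features = c("met_006", "met_007"),
                                    form = "xor", beta = 1.5),
                               list(features = c("met_008", "met_009",
                                                 "met_010"),
                                    form = "product", beta = 0.8)
                             ),
                             noise_sdlog = 0.5,
                             feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- sprintf("met_%03d", seq_len(n_features))
  }
  stopifnot(length(feature_names) == n_features,
            !anyDuplicated(feature_names),
            n_cases >= 1, n_controls >= 1, n_batches >= 1)
  planted <- c(names(main_effects),
               unlist(lapply(synergies, `[[`, "features")))
  if (anyDuplicated(planted)) abort("planted features must be disjoint")
  if (!all(planted %in% feature_names)) {
    abort("planted features must be among the feature names")
  }
  for (s in synergies) {
    if (!s$form %in% c("product", "xor")) abort("unknown synergy form")
    if (s$form == "xor" && length(s$features) != 2) {
      abort("XOR-threshold synergies must be pairs")
    }
    if (!is.finite(s$beta)) abort("synergy coefficients must be finite")
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_features = as.integer(n_features), n_batches = as.integer(n_batches),
    batch_sd = batch_sd, covariate_sd = covariate_sd,
    main_effects = main_effects, synergies = synergies,
    noise_sdlog = noise_sdlog, feature_names = feature_names
  ), class = "synthetic_config")
}

# latent logit of the generative label model given latent signal matrix Z
# (columns named); interaction terms are centered so the intercept controls
# the case fraction
latent_logit <- function(Z, config, intercept) {
  lg <- rep(intercept, nrow(Z))
  for (f in names(config$main_effects)) {
    lg <- lg + config$main_effects[[f]] * Z[, f]
  }
  for (s in config$synergies) {
    term <- if (s$form == "product") {
      apply(Z[, s$features, drop = FALSE], 1, prod)
    } else {
      xor <- (Z[, s$features[1]] > 0) != (Z[, s$features[2]] > 0)
      xor - 0.5
    }
    lg <- lg + s$beta * term
  }
  lg
}

#' Generate a synthetic case-control dataset
#'
#' Samples are drawn until the requested case/control quotas are filled
#' (bounded rejection sampling; labels are Bernoulli draws from the logistic
#' model, so the conditional feature distributions stay exact).
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed.
#' @param truth_json Optional path: writes a sidecar JSON recording the
#'   planted truth (features, forms, coefficients) for recovery tests.
#' @return A dataset tibble (`sample_id`, `label`, `batch`, `age`, `sex`,
#'   `bmi`, then feature columns) with the planted truth attached as
#'   attribute `"truth"`.
#' @export
generate_dataset <- function(config, seed = NULL, truth_json = NULL) {
  with_seed(seed, {
    n_target <- config$n_cases + config$n_controls
    intercept <- qlogis(config$n_cases / n_target)
    max_draws <- 50 * n_target
    # per-feature log-normal location/scale and covariate coefficients
    mu <- rnorm(config$n_features, mean = 1.2, sd = 0.5)
    sdlog <- rep(config$noise_sdlog, config$n_features)
    batch_fac <- matrix(
      exp(rnorm(config$n_batches * config$n_features, 0, config$batch_sd)),
      nrow = config$n_batches
    )
    cov_beta <- matrix(
      rnorm(3 * config$n_features, 0, config$covariate_sd),
      nrow = 3
    )
    need <- c(control = config$n_controls, case = config$n_cases)
    keep_Z <- list(); keep_lab <- list(); drawn <- 0
    while ((need["case"] > 0 || need["control"] > 0) && drawn < max_draws) {
      block <- min(max(2 * sum(need), 100), max_draws - drawn)
      drawn <- drawn + block
      Z <- matrix(rnorm(block * config$n_features), nrow = block,
                  dimnames = list(NULL, config$feature_names))
      lab <- rbinom(block, 1, plogis(latent_logit(Z, config, intercept)))
      for (cl in c(0, 1)) {
        want <- if (cl == 1) need["case"] else need["control"]
        idx <- which(lab == cl)[seq_len(min(want, sum(lab == cl)))]
        if (length(idx) > 0) {
          keep_Z[[length(keep_Z) + 1]] <- Z[idx, , drop = FALSE]
          keep_lab[[length(keep_lab) + 1]] <- lab[idx]
          if (cl == 1) need["case"] <- need["case"] - length(idx)
          else need["control"] <- need["control"] - length(idx)
        }
      }
    }
    if (need["case"] > 0 || need["control"] > 0) {
      abort("could not reach requested case/control counts; check effect sizes")
    }
    Z <- do.call(rbind, keep_Z)
    label <- unlist(keep_lab)
    ord <- sample(length(label))   # interleave classes
    Z <- Z[ord, , drop = FALSE]
    label <- label[ord]
    n <- length(label)
    conc <- exp(sweep(sweep(Z, 2, sdlog, `*`), 2, mu, `+`))
    batch <- sample(rep_len(seq_len(config$n_batches), n))
    conc <- conc * batch_fac[batch, , drop = FALSE]
    age <- rnorm(n, 55, 10)
    sex <- rbinom(n, 1, 0.5)
    bmi <- rnorm(n, 27.5, 4)
    if (config$covariate_sd > 0) {
      C <- cbind(scale(age), sex - mean(sex), scale(bmi))
      feat_sd <- apply(conc, 2, sd)
      conc <- conc + (C %*% cov_beta) * rep(feat_sd, each = n)
    }
    colnames(conc) <- config$feature_names
    truth <- list(
      main_effects = as.list(config$main_effects),
      synergies = config$synergies,
      intercept = intercept
    )
    if (!is.null(truth_json)) {
      writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
                 truth_json)
    }
    out <- dplyr::bind_cols(
      tibble(sample_id = sprintf("S%04d", seq_len(n)), label = label,
             batch = batch, age = age, sex = sex, bmi = bmi),
      as_tibble(conc)
    )
    attr(out, "truth") <- truth
    out
  })
}

#' Bayes-optimal AUC of the generative label model (Monte-Carlo)
#'
#' Draws fresh samples, scores them with the true class-probability function
#' and computes the AUC of that oracle score — the ceiling any classifier can
#' reach on this generator.
#'
#' @param config A [synthetic_config()].
#' @param n_samples Monte-Carlo size.
#' @param seed Optional integer seed.
#' @return Scalar AUC estimate.
#' @export
bayes_auc <- function(config, n_samples = 10000, seed = NULL) {
  with_seed(seed, {
    intercept <- qlogis(config$n_cases / (config$n_cases + config$n_controls))
    Z <- matrix(rnorm(n_samples * config$n_features), nrow = n_samples,
                dimnames = list(NULL, config$feature_names))
    p <- plogis(latent_logit(Z, config, intercept))
    lab <- rbinom(n_samples, 1, p)
    if (length(unique(lab)) < 2) return(NA_real_)
    auc_trapezoid(p, lab)
  })
}

# Preprocessing chain ----------------------------------------------------------

#' Mean-ratio batch correction
#'
#' Each concentration is multiplied by the ratio of the feature's overall
#' mean to its batch mean, so after correction every (feature, batch) mean
#' equals the feature's overall pre-correction mean.
#'
#' @param data Dataset tibble with a `batch` column.
#' @return Corrected dataset tibble.
#' @export
batch_correct <- function(data) {
  if (!"batch" %in% names(data)) abort("no `batch` column")
  fn <- feature_names(data)
  X <- as.matrix(data[, fn, drop = FALSE])
  overall <- colMeans(X)
  for (b in unique(data$batch)) {
    rows <- data$batch == b
    bm <- colMeans(X[rows, , drop = FALSE])
    bad <- abs(bm) < 1e-12
    if (any(bad)) {
      abort(sprintf("zero batch mean for feature %s in batch %s",
                    fn[which(bad)[1]], b))
    }
    X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, overall / bm, `*`)
  }
  data[, fn] <- as_tibble(X)
  data
}

#' Covariate adjustment by OLS residualization
#'
#' Replaces every feature with the residuals of an ordinary least-squares
#' fit on an intercept plus age, sex and BMI, removing linear covariate
#' variation.
#'
#' @param data Dataset tibble with complete `age`, `sex`, `bmi` columns.
#' @param covariates Covariate column names to adjust for.
#' @return Adjusted dataset tibble.
#' @export
adjust_covariates <- function(data, covariates = c("age", "sex", "bmi")) {
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    abort(paste0("missing covariate columns: ",
                 paste(missing_cov, collapse = ", ")))
  }
  M <- cbind(intercept = 1, as.matrix(data[, covariates, drop = FALSE]))
  if (qr(M)$rank < ncol(M)) abort("collinear covariates")
  fn <- feature_names(data)
  Y <- as.matrix(data[, fn, drop = FALSE])
  fit <- lm.fit(M, Y)
  data[, fn] <- as_tibble(as.matrix(fit$residuals))
  data
}

#' Stratified discovery/replication split
#'
#' Cases and controls are each divided as evenly as possible between the two
#' halves (discovery receives the extra sample of an odd class).
#'
#' @param data Dataset tibble with `label`.
#' @param seed Optional integer seed.
#' @return Named list of two disjoint dataset tibbles, `discovery` and
#'   `replication`.
#' @export
split_discovery_replication <- function(data, seed = NULL) {
  if (sum(data$label == 1) < 2 || sum(data$label == 0) < 2) {
    abort("need at least two samples of each class to split")
  }
  with_seed(seed, {
    disc_idx <- integer()
    for (cl in c(0, 1)) {
      idx <- sample(which(data$label == cl))
      disc_idx <- c(disc_idx, idx[seq_len(ceiling(length(idx) / 2))])
    }
    disc_idx <- sort(disc_idx)
    list(discovery = data[disc_idx, , drop = FALSE],
         replication = data[-disc_idx, , drop = FALSE])
  })
}

#' Z-score normalization of the feature columns
#'
#' Centers each feature to mean zero and scales to unit variance (n-1
#' denominator).
#'
#' @param data Dataset tibble.
#' @return Normalized dataset tibble.
#' @export
normalize_features <- function(data) {
  fn <- feature_names(data)
  X <- as.matrix(data[, fn, drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance feature: %s", fn[which(sds == 0)[1]]))
  }
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  data[, fn] <- as_tibble(as.matrix(X))
  data
}

#' Full preprocessing chain
#'
#' Batch correction, covariate adjustment, stratified discovery/replication
#' split, then per-dataset z-score normalization (normalization happens
#' within each half, after the split).
#'
#' @param data Raw dataset tibble.
#' @param seed Optional integer seed for the split.
#' @return Named list `discovery`, `replication`.
#' @export
preprocess <- function(data, seed = NULL) {
  if ("batch" %in% names(data) && length(unique(data$batch)) > 1) {
    data <- batch_correct(data)
  }
  if (all(c("age", "sex", "bmi") %in% names(data))) {
    data <- adjust_covariates(data)
  }
  halves <- split_discovery_replication(data, seed = seed)
  lapply(halves, normalize_features)
}

#' Read/write the dataset CSV dialect
#'
#' Header row with `sample_id`, `label`, then optional `batch`, `age`,
#' `sex`, `bmi`, then one column per feature.
#'
#' @param data Dataset tibble.
#' @param path CSV path.
#' @return `read_dataset` returns the dataset tibble.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(out))) {
    abort("dataset CSV needs `sample_id` and `label` columns")
  }
  out
}
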