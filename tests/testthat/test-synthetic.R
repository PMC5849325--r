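test_that("the generator echoes the configured dimensions and balance", {
  cfg <- synthetic_config()   # study-scale defaults
  d <- generate_dataset(cfg, seed = 1)
  expect_equal(nrow(d), 389)
  expect_equal(sum(d$label == 1), 153)
  expect_equal(sum(d$label == 0), 236)
  expect_length(feature_names(d), 167)
  expect_false(anyNA(d))
  expect_true(all(d$batch %in% 1:3))
  # planted truth recorded alongside
  truth <- attr(d, "truth")
  expect_equal(names(truth$main_effects), c("met_001", "met_002", "met_003"))
  expect_equal(truth$synergies[[2]]$form, "xor")
})

test_that("all-zero effects make labels independent of features", {
  cfg <- synthetic_config(n_cases = 150, n_controls = 150, n_features = 12,
                          main_effects = NULL, synergies = NULL)
  d <- generate_dataset(cfg, seed = 5)
  cors <- vapply(feature_names(d), function(f) cor(d[[f]], d$label),
                 numeric(1))
  expect_lt(max(abs(cors)), 0.2)
  expect_true(is.na(bayes_auc(cfg, seed = 5)) ||
                abs(bayes_auc(cfg, n_samples = 5000, seed = 5) - 0.5) < 0.03)
})

test_that("a strong XOR pair has tiny marginals but high joint Bayes AUC", {
  cfg <- synthetic_config(
    n_cases = 400, n_controls = 400, n_features = 10, n_batches = 1,
    covariate_sd = 0, main_effects = NULL,
    synergies = list(list(features = c("met_003", "met_004"),
                          form = "xor", beta = 4.5)))
  d <- generate_dataset(cfg, seed = 7)
  # members individually carry almost no signal
  for (f in c("met_003", "met_004")) {
    expect_lt(abs(cor(d[[f]], d$label)), 0.15)
  }
  # the generative oracle separates well: closed form for a binary
  # +/- beta/2 logit is AUC = p^2 + p(1-p) = p with p = plogis(beta/2)
  a <- bayes_auc(cfg, n_samples = 20000, seed = 11)
  expect_equal(a, plogis(4.5 / 2), tolerance = 0.02)
})

test_that("synthetic configs validate planted structure", {
  expect_error(synthetic_config(main_effects = c(met_001 = 1),
                                synergies = list(list(
                                  features = c("met_001", "met_002"),
                                  form = "xor", beta = 1))), "disjoint")
  expect_error(synthetic_config(synergies = list(list(
    features = c("met_004", "met_005", "met_006"), form = "xor",
    beta = 1))), "pairs")
  expect_error(synthetic_config(n_features = 5,
                                main_effects = c(met_099 = 1),
                                synergies = NULL), "among the feature names")
})

test_that("mean-ratio batch correction equalizes batch means exactly", {
  cfg <- synthetic_config(n_cases = 60, n_controls = 60, n_features = 8,
                          n_batches = 3, batch_sd = 0.6,
                          main_effects = NULL, synergies = NULL)
  d <- generate_dataset(cfg, seed = 9)
  pre_means <- colMeans(d[, feature_names(d)])
  corr <- batch_correct(d)
  for (b in unique(corr$batch)) {
    bm <- colMeans(corr[corr$batch == b, feature_names(corr)])
    expect_equal(unname(bm), unname(pre_means), tolerance = 1e-12)
  }
  # direct two-batch hand check: batch-A mean 4, overall mean 2 -> halved
  toy <- tibble::tibble(sample_id = as.character(1:4), label = c(0, 1, 0, 1),
                        batch = c("A", "A", "B", "B"),
                        f1 = c(3, 5, 0, 0))
  expect_error(batch_correct(toy), "zero batch mean")
  toy$f1 <- c(3, 5, -1, 1)   # batch B mean 0 still errors
  expect_error(batch_correct(toy), "zero batch mean")
  toy$f1 <- c(3, 5, 1, 1)    # overall mean 2.5, batch A mean 4
  out <- batch_correct(toy)
  expect_equal(out$f1[1:2], c(3, 5) * 2.5 / 4)
  # single batch leaves data unchanged
  one <- dplyr::mutate(toy, batch = "A")
  expect_equal(batch_correct(one)$f1, one$f1)
})

test_that("covariate residualization is exact for linear structure", {
  withr::with_seed(33, {
    n <- 50
    d <- tibble::tibble(
      sample_id = as.character(1:n), label = rep_len(0:1, n),
      age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 27, 3),
      f1 = NA_real_, f2 = rnorm(n)
    )
    d$f1 <- 2 * d$age            # pure covariate signal -> residuals 0
    out <- adjust_covariates(d)
    expect_lt(max(abs(out$f1)), 1e-10)
    # residuals are orthogonal to every covariate column
    M <- cbind(1, d$age, d$sex, d$bmi)
    expect_lt(max(abs(crossprod(M, out$f2))), 1e-8)
    # independent feature is merely centered, up to the fitted noise
    expect_lt(abs(mean(out$f2)), 1e-10)
    expect_gt(cor(out$f2, d$f2 - mean(d$f2)), 0.9)
    # collinear covariates are rejected
    d$bmi <- d$age
    expect_error(adjust_covariates(d), "collinear")
  })
})

test_that("the discovery/replication split divides both classes evenly", {
  cfg <- synthetic_config(main_effects = NULL, synergies = NULL)
  d <- generate_dataset(cfg, seed = 13)
  halves <- split_discovery_replication(d, seed = 3)
  expect_equal(sum(halves$discovery$label == 1), 77)   # 153 cases -> 77/76
  expect_equal(sum(halves$replication$label == 1), 76)
  expect_equal(sum(halves$discovery$label == 0), 118)  # 236 controls
  expect_equal(sum(halves$replication$label == 0), 118)
  # disjoint and exhaustive
  expect_length(intersect(halves$discovery$sample_id,
                          halves$replication$sample_id), 0)
  expect_setequal(c(halves$discovery$sample_id,
                    halves$replication$sample_id), d$sample_id)
  # seeded determinism
  again <- split_discovery_replication(d, seed = 3)
  expect_identical(again$discovery$sample_id, halves$discovery$sample_id)
})

test_that("z-score normalization and its degenerate input", {
  d <- tibble::tibble(sample_id = as.character(1:6), label = rep_len(0:1, 6),
                      f1 = c(4, 8, 15, 16, 23, 42), f2 = rnorm(6))
  out <- normalize_features(d)
  for (f in c("f1", "f2")) {
    expect_lt(abs(mean(out[[f]])), 1e-10)
    expect_equal(sd(out[[f]]), 1)
  }
  # already-standardized input passes through
  out2 <- normalize_features(out)
  expect_equal(out2$f1, out$f1, tolerance = 1e-12)
  d$f2 <- 7
  expect_error(normalize_features(d), "zero-variance feature: f2")
})

test_that("dataset CSV and truth JSON round-trip", {
  cfg <- synthetic_config(n_cases = 10, n_controls = 12, n_features = 4,
                          main_effects = NULL,
                          synergies = list(list(
                            features = c("met_001", "met_002"),
                            form = "product", beta = 2)))
  dir <- withr::local_tempdir()
  truth_path <- file.path(dir, "truth.json")
  d <- generate_dataset(cfg, seed = 21, truth_json = truth_path)
  csv <- file.path(dir, "data.csv")
  write_dataset(d, csv)
  back <- read_dataset(csv)
  expect_equal(dim(back), dim(d))
  expect_equal(back$label, d$label)
  expect_equal(back$met_003, d$met_003)
  truth <- jsonlite::fromJSON(truth_path)
  expect_equal(truth$synergies$features[[1]], c("met_001", "met_002"))
  expect_equal(truth$synergies$beta, 2)
})

test_that("the preprocessing chain runs in its fixed order end to end", {
  cfg <- synthetic_config(n_cases = 40, n_controls = 40, n_features = 6,
                          main_effects = NULL, synergies = NULL)
  d <- generate_dataset(cfg, seed = 17)
  halves <- preprocess(d, seed = 17)
  for (half in halves) {
    X <- as.matrix(half[, feature_names(half)])
    expect_lt(max(abs(colMeans(X))), 1e-10)
    expect_equal(unname(apply(X, 2, sd)), rep(1, ncol(X)))
  }
})
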