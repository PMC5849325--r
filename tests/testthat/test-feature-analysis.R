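# build a minimal model collection from explicit effective-feature sets
models_from_sets <- function(sets, universe) {
  proto <- lgp_program(lgp_instruction("+", 1, 1, dest = 0),
                       n_features = length(universe),
                       n_calc_registers = 2, feature_names = universe)
  lgpnet:::new_lgp_models(tibble::tibble(
    seed = seq_along(sets), fold = 1L,
    program = rep(list(proto), length(sets)),
    train_mce = seq(0.1, 0.5, length.out = length(sets)),
    n_features_effective = lengths(sets),
    features = sets,
    mce = seq(0.1, 0.5, length.out = length(sets))
  ))
}

test_that("occurrence counting is per-model and binary", {
  u <- c("A", "B", "C", "D")
  sets <- list(c("A", "B"), c("A"), character(), c("B", "C", "B"))
  occ <- count_occurrences(models_from_sets(sets, u))
  ft <- occ$features
  expect_equal(ft$count[match(c("A", "B", "C", "D"), ft$feature)],
               c(2L, 2L, 1L, 0L))
  expect_equal(ft$frequency[ft$feature == "A"], 0.5)
  # duplicated feature inside one model counts once
  expect_equal(ft$count[ft$feature == "B"], 2L)
  # pair (A,B) co-occurs in exactly one of four models
  ab <- dplyr::filter(occ$pairs, feature_a == "A", feature_b == "B")
  expect_equal(ab$frequency, 0.25)
  expect_lte(ab$frequency, min(ft$frequency[ft$feature %in% c("A", "B")]))
})

test_that("pair frequencies never exceed either singleton frequency", {
  withr::with_seed(23, {
    u <- paste0("m", 1:8)
    for (rep in 1:20) {
      sets <- lapply(1:15, function(i) sample(u, sample(0:5, 1)))
      occ <- count_occurrences(models_from_sets(sets, u))
      if (nrow(occ$pairs) == 0) next
      fa <- occ$features$frequency[match(occ$pairs$feature_a,
                                         occ$features$feature)]
      fb <- occ$features$frequency[match(occ$pairs$feature_b,
                                         occ$features$feature)]
      expect_true(all(occ$pairs$frequency <= pmin(fa, fb)))
    }
  })
})

test_that("counting ignores model order and intron content", {
  u <- c("A", "B", "C")
  sets <- list(c("A", "B"), c("C"), c("A"))
  occ1 <- count_occurrences(models_from_sets(sets, u))
  occ2 <- count_occurrences(models_from_sets(rev(sets), u))
  expect_equal(occ1$features, occ2$features)
  expect_equal(occ1$pairs, occ2$pairs)

  # a model whose only feature reads sit in introns contributes nothing
  intron <- lgp_program(rbind(lgp_instruction("+", feat(0), feat(1), dest = 2),
                              lgp_instruction("*", 2, 2, dest = 0)),
                        n_features = 3, n_calc_registers = 3,
                        feature_names = u)
  models <- lgpnet:::new_lgp_models(tibble::tibble(
    seed = 1L, fold = 1L, program = list(intron),
    train_mce = 0.2, n_features_effective = 0L,
    mce = 0.2
  ))
  occ <- count_occurrences(models)   # no `features` column: recomputed
  expect_true(all(occ$features$count == 0))
})

test_that("top_k ranks by frequency with deterministic lexicographic ties", {
  u <- c("zeta", "alpha", "mid", "low")
  sets <- list(c("zeta", "alpha"), c("zeta", "alpha", "mid"))
  occ <- count_occurrences(models_from_sets(sets, u))
  top <- top_k(occ, 10)
  # zeta and alpha tie at 2/3: alphabetical order breaks the tie
  expect_equal(top$feature, c("alpha", "zeta", "mid", "low"))
  expect_equal(top$rank, 1:4)
  expect_equal(nrow(top_k(occ, 2)), 2)
  pairs <- top_k(occ, 5, "pairs")
  expect_equal(pairs$feature_a[1], "alpha")
})

test_that("fitness/feature-count correlation behaves on stereotyped inputs", {
  u <- paste0("m", 1:6)
  # feature counts proportional to MCE -> r = 1
  sets <- list("m1", c("m1", "m2"), c("m1", "m2", "m3"),
               c("m1", "m2", "m3", "m4"), u[1:5])
  models <- models_from_sets(sets, u)
  ct <- fitness_feature_correlation(models)
  expect_equal(ct$estimate, 1)
  expect_lt(ct$p.value, 1e-3)

  # constant feature count -> flagged undefined
  flat <- models_from_sets(list("m1", "m2", "m3"), u)
  expect_warning(res <- fitness_feature_correlation(flat), "variance")
  expect_true(is.na(res$estimate))

  # independent variables at larger n -> |r| small
  withr::with_seed(29, {
    sets <- lapply(1:200, function(i) sample(u, sample(1:5, 1)))
    big <- models_from_sets(sets, u)
    big$train_mce <- runif(200)
    expect_lt(abs(fitness_feature_correlation(big)$estimate), 0.2)
  })
})

test_that("top-k intersection preserves discovery order", {
  u <- paste0("m", 1:9)
  d <- count_occurrences(models_from_sets(
    list(c("m1", "m2", "m3"), c("m1", "m2"), "m1"), u))
  r_same <- count_occurrences(models_from_sets(
    list(c("m1", "m2", "m3"), c("m1", "m2"), "m1"), u))
  expect_equal(intersect_top(d, r_same, 3), c("m1", "m2", "m3"))
  r_disjoint <- count_occurrences(models_from_sets(
    list(c("m7", "m8"), c("m7", "m9")), u))
  expect_equal(intersect_top(d, r_disjoint, 2), character())
  r_partial <- count_occurrences(models_from_sets(
    list(c("m2", "m9"), c("m2", "m9")), u))
  expect_equal(intersect_top(d, r_partial, 2), "m2")
})

test_that("occurrence tables export to CSV", {
  u <- c("A", "B")
  occ <- count_occurrences(models_from_sets(list(c("A", "B"), "A"), u))
  prefix <- file.path(withr::local_tempdir(), "occ")
  paths <- write_occurrence(occ, prefix)
  ft <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(ft$count[ft$feature == "A"], 2)
  pr <- readr::read_csv(paths[2], show_col_types = FALSE)
  expect_equal(nrow(pr), 1)
})
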