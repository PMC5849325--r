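# Evolutionary loop ------------------------------------------------------------
#
# (mu + lambda) generational scheme: mu = population_size parents and
# lambda = n_parents offspring per generation; offspring are produced by
# tournament parent selection, segment recombination and single-element
# mutation restricted to effective instructions; survival is truncation of the
# pooled parents + offspring to the population_size lowest-MCE individuals,
# which makes the best-fitness trajectory monotone (elitism).

#' Evolution configuration
#'
#' Defaults follow the study design this package implements: population 500,
#' 500 parents, 500 generations, tournament size 16, truncation survival,
#' program length in \[1, 500\], operator set \{+, -, *, /, ^, if <, if >\},
#' constants \{1, ..., 10\}, 150 calculation registers, mutation restricted to
#' effective instructions.  Instruction-kind and operand-type sampling
#' probabilities are not part of that design and are exposed here
#' (`p_branch`, `operand_probs`), as are the variation rates.
#'
#' @param population_size Number of individuals kept each generation.
#' @param n_parents Number of offspring produced each generation.
#' @param n_generations Number of generations.
#' @param tournament_size Tournament size for parent selection.
#' @param min_program_length,max_program_length Instruction-count bounds
#'   (branches count as instructions).
#' @param n_calc_registers Calculation registers per program.
#' @param constant_set Numeric constants available to operands.
#' @param mutation_rate,recombination_rate Per-offspring probabilities of
#'   applying mutation / recombination.
#' @param p_branch Probability a sampled instruction is a branch.
#' @param operand_probs Probabilities of feature register / calculation
#'   register / constant operands.
#' @param both_offspring Admit both recombination children (`TRUE`) or one.
#' @param n_features,feature_names Filled in from the training data by
#'   [evolve_lgp()]; only needed for standalone [random_program()] calls.
#' @return A list of class `lgp_config`.
#' @export
evolution_config <- function(population_size = 500,
                             n_parents = 500,
                             n_generations = 500,
                             tournament_size = 16,
                             min_program_length = 1,
                             max_program_length = 500,
                             n_calc_registers = 150,
                             constant_set = 1:10,
                             mutation_rate = 0.9,
                             recombination_rate = 0.7,
                             p_branch = 0.25,
                             operand_probs = c(0.4, 0.4, 0.2),
                             both_offspring = TRUE,
                             n_features = NULL,
                             feature_names = NULL) {
  cfg <- list(
    population_size = as.integer(population_size),
    n_parents = as.integer(n_parents),
    n_generations = as.integer(n_generations),
    tournament_size = as.integer(tournament_size),
    min_program_length = as.integer(min_program_length),
    max_program_length = as.integer(max_program_length),
    n_calc_registers = as.integer(n_calc_registers),
    constant_set = constant_set,
    mutation_rate = mutation_rate,
    recombination_rate = recombination_rate,
    p_branch = p_branch,
    operand_probs = operand_probs / sum(operand_probs),
    both_offspring = isTRUE(both_offspring),
    n_features = if (is.null(n_features)) NULL else as.integer(n_features),
    feature_names = feature_names
  )
  stopifnot(cfg$population_size > 0, cfg$n_parents > 0,
            cfg$n_generations >= 0,
            cfg$tournament_size > 0,
            cfg$tournament_size <= cfg$population_size,
            cfg$min_program_length >= 1,
            cfg$max_program_length >= cfg$min_program_length)
  structure(cfg, class = "lgp_config")
}

#' Read an evolution configuration from YAML or JSON
#'
#' Field names mirror [evolution_config()] arguments; missing fields keep
#' their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `lgp_config`.
#' @export
read_evolution_config <- function(path) {
  obj <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(evolution_config, obj)
}

#' Mean classification error
#'
#' Fraction of samples whose predicted class differs from the label; the
#' evolutionary fitness (lower is better).
#'
#' @param program An `lgp_program`.
#' @param data Dataset tibble with a `label` column, or a feature matrix
#'   (then pass `labels`).
#' @param labels Optional 0/1 vector overriding `data$label`.
#' @return MCE in \[0, 1\].
#' @export
mce_fitness <- function(program, data, labels = NULL) {
  if (is.null(labels)) {
    if (!is.matrix(data) && "label" %in% names(data)) {
      labels <- data$label
    } else {
      abort("`labels` required when `data` has no label column")
    }
  }
  if (length(labels) == 0) abort("empty dataset")
  X <- as_feature_matrix(data, program)
  out <- cpp_execute_batch(program$code, X, program$n_calc_registers)
  mean((out >= 0) != (labels == 1))
}

#' Tournament parent selection
#'
#' Samples `k` individuals uniformly with replacement and returns the one
#' with the lowest MCE (ties go to the first sampled).
#'
#' @param population List of individuals (as produced inside [evolve_lgp()]),
#'   each with a `fitness` element.
#' @param k Tournament size.
#' @return The selected individual.
#' @export
tournament_select <- function(population, k) {
  idx <- sample.int(length(population), k, replace = TRUE)
  fit <- vapply(population[idx], `[[`, numeric(1), "fitness")
  population[[idx[which.min(fit)]]]
}

#' Mutate one element of one effective instruction
#'
#' Picks an effective instruction uniformly (falling back to any instruction
#' when none is effective) and replaces exactly one of its elements —
#' destination, operator/comparator, or one operand — with a freshly sampled
#' value guaranteed to differ.
#'
#' @param program An `lgp_program`.
#' @param config An `lgp_config` (supplies sampling distributions).
#' @return A mutated copy of the program.
#' @export
mutate_program <- function(program, config) {
  code <- program$code
  mask <- as.logical(cpp_effective_mask(code, program$n_calc_registers))
  pool <- if (any(mask)) which(mask) else seq_len(nrow(code))
  i <- sample1(pool)
  branch <- code[i, "kind"] == 1
  # candidate elements with more than one possible value
  elems <- c("lhs", "rhs")
  if (branch) {
    elems <- c(elems, "cmp")
  } else {
    elems <- c(elems, "op")
    if (config$n_calc_registers > 1) elems <- c(elems, "dest")
  }
  elem <- sample(elems, 1)
  if (elem == "dest") {
    others <- setdiff(seq_len(config$n_calc_registers) - 1, code[i, "dest"])
    code[i, "dest"] <- sample1(others)
  } else if (elem == "op") {
    others <- setdiff(1:5, code[i, "op"])
    code[i, "op"] <- sample1(others)
  } else if (elem == "cmp") {
    code[i, "op"] <- 3 - code[i, "op"]
  } else {
    cols <- if (elem == "lhs") c("lhs_type", "lhs_val") else
      c("rhs_type", "rhs_val")
    for (try in 1:100) {
      cand <- random_operand(config)
      if (!identical(unname(code[i, cols]), cand)) break
    }
    code[i, cols] <- cand
  }
  fast_program(code, program)
}

#' Segment recombination
#'
#' Chooses one contiguous (possibly empty) segment in each parent with
#' uniform endpoints and exchanges them; segment pairs are resampled until
#' both offspring lengths fall within the configured bounds.
#'
#' @param p1,p2 Parent `lgp_program`s.
#' @param config An `lgp_config` (length bounds).
#' @return List of two offspring programs.
#' @export
recombine_programs <- function(p1, p2, config) {
  n1 <- nrow(p1$code)
  n2 <- nrow(p2$code)
  lo <- config$min_program_length
  hi <- config$max_program_length
  for (try in 1:200) {
    s1 <- sample.int(n1 + 1, 1)
    e1 <- if (s1 > n1) s1 - 1 else sample1((s1 - 1):n1)
    s2 <- sample.int(n2 + 1, 1)
    e2 <- if (s2 > n2) s2 - 1 else sample1((s2 - 1):n2)
    l1 <- e1 - s1 + 1
    l2 <- e2 - s2 + 1
    c1_len <- n1 - l1 + l2
    c2_len <- n2 - l2 + l1
    if (c1_len >= lo && c1_len <= hi && c2_len >= lo && c2_len <= hi) {
      seg1 <- p1$code[seq_len(l1) + s1 - 1, , drop = FALSE]
      seg2 <- p2$code[seq_len(l2) + s2 - 1, , drop = FALSE]
      c1 <- rbind(p1$code[seq_len(s1 - 1), , drop = FALSE], seg2,
                  if (e1 < n1) p1$code[(e1 + 1):n1, , drop = FALSE])
      c2 <- rbind(p2$code[seq_len(s2 - 1), , drop = FALSE], seg1,
                  if (e2 < n2) p2$code[(e2 + 1):n2, , drop = FALSE])
      return(list(fast_program(c1, p1), fast_program(c2, p2)))
    }
  }
  list(p1, p2)
}

#' Evolve a population of LGP classifiers
#'
#' Runs the full generational loop against a training set and returns the
#' lowest-MCE individual of the final population.  Survivor truncation sorts
#' by (MCE, fewer effective instructions, insertion order), a deterministic
#' tie-break with mild parsimony pressure.
#'
#' @param train Training dataset tibble (metadata + feature columns) with a
#'   0/1 `label` column.
#' @param config An [evolution_config()].
#' @param seed Optional integer seed; the run is a pure function of
#'   (train, config, seed).
#' @return A list of class `lgp_individual`: `program`, `fitness` (training
#'   MCE), `n_effective`, and `history` (best MCE per generation, length
#'   `n_generations + 1`).
#' @export
evolve_lgp <- function(train, config, seed = NULL) {
  fn <- feature_names(train)
  if (length(fn) == 0) abort("training data has no feature columns")
  if (nrow(train) == 0) abort("empty training set")
  config$n_features <- length(fn)
  config$feature_names <- fn
  X <- as_feature_matrix(train)
  labels <- train$label == 1
  with_seed(seed, {
    mu <- config$population_size
    lambda <- config$n_parents
    ts <- config$tournament_size
    n_calc <- config$n_calc_registers
    # parallel vectors instead of a list of individual records: the loop is
    # dominated by per-offspring bookkeeping, so keep it flat
    progs <- lapply(seq_len(mu), function(i) random_program(config))
    ev <- vapply(progs, function(p) cpp_eval_program(p$code, X, labels,
                                                     n_calc), numeric(2))
    fit <- ev[1, ]
    neff <- ev[2, ]
    ord <- order(fit, neff)
    progs <- progs[ord]; fit <- fit[ord]; neff <- neff[ord]
    history <- numeric(config$n_generations + 1)
    history[1] <- fit[1]
    codes <- lapply(progs, `[[`, "code")
    proto <- progs[[1]]
    for (g in seq_len(config$n_generations)) {
      off <- cpp_offspring(codes, fit, X, labels, lambda, ts,
                           config$recombination_rate, config$mutation_rate,
                           config$both_offspring,
                           config$min_program_length,
                           config$max_program_length,
                           config$n_features, n_calc,
                           as.numeric(config$constant_set),
                           config$operand_probs)
      # truncation over the pooled mu + lambda, stable in (fitness,
      # effective size, insertion order) — elitist by construction
      all_fit <- c(fit, off$fit)
      all_neff <- c(neff, off$neff)
      keep <- order(all_fit, all_neff)[seq_len(mu)]
      codes <- c(codes, off$codes)[keep]
      fit <- all_fit[keep]
      neff <- all_neff[keep]
      history[g + 1] <- fit[1]
    }
    best_code <- codes[[1]]
    colnames(best_code) <- .code_cols
    structure(list(program = fast_program(best_code, proto),
                   fitness = fit[1],
                   n_effective = as.integer(neff[1]), history = history),
              class = "lgp_individual")
  })
}

#' @export
print.lgp_individual <- function(x, ...) {
  cat(sprintf("<lgp_individual: training MCE %.4f, %d effective instructions>\n",
              x$fitness, x$n_effective))
  print(x$program)
  invisible(x)
}

#' @method glance lgp_individual
#' @export
glance.lgp_individual <- function(x, ...) {
  tibble(fitness = x$fitness, n_effective = x$n_effective,
         n_instructions = length(x$program),
         n_features_effective = length(effective_features(x$program,
                                                          names = FALSE)))
}
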