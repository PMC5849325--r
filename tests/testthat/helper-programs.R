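# Shared fixtures: small programs, configs and datasets built in code.

# the eight-instruction three-metabolite demonstration program and the
# sample that exercises its control flow
demo_input <- c(0.2, 0.01, 0.085)

# small config for random-program sweeps and evolution tests
small_config <- function(...) {
  evolution_config(
    population_size = 30, n_parents = 30, n_generations = 20,
    tournament_size = 4, max_program_length = 12, n_calc_registers = 5,
    n_features = 4, feature_names = paste0("f", 1:4), ...
  )
}

# reference (pure-R) execution of the effective subset of a program
run_effective_subset <- function(program, features) {
  mask <- effective_instructions(program)
  if (!any(mask)) {
    return(1)   # r[0] keeps its initial value
  }
  sub <- lgp_program(program$code[mask, , drop = FALSE], program$n_features,
                     program$n_calc_registers, program$feature_names)
  execute_program(sub, features)$final_output
}

# labelled toy dataset: one informative feature, label = feature > 0
separable_data <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    x <- c(runif(n / 2, -2, -0.2), runif(n / 2, 0.2, 2))
    tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                   label = as.integer(x > 0),
                   f1 = x)
  })
}

# random labelled dataset with several noise features
noise_data <- function(n = 30, p = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                     label = rep_len(0:1, n)),
      tibble::as_tibble(X)
    )
  })
}
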