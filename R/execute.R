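# Program execution semantics -------------------------------------------------
#
# Instructions run sequentially.  A branch whose condition is false skips the
# single instruction that follows it; if that instruction is itself a branch,
# the skipped branch's own guarded instruction is also not executed, so a chain
# of k consecutive branches guards the one instruction after the chain and the
# chain fires only when every condition holds.  A trailing branch guards
# nothing and is a no-op.  All calculation registers start at 1; the final
# value of r[0], pushed through the logistic sigmoid and thresholded at 0.5,
# is the class prediction (score >= 0.5 -> class 1).

#' Protected arithmetic operators
#'
#' Division by a (near-)zero denominator (|b| < 1e-9) returns 1, the neutral
#' register-initialization value.  Power is computed as `|a|^b` with the
#' result capped at 1e6 and domain errors/overflow returning 1.  Any other
#' operator result that overflows to non-finite collapses to 1, so execution
#' is total on finite inputs.
#'
#' @param op One of `"+", "-", "*", "/", "^"`.
#' @param a,b Finite numeric scalars.
#' @return A finite numeric scalar.
#' @export
apply_operator <- function(op, a, b) {
  r <- switch(op,
    "+" = a + b,
    "-" = a - b,
    "*" = a * b,
    "/" = if (abs(b) < 1e-9) return(1) else a / b,
    "^" = {
      p <- abs(a)^b
      if (!is.finite(p)) return(1)
      return(min(p, 1e6))
    },
    abort(paste0("unknown operator: ", op))
  )
  if (!is.finite(r)) 1 else r
}

#' Logistic sigmoid
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) plogis(x)

#' Execute a program on one sample (reference interpreter)
#'
#' A plain-R interpreter used as the readable reference for the compiled
#' executor; it can also record the full register trace.  For scoring whole
#' datasets use [program_scores()], which runs the same semantics in compiled
#' code.
#'
#' @param program An `lgp_program`.
#' @param features Numeric vector of feature values, length
#'   `program$n_features`.
#' @param trace If `TRUE`, also return the value of every calculation
#'   register after each executed instruction.
#' @return A list with `final_output` (final r\[0\]), `score`
#'   (sigmoid-transformed output), `predicted_class` (1 iff score >= 0.5),
#'   and, if requested, `trace`: a tibble with one row per instruction
#'   (`executed`, `r0`, and a `registers` list-column).
#' @export
execute_program <- function(program, features, trace = FALSE) {
  code <- program$code
  stopifnot(length(features) == program$n_features)
  n <- nrow(code)
  r <- rep(1, program$n_calc_registers)
  executed <- logical(n)
  r0_after <- rep(NA_real_, n)
  regs <- if (trace) vector("list", n) else NULL
  op_names <- names(.op_codes)
  val <- function(type, v) {
    switch(as.character(type), "0" = features[v + 1], "1" = r[v + 1], v)
  }
  i <- 1
  while (i <= n) {
    a <- val(code[i, "lhs_type"], code[i, "lhs_val"])
    b <- val(code[i, "rhs_type"], code[i, "rhs_val"])
    executed[i] <- TRUE
    if (code[i, "kind"] == 0) {
      r[code[i, "dest"] + 1] <- apply_operator(op_names[code[i, "op"]], a, b)
      r0_after[i] <- r[1]
      if (trace) regs[[i]] <- r
      i <- i + 1
    } else {
      cond <- if (code[i, "op"] == 1) a < b else a > b
      r0_after[i] <- r[1]
      if (trace) regs[[i]] <- r
      if (cond) {
        i <- i + 1
      } else {
        j <- i + 1
        while (j <= n && code[j, "kind"] == 1) j <- j + 1
        i <- j + 1
      }
    }
  }
  out <- list(final_output = r[1], score = sigmoid(r[1]),
              predicted_class = as.integer(sigmoid(r[1]) >= 0.5))
  if (trace) {
    out$trace <- tibble(instruction = seq_len(n), executed = executed,
                        r0 = r0_after, registers = regs)
  }
  out
}

#' Score a program on every sample of a dataset
#'
#' Runs the compiled executor over a whole sample-by-feature matrix.
#'
#' @param program An `lgp_program`.
#' @param data A dataset tibble (see [feature_names()]) or a numeric matrix
#'   whose columns are the program's features.
#' @return A tibble with `output` (final r\[0\]), `score` and
#'   `predicted_class` per sample.
#' @export
program_scores <- function(program, data) {
  X <- as_feature_matrix(data, program)
  out <- cpp_execute_batch(program$code, X, program$n_calc_registers)
  tibble(output = out, score = sigmoid(out),
         predicted_class = as.integer(out >= 0))
}

as_feature_matrix <- function(data, program = NULL) {
  if (is.matrix(data)) {
    X <- data
  } else {
    fn <- if (!is.null(program) && !is.null(program$feature_names)) {
      program$feature_names
    } else {
      feature_names(data)
    }
    X <- as.matrix(data[, fn, drop = FALSE])
  }
  storage.mode(X) <- "double"
  if (!is.null(program) && ncol(X) != program$n_features) {
    abort("dataset feature count does not match program n_features")
  }
  X
}

#' Effective instructions of a program
#'
#' Backward structural reachability from the output register r\[0\]: an
#' assignment is effective iff some later effective instruction can read its
#' destination; a branch is effective iff the instruction it guards (through
#' any chain of consecutive branches) is effective.  Writes guarded by a
#' branch are conditional, so a guarded assignment does not satisfy an earlier
#' writer's read — the analysis is conservative, and the marked subset
#' executed alone reproduces the full program's final r\[0\] exactly on every
#' input.
#'
#' @param program An `lgp_program`.
#' @return Logical vector, one element per instruction.
#' @export
effective_instructions <- function(program) {
  as.logical(cpp_effective_mask(program$code, program$n_calc_registers))
}

#' Effective features of a program
#'
#' Feature registers read by at least one effective instruction (branch
#' operands included).
#'
#' @param program An `lgp_program`.
#' @param names If `TRUE` (default when the program carries feature names)
#'   return feature names, otherwise 0-based indices.
#' @return Character vector of names or sorted integer vector of indices.
#' @export
effective_features <- function(program,
                               names = !is.null(program$feature_names)) {
  mask <- effective_instructions(program)
  code <- program$code[mask, , drop = FALSE]
  idx <- sort(unique(c(
    code[code[, "lhs_type"] == 0, "lhs_val"],
    code[code[, "rhs_type"] == 0, "rhs_val"]
  )))
  if (names) program$feature_names[idx + 1] else as.integer(idx)
}

#' Drop introns from a program
#'
#' @param program An `lgp_program`.
#' @return The program restricted to its effective instructions (the full
#'   program if none are effective, to keep the result a valid program).
#' @export
remove_introns <- function(program) {
  mask <- effective_instructions(program)
  if (!any(mask)) return(program)
  lgp_program(program$code[mask, , drop = FALSE], program$n_features,
              program$n_calc_registers, program$feature_names)
}
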