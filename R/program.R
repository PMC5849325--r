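# Register-machine program representation ------------------------------------
#
# A program is an ordered list of instructions over a register file: read-only
# feature registers (one per input feature), writable calculation registers
# (r[0] is the designated output), and literal constants.  Internally the
# instruction list is a numeric matrix (one row per instruction) so that the
# compiled executor can run it without any translation:
#   kind, dest, op, lhs_type, lhs_val, rhs_type, rhs_val
# kind 0 = assignment, 1 = branch; op codes 1..5 = + - * / ^ for assignments
# and 1 '<', 2 '>' for branch comparators; operand types 0 feature register,
# 1 calculation register, 2 constant.  All register indices are 0-based.

.op_codes <- c("+" = 1, "-" = 2, "*" = 3, "/" = 4, "^" = 5)
.cmp_codes <- c("<" = 1, ">" = 2)

#' Construct an LGP program
#'
#' Builds a program from an instruction matrix (see [lgp_instruction()] for a
#' friendlier way to assemble one).  The output register is always
#' calculation register `r[0]`; all calculation registers are initialized to 1
#' at execution time.
#'
#' @param code Numeric instruction matrix with columns `kind, dest, op,
#'   lhs_type, lhs_val, rhs_type, rhs_val` (0-based register indices).
#' @param n_features Number of feature registers the program may read.
#' @param n_calc_registers Number of calculation registers (default 150).
#' @param feature_names Optional character vector naming the features.
#' @return An object of class `lgp_program`.
#' @export
lgp_program <- function(code, n_features, n_calc_registers = 150,
                        feature_names = NULL) {
  code <- as.matrix(code)
  if (ncol(code) != 7) abort("`code` must have 7 columns.")
  storage.mode(code) <- "double"
  colnames(code) <- c("kind", "dest", "op", "lhs_type", "lhs_val",
                      "rhs_type", "rhs_val")
  validate_program_code(code, n_features, n_calc_registers)
  if (!is.null(feature_names) && length(feature_names) != n_features) {
    abort("`feature_names` must have length `n_features`.")
  }
  structure(
    list(code = code, n_features = as.integer(n_features),
         n_calc_registers = as.integer(n_calc_registers),
         feature_names = feature_names),
    class = "lgp_program"
  )
}

validate_program_code <- function(code, n_features, n_calc) {
  n <- nrow(code)
  if (n < 1) abort("a program must contain at least one instruction")
  assign <- code[, "kind"] == 0
  if (any(code[assign, "dest"] < 0 | code[assign, "dest"] >= n_calc)) {
    abort("assignment destination must be a calculation register")
  }
  for (side in c("lhs", "rhs")) {
    type <- code[, paste0(side, "_type")]
    val <- code[, paste0(side, "_val")]
    if (any(type == 0 & (val < 0 | val >= n_features))) {
      abort("feature register operand out of range")
    }
    if (any(type == 1 & (val < 0 | val >= n_calc))) {
      abort("calculation register operand out of range")
    }
  }
  invisible(code)
}

#' Build a single instruction row
#'
#' Helper to assemble instruction matrices for [lgp_program()] by hand, mainly
#' for tests and worked examples.  Operands are written as `feat(i)`,
#' `calc(i)` (0-based index) or a bare number (constant).
#'
#' @param dest Destination calculation-register index (assignments only).
#' @param op Operator: one of `"+", "-", "*", "/", "^"` for assignments or
#'   `"<", ">"` for branches.
#' @param lhs,rhs Operands created by [feat()], [calc()], or a numeric
#'   constant.
#' @return A 1x7 numeric instruction row.
#' @export
lgp_instruction <- function(op, lhs, rhs, dest = NULL) {
  branch <- op %in% names(.cmp_codes)
  if (!branch && !op %in% names(.op_codes)) {
    abort(paste0("unknown operator: ", op))
  }
  if (branch && !is.null(dest)) abort("branches have no destination")
  if (!branch && is.null(dest)) abort("assignments need a destination")
  l <- as_operand(lhs)
  r <- as_operand(rhs)
  matrix(c(if (branch) 1 else 0,
           if (branch) -1 else dest,
           if (branch) .cmp_codes[[op]] else .op_codes[[op]],
           l[1], l[2], r[1], r[2]),
         nrow = 1)
}

#' @rdname lgp_instruction
#' @param i 0-based register index.
#' @export
feat <- function(i) structure(c(0, i), class = "lgp_operand")

#' @rdname lgp_instruction
#' @export
calc <- function(i) structure(c(1, i), class = "lgp_operand")

as_operand <- function(x) {
  if (inherits(x, "lgp_operand")) return(unclass(x))
  if (is.numeric(x) && length(x) == 1) return(c(2, x))
  abort("operands must be feat(i), calc(i) or a numeric constant")
}

#' @export
length.lgp_program <- function(x) nrow(x$code)

#' Tidy a program into an instruction tibble
#'
#' @param x An `lgp_program`.
#' @param ... Unused.
#' @return A tibble with one row per instruction: index, kind, destination,
#'   operator and rendered operands.
#' @method tidy lgp_program
#' @export
tidy.lgp_program <- function(x, ...) {
  code <- x$code
  kind <- ifelse(code[, "kind"] == 1, "branch", "assignment")
  op <- ifelse(code[, "kind"] == 1,
               names(.cmp_codes)[code[, "op"]],
               names(.op_codes)[code[, "op"]])
  tibble(
    instruction = seq_len(nrow(code)),
    kind = kind,
    dest = ifelse(code[, "kind"] == 0, code[, "dest"], NA_real_),
    op = op,
    lhs = render_operand(code[, "lhs_type"], code[, "lhs_val"], x),
    rhs = render_operand(code[, "rhs_type"], code[, "rhs_val"], x),
    effective = effective_instructions(x)
  )
}

render_operand <- function(type, val, program) {
  out <- character(length(type))
  fn <- program$feature_names
  for (k in seq_along(type)) {
    out[k] <- switch(as.character(type[k]),
      "0" = if (is.null(fn)) sprintf("f[%d]", val[k]) else fn[val[k] + 1],
      "1" = sprintf("r[%d]", val[k]),
      format(val[k])
    )
  }
  out
}

#' @export
format.lgp_program <- function(x, ...) {
  code <- x$code
  n <- nrow(code)
  lines <- character(n)
  depth <- 0
  for (i in seq_len(n)) {
    lhs <- render_operand(code[i, "lhs_type"], code[i, "lhs_val"], x)
    rhs <- render_operand(code[i, "rhs_type"], code[i, "rhs_val"], x)
    indent <- strrep("  ", depth)
    if (code[i, "kind"] == 1) {
      cmp <- names(.cmp_codes)[code[i, "op"]]
      lines[i] <- sprintf("I%d: %sif %s %s %s", i, indent, lhs, cmp, rhs)
      depth <- depth + 1
    } else {
      op <- names(.op_codes)[code[i, "op"]]
      lines[i] <- sprintf("I%d: %sr[%d] = %s %s %s", i, indent,
                          code[i, "dest"], lhs, op, rhs)
      depth <- 0
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
print.lgp_program <- function(x, ...) {
  cat(sprintf("<lgp_program: %d instructions, %d features, %d calc registers>\n",
              nrow(x$code), x$n_features, x$n_calc_registers))
  cat(format(x), "\n")
  invisible(x)
}

# JSON serialization ----------------------------------------------------------

#' Serialize a program to JSON (and back)
#'
#' The JSON form lists one record per instruction with named operator and
#' operand types so programs can be stored alongside experiment reports and
#' round-trip exactly.
#'
#' @param program An `lgp_program`.
#' @param path File path; for `program_from_json`, a path or JSON string.
#' @return `program_to_json` returns the JSON string invisibly (written to
#'   `path` when given); `program_from_json` returns an `lgp_program`.
#' @export
program_to_json <- function(program, path = NULL) {
  code <- program$code
  instr <- lapply(seq_len(nrow(code)), function(i) {
    branch <- code[i, "kind"] == 1
    list(
      kind = if (branch) "branch" else "assignment",
      dest = if (branch) NULL else unname(code[i, "dest"]),
      op = if (branch) names(.cmp_codes)[code[i, "op"]] else
        names(.op_codes)[code[i, "op"]],
      lhs = operand_json(code[i, "lhs_type"], code[i, "lhs_val"]),
      rhs = operand_json(code[i, "rhs_type"], code[i, "rhs_val"])
    )
  })
  obj <- list(
    n_features = program$n_features,
    n_calc_registers = program$n_calc_registers,
    feature_names = program$feature_names,
    instructions = instr
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

operand_json <- function(type, val) {
  list(type = c("feature", "calc", "const")[type + 1], value = unname(val))
}

#' @rdname program_to_json
#' @export
program_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  type_code <- c(feature = 0, calc = 1, const = 2)
  code <- do.call(rbind, lapply(obj$instructions, function(ins) {
    branch <- identical(ins$kind, "branch")
    c(if (branch) 1 else 0,
      if (branch) -1 else ins$dest,
      if (branch) .cmp_codes[[ins$op]] else .op_codes[[ins$op]],
      type_code[[ins$lhs$type]], ins$lhs$value,
      type_code[[ins$rhs$type]], ins$rhs$value)
  }))
  lgp_program(code, obj$n_features, obj$n_calc_registers,
              feature_names = unlist(obj$feature_names))
}

#' The eight-instruction demonstration program
#'
#' A small hand-written classifier over three metabolite features
#' (`m1`, `m2`, `m3`) exercising every control-flow rule: a guarded
#' assignment, a two-branch chain whose guarded instruction only runs when
#' both conditions hold, and intron-free data flow into the output register.
#' Registers r\[0\], r\[4\], r\[5\] (and the rest of the calculation file)
#' start at 1.  On the sample `(0.2, 0.01, 0.085)` the first condition holds,
#' r\[0\] becomes 0.51 after the second instruction, the two-branch chain
#' fails at its first condition, and the final r\[0\] is 1.0039 (4 d.p.),
#' classified as class one.
#'
#' @return An `lgp_program` with 8 instructions, 3 features and 6
#'   calculation registers.
#' @export
demo_program <- function() {
  code <- rbind(
    lgp_instruction(">", feat(0), feat(2)),               # I1 if m1 > m3
    lgp_instruction("+", feat(1), 0.5, dest = 0),         # I2 r0 = m2 + 0.5
    lgp_instruction("/", feat(1), calc(0), dest = 4),     # I3 r4 = m2 / r0
    lgp_instruction(">", calc(0), 4),                     # I4 if r0 > 4
    lgp_instruction("<", feat(2), 10),                    # I5   if m3 < 10
    lgp_instruction("-", feat(2), calc(4), dest = 5),     # I6     r5 = m3 - r4
    lgp_instruction("*", calc(4), feat(0), dest = 4),     # I7 r4 = r4 * m1
    lgp_instruction("+", calc(5), calc(4), dest = 0)      # I8 r0 = r5 + r4
  )
  lgp_program(code, n_features = 3, n_calc_registers = 6,
              feature_names = c("m1", "m2", "m3"))
}

# Random generation -----------------------------------------------------------

# internal constructor for variation operators: code is valid by construction
# (sampled from the same distributions lgp_program() validates), so skip the
# checks in the per-offspring hot path
fast_program <- function(code, proto) {
  structure(list(code = code, n_features = proto$n_features,
                 n_calc_registers = proto$n_calc_registers,
                 feature_names = proto$feature_names),
            class = "lgp_program")
}

.code_cols <- c("kind", "dest", "op", "lhs_type", "lhs_val", "rhs_type",
                "rhs_val")

random_operand <- function(config) {
  type <- sample.int(3, 1, prob = config$operand_probs) - 1
  val <- switch(as.character(type),
    "0" = sample.int(config$n_features, 1) - 1,
    "1" = sample.int(config$n_calc_registers, 1) - 1,
    sample1(config$constant_set)
  )
  c(type, val)
}

random_instruction <- function(config) {
  branch <- runif(1) < config$p_branch
  l <- random_operand(config)
  r <- random_operand(config)
  c(if (branch) 1 else 0,
    if (branch) -1 else sample.int(config$n_calc_registers, 1) - 1,
    if (branch) sample.int(2, 1) else sample.int(5, 1),
    l, r)
}

#' Generate a random program
#'
#' Length is uniform on `[min_program_length, max_program_length]`; each
#' instruction is a branch with probability `p_branch`, operands are feature
#' register / calculation register / constant with probabilities
#' `operand_probs`, operators uniform over the operator set, constants uniform
#' over the constant set.
#'
#' @param config An [evolution_config()].
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return An `lgp_program`.
#' @export
random_program <- function(config, seed = NULL) {
  with_seed(seed, {
    n <- sample1(seq(config$min_program_length, config$max_program_length))
    code <- t(vapply(seq_len(n), function(i) random_instruction(config),
                     numeric(7)))
    colnames(code) <- .code_cols
    fast_program(code, list(n_features = as.integer(config$n_features),
                            n_calc_registers =
                              as.integer(config$n_calc_registers),
                            feature_names = config$feature_names))
  })
}
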