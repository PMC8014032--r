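# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package take an explicit
# seed; nothing relies on hidden global state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Printed appraisal values in the plant-fingerprinting literature are
#' conventionally rounded half away from zero, not to even as [base::round()]
#' does. Used when comparing computed statistics against published decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties going away from zero.
#' @export
#' @examples
#' round_half_up(0.0625, 3)  # 0.063, where round() gives 0.062
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# C(n, 2) without relying on choose()'s generality; n may be a vector.
choose2 <- function(n) n * (n - 1) / 2

stop_validity <- function(...) {
  stop(structure(class = c("vdp_validity_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("vdp_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
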