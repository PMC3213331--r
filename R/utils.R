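# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  # round half away from zero, matching how the printed tables round
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their seed and never disturb the caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# condition constructors used by the CLI to map failures to exit codes
usage_error <- function(msg) {
  structure(class = c("hfactor_usage_error", "error", "condition"),
            list(message = msg, call = NULL))
}

data_error <- function(msg) {
  structure(class = c("hfactor_data_error", "error", "condition"),
            list(message = msg, call = NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
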