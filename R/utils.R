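# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions never leak RNG
#' state into the caller's session.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Spawn reproducible child seeds from a master seed
#'
#' All multi-replicate computations (envelopes, simulations) draw one child
#' seed per replicate up front, so results are identical regardless of the
#' order replicates are evaluated in.
#' @noRd
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_ddd <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_ddd(sprintf("`%s` must be a single finite number", name))
  }
  if (strict && x <= lower) stop_ddd(sprintf("`%s` must be > %g", name, lower))
  if (!strict && x < lower) stop_ddd(sprintf("`%s` must be >= %g", name, lower))
  invisible(x)
}

# Square-metre / hectare conversions used throughout: densities are reported
# per hectare but enter the Clark-Evans index per square metre.
M2_PER_HA <- 1e4
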