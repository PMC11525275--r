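#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the R random number generator, evaluates `expr`, and restores the
#' caller's RNG state afterwards, so seeded package functions never perturb
#' the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage child seed from a master seed
#'
#' Deterministic, stage-keyed seed spawning so pipeline stages are
#' individually rerunnable. Always returns a non-negative integer below
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 2654435 + h * 40503) %% 2147483629)
}

# stopifnot-style check with a formatted message
check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
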