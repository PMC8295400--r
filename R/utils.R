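#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm qnorm rbinom rgeom rnorm rpois runif setNames
NULL

# Internal argument checks ---------------------------------------------------

stop_if_not_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", what))
  }
  invisible(x)
}

stop_if_not_count <- function(x, what, positive = TRUE) {
  ok <- is.numeric(x) && !anyNA(x) && all(x == floor(x)) &&
    all(x >= if (positive) 1 else 0)
  if (!ok) {
    abort(sprintf("`%s` must be %s integer(s).", what,
                  if (positive) "positive" else "non-negative"))
  }
  invisible(as.integer(x))
}

# Seed handling: every stochastic entry point takes a single integer seed and
# derives per-purpose substreams so that adding one consumer never perturbs
# the draws of another.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed_local <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}
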