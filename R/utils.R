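# Internal helpers: typed errors, seeded RNG scopes, batched array algebra.

stop_axialseg <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "axialseg_error", "error"),
                      call = call))
}

check_that <- function(ok, class, msg) {
  if (!isTRUE(ok)) stop_axialseg(class, msg, call = sys.call(-1))
  invisible(TRUE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds with `seed`, evaluates `expr`, and
#' restores the previous state, so seeded generators do not disturb the
#' global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)
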