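#' @keywords internal
"_PACKAGE"

#' @importFrom stats glm binomial coef predict plogis qnorm pnorm rnorm rexp
#'   rbinom runif rpois uniroot median quantile sd var weighted.mean
#' @importFrom utils head tail write.table read.delim
NULL

# Stop with the name of the violated invariant in the message.
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Run an expression under a locally-set RNG seed, restoring the caller's
# RNG state afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
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

# Derive a child seed from a parent seed and a stream label, staying well
# inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  s <- utf8ToInt(as.character(stream))
  h <- sum(s * seq_along(s))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
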