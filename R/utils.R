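#' @importFrom stats rnorm setNames var cor pchisq qchisq sd optim
#' @importFrom utils head modifyList
#' @importFrom methods as is
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded generators never perturb the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# sample() without the length-1 surprise
sample_safe <- function(x, size = length(x), replace = FALSE) {
  if (length(x) == 1L && !replace && size == 1L) return(x)
  x[sample.int(length(x), size, replace = replace)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# letters A.. used for plate rows
PLATE_ROW_LABELS <- LETTERS[1:8]
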