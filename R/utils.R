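#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft mvfft sd var median quantile cor cov rnorm runif
#'   rlnorm pf pnorm lm.fit model.matrix setNames
#' @importFrom rlang .data %||%
#' @importFrom utils head tail
NULL

stop_bad_arg <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

#' Deterministic child seed
#'
#' Derives a reproducible 31-bit integer seed from a parent seed and a
#' string label, so independent simulation stages never share an RNG stream.
#'
#' @param seed parent integer seed
#' @param label character tag of the consuming stage
#' @return a single integer in `[0, 2^31)`
#' @keywords internal
child_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(label, ":", as.integer(seed)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)
}
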