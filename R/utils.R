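#' @useDynLib fcfingerprint, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor quantile rnorm runif sd qnorm pchisq qt var coef lm
NULL

#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed as a pure function of
#' the global seed and a stage tag, so that no stage consumes another stage's
#' random-number stream and any stage can be re-run in isolation.
#'
#' @param seed Integer global seed.
#' @param ... Character tags (and/or integers) identifying the stage, e.g.
#'   `derive_seed(7, "family", 3)`.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "simulate")
#' derive_seed(1, "family", 12)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  tags <- vapply(list(...), function(x) paste(as.character(x), collapse = "/"),
                 character(1))
  key <- paste(c(format(seed, scientific = FALSE), tags), collapse = "/")
  bytes <- utf8ToInt(key)
  # 31-bit FNV-style rolling hash; stays inside R's integer range
  h <- 2166136261
  m <- 2^31 - 1
  for (b in bytes) {
    h <- (h * 16777619) %% m
    h <- bitwXor(as.integer(h), as.integer(b))
  }
  as.integer(h %% m)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
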