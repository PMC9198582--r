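#' @useDynLib berryvae, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile median sd var setNames
#' @importFrom utils head tail
NULL

abort_validation <- function(msg, class = "berryvae_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_that <- function(ok, msg, class = "berryvae_validation_error") {
  if (!isTRUE(ok)) abort_validation(msg, class)
  invisible(TRUE)
}

#' Derive a reproducible child seed from a base seed and an index
#'
#' Used to give every scene / model / split its own RNG substream so that
#' results do not depend on generation order. The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed integer base seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) * 48271 + as.numeric(index) * 7919 + 12345) %%
    2147483563
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Cheap deterministic fingerprint of a list of numeric arrays (no digest pkg).
weights_fingerprint <- function(params) {
  acc <- 0
  i <- 0
  for (p in params) {
    v <- as.numeric(p)
    i <- i + 1
    acc <- (acc + sum(v * (seq_along(v) %% 97 + 1)) * (i %% 89 + 1)) %% 1e12
  }
  sprintf("fp%012.0f", abs(acc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
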