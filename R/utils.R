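#' @useDynLib treefusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbeta qbeta plogis setNames cor sd predict
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range.
# Character parts are hashed by code point so IDs and tags mix in.
derive_seed <- function(seed, ...) {
  parts <- list(seed, ...)
  s <- 0
  for (p in parts) {
    v <- if (is.character(p)) {
      h <- 0
      for (cp in utf8ToInt(paste(p, collapse = ""))) h <- (h * 131 + cp) %% 2147483647
      h
    } else as.numeric(p)
    s <- (s * 7919 + (v %% 2147483647)) %% 2147483647
  }
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Add a length-C vector to every row of an S x C matrix.
addrow <- function(x, v) x + rep(v, each = nrow(x))
mulrow <- function(x, v) x * rep(v, each = nrow(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
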