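# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Min-max rescale a raster to [0, 1]
#'
#' Returns NULL when the raster is constant (rescale undefined); callers
#' decide how to handle that degenerate case.
#' @noRd
rescale01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("raster contains non-finite values")
  if (rng[1] == rng[2]) return(NULL)
  (x - rng[1]) / (rng[2] - rng[1])
}

assert_raster <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name))
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name))
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that library code never
#' perturbs user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Small deterministic hash used to derive per-well sub-seeds from a base seed.
# Keeps every derived seed in the 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}
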