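#' @keywords internal
"_PACKAGE"

# Clamp numeric values to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded helpers do not
#' disturb the caller's random stream. All randomness in the package funnels
#' through explicit `seed` arguments via this helper.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Euclidean distance between two (x, y) points.
pt_dist <- function(p, q) sqrt(sum((p - q)^2))

stopifnot_image <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop(sprintf("image must be at least %dx%d", min_dim, min_dim), call. = FALSE)
  if (!all(is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  invisible(img)
}
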