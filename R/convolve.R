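# Separable convolution machinery with reflected borders.
#
# All filtering in the package (Gaussian smoothing, finite-difference
# derivatives, center-map blurring) is expressed as dense 1-D convolution
# matrices applied along rows and columns: out = A_h %*% img %*% t(A_w).
# Images here are small (eye regions and schematic faces, <= a few hundred
# pixels per side) so dense operators are both fast and easy to reason about.

# Fold an index into 1..n by edge-repeating reflection:
# 0 -> 1, -1 -> 2, n+1 -> n, n+2 -> n-1, ...
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  # period of the reflected sequence is 2n
  j <- (j - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Dense n x n matrix implementing 1-D correlation with the given kernel and
# reflected (edge-repeating) borders. `anchor` is the 1-based kernel index
# aligned with the output position; the default centers odd kernels and puts
# the anchor at floor(s/2)+1 for even ones (the lower-right-of-center cell).
conv_matrix <- function(n, kernel, anchor = floor(length(kernel) / 2) + 1L) {
  s <- length(kernel)
  A <- matrix(0, n, n)
  i <- seq_len(n)
  for (m in seq_len(s)) {
    j <- reflect_index(i + m - anchor, n)
    idx <- cbind(i, j)
    A[idx] <- A[idx] + kernel[m]
  }
  A
}

# Normalized 1-D Gaussian kernel; support radius ~3.5 sigma.
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3.5 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing with reflected borders
#'
#' Separable Gaussian filter, the scale-space front end of the isophote
#' voting pipeline. A constant image is preserved exactly and kernel mass is
#' conserved for interior structure.
#'
#' @param img numeric matrix (grayscale image, `[row, col]`).
#' @param sigma positive Gaussian standard deviation in pixels.
#' @return Smoothed matrix of the same dimensions.
#' @export
#' @examples
#' img <- matrix(0, 33, 33); img[17, 17] <- 1
#' sum(smooth_image(img, 2))  # ~1: kernel mass conserved
smooth_image <- function(img, sigma) {
  stopifnot_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive number", call. = FALSE)
  k <- gaussian_kernel(sigma)
  Ah <- conv_matrix(nrow(img), k)
  Aw <- conv_matrix(ncol(img), k)
  Ah %*% img %*% t(Aw)
}

# Scatter-form (adjoint) separable box filter: each cell's mass is spread
# uniformly over its size[1] x size[2] neighborhood and mass falling outside
# the grid is folded back by reflection. Conserves total mass exactly and
# equals the ordinary box average away from borders. Used for vote maps,
# where conservation of accumulated votes is the meaningful invariant.
box_scatter <- function(mat, size = c(6L, 6L)) {
  size <- as.integer(rep(size, length.out = 2L))
  if (any(size < 1L)) stop("filter size must be positive", call. = FALSE)
  kh <- rep(1 / size[1], size[1])
  kw <- rep(1 / size[2], size[2])
  Gh <- conv_matrix(nrow(mat), kh)
  Gw <- conv_matrix(ncol(mat), kw)
  t(Gh) %*% mat %*% Gw
}
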