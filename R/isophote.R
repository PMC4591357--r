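# Isophote curvature center voting.
#
# An isophote is a curve of constant luminance; around the iris/pupil
# boundary isophotes are nearly circular, so the center of curvature of the
# isophote through each edge pixel is an estimate of the eye center. Every
# pixel casts a curvedness-weighted vote at the tip of its displacement
# vector; maxima of the resulting accumulator (center map) are isocenters,
# and the maximum isocenter (MIC) is the basic eye-center estimate.
#
# Conventions: images are numeric matrices indexed [row, col] = [y, x];
# points are c(x, y), 1-based. Lx is the derivative along x (columns),
# Ly along y (rows), with y increasing downward.

#' First- and second-order image derivatives
#'
#' Central finite differences (exact for quadratic luminance surfaces at
#' interior pixels) computed on the, typically Gaussian-smoothed, image.
#' The mixed term Lxy is the x-derivative of the y-derivative. Borders use
#' reflected padding; callers concerned with border accuracy should ignore
#' the outermost ring (the voting stage does).
#'
#' @param img numeric matrix, at least 3x3.
#' @return An object of class `deriv_stack`: list with matrices
#'   `Lx, Ly, Lxx, Lxy, Lyy`, all the shape of `img`.
#' @export
image_derivatives <- function(img) {
  stopifnot_image(img, min_dim = 3L)
  h <- nrow(img); w <- ncol(img)
  D1h <- conv_matrix(h, c(-0.5, 0, 0.5))
  D1w <- conv_matrix(w, c(-0.5, 0, 0.5))
  D2h <- conv_matrix(h, c(1, -2, 1))
  D2w <- conv_matrix(w, c(1, -2, 1))
  Ly <- D1h %*% img
  structure(list(
    Lx  = img %*% t(D1w),
    Ly  = Ly,
    Lxx = img %*% t(D2w),
    Lxy = Ly %*% t(D1w),
    Lyy = D2h %*% img
  ), class = "deriv_stack")
}

# Shared pieces of Eq-style curvature/displacement algebra:
# grad2 = Lx^2 + Ly^2
# den   = Ly^2 Lxx - 2 Lx Lxy Ly + Lx^2 Lyy  (the curvature numerator and
#         the displacement denominator)
iso_terms <- function(d) {
  grad2 <- d$Lx^2 + d$Ly^2
  den <- d$Ly^2 * d$Lxx - 2 * d$Lx * d$Lxy * d$Ly + d$Lx^2 * d$Lyy
  list(grad2 = grad2, den = den)
}

# Dynamic range proxy used to scale validity tolerances.
deriv_drange <- function(d) {
  # recover an intensity scale from the gradient fields; fall back to 1
  s <- max(abs(d$Lx), abs(d$Ly), abs(d$Lxx), abs(d$Lyy))
  if (s == 0) 1 else s
}

#' Isophote curvature
#'
#' Curvature of the isophote through each pixel, the reciprocal of the
#' radius of its osculating circle:
#' \deqn{k = - (Ly^2 Lxx - 2 Lx Lxy Ly + Lx^2 Lyy) / (Lx^2 + Ly^2)^{3/2}}
#' With y increasing downward and this sign convention, `k < 0` at edge
#' pixels whose isophote encloses a darker interior (an iris on sclera).
#'
#' @param d a `deriv_stack` from [image_derivatives()].
#' @param grad_tol gradient-magnitude tolerance; pixels with
#'   `sqrt(Lx^2+Ly^2)` below it are flagged invalid (flat regions).
#' @return list with `values` (matrix, NA where invalid) and `valid`
#'   (logical matrix).
#' @export
isophote_curvature <- function(d, grad_tol = NULL) {
  t0 <- iso_terms(d)
  if (is.null(grad_tol)) grad_tol <- 1e-6 * deriv_drange(d)
  valid <- sqrt(t0$grad2) >= grad_tol
  k <- matrix(NA_real_, nrow(d$Lx), ncol(d$Lx))
  k[valid] <- -t0$den[valid] / (t0$grad2[valid]^1.5)
  list(values = k, valid = valid)
}

#' Displacement vectors to isophote centers
#'
#' Per-pixel vector from the pixel to the estimated center of the osculating
#' circle of its isophote:
#' \deqn{\{D_x, D_y\} = -\{Lx, Ly\} (Lx^2 + Ly^2) /
#'       (Ly^2 Lxx - 2 Lx Lxy Ly + Lx^2 Lyy)}
#' Pixels whose denominator magnitude falls below `den_tol` (flat or
#' straight-isophote regions where the center is ill-defined) are invalid.
#'
#' @param d a `deriv_stack`.
#' @param den_tol denominator tolerance; defaults to
#'   `1e-8 * (dynamic range)^2`.
#' @return list with matrices `dx`, `dy` (NA where invalid) and logical
#'   `valid`.
#' @export
isophote_displacement <- function(d, den_tol = NULL) {
  t0 <- iso_terms(d)
  if (is.null(den_tol)) den_tol <- 1e-8 * deriv_drange(d)^2
  valid <- abs(t0$den) >= den_tol & t0$grad2 > 0
  dx <- matrix(NA_real_, nrow(d$Lx), ncol(d$Lx))
  dy <- dx
  f <- t0$grad2[valid] / t0$den[valid]
  dx[valid] <- -d$Lx[valid] * f
  dy[valid] <- -d$Ly[valid] * f
  list(dx = dx, dy = dy, valid = valid)
}

#' Curvedness
#'
#' Magnitude of second-order image structure,
#' \eqn{\sqrt{Lxx^2 + 2 Lxy^2 + Lyy^2}}, used as the (non-negative) weight
#' of each pixel's vote: pixels on strongly curved edges speak louder than
#' near-flat ones.
#'
#' @param d a `deriv_stack`.
#' @return non-negative numeric matrix.
#' @export
curvedness <- function(d) {
  sqrt(d$Lxx^2 + 2 * d$Lxy^2 + d$Lyy^2)
}

#' Accumulate the center voting map
#'
#' Every valid pixel whose displacement magnitude lies within `r_bounds` and
#' whose curvature sign indicates a darker interior (`k < 0`: iris darker
#' than sclera) casts a vote of weight `w` at the nearest-integer cell of
#' `p + D(p)`. Votes landing outside the image are discarded, and the
#' outermost 1-pixel ring does not vote (border derivatives are unreliable).
#'
#' @param vf displacement field from [isophote_displacement()].
#' @param w curvedness weight matrix from [curvedness()].
#' @param k curvature from [isophote_curvature()].
#' @param r_bounds length-2 numeric, min/max accepted displacement radius in
#'   pixels (0 < min < max).
#' @return An object of class `center_map`: list with `votes` (matrix) and
#'   `n_votes` (count of accepted votes).
#' @export
accumulate_votes <- function(vf, w, k, r_bounds) {
  h <- nrow(vf$valid); wd <- ncol(vf$valid)
  if (!is.numeric(r_bounds) || length(r_bounds) != 2L ||
      !(r_bounds[1] > 0 && r_bounds[2] > r_bounds[1]))
    stop("r_bounds must satisfy 0 < min < max", call. = FALSE)
  rows <- row(vf$valid); cols <- col(vf$valid)
  interior <- rows > 1L & rows < h & cols > 1L & cols < wd
  voter <- vf$valid & k$valid & interior
  voter[voter] <- k$values[voter] < 0
  votes <- matrix(0, h, wd)
  if (any(voter)) {
    dx <- vf$dx[voter]; dy <- vf$dy[voter]
    r <- sqrt(dx^2 + dy^2)
    inb <- r >= r_bounds[1] & r <= r_bounds[2]
    tx <- round(cols[voter][inb] + dx[inb])
    ty <- round(rows[voter][inb] + dy[inb])
    wt <- w[voter][inb]
    keep <- tx >= 1 & tx <= wd & ty >= 1 & ty <= h
    tx <- tx[keep]; ty <- ty[keep]; wt <- wt[keep]
    if (length(wt)) {
      idx <- (tx - 1) * h + ty
      acc <- rowsum(wt, idx)
      votes[as.integer(rownames(acc))] <- acc[, 1]
    }
    n <- length(wt)
  } else n <- 0L
  structure(list(votes = votes, n_votes = as.integer(n)), class = "center_map")
}

#' Maximum isocenter (MIC) of a center map
#'
#' Location and response of the global maximum of the accumulator. Ties are
#' broken deterministically by smallest row, then smallest column.
#'
#' @param cm a `center_map`.
#' @return list with `x`, `y` (1-based pixel coordinates) and `response`.
#' @export
mic <- function(cm) {
  if (!inherits(cm, "center_map")) stop("expected a center_map", call. = FALSE)
  if (cm$n_votes == 0L) stop("center map holds no votes: no candidate", call. = FALSE)
  m <- max(cm$votes)
  idx <- which(cm$votes == m)
  h <- nrow(cm$votes)
  r <- (idx - 1L) %% h + 1L
  c_ <- (idx - 1L) %/% h + 1L
  o <- order(r, c_)[1L]
  list(x = c_[o], y = r[o], response = m)
}

#' Full isophote voting pass over one image
#'
#' Convenience wrapper: smooth, differentiate, and accumulate votes.
#'
#' @inheritParams smooth_image
#' @inheritParams accumulate_votes
#' @param sigma Gaussian smoothing width in pixels.
#' @return a `center_map`.
#' @export
center_map <- function(img, sigma, r_bounds = c(0.05, 0.5) * ncol(img)) {
  s <- smooth_image(img, sigma)
  d <- image_derivatives(s)
  accumulate_votes(isophote_displacement(d), curvedness(d),
                   isophote_curvature(d), r_bounds)
}
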