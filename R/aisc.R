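# Affine-invariant shape-constraint (AISC) eye-center reconstruction.
#
# Each eye center is expressed as a linear combination of its neighboring
# landmarks (eye contour + eyebrow). With the weights constrained to sum
# to one the combination is affine: any affine transform A of the shape
# maps the reconstruction to A(m'), so the learned weights transfer across
# pose, scale and shear. At run time the aligned shape reconstructs
# m' = M' %*% omega and the multi-scale candidate nearest m' wins.

#' Neighbor basis for one eye center
#'
#' @param scheme a landmark scheme (see [ec_scheme_synth29()]).
#' @param eye `"left"` or `"right"` (image coordinates).
#' @param neighbor_ids optional explicit landmark indices (>= 3); default
#'   the scheme's 4 eye-contour + 2 eyebrow landmarks.
#' @return list of class `neighbor_basis` with `center_id`, `neighbor_ids`.
#' @export
neighbor_basis <- function(scheme, eye = c("left", "right"),
                           neighbor_ids = NULL) {
  eye <- match.arg(eye)
  e <- scheme[[eye]]
  if (is.null(neighbor_ids)) neighbor_ids <- c(e$contour, e$brow)
  neighbor_ids <- as.integer(neighbor_ids)
  if (length(neighbor_ids) < 3L)
    stop("need at least 3 neighbors (affine rank requirement)", call. = FALSE)
  if (e$center %in% neighbor_ids)
    stop("the eye-center landmark cannot be its own neighbor", call. = FALSE)
  structure(list(center_id = e$center, neighbor_ids = neighbor_ids),
            class = "neighbor_basis")
}

#' Fit affine-invariant reconstruction weights
#'
#' Solves, in closed form, the constrained least-squares problem
#' \deqn{\min_\omega \sum_{shapes} \| m_c - M' \omega \|^2
#'       \quad s.t.\quad \sum_i \omega_i = 1,}
#' stacking the x and y coordinates of all training shapes. The sum-to-one
#' constraint is what makes the reconstruction commute with affine
#' transforms. A rank-deficient neighbor configuration triggers a ridge-
#' regularized solve with a warning. Set `constrain = FALSE` for plain
#' unconstrained least squares.
#'
#' @param shapes list of L x 2 training shapes (>= k shapes recommended).
#' @param basis a [neighbor_basis()].
#' @param constrain enforce `sum(omega) == 1` (default TRUE).
#' @return list of class `aisc_weights`: `omega`, `basis`, `residual`
#'   (root-mean-square reconstruction error over the training shapes).
#' @export
fit_aisc_weights <- function(shapes, basis, constrain = TRUE) {
  k <- length(basis$neighbor_ids)
  X <- do.call(rbind, lapply(shapes, function(s)
    rbind(t(s[basis$neighbor_ids, 1]), t(s[basis$neighbor_ids, 2]))))
  b <- as.numeric(vapply(shapes, function(s)
    s[basis$center_id, ], numeric(2L)))   # interleaved x, y per shape
  XtX <- crossprod(X)
  Xtb <- crossprod(X, b)
  solve_kkt <- function(XtX) {
    if (constrain) {
      M <- rbind(cbind(2 * XtX, rep(1, k)), c(rep(1, k), 0))
      solve(M, c(2 * Xtb, 1))[seq_len(k)]
    } else as.numeric(solve(XtX, Xtb))
  }
  omega <- tryCatch(solve_kkt(XtX), error = function(e) {
    warning("rank-deficient neighbor configuration; using ridge-regularized solve",
            call. = FALSE)
    solve_kkt(XtX + diag(1e-8 * max(diag(XtX), 1), k))
  })
  resid <- sqrt(mean((X %*% omega - b)^2))
  structure(list(omega = omega, basis = basis, residual = resid),
            class = "aisc_weights")
}

#' Reconstruct an eye center from an aligned shape
#'
#' `m' = sum_i omega_i * neighbor_i`, applied per coordinate.
#'
#' @param shape L x 2 shape containing all basis landmarks.
#' @param w an `aisc_weights`.
#' @return point `c(x, y)`.
#' @export
aisc_reconstruct <- function(shape, w) {
  ids <- w$basis$neighbor_ids
  if (max(ids, w$basis$center_id) > nrow(shape))
    stop("shape is missing basis landmarks", call. = FALSE)
  as.numeric(w$omega %*% shape[ids, , drop = FALSE])
}

#' Select the candidate nearest the reconstructed eye center
#'
#' Argmin over candidates of Euclidean distance to `m_prime`. Candidates
#' live on integer accumulator cells, so distance differences below one
#' cell carry no information: every candidate within `tie_tol` pixels of
#' the minimum distance counts as tied, and ties are broken by higher vote
#' response (the maximum-isocenter ordering), then by scale order. Set
#' `tie_tol = 0` for the strict argmin. An empty candidate set returns
#' `m_prime` itself with `fallback = TRUE` (the alignment estimate is used
#' as-is).
#'
#' @param candidates a `candidate_set` data.frame (possibly zero rows).
#' @param m_prime point `c(x, y)`.
#' @param tie_tol distance slack (pixels) within which candidates are
#'   treated as equidistant; default one accumulator cell.
#' @return list with `point`, `fallback`, and (when a candidate won)
#'   `index` into the candidate set.
#' @export
select_candidate <- function(candidates, m_prime, tie_tol = 1) {
  if (nrow(candidates) == 0L)
    return(list(point = as.numeric(m_prime), fallback = TRUE, index = NA_integer_))
  d <- sqrt((candidates$x - m_prime[1])^2 + (candidates$y - m_prime[2])^2)
  tied <- which(d <= min(d) + tie_tol)
  o <- order(-candidates$response[tied], candidates$scale_index[tied], d[tied])
  i <- tied[o[1L]]
  list(point = c(candidates$x[i], candidates$y[i]), fallback = FALSE,
       index = i)
}
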