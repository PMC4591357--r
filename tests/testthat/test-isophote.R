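# Isophote curvature, displacement and center voting.

test_that("Gaussian smoothing preserves constants and conserves kernel mass", {
  img <- matrix(3.7, 20, 25)
  expect_equal(smooth_image(img, 2), img)
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  expect_lt(abs(sum(smooth_image(imp, 2)) - 1), 1e-6)
  expect_error(smooth_image(img, 0), "positive")
  expect_error(smooth_image(img, -1), "positive")
})

test_that("smoothing matches a brute-force convolution oracle and shrinks noise", {
  set.seed(7)
  img <- matrix(rnorm(12 * 14), 12, 14)
  sm <- smooth_image(img, 1.5)
  # independent oracle: explicit loops with edge-repeated reflection
  k <- exp(-(-6:6)^2 / (2 * 1.5^2)); k <- k / sum(k)
  refl <- function(j, n) { j <- (j - 1) %% (2 * n); ifelse(j < n, j + 1, 2 * n - j) }
  oracle <- img
  for (r in 1:12) for (c in 1:14) {
    acc <- 0
    for (mi in -6:6) for (mj in -6:6)
      acc <- acc + k[mi + 7] * k[mj + 7] *
        img[refl(r + mi, 12), refl(c + mj, 14)]
    oracle[r, c] <- acc
  }
  expect_equal(sm, oracle, tolerance = 1e-12)
  big <- matrix(rnorm(50 * 50), 50, 50)
  expect_lt(var(as.numeric(smooth_image(big, 3))), var(as.numeric(big)))
})

test_that("central differences are exact on linear, bilinear and quadratic fields", {
  n <- 15
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  inner <- 2:(n - 1)

  d <- image_derivatives(3 * xs + 2)
  expect_equal(d$Lx[inner, inner], matrix(3, n - 2, n - 2))
  expect_equal(d$Ly[inner, inner], matrix(0, n - 2, n - 2))
  expect_equal(d$Lxx[inner, inner] + d$Lxy[inner, inner] + d$Lyy[inner, inner],
               matrix(0, n - 2, n - 2))

  d <- image_derivatives(xs * ys)
  expect_equal(d$Lxy[inner, inner], matrix(1, n - 2, n - 2))
  expect_equal(d$Lxx[inner, inner], matrix(0, n - 2, n - 2))
  expect_equal(d$Lyy[inner, inner], matrix(0, n - 2, n - 2))

  d <- image_derivatives(xs^2 + ys^2)
  expect_equal(d$Lxx[inner, inner], matrix(2, n - 2, n - 2))
  expect_equal(d$Lyy[inner, inner], matrix(2, n - 2, n - 2))
  expect_equal(d$Lxy[inner, inner], matrix(0, n - 2, n - 2))
  expect_equal(d$Lx[inner, inner], 2 * xs[inner, inner])

  expect_error(image_derivatives(matrix(1, 2, 5)), "3x3")
})

test_that("curvature magnitude is 1/r on circular isophotes, invalid on flat/linear", {
  img <- quad_image(41)
  d <- image_derivatives(img)
  k <- isophote_curvature(d)
  r <- sqrt(outer((1:41 - 21)^2, (1:41 - 21)^2, function(a, b) b + a))
  r <- sqrt(outer((1:41 - 21)^2, rep(1, 41)) + outer(rep(1, 41), (1:41 - 21)^2))
  interior <- row(img) > 1 & row(img) < 41 & col(img) > 1 & col(img) < 41
  sel <- interior & k$valid & r >= 3
  expect_true(all(abs(abs(k$values[sel]) * r[sel] - 1) < 0.02))
  # dark interior => negative curvature under this sign convention
  expect_true(all(k$values[sel] < 0))

  flat <- isophote_curvature(image_derivatives(matrix(1, 9, 9)))
  expect_false(any(flat$valid))
  ramp <- isophote_curvature(image_derivatives(
    matrix(seq_len(9), 9, 9, byrow = TRUE) * 1.0))
  kv <- ramp$values[2:8, 2:8]
  expect_true(all(is.na(kv) | abs(kv) < 1e-8))
})

test_that("displacement vectors point at the isophote center (analytic oracle)", {
  # L = alpha (x^2 + y^2) + c: D = (-x, -y) exactly at interior pixels
  for (alpha in c(1, 0.3)) {
    n <- 31; ctr <- 16
    img <- alpha * quad_image(n) + 5
    d <- image_derivatives(img)
    vf <- isophote_displacement(d)
    xs <- col(img) - ctr; ys <- row(img) - ctr
    interior <- row(img) > 1 & row(img) < n & col(img) > 1 & col(img) < n &
      (xs != 0 | ys != 0)
    ok <- interior & vf$valid
    expect_gt(sum(ok), 700)
    expect_lt(max(abs(vf$dx[ok] + xs[ok])), 0.5)
    expect_lt(max(abs(vf$dy[ok] + ys[ok])), 0.5)
  }
  flat <- isophote_displacement(image_derivatives(matrix(2, 9, 9)))
  expect_false(any(flat$valid))
})

test_that("displacements on a rendered dark disk converge on the true center", {
  e <- render_eye(eye_spec(size = c(40, 40), iris_center = c(20, 21),
                           iris_radius = 10, pupil_radius = 4))
  s <- smooth_image(e$image, 2)
  d <- image_derivatives(s)
  vf <- isophote_displacement(d)
  k <- isophote_curvature(d)
  # edge band of the iris: pixels 7..13 px from center with valid votes
  r <- sqrt((col(s) - 20)^2 + (row(s) - 21)^2)
  band <- vf$valid & k$valid & k$values < 0 & r >= 7 & r <= 13
  tx <- col(s)[band] + vf$dx[band]
  ty <- row(s)[band] + vf$dy[band]
  hit <- sqrt((tx - 20)^2 + (ty - 21)^2) <= 2
  expect_gt(mean(hit), 0.9)
})

test_that("curvedness is the non-negative second-order magnitude", {
  d <- image_derivatives(quad_image(21))
  cw <- curvedness(d)
  expect_equal(cw[5:17, 5:17], matrix(2 * sqrt(2), 13, 13))
  expect_true(all(curvedness(image_derivatives(matrix(rnorm(100), 10))) >= 0))
  lin <- curvedness(image_derivatives(matrix(1:9, 9, 9) * 1.0))
  expect_true(all(abs(lin[2:8, 2:8]) < 1e-10))
})

test_that("vote accumulation respects gating, bounds and mass bookkeeping", {
  img <- quad_image(41)
  d <- image_derivatives(img)
  vf <- isophote_displacement(d)
  k <- isophote_curvature(d)
  w <- curvedness(d)
  cm <- accumulate_votes(vf, w, k, r_bounds = c(2, 18))
  expect_s3_class(cm, "center_map")
  expect_true(all(cm$votes >= 0))
  expect_gt(cm$n_votes, 0)
  # total mass equals the curvedness of accepted voters (recomputed here)
  r <- sqrt(vf$dx^2 + vf$dy^2)
  interior <- row(img) > 1 & row(img) < 41 & col(img) > 1 & col(img) < 41
  voters <- vf$valid & k$valid & interior
  voters[voters] <- k$values[voters] < 0
  inb <- voters & r >= 2 & r <= 18
  tx <- round(col(img) + vf$dx); ty <- round(row(img) + vf$dy)
  inb <- inb & tx >= 1 & tx <= 41 & ty >= 1 & ty <= 41
  expect_lt(abs(sum(cm$votes) - sum(w[inb])), 1e-6)
  expect_equal(cm$n_votes, sum(inb))
  # votes concentrate on the bowl center
  m <- mic(cm)
  expect_lt(pt_dist(c(m$x, m$y), c(21, 21)), 1.5)
  expect_error(accumulate_votes(vf, w, k, c(5, 2)), "min < max")
})

test_that("an all-invalid field yields an empty map and mic() refuses it", {
  d <- image_derivatives(matrix(1, 20, 20))
  cm <- accumulate_votes(isophote_displacement(d), curvedness(d),
                         isophote_curvature(d), c(1, 8))
  expect_equal(cm$n_votes, 0L)
  expect_true(all(cm$votes == 0))
  expect_error(mic(cm), "no candidate")
})

test_that("mic finds the max with row-then-column tie-breaking", {
  v <- matrix(0, 12, 12); v[5, 7] <- 3
  cm <- structure(list(votes = v, n_votes = 1L), class = "center_map")
  expect_equal(mic(cm)[c("x", "y")], list(x = 7L, y = 5L))
  v2 <- matrix(0, 12, 12); v2[3, 9] <- 2; v2[3, 4] <- 2
  cm2 <- structure(list(votes = v2, n_votes = 2L), class = "center_map")
  expect_equal(mic(cm2)[c("x", "y")], list(x = 4L, y = 3L))
  # brute-force argmax agreement on a blurred fixture map
  e <- render_eye(eye_spec(seed = 5, noise_sigma = 0.05))
  cm3 <- blur_center_map(center_map(e$image, 2))
  m <- mic(cm3)
  expect_equal(cm3$votes[m$y, m$x], max(cm3$votes))
})

test_that("MIC location is invariant to affine intensity rescaling", {
  e <- render_eye(eye_spec(size = c(44, 44), iris_center = c(23, 22),
                           iris_radius = 9, noise_sigma = 0.03, seed = 9))
  m1 <- mic(center_map(e$image, 2))
  m2 <- mic(center_map(2 * e$image + 0.4, 2))
  expect_equal(m1[c("x", "y")], m2[c("x", "y")])
})

test_that("rotating an iris fixture by 90 degrees rotates the MIC with it", {
  e <- render_eye(eye_spec(size = c(44, 44), iris_center = c(18, 25),
                           iris_radius = 8, noise_sigma = 0.02, seed = 4))
  n <- 44
  rot <- t(e$image)[, n:1]            # 90-degree counterclockwise
  m0 <- mic(blur_center_map(center_map(e$image, 2)))
  m1 <- mic(blur_center_map(center_map(rot, 2)))
  # rot[r, c] = img[n + 1 - c, r]: pixel (x, y) maps to (n + 1 - y, x)
  expect_lt(pt_dist(c(m1$x, m1$y), c(n + 1 - m0$y, m0$x)), 1 + 1e-9)
})
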