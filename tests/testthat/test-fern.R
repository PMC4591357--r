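# Cascaded fern regression: augmentation, features, ferns, cascade.

fake_samples <- function(n, seed = 1) {
  withr_seed <- function(s, e) eyecenter:::with_seed(s, e)
  withr_seed(seed, lapply(seq_len(n), function(i) {
    list(image = matrix(runif(100), 10, 10),
         true_shape = matrix(runif(10, 1, 9), 5, 2))
  }))
}

test_that("augmentation exchanges initial shapes deterministically", {
  samples <- fake_samples(25)
  aug <- augment_training(samples, n_inits = 20, seed = 7)
  expect_length(aug, 500L)
  # every copy borrows a different sample's shape (aligned into the box,
  # so it differs from the target's own true shape)
  expect_false(isTRUE(all.equal(aug[[1]]$init_shape, aug[[1]]$true_shape)))
  expect_false(isTRUE(all.equal(aug[[2]]$init_shape, aug[[2]]$true_shape)))
  aug2 <- augment_training(samples, n_inits = 20, seed = 7)
  expect_identical(aug, aug2)
  expect_length(augment_training(samples, n_inits = 1, seed = 1), 25L)
  expect_error(augment_training(samples[1:20], n_inits = 20), "at least")
})

test_that("shape-indexed pixels transform with the current shape", {
  mean_shape <- ec_scheme_synth29()$template
  anchors <- eyecenter:::with_seed(3, eyecenter:::make_anchors(50, mean_shape))
  # identity: anchor point = landmark + stored offset
  pts <- index_pixels(anchors, mean_shape, mean_shape)
  expect_equal(pts, mean_shape[anchors$landmark, ] + anchors$offset,
               tolerance = 1e-12, ignore_attr = TRUE)
  # translation equivariance
  shift <- mean_shape; shift[, 1] <- shift[, 1] + 10
  pts_t <- index_pixels(anchors, shift, mean_shape)
  expect_equal(pts_t[, 1], pts[, 1] + 10, tolerance = 1e-9)
  expect_equal(pts_t[, 2], pts[, 2], tolerance = 1e-9)
  # doubling the shape doubles offset lengths
  pts_s <- index_pixels(anchors, 2 * mean_shape, mean_shape)
  off_s <- pts_s - 2 * mean_shape[anchors$landmark, ]
  expect_equal(off_s, 2 * anchors$offset, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(index_pixels(anchors, mean_shape * 0, mean_shape),
               "degenerate")
})

test_that("correlation-based selection finds a planted pixel-difference feature", {
  set.seed(11)
  N <- 200; P <- 20
  V <- matrix(rnorm(N * P), N, P)
  res <- matrix(rep(V[, 3] - V[, 7], 4), N, 4)   # residual IS feature (3,7)
  sel <- select_features(V, res, F = 1, seed = 5)
  expect_setequal(as.integer(sel$pairs[1, ]), c(3L, 7L))
  # brute-force oracle: the chosen pair attains the maximal |corr|
  y <- as.numeric(res %*% eyecenter:::with_seed(5, rnorm(4)))
  best <- 0
  for (p in 1:P) for (q in 1:P) if (p != q) {
    fv <- V[, p] - V[, q]
    if (sd(fv) > 0) best <- max(best, abs(cor(y, fv)))
  }
  got <- abs(cor(y, V[, sel$pairs[1, 1]] - V[, sel$pairs[1, 2]]))
  expect_equal(got, best, tolerance = 1e-9)
  # threshold lies in the observed feature range
  fv <- V[, sel$pairs[1, 1]] - V[, sel$pairs[1, 2]]
  expect_gte(sel$thresholds[1], min(fv))
  expect_lte(sel$thresholds[1], max(fv))
  # determinism
  expect_identical(select_features(V, res, 3, seed = 9),
                   select_features(V, res, 3, seed = 9))
  expect_error(select_features(matrix(1, 5, 4), matrix(rnorm(20), 5, 4), 1),
               "zero variance")
})

test_that("fern bin outputs are shrunken mean residuals", {
  set.seed(2)
  N <- 50
  V <- matrix(rnorm(N * 6), N, 6)
  res <- matrix(rnorm(N * 4), N, 4)
  # F = 0: single bin; beta = 0 gives the exact mean residual
  f0 <- train_fern(V, res, F = 0, beta = 0)
  expect_equal(as.numeric(f0$outputs), colMeans(res), tolerance = 1e-12)
  # beta -> infinity: outputs vanish
  finf <- train_fern(V, res, F = 0, beta = 1e12)
  expect_lt(max(abs(finf$outputs)), 1e-8)
  # single-sample bins with beta = 1000: output = residual / 1001 exactly
  V2 <- matrix(c(0, 10, 5, -5), 2, 2)
  res2 <- matrix(c(3, -5, 7, 1), 2, 2)
  f1 <- train_fern(V2, res2, F = 1, beta = 1000, seed = 3)
  bins <- eyecenter:::fern_bins(V2, f1$pairs, f1$thresholds)
  expect_equal(sort(bins), c(1L, 2L))   # the two samples separate
  for (i in 1:2)
    expect_equal(f1$outputs[bins[i], ], res2[i, ] / 1001, tolerance = 1e-15)
  # shrinkage magnitude is non-increasing in beta for fixed binning
  f_b1 <- train_fern(V, res, F = 2, beta = 10, seed = 4)
  f_b2 <- train_fern(V, res, F = 2, beta = 1000, seed = 4)
  expect_identical(f_b1$pairs, f_b2$pairs)
  n1 <- sqrt(rowSums(f_b1$outputs^2)); n2 <- sqrt(rowSums(f_b2$outputs^2))
  expect_true(all(n2 <= n1 + 1e-12))
})

test_that("cascade training reduces alignment error monotonically and is reproducible", {
  model <- desk_model()
  expect_length(model$error_trace, 6L)          # init + 5 stages
  expect_true(all(diff(model$error_trace) <= 1e-9))
  expect_lt(model$error_trace[6], 0.25 * model$error_trace[1])
  # serialization round trip is exact
  p <- tempfile(fileext = ".json")
  save_model(model, p)
  m2 <- load_model(p)
  expect_equal(m2$mean_shape, model$mean_shape, tolerance = 0)
  expect_equal(m2$stages[[3]]$ferns[[17]]$outputs,
               model$stages[[3]]$ferns[[17]]$outputs, tolerance = 0)
  expect_equal(m2$stages[[1]]$anchors$offset, model$stages[[1]]$anchors$offset,
               tolerance = 0, ignore_attr = TRUE)
  expect_equal(m2$aisc$left$omega, model$aisc$left$omega, tolerance = 0)
  # and a reloaded model predicts identically
  f <- render_face(sample_face_specs(1, seed = 400)[[1]])
  expect_identical(cascade_predict(f$image, f$box, model, seed = 2),
                   cascade_predict(f$image, f$box, m2, seed = 2))
})

test_that("identical seed and data give a bit-identical serialized model", {
  samples <- lapply(sample_face_specs(20, seed = 55), function(sp) {
    f <- render_face(sp)
    list(image = f$image, true_shape = f$landmarks)
  })
  aug <- augment_training(samples, n_inits = 5, seed = 2)
  m1 <- cascade_train(aug, list(T = 2, K = 10, P = 40), seed = 8)
  m2 <- cascade_train(aug, list(T = 2, K = 10, P = 40), seed = 8)
  p1 <- tempfile(); p2 <- tempfile()
  save_model(m1, p1); save_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("prediction composes stage by stage and respects geometry", {
  model <- desk_model()
  f <- render_face(sample_face_specs(1, seed = 321)[[1]])
  # truncated-cascade composition: running t stages then stage t+1 by hand
  # equals running t+1 stages
  S_t <- cascade_predict(f$image, f$box, model, n_init = 1, seed = 1,
                         max_stages = 3)
  st <- model$stages[[4]]
  tr <- sim_fit(model$mean_shape, S_t)
  pts <- S_t[st$anchors$landmark, ] + eyecenter:::sim_rotate(tr, st$anchors$offset)
  pts[, 1] <- pmin(pmax(pts[, 1], 1), ncol(f$image))
  pts[, 2] <- pmin(pmax(pts[, 2], 1), nrow(f$image))
  v <- matrix(eyecenter:::sample_pixels(f$image, pts), 1)
  dz <- numeric(2 * model$n_landmarks)
  for (fern in st$ferns) dz <- dz + as.numeric(eyecenter:::apply_fern(fern, v))
  z <- tr$a * complex(real = dz[1:29], imaginary = dz[30:58])
  S_manual <- S_t + cbind(Re(z), Im(z))
  S_t1 <- cascade_predict(f$image, f$box, model, n_init = 1, seed = 1,
                          max_stages = 4)
  expect_equal(S_manual, S_t1, tolerance = 1e-12, ignore_attr = TRUE)

  # 5 inits with zero perturbation collapse to the single-init result
  expect_equal(cascade_predict(f$image, f$box, model, n_init = 5, seed = 1,
                               perturb = 0),
               cascade_predict(f$image, f$box, model, n_init = 1, seed = 1))

  # translation equivariance of the whole predictor
  sh <- 5L
  img2 <- matrix(0.35, nrow(f$image), ncol(f$image))
  img2[, (sh + 1):ncol(f$image)] <- f$image[, 1:(ncol(f$image) - sh)]
  box2 <- f$box; box2$x <- box2$x + sh
  S1 <- cascade_predict(f$image, f$box, model, seed = 2)
  S2 <- cascade_predict(img2, box2, model, seed = 2)
  expect_lt(max(abs(S2 - cbind(S1[, 1] + sh, S1[, 2]))), 0.5)

  expect_error(cascade_predict(f$image, list(x = 1e4, y = 1, width = 10,
                                             height = 10), model),
               "outside")
})

test_that("desk-scale training recovers held-out eye centers (median e_worst < 0.1)", {
  model <- desk_model()
  sch <- ec_scheme_synth29()
  hspecs <- sample_face_specs(20, seed = 99)
  ew <- vapply(hspecs, function(sp) {
    f <- render_face(sp)
    S <- cascade_predict(f$image, f$box, model, seed = 5)
    est <- list(left = S[sch$left$center, ], right = S[sch$right$center, ])
    normalized_error(est, eye_truth(f))$e_worst
  }, 0)
  expect_lt(median(ew), 0.1)
})
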