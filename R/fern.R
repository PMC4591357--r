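# Two-level cascaded fern shape regression for face alignment.
#
# T stage regressors, each a sequence of K random ferns, progressively move
# an initial landmark shape toward the true shape:
#   S^t = S^{t-1} + R^t(I, S^{t-1}),   t = 1..T.
# Within a stage the appearance is frozen: P pixels are sampled at
# shape-indexed locations (offset from the nearest landmark, expressed in
# the mean-shape frame and carried through the per-sample similarity
# transform), and every fern draws its F pixel-difference features from the
# same P^2 pool by correlation with a random projection of the current
# residuals. Each fern partitions samples into 2^F threshold bins; a bin's
# output is the shrunken mean residual of its members,
#   delta_b = 1 / (1 + beta / |Omega_b|) * mean_{i in Omega_b}(r_i),
# so sparsely populated bins are regularized toward zero. Residuals and
# fern outputs live in the similarity-normalized (mean-shape) frame, which
# makes the learned increments invariant to face scale and rotation.

default_hyperparams <- function() {
  list(T = 10L, K = 500L, P = 300L, F = 5L, beta = 1000)
}

#' Augment training samples with exchanged initial shapes
#'
#' Each sample is duplicated `n_inits` times; every copy borrows the true
#' shape of a distinct *other* sample, mapped into the target's face box.
#' Initializing from plausible but wrong shapes is what teaches the
#' cascade to correct coarse placement errors.
#'
#' @param samples list of lists with `image`, `true_shape` and optionally
#'   `box` (face box; defaults to the landmark bounding box).
#' @param n_inits copies per sample (default 20).
#' @param seed integer seed.
#' @return list of training instances, each adding `init_shape` and
#'   `source_id`.
#' @export
augment_training <- function(samples, n_inits = 20L, seed = 1L) {
  n <- length(samples)
  if (n < n_inits + 1L)
    stop(sprintf("need at least n_inits + 1 = %d samples, got %d",
                 n_inits + 1L, n), call. = FALSE)
  with_seed(seed, {
    out <- vector("list", n * n_inits)
    pos <- 0L
    for (i in seq_len(n)) {
      box_i <- samples[[i]]$box
      if (is.null(box_i)) box_i <- shape_facebox(samples[[i]]$true_shape)
      src <- sample(setdiff(seq_len(n), i), n_inits)
      for (j in seq_len(n_inits)) {
        init <- shape_from_unit(shape_to_unit(samples[[src[j]]]$true_shape),
                                box_i)
        pos <- pos + 1L
        out[[pos]] <- list(image = samples[[i]]$image,
                           true_shape = samples[[i]]$true_shape,
                           init_shape = init, box = box_i, source_id = i)
      }
    }
    out
  })
}

# P shape-indexed pixel anchors: uniform points in the (slightly expanded)
# mean-shape bounding box, each stored as nearest-landmark index + offset
# in the mean-shape frame.
make_anchors <- function(P, mean_shape) {
  b <- shape_bbox(mean_shape)
  w <- b[["x1"]] - b[["x0"]]; h <- b[["y1"]] - b[["y0"]]
  x <- stats::runif(P, b[["x0"]] - 0.05 * w, b[["x1"]] + 0.05 * w)
  y <- stats::runif(P, b[["y0"]] - 0.05 * h, b[["y1"]] + 0.05 * h)
  d2 <- outer(x, mean_shape[, 1], "-")^2 + outer(y, mean_shape[, 2], "-")^2
  lm <- max.col(-d2, ties.method = "first")
  list(landmark = lm,
       offset = cbind(x - mean_shape[lm, 1], y - mean_shape[lm, 2]))
}

#' Map shape-indexed anchors to image points
#'
#' Each anchor's stored offset (relative to its nearest mean-shape
#' landmark, in the mean-shape frame) is rotated and scaled by the
#' similarity transform from the mean shape to `current_shape` and added to
#' the corresponding current landmark. Points falling off the image are
#' clamped to the border.
#'
#' @param anchors anchor set (`landmark`, `offset`).
#' @param current_shape,mean_shape L x 2 shapes.
#' @param dim image dimensions `c(nrow, ncol)` for clamping, or `NULL`.
#' @return P x 2 matrix of image points.
#' @export
index_pixels <- function(anchors, current_shape, mean_shape, dim = NULL) {
  tr <- sim_fit(mean_shape, current_shape)
  pts <- current_shape[anchors$landmark, , drop = FALSE] +
    sim_rotate(tr, anchors$offset)
  if (!is.null(dim)) {
    pts[, 1] <- clamp(pts[, 1], 1, dim[2])
    pts[, 2] <- clamp(pts[, 2], 1, dim[1])
  }
  pts
}

# Nearest-neighbor intensity lookup (deterministic, no interpolation).
sample_pixels <- function(img, pts) {
  r <- clamp(round(pts[, 2]), 1, nrow(img))
  c_ <- clamp(round(pts[, 1]), 1, ncol(img))
  img[(c_ - 1) * nrow(img) + r]
}

#' Correlation-based selection of fern features
#'
#' For each of `F` draws, the residual matrix is projected onto a random
#' direction and the pixel-difference feature (pair from the implicit P^2
#' pool) with maximum absolute correlation to the projection is chosen;
#' its threshold is drawn uniformly within the central 80% of the
#' feature's observed range. Correlations with difference features are
#' computed from pairwise pixel covariances without materializing N x P^2
#' features.
#'
#' @param pixel_values N x P intensity matrix.
#' @param residuals N x 2L matrix of shape residuals (normalized frame).
#' @param F number of features.
#' @param seed optional seed (NULL: continue current stream).
#' @param cov_cache optional precomputed `list(C, v)` pixel covariance.
#' @return list with `pairs` (F x 2 pixel indices) and `thresholds`.
#' @export
select_features <- function(pixel_values, residuals, F, seed = NULL,
                            cov_cache = NULL) {
  N <- nrow(pixel_values); P <- ncol(pixel_values)
  if (N < 2L) stop("need at least 2 samples", call. = FALSE)
  with_seed(seed, {
    if (is.null(cov_cache)) {
      C <- stats::cov(pixel_values)
      cov_cache <- list(C = C, v = diag(C))
    }
    vsum <- outer(cov_cache$v, cov_cache$v, "+") - 2 * cov_cache$C
    vsum[vsum < 0] <- 0           # numerical guard
    diag(vsum) <- 0
    if (all(vsum <= .Machine$double.eps))
      stop("all pixel-difference features have zero variance", call. = FALSE)
    pairs <- matrix(0L, F, 2L)
    thresholds <- numeric(F)
    if (F == 0L) return(list(pairs = pairs, thresholds = thresholds))
    sdspair <- sqrt(vsum)
    for (f in seq_len(F)) {
      u <- stats::rnorm(ncol(residuals))
      y <- as.numeric(residuals %*% u)
      sy <- stats::sd(y)
      if (!is.finite(sy) || sy == 0) sy <- 1   # direction uninformative; any pair ok
      covy <- as.numeric(stats::cov(y, pixel_values))
      num <- outer(covy, covy, "-")
      corr <- abs(num) / (sy * sdspair)
      corr[!is.finite(corr)] <- -Inf
      best <- arrayInd(which.max(corr), dim(corr))
      p <- best[1L]; q <- best[2L]
      fv <- pixel_values[, p] - pixel_values[, q]
      rng <- range(fv)
      d <- diff(rng)
      thresholds[f] <- stats::runif(1, rng[1] + 0.1 * d, rng[2] - 0.1 * d)
      pairs[f, ] <- c(p, q)
    }
    list(pairs = pairs, thresholds = thresholds)
  })
}

fern_bins <- function(pixel_values, pairs, thresholds) {
  F <- nrow(pairs)
  if (F == 0L) return(rep(1L, nrow(pixel_values)))
  bits <- sapply(seq_len(F), function(f)
    (pixel_values[, pairs[f, 1]] - pixel_values[, pairs[f, 2]]) >= thresholds[f])
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  1L + as.integer(bits %*% 2^(seq_len(F) - 1L))
}

#' Train one random fern
#'
#' Selects `F` pixel-difference features, bins the samples by threshold
#' comparisons, and stores per-bin shrunken mean residuals
#' `1/(1 + beta/|bin|) * mean(residuals in bin)`; empty bins output zero.
#'
#' @inheritParams select_features
#' @param beta shrinkage strength (default 1000).
#' @return list of class `ec_fern`: `pairs`, `thresholds`, `outputs`
#'   (2^F x 2L matrix).
#' @export
train_fern <- function(pixel_values, residuals, F = 5L, beta = 1000,
                       seed = NULL, cov_cache = NULL) {
  sel <- select_features(pixel_values, residuals, F, seed, cov_cache)
  bins <- fern_bins(pixel_values, sel$pairs, sel$thresholds)
  nb <- 2L^F
  outputs <- matrix(0, nb, ncol(residuals))
  sums <- rowsum(residuals, bins)
  counts <- as.numeric(table(factor(bins, levels = seq_len(nb))))
  got <- as.integer(rownames(sums))
  shrink <- 1 / (1 + beta / counts[got])
  outputs[got, ] <- sums / counts[got] * shrink
  structure(list(pairs = sel$pairs, thresholds = sel$thresholds,
                 outputs = outputs), class = "ec_fern")
}

apply_fern <- function(fern, pixel_values) {
  bins <- fern_bins(pixel_values, fern$pairs, fern$thresholds)
  fern$outputs[bins, , drop = FALSE]
}

# residuals in the normalized frame: (true - current) / a_i, flattened
# (x1..xL, y1..yL)
norm_residuals <- function(true_shapes, cur_shapes, a) {
  t(vapply(seq_along(a), function(i) {
    z <- (shape_cx(true_shapes[[i]]) - shape_cx(cur_shapes[[i]])) / a[i]
    c(Re(z), Im(z))
  }, numeric(2L * nrow(true_shapes[[1]]))))
}

#' Train the cascaded fern regressor
#'
#' @param samples augmented training instances from [augment_training()].
#' @param hyperparams list with `T`, `K`, `P`, `F`, `beta` (defaults
#'   10, 500, 300, 5, 1000).
#' @param seed integer seed; all training randomness derives from it.
#' @param scheme optional landmark scheme; when supplied, affine-invariant
#'   eye-center reconstruction weights are fitted on the training shapes
#'   and stored in the model.
#' @param verbose print per-stage mean alignment error.
#' @return object of class `cascade_model`: `stages` (each with `anchors`
#'   and `ferns`), `mean_shape` (unit frame), `hyperparams`, `seed`,
#'   `error_trace` (mean image-frame landmark error after init and each
#'   stage) and optionally `aisc` weights + `scheme`.
#' @export
cascade_train <- function(samples, hyperparams = list(), seed = 1L,
                          scheme = NULL, verbose = FALSE) {
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  N <- length(samples)
  if (N < 2L) stop("need at least 2 training instances", call. = FALSE)
  L <- nrow(samples[[1]]$true_shape)
  mean_shape <- Reduce(`+`, lapply(samples, function(s)
    shape_to_unit(s$true_shape))) / N
  mean_shape <- as_shape(mean_shape)

  true_shapes <- lapply(samples, `[[`, "true_shape")
  cur_shapes <- lapply(samples, `[[`, "init_shape")
  images <- lapply(samples, `[[`, "image")

  mean_err <- function() {
    mean(vapply(seq_len(N), function(i)
      mean(sqrt(rowSums((true_shapes[[i]] - cur_shapes[[i]])^2))), 0))
  }
  trace <- mean_err()
  stages <- vector("list", hp$T)

  with_seed(seed, {
    for (t in seq_len(hp$T)) {
      anchors <- make_anchors(hp$P, mean_shape)
      trs <- lapply(cur_shapes, function(s) sim_fit(mean_shape, s))
      a <- vapply(trs, `[[`, complex(1), "a")
      V <- t(vapply(seq_len(N), function(i) {
        pts <- cur_shapes[[i]][anchors$landmark, , drop = FALSE] +
          sim_rotate(trs[[i]], anchors$offset)
        sample_pixels(images[[i]], pts)
      }, numeric(hp$P)))
      C <- stats::cov(V)
      cov_cache <- list(C = C, v = diag(C))
      res <- norm_residuals(true_shapes, cur_shapes, a)
      ferns <- vector("list", hp$K)
      for (k in seq_len(hp$K)) {
        fern <- train_fern(V, res, hp$F, hp$beta, seed = NULL,
                           cov_cache = cov_cache)
        delta <- apply_fern(fern, V)
        res <- res - delta
        ferns[[k]] <- fern
      }
      # commit the stage's accumulated normalized-frame correction
      for (i in seq_len(N)) {
        zi <- a[i] * complex(real = resid_to_xy(res[i, ], L)[, 1],
                             imaginary = resid_to_xy(res[i, ], L)[, 2])
        # res now holds the REMAINING residual; correction = initial - remaining
        cur_shapes[[i]] <- true_shapes[[i]] -
          cbind(Re(zi), Im(zi))
      }
      stages[[t]] <- list(anchors = anchors, ferns = ferns)
      trace <- c(trace, mean_err())
      if (verbose)
        message(sprintf("stage %d/%d: mean landmark error %.3f px",
                        t, hp$T, trace[t + 1L]))
    }
  })

  model <- structure(list(version = 1L, stages = stages,
                          mean_shape = mean_shape, hyperparams = hp,
                          seed = seed, n_landmarks = L,
                          error_trace = trace), class = "cascade_model")
  if (!is.null(scheme)) {
    if (scheme$n != L)
      stop("scheme landmark count does not match training shapes", call. = FALSE)
    model$scheme <- scheme
    model$aisc <- list(
      left = fit_aisc_weights(true_shapes, neighbor_basis(scheme, "left")),
      right = fit_aisc_weights(true_shapes, neighbor_basis(scheme, "right")))
  }
  model
}

# reshape a flat residual (x1..xL, y1..yL) into L x 2
resid_to_xy <- function(r, L) cbind(r[seq_len(L)], r[L + seq_len(L)])

#' Predict a landmark shape for one face
#'
#' Places the model's mean shape into the face box (plus random
#' translation/scale perturbations for initializations 2..n_init), runs
#' every stage's ferns, and returns the per-landmark mean over the
#' initializations.
#'
#' @param img grayscale image matrix.
#' @param box face box `list(x, y, width, height)`.
#' @param model a `cascade_model`.
#' @param n_init number of initializations (default 5).
#' @param seed integer seed for the perturbations.
#' @param max_stages run only the first `max_stages` stages (diagnostics).
#' @param perturb perturbation magnitude as a fraction of box size.
#' @return L x 2 shape matrix.
#' @export
cascade_predict <- function(img, box, model, n_init = 5L, seed = 1L,
                            max_stages = NULL, perturb = 0.05) {
  if (box$x > ncol(img) || box$y > nrow(img) ||
      box$x + box$width < 1 || box$y + box$height < 1 ||
      box$width <= 0 || box$height <= 0)
    stop("face box lies outside the image", call. = FALSE)
  stages <- model$stages
  if (!is.null(max_stages)) stages <- stages[seq_len(max_stages)]
  dims <- dim(img)
  shapes <- with_seed(seed, {
    lapply(seq_len(n_init), function(j) {
      b <- box
      if (j > 1L && perturb > 0) {
        b$x <- b$x + stats::runif(1, -perturb, perturb) * box$width
        b$y <- b$y + stats::runif(1, -perturb, perturb) * box$height
        s <- 1 + stats::runif(1, -perturb, perturb)
        b$width <- b$width * s; b$height <- b$height * s
      }
      S <- shape_from_unit(model$mean_shape, b)
      for (st in stages) {
        tr <- sim_fit(model$mean_shape, S)
        pts <- S[st$anchors$landmark, , drop = FALSE] +
          sim_rotate(tr, st$anchors$offset)
        pts[, 1] <- clamp(pts[, 1], 1, dims[2])
        pts[, 2] <- clamp(pts[, 2], 1, dims[1])
        v <- sample_pixels(img, pts)
        vrow <- matrix(v, 1L)
        dz <- numeric(2L * model$n_landmarks)
        for (fern in st$ferns)
          dz <- dz + as.numeric(apply_fern(fern, vrow))
        z <- tr$a * complex(real = dz[seq_len(model$n_landmarks)],
                            imaginary = dz[model$n_landmarks +
                                             seq_len(model$n_landmarks)])
        S <- S + cbind(Re(z), Im(z))
      }
      S
    })
  })
  as_shape(Reduce(`+`, shapes) / length(shapes))
}

# --- model serialization (versioned JSON, full-precision doubles) ---

#' Save / load a cascade model
#'
#' The model is stored as a single versioned JSON document: a header with
#' hyperparameters, seed and landmark scheme, followed by the dense stage
#' arrays. Doubles are written at full precision so a save/load round trip
#' is bit-exact.
#'
#' @param model a `cascade_model`.
#' @param path file path (conventionally `.json`).
#' @export
save_model <- function(model, path) {
  ser <- list(
    container = "eyecenter-cascade", format_version = 1L,
    header = list(hyperparams = model$hyperparams, seed = model$seed,
                  n_landmarks = model$n_landmarks,
                  scheme_name = if (!is.null(model$scheme)) model$scheme$name),
    mean_shape = model$mean_shape,
    error_trace = model$error_trace,
    stages = lapply(model$stages, function(st) list(
      anchor_landmark = st$anchors$landmark,
      anchor_offset = st$anchors$offset,
      ferns = lapply(st$ferns, function(f) list(
        pairs = f$pairs, thresholds = f$thresholds, outputs = f$outputs)))),
    aisc = if (!is.null(model$aisc)) lapply(model$aisc, function(w) list(
      omega = w$omega, center_id = w$basis$center_id,
      neighbor_ids = w$basis$neighbor_ids, residual = w$residual)))
  json <- jsonlite::toJSON(ser, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the `cascade_model`.
#' @export
load_model <- function(path) {
  ser <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(ser$container, "eyecenter-cascade"))
    stop("not an eyecenter cascade model file", call. = FALSE)
  hp <- ser$header$hyperparams
  stages <- lapply(ser$stages, function(st) list(
    anchors = list(landmark = as.integer(st$anchor_landmark),
                   offset = matrix(st$anchor_offset, ncol = 2L)),
    ferns = lapply(st$ferns, function(f) structure(list(
      pairs = matrix(as.integer(f$pairs), ncol = 2L),
      thresholds = as.numeric(f$thresholds),
      outputs = matrix(f$outputs, nrow = 2L^length(f$thresholds))),
      class = "ec_fern"))))
  model <- structure(list(version = ser$format_version, stages = stages,
                          mean_shape = as_shape(matrix(ser$mean_shape, ncol = 2L)),
                          hyperparams = hp, seed = ser$header$seed,
                          n_landmarks = as.integer(ser$header$n_landmarks),
                          error_trace = as.numeric(ser$error_trace)),
                     class = "cascade_model")
  if (!is.null(ser$header$scheme_name) &&
      identical(ser$header$scheme_name, "synth29"))
    model$scheme <- ec_scheme_synth29()
  if (!is.null(ser$aisc))
    model$aisc <- lapply(ser$aisc, function(w) structure(list(
      omega = as.numeric(w$omega),
      basis = structure(list(center_id = as.integer(w$center_id),
                             neighbor_ids = as.integer(w$neighbor_ids)),
                        class = "neighbor_basis"),
      residual = as.numeric(w$residual)), class = "aisc_weights"))
  model
}
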