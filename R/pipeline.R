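# End-to-end orchestration, evaluation and tracking.
#
# detect face -> align landmarks (fern cascade, 5 initializations) ->
# per eye: crop region, pool multi-scale isophote candidates ->
# AISC reconstruction from the aligned shape -> nearest candidate wins.
# Evaluation uses the normalized error e = d / omega (eye-center error
# over inter-ocular distance) under the worst/best/average-eye
# conventions, summarized as accuracy curves over error thresholds.

#' Face detection (plugin interface)
#'
#' The detector is a plugin: any function `img -> list(x, y, width,
#' height)` (or `NULL` when no face is found). A `manual_box` override is
#' honored verbatim. The built-in default, [detect_face_bright()], is a
#' brightness-blob heuristic that works on this package's schematic faces;
#' real-world use should plug in an external cascade detector.
#'
#' @param img grayscale image matrix.
#' @param detector plugin function, default [detect_face_bright()].
#' @param manual_box optional face box returned verbatim.
#' @return face box `list(x, y, width, height, source)`.
#' @export
detect_face <- function(img, detector = detect_face_bright,
                        manual_box = NULL) {
  if (!is.null(manual_box)) {
    manual_box$source <- "manual"
    return(manual_box)
  }
  box <- detector(img)
  if (is.null(box)) stop("no face detected", call. = FALSE)
  box$source <- "detector"
  box
}

#' @rdname detect_face
#' @param threshold intensity above which pixels count as face (skin).
#' @export
detect_face_bright <- function(img, threshold = 0.55) {
  bright <- which(img > threshold, arr.ind = TRUE)
  if (nrow(bright) < 25L) return(NULL)
  ex0 <- min(bright[, 2]); ex1 <- max(bright[, 2])
  ey0 <- min(bright[, 1]); ey1 <- max(bright[, 1])
  ew <- ex1 - ex0; eh <- ey1 - ey0
  # the bright blob is the skin ellipse (unit-frame span ~[-0.05, 1.05] x
  # [-0.03, 1.07]); shrink to the landmark span ([0.16, 0.84] x
  # [0.26, 0.92]) of the canonical template
  x0 <- ex0 + (0.16 + 0.05) / 1.10 * ew
  x1 <- ex0 + (0.84 + 0.05) / 1.10 * ew
  y0 <- ey0 + (0.26 + 0.03) / 1.10 * eh
  y1 <- ey0 + (0.92 + 0.03) / 1.10 * eh
  list(x = x0, y = y0, width = x1 - x0, height = y1 - y0)
}

#' Eye regions from an aligned shape
#'
#' Axis-aligned box around each eye's contour landmarks, expanded by
#' `margin` on every side and grown vertically to at least
#' `min_aspect * width` so the full iris fits; clamped to the image.
#'
#' @param landmarks aligned L x 2 shape.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param scheme landmark scheme.
#' @param margin per-side expansion as a fraction of the landmark span.
#' @param min_aspect minimum height/width ratio of the region.
#' @return list with `left` and `right`, each
#'   `list(x0, y0, x1, y1, offset)` where `offset = c(x0 - 1, y0 - 1)`
#'   translates region to base-image coordinates.
#' @export
eye_regions <- function(landmarks, dim, scheme = ec_scheme_synth29(),
                        margin = 0.4, min_aspect = 0.8) {
  one <- function(eye) {
    ids <- c(eye$contour, eye$center)
    xs <- landmarks[ids, 1]; ys <- landmarks[ids, 2]
    w <- max(max(xs) - min(xs), 1); h <- max(max(ys) - min(ys), 1)
    x0 <- min(xs) - margin * w; x1 <- max(xs) + margin * w
    y0 <- min(ys) - margin * h; y1 <- max(ys) + margin * h
    want_h <- min_aspect * (x1 - x0)
    if (y1 - y0 < want_h) {
      cy <- (y0 + y1) / 2
      y0 <- cy - want_h / 2; y1 <- cy + want_h / 2
    }
    # enforce a workable minimum size, then clamp to the image
    for (grow in 1:2) {
      if (x1 - x0 < 15) { cx <- (x0 + x1) / 2; x0 <- cx - 7.5; x1 <- cx + 7.5 }
      if (y1 - y0 < 15) { cy <- (y0 + y1) / 2; y0 <- cy - 7.5; y1 <- cy + 7.5 }
      x0 <- max(1, floor(x0)); y0 <- max(1, floor(y0))
      x1 <- min(dim[2], ceiling(x1)); y1 <- min(dim[1], ceiling(y1))
    }
    if (x1 - x0 < 4 || y1 - y0 < 4)
      stop("eye region degenerate after clamping", call. = FALSE)
    list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, offset = c(x0 - 1, y0 - 1))
  }
  list(left = one(scheme$left), right = one(scheme$right))
}

crop_region <- function(img, rg) img[rg$y0:rg$y1, rg$x0:rg$x1, drop = FALSE]

#' Locate both eye centers in a face image
#'
#' Runs the full hybrid pipeline. With `method = "mic"` the pure
#' isophote baseline is used instead: the maximum isocenter of the
#' blurred center map at the base Gaussian kernel (the single-scale MIC
#' method, of which the scale bank is the multi-scale extension), with no
#' shape constraint; it is the comparison baseline for robustness
#' experiments.
#'
#' @param img grayscale image matrix.
#' @param box face box (e.g. from [detect_face()]).
#' @param model trained `cascade_model` carrying AISC weights.
#' @param config an [ec_config()].
#' @param method `"hybrid"` (default) or `"mic"`.
#' @param n_init,seed passed to [cascade_predict()].
#' @return object of class `eye_estimate`: `left`, `right` (points,
#'   image-left eye first), `landmarks`, `fallback` (named logical),
#'   `candidates` (per-eye candidate sets), `regions`.
#' @export
locate_eyes <- function(img, box, model, config = ec_config(),
                        method = c("hybrid", "mic"), n_init = 5L, seed = 1L) {
  method <- match.arg(method)
  if (is.null(model$scheme) || is.null(model$aisc))
    stop("model carries no landmark scheme / AISC weights", call. = FALSE)
  landmarks <- cascade_predict(img, box, model, n_init = n_init, seed = seed)
  regions <- eye_regions(landmarks, dim(img), model$scheme)
  est <- list(landmarks = landmarks, regions = regions,
              fallback = c(left = FALSE, right = FALSE),
              candidates = list())
  for (side in c("left", "right")) {
    rg <- regions[[side]]
    eye_img <- crop_region(img, rg)
    if (method == "mic") {
      rc <- resolve_config(config, ncol(eye_img))
      cm <- center_map(eye_img, rc$sigmas[1], rc$r_bounds)
      if (cm$n_votes == 0L) {
        est[[side]] <- aisc_reconstruct(landmarks, model$aisc[[side]])
        est$fallback[side] <- TRUE
      } else {
        p <- mic(blur_center_map(cm, rc$blur_size))
        est[[side]] <- c(p$x, p$y) + rg$offset
      }
      next
    }
    cands <- collect_candidates(eye_img, rg$offset, config)
    m_prime <- aisc_reconstruct(landmarks, model$aisc[[side]])
    sel <- select_candidate(cands, m_prime)
    est[[side]] <- sel$point
    est$fallback[side] <- sel$fallback
    est$candidates[[side]] <- cands
  }
  if (est$left[1] > est$right[1]) {   # keep image-left eye in `left`
    tmp <- est$left; est$left <- est$right; est$right <- tmp
    est$fallback <- est$fallback[c(2, 1)]
    names(est$fallback) <- c("left", "right")
  }
  class(est) <- "eye_estimate"
  est
}

#' Normalized eye-localization error
#'
#' `d_left`, `d_right` are the Euclidean errors of the two estimates and
#' `omega` the true inter-ocular distance. The primary score is the
#' worst-eye convention `e_worst = max(d_left, d_right) / omega`; the
#' best/average conventions and the summed variant
#' `e_sum = (d_left + d_right) / omega` are reported alongside.
#'
#' @param est an `eye_estimate` (or list with `left`, `right` points).
#' @param truth list with true `left`, `right` eye centers (distinct).
#' @return one-row data.frame: `d_left, d_right, omega, e_worst, e_best,
#'   e_avg, e_sum`.
#' @export
normalized_error <- function(est, truth) {
  omega <- pt_dist(truth$left, truth$right)
  if (omega <= 0)
    stop("coincident true eye centers: metric undefined", call. = FALSE)
  dl <- pt_dist(as.numeric(est$left)[1:2], as.numeric(truth$left)[1:2])
  dr <- pt_dist(as.numeric(est$right)[1:2], as.numeric(truth$right)[1:2])
  data.frame(d_left = dl, d_right = dr, omega = omega,
             e_worst = max(dl, dr) / omega, e_best = min(dl, dr) / omega,
             e_avg = mean(c(dl, dr)) / omega, e_sum = (dl + dr) / omega)
}

#' Accuracy curves over normalized-error thresholds
#'
#' Fraction of records with `e <= tau` for each threshold and convention.
#'
#' @param records data.frame of [normalized_error()] rows.
#' @param thresholds error thresholds (default the conventional
#'   0.05..0.25 grid; 0.05 ~ pupil diameter, 0.10 ~ iris diameter,
#'   0.25 ~ eye width).
#' @param conventions subset of `c("worst", "best", "avg")`.
#' @return data.frame with `threshold`, `convention`, `accuracy`.
#' @export
accuracy_curve <- function(records,
                           thresholds = c(0.05, 0.1, 0.15, 0.2, 0.25),
                           conventions = c("worst", "best", "avg")) {
  if (nrow(records) < 1L) stop("need at least one record", call. = FALSE)
  out <- expand.grid(threshold = thresholds, convention = conventions,
                     stringsAsFactors = FALSE)
  out$accuracy <- mapply(function(tau, conv) {
    mean(records[[paste0("e_", conv)]] <= tau)
  }, out$threshold, out$convention)
  out
}

#' @rdname accuracy_curve
#' @param path PNG output path for a base-graphics plot of the curves.
#' @export
plot_accuracy_curve <- function(records, path,
                                thresholds = seq(0.025, 0.25, by = 0.025)) {
  curve <- accuracy_curve(records, thresholds)
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  plot(NULL, xlim = range(thresholds), ylim = c(0, 1),
       xlab = "normalized error threshold", ylab = "accuracy",
       main = "Eye-center localization accuracy")
  cols <- c(worst = "red", best = "darkgreen", avg = "blue")
  for (conv in unique(curve$convention)) {
    sub <- curve[curve$convention == conv, ]
    graphics::lines(sub$threshold, sub$accuracy, col = cols[[conv]], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(cols), col = cols, lwd = 2)
  invisible(curve)
}

#' Track eye centers over an ordered frame sequence
#'
#' Frame 1 uses face detection (or a supplied box); each later frame
#' derives its face box from the previous frame's estimated landmarks
#' (their bounding box, optionally grown by `margin`), so no detector runs
#' in steady state. The cascade is trained against landmark bounding
#' boxes, so the default margin is 0; a non-zero margin inflates the box
#' a little every frame and is only useful for fast-moving faces.
#' A failed frame (both eyes falling back with a degenerate shape) is
#' retried with full detection; `fail_window` consecutive failures raise a
#' tracking-lost error.
#'
#' @param frames list of grayscale image matrices.
#' @param model trained `cascade_model`.
#' @param config an [ec_config()].
#' @param first_box optional face box for frame 1 (skips detection).
#' @param detector detection plugin for frame 1 / recovery.
#' @param margin box growth per side, fraction of the landmark span.
#' @param fail_window consecutive-failure limit.
#' @param seed integer seed.
#' @return list of per-frame `eye_estimate`s, with a `summary` attribute
#'   data.frame (`frame, lx, ly, rx, ry, fallback_left, fallback_right`).
#' @export
track_eyes <- function(frames, model, config = ec_config(),
                       first_box = NULL, detector = detect_face_bright,
                       margin = 0, fail_window = 5L, seed = 1L) {
  ests <- vector("list", length(frames))
  box <- NULL
  fails <- 0L
  for (i in seq_along(frames)) {
    img <- frames[[i]]
    if (i == 1L) {
      box <- if (!is.null(first_box)) first_box else
        detect_face(img, detector)
    } else {
      lm <- ests[[i - 1L]]$landmarks
      b <- shape_facebox(lm)
      box <- list(x = b$x - margin * b$width, y = b$y - margin * b$height,
                  width = b$width * (1 + 2 * margin),
                  height = b$height * (1 + 2 * margin),
                  source = "previous-frame")
    }
    est <- tryCatch(
      locate_eyes(img, box, model, config, seed = seed + i),
      error = function(e) NULL)
    if (is.null(est) || all(est$fallback)) {
      # re-detect and retry once
      est2 <- tryCatch(
        locate_eyes(img, detect_face(img, detector), model, config,
                    seed = seed + i),
        error = function(e) NULL)
      if (!is.null(est2)) est <- est2
    }
    if (is.null(est)) {
      fails <- fails + 1L
      if (fails >= fail_window)
        stop(sprintf("tracking lost: %d consecutive failed frames", fails),
             call. = FALSE)
      ests[[i]] <- ests[[i - 1L]]   # hold last estimate
    } else {
      fails <- 0L
      ests[[i]] <- est
    }
  }
  attr(ests, "summary") <- do.call(rbind, lapply(seq_along(ests), function(i) {
    e <- ests[[i]]
    data.frame(frame = i, lx = e$left[1], ly = e$left[2],
               rx = e$right[1], ry = e$right[2],
               fallback_left = e$fallback[["left"]],
               fallback_right = e$fallback[["right"]])
  }))
  ests
}
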