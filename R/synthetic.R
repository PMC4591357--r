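# Seeded synthetic fixtures: eye patches and schematic faces.
#
# The generators provide ground-truth-complete training and test material
# so the whole pipeline is exercisable without downloading face datasets.
# Eye patches emulate the structures the isophote stage sees (bright
# sclera, dark circular iris with darker pupil, eyelid occlusion, glints,
# eyebrow-like distractor bars, sensor noise); schematic faces carry the
# full 29-landmark ground truth with pose variation (translation, scale,
# in-plane rotation, horizontal shear standing in for yaw) and render
# every feature as a deterministic function of the landmark positions.
# Every generator is a pure function of its spec and seed.

# --- anti-aliased raster primitives (1-px soft edges) ---

aa_blend <- function(img, rows, cols, cov, value) {
  sub <- img[rows, cols, drop = FALSE]
  img[rows, cols] <- sub * (1 - cov) + value * cov
  img
}

aa_disk <- function(img, center, r, value) {
  h <- nrow(img); w <- ncol(img)
  rows <- max(1L, floor(center[2] - r - 1)):min(h, ceiling(center[2] + r + 1))
  cols <- max(1L, floor(center[1] - r - 1)):min(w, ceiling(center[1] + r + 1))
  if (!length(rows) || !length(cols)) return(img)
  d <- sqrt(outer((rows - center[2])^2, (cols - center[1])^2, "+"))
  aa_blend(img, rows, cols, clamp(r - d + 0.5, 0, 1), value)
}

# Thick line segment with rounded caps.
aa_capsule <- function(img, p1, p2, halfwidth, value) {
  h <- nrow(img); w <- ncol(img)
  m <- halfwidth + 1
  rows <- max(1L, floor(min(p1[2], p2[2]) - m)):min(h, ceiling(max(p1[2], p2[2]) + m))
  cols <- max(1L, floor(min(p1[1], p2[1]) - m)):min(w, ceiling(max(p1[1], p2[1]) + m))
  if (!length(rows) || !length(cols)) return(img)
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  py <- matrix(rows, length(rows), length(cols))
  v <- p2 - p1
  len2 <- max(sum(v^2), .Machine$double.eps)
  tt <- clamp(((px - p1[1]) * v[1] + (py - p1[2]) * v[2]) / len2, 0, 1)
  d <- sqrt((px - (p1[1] + tt * v[1]))^2 + (py - (p1[2] + tt * v[2]))^2)
  aa_blend(img, rows, cols, clamp(halfwidth - d + 0.5, 0, 1), value)
}

# Axis-aligned rectangle (sharp edges softened by 0.5 px).
aa_rect <- function(img, x, y, width, height, value) {
  aa_capsule(img, c(x + height / 2, y + height / 2),
             c(x + width - height / 2, y + height / 2), height / 2, value)
}

# --- eye patches ---

#' Specification for a synthetic eye patch
#'
#' @param size image size `c(width, height)` in pixels.
#' @param iris_center `c(x, y)`; default the patch center.
#' @param iris_radius,pupil_radius radii in pixels
#'   (`pupil_radius < iris_radius < min(size)/2`).
#' @param sclera,iris,pupil intensities in `[0, 1]`, ordered
#'   `pupil < iris < sclera`.
#' @param eyelid_coverage fraction of the iris diameter occluded from the
#'   top by a skin-toned lid, in `[0, 1]`.
#' @param eyelid_intensity lid intensity.
#' @param glint optional list `(offset = c(dx, dy), radius, intensity)`
#'   for a specular highlight.
#' @param noise_sigma Gaussian noise s.d. as a fraction of the
#'   sclera-pupil dynamic range.
#' @param distractors list of eyebrow-like bars, each a list
#'   `(x, y, width, height, intensity)` (top-left corner, pixels).
#' @param seed integer RNG seed for the noise.
#' @return list of class `eye_spec`.
#' @export
eye_spec <- function(size = c(48, 48), iris_center = NULL, iris_radius = 10,
                     pupil_radius = 0.4 * iris_radius, sclera = 0.85,
                     iris = 0.30, pupil = 0.10, eyelid_coverage = 0,
                     eyelid_intensity = 0.65, glint = NULL, noise_sigma = 0,
                     distractors = list(), seed = NULL) {
  if (is.null(iris_center)) iris_center <- (size + 1) / 2
  spec <- list(size = size, iris_center = iris_center,
               iris_radius = iris_radius, pupil_radius = pupil_radius,
               sclera = sclera, iris = iris, pupil = pupil,
               eyelid_coverage = eyelid_coverage,
               eyelid_intensity = eyelid_intensity, glint = glint,
               noise_sigma = noise_sigma, distractors = distractors,
               seed = seed)
  if (!(pupil_radius < iris_radius && iris_radius < min(size) / 2))
    stop("need pupil_radius < iris_radius < min(size)/2", call. = FALSE)
  if (!(pupil < iris && iris < sclera))
    stop("intensities must be ordered pupil < iris < sclera", call. = FALSE)
  if (eyelid_coverage < 0 || eyelid_coverage > 1)
    stop("eyelid_coverage must lie in [0, 1]", call. = FALSE)
  class(spec) <- "eye_spec"
  spec
}

#' Render a synthetic eye patch
#'
#' @param spec an [eye_spec()].
#' @return list with `image` (matrix, values in `[0, 1]`), `center`
#'   (`c(x, y)`, the exact iris center) and `spec`.
#' @export
render_eye <- function(spec) {
  if (!inherits(spec, "eye_spec")) spec <- do.call(eye_spec, spec)
  w <- spec$size[1]; h <- spec$size[2]
  img <- matrix(spec$sclera, h, w)
  for (d in spec$distractors)
    img <- aa_rect(img, d$x, d$y, d$width, d$height, d$intensity)
  img <- aa_disk(img, spec$iris_center, spec$iris_radius, spec$iris)
  img <- aa_disk(img, spec$iris_center, spec$pupil_radius, spec$pupil)
  if (!is.null(spec$glint))
    img <- aa_disk(img, spec$iris_center + spec$glint$offset,
                   spec$glint$radius, spec$glint$intensity)
  if (spec$eyelid_coverage > 0) {
    lid_y <- spec$iris_center[2] - spec$iris_radius +
      spec$eyelid_coverage * 2 * spec$iris_radius
    cov <- clamp(lid_y - matrix(seq_len(h), h, w) + 0.5, 0, 1)
    img <- img * (1 - cov) + spec$eyelid_intensity * cov
  }
  if (spec$noise_sigma > 0) {
    img <- with_seed(spec$seed, {
      img + matrix(stats::rnorm(h * w, 0,
        spec$noise_sigma * (spec$sclera - spec$pupil)), h, w)
    })
  }
  list(image = clamp(img, 0, 1), center = spec$iris_center, spec = spec)
}

# --- schematic faces ---

#' Specification for a schematic face
#'
#' Pose maps the unit landmark template into the canvas through
#' `A = scale * R(rotation) %*% shear(shear) %*% diag(box_size)`, centered
#' at `canvas/2 + translation`. Horizontal shear stands in for yaw.
#'
#' @param canvas `c(width, height)` pixels.
#' @param box_size nominal face-box side in pixels.
#' @param scale,rotation,shear,translation pose parameters (scale factor,
#'   radians, dimensionless shear, `c(dx, dy)` pixels).
#' @param jitter_sigma per-landmark Gaussian jitter s.d. (pixels).
#' @param noise_sigma image Gaussian noise s.d. (intensity units).
#' @param eyes_open if `FALSE` no sclera/iris/pupil is rendered (closed
#'   lids), exercising the no-candidate fallback path.
#' @param eyelid_coverage fraction of the iris diameter occluded from the
#'   top by the upper lid (0 = fully open).
#' @param iris_frac iris radius as a fraction of `box_size * scale`.
#' @param brow_strength multiplies eyebrow thickness and darkness
#'   (distractor severity dial for robustness experiments).
#' @param brow_drop renders the eyebrow bars lowered toward the eyes by
#'   this fraction of the face box (hooded brows / heavy glasses rim); the
#'   planted-distractor regime where a dark bar enters the eye region and
#'   competes with the iris for the maximum isocenter. Landmark ground
#'   truth is unaffected.
#' @param brow_blob radius, as a multiple of the iris radius, of a dark
#'   rounded brow head drawn at each brow's mid landmark (0 = none). A
#'   circular dark blob is the distractor that genuinely competes with a
#'   (partially occluded) iris for the maximum isocenter, emulating thick
#'   brow heads and glasses-rim corners.
#' @param seed integer RNG seed (jitter + noise).
#' @return list of class `face_spec`.
#' @export
face_spec <- function(canvas = c(150, 150), box_size = 0.6 * min(canvas),
                      scale = 1, rotation = 0, shear = 0,
                      translation = c(0, 0), jitter_sigma = 0,
                      noise_sigma = 0, eyes_open = TRUE,
                      eyelid_coverage = 0, iris_frac = 0.05,
                      brow_strength = 1, brow_drop = 0, brow_blob = 0,
                      seed = NULL) {
  structure(list(canvas = canvas, box_size = box_size, scale = scale,
                 rotation = rotation, shear = shear,
                 translation = translation, jitter_sigma = jitter_sigma,
                 noise_sigma = noise_sigma, eyes_open = eyes_open,
                 eyelid_coverage = eyelid_coverage, iris_frac = iris_frac,
                 brow_strength = brow_strength,
                 brow_drop = brow_drop, brow_blob = brow_blob,
                 seed = seed), class = "face_spec")
}

face_affine <- function(spec) {
  s <- spec$box_size * spec$scale
  R <- matrix(c(cos(spec$rotation), sin(spec$rotation),
                -sin(spec$rotation), cos(spec$rotation)), 2, 2)
  Sh <- matrix(c(1, 0, spec$shear, 1), 2, 2)
  A <- s * R %*% Sh
  list(A = A, center = spec$canvas / 2 + spec$translation)
}

#' Render a schematic face with landmark ground truth
#'
#' @param spec a [face_spec()].
#' @param scheme landmark scheme, default [ec_scheme_synth29()].
#' @return list with `image`, `landmarks` (29 x 2 shape, exact ground
#'   truth incl. both eye centers), `box` (landmark bounding box as a face
#'   box) and `spec`.
#' @export
render_face <- function(spec, scheme = ec_scheme_synth29()) {
  if (!inherits(spec, "face_spec")) spec <- do.call(face_spec, spec)
  aff <- face_affine(spec)
  lm <- t(aff$A %*% t(scheme$template - 0.5)) +
    matrix(aff$center, scheme$n, 2, byrow = TRUE)
  lm <- with_seed(spec$seed, {
    jit <- if (spec$jitter_sigma > 0)
      matrix(stats::rnorm(2 * scheme$n, 0, spec$jitter_sigma), scheme$n, 2)
    else matrix(0, scheme$n, 2)
    lm + jit
  })
  lm <- as_shape(lm)
  w <- spec$canvas[1]; h <- spec$canvas[2]
  img <- matrix(0.35, h, w)
  s_img <- spec$box_size * spec$scale       # local pixel scale of the face
  iris_r <- spec$iris_frac * s_img

  # skin ellipse: image of the unit-frame disk r=0.55 about (0.5, 0.52)
  Ainv <- solve(aff$A)
  px <- matrix(seq_len(w), h, w, byrow = TRUE) - aff$center[1]
  py <- matrix(seq_len(h), h, w) - aff$center[2]
  qx <- Ainv[1, 1] * px + Ainv[1, 2] * py
  qy <- Ainv[2, 1] * px + Ainv[2, 2] * py
  d_unit <- sqrt((qx - 0)^2 + (qy - 0.02)^2)    # offsets from box center
  cov <- clamp((0.55 - d_unit) * s_img + 0.5, 0, 1)
  img <- img * (1 - cov) + 0.75 * cov

  ydir <- as.numeric(aff$A %*% c(0, 1))
  ydir <- ydir / sqrt(sum(ydir^2))          # face-frame "down", unit pixels
  for (eye in list(scheme$left, scheme$right)) {
    corners <- lm[eye$contour[c(1, 3)], ]
    ctr <- lm[eye$center, ]
    if (spec$eyes_open) {
      img <- aa_capsule(img, corners[1, ], corners[2, ], 1.15 * iris_r, 0.92)
      img <- aa_disk(img, ctr, iris_r, 0.22)
      img <- aa_disk(img, ctr, 0.4 * iris_r, 0.08)
      if (spec$eyelid_coverage > 0) {
        # skin-toned upper lid descending over the iris (partial occlusion)
        hw_lid <- 1.6 * iris_r
        edge <- (-1 + 2 * spec$eyelid_coverage) * iris_r   # lid edge vs center
        off <- (edge - hw_lid) * ydir
        img <- aa_capsule(img, corners[1, ] + off, corners[2, ] + off,
                          hw_lid, 0.72)
      }
    } else {
      img <- aa_capsule(img, corners[1, ], corners[2, ], 1.0 * iris_r, 0.72)
      img <- aa_capsule(img, corners[1, ], corners[2, ], 0.015 * s_img, 0.45)
    }
  }

  # brows drawn in front of the lids (hooded-brow distractors must not be
  # painted over by eyelid skin)
  brows <- list(c(1L, 2L), c(2L, 3L), c(4L, 5L), c(5L, 6L))
  brow_hw <- 0.02 * s_img * spec$brow_strength
  brow_val <- clamp(0.30 - 0.08 * (spec$brow_strength - 1), 0.05, 1)
  drop_px <- as.numeric(aff$A %*% c(0, spec$brow_drop))  # along the face y axis
  for (b in brows)
    img <- aa_capsule(img, lm[b[1], ] + drop_px, lm[b[2], ] + drop_px,
                      brow_hw, brow_val)
  if (spec$brow_blob > 0) {
    blob_r <- spec$brow_blob * spec$iris_frac * s_img
    for (i in c(2L, 5L))
      img <- aa_disk(img, lm[i, ] + drop_px, blob_r, 0.12)
  }

  img <- aa_capsule(img, lm[17, ], lm[18, ], 0.012 * s_img, 0.66)
  img <- aa_disk(img, lm[19, ], 0.015 * s_img, 0.50)
  img <- aa_disk(img, lm[20, ], 0.015 * s_img, 0.50)
  img <- aa_capsule(img, lm[21, ], lm[25, ], 0.02 * s_img, 0.30)
  img <- aa_capsule(img, lm[26, ], lm[26, ] + c(0, 1e-6), 0.018 * s_img, 0.40)

  if (spec$noise_sigma > 0) {
    img <- with_seed(if (is.null(spec$seed)) NULL else spec$seed + 1L,
      img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w))
  }
  list(image = clamp(img, 0, 1), landmarks = lm,
       box = shape_facebox(lm), spec = spec)
}

#' Draw random face specifications
#'
#' Pose and nuisance parameters are drawn uniformly (translation:
#' Gaussian) from ranges emulating moderate frontal-to-near-profile pose
#' variation.
#'
#' @param n number of faces.
#' @param seed integer seed.
#' @param scale_range,rotation_range,shear_range uniform ranges.
#' @param translation_sd Gaussian s.d. of the face-center offset, pixels.
#' @param jitter_sigma,noise_sigma,brow_strength,eyes_open,canvas passed to
#'   [face_spec()].
#' @return list of `face_spec`s (each with its own derived seed).
#' @export
sample_face_specs <- function(n, seed = 1L, canvas = c(150, 150),
                              scale_range = c(0.85, 1.15),
                              rotation_range = c(-0.12, 0.12),
                              shear_range = c(-0.15, 0.15),
                              translation_sd = 3, jitter_sigma = 0.5,
                              noise_sigma = 0.02, brow_strength = 1,
                              brow_drop = 0, brow_blob = 0, eyes_open = TRUE,
                              eyelid_coverage_range = c(0, 0)) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      face_spec(canvas = canvas,
                scale = stats::runif(1, scale_range[1], scale_range[2]),
                rotation = stats::runif(1, rotation_range[1], rotation_range[2]),
                shear = stats::runif(1, shear_range[1], shear_range[2]),
                translation = stats::rnorm(2, 0, translation_sd),
                jitter_sigma = jitter_sigma, noise_sigma = noise_sigma,
                brow_strength = brow_strength, brow_drop = brow_drop,
                brow_blob = brow_blob, eyes_open = eyes_open,
                eyelid_coverage = stats::runif(1, eyelid_coverage_range[1],
                                               eyelid_coverage_range[2]),
                seed = sample.int(2^30, 1))
    })
  })
}

#' Write a synthetic face dataset to disk
#'
#' Renders `n` schematic faces and writes, per face, a PGM image and a
#' points-list landmark file, plus an eye-center CSV
#' (`filename, lx, ly, rx, ry`) and a manifest CSV recording each face's
#' pose parameters and seed. Re-running with the same arguments reproduces
#' the directory byte-for-byte.
#'
#' @param n number of faces (>= 1).
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param ... forwarded to [sample_face_specs()].
#' @return invisibly, a data.frame manifest.
#' @export
make_dataset <- function(n, dir, seed = 1L, ...) {
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- sample_face_specs(n, seed = seed, ...)
  scheme <- ec_scheme_synth29()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- render_face(specs[[i]], scheme)
    img_file <- sprintf("face_%04d.pgm", i)
    pts_file <- sprintf("face_%04d.pts", i)
    write_pgm(f$image, file.path(dir, img_file))
    write_landmarks(f$landmarks, file.path(dir, pts_file), format = "pts")
    sp <- specs[[i]]
    rows[[i]] <- data.frame(
      filename = img_file, landmarks = pts_file,
      lx = f$landmarks[scheme$left$center, 1],
      ly = f$landmarks[scheme$left$center, 2],
      rx = f$landmarks[scheme$right$center, 1],
      ry = f$landmarks[scheme$right$center, 2],
      scale = sp$scale, rotation = sp$rotation, shear = sp$shear,
      tx = sp$translation[1], ty = sp$translation[2], seed = sp$seed)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest[, c("filename", "lx", "ly", "rx", "ry")],
                   file.path(dir, "eyes.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
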