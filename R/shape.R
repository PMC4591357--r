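# Shapes, similarity transforms and the landmark scheme.
#
# A shape is an L x 2 numeric matrix of landmark (x, y) positions in image
# pixels, row order fixed by the annotation scheme. The 29-point "synth29"
# scheme mirrors the structural roles of the 29-landmark annotation used by
# common face-alignment training sets (eyebrows, eye contours including
# explicit eye centers, nose, mouth, jaw); it is a synthetic scheme defined
# by this package for its schematic-face generator.

as_shape <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L || !is.numeric(x) || !all(is.finite(x)))
    stop("a shape must be a finite L x 2 numeric matrix", call. = FALSE)
  colnames(x) <- c("x", "y")
  x
}

shape_bbox <- function(shape) {
  c(x0 = min(shape[, 1]), y0 = min(shape[, 2]),
    x1 = max(shape[, 1]), y1 = max(shape[, 2]))
}

# Bounding box as a face-box list(x, y, width, height).
shape_facebox <- function(shape) {
  b <- shape_bbox(shape)
  list(x = b[["x0"]], y = b[["y0"]],
       width = b[["x1"]] - b[["x0"]], height = b[["y1"]] - b[["y0"]],
       source = "landmarks")
}

# Map a shape into the unit square of its own bounding box.
shape_to_unit <- function(shape) {
  b <- shape_bbox(shape)
  w <- max(b[["x1"]] - b[["x0"]], .Machine$double.eps)
  h <- max(b[["y1"]] - b[["y0"]], .Machine$double.eps)
  cbind((shape[, 1] - b[["x0"]]) / w, (shape[, 2] - b[["y0"]]) / h)
}

# Place a unit-frame shape into a face box list(x, y, width, height).
shape_from_unit <- function(unit_shape, box) {
  cbind(box$x + unit_shape[, 1] * box$width,
        box$y + unit_shape[, 2] * box$height)
}

# --- similarity transform (scale + rotation + translation), complex form ---

shape_cx <- function(shape) complex(real = shape[, 1], imaginary = shape[, 2])

#' Least-squares similarity transform between two shapes
#'
#' Fits scale, rotation and translation mapping `from` onto `to`
#' (Procrustes without reflection), in closed form via the complex
#' representation.
#'
#' @param from,to L x 2 shape matrices with matching landmark order.
#' @return list with complex scale-rotation `a`, centroids `cf`, `ct`;
#'   apply with [sim_apply()].
#' @export
sim_fit <- function(from, to) {
  zf <- shape_cx(from); zt <- shape_cx(to)
  cf <- mean(zf); ct <- mean(zt)
  z0 <- zf - cf
  ss <- sum(Mod(z0)^2)
  if (ss < .Machine$double.eps)
    stop("degenerate shape: zero spatial extent", call. = FALSE)
  a <- sum(Conj(z0) * (zt - ct)) / ss
  if (Mod(a) < .Machine$double.eps)
    stop("degenerate similarity transform (zero scale)", call. = FALSE)
  list(a = a, cf = cf, ct = ct)
}

#' @rdname sim_fit
#' @param tr a transform from `sim_fit`.
#' @param shape shape matrix to transform.
#' @export
sim_apply <- function(tr, shape) {
  z <- tr$a * (shape_cx(shape) - tr$cf) + tr$ct
  cbind(Re(z), Im(z))
}

# Rotate/scale offset vectors (no translation) by the transform.
sim_rotate <- function(tr, offsets) {
  z <- tr$a * complex(real = offsets[, 1], imaginary = offsets[, 2])
  cbind(Re(z), Im(z))
}

#' The synthetic 29-point landmark scheme
#'
#' Canonical landmark template in the unit face box (x right, y down),
#' with explicit eye-center landmarks and the per-eye neighbor bases
#' (4 eye-contour + 2 eyebrow landmarks) used by the affine-invariant
#' shape-constraint reconstruction. "left"/"right" refer to image
#' coordinates (image-left eye = the subject's right eye).
#'
#' @return list with `name`, `n`, `template` (29 x 2), and per-eye index
#'   lists `left`, `right` (`center`, `contour`, `brow`).
#' @export
ec_scheme_synth29 <- function() {
  template <- rbind(
    # image-left eyebrow: outer, mid, inner (1-3)
    c(0.18, 0.30), c(0.28, 0.26), c(0.38, 0.30),
    # image-right eyebrow: inner, mid, outer (4-6)
    c(0.62, 0.30), c(0.72, 0.26), c(0.82, 0.30),
    # image-left eye: outer corner, top, inner corner, bottom, center (7-11)
    c(0.20, 0.40), c(0.28, 0.37), c(0.36, 0.40), c(0.28, 0.43), c(0.28, 0.40),
    # image-right eye: inner corner, top, outer corner, bottom, center (12-16)
    c(0.64, 0.40), c(0.72, 0.37), c(0.80, 0.40), c(0.72, 0.43), c(0.72, 0.40),
    # nose: bridge, tip, left nostril, right nostril (17-20)
    c(0.50, 0.45), c(0.50, 0.58), c(0.43, 0.62), c(0.57, 0.62),
    # mouth: left corner, upper-left, top center, upper-right, right corner,
    # bottom center (21-26)
    c(0.36, 0.74), c(0.43, 0.71), c(0.50, 0.70), c(0.57, 0.71),
    c(0.64, 0.74), c(0.50, 0.78),
    # chin, jaw left, jaw right (27-29)
    c(0.50, 0.92), c(0.16, 0.70), c(0.84, 0.70))
  list(name = "synth29", n = 29L, template = as_shape(template),
       left  = list(center = 11L, contour = c(7L, 8L, 9L, 10L),
                    brow = c(1L, 3L)),
       right = list(center = 16L, contour = c(12L, 13L, 14L, 15L),
                    brow = c(4L, 6L)))
}

# --- annotation I/O ---

#' Read landmark annotations
#'
#' Accepts two plain-text dialects: one "x y" pair per line, or a
#' points-list file with a count header
#' (`version: 1`, `n_points: L`, `{`, L coordinate lines, `}`).
#'
#' @param path file path.
#' @return L x 2 shape matrix.
#' @export
read_landmarks <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^version", lines[1], ignore.case = TRUE)) {
    n <- as.integer(sub("^n_points:\\s*", "", lines[2], ignore.case = TRUE))
    body <- lines[!(lines %in% c("{", "}"))][-(1:2)]
    if (length(body) != n)
      stop(sprintf("points file declares %d landmarks but holds %d",
                   n, length(body)), call. = FALSE)
    lines <- body
  }
  vals <- lapply(strsplit(lines, "\\s+"), as.numeric)
  if (any(vapply(vals, length, 1L) != 2L) || anyNA(unlist(vals)))
    stop("landmark file must hold one 'x y' pair per line", call. = FALSE)
  as_shape(do.call(rbind, vals))
}

#' @rdname read_landmarks
#' @param shape L x 2 shape matrix.
#' @param format `"xy"` (bare pairs) or `"pts"` (count-header dialect).
#' @export
write_landmarks <- function(shape, path, format = c("xy", "pts")) {
  format <- match.arg(format)
  shape <- as_shape(shape)
  body <- sprintf("%.6f %.6f", shape[, 1], shape[, 2])
  lines <- if (format == "pts")
    c("version: 1", sprintf("n_points: %d", nrow(shape)), "{", body, "}")
  else body
  writeLines(lines, path)
  invisible(path)
}

#' Read ground-truth eye-center annotations
#'
#' Reads the classic one-line eye-position format (comment lines starting
#' with `#` skipped; four numbers: left-eye x y, right-eye x y) or a CSV
#' with columns `filename, lx, ly, rx, ry`.
#'
#' @param path file path; `.csv` selects the CSV dialect.
#' @return For the one-line format, a list with `left`, `right` points;
#'   for CSV, a data.frame.
#' @export
read_eye_annotation <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("filename", "lx", "ly", "rx", "ry")
    if (!all(need %in% names(df)))
      stop("eye CSV must have columns filename, lx, ly, rx, ry", call. = FALSE)
    return(df)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  lines <- lines[nzchar(lines)]
  v <- as.numeric(strsplit(lines[1], "[\\s,]+", perl = TRUE)[[1]])
  if (length(v) < 4L || anyNA(v[1:4]))
    stop("eye file must hold four numbers: lx ly rx ry", call. = FALSE)
  list(left = c(x = v[1], y = v[2]), right = c(x = v[3], y = v[4]))
}
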