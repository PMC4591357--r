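# Raster I/O and debug exports.
#
# Supported formats: PNG (via the png package), portable graymap PGM
# (ASCII P2 and binary P5, read; ASCII P2, write) and whitespace-delimited
# plain-text grids. Color input collapses to luminance with the standard
# Rec. 601 luma weights.

#' Read an image as a grayscale matrix
#'
#' @param path file path; format chosen by extension (`.png`, `.pgm`,
#'   anything else is read as a plain-text grid).
#' @return numeric matrix `[row, col]`, values in the file's native scale
#'   (PNG: 0..1, PGM: 0..maxval).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = to_gray(png::readPNG(path)),
    pgm = read_pgm(path),
    as.matrix(utils::read.table(path)))
  storage.mode(img) <- "double"
  dimnames(img) <- NULL
  img
}

#' @rdname read_image
#' @param x matrix or h x w x c array (RGB/RGBA).
#' @export
to_gray <- function(x) {
  if (is.matrix(x)) return(x)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L)
      return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
    return(x[, , 1])
  }
  stop("cannot interpret input as an image", call. = FALSE)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens may be interleaved with comments
  tok <- character(); buf <- raw(0)
  read_token <- function() {
    repeat {
      ch <- readBin(con, "raw", 1L)
      if (!length(ch)) stop("truncated PGM header", call. = FALSE)
      c2 <- rawToChar(ch)
      if (c2 == "#") { # comment to end of line
        repeat {
          ch <- readBin(con, "raw", 1L)
          if (!length(ch) || rawToChar(ch) == "\n") break
        }
      } else if (grepl("\\s", c2)) {
        if (length(buf)) break
      } else buf <<- c(buf, ch)
    }
    out <- rawToChar(buf); buf <<- raw(0); out
  }
  magic <- read_token()
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  if (magic == "P5") {
    vals <- if (maxval < 256) as.integer(readBin(con, "raw", n)) else
      readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  } else if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else stop("not a PGM file (expected P2 or P5)", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale matrix as an ASCII PGM (P2) file
#'
#' @param img numeric matrix; values are rescaled from `range` to
#'   `0..maxval`.
#' @param path output path.
#' @param maxval maximum gray value.
#' @param range intensity range mapped onto `0..maxval` (default `c(0, 1)`).
#' @export
write_pgm <- function(img, path, maxval = 255L, range = c(0, 1)) {
  v <- round(clamp((img - range[1]) / diff(range), 0, 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", maxval)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a field as a plain-text grid or a PNG heatmap
#'
#' Debug outputs for center maps and curvedness fields.
#'
#' @param mat numeric matrix (e.g. `cm$votes`).
#' @param path output path.
#' @export
write_text_grid <- function(mat, path) {
  utils::write.table(format(mat, digits = 10, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_text_grid
#' @export
read_text_grid <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' @rdname write_text_grid
#' @export
write_heatmap_png <- function(mat, path) {
  rng <- range(mat)
  u <- if (diff(rng) > 0) (mat - rng[1]) / diff(rng) else mat * 0
  # simple black-red-yellow-white ramp
  r <- clamp(3 * u, 0, 1)
  g <- clamp(3 * u - 1, 0, 1)
  b <- clamp(3 * u - 2, 0, 1)
  png::writePNG(array(c(r, g, b), dim = c(dim(mat), 3L)), path)
  invisible(path)
}
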