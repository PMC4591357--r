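# Multi-scale candidate extraction.
#
# A single center map can lock onto an eyebrow, eyelid or glint instead of
# the iris. Five differently-smoothed center maps are therefore built per
# eye region, each blurred with a small mean filter, and the two strongest
# separation-constrained isocenters of each map are pooled into a set of up
# to ten candidates; a downstream shape constraint picks the winner.

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the candidate stage. Scale-dependent
#' quantities (Gaussian widths, MIC separation, blur size) are by default
#' expressed relative to a reference eye-region width `ref_width` so the
#' pipeline behaves identically across image resolutions; `"fixed"` modes
#' reproduce absolute-pixel behavior.
#'
#' @param sigmas five increasing Gaussian widths at the reference width;
#'   scaled by `region_width / ref_width` unless `sigma_mode = "fixed"`.
#' @param sigma_mode,separation_mode,blur_mode `"scaled"` or `"fixed"`.
#' @param min_separation minimum Euclidean distance (pixels at reference
#'   width) between the two isocenters taken from one map.
#' @param blur_size mean-filter size (rows, cols) at the reference width.
#' @param r_bounds_frac accepted displacement radii as fractions of the
#'   eye-region width.
#' @param ref_width reference eye-region width in pixels.
#' @return list of class `ec_config`.
#' @export
ec_config <- function(sigmas = c(1, 1.5, 2.25, 3.4, 5.1),
                      sigma_mode = c("scaled", "fixed"),
                      min_separation = 21,
                      separation_mode = c("scaled", "fixed"),
                      blur_size = c(6, 6),
                      blur_mode = c("scaled", "fixed"),
                      r_bounds_frac = c(0.05, 0.5),
                      ref_width = 60) {
  if (length(sigmas) != 5L || any(diff(sigmas) <= 0) || any(sigmas <= 0))
    stop("sigmas must be 5 positive increasing values", call. = FALSE)
  cfg <- list(sigmas = sigmas,
              sigma_mode = match.arg(sigma_mode),
              min_separation = min_separation,
              separation_mode = match.arg(separation_mode),
              blur_size = blur_size,
              blur_mode = match.arg(blur_mode),
              r_bounds_frac = r_bounds_frac,
              ref_width = ref_width)
  class(cfg) <- "ec_config"
  cfg
}

# Resolve scale-dependent config values for a concrete region width.
resolve_config <- function(cfg, region_width) {
  f <- region_width / cfg$ref_width
  list(
    sigmas = if (cfg$sigma_mode == "scaled") cfg$sigmas * f else cfg$sigmas,
    min_separation = if (cfg$separation_mode == "scaled")
      cfg$min_separation * f else cfg$min_separation,
    blur_size = if (cfg$blur_mode == "scaled")
      pmax(2L, round(cfg$blur_size * f)) else as.integer(cfg$blur_size),
    r_bounds = cfg$r_bounds_frac * region_width
  )
}

#' Write/read configuration as a YAML file
#'
#' @param cfg an `ec_config`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(ec_config, vals)
}

#' Build the five-scale bank of center maps
#'
#' Runs the full isophote voting pass (smooth, differentiate, accumulate)
#' once per Gaussian width.
#'
#' @param eye_img numeric matrix, the eye-region image (at least 16x16).
#' @param sigmas five positive increasing Gaussian widths in pixels.
#' @param r_bounds accepted displacement radii in pixels.
#' @return list of class `scale_bank`: `sigmas` and `maps` (five
#'   `center_map`s).
#' @export
build_scale_bank <- function(eye_img, sigmas,
                             r_bounds = c(0.05, 0.5) * ncol(eye_img)) {
  if (nrow(eye_img) < 16L || ncol(eye_img) < 16L)
    stop("eye region too small (need at least 16x16 pixels)", call. = FALSE)
  if (length(sigmas) != 5L || any(sigmas <= 0) || any(diff(sigmas) < 0))
    stop("need 5 positive non-decreasing sigmas", call. = FALSE)
  maps <- lapply(sigmas, function(s) center_map(eye_img, s, r_bounds))
  structure(list(sigmas = sigmas, maps = maps), class = "scale_bank")
}

#' Blur a center map with a mean filter
#'
#' Smooths the vote accumulator before isocenter extraction so that slight
#' displacement errors do not fragment the peak. Total vote mass is
#' conserved exactly (out-of-image filter mass folds back by reflection);
#' in the interior this is the ordinary `size` box average, with the even
#' kernel anchored at the lower-right-of-center cell.
#'
#' @param cm a `center_map`.
#' @param size filter size `(rows, cols)`, default `c(6, 6)`.
#' @return blurred `center_map` (same `n_votes`).
#' @export
blur_center_map <- function(cm, size = c(6L, 6L)) {
  structure(list(votes = box_scatter(cm$votes, size), n_votes = cm$n_votes),
            class = "center_map")
}

#' Two separation-constrained isocenters of a map
#'
#' The first point is the global maximum; the second is the
#' highest-response cell at Euclidean distance at least `min_separation`
#' from it (two near-coincident maxima would describe the same isocenter).
#' If no positive-response cell is far enough away, only one point is
#' returned.
#'
#' @param cm a `center_map` with `n_votes > 0`.
#' @param min_separation minimum distance between the two points, pixels.
#' @return list of 1 or 2 lists `(x, y, response)`.
#' @export
top2_mics <- function(cm, min_separation = 21) {
  p1 <- mic(cm)
  v <- cm$votes
  h <- nrow(v)
  rows <- row(v); cols <- col(v)
  far <- (cols - p1$x)^2 + (rows - p1$y)^2 >= min_separation^2
  pool <- v[far]
  if (!length(pool) || max(pool) <= 0) return(list(p1))
  m2 <- max(pool)
  idx <- which(far & v == m2)
  r <- (idx - 1L) %% h + 1L
  c_ <- (idx - 1L) %/% h + 1L
  o <- order(r, c_)[1L]
  list(p1, list(x = c_[o], y = r[o], response = m2))
}

#' Pool multi-scale candidates for one eye region
#'
#' Builds the five-scale bank, blurs each map, extracts up to two
#' isocenters per map, and translates them by `region_offset` into
#' base-image coordinates.
#'
#' @param eye_img eye-region image matrix.
#' @param region_offset `c(x, y)` offset such that base-image coordinate =
#'   region coordinate + offset.
#' @param config an [ec_config()].
#' @return data.frame of class `candidate_set` with columns
#'   `x, y, response, scale_index (1..5), rank_in_map (1..2)`; zero rows if
#'   every map is empty.
#' @export
collect_candidates <- function(eye_img, region_offset = c(0, 0),
                               config = ec_config()) {
  rc <- resolve_config(config, ncol(eye_img))
  bank <- build_scale_bank(eye_img, rc$sigmas, rc$r_bounds)
  out <- list()
  for (i in seq_along(bank$maps)) {
    cmi <- bank$maps[[i]]
    if (cmi$n_votes == 0L) next
    cmi <- blur_center_map(cmi, rc$blur_size)
    pts <- top2_mics(cmi, rc$min_separation)
    for (j in seq_along(pts)) {
      p <- pts[[j]]
      if (p$response <= 0) next
      out[[length(out) + 1L]] <- data.frame(
        x = p$x + region_offset[1], y = p$y + region_offset[2],
        response = p$response, scale_index = i, rank_in_map = j)
    }
  }
  cs <- if (length(out)) do.call(rbind, out) else
    data.frame(x = numeric(), y = numeric(), response = numeric(),
               scale_index = integer(), rank_in_map = integer())
  class(cs) <- c("candidate_set", "data.frame")
  cs
}
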