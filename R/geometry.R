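#' Specify a stripe-shaped microlane pattern
#'
#' A microlane is a stripe of adhesive substrate of tip-to-tip length
#' `length_L` and width `width_W` (both in micrometres), capped by one of
#' four tip shapes:
#'
#' * `"round"`: rectangle of length `L - W` capped by two half-discs of
#'   radius `W/2`,
#' * `"blunt"`: plain rectangle,
#' * `"sharp"`: rectangle capped by two isoceles triangles (half-angle
#'   `sharp_half_angle` degrees at the lane axis),
#' * `"concave"`: rectangle with an inward circular arc of radius
#'   `concave_radius` cut into each flat end.
#'
#' The long-axis coordinate ("koor") is measured in micrometres from the
#' lane centre, increasing along the long axis; tips sit at `+/- L/2`.
#'
#' @param length_L Tip-to-tip lane length in micrometres.
#' @param width_W Lane width in micrometres; must exceed 0 and be smaller
#'   than `length_L`, and must be an integer multiple of `spacing`.
#' @param tip_shape One of `"round"`, `"blunt"`, `"sharp"`, `"concave"`.
#' @param spacing Lattice spacing in micrometres per site (default 2, so a
#'   20-um lane is 10 sites wide).
#' @param sharp_half_angle Half-opening angle of the sharp tip in degrees.
#' @param concave_radius Radius of the concave cut in micrometres
#'   (default `width_W / 2`; larger cuts are rejected as infeasible).
#' @return An object of class `pattern_spec`.
#' @examples
#' spec <- pattern_spec(170, 20, "round")
#' pattern_area(spec)
#' @export
pattern_spec <- function(length_L, width_W, tip_shape = c("round", "blunt",
                                                          "sharp", "concave"),
                         spacing = 2, sharp_half_angle = 55,
                         concave_radius = width_W / 2) {
  tip_shape <- match.arg(tip_shape)
  stopifnot(is.numeric(length_L), is.numeric(width_W), length(length_L) == 1,
            length(width_W) == 1, is.numeric(spacing), spacing > 0)
  if (!(length_L > width_W && width_W > 0))
    stop("need length_L > width_W > 0")
  if (abs(width_W / spacing - round(width_W / spacing)) > 1e-9)
    stop("spacing must divide width_W evenly")
  if (width_W / spacing < 4)
    stop("spacing too coarse to resolve the tip: width must span >= 4 sites")
  if (tip_shape == "sharp" && !(sharp_half_angle > 0 && sharp_half_angle < 90))
    stop("sharp_half_angle must be in (0, 90) degrees")
  if (tip_shape == "concave" && concave_radius > width_W / 2 + 1e-9)
    stop("concave cut deeper than possible: concave_radius must be <= width_W/2")
  if (tip_shape == "concave" && concave_radius <= 0)
    stop("concave_radius must be positive")
  if (tip_shape == "sharp") {
    tip_len <- (width_W / 2) / tan(sharp_half_angle * pi / 180)
    if (2 * tip_len >= length_L)
      stop("sharp tips would overlap: lane too short for this half-angle")
  }
  structure(list(length_L = length_L, width_W = width_W,
                 tip_shape = tip_shape, spacing = spacing,
                 sharp_half_angle = sharp_half_angle,
                 concave_radius = concave_radius),
            class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat(sprintf("microlane pattern: %s tip, L = %g um, W = %g um, spacing %g um (area %.2f um^2)\n",
              x$tip_shape, x$length_L, x$width_W, x$spacing, pattern_area(x)))
  invisible(x)
}

#' Analytic adhesive area of a microlane pattern
#'
#' Closed-form area of the continuous (un-rasterized) pattern in square
#' micrometres.
#'
#' @param spec A [pattern_spec()].
#' @return Area in um^2.
#' @export
pattern_area <- function(spec) {
  L <- spec$length_L; W <- spec$width_W
  switch(spec$tip_shape,
         blunt = L * W,
         round = (L - W) * W + pi * (W / 2)^2,
         sharp = L * W - W^2 / (2 * tan(spec$sharp_half_angle * pi / 180)),
         concave = L * W - pi * spec$concave_radius^2)
}

#' Rasterize a microlane pattern
#'
#' Builds the boolean site raster of admissible (adhesive) lattice sites.
#' A site belongs to the mask when its centre lies inside the continuous
#' pattern. Site centres sit at `(i - 1/2) * spacing` relative to the grid
#' edge; the grid is sized so that the raster is mirror-symmetric about
#' both lane midlines.
#'
#' @param spec A [pattern_spec()].
#' @return An object of class `lane_mask`: a list with elements `grid`
#'   (logical matrix, rows = long axis), `spacing`, `x` and `y` (site-centre
#'   coordinates in the koor frame, micrometres from the lane centre), and
#'   `spec`.
#' @examples
#' m <- make_mask(pattern_spec(170, 20, "round"))
#' sum(m$grid) * m$spacing^2   # raster area, close to pattern_area()
#' @export
make_mask <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  h <- spec$spacing
  L <- spec$length_L; W <- spec$width_W
  nx <- ceiling(L / h); ny <- round(W / h)
  x <- ((seq_len(nx) - 0.5) - nx / 2) * h
  y <- ((seq_len(ny) - 0.5) - ny / 2) * h
  ax <- abs(outer(x, rep(1, ny)))          # |long-axis coord| per site
  ay <- abs(outer(rep(1, nx), y))          # |short-axis coord| per site
  grid <- switch(spec$tip_shape,
    blunt = ax <= L / 2 & ay <= W / 2,
    round = {
      incap <- (ax - (L / 2 - W / 2))^2 + ay^2 <= (W / 2)^2
      (ax <= L / 2 - W / 2 & ay <= W / 2) | incap
    },
    sharp = {
      tn <- tan(spec$sharp_half_angle * pi / 180)
      tip_len <- (W / 2) / tn
      (ax <= L / 2 - tip_len & ay <= W / 2) |
        (ax > L / 2 - tip_len & ax <= L / 2 & ay <= (L / 2 - ax) * tn)
    },
    concave = {
      r <- spec$concave_radius
      ax <= L / 2 & ay <= W / 2 & (ax - L / 2)^2 + ay^2 > r^2
    })
  structure(list(grid = grid, spacing = h, x = x, y = y, spec = spec),
            class = "lane_mask")
}

#' @export
print.lane_mask <- function(x, ...) {
  cat(sprintf("lane mask: %s tip, %d x %d sites at %g um (raster area %.1f um^2)\n",
              x$spec$tip_shape, nrow(x$grid), ncol(x$grid), x$spacing,
              sum(x$grid) * x$spacing^2))
  invisible(x)
}

#' Raster area of a mask
#'
#' @param mask A [make_mask()] result.
#' @return Occupied-site count times spacing squared, in um^2.
#' @export
mask_area <- function(mask) sum(mask$grid) * mask$spacing^2

#' Match the adhesive area of a reference pattern with a different tip shape
#'
#' Returns a spec of the requested tip shape whose analytic area equals the
#' reference area, keeping the width (and spacing) fixed and adjusting only
#' the length. This mirrors microlane designs where differently shaped tips
#' are compared at constant total adhesive area.
#'
#' @param tip_shape Requested tip shape.
#' @param reference A [pattern_spec()] whose area is to be matched.
#' @param sharp_half_angle,concave_radius Tip geometry of the requested
#'   shape (defaults as in [pattern_spec()]).
#' @return A `pattern_spec` with the same width and an adjusted length.
#' @examples
#' ref <- pattern_spec(170, 20, "round")
#' equalize_area("blunt", ref)   # length 165.7 um
#' @export
equalize_area <- function(tip_shape, reference,
                          sharp_half_angle = 55,
                          concave_radius = reference$width_W / 2) {
  stopifnot(inherits(reference, "pattern_spec"))
  A <- pattern_area(reference)
  W <- reference$width_W
  L <- switch(tip_shape,
              blunt = A / W,
              round = (A - pi * (W / 2)^2) / W + W,
              sharp = (A + W^2 / (2 * tan(sharp_half_angle * pi / 180))) / W,
              concave = (A + pi * concave_radius^2) / W,
              stop("unknown tip shape: ", tip_shape))
  if (!(L > W)) stop("infeasible geometry: equal-area length would not exceed the width")
  pattern_spec(L, W, tip_shape, spacing = reference$spacing,
               sharp_half_angle = sharp_half_angle,
               concave_radius = concave_radius)
}

#' Define the reversal regions at the lane tips
#'
#' The reversal region consists of the two stretches of the lane within
#' `xi0` micrometres of either tip. `xi0` is the tip-to-changepoint
#' distance of the spatial speed profile (about 55 um in MDA-MB-231
#' experiments across lane lengths); a cell "reverses" while its position
#' lies inside one of these intervals.
#'
#' @param spec A [pattern_spec()], or a lane length in micrometres.
#' @param xi0 Distance from each tip, micrometres; must satisfy
#'   `0 <= xi0 < L/2` (at `xi0 >= L/2` the two regions would cover the
#'   entire lane and no run phase exists).
#' @return An object of class `reversal_region`: list with `xi0`,
#'   `lane_length`, and tip intervals `left`, `right` in koor coordinates.
#' @examples
#' reversal_region(170, 55)  # intervals [-85,-30] and [30,85]
#' @export
reversal_region <- function(spec, xi0 = 55) {
  L <- if (inherits(spec, "pattern_spec")) spec$length_L else as.numeric(spec)
  stopifnot(is.numeric(xi0), length(xi0) == 1, xi0 >= 0)
  if (xi0 >= L / 2)
    stop("xi0 >= L/2: reversal regions cover the whole lane (no run phase)")
  structure(list(xi0 = xi0, lane_length = L,
                 left = c(-L / 2, -L / 2 + xi0),
                 right = c(L / 2 - xi0, L / 2)),
            class = "reversal_region")
}

#' Export a mask as a PNG raster with a plain-text sidecar header
#'
#' Writes a single-channel PNG (0 = forbidden, 255 = adhesive; image rows
#' run across the lane) and a `<path>.txt` sidecar recording spacing and
#' origin so the raster can be reinterpreted in physical units.
#'
#' @param mask A [make_mask()] result.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
write_mask_png <- function(mask, path) {
  img <- t(mask$grid) * 1.0        # rows = short axis, columns = long axis
  png::writePNG(img, target = path)
  hdr <- c(sprintf("spacing_um: %g", mask$spacing),
           sprintf("tip_shape: %s", mask$spec$tip_shape),
           sprintf("length_um: %g", mask$spec$length_L),
           sprintf("width_um: %g", mask$spec$width_W),
           "origin: lane centre (koor = 0); columns run along the long axis",
           sprintf("x_first_site_um: %g", mask$x[1]))
  writeLines(hdr, paste0(path, ".txt"))
  invisible(path)
}

#' Read a mask written by [write_mask_png()]
#'
#' @param path PNG path with sidecar `<path>.txt`.
#' @return A `lane_mask`-like list with `grid`, `spacing`, `x`, `y`.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  grid <- t(img > 0.5)
  hdr <- readLines(paste0(path, ".txt"))
  getval <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    sub(paste0("^", key, ":\\s*"), "", ln[1])
  }
  h <- as.numeric(getval("spacing_um"))
  nx <- nrow(grid); ny <- ncol(grid)
  structure(list(grid = grid, spacing = h,
                 x = ((seq_len(nx) - 0.5) - nx / 2) * h,
                 y = ((seq_len(ny) - 0.5) - ny / 2) * h,
                 spec = NULL),
            class = "lane_mask")
}
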