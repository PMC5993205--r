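# Synthetic ground-truth slides and a simulated microscope.
#
# Slides follow the standard 75 x 25 mm format with a frosted labelling band
# at the left end; objects are embryo-scale textured ellipses placed under a
# coverslip region on the clear glass. Every operation is a pure function of
# its inputs and seed, and the generator records full ground truth (object
# table, frosted-edge position, per-load pose) so downstream stages can be
# scored against it.

#' Specify a synthetic slide
#'
#' Defaults model a 75 x 25 mm slide with a 19 mm frosted band, a centered
#' 22 x 22 mm coverslip on the clear glass, and embryo-scale objects
#' (400-550 um long, aspect ratio 2.2-3).
#'
#' @param width_um,height_um Slide dimensions, um.
#' @param frosted_band_w_um Width of the frosted band at the slide's left end.
#' @param coverslip A [region()] on the clear glass holding the objects.
#' @param n_objects Number of objects to place.
#' @param object_len_um_range Range of object major-axis lengths, um.
#' @param object_aspect_range Range of length/width aspect ratios.
#' @param texture_granularity_um Spatial scale of the object texture, um.
#' @param background_level Clear-glass intensity in `[0, 1]`.
#' @param object_contrast Peak fractional darkening of objects vs background.
#' @param min_gap_um Minimum clearance enforced between placed objects, um.
#' @param seed Integer seed making the slide reproducible.
#' @return An object of class `sf_slide_spec`.
#' @export
slide_spec <- function(width_um = 75000, height_um = 25000,
                       frosted_band_w_um = 19000,
                       coverslip = region(30000, 1500, 22000, 22000),
                       n_objects = 300,
                       object_len_um_range = c(400, 550),
                       object_aspect_range = c(2.2, 3.0),
                       texture_granularity_um = 15,
                       background_level = 0.85,
                       object_contrast = 0.35,
                       min_gap_um = 80,
                       seed = 1L) {
  stopifnot(width_um > 0, height_um > 0,
            frosted_band_w_um > 0, frosted_band_w_um < width_um,
            inherits(coverslip, "sf_region"), n_objects >= 0,
            object_len_um_range[1] > 0, diff(object_len_um_range) >= 0,
            object_aspect_range[1] >= 1,
            background_level >= 0, background_level <= 1,
            object_contrast >= 0, object_contrast <= 1)
  if (coverslip$x_um < frosted_band_w_um ||
      coverslip$x_um + coverslip$w_um > width_um ||
      coverslip$y_um < 0 || coverslip$y_um + coverslip$h_um > height_um)
    sf_stop("sf_spec_error",
            "coverslip region must lie entirely on the clear (non-frosted) glass")
  structure(list(width_um = width_um, height_um = height_um,
                 frosted_band_w_um = frosted_band_w_um, coverslip = coverslip,
                 n_objects = as.integer(n_objects),
                 object_len_um_range = object_len_um_range,
                 object_aspect_range = object_aspect_range,
                 texture_granularity_um = texture_granularity_um,
                 background_level = background_level,
                 object_contrast = object_contrast,
                 min_gap_um = min_gap_um, seed = as.integer(seed)),
            class = "sf_slide_spec")
}

#' Camera model for the simulated microscope
#'
#' @param sensor_w_px,sensor_h_px Sensor dimensions in pixels.
#' @param ref_um_per_px_at_1x Pixel pitch referred to 1x magnification; the
#'   pitch at magnification M is `ref_um_per_px_at_1x / M`.
#' @param read_noise_sd Gaussian read-noise standard deviation (intensity
#'   units on `[0, 1]`).
#' @param bit_depth Output quantisation depth, bits.
#' @export
camera_model <- function(sensor_w_px = 1024L, sensor_h_px = 768L,
                         ref_um_per_px_at_1x = 10, read_noise_sd = 0.01,
                         bit_depth = 8L) {
  stopifnot(sensor_w_px >= 8, sensor_h_px >= 8, ref_um_per_px_at_1x > 0,
            read_noise_sd >= 0, bit_depth >= 1)
  structure(list(sensor_w_px = as.integer(sensor_w_px),
                 sensor_h_px = as.integer(sensor_h_px),
                 ref_um_per_px_at_1x = as.numeric(ref_um_per_px_at_1x),
                 read_noise_sd = as.numeric(read_noise_sd),
                 bit_depth = as.integer(bit_depth)),
            class = "sf_camera_model")
}

#' Defocus model
#'
#' Gaussian blur whose sigma (in pixels) grows linearly with the distance
#' from the focal plane; sigma is exactly 0 at true focus. An optional linear
#' focal-plane tilt across the slide can be supplied.
#'
#' @param blur_sigma_px_per_um Blur growth rate, px per um of defocus.
#' @param z_tilt Length-2 focal-plane gradient (um of z per um of x, y).
#' @export
focus_model <- function(blur_sigma_px_per_um = 0.5, z_tilt = c(0, 0)) {
  stopifnot(blur_sigma_px_per_um > 0, length(z_tilt) == 2)
  structure(list(blur_sigma_px_per_um = blur_sigma_px_per_um, z_tilt = z_tilt),
            class = "sf_focus_model")
}

# run code under a temporary RNG state; seed = NULL leaves the RNG alone
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

clamp01 <- function(x) {
  a <- attributes(x)
  x <- pmin(1, pmax(0, x))
  attributes(x) <- a
  x
}

# deterministic band-limited value noise over intrinsic slide coordinates:
# hash of the integer lattice, bilinearly interpolated with a smoothstep fade.
# A pure function of position, so texture is identical across overlapping
# fields, magnifications and slide reloads.
vnoise <- function(x, y, gran, seed) {
  .vnoise_cpp(as.numeric(x), as.numeric(y), gran, as.integer(seed %% 2147483647))
}

#' Generate a synthetic slide with full ground truth
#'
#' Objects are placed by rejection sampling (at most 1000 attempts each) so
#' that every ellipse lies fully inside the coverslip region and no two
#' objects come closer than `min_gap_um`. Deterministic for a fixed spec.
#'
#' @param spec An [slide_spec()].
#' @return An object of class `sf_slide`: the spec, the object table
#'   (intrinsic-frame centers, semi-axes, orientation, texture seed), the
#'   frosted-edge position, the focal plane, and the current load pose
#'   (identity until [load_slide()] is called).
#' @export
make_slide <- function(spec) {
  stopifnot(inherits(spec, "sf_slide_spec"))
  cs <- spec$coverslip
  objects <- local_seed(spec$seed, {
    n <- spec$n_objects
    xs <- ys <- a_um <- b_um <- th <- numeric(n)
    tseed <- integer(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(1000)) {
        len <- stats::runif(1, spec$object_len_um_range[1], spec$object_len_um_range[2])
        asp <- stats::runif(1, spec$object_aspect_range[1], spec$object_aspect_range[2])
        a <- len / 2; b <- a / asp
        cx <- stats::runif(1, cs$x_um + a, cs$x_um + cs$w_um - a)
        cy <- stats::runif(1, cs$y_um + a, cs$y_um + cs$h_um - a)
        if (i > 1) {
          j <- seq_len(i - 1)
          dd <- sqrt((xs[j] - cx)^2 + (ys[j] - cy)^2)
          if (any(dd < a_um[j] + a + spec$min_gap_um)) next
        }
        xs[i] <- cx; ys[i] <- cy; a_um[i] <- a; b_um[i] <- b
        th[i] <- stats::runif(1, 0, pi)
        tseed[i] <- sample.int(1e6, 1)
        placed <- TRUE
        break
      }
      if (!placed)
        sf_stop("sf_placement_error",
                "could not place object %d without overlap after 1000 attempts", i)
    }
    data.frame(id = seq_len(n), x_um = xs, y_um = ys, a_um = a_um, b_um = b_um,
               theta_rad = th, texture_seed = tseed)
  })
  structure(list(spec = spec, objects = objects,
                 frosted_edge_x_um = spec$frosted_band_w_um,
                 focal_plane_z_um = 0,
                 pose = offset_correction()),
            class = "sf_slide")
}

#' @export
print.sf_slide <- function(x, ...) {
  cat(sprintf("<slide: %g x %g um, %d objects, pose (%.1f, %.1f um, %.2e rad)>\n",
              x$spec$width_um, x$spec$height_um, nrow(x$objects),
              x$pose$dx_um, x$pose$dy_um, x$pose$rot_rad))
  invisible(x)
}

#' Slide center (rotation pivot for load poses)
#' @param slide An `sf_slide`.
#' @export
slide_center <- function(slide) {
  stage_point(slide$spec$width_um / 2, slide$spec$height_um / 2)
}

#' Simulate (re)loading a slide onto the stage
#'
#' Draws a fresh seating pose: dx, dy ~ N(0, sd_um^2) and a rotation
#' ~ N(0, sd_rad^2) about the slide center. The pose is recorded in the
#' returned slide as ground truth for calibration scoring.
#'
#' @param slide An `sf_slide`.
#' @param sd_um Seating translation noise, um (both axes).
#' @param sd_rad Seating rotation noise, radians.
#' @param seed Optional integer seed.
#' @export
load_slide <- function(slide, sd_um = 200, sd_rad = 5e-4, seed = NULL) {
  stopifnot(sd_um >= 0, sd_rad >= 0)
  pose <- local_seed(seed, {
    offset_correction(stats::rnorm(1, 0, sd_um), stats::rnorm(1, 0, sd_um),
                      stats::rnorm(1, 0, sd_rad))
  })
  slide$pose <- pose
  slide
}

#' Ground-truth object centers under the current load pose
#'
#' @param slide An `sf_slide`.
#' @return An n x 2 matrix of stage coordinates, um.
#' @export
true_object_centers <- function(slide) {
  if (nrow(slide$objects) == 0) return(matrix(numeric(0), 0, 2))
  apply_offset(cbind(slide$objects$x_um, slide$objects$y_um), slide$pose,
               slide_center(slide))
}

#' Pixel-to-stage mapping for a field centered at a stage point
#'
#' @param center Field center, a [stage_point()].
#' @param objective An [objective()].
#' @param camera A [camera_model()].
#' @export
field_mapping <- function(center, objective, camera = camera_model()) {
  umpp <- camera$ref_um_per_px_at_1x / objective$magnification
  origin <- stage_point(center$x_um - (camera$sensor_w_px - 1) / 2 * umpp,
                        center$y_um - (camera$sensor_h_px - 1) / 2 * umpp)
  camera_mapping(umpp, umpp, origin = origin, objective = objective)
}

#' Render a camera field of the simulated slide
#'
#' Renders background glass, the frosted band (dark, high-variance texture),
#' the slide's physical edges, and textured elliptical objects under the
#' slide's current pose; applies defocus blur proportional to
#' `|z_um - focal plane|`; adds seeded Gaussian read noise and quantises to
#' the camera bit depth. Identical inputs give identical images.
#'
#' @param slide An `sf_slide`.
#' @param center Field center in stage coordinates (must fall on the slide).
#' @param objective An [objective()].
#' @param camera A [camera_model()].
#' @param z_um Focus-axis position; default is the true focal plane.
#' @param focus A [focus_model()].
#' @param seed Optional seed for the read noise.
#' @return An h x w intensity matrix in `[0, 1]`.
#' @export
render_field <- function(slide, center, objective, camera = camera_model(),
                         z_um = NULL, focus = focus_model(), seed = NULL) {
  stopifnot(inherits(slide, "sf_slide"), inherits(center, "sf_stage_point"))
  spec <- slide$spec
  piv <- slide_center(slide)
  cin <- apply_offset(center, slide$pose, piv, inverse = TRUE)
  if (cin$x_um < 0 || cin$x_um > spec$width_um ||
      cin$y_um < 0 || cin$y_um > spec$height_um)
    sf_stop("sf_out_of_bounds", "field center (%.0f, %.0f) falls off the slide",
            center$x_um, center$y_um)
  if (is.null(z_um)) z_um <- slide$focal_plane_z_um
  umpp <- camera$ref_um_per_px_at_1x / objective$magnification
  w <- camera$sensor_w_px; hgt <- camera$sensor_h_px
  xs <- center$x_um + (seq_len(w) - 1 - (w - 1) / 2) * umpp
  ys <- center$y_um + (seq_len(hgt) - 1 - (hgt - 1) / 2) * umpp

  # intrinsic (slide-frame) coordinates of pixel centers: the inverse pose is
  # affine, so each coordinate splits into a row term + a column term; grids
  # are built lazily (whole-field grids only when the field actually shows
  # the frosted band or a slide edge, subwindow grids per object)
  cr <- cos(slide$pose$rot_rad); sr <- sin(slide$pose$rot_rad)
  dxs <- xs - slide$pose$dx_um - piv$x_um
  dys <- ys - slide$pose$dy_um - piv$y_um
  colx <- piv$x_um + cr * dxs; rowx <- sr * dys
  coly <- -sr * dxs;           rowy <- piv$y_um + cr * dys
  qgrid <- function(rows, cols) {
    n <- length(rows)
    gx <- rep(colx[cols], each = n) + rowx[rows]; dim(gx) <- c(n, length(cols))
    gy <- rep(coly[cols], each = n) + rowy[rows]; dim(gy) <- c(n, length(cols))
    list(x = gx, y = gy)
  }
  # exact intrinsic bounding box of the field (affine image of a rectangle)
  corners <- qgrid(c(1L, hgt), c(1L, w))
  cqx <- range(corners$x); cqy <- range(corners$y)

  bg <- spec$background_level
  img <- matrix(bg, hgt, w)

  # frosted band: dark, high-variance texture left of the edge, with a
  # one-pixel anti-aliased transition so the edge localises sub-pixel
  edge <- slide$frosted_edge_x_um
  if (cqx[1] < edge + umpp) {
    q <- qgrid(seq_len(hgt), seq_len(w))
    sel <- which(q$x < edge + umpp)
    tex <- vnoise(q$x[sel], q$y[sel], 80, spec$seed + 11L)
    fr <- bg * (0.45 + 0.28 * (tex - 0.5))
    f <- clamp01((q$x[sel] - edge) / umpp + 0.5)
    img[sel] <- f * img[sel] + (1 - f) * fr
  }

  # objects intersecting this field, composed in C++ over their rotated
  # bounding boxes
  obj <- slide$objects
  if (nrow(obj) > 0) {
    pc <- apply_offset(cbind(obj$x_um, obj$y_um), slide$pose, piv)
    mw <- sqrt((obj$a_um * cos(obj$theta_rad))^2 +
               (obj$b_um * sin(obj$theta_rad))^2) + 3 * umpp
    mh <- sqrt((obj$a_um * sin(obj$theta_rad))^2 +
               (obj$b_um * cos(obj$theta_rad))^2) + 3 * umpp
    near <- which(pc[, 1] > xs[1] - mw & pc[, 1] < xs[w] + mw &
                  pc[, 2] > ys[1] - mh & pc[, 2] < ys[hgt] + mh)
    if (length(near)) {
      windows <- t(vapply(near, function(i) {
        c(max(1L, ceiling((pc[i, 2] - mh[i] - ys[1]) / umpp) + 1L),
          min(hgt, floor((pc[i, 2] + mh[i] - ys[1]) / umpp) + 1L),
          max(1L, ceiling((pc[i, 1] - mw[i] - xs[1]) / umpp) + 1L),
          min(w, floor((pc[i, 1] + mw[i] - xs[1]) / umpp) + 1L),
          obj$x_um[i], obj$y_um[i], obj$a_um[i], obj$b_um[i],
          obj$theta_rad[i], obj$texture_seed[i])
      }, numeric(10)))
      ok <- windows[, 1] <= windows[, 2] & windows[, 3] <= windows[, 4]
      if (any(ok))
        .render_objects_cpp(img, colx, rowx, coly, rowy,
                            windows[ok, , drop = FALSE], bg,
                            spec$object_contrast,
                            spec$texture_granularity_um, umpp)
    }
  }

  # physical slide boundary: off-slide pixels show the dark stage background
  stage_bg <- 0.02
  if (cqx[1] < 2 * umpp || cqx[2] > spec$width_um - 2 * umpp ||
      cqy[1] < 2 * umpp || cqy[2] > spec$height_um - 2 * umpp) {
    q <- qgrid(seq_len(hgt), seq_len(w))
    cov <- clamp01(q$x / umpp + 0.5) *
      clamp01((spec$width_um - q$x) / umpp + 0.5) *
      clamp01(q$y / umpp + 0.5) *
      clamp01((spec$height_um - q$y) / umpp + 0.5)
    img <- stage_bg + cov * (img - stage_bg)
  }

  # defocus blur: sigma grows linearly with distance from the (possibly
  # tilted) focal plane evaluated at the field center
  focal_z <- slide$focal_plane_z_um +
    focus$z_tilt[1] * (cin$x_um - piv$x_um) + focus$z_tilt[2] * (cin$y_um - piv$y_um)
  sigma <- focus$blur_sigma_px_per_um * abs(z_um - focal_z)
  if (sigma > 0.02) img <- .gauss_blur_cpp(img, sigma)

  local_seed(seed,
    .finish_frame_cpp(img, camera$read_noise_sd, 2^camera$bit_depth - 1))
}

#' Sample a cheap live-view survey frame
#'
#' Renders a field and block-mean downsamples it, modelling the low-fidelity
#' video-feed frames used by the live-view survey mode. With
#' `downsample = 1` the result is identical to [render_field()] under the
#' same seed.
#'
#' @inheritParams render_field
#' @param downsample Integer block size (>= 1).
#' @export
survey_frame <- function(slide, center, objective, camera = camera_model(),
                         downsample = 4L, z_um = NULL, focus = focus_model(),
                         seed = NULL) {
  stopifnot(downsample >= 1)
  img <- render_field(slide, center, objective, camera, z_um, focus, seed)
  block_mean(img, as.integer(downsample))
}

# block-mean downsample an h x w matrix by integer factor k (trailing
# rows/cols that do not fill a block are dropped)
block_mean <- function(m, k) {
  if (k == 1L) return(m)
  h2 <- nrow(m) %/% k; w2 <- ncol(m) %/% k
  m <- m[seq_len(h2 * k), seq_len(w2 * k), drop = FALSE]
  a <- matrix(colMeans(matrix(m, nrow = k)), nrow = h2)        # rows pooled
  t(matrix(colMeans(matrix(t(a), nrow = k)), nrow = w2))       # cols pooled
}

#' Export slide ground truth as JSON
#' @param slide An `sf_slide`.
#' @param path Output path.
#' @export
write_slide <- function(slide, path) {
  out <- list(spec = unclass(slide$spec), objects = slide$objects,
              frosted_edge_x_um = slide$frosted_edge_x_um,
              focal_plane_z_um = slide$focal_plane_z_um,
              pose = unclass(slide$pose))
  out$spec$coverslip <- unclass(out$spec$coverslip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a slide written by [write_slide()]
#' @param path Input path.
#' @export
read_slide <- function(path) {
  x <- jsonlite::fromJSON(path)
  cs <- x$spec$coverslip
  spec <- slide_spec(width_um = x$spec$width_um, height_um = x$spec$height_um,
                     frosted_band_w_um = x$spec$frosted_band_w_um,
                     coverslip = region(cs$x_um, cs$y_um, cs$w_um, cs$h_um),
                     n_objects = 0,
                     object_len_um_range = x$spec$object_len_um_range,
                     object_aspect_range = x$spec$object_aspect_range,
                     texture_granularity_um = x$spec$texture_granularity_um,
                     background_level = x$spec$background_level,
                     object_contrast = x$spec$object_contrast,
                     min_gap_um = x$spec$min_gap_um, seed = x$spec$seed)
  spec$n_objects <- as.integer(nrow(x$objects))
  obj <- as.data.frame(x$objects)
  if (nrow(obj) == 0)
    obj <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      a_um = numeric(), b_um = numeric(), theta_rad = numeric(),
                      texture_seed = integer())
  structure(list(spec = spec, objects = obj,
                 frosted_edge_x_um = x$frosted_edge_x_um,
                 focal_plane_z_um = x$focal_plane_z_um,
                 pose = offset_correction(x$pose$dx_um, x$pose$dy_um, x$pose$rot_rad)),
            class = "sf_slide")
}
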