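# Coordinate frames and tiling.
#
# Conventions used throughout the package: the stage frame has +x to the
# right and +y down (matching image row/column order), units are micrometres;
# pixel coordinates are 0-based (x, y) with pixel (0, 0) the top-left sensor
# corner.

#' Create a stage point
#'
#' A physical stage position in micrometres. `z_um = NA` means "use the
#' current focus".
#'
#' @param x_um,y_um Stage coordinates in micrometres (+x right, +y down).
#' @param z_um Focus-axis position in micrometres, or `NA`.
#' @return An object of class `sf_stage_point`.
#' @export
stage_point <- function(x_um, y_um, z_um = NA_real_) {
  if (!is.finite(x_um) || !is.finite(y_um))
    sf_stop("sf_coordinate_error", "stage coordinates must be finite")
  structure(list(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 z_um = as.numeric(z_um)),
            class = "sf_stage_point")
}

#' @export
format.sf_stage_point <- function(x, ...) {
  sprintf("<stage %.3f, %.3f%s um>", x$x_um, x$y_um,
          if (is.finite(x$z_um)) sprintf(", z=%.3f", x$z_um) else "")
}

#' @export
print.sf_stage_point <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Describe a microscope objective
#'
#' @param name Objective label, e.g. `"5x"`.
#' @param magnification Positive magnification factor.
#' @param fov_w_um,fov_h_um Field-of-view extents at this magnification, um.
#' @return An object of class `sf_objective`.
#' @export
objective <- function(name, magnification, fov_w_um, fov_h_um) {
  stopifnot(magnification > 0, fov_w_um > 0, fov_h_um > 0)
  structure(list(name = name, magnification = as.numeric(magnification),
                 fov_w_um = as.numeric(fov_w_um), fov_h_um = as.numeric(fov_h_um)),
            class = "sf_objective")
}

#' Derive an objective from a camera model
#'
#' The field of view follows the camera model: the pixel pitch at
#' magnification M is `ref_um_per_px_at_1x / M`, so the field scales as
#' 1/magnification.
#'
#' @param camera A [camera_model()].
#' @param magnification Positive magnification factor.
#' @param name Optional label; defaults to `"<M>x"`.
#' @export
objective_from_camera <- function(camera, magnification, name = NULL) {
  umpp <- camera$ref_um_per_px_at_1x / magnification
  objective(name %||% sprintf("%gx", magnification), magnification,
            camera$sensor_w_px * umpp, camera$sensor_h_px * umpp)
}

#' Pixel-to-stage affine mapping
#'
#' Ties sensor pixels to stage space for one objective: a pixel vector is
#' rotated by `rotation_rad`, scaled to micrometres, then translated by the
#' stage location of pixel (0, 0).
#'
#' @param um_per_px_x,um_per_px_y Positive pixel pitches in um/px.
#' @param origin Stage location of pixel (0, 0), a [stage_point()].
#' @param rotation_rad Sensor rotation relative to the stage axes, radians.
#' @param objective Optional [objective()] attached for bookkeeping.
#' @return An object of class `sf_camera_mapping`.
#' @export
camera_mapping <- function(um_per_px_x, um_per_px_y, origin = stage_point(0, 0),
                           rotation_rad = 0, objective = NULL) {
  if (!(um_per_px_x > 0) || !(um_per_px_y > 0))
    sf_stop("sf_coordinate_error", "pixel scales must be positive (mapping must be invertible)")
  structure(list(um_per_px_x = as.numeric(um_per_px_x),
                 um_per_px_y = as.numeric(um_per_px_y),
                 origin = origin, rotation_rad = as.numeric(rotation_rad),
                 objective = objective),
            class = "sf_camera_mapping")
}

#' A rectangular stage-frame region
#'
#' @param x_um,y_um Top-left corner in the stage frame, um.
#' @param w_um,h_um Positive extents, um.
#' @export
region <- function(x_um, y_um, w_um, h_um) {
  stopifnot(is.finite(x_um), is.finite(y_um), w_um > 0, h_um > 0)
  structure(list(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 w_um = as.numeric(w_um), h_um = as.numeric(h_um)),
            class = "sf_region")
}

#' A rigid offset correction
#'
#' Rotation about a pivot followed by a translation; the identity is
#' `(0, 0, 0)` and corrections compose.
#'
#' @param dx_um,dy_um Translation, um.
#' @param rot_rad Rotation, radians.
#' @export
offset_correction <- function(dx_um = 0, dy_um = 0, rot_rad = 0) {
  structure(list(dx_um = as.numeric(dx_um), dy_um = as.numeric(dy_um),
                 rot_rad = as.numeric(rot_rad)),
            class = "sf_offset_correction")
}

# normalize a point argument to an n x 2 matrix
as_xy <- function(p) {
  if (inherits(p, "sf_stage_point")) return(matrix(c(p$x_um, p$y_um), 1))
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2)
    return(p)
  }
  stopifnot(length(p) == 2)
  matrix(as.numeric(p), 1)
}

check_finite_xy <- function(m) {
  if (!all(is.finite(m)))
    sf_stop("sf_coordinate_error", "non-finite coordinate input")
  m
}

#' Map pixel coordinates to stage coordinates
#'
#' Applies the mapping's rotation, then the um/px scales, then the origin
#' translation. Exact inverse of [stage_to_pixel()].
#'
#' @param p A length-2 `(x, y)` pixel coordinate or an n x 2 matrix.
#' @param mapping A [camera_mapping()].
#' @return A [stage_point()] for a single input, otherwise an n x 2 matrix of
#'   stage coordinates in um.
#' @export
pixel_to_stage <- function(p, mapping) {
  single <- !is.matrix(p)
  m <- check_finite_xy(as_xy(p))
  cr <- cos(mapping$rotation_rad); sr <- sin(mapping$rotation_rad)
  rx <- cr * m[, 1] - sr * m[, 2]
  ry <- sr * m[, 1] + cr * m[, 2]
  out <- cbind(rx * mapping$um_per_px_x + mapping$origin$x_um,
               ry * mapping$um_per_px_y + mapping$origin$y_um)
  if (single) stage_point(out[1, 1], out[1, 2]) else unname(out)
}

#' Map stage coordinates to pixel coordinates
#'
#' @param s A [stage_point()], length-2 `(x, y)` vector, or n x 2 matrix.
#' @inheritParams pixel_to_stage
#' @return A length-2 pixel coordinate for a single input, else n x 2 matrix.
#' @export
stage_to_pixel <- function(s, mapping) {
  single <- !is.matrix(s)
  m <- check_finite_xy(as_xy(s))
  sx <- (m[, 1] - mapping$origin$x_um) / mapping$um_per_px_x
  sy <- (m[, 2] - mapping$origin$y_um) / mapping$um_per_px_y
  cr <- cos(mapping$rotation_rad); sr <- sin(mapping$rotation_rad)
  out <- cbind(cr * sx + sr * sy, -sr * sx + cr * sy)
  if (single) c(out[1, 1], out[1, 2]) else unname(out)
}

#' Apply a rigid offset correction to stage coordinates
#'
#' Rotates `s` about `pivot` by `rot_rad`, then translates by
#' `(dx_um, dy_um)`. The identity correction returns `s` unchanged. With
#' `inverse = TRUE` the exact inverse transform is applied.
#'
#' @param s A [stage_point()], length-2 vector, or n x 2 matrix.
#' @param correction An [offset_correction()].
#' @param pivot Rotation pivot, a [stage_point()].
#' @param inverse Apply the inverse transform instead.
#' @export
apply_offset <- function(s, correction, pivot = stage_point(0, 0), inverse = FALSE) {
  single <- !is.matrix(s)
  m <- check_finite_xy(as_xy(s))
  cr <- cos(correction$rot_rad); sr <- sin(correction$rot_rad)
  if (!inverse) {
    px <- m[, 1] - pivot$x_um; py <- m[, 2] - pivot$y_um
    out <- cbind(pivot$x_um + cr * px - sr * py + correction$dx_um,
                 pivot$y_um + sr * px + cr * py + correction$dy_um)
  } else {
    px <- m[, 1] - correction$dx_um - pivot$x_um
    py <- m[, 2] - correction$dy_um - pivot$y_um
    out <- cbind(pivot$x_um + cr * px + sr * py,
                 pivot$y_um - sr * px + cr * py)
  }
  if (single) stage_point(out[1, 1], out[1, 2]) else unname(out)
}

#' Plan an overlapping tiling of a region
#'
#' Computes snake-ordered (boustrophedon) field centers whose union covers
#' `reg` entirely, with adjacent fields along each axis overlapping by at
#' least `overlap_frac` of the field size. The per-axis tile count is
#' `max(1, ceil((extent - fov) / (fov * (1 - overlap_frac))) + 1)`; a field
#' larger than the region in an axis yields a single, centered tile.
#'
#' @param reg A [region()] to cover.
#' @param objective An [objective()] supplying the field of view.
#' @param overlap_frac Fractional overlap in `[0, 0.9]`.
#' @return An object of class `sf_tile_plan` with element `centers`, a data
#'   frame (`index`, `row`, `col`, `x_um`, `y_um`) in acquisition order.
#' @export
plan_tiles <- function(reg, objective, overlap_frac = 0.1) {
  stopifnot(inherits(reg, "sf_region"), inherits(objective, "sf_objective"))
  if (!(overlap_frac >= 0 && overlap_frac <= 0.9))
    sf_stop("sf_plan_error", "overlap_frac must lie in [0, 0.9]")
  fw <- objective$fov_w_um; fh <- objective$fov_h_um
  axis_centers <- function(start, extent, fov) {
    if (extent <= fov) return(start + extent / 2)
    n <- max(1L, as.integer(ceiling((extent - fov) / (fov * (1 - overlap_frac)))) + 1L)
    # fixed step at the requested overlap; the last tile is clamped to the
    # region end, so only the final pair overlaps by more
    step <- fov * (1 - overlap_frac)
    ctrs <- start + fov / 2 + step * (seq_len(n) - 1)
    ctrs[n] <- start + extent - fov / 2
    ctrs
  }
  xs <- axis_centers(reg$x_um, reg$w_um, fw)
  ys <- axis_centers(reg$y_um, reg$h_um, fh)
  nx <- length(xs); ny <- length(ys)
  rows <- rep(seq_len(ny), each = nx)
  cols <- unlist(lapply(seq_len(ny), function(r) {
    if (r %% 2 == 1L) seq_len(nx) else rev(seq_len(nx))
  }))
  centers <- data.frame(index = seq_len(nx * ny), row = rows, col = cols,
                        x_um = xs[cols], y_um = ys[rows])
  structure(list(centers = centers, nx = nx, ny = ny,
                 fov_w_um = fw, fov_h_um = fh,
                 overlap_frac = overlap_frac, region = reg,
                 objective = objective),
            class = "sf_tile_plan")
}

#' @export
print.sf_tile_plan <- function(x, ...) {
  cat(sprintf("<tile plan: %d x %d = %d tiles, fov %g x %g um, overlap %g>\n",
              x$nx, x$ny, nrow(x$centers), x$fov_w_um, x$fov_h_um, x$overlap_frac))
  invisible(x)
}

#' Export tile centers as a positions list
#'
#' Writes one JSON record per tile center with fields `label`, `x_um`,
#' `y_um`, `z_um`, in the spirit of a micro-manager position list.
#'
#' @param plan An `sf_tile_plan` or a data frame with `x_um`, `y_um`.
#' @param path Output file path.
#' @param z_um Focus position recorded with every center (may be `NA`).
#' @export
write_positions <- function(plan, path, z_um = NA_real_) {
  centers <- if (inherits(plan, "sf_tile_plan")) plan$centers else plan
  recs <- data.frame(label = sprintf("Pos%04d", seq_len(nrow(centers))),
                     x_um = centers$x_um, y_um = centers$y_um,
                     z_um = rep(as.numeric(z_um), length.out = nrow(centers)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a positions list written by [write_positions()]
#'
#' @param path Input file path.
#' @return A data frame with `label`, `x_um`, `y_um`, `z_um`.
#' @export
read_positions <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (is.null(df$z_um)) df$z_um <- NA_real_
  df$z_um <- as.numeric(df$z_um)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed condition helper shared across modules
sf_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "scopeflow_error")))
}
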