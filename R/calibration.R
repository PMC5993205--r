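# Re-localising a reloaded slide from the frosted-band edge.
#
# The boundary between the frosted labelling band and the clear glass is a
# location-invariant landmark: after a slide is reloaded (with an unknown
# seating offset), imaging the boundary and comparing its apparent stage
# position against the position recorded in an earlier pass yields the
# translation needed to map stored coordinates onto the new seating.

#' Per-column edge score profile of an image
#'
#' Each column is scored by the row-mean absolute horizontal gradient
#' (central differences) plus the intensity variance down the column; the
#' profile is smoothed with a fixed 5-column moving mean. A step or textured
#' boundary produces a sharp peak at the transition column.
#'
#' @param img An intensity matrix with at least 8 columns.
#' @return A numeric vector of length `ncol(img)`.
#' @export
edge_profile <- function(img) {
  smooth5(col_scores(img))
}

# per-column score before smoothing: row-mean |central horizontal gradient|
# plus per-column variance
col_scores <- function(img) {
  if (!is.matrix(img) || ncol(img) < 8)
    sf_stop("sf_calibration_error", "edge profile needs an image with >= 8 columns")
  w <- ncol(img)
  grad <- matrix(0, nrow(img), w)
  grad[, 2:(w - 1)] <- abs(img[, 3:w] - img[, 1:(w - 2)]) / 2
  grad[, 1] <- grad[, 2]; grad[, w] <- grad[, w - 1]
  colMeans(grad) + apply(img, 2, stats::var)
}

# 5-point moving mean with replicated ends
smooth5 <- function(score) {
  w <- length(score)
  padded <- c(rep(score[1], 2), score, rep(score[w], 2))
  as.numeric(stats::filter(padded, rep(1 / 5, 5), sides = 2))[3:(w + 2)]
}

#' Locate the edge in a score profile
#'
#' Takes the argmax of the profile (ties broken toward the lower column
#' index, with reduced confidence when distinct equal peaks exist) and
#' refines it with a 3-point parabolic fit. Confidence is
#' `(peak - median) / (max - min + eps)`, clamped to `[0, 1]`; a flat
#' profile returns confidence 0 with the edge flagged undefined.
#'
#' @param profile Numeric vector (length >= 8) from [edge_profile()].
#' @param flat_floor Profiles whose range falls below this floor are treated
#'   as featureless.
#' @return A list with `edge_col` (0-based, sub-column; `NA` if flat),
#'   `confidence`, and `flat`.
#' @export
find_edge <- function(profile, flat_floor = 1e-6) {
  stopifnot(length(profile) >= 8)
  rng <- max(profile) - min(profile)
  if (!is.finite(rng) || rng < flat_floor)
    return(list(edge_col = NA_real_, confidence = 0, flat = TRUE))
  i <- which.max(profile)
  conf <- (profile[i] - stats::median(profile)) / (rng + 1e-12)
  conf <- min(1, max(0, conf))
  # distinct (non-contiguous) equal peaks: keep the lower index, reduce
  # confidence; a contiguous plateau is a single peak
  ties <- which(profile >= profile[i] - 1e-12 * max(abs(profile[i]), 1))
  if (any(diff(ties) > 1)) conf <- conf / 2
  delta <- 0
  if (i > 1 && i < length(profile)) {
    den <- profile[i - 1] - 2 * profile[i] + profile[i + 1]
    if (den < 0) delta <- min(0.5, max(-0.5, 0.5 * (profile[i - 1] - profile[i + 1]) / den))
  }
  list(edge_col = (i - 1) + delta, confidence = conf, flat = FALSE)
}

#' Observe the frosted-band edge in one field
#'
#' Runs [edge_profile()] and [find_edge()] on an image and converts the
#' found column into a stage x coordinate through the field's pixel-to-stage
#' mapping. With `axis = "y"` the image is transposed and the found row is
#' converted into a stage y coordinate, which localises a horizontal
#' boundary (such as the slide's long edge) instead.
#'
#' @param img An intensity matrix.
#' @param mapping The field's [camera_mapping()].
#' @param axis `"x"` for a vertical edge, `"y"` for a horizontal one.
#' @param flat_floor Minimum profile range (intensity gradient per pixel)
#'   for an edge to count as present; profiles below it -- featureless glass
#'   under read noise -- are flagged flat with confidence 0.
#' @return A list of class `sf_edge_observation`: `found_edge_um`,
#'   `confidence`, `axis`, `nominal_center` (stage position of the image
#'   center), and `flat`.
#' @export
observe_edge <- function(img, mapping, axis = c("x", "y"), flat_floor = 0.01) {
  axis <- match.arg(axis)
  work <- if (axis == "x") img else t(img)
  raw <- col_scores(work)
  hit <- find_edge(smooth5(raw), flat_floor = flat_floor)
  ctr_px <- c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2)
  ctr <- pixel_to_stage(ctr_px, mapping)
  found <- NA_real_
  if (!hit$flat) {
    # the boxcar smoothing flattens the peak, which quantises the parabola
    # refinement; re-localise with a baseline-subtracted centroid of the raw
    # per-column scores in a small window around the smoothed peak
    i <- round(hit$edge_col) + 1L
    win <- max(1L, i - 2L):min(length(raw), i + 2L)
    wgt <- pmax(0, raw[win] - stats::median(raw))
    col <- if (sum(wgt) > 0) sum(wgt * (win - 1)) / sum(wgt) else hit$edge_col
    p <- if (axis == "x") c(col, ctr_px[2]) else c(ctr_px[1], col)
    s <- pixel_to_stage(p, mapping)
    found <- if (axis == "x") s$x_um else s$y_um
  }
  structure(list(found_edge_um = found, confidence = hit$confidence,
                 axis = axis, nominal_center = ctr, flat = hit$flat),
            class = "sf_edge_observation")
}

#' Estimate the reload offset from edge observations
#'
#' The along-axis displacement is the mean of `found - reference` over all
#' observations above the confidence floor. For a vertical edge
#' (`axis = "x"`) only the x component is observable, so `dy_um = 0`;
#' optionally, with at least two observations at distinct y positions, an
#' apparent edge tilt `rot_rad = atan(slope of found x vs y)` is also fitted.
#'
#' @param reference_edge_um Stage coordinate of the edge recorded in the
#'   reference pass, um.
#' @param observations A list of `sf_edge_observation` objects.
#' @param confidence_floor Observations below this confidence are discarded;
#'   if none survive, a calibration-failed error is raised.
#' @param estimate_rotation Fit the apparent edge tilt (default off).
#' @param axis Which axis the observations measure.
#' @return An [offset_correction()].
#' @export
estimate_offset <- function(reference_edge_um, observations,
                            confidence_floor = 0.2, estimate_rotation = FALSE,
                            axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (inherits(observations, "sf_edge_observation")) observations <- list(observations)
  keep <- Filter(function(o) !o$flat && o$confidence >= confidence_floor, observations)
  if (length(keep) == 0)
    sf_stop("sf_calibration_error",
            "calibration failed: no edge observation above confidence floor %.2f",
            confidence_floor)
  found <- vapply(keep, function(o) o$found_edge_um, numeric(1))
  d <- mean(found - reference_edge_um)
  rot <- 0
  if (estimate_rotation && length(keep) >= 2) {
    ortho <- vapply(keep, function(o)
      if (axis == "x") o$nominal_center$y_um else o$nominal_center$x_um, numeric(1))
    if (length(unique(ortho)) >= 2) {
      fit <- stats::lm.fit(cbind(1, ortho), found)
      rot <- atan(fit$coefficients[2])
    }
  }
  if (axis == "x") offset_correction(d, 0, rot) else offset_correction(0, d, rot)
}

#' Locate an edge near a nominal stage position, with lateral search
#'
#' Renders observation fields with the simulated microscope, starting at the
#' nominal edge position and stepping sideways (0, -1, +1, -2, +2 fields) if
#' no confident observation is found -- a reloaded slide can displace the
#' edge out of the first field. Used by the acquisition workflow for both
#' the frosted-band edge (axis `"x"`) and the slide's long top edge
#' (axis `"y"`).
#'
#' @param slide An `sf_slide`.
#' @param nominal Nominal stage position of the edge crossing, a
#'   [stage_point()].
#' @param objective,camera Imaging configuration for the observation fields.
#' @param axis Edge orientation to localise.
#' @param accept_confidence Stop searching once an observation reaches this
#'   confidence.
#' @param max_steps Maximum lateral steps to each side.
#' @param seed Seed for the observation renders.
#' @return The best `sf_edge_observation` found (may be flat if all
#'   candidates are featureless).
#' @export
locate_edge <- function(slide, nominal, objective, camera = camera_model(),
                        axis = c("x", "y"), accept_confidence = 0.5,
                        max_steps = 2L, seed = NULL) {
  axis <- match.arg(axis)
  umpp <- camera$ref_um_per_px_at_1x / objective$magnification
  span <- if (axis == "x") camera$sensor_w_px * umpp else camera$sensor_h_px * umpp
  best <- NULL
  steps <- c(0, as.vector(rbind(-seq_len(max_steps), seq_len(max_steps))))
  for (k in steps) {
    ctr <- if (axis == "x")
      stage_point(nominal$x_um + k * 0.5 * span, nominal$y_um)
    else
      stage_point(nominal$x_um, nominal$y_um + k * 0.5 * span)
    obs <- tryCatch({
      img <- render_field(slide, ctr, objective, camera, seed = seed)
      observe_edge(img, field_mapping(ctr, objective, camera), axis)
    }, sf_out_of_bounds = function(e) NULL)
    if (is.null(obs)) next
    if (is.null(best) || obs$confidence > best$confidence) best <- obs
    if (obs$confidence >= accept_confidence) break
  }
  if (is.null(best))
    sf_stop("sf_calibration_error", "no valid edge observation field near (%.0f, %.0f)",
            nominal$x_um, nominal$y_um)
  best
}
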