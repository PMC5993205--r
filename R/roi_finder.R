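# Object detection on low-magnification imagery.
#
# The detector is deliberately simple and generalisable: polarity
# normalisation, Otsu (or fixed) thresholding, morphological closing,
# 8-connected components and an area filter, with all size parameters
# denominated in micrometres so one configuration works at survey and at
# full 5x sampling. A user-supplied detector can replace the built-in
# pipeline; its output is validated against the same ROI invariants.

#' Detection parameters
#'
#' @param threshold `"otsu"` (default) or `"fixed"`.
#' @param fixed_value Threshold used when `threshold = "fixed"` (applied to
#'   the polarity-normalised image, objects bright).
#' @param closing_radius_um Morphological closing radius, um.
#' @param min_area_um2,max_area_um2 Component area bounds, um^2.
#' @param pad_frac Fractional padding added per side to each ROI box.
#' @param merge_overlap_frac Boxes whose intersection is at least this
#'   fraction of the smaller box area are merged; 0 means any overlap merges.
#' @param min_class_contrast Minimum intensity separation between the two
#'   Otsu classes (intensity units); below it the image is treated as
#'   object-free rather than thresholding into the noise tail.
#' @export
detection_params <- function(threshold = c("otsu", "fixed"), fixed_value = 0.5,
                             closing_radius_um = 20,
                             min_area_um2 = 20000, max_area_um2 = 600000,
                             pad_frac = 0.10, merge_overlap_frac = 0,
                             min_class_contrast = 0.05) {
  threshold <- match.arg(threshold)
  stopifnot(min_area_um2 < max_area_um2, pad_frac >= 0,
            closing_radius_um >= 0, merge_overlap_frac >= 0,
            min_class_contrast >= 0)
  structure(list(threshold = threshold, fixed_value = fixed_value,
                 closing_radius_um = closing_radius_um,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 pad_frac = pad_frac, merge_overlap_frac = merge_overlap_frac,
                 min_class_contrast = min_class_contrast),
            class = "sf_detection_params")
}

#' Label connected components of a binary mask
#'
#' Run-length, union-find labelling supporting 8-connectivity (diagonal
#' neighbours connect), which the detection pipeline requires.
#'
#' @param mask A logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return An integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (!any(mask)) return(lab)
  # horizontal runs per row: encode each row, find starts/ends
  runs <- vector("list", h)
  nrun <- 0L
  for (r in seq_len(h)) {
    v <- mask[r, ]
    d <- diff(c(FALSE, v, FALSE))
    st <- which(d == 1L); en <- which(d == -1L) - 1L
    if (length(st)) {
      runs[[r]] <- cbind(start = st, end = en, id = nrun + seq_along(st))
      nrun <- nrun + length(st)
    }
  }
  parent <- seq_len(nrun)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  slack <- if (connectivity == 8L) 1L else 0L
  for (r in seq_len(h)[-1]) {
    a <- runs[[r - 1]]; b <- runs[[r]]
    if (is.null(a) || is.null(b)) next
    for (i in seq_len(nrow(b))) {
      # runs in the previous row that touch this run (with diagonal slack)
      hit <- which(a[, "start"] <= b[i, "end"] + slack & a[, "end"] >= b[i, "start"] - slack)
      for (j in hit) union2(a[j, "id"], b[i, "id"])
    }
  }
  roots <- vapply(seq_len(nrun), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  for (r in seq_len(h)) {
    rr <- runs[[r]]
    if (is.null(rr)) next
    for (i in seq_len(nrow(rr)))
      lab[r, rr[i, "start"]:rr[i, "end"]] <- relab[rr[i, "id"]]
  }
  lab
}

#' Segment objects in a grayscale image
#'
#' Pipeline: polarity normalisation (objects darker than background are
#' inverted so objects are the bright minority phase), thresholding,
#' morphological closing (radius converted from um to pixels through the
#' mapping), 8-connected components, and an area filter in um^2.
#'
#' @param img An intensity matrix in `[0, 1]`.
#' @param params An [detection_params()].
#' @param mapping The image's [camera_mapping()] (converts um parameters to
#'   pixels and component areas to um^2).
#' @return A list with `labels` (integer component matrix, filtered and
#'   relabelled compactly), `n`, and `areas_um2`.
#' @export
segment_objects <- function(img, params = detection_params(), mapping) {
  stopifnot(is.matrix(img))
  # polarity: the background is the majority phase, so the median tracks it;
  # objects darker than the background flip the sign of (median - mean)
  if (stats::median(img) > mean(img)) img <- max(img) - img
  thr <- if (params$threshold == "otsu") EBImage::otsu(img, range = c(0, 1))
         else params$fixed_value
  mask <- img > thr
  nothing <- list(labels = matrix(0L, nrow(img), ncol(img)), n = 0L,
                  areas_um2 = numeric(0))
  # objects are assumed to be the minority phase; a threshold that labels
  # close to half the image (blank or noise-only input) detects nothing
  if (mean(mask) > 0.4 || !any(mask)) return(nothing)
  # bimodality guard for the automatic threshold: on an object-free image
  # Otsu splits the noise distribution, leaving the class means almost
  # equal; require a minimum separation before accepting any foreground
  if (params$threshold == "otsu" &&
      mean(img[mask]) - mean(img[!mask]) < params$min_class_contrast)
    return(nothing)
  px_area_um2 <- mapping$um_per_px_x * mapping$um_per_px_y
  r_px <- params$closing_radius_um / ((mapping$um_per_px_x + mapping$um_per_px_y) / 2)
  if (r_px >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(round(r_px)) + 1L, shape = "disc")
    mask <- EBImage::closing(mask, brush) > 0
  }
  lab <- label_components(mask, 8L)
  if (max(lab) == 0L)
    return(list(labels = lab, n = 0L, areas_um2 = numeric(0)))
  sizes <- tabulate(lab, nbins = max(lab))
  areas <- sizes * px_area_um2
  keep <- which(areas >= params$min_area_um2 & areas <= params$max_area_um2)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[] <- ifelse(lab > 0L, relab[pmax(lab, 1L)], 0L)
  list(labels = lab, n = length(keep), areas_um2 = areas[keep])
}

new_roi <- function(slide_id, bbox, n_component_px = 0L,
                    source = c("phase1_tiles", "survey"), label = "") {
  source <- match.arg(source)
  structure(list(slide_id = slide_id, bbox = bbox,
                 n_component_px = as.integer(n_component_px),
                 source = source, label = label),
            class = "sf_roi")
}

#' Convert labelled components into stage-coordinate ROIs
#'
#' Each component's pixel bounding box is mapped to a stage-frame
#' [region()], padded by `pad_frac` per side, clipped to the slide bounds,
#' and labelled `"R0001"...` in reading order (top-to-bottom then
#' left-to-right by box corner).
#'
#' @param components Output of [segment_objects()].
#' @param mapping The image's [camera_mapping()].
#' @param params An [detection_params()].
#' @param slide_id Slide identifier carried on every ROI.
#' @param source ROI provenance: `"phase1_tiles"` or `"survey"`.
#' @param slide_bounds Optional [region()] to clip padded boxes against.
#' @return A list of `sf_roi` objects.
#' @export
components_to_rois <- function(components, mapping, params = detection_params(),
                               slide_id = "slide", source = "phase1_tiles",
                               slide_bounds = NULL) {
  lab <- components$labels
  n <- components$n
  if (n == 0L) return(list())
  rois <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    # bbox corners at the extreme pixel centers
    px0 <- min(idx[, 2]) - 1L; px1 <- max(idx[, 2]) - 1L
    py0 <- min(idx[, 1]) - 1L; py1 <- max(idx[, 1]) - 1L
    c0 <- pixel_to_stage(c(px0, py0), mapping)
    c1 <- pixel_to_stage(c(px1, py1), mapping)
    x0 <- min(c0$x_um, c1$x_um); x1 <- max(c0$x_um, c1$x_um)
    y0 <- min(c0$y_um, c1$y_um); y1 <- max(c0$y_um, c1$y_um)
    w <- x1 - x0; h <- y1 - y0
    x0 <- x0 - params$pad_frac * w; x1 <- x1 + params$pad_frac * w
    y0 <- y0 - params$pad_frac * h; y1 <- y1 + params$pad_frac * h
    if (!is.null(slide_bounds)) {
      x0 <- max(x0, slide_bounds$x_um); y0 <- max(y0, slide_bounds$y_um)
      x1 <- min(x1, slide_bounds$x_um + slide_bounds$w_um)
      y1 <- min(y1, slide_bounds$y_um + slide_bounds$h_um)
    }
    rois[[k]] <- new_roi(slide_id, region(x0, y0, x1 - x0, y1 - y0),
                         n_component_px = nrow(idx), source = source)
  }
  relabel_rois(rois)
}

# reading order: top-to-bottom then left-to-right by bbox corner
relabel_rois <- function(rois) {
  if (length(rois) == 0) return(rois)
  ys <- vapply(rois, function(r) r$bbox$y_um, numeric(1))
  xs <- vapply(rois, function(r) r$bbox$x_um, numeric(1))
  ord <- order(ys, xs)
  rois <- rois[ord]
  for (i in seq_along(rois)) rois[[i]]$label <- sprintf("R%04d", i)
  rois
}

#' Merge overlapping ROIs
#'
#' Iteratively unions boxes whose intersection is at least
#' `merge_overlap_frac` times the smaller box's area (any positive overlap
#' when the fraction is 0) until a fixed point, then relabels the result in
#' reading order. Merging is transitive: chains of pairwise-overlapping
#' boxes collapse into one.
#'
#' @param rois A list of `sf_roi` for one slide.
#' @param merge_overlap_frac Merge threshold as a fraction of the smaller
#'   box's area.
#' @return A list of merged `sf_roi`.
#' @export
merge_rois <- function(rois, merge_overlap_frac = 0) {
  if (length(rois) <= 1) return(relabel_rois(rois))
  sid <- unique(vapply(rois, function(r) r$slide_id, character(1)))
  if (length(sid) > 1)
    sf_stop("sf_roi_error", "merge_rois requires ROIs from a single slide")
  box <- t(vapply(rois, function(r)
    c(r$bbox$x_um, r$bbox$y_um, r$bbox$x_um + r$bbox$w_um, r$bbox$y_um + r$bbox$h_um,
      r$n_component_px), numeric(5)))
  src <- vapply(rois, function(r) r$source, character(1))
  repeat {
    n <- nrow(box)
    if (n <= 1) break
    merged <- FALSE
    i <- 1L
    while (i < nrow(box)) {
      j <- i + 1L
      while (j <= nrow(box)) {
        iw <- min(box[i, 3], box[j, 3]) - max(box[i, 1], box[j, 1])
        ih <- min(box[i, 4], box[j, 4]) - max(box[i, 2], box[j, 2])
        inter <- max(0, iw) * max(0, ih)
        smaller <- min((box[i, 3] - box[i, 1]) * (box[i, 4] - box[i, 2]),
                       (box[j, 3] - box[j, 1]) * (box[j, 4] - box[j, 2]))
        if (inter > 0 && inter >= merge_overlap_frac * smaller) {
          box[i, ] <- c(min(box[i, 1], box[j, 1]), min(box[i, 2], box[j, 2]),
                        max(box[i, 3], box[j, 3]), max(box[i, 4], box[j, 4]),
                        box[i, 5] + box[j, 5])
          box <- box[-j, , drop = FALSE]
          src <- src[-j]
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  out <- lapply(seq_len(nrow(box)), function(k)
    new_roi(sid, region(box[k, 1], box[k, 2], box[k, 3] - box[k, 1], box[k, 4] - box[k, 2]),
            n_component_px = box[k, 5], source = src[k]))
  relabel_rois(out)
}

#' Run a user-supplied detector under the ROI contract
#'
#' The hook receives `(img, mapping)` and must return a list of `sf_roi`
#' (or lists with a `bbox` [region()]). The output is validated -- finite,
#' positive-size boxes inside the slide bounds -- and normalised into
#' reading order; a violation raises a plugin-contract error naming the
#' offending field.
#'
#' @param img An intensity matrix.
#' @param mapping The image's [camera_mapping()].
#' @param hook A function `(img, mapping) -> list of ROI`.
#' @param slide_id Slide identifier stamped on the returned ROIs.
#' @param slide_bounds Optional [region()] the boxes must lie within.
#' @return A validated, relabelled list of `sf_roi`.
#' @export
run_plugin_detector <- function(img, mapping, hook, slide_id = "slide",
                                slide_bounds = NULL) {
  stopifnot(is.function(hook))
  out <- hook(img, mapping)
  if (!is.list(out))
    sf_stop("sf_plugin_error", "plugin detector must return a list of ROIs")
  rois <- lapply(out, function(r) {
    bb <- if (inherits(r, "sf_roi")) r$bbox else r$bbox
    if (is.null(bb) || !all(is.finite(c(bb$x_um, bb$y_um, bb$w_um, bb$h_um))))
      sf_stop("sf_plugin_error", "plugin ROI violates contract: field 'bbox' missing or non-finite")
    if (bb$w_um <= 0 || bb$h_um <= 0)
      sf_stop("sf_plugin_error", "plugin ROI violates contract: field 'bbox' has non-positive size")
    if (!is.null(slide_bounds) &&
        (bb$x_um < slide_bounds$x_um || bb$y_um < slide_bounds$y_um ||
         bb$x_um + bb$w_um > slide_bounds$x_um + slide_bounds$w_um ||
         bb$y_um + bb$h_um > slide_bounds$y_um + slide_bounds$h_um))
      sf_stop("sf_plugin_error", "plugin ROI violates contract: field 'bbox' outside slide bounds")
    n_px <- if (!is.null(r$n_component_px)) r$n_component_px else 0L
    new_roi(slide_id, bb, n_component_px = n_px,
            source = if (!is.null(r$source) && r$source %in% c("phase1_tiles", "survey"))
              r$source else "phase1_tiles")
  })
  relabel_rois(rois)
}

#' ROI list to data frame
#' @param rois A list of `sf_roi`.
#' @export
rois_to_df <- function(rois) {
  if (length(rois) == 0)
    return(data.frame(label = character(), slide_id = character(),
                      x_um = numeric(), y_um = numeric(),
                      w_um = numeric(), h_um = numeric(),
                      n_component_px = integer(), source = character()))
  do.call(rbind, lapply(rois, function(r)
    data.frame(label = r$label, slide_id = r$slide_id,
               x_um = r$bbox$x_um, y_um = r$bbox$y_um,
               w_um = r$bbox$w_um, h_um = r$bbox$h_um,
               n_component_px = r$n_component_px, source = r$source)))
}

#' Data frame to ROI list
#' @param df A data frame as produced by [rois_to_df()].
#' @export
df_to_rois <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    new_roi(df$slide_id[i], region(df$x_um[i], df$y_um[i], df$w_um[i], df$h_um[i]),
            n_component_px = df$n_component_px[i], source = df$source[i],
            label = df$label[i]))
}
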