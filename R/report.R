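# Dataset layout, run reports and configuration files.
#
# Images are stored in a micro-manager-inspired layout: one directory per
# slide per pass holding one TIFF per tile and a sidecar metadata JSON
# listing every entry with its stage position. The schema is this package's
# own (documented here), not byte-compatible with any specific metadata
# version.

dataset_dir <- function(root, slide_id, pass) {
  file.path(root, "data", slide_id, pass)
}

meta_path <- function(root, slide_id, pass) {
  file.path(dataset_dir(root, slide_id, pass), "metadata.json")
}

empty_entries <- function() {
  data.frame(file = character(), tile_index = integer(),
             roi_label = character(), x_um = numeric(), y_um = numeric(),
             z_um = numeric(), seed = integer(), timestamp = character())
}

# Tile entries live in an append-only journal (entries.jsonl, one JSON
# object per line) next to the pass header (metadata.json): appending one
# entry is O(1), a half-written trailing line after a crash is skipped on
# read, and an in-process cache avoids re-parsing the journal on every tile.
entries_path <- function(root, slide_id, pass) {
  file.path(dataset_dir(root, slide_id, pass), "entries.jsonl")
}

.sf_entries_cache <- new.env(parent = emptyenv())

# cache: rows (list of 1-row data frames), idx (tile_index vector), df
# (memoised rbind), size (journal bytes for cross-process invalidation)
load_entries_cache <- function(root, slide_id, pass) {
  ep <- entries_path(root, slide_id, pass)
  if (!file.exists(ep)) return(NULL)
  sz <- file.size(ep)
  hit <- .sf_entries_cache[[ep]]
  if (!is.null(hit) && identical(hit$size, sz)) return(hit)
  lines <- readLines(ep, warn = FALSE)
  rows <- lapply(lines, function(l) {
    r <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(r)) return(NULL)   # half-written trailing line after a crash
    data.frame(file = r$file, tile_index = as.integer(r$tile_index),
               roi_label = if (is.null(r$roi_label)) NA_character_ else r$roi_label,
               x_um = as.numeric(r$x_um), y_um = as.numeric(r$y_um),
               z_um = if (is.null(r$z_um)) NA_real_ else as.numeric(r$z_um),
               seed = if (is.null(r$seed)) NA_integer_ else as.integer(r$seed),
               timestamp = r$timestamp)
  })
  rows <- Filter(Negate(is.null), rows)
  hit <- list(size = sz, rows = rows,
              idx = vapply(rows, function(r) r$tile_index, integer(1)),
              df = NULL)
  .sf_entries_cache[[ep]] <- hit
  hit
}

read_entries <- function(root, slide_id, pass) {
  ep <- entries_path(root, slide_id, pass)
  hit <- load_entries_cache(root, slide_id, pass)
  if (is.null(hit) || !length(hit$rows)) return(empty_entries())
  if (is.null(hit$df)) {
    hit$df <- do.call(rbind, hit$rows)
    .sf_entries_cache[[ep]] <- hit
  }
  hit$df
}

has_tile <- function(root, slide_id, pass, tile_index) {
  hit <- load_entries_cache(root, slide_id, pass)
  !is.null(hit) && tile_index %in% hit$idx
}

append_entry <- function(root, slide_id, pass, row) {
  ep <- entries_path(root, slide_id, pass)
  hit <- load_entries_cache(root, slide_id, pass)
  if (is.null(hit)) hit <- list(size = 0, rows = list(), idx = integer(), df = NULL)
  cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = NA, na = "null"),
      "\n", sep = "", file = ep, append = TRUE)
  hit$size <- file.size(ep)
  hit$rows[[length(hit$rows) + 1L]] <- row
  hit$idx <- c(hit$idx, row$tile_index)
  hit$df <- NULL
  .sf_entries_cache[[ep]] <- hit
  invisible(NULL)
}

read_meta <- function(root, slide_id, pass) {
  mp <- meta_path(root, slide_id, pass)
  if (!file.exists(mp)) return(NULL)
  m <- tryCatch(jsonlite::fromJSON(mp),
                error = function(e)
                  sf_stop("sf_dataset_error", "corrupt metadata at %s: %s", mp,
                          conditionMessage(e)))
  m$entries <- read_entries(root, slide_id, pass)
  m
}

write_meta <- function(root, slide_id, pass, meta) {
  mp <- meta_path(root, slide_id, pass)
  tmp <- paste0(mp, ".tmp")
  meta$entries <- NULL
  jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  file.rename(tmp, mp)
  invisible(mp)
}

meta_objective <- function(meta) {
  o <- meta$objective
  if (is.null(o) || !length(o$magnification)) return(NULL)
  objective(o$name, o$magnification, o$fov_w_um, o$fov_h_um)
}

meta_camera <- function(meta) {
  cm <- meta$camera
  if (is.null(cm) || !length(cm$sensor_w_px)) return(NULL)
  camera_model(cm$sensor_w_px, cm$sensor_h_px, cm$ref_um_per_px_at_1x,
               cm$read_noise_sd, cm$bit_depth)
}

#' Begin (or resume) a dataset pass
#'
#' Creates the pass directory and metadata sidecar. An already existing
#' pass is refused unless `resume = TRUE`.
#'
#' @param root Storage root.
#' @param slide_id,pass Dataset coordinates.
#' @param objective,camera Acquisition configuration recorded in the
#'   metadata.
#' @param resume Allow appending to an existing pass.
#' @export
open_pass <- function(root, slide_id, pass, objective = NULL, camera = NULL,
                      resume = FALSE) {
  existing <- read_meta(root, slide_id, pass)
  if (!is.null(existing) && !resume)
    sf_stop("sf_dataset_error",
            "pass '%s' already exists for slide '%s' (use resume mode)",
            pass, slide_id)
  if (!is.null(existing)) return(invisible(existing))
  dir.create(dataset_dir(root, slide_id, pass), recursive = TRUE,
             showWarnings = FALSE)
  file.create(entries_path(root, slide_id, pass))
  meta <- list(slide_id = slide_id, pass = pass,
               objective = if (!is.null(objective)) unclass(objective),
               camera = if (!is.null(camera)) unclass(camera),
               entries = empty_entries())
  write_meta(root, slide_id, pass, meta)
  invisible(meta)
}

#' Write one tile into a dataset pass
#'
#' Stores the image as an 8-bit (or 16-bit) TIFF and appends its entry to
#' the pass metadata. Re-writing an existing `tile_index` is refused, which
#' gives resumable acquisition its at-most-once guarantee.
#'
#' @param root,slide_id,pass Dataset coordinates; the pass must be open.
#' @param tile_index Integer tile number within the pass.
#' @param image Intensity matrix in `[0, 1]`.
#' @param center Stage position the tile was acquired at.
#' @param z_um Focus position (may be `NA`).
#' @param seed Render seed recorded for reproducibility.
#' @param roi_label Optional ROI label the tile belongs to.
#' @param bits 8 or 16.
#' @export
write_tile <- function(root, slide_id, pass, tile_index, image, center,
                       z_um = NA_real_, seed = NA_integer_, roi_label = NA_character_,
                       bits = 8L) {
  if (!file.exists(meta_path(root, slide_id, pass)))
    sf_stop("sf_dataset_error", "pass '%s'/'%s' is not open", slide_id, pass)
  if (has_tile(root, slide_id, pass, tile_index))
    sf_stop("sf_dataset_error", "tile %d already written in %s/%s",
            tile_index, slide_id, pass)
  fn <- sprintf("tile_%05d.tif", tile_index)
  tiff::writeTIFF(image, file.path(dataset_dir(root, slide_id, pass), fn),
                  bits.per.sample = as.integer(bits), compression = "none")
  append_entry(root, slide_id, pass,
               data.frame(file = fn, tile_index = as.integer(tile_index),
                          roi_label = roi_label,
                          x_um = center$x_um, y_um = center$y_um,
                          z_um = as.numeric(z_um), seed = as.integer(seed),
                          timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")))
  invisible(fn)
}

#' Write a complete dataset pass
#'
#' @param images List of intensity matrices.
#' @param centers List of [stage_point()] (one per image).
#' @inheritParams open_pass
#' @param seeds Optional integer vector of render seeds.
#' @export
write_dataset <- function(images, centers, root, slide_id, pass,
                          objective = NULL, camera = NULL, seeds = NULL,
                          resume = FALSE) {
  stopifnot(length(images) == length(centers))
  open_pass(root, slide_id, pass, objective, camera, resume = resume)
  done <- read_meta(root, slide_id, pass)$entries$tile_index
  for (k in seq_along(images)) {
    if (k %in% done) next
    write_tile(root, slide_id, pass, k, images[[k]], centers[[k]],
               seed = if (is.null(seeds)) NA_integer_ else seeds[k])
  }
  invisible(meta_path(root, slide_id, pass))
}

#' Read a dataset pass
#'
#' Reconstructs the tile sequence (with pixel-to-stage mappings) so the
#' stitcher can re-run without re-acquisition.
#'
#' @param root,slide_id,pass Dataset coordinates.
#' @return A list with `tiles` (list of [tile_image()]) and `meta`.
#' @export
read_dataset <- function(root, slide_id, pass) {
  meta <- read_meta(root, slide_id, pass)
  if (is.null(meta))
    sf_stop("sf_dataset_error", "no pass '%s' for slide '%s' under %s",
            pass, slide_id, root)
  ent <- meta$entries
  objv <- meta_objective(meta)
  cam <- meta_camera(meta)
  tiles <- lapply(seq_len(nrow(ent)), function(k) {
    fp <- file.path(dataset_dir(root, slide_id, pass), ent$file[k])
    if (!file.exists(fp))
      sf_stop("sf_dataset_error", "missing tile file %s listed in metadata", fp)
    img <- tiff::readTIFF(fp)
    if (length(dim(img)) == 3) img <- img[, , 1]
    ctr <- stage_point(ent$x_um[k], ent$y_um[k])
    mp <- if (!is.null(objv) && !is.null(cam)) field_mapping(ctr, objv, cam)
          else camera_mapping(1, 1, origin = ctr)
    tile_image(img, ctr, mp, ent$tile_index[k])
  })
  list(tiles = tiles, meta = meta)
}

#' Read a single tile of a dataset pass
#'
#' Lazy counterpart of [read_dataset()] for passes too large to hold in
#' memory at once.
#'
#' @param root,slide_id,pass Dataset coordinates.
#' @param tile_index Tile to read.
#' @export
read_tile <- function(root, slide_id, pass, tile_index) {
  meta <- read_meta(root, slide_id, pass)
  if (is.null(meta))
    sf_stop("sf_dataset_error", "no pass '%s' for slide '%s'", pass, slide_id)
  k <- match(tile_index, meta$entries$tile_index)
  if (is.na(k))
    sf_stop("sf_dataset_error", "no tile %s in %s/%s", tile_index, slide_id, pass)
  ent <- meta$entries[k, ]
  fp <- file.path(dataset_dir(root, slide_id, pass), ent$file)
  if (!file.exists(fp))
    sf_stop("sf_dataset_error", "missing tile file %s listed in metadata", fp)
  img <- tiff::readTIFF(fp)
  if (length(dim(img)) == 3) img <- img[, , 1]
  ctr <- stage_point(ent$x_um, ent$y_um)
  objv <- meta_objective(meta)
  cam <- meta_camera(meta)
  mp <- if (!is.null(objv) && !is.null(cam)) field_mapping(ctr, objv, cam)
        else camera_mapping(1, 1, origin = ctr)
  tile_image(img, ctr, mp, ent$tile_index)
}

# ---- configuration --------------------------------------------------------

#' Default run configuration
#'
#' Every tunable default of the acquisition pipeline in one structure:
#' slide model, camera, phase-1 survey, detection, phase-2 re-imaging,
#' loader noise and seeds. Written to and read from YAML by
#' [write_config()] / [read_config()].
#'
#' @export
default_config <- function() {
  list(
    camera = list(sensor_w_px = 1024L, sensor_h_px = 768L,
                  ref_um_per_px_at_1x = 10, read_noise_sd = 0.01,
                  bit_depth = 8L),
    slide = list(width_um = 75000, height_um = 25000,
                 frosted_band_w_um = 19000,
                 coverslip = list(x_um = 30000, y_um = 1500,
                                  w_um = 22000, h_um = 22000),
                 n_objects = 300L,
                 object_len_um_range = c(400, 550),
                 object_aspect_range = c(2.2, 3.0),
                 texture_granularity_um = 15,
                 background_level = 0.85, object_contrast = 0.35,
                 min_gap_um = 80),
    phase1 = list(magnification = 5, survey_mode = "live_view",
                  overlap_frac = 0.10, survey_overlap_frac = 0.05,
                  downsample = 4L),
    detection = list(threshold = "otsu", fixed_value = 0.5,
                     closing_radius_um = 20,
                     min_area_um2 = 20000, max_area_um2 = 600000,
                     pad_frac = 0.10, merge_overlap_frac = 0,
                     min_class_contrast = 0.05),
    phase2 = list(magnification = 20, pad_frac = 0.10, overlap_frac = 0.10,
                  autofocus = list(enabled = TRUE, policy = "per_slide",
                                   z_range_um = c(-50, 50),
                                   coarse_step_um = 10, fine_step_um = 2,
                                   metric = "brenner", crop_frac = 0.5)),
    calibration = list(confidence_floor = 0.2, accept_confidence = 0.5,
                       estimate_rotation = FALSE, n_observations = 3L),
    stitch = list(confidence_floor = 0.1, margin_px = 16L, blend = "linear"),
    loader = list(mode = "auto", sd_um = 200, sd_rad = 5e-4),
    seed = 1L
  )
}

#' Write a configuration file
#' @param config A configuration list (see [default_config()]).
#' @param path Output YAML path.
#' @export
write_config <- function(config = default_config(), path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a configuration file, filling unset values with defaults
#' @param path Input YAML path.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

config_slide_spec <- function(config, seed = config$seed) {
  s <- config$slide
  slide_spec(width_um = s$width_um, height_um = s$height_um,
             frosted_band_w_um = s$frosted_band_w_um,
             coverslip = region(s$coverslip$x_um, s$coverslip$y_um,
                                s$coverslip$w_um, s$coverslip$h_um),
             n_objects = s$n_objects,
             object_len_um_range = as.numeric(s$object_len_um_range),
             object_aspect_range = as.numeric(s$object_aspect_range),
             texture_granularity_um = s$texture_granularity_um,
             background_level = s$background_level,
             object_contrast = s$object_contrast,
             min_gap_um = s$min_gap_um, seed = seed)
}

config_camera <- function(config) {
  c <- config$camera
  camera_model(c$sensor_w_px, c$sensor_h_px, c$ref_um_per_px_at_1x,
               c$read_noise_sd, c$bit_depth)
}

config_detection <- function(config) {
  d <- config$detection
  detection_params(threshold = d$threshold, fixed_value = d$fixed_value,
                   closing_radius_um = d$closing_radius_um,
                   min_area_um2 = d$min_area_um2, max_area_um2 = d$max_area_um2,
                   pad_frac = d$pad_frac,
                   merge_overlap_frac = d$merge_overlap_frac,
                   min_class_contrast = d$min_class_contrast %||% 0.05)
}

# ---- report ---------------------------------------------------------------

png_b64 <- function(img, max_w = 700L) {
  img <- clamp01(img)
  if (ncol(img) > max_w) {
    k <- ceiling(ncol(img) / max_w)
    img <- block_mean(img, as.integer(k))
  }
  jsonlite::base64_enc(png::writePNG(img, target = raw()))
}

png_b64_rgb <- function(arr, max_w = 700L) {
  if (dim(arr)[2] > max_w) {
    k <- as.integer(ceiling(dim(arr)[2] / max_w))
    arr <- simplify2array(lapply(1:3, function(ch) block_mean(arr[, , ch], k)))
  }
  jsonlite::base64_enc(png::writePNG(clamp01(arr), target = raw()))
}

# grayscale image + ROI boxes (stage coords) -> RGB with red rectangles
overlay_rois <- function(img, rois, mapping) {
  arr <- simplify2array(list(img, img, img))
  for (r in rois) {
    p0 <- stage_to_pixel(c(r$bbox$x_um, r$bbox$y_um), mapping)
    p1 <- stage_to_pixel(c(r$bbox$x_um + r$bbox$w_um, r$bbox$y_um + r$bbox$h_um),
                         mapping)
    c0 <- max(1L, round(min(p0[1], p1[1])) + 1L); c1 <- min(ncol(img), round(max(p0[1], p1[1])) + 1L)
    r0 <- max(1L, round(min(p0[2], p1[2])) + 1L); r1 <- min(nrow(img), round(max(p0[2], p1[2])) + 1L)
    if (c1 <= c0 || r1 <= r0) next
    arr[r0:r1, c(c0, c1), 1] <- 1; arr[r0:r1, c(c0, c1), 2:3] <- 0
    arr[c(r0, r1), c0:c1, 1] <- 1; arr[c(r0, r1), c0:c1, 2:3] <- 0
  }
  arr
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a self-contained HTML run report
#'
#' One overview per slide (survey or phase-1 mosaic with red ROI boxes), a
#' panel per ROI showing the low-magnification crop beside the
#' high-magnification stitched composite, and a run summary table with task
#' statuses and the imaging-cost summary. The store is only read, and the
#' output is deterministic apart from the generation timestamp.
#'
#' @param store An [wf_store()] (its path is also the dataset root).
#' @param out Output HTML path (default `report.html` under the store).
#' @param max_rois_per_slide Cap on per-ROI panels per slide.
#' @return The output path, invisibly.
#' @export
generate_report <- function(store, out = file.path(store$path, "report.html"),
                            max_rois_per_slide = 12L) {
  root <- store$path
  tt <- wf_tasks(store)
  slide_ids <- sort(unique(tt$slide_id))
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>scopeflow run report</title>",
            "<style>body{font-family:sans-serif;margin:2em;}",
            "table{border-collapse:collapse;} td,th{border:1px solid #999;padding:4px 8px;}",
            ".panel{display:inline-block;margin:4px;vertical-align:top;text-align:center;}",
            "img{image-rendering:pixelated;}</style></head><body>",
            "<h1>Run report</h1>",
            sprintf("<p class='ts'>generated %s</p>", format(Sys.time())))
  # summary table
  html <- c(html, "<h2>Task summary</h2><table><tr><th>slide</th>",
            paste0("<th>", TASK_STATUSES, "</th>", collapse = ""), "<th>ROIs</th></tr>")
  for (s in slide_ids) {
    counts <- table(factor(tt$status[tt$slide_id == s], levels = TASK_STATUSES))
    roi_file <- file.path(root, "rois", paste0(s, ".csv"))
    nroi <- if (file.exists(roi_file)) nrow(utils::read.csv(roi_file)) else 0L
    html <- c(html, sprintf("<tr><td>%s</td>%s<td>%d</td></tr>", html_escape(s),
                            paste0("<td>", as.integer(counts), "</td>", collapse = ""),
                            nroi))
  }
  html <- c(html, "</table>")
  for (s in slide_ids) {
    html <- c(html, sprintf("<h2>Slide %s</h2>", html_escape(s)))
    sv <- tryCatch(read_dataset(root, s, "survey"), error = function(e) NULL)
    roi_file <- file.path(root, "rois", paste0(s, ".csv"))
    rois <- if (file.exists(roi_file)) df_to_rois(utils::read.csv(roi_file)) else list()
    if (!is.null(sv) && length(sv$tiles)) {
      mos <- sv$tiles[[1]]
      ov <- overlay_rois(mos$image, rois, mos$mapping)
      html <- c(html, "<h3>Overview</h3>",
                sprintf("<img src='data:image/png;base64,%s'/>", png_b64_rgb(ov)))
    }
    if (length(rois)) {
      html <- c(html, "<h3>Regions of interest</h3>")
      for (r in utils::head(rois, max_rois_per_slide)) {
        low <- NULL
        if (!is.null(sv) && length(sv$tiles)) {
          mos <- sv$tiles[[1]]
          p0 <- stage_to_pixel(c(r$bbox$x_um, r$bbox$y_um), mos$mapping)
          p1 <- stage_to_pixel(c(r$bbox$x_um + r$bbox$w_um,
                                 r$bbox$y_um + r$bbox$h_um), mos$mapping)
          c0 <- max(1L, round(min(p0[1], p1[1]))); c1 <- min(ncol(mos$image), round(max(p0[1], p1[1])))
          r0 <- max(1L, round(min(p0[2], p1[2]))); r1 <- min(nrow(mos$image), round(max(p0[2], p1[2])))
          if (c1 > c0 && r1 > r0) low <- mos$image[r0:r1, c0:c1]
        }
        comp <- NULL
        stm <- read_meta(root, s, "phase2_stitched")
        if (!is.null(stm)) {
          hit <- which(stm$entries$roi_label == r$label)
          if (length(hit))
            comp <- read_tile(root, s, "phase2_stitched",
                              stm$entries$tile_index[hit[1]])$image
        }
        html <- c(html, sprintf("<div class='panel'><b>%s</b><br/>", html_escape(r$label)))
        if (!is.null(low))
          html <- c(html, sprintf("<img src='data:image/png;base64,%s' width='160'/>",
                                  png_b64(low)))
        if (!is.null(comp))
          html <- c(html, sprintf("<img src='data:image/png;base64,%s' width='320'/>",
                                  png_b64(comp)))
        html <- c(html, "</div>")
      }
    }
  }
  html <- c(html, "</body></html>")
  writeLines(html, out)
  invisible(out)
}
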