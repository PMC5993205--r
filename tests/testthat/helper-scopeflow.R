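# Shared fixtures: small slides and cameras keep unit tests fast; the
# acceptance suite uses the package defaults.

small_spec <- function(n_objects = 15, seed = 1,
                       coverslip = region(30000, 8000, 8000, 8000), ...) {
  slide_spec(coverslip = coverslip, n_objects = n_objects, seed = seed, ...)
}

small_config <- function(n_objects = 15, seed = 7) {
  cfg <- default_config()
  cfg$slide$coverslip <- list(x_um = 30000, y_um = 8000, w_um = 8000, h_um = 8000)
  cfg$slide$n_objects <- as.integer(n_objects)
  cfg$seed <- as.integer(seed)
  cfg
}

# cyclically roll a matrix by (dx, dy) pixels (content moves right/down)
roll2 <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

point_in_roi <- function(pt, roi) {
  bb <- roi$bbox
  pt[1] >= bb$x_um && pt[1] <= bb$x_um + bb$w_um &&
    pt[2] >= bb$y_um && pt[2] <= bb$y_um + bb$h_um
}

# recall / precision of ROI boxes against true centers (center-in-box)
roi_detection_scores <- function(rois, truth) {
  if (nrow(truth) == 0 || length(rois) == 0)
    return(c(recall = NA_real_, precision = NA_real_))
  hit_obj <- vapply(seq_len(nrow(truth)), function(i)
    any(vapply(rois, function(r) point_in_roi(truth[i, ], r), TRUE)), TRUE)
  hit_roi <- vapply(rois, function(r)
    any(vapply(seq_len(nrow(truth)), function(i)
      point_in_roi(truth[i, ], r), TRUE)), TRUE)
  c(recall = mean(hit_obj), precision = mean(hit_roi))
}

# a smooth, feature-rich test texture (deterministic)
smooth_texture <- function(h, w, seed = 1, sigma = 3) {
  set.seed(seed)
  scopeflow:::clamp01(0.5 + 4 * (scopeflow:::.gauss_blur_cpp(
    matrix(stats::runif(h * w) - 0.5, h, w), sigma)))
}

# counting module entry used across workflow tests
counting_entry <- local({
  registered <- FALSE
  function() {
    if (!registered) {
      register_module_entry("test_count", function(task, ctx) {
        key <- paste(task$module, task$slide_id)
        prev <- ctx$counts$n[[key]]
        ctx$counts$n[[key]] <- (if (is.null(prev)) 0L else prev) + 1L
        list(status = "SUCCESS")
      })
      register_module_entry("test_fail", function(task, ctx) stop("boom"))
      registered <<- TRUE
    }
    invisible(TRUE)
  }
})
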