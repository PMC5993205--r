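# Focus scoring and coarse-to-fine z search.

#' Configuration for the autofocus search
#'
#' @param z_range_um Length-2 search range along the focus axis, um.
#' @param coarse_step_um Coarse grid step, um.
#' @param fine_step_um Fine grid step, um (must not exceed the coarse step).
#' @param metric Focus metric: `"brenner"` (squared lag-2 horizontal
#'   differences) or `"laplacian_var"` (variance of the 3x3 Laplacian).
#' @param crop_frac Central crop fraction evaluated, in `(0, 1]`; cropping
#'   dodges tile-edge artifacts.
#' @export
focus_search_config <- function(z_range_um = c(-50, 50), coarse_step_um = 10,
                                fine_step_um = 2, metric = c("brenner", "laplacian_var"),
                                crop_frac = 0.5) {
  metric <- match.arg(metric)
  stopifnot(length(z_range_um) == 2, diff(z_range_um) >= 0,
            coarse_step_um > 0, fine_step_um > 0,
            fine_step_um <= coarse_step_um,
            crop_frac > 0, crop_frac <= 1)
  structure(list(z_range_um = as.numeric(z_range_um),
                 coarse_step_um = as.numeric(coarse_step_um),
                 fine_step_um = as.numeric(fine_step_um),
                 metric = metric, crop_frac = as.numeric(crop_frac)),
            class = "sf_focus_search_config")
}

central_crop <- function(img, frac) {
  if (frac >= 1) return(img)
  h <- nrow(img); w <- ncol(img)
  ch <- max(3L, floor(h * frac)); cw <- max(3L, floor(w * frac))
  r0 <- (h - ch) %/% 2L; c0 <- (w - cw) %/% 2L
  img[(r0 + 1L):(r0 + ch), (c0 + 1L):(c0 + cw), drop = FALSE]
}

#' Score the sharpness of an image
#'
#' Both metrics are invariant to adding a constant to all pixels and return
#' 0 for a constant image.
#'
#' @param img An intensity matrix (>= 3 x 3).
#' @param metric `"brenner"` or `"laplacian_var"`.
#' @param crop_frac Central crop fraction evaluated.
#' @return A non-negative focus score.
#' @export
focus_score <- function(img, metric = c("brenner", "laplacian_var"),
                        crop_frac = 1) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(img), nrow(img) >= 3, ncol(img) >= 3)
  img <- central_crop(img, crop_frac)
  if (metric == "brenner") {
    w <- ncol(img)
    d <- img[, 3:w, drop = FALSE] - img[, 1:(w - 2), drop = FALSE]
    mean(d * d)
  } else {
    h <- nrow(img); w <- ncol(img)
    ri <- 2:(h - 1); ci <- 2:(w - 1)
    lap <- img[ri - 1, ci] + img[ri + 1, ci] + img[ri, ci - 1] + img[ri, ci + 1] -
      4 * img[ri, ci]
    stats::var(as.vector(lap))
  }
}

#' Coarse-to-fine autofocus search
#'
#' Evaluates the focus metric on a coarse z grid over the search range, then
#' on a fine grid spanning +/- one coarse step around the coarse optimum, and
#' returns the fine-grid optimum. The total number of renders is at most the
#' two grid lengths combined. A featureless field (all scores equal) returns
#' the range midpoint flagged `featureless`.
#'
#' @param render_fun Function of one argument `z_um` returning an image.
#' @param config An [focus_search_config()].
#' @return A list with `best_z_um`, `n_renders`, `featureless`, and the
#'   evaluated `grid` (data frame of z and score).
#' @export
autofocus_search <- function(render_fun, config = focus_search_config()) {
  stopifnot(is.function(render_fun), inherits(config, "sf_focus_search_config"))
  score1 <- function(z) focus_score(render_fun(z), config$metric, config$crop_frac)
  zc <- seq(config$z_range_um[1], config$z_range_um[2], by = config$coarse_step_um)
  if (zc[length(zc)] < config$z_range_um[2]) zc <- c(zc, config$z_range_um[2])
  sc <- vapply(zc, score1, numeric(1))
  if (max(sc) - min(sc) <= 1e-9 * max(sc, 1e-12)) {
    return(list(best_z_um = mean(config$z_range_um), n_renders = length(zc),
                featureless = TRUE,
                grid = data.frame(z_um = zc, score = sc, stage = "coarse")))
  }
  z0 <- zc[which.max(sc)]
  zf <- seq(max(config$z_range_um[1], z0 - config$coarse_step_um),
            min(config$z_range_um[2], z0 + config$coarse_step_um),
            by = config$fine_step_um)
  sf <- vapply(zf, score1, numeric(1))
  list(best_z_um = zf[which.max(sf)], n_renders = length(zc) + length(zf),
       featureless = FALSE,
       grid = data.frame(z_um = c(zc, zf), score = c(sc, sf),
                         stage = rep(c("coarse", "fine"), c(length(zc), length(zf)))))
}
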