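# synthetic segmentation scene: dark ellipses on bright background
draw_ellipses <- function(h, w, ellipses, bg = 0.85, fg = 0.45) {
  img <- matrix(bg, h, w)
  for (e in ellipses) {
    rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    inside <- ((cc - e[1]) / e[3])^2 + ((rr - e[2]) / e[4])^2 <= 1
    img[inside] <- fg
  }
  img
}

test_that("label_components implements 8- and 4-connectivity", {
  d <- matrix(0, 5, 5); d[2, 2] <- 1; d[3, 3] <- 1
  expect_equal(max(label_components(d, 8)), 1)
  expect_equal(max(label_components(d, 4)), 2)

  # 4-connectivity agrees with the EBImage labeller on random masks
  set.seed(3)
  for (k in 1:5) {
    m <- matrix(runif(60 * 80) > 0.6, 60, 80)
    expect_equal(max(label_components(m, 4)), max(EBImage::bwlabel(m * 1)))
  }
})

test_that("segment_objects counts objects and filters by area", {
  mapping <- camera_mapping(2, 2)   # 2 um/px
  params <- detection_params(closing_radius_um = 4)
  blank <- matrix(0.85, 200, 300)
  expect_equal(segment_objects(blank, params, mapping)$n, 0)

  # 10 large ellipses (above min area at 2 um/px) + 3 specks (below)
  big <- lapply(1:10, function(i)
    c(90 + (i - 1) %% 5 * 150, 110 + (i - 1) %/% 5 * 200, 60, 35))
  specks <- list(c(30, 30, 4, 4), c(760, 390, 4, 4), c(400, 30, 3, 3))
  img <- draw_ellipses(420, 800, c(big, specks))
  seg <- segment_objects(img, params, mapping)
  expect_equal(seg$n, 10)
  expect_true(all(seg$areas_um2 >= params$min_area_um2 &
                  seg$areas_um2 <= params$max_area_um2))

  # area filter oracle: brute-force recount of every surviving component
  for (k in seq_len(seg$n)) {
    area <- sum(seg$labels == k) * 4
    expect_true(area >= params$min_area_um2 && area <= params$max_area_um2)
  }
})

test_that("components_to_rois maps pixel boxes to padded stage boxes", {
  # component with pixel bbox (10,20)-(110,70) at 1.3 um/px, 10% padding
  lab <- matrix(0L, 100, 150)
  lab[21:71, 11:111] <- 1L
  comp <- list(labels = lab, n = 1L, areas_um2 = sum(lab) * 1.3^2)
  mapping <- camera_mapping(1.3, 1.3)
  rois <- components_to_rois(comp, mapping, detection_params(pad_frac = 0.10),
                             "s", "phase1_tiles")
  bb <- rois[[1]]$bbox
  expect_equal(bb$w_um, 156, tolerance = 1e-9)   # 130 grown by 10% per side
  expect_equal(bb$h_um, 78, tolerance = 1e-9)    # 65 grown by 10% per side
  expect_equal(bb$x_um + bb$w_um / 2, (10 + 110) / 2 * 1.3)  # center preserved
  expect_equal(bb$y_um + bb$h_um / 2, (20 + 70) / 2 * 1.3)
  expect_equal(rois[[1]]$label, "R0001")
  expect_equal(components_to_rois(list(labels = lab * 0L, n = 0L,
                                       areas_um2 = numeric(0)),
                                  mapping, detection_params(), "s"),
               list())
})

test_that("merge_rois unions overlaps transitively (union-find oracle)", {
  mk <- function(x, y, w, h)
    scopeflow:::new_roi("s", region(x, y, w, h), 10L, "phase1_tiles")
  disjoint <- list(mk(0, 0, 10, 10), mk(50, 50, 10, 10))
  m1 <- merge_rois(disjoint)
  expect_equal(length(m1), 2)

  two <- list(mk(0, 0, 10, 10), mk(5, 0, 10, 10))
  m2 <- merge_rois(two, 0)
  expect_equal(length(m2), 1)
  expect_equal(c(m2[[1]]$bbox$x_um, m2[[1]]$bbox$w_um), c(0, 15))

  # chain A-B, B-C with A,C disjoint collapses via transitivity
  chain <- list(mk(0, 0, 10, 10), mk(8, 0, 10, 10), mk(16, 0, 10, 10))
  m3 <- merge_rois(chain, 0)
  expect_equal(length(m3), 1)
  # brute-force union-find oracle over pairwise overlaps
  overlap <- function(a, b) {
    iw <- min(a$bbox$x_um + a$bbox$w_um, b$bbox$x_um + b$bbox$w_um) -
      max(a$bbox$x_um, b$bbox$x_um)
    ih <- min(a$bbox$y_um + a$bbox$h_um, b$bbox$y_um + b$bbox$h_um) -
      max(a$bbox$y_um, b$bbox$y_um)
    iw > 0 && ih > 0
  }
  parent <- 1:3
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:2) for (j in (i + 1):3)
    if (overlap(chain[[i]], chain[[j]]))
      parent[max(find(i), find(j))] <- min(find(i), find(j))
  expect_equal(length(unique(vapply(1:3, find, 1L))), length(m3))
})

test_that("merge_rois is idempotent and order-independent", {
  set.seed(8)
  rois <- lapply(1:12, function(i)
    scopeflow:::new_roi("s", region(runif(1, 0, 100), runif(1, 0, 100),
                                    runif(1, 5, 30), runif(1, 5, 30)),
                        5L, "phase1_tiles"))
  merged <- merge_rois(rois)
  again <- merge_rois(merged)
  key <- function(rs) sort(vapply(rs, function(r)
    paste(round(c(r$bbox$x_um, r$bbox$y_um, r$bbox$w_um, r$bbox$h_um), 6),
          collapse = ","), ""))
  expect_equal(key(again), key(merged))
  for (k in 1:20) {
    shuffled <- merge_rois(sample(rois))
    expect_equal(key(shuffled), key(merged))
  }
})

test_that("plugin detectors are validated and normalised", {
  mapping <- camera_mapping(2, 2)
  params <- detection_params(closing_radius_um = 4)
  img <- draw_ellipses(420, 800, list(c(200, 120, 60, 35), c(550, 300, 60, 35)))
  builtin <- components_to_rois(segment_objects(img, params, mapping),
                                mapping, params, "s")

  hook_same <- function(img, mapping) builtin
  out <- run_plugin_detector(img, mapping, hook_same, "s")
  expect_equal(rois_to_df(out)[, c("x_um", "y_um", "w_um", "h_um")],
               rois_to_df(builtin)[, c("x_um", "y_um", "w_um", "h_um")])

  hook_reversed <- function(img, mapping) rev(builtin)
  out2 <- run_plugin_detector(img, mapping, hook_reversed, "s")
  expect_equal(vapply(out2, function(r) r$label, ""),
               sprintf("R%04d", seq_along(out2)))
  expect_equal(rois_to_df(out2)$y_um, sort(rois_to_df(out2)$y_um))

  hook_bad <- function(img, mapping)
    list(scopeflow:::new_roi("s", region(-5000, 0, 100, 100), 1L, "survey"))
  err <- tryCatch(
    run_plugin_detector(img, mapping, hook_bad, "s",
                        slide_bounds = region(0, 0, 1000, 1000)),
    error = function(e) e)
  expect_s3_class(err, "sf_plugin_error")
  expect_match(conditionMessage(err), "bbox")
})
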