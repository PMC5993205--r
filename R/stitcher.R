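# Mosaic assembly: nominal placement from stage positions, pairwise
# refinement by phase correlation on overlap strips, translation-only global
# least squares.

#' Bundle an acquired tile with its stage metadata
#'
#' @param image Intensity matrix.
#' @param nominal_center Stage position the tile was acquired at.
#' @param mapping The tile's [camera_mapping()] (shared within one pass).
#' @param tile_index Integer index within the acquisition (1-based).
#' @export
tile_image <- function(image, nominal_center, mapping, tile_index) {
  stopifnot(is.matrix(image), inherits(nominal_center, "sf_stage_point"))
  structure(list(image = image, nominal_center = nominal_center,
                 mapping = mapping, tile_index = as.integer(tile_index)),
            class = "sf_tile_image")
}

#' Estimate the translation between two equally sized images
#'
#' Computes the normalised cross-power spectrum, inverse-transforms it, and
#' takes the correlation peak with 3x3 centroid sub-pixel refinement. The
#' period ambiguity of the peak (shifts differing by one image period) is
#' resolved by scoring each candidate against the direct overlap
#' correlation, preferring candidates near `nominal` when supplied.
#'
#' Convention: the returned `(dx_px, dy_px)` is the displacement of `b`'s
#' content relative to `a`'s, so `b == roll(a, by = (dx, dy))` returns
#' `(dx, dy)`.
#'
#' @param a,b Equal-size intensity matrices, at least 32 x 32.
#' @param nominal Optional expected `(dx, dy)` used to rank ambiguous
#'   candidates.
#' @param confidence_floor Peaks below this value are flagged unreliable.
#' @return A list with `dx_px`, `dy_px`, `confidence`, `reliable`.
#' @export
phase_correlate <- function(a, b, nominal = NULL, confidence_floor = 0.1) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)),
            nrow(a) >= 32, ncol(a) >= 32)
  h <- nrow(a); w <- ncol(a)
  fa <- stats::fft(a); fb <- stats::fft(b)
  cp <- fa * Conj(fb)
  cp <- cp / (Mod(cp) + 1e-12)
  r <- Re(stats::fft(cp, inverse = TRUE)) / length(cp)

  # the global correlation maximum is not always the true shift (periodic
  # texture and quantisation contours produce spurious peaks), so the top
  # peaks are each tested against the direct overlap correlation
  n_peaks <- 5L
  # partial sort: only the top slice of the surface is ever inspected
  rv_ <- as.vector(r)
  ncand <- min(length(rv_), 64L)
  th <- -sort(-rv_, partial = ncand)[ncand]
  ord <- which(rv_ >= th)
  ord <- ord[order(rv_[ord], decreasing = TRUE)]
  cells <- integer(0)
  for (o in ord) {
    rc <- arrayInd(o, dim(r))
    clash <- FALSE
    for (cprev in cells) {
      pc <- arrayInd(cprev, dim(r))
      dr <- min(abs(rc[1] - pc[1]), h - abs(rc[1] - pc[1]))
      dc <- min(abs(rc[2] - pc[2]), w - abs(rc[2] - pc[2]))
      if (dr <= 2 && dc <= 2) { clash <- TRUE; break }
    }
    if (!clash) cells <- c(cells, o)
    if (length(cells) >= n_peaks) break
  }
  # secondary peaks far below the leader cannot win the overlap scoring
  cells <- cells[rv_[cells] >= 0.3 * rv_[cells[1]]]

  # under b(x) = a(x - d), pixel (r, c) of a matches pixel (r + dy, c + dx)
  # of b over the in-bounds overlap
  overlap_cor <- function(dx, dy) {
    dx <- round(dx); dy <- round(dy)
    ax <- max(1, 1 - dx):min(w, w - dx); ay <- max(1, 1 - dy):min(h, h - dy)
    if (length(ax) < 4 || length(ay) < 4) return(-Inf)
    # 2x2 subsampling: candidate ranking does not need every pixel
    ax <- ax[seq(1, length(ax), by = 2)]; ay <- ay[seq(1, length(ay), by = 2)]
    av <- a[ay, ax]; bv <- b[ay + dy, ax + dx]
    if (stats::sd(av) < 1e-12 || stats::sd(bv) < 1e-12) return(0)
    stats::cor(as.vector(av), as.vector(bv))
  }

  refine <- function(pk) {
    # 3x3 centroid refinement around the peak (wraparound indexing); the
    # confidence integrates the peak neighbourhood because sub-pixel shifts
    # split the correlation energy across adjacent cells
    ri <- ((pk[1] - 2):(pk[1])) %% h + 1L
    ci <- ((pk[2] - 2):(pk[2])) %% w + 1L
    nb <- r[ri, ci]
    para <- function(m1, p0, p1) {
      den <- m1 - 2 * p0 + p1
      if (den < 0) min(0.5, max(-0.5, 0.5 * (m1 - p1) / den)) else 0
    }
    dr <- para(nb[1, 2], nb[2, 2], nb[3, 2])
    dc <- para(nb[2, 1], nb[2, 2], nb[2, 3])
    # peak at index p (1-based) means the phase shift is -(p - 1) mod N
    # under the b(x) = a(x - d) convention
    list(py = -(pk[1] - 1 + dr), px = -(pk[2] - 1 + dc),
         conf = min(1, sum(pmax(0, nb))))
  }

  best <- NULL; best_score <- -Inf; best_conf <- 0
  for (cell in cells) {
    pk <- arrayInd(cell, dim(r))
    rf <- refine(c(pk[1], pk[2]))
    cand_x <- c(rf$px, rf$px + w, rf$px - w); cand_x <- cand_x[abs(cand_x) < w]
    cand_y <- c(rf$py, rf$py + h, rf$py - h); cand_y <- cand_y[abs(cand_y) < h]
    # order by shift magnitude so exact ties (cyclic inputs) resolve to the
    # largest-overlap interpretation; with a nominal shift, drop candidates
    # in the wrong period before the (relatively costly) overlap scoring
    cand_x <- cand_x[order(abs(cand_x))]; cand_y <- cand_y[order(abs(cand_y))]
    if (!is.null(nominal)) {
      kx <- abs(cand_x - nominal[1]) <= w / 2
      if (any(kx)) cand_x <- cand_x[kx]
      ky <- abs(cand_y - nominal[2]) <= h / 2
      if (any(ky)) cand_y <- cand_y[ky]
    }
    for (cx in cand_x) for (cy in cand_y) {
      score <- overlap_cor(cx, cy)
      if (!is.null(nominal))
        score <- score - 1e-6 * (abs(cx - nominal[1]) + abs(cy - nominal[2])) / max(h, w)
      if (score > best_score + 1e-9) {
        best_score <- score; best <- c(cx, cy); best_conf <- rf$conf
      }
    }
  }

  # sub-pixel refinement: iterative gradient-based least squares on the
  # integer-aligned overlap, warping the moving image by the current
  # fractional estimate (bilinear). Run in both directions (a as template,
  # then b) and averaged, which cancels the interpolation-induced bias.
  # The whitened cross-power localises the integer peak and resolves the
  # period ambiguity, but its sub-pixel phases are dominated by
  # quantisation residuals, so refinement works in the image domain.
  bx <- round(best[1]); by <- round(best[2])
  lk_shift <- function(tmpl, move, oy0, ox0, rows, cols) {
    # fractional shift of `move` (sampled at rows+oy0, cols+ox0) vs `tmpl`
    tv <- tmpl[rows, cols]
    gx <- (tmpl[rows, cols + 1] - tmpl[rows, cols - 1]) / 2
    gy <- (tmpl[rows + 1, cols] - tmpl[rows - 1, cols]) / 2
    sxx <- sum(gx * gx); sxy <- sum(gx * gy); syy <- sum(gy * gy)
    det <- sxx * syy - sxy * sxy
    if (det <= 1e-12) return(NULL)
    ex <- 0; ey <- 0
    for (it in 1:6) {
      fx <- ex - floor(ex); fy <- ey - floor(ey)
      ox <- ox0 + floor(ex); oy <- oy0 + floor(ey)
      mv <- (1 - fy) * (1 - fx) * move[rows + oy, cols + ox] +
            (1 - fy) * fx       * move[rows + oy, cols + ox + 1] +
            fy       * (1 - fx) * move[rows + oy + 1, cols + ox] +
            fy       * fx       * move[rows + oy + 1, cols + ox + 1]
      rv <- mv - tv
      tx <- sum(gx * rv); ty <- sum(gy * rv)
      dxs <- -(syy * tx - sxy * ty) / det
      dys <- -(sxx * ty - sxy * tx) / det
      ex <- ex + dxs; ey <- ey + dys
      if (abs(ex) > 1.25 || abs(ey) > 1.25) return(NULL)
      if (max(abs(dxs), abs(dys)) < 0.005) break
    }
    c(ex, ey)
  }
  ax <- max(1, 1 - bx):min(w, w - bx); ay <- max(1, 1 - by):min(h, h - by)
  if (length(ax) >= 10 && length(ay) >= 10) {
    ayi <- ay[3:(length(ay) - 2)]; axi <- ax[3:(length(ax) - 2)]
    fwd <- lk_shift(a, b, by, bx, ayi, axi)
    bwd <- lk_shift(b, a, -by, -bx, ayi + by, axi + bx)
    if (!is.null(fwd) && !is.null(bwd)) {
      best <- c(bx + (fwd[1] - bwd[1]) / 2, by + (fwd[2] - bwd[2]) / 2)
    } else if (!is.null(fwd)) {
      best <- c(bx + fwd[1], by + fwd[2])
    } else best <- c(bx, by)
  } else best <- c(bx, by)
  list(dx_px = best[1], dy_px = best[2], confidence = best_conf,
       reliable = best_conf >= confidence_floor)
}


# grid adjacency (4-neighbourhood) from a tile plan
plan_adjacency <- function(plan) {
  ctr <- plan$centers
  pairs <- list()
  for (k in seq_len(nrow(ctr))) {
    right <- which(ctr$row == ctr$row[k] & ctr$col == ctr$col[k] + 1L)
    below <- which(ctr$col == ctr$col[k] & ctr$row == ctr$row[k] + 1L)
    if (length(right)) pairs[[length(pairs) + 1L]] <- c(ctr$index[k], ctr$index[right], 1L)
    if (length(below)) pairs[[length(pairs) + 1L]] <- c(ctr$index[k], ctr$index[below], 2L)
  }
  if (!length(pairs)) return(matrix(integer(0), 0, 3))
  do.call(rbind, pairs)
}

#' Measure pairwise offsets between adjacent tiles
#'
#' For each 4-neighbour pair in the tile plan, phase-correlates the two
#' overlap strips (cropped from the nominal overlap plus a search margin)
#' and expresses the measured displacement of tile j relative to tile i in
#' full-tile pixels. Pairs whose correlation confidence falls below the
#' floor are omitted, so featureless (glass-only) tiles fall back to their
#' nominal stage placement in [global_place()].
#'
#' @param tiles List of [tile_image()] in plan order.
#' @param plan The `sf_tile_plan` the tiles were acquired from.
#' @param confidence_floor Minimum phase-correlation confidence.
#' @param margin_px Extra strip width beyond the nominal overlap, px.
#' @return A data frame with columns `i`, `j`, `dx_px`, `dy_px`,
#'   `confidence` (one row per accepted pair).
#' @export
pairwise_offsets <- function(tiles, plan, confidence_floor = 0.1, margin_px = 16L) {
  adj <- plan_adjacency(plan)
  empty <- data.frame(i = integer(), j = integer(), dx_px = numeric(),
                      dy_px = numeric(), confidence = numeric())
  if (nrow(adj) == 0) return(empty)
  umpp_x <- tiles[[1]]$mapping$um_per_px_x; umpp_y <- tiles[[1]]$mapping$um_per_px_y
  out <- empty
  for (k in seq_len(nrow(adj))) {
    i <- adj[k, 1]; j <- adj[k, 2]
    a <- tiles[[i]]$image; b <- tiles[[j]]$image
    h <- nrow(a); w <- ncol(a)
    ndx <- (tiles[[j]]$nominal_center$x_um - tiles[[i]]$nominal_center$x_um) / umpp_x
    ndy <- (tiles[[j]]$nominal_center$y_um - tiles[[i]]$nominal_center$y_um) / umpp_y
    # strip width: the nominal overlap plus a search margin, capped -- wide
    # overlaps carry no extra information and inflate the FFT. The cross
    # dimension is also cropped to its central 512 px: fields are centered
    # on their targets, so the outer rows/columns are mostly glass.
    cap <- 256L; cross_cap <- 640L
    if (adj[k, 3] == 1L) {                       # j to the right of i
      wov <- min(w, max(32L, w - round(ndx) + margin_px))
      ws <- min(wov, cap)
      ca0 <- w - ws                              # 0-based start col of strip in a
      cb0 <- max(0L, min(w - ws, round(ca0 - ndx)))
      hs2 <- min(h, cross_cap)
      rr <- ((h - hs2) %/% 2L + 1L):((h - hs2) %/% 2L + hs2)
      sa <- a[rr, (ca0 + 1L):(ca0 + ws), drop = FALSE]
      sb <- b[rr, (cb0 + 1L):(cb0 + ws), drop = FALSE]
      pc <- phase_correlate(sa, sb, nominal = c(ca0 - cb0 - ndx, -ndy))
      dx <- ca0 - cb0 - pc$dx_px; dy <- -pc$dy_px
    } else {                                     # j below i
      hov <- min(h, max(32L, h - round(ndy) + margin_px))
      hs <- min(hov, cap)
      ra0 <- h - hs
      rb0 <- max(0L, min(h - hs, round(ra0 - ndy)))
      ws2 <- min(w, cross_cap)
      cc <- ((w - ws2) %/% 2L + 1L):((w - ws2) %/% 2L + ws2)
      sa <- a[(ra0 + 1L):(ra0 + hs), cc, drop = FALSE]
      sb <- b[(rb0 + 1L):(rb0 + hs), cc, drop = FALSE]
      pc <- phase_correlate(sa, sb, nominal = c(-ndx, ra0 - rb0 - ndy))
      dx <- -pc$dx_px; dy <- ra0 - rb0 - pc$dy_px
    }
    if (pc$reliable)
      out <- rbind(out, data.frame(i = i, j = j, dx_px = dx, dy_px = dy,
                                   confidence = pc$confidence))
  }
  out
}

#' Globally place tiles from pairwise offsets
#'
#' Solves the translation-only weighted least squares
#' sum over edges of confidence * ||(p_j - p_i) - measured||^2, with the
#' first tile of each connected component anchored at its nominal stage
#' position (mapped to pixels). With no usable offsets the layout equals the
#' nominal stage placement.
#'
#' @param tiles List of [tile_image()].
#' @param offsets Data frame from [pairwise_offsets()].
#' @return An `sf_mosaic_layout`: data frame `positions` (`tile_index`,
#'   `x_px`, `y_px` of each tile's top-left corner in the mosaic pixel
#'   frame), `provenance` (`"stage_only"` or `"refined"`), and `umpp`.
#' @export
global_place <- function(tiles, offsets = NULL) {
  stopifnot(length(tiles) >= 1)
  umpp_x <- tiles[[1]]$mapping$um_per_px_x; umpp_y <- tiles[[1]]$mapping$um_per_px_y
  n <- length(tiles)
  nom <- t(vapply(tiles, function(t)
    c(t$mapping$origin$x_um / umpp_x, t$mapping$origin$y_um / umpp_y), numeric(2)))
  if (is.null(offsets) || nrow(offsets) == 0) {
    return(structure(list(
      positions = data.frame(tile_index = vapply(tiles, `[[`, 1L, "tile_index"),
                             x_px = nom[, 1], y_px = nom[, 2]),
      provenance = "stage_only", umpp = c(umpp_x, umpp_y)), class = "sf_mosaic_layout"))
  }
  # connected components over the offset graph
  parent <- seq_len(n)
  find <- function(i) { i <- as.integer(i)
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i }
  for (k in seq_len(nrow(offsets))) {
    ra <- find(offsets$i[k]); rb <- find(offsets$j[k])
    if (ra != rb) parent[max(ra, rb)] <- as.integer(min(ra, rb))
  }
  comp <- vapply(seq_len(n), find, integer(1))
  anchors <- vapply(unique(comp), function(cc) min(which(comp == cc)), integer(1))
  # stacked weighted least squares per axis: edge rows + anchor rows
  ne <- nrow(offsets)
  A <- matrix(0, ne + length(anchors), n)
  wts <- numeric(ne + length(anchors))
  bx <- by <- numeric(ne + length(anchors))
  for (k in seq_len(ne)) {
    A[k, offsets$i[k]] <- -1; A[k, offsets$j[k]] <- 1
    wts[k] <- sqrt(max(offsets$confidence[k], 1e-6))
    bx[k] <- offsets$dx_px[k]; by[k] <- offsets$dy_px[k]
  }
  for (m in seq_along(anchors)) {
    r <- ne + m
    A[r, anchors[m]] <- 1
    wts[r] <- 1e4                       # hard anchor
    bx[r] <- nom[anchors[m], 1]; by[r] <- nom[anchors[m], 2]
  }
  Aw <- A * wts
  px <- qr.solve(Aw, bx * wts)
  py <- qr.solve(Aw, by * wts)
  structure(list(
    positions = data.frame(tile_index = vapply(tiles, `[[`, 1L, "tile_index"),
                           x_px = px, y_px = py),
    provenance = "refined", umpp = c(umpp_x, umpp_y)), class = "sf_mosaic_layout")
}

#' Render a mosaic from placed tiles
#'
#' Pastes tiles on a canvas sized to the layout bounds. `"overwrite"` pastes
#' in tile order; `"linear"` feathers overlaps with weights ramping linearly
#' from each tile's border.
#'
#' @param tiles List of [tile_image()].
#' @param layout An `sf_mosaic_layout` from [global_place()].
#' @param blend `"overwrite"` or `"linear"`.
#' @return A list with `image` and `origin_px` (mosaic-frame pixel
#'   coordinate of the canvas top-left corner).
#' @export
render_mosaic <- function(tiles, layout, blend = c("overwrite", "linear")) {
  blend <- match.arg(blend)
  pos <- layout$positions
  x0 <- round(pos$x_px); y0 <- round(pos$y_px)
  hs <- vapply(tiles, function(t) nrow(t$image), integer(1))
  ws <- vapply(tiles, function(t) ncol(t$image), integer(1))
  ox <- min(x0); oy <- min(y0)
  W <- max(x0 + ws) - ox; H <- max(y0 + hs) - oy
  if (blend == "overwrite") {
    canvas <- matrix(0, H, W)
    for (k in seq_along(tiles)) {
      rr <- (y0[k] - oy + 1L):(y0[k] - oy + hs[k])
      cc <- (x0[k] - ox + 1L):(x0[k] - ox + ws[k])
      canvas[rr, cc] <- tiles[[k]]$image
    }
  } else {
    acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
    for (k in seq_along(tiles))
      .mosaic_accum_cpp(acc, wacc, tiles[[k]]$image,
                        y0[k] - oy, x0[k] - ox)
    .mosaic_norm_cpp(acc, wacc)
    canvas <- acc
  }
  list(image = canvas, origin_px = c(ox, oy))
}
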