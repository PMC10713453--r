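# Laminar windows, stage 1: tissue mask and contour, smoothed distance
# transform, placement of contour-anchored rectangular windows, orientation
# along the inner-outer axis by maximizing captured distance-transform
# signal, profile extraction and window filtering.
#
# Conventions: 1-based (row, col) coordinates, pixel centres at integers;
# angles in radians from the +col axis toward the +row axis. A window is a
# width_px x length_px rectangle whose anchor is the midpoint of the outer
# (contour-touching) short edge; its angle points inward.

#' Build a binary tissue mask from structural channels
#'
#' Each channel is percentile-scaled (1st to 99th) to [0, 1]; channels are
#' averaged, Otsu-thresholded, dilated with a disk, holes are filled, and
#' the largest connected component is kept.
#'
#' @param channels H x W x C array or a single matrix of structural stains.
#' @param dilation_radius disk radius in px (default 5).
#' @return 0/1 integer matrix.
#' @export
build_tissue_mask <- function(channels, dilation_radius = 5L) {
  if (length(dim(channels)) == 2L) dim(channels) <- c(dim(channels), 1L)
  C <- dim(channels)[3]
  acc <- matrix(0, dim(channels)[1], dim(channels)[2])
  for (ch in seq_len(C)) {
    v <- channels[, , ch]
    q <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
    span <- if (q[2] > q[1]) q[2] - q[1] else 1
    acc <- acc + pmin(pmax((v - q[1]) / span, 0), 1)
  }
  acc <- acc / C
  if (max(acc) == min(acc)) stopf("structural channels are constant; no tissue found")
  th <- otsu_level(acc)
  bw <- EBImage::Image(acc > th)
  if (sum(bw) == 0) stopf("empty mask after Otsu thresholding")
  if (dilation_radius > 0)
    bw <- EBImage::dilate(bw, EBImage::makeBrush(2L * dilation_radius + 1L, "disc"))
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  tab <- tabulate(as.integer(lab))
  keep <- which.max(tab)
  mask <- (as.matrix(lab) == keep) * 1L
  mask
}

#' Extract the tissue contour from a mask
#'
#' The binary mask is Gaussian-smoothed, re-thresholded with Otsu, and the
#' longest marching-squares iso-contour at that level is returned as an
#' ordered, closed, counter-clockwise polyline with subpixel coordinates.
#'
#' @param mask 0/1 matrix.
#' @param sigma Gaussian smoothing sd in px (default 50).
#' @return object of class `tissue_contour`: matrix with columns row, col
#'   (first row repeated at the end), attribute `sigma`.
#' @export
extract_contour <- function(mask, sigma = 50) {
  if (sum(mask) == 0) stopf("mask is empty")
  sm <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (sigma > 0)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(sm), sigma = sigma))
  level <- otsu_level(sm)
  # contourLines treats the matrix as z[x, y]; pass rows as x, cols as y
  cl <- grDevices::contourLines(x = seq_len(nrow(sm)), y = seq_len(ncol(sm)),
                                z = sm, levels = level)
  if (length(cl) == 0) stopf("no iso-contour found at the Otsu level")
  arclen <- vapply(cl, function(ct) {
    sum(sqrt(diff(ct$x)^2 + diff(ct$y)^2))
  }, numeric(1))
  ct <- cl[[which.max(arclen)]]
  coords <- cbind(row = ct$x, col = ct$y)
  # close the polyline
  if (any(coords[1, ] != coords[nrow(coords), ]))
    coords <- rbind(coords, coords[1, ])
  # orient counter-clockwise in (col, row) = (x, y) axes
  a <- sum(coords[-nrow(coords), 2] * coords[-1, 1] -
             coords[-1, 2] * coords[-nrow(coords), 1])
  if (a < 0) coords <- coords[rev(seq_len(nrow(coords))), ]
  structure(coords, sigma = sigma, class = c("tissue_contour", class(coords)))
}

#' Smoothed Euclidean distance transform of a tissue mask
#'
#' @param mask 0/1 matrix.
#' @param sigma Gaussian smoothing sd in px (default 25); `sigma = 0`
#'   returns the raw exact distance transform.
#' @return numeric matrix (class `distance_map`, attribute `sigma`).
#' @export
distance_map <- function(mask, sigma = 25) {
  if (sum(mask) == 0) stopf("mask is empty")
  d <- as.matrix(EBImage::distmap(EBImage::Image(mask), metric = "euclidean"))
  if (sigma > 0) d <- as.matrix(EBImage::gblur(EBImage::Image(d), sigma = sigma))
  structure(d, sigma = sigma, class = c("distance_map", class(d)))
}

# inward normal estimate at contour index i: local tangent by PCA over
# +/- span points, normal sign chosen toward the higher distance-map value
initial_normal <- function(contour, i, dmap, span = 10L, probe = 5) {
  n <- nrow(contour) - 1L                      # last point duplicates first
  idx <- ((i - 1L + seq(-span, span)) %% n) + 1L
  pts <- contour[idx, , drop = FALSE]
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  tang <- pc$rotation[, 1]
  nrm <- c(-tang[2], tang[1])
  p <- contour[i, ]
  v_pos <- bilinear_sample(dmap, p[1] + probe * nrm[1], p[2] + probe * nrm[2])
  v_neg <- bilinear_sample(dmap, p[1] - probe * nrm[1], p[2] - probe * nrm[2])
  if (v_neg > v_pos) nrm <- -nrm
  atan2(nrm[1], nrm[2])
}

#' Place laminar windows on the tissue contour
#'
#' One window is anchored at every `stride`-th contour coordinate, with an
#' initial inward-normal angle estimated from the local contour tangent
#' (PCA over +/- 10 neighbouring points), the sign chosen toward the higher
#' distance-map value.
#'
#' @param contour an [extract_contour()] result.
#' @param dmap a [distance_map()] for the same section.
#' @param stride contour-coordinate spacing between anchors (default 100).
#' @param width_px,length_px window dimensions in px (defaults 100 x 1000).
#' @param pixel_size_um microns per pixel (default 0.1625); stored so window
#'   extents are reportable in microns.
#' @return object of class `window_set`: data.frame with anchor_row,
#'   anchor_col, angle, valid_fraction, dt_score, flags; attributes
#'   `width_px`, `length_px`, `pixel_size_um`.
#' @export
place_windows <- function(contour, dmap, stride = 100L,
                          width_px = 100L, length_px = 1000L,
                          pixel_size_um = 0.1625) {
  n <- nrow(contour) - 1L
  if (stride >= n) stopf("stride (%d) must be smaller than the contour length (%d)",
                         stride, n)
  at <- seq(1L, n, by = stride)
  ws <- data.frame(
    window = seq_along(at),
    anchor_row = contour[at, 1], anchor_col = contour[at, 2],
    angle = vapply(at, function(i) initial_normal(contour, i, dmap), numeric(1)),
    contour_index = at,
    valid_fraction = NA_real_, dt_score = NA_real_,
    straight_contour = FALSE, out_of_bounds = FALSE
  )
  structure(ws, width_px = as.integer(width_px),
            length_px = as.integer(length_px),
            pixel_size_um = pixel_size_um,
            contour = contour,
            class = c("window_set", "data.frame"))
}

#' Physical extent of a window set in microns
#' @param windows a `window_set`.
#' @return named numeric: width_um, length_um.
#' @export
window_extent_um <- function(windows) {
  c(width_um = attr(windows, "width_px") * attr(windows, "pixel_size_um"),
    length_um = attr(windows, "length_px") * attr(windows, "pixel_size_um"))
}

# footprint sample coordinates for a window at a given angle: the anchor is
# the midpoint of the outer short edge, v runs inward 0..length-1, u spans
# the transverse width
window_grid <- function(anchor, angle, width_px, length_px) {
  u <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  v <- seq(0, length_px - 1)
  dv <- c(sin(angle), cos(angle))   # inward axis
  du <- c(cos(angle), -sin(angle))  # transverse axis
  r <- anchor[1] + outer(u * du[1], v * dv[1], "+")
  c_ <- anchor[2] + outer(u * du[2], v * dv[2], "+")
  list(r = r, c = c_)               # width_px x length_px each
}

# sum of bilinearly sampled distance-map values under the footprint
dt_score_at <- function(dmap, anchor, angle, width_px, length_px) {
  g <- window_grid(anchor, angle, width_px, length_px)
  sum(bilinear_sample(dmap, as.numeric(g$r), as.numeric(g$c), outside = 0))
}

#' Orient laminar windows against the distance transform
#'
#' Each window is rotated about its anchor over `initial angle +/- search`
#' in `coarse_step` increments, then refined at `refine_step` around the
#' coarse argmax; the distance-transform signal summed under the footprint
#' (bilinear samples; out-of-image contributes 0) is maximized. Ties take
#' the angle closest to the initial normal. A window whose score is 0 at
#' every angle keeps its initial angle and is flagged `out_of_bounds`.
#'
#' @param windows a [place_windows()] result.
#' @param dmap the section's [distance_map()].
#' @param coarse_step,refine_step scan steps in degrees (defaults 2, 0.5).
#' @param search half-arc of the scan in degrees (default 90); `full_circle
#'   = TRUE` scans all 360 degrees instead.
#' @param full_circle scan the full circle (default FALSE).
#' @return the window set with `angle`, `dt_score`, `out_of_bounds` updated.
#' @export
orient_windows <- function(windows, dmap, coarse_step = 2, refine_step = 0.5,
                           search = 90, full_circle = FALSE) {
  wpx <- attr(windows, "width_px"); lpx <- attr(windows, "length_px")
  to_rad <- pi / 180
  for (i in seq_len(nrow(windows))) {
    anchor <- c(windows$anchor_row[i], windows$anchor_col[i])
    a0 <- windows$angle[i]
    offs <- if (full_circle) seq(-180, 180 - coarse_step, by = coarse_step)
            else seq(-search, search, by = coarse_step)
    cand <- a0 + offs * to_rad
    sc <- vapply(cand, function(a) dt_score_at(dmap, anchor, a, wpx, lpx),
                 numeric(1))
    if (max(sc) <= 0) {
      windows$out_of_bounds[i] <- TRUE
      windows$dt_score[i] <- 0
      next
    }
    best <- cand[best_tie(sc, cand, a0)]
    fine <- best + seq(-coarse_step, coarse_step, by = refine_step) * to_rad
    scf <- vapply(fine, function(a) dt_score_at(dmap, anchor, a, wpx, lpx),
                  numeric(1))
    bestf <- fine[best_tie(scf, fine, a0)]
    windows$angle[i] <- atan2(sin(bestf), cos(bestf))
    windows$dt_score[i] <- max(scf)
  }
  windows
}

# index of the maximal score; ties broken by angular proximity to a0
best_tie <- function(scores, angles, a0) {
  mx <- max(scores)
  cand <- which(scores >= mx - 1e-12 * max(1, abs(mx)))
  if (length(cand) == 1L) return(cand)
  dang <- abs(atan2(sin(angles[cand] - a0), cos(angles[cand] - a0)))
  cand[which.min(dang)]
}

#' Extract inner-outer intensity profiles under laminar windows
#'
#' Each window footprint is resampled on its width x length grid (bilinear
#' for intensity channels, nearest-neighbour for label images). Profiles
#' average the transverse (width) samples at each inner-outer position;
#' position 1 is the outer (contour) edge. Out-of-mask samples are excluded
#' from the mean and recorded as missing. MTU label features are one-hot
#' encoded per id, yielding per-MTU occupancy profiles in [0, 1].
#'
#' @param windows an oriented `window_set`.
#' @param channels H x W x C array of intensity features (or NULL).
#' @param mask 0/1 tissue mask.
#' @param mtu_labels optional integer label matrix ([assign_pixels()] result
#'   accepted); adds one occupancy feature per MTU id present.
#' @param channel_names optional names for the intensity features.
#' @return object of class `profile_matrix`: list with `values` (windows x
#'   positions x features array, NA = missing), `windows` (metadata
#'   data.frame), `features`, `positions`.
#' @export
extract_profiles <- function(windows, channels = NULL, mask, mtu_labels = NULL,
                             channel_names = NULL) {
  wpx <- attr(windows, "width_px"); lpx <- attr(windows, "length_px")
  if (inherits(mtu_labels, "mtu_label_image")) mtu_labels <- mtu_labels$labels
  if (!is.null(channels) && length(dim(channels)) == 2L)
    dim(channels) <- c(dim(channels), 1L)
  if (!is.null(channels) && !all(dim(channels)[1:2] == dim(mask)))
    stopf("channels and mask dimensions disagree")
  if (!is.null(mtu_labels) && !all(dim(mtu_labels) == dim(mask)))
    stopf("mtu_labels and mask dimensions disagree")
  C <- if (is.null(channels)) 0L else dim(channels)[3]
  if (C > 0 && is.null(channel_names))
    channel_names <- paste0("ch", seq_len(C))
  mtu_ids <- if (is.null(mtu_labels)) integer(0) else
    sort(setdiff(unique(as.integer(mtu_labels)), 0L))
  feats <- c(channel_names, if (length(mtu_ids)) paste0("mtu", mtu_ids))
  W <- nrow(windows)
  vals <- array(NA_real_, c(W, lpx, length(feats)),
                dimnames = list(NULL, NULL, feats))
  maskn <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))

  for (i in seq_len(W)) {
    g <- window_grid(c(windows$anchor_row[i], windows$anchor_col[i]),
                     windows$angle[i], wpx, lpx)
    r <- as.numeric(g$r); c_ <- as.numeric(g$c)
    valid <- nearest_sample(maskn, r, c_, outside = 0) > 0
    windows$valid_fraction[i] <- mean(valid)
    vmat <- matrix(valid, wpx, lpx)
    nv <- colSums(vmat)
    for (ch in seq_len(C)) {
      s <- matrix(bilinear_sample(channels[, , ch], r, c_), wpx, lpx)
      s[!vmat] <- 0
      prof <- ifelse(nv > 0, colSums(s) / nv, NA_real_)
      vals[i, , ch] <- prof
    }
    if (length(mtu_ids)) {
      lab <- matrix(nearest_sample(mtu_labels, r, c_, outside = 0), wpx, lpx)
      for (j in seq_along(mtu_ids)) {
        onehot <- (lab == mtu_ids[j]) * 1
        onehot[!vmat] <- 0
        vals[i, , C + j] <- ifelse(nv > 0, colSums(onehot) / nv, NA_real_)
      }
    }
  }
  structure(list(values = vals, windows = windows, features = feats,
                 positions = seq_len(lpx)),
            class = "profile_matrix")
}

#' Filter laminar windows by coverage and contour straightness
#'
#' Windows are kept only if strictly more than `min_valid` of their
#' footprint samples lie inside the mask. Optionally, windows anchored on a
#' straight contour span (maximum perpendicular deviation of the local
#' contour from its chord below `straightness_threshold`) are removed.
#'
#' @param pm a [extract_profiles()] result (carries the window set).
#' @param min_valid minimum in-mask fraction, exclusive (default 0.99).
#' @param straightness_threshold px; NULL (default) disables the filter.
#' @return filtered `profile_matrix`.
#' @export
filter_windows <- function(pm, min_valid = 0.99, straightness_threshold = NULL) {
  ws <- pm$windows
  keep <- ws$valid_fraction > min_valid & !ws$out_of_bounds
  n_low <- sum(!keep)
  n_straight <- 0L
  if (!is.null(straightness_threshold)) {
    contour <- attr(ws, "contour")
    wpx <- attr(ws, "width_px")
    straight <- vapply(seq_len(nrow(ws)), function(i) {
      contour_straightness(contour, ws$contour_index[i], span = wpx) <
        straightness_threshold
    }, logical(1))
    ws$straight_contour <- straight
    n_straight <- sum(straight & keep)
    keep <- keep & !straight
  }
  if (!any(keep))
    stopf("all windows removed (low coverage: %d, straight contour: %d)",
          n_low, n_straight)
  out <- pm
  out$values <- pm$values[keep, , , drop = FALSE]
  out$windows <- ws[keep, , drop = FALSE]
  for (a in c("width_px", "length_px", "pixel_size_um", "contour"))
    attr(out$windows, a) <- attr(ws, a)
  class(out$windows) <- class(ws)
  out
}

# max perpendicular deviation of the contour span centred at index i from
# its chord (px)
contour_straightness <- function(contour, i, span) {
  n <- nrow(contour) - 1L
  half <- max(2L, round(span / 2))
  idx <- ((i - 1L + seq(-half, half)) %% n) + 1L
  pts <- contour[idx, , drop = FALSE]
  a <- pts[1, ]; b <- pts[nrow(pts), ]
  chord <- b - a
  len <- sqrt(sum(chord^2))
  if (len == 0) return(0)
  d <- abs((pts[, 1] - a[1]) * chord[2] - (pts[, 2] - a[2]) * chord[1]) / len
  max(d)
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows of %d x %d px (%.2f x %.1f um)\n",
              nrow(x), attr(x, "width_px"), attr(x, "length_px"),
              window_extent_um(x)[1], window_extent_um(x)[2]))
  invisible(x)
}

#' @export
print.profile_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("profile_matrix: %d windows x %d positions x %d features\n",
              d[1], d[2], d[3]))
  invisible(x)
}
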