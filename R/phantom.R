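# Synthetic organoid phantom: a wobbled elliptical tissue section with
# depth-dependent channel intensities, ground-truth pixel classes, nuclei,
# and an analytic contour with inward normals. Every downstream stage of the
# package (masking, windows, profiles, trajectories, neighborhoods) can be
# validated against the closed-form fields generated here.

#' Specification of a synthetic organoid section
#'
#' Tissue is a filled ellipse whose polar radius is modulated by a
#' low-frequency sinusoid (so the contour is not trivially circular and
#' window orientation is non-degenerate). Channel intensity at a pixel of
#' normalized depth \eqn{d} (Euclidean distance to the boundary divided by
#' the section's maximum depth) is a sum of Gaussian layer profiles
#' \deqn{I_c(d) = \sum_l A_{c,l}(t)\, e^{-(d-\mu_l)^2 / (2 s_l^2)},}
#' where the per-channel amplitude \eqn{A_{c,l}(t)} interpolates linearly
#' between its `t = 0` and `t = 1` values with the maturation parameter
#' `maturation_t`. The default layer set is uniform (no lamination) at
#' `t = 0` and laminated — one dominant channel per layer — at `t = 1`,
#' emulating the progressive emergence of retinal layers over development.
#'
#' @param image_size integer (H, W), at least 128 x 128.
#' @param pixel_size_um microns per pixel (default 0.1625, a typical 40x
#'   high-NA acquisition).
#' @param n_channels number of stain channels.
#' @param maturation_t scalar in [0, 1]; 0 = immature/uniform, 1 = fully
#'   laminated.
#' @param layer_defs list of layers, each a list with `center` and `width`
#'   (normalized depth, in (0, 1]) and `amp0`, `amp1` (length-`n_channels`
#'   nonnegative amplitude vectors at t = 0 and t = 1). `NULL` for the
#'   default three-layer set.
#' @param shape list: `center` (row, col; default image centre), `radii`
#'   (col/row semi-axes in px; default 0.45/0.40 of the smaller image side),
#'   `wobble_amp` (relative radius modulation, default 0.05),
#'   `wobble_freq` (integer cycles, default 3), `wobble_phase` (radians).
#' @param nuclei list: `n` (count, default 60) and `radius` (px, default 3).
#' @param noise list: `sd` (Gaussian noise sd, default 0.02) and `poisson`
#'   (logical; add signal-scaled shot-like noise, default FALSE).
#' @param seed integer RNG seed; the section is a deterministic function of
#'   the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(256L, 256L),
                         pixel_size_um = 0.1625,
                         n_channels = 4L,
                         maturation_t = 0,
                         layer_defs = NULL,
                         shape = list(),
                         nuclei = list(n = 60L, radius = 3L),
                         noise = list(sd = 0.02, poisson = FALSE),
                         seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 128L))
    stopf("image_size must be (H, W) with both >= 128")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be positive")
  if (maturation_t < 0 || maturation_t > 1)
    stopf("maturation_t must lie in [0, 1]")
  if (is.null(layer_defs)) layer_defs <- default_layer_defs(n_channels)
  for (ld in layer_defs) {
    if (ld$center <= 0 || ld$center > 1 || ld$width <= 0 || ld$width > 1)
      stopf("layer center and width must lie in (0, 1]")
    if (length(ld$amp0) != n_channels || length(ld$amp1) != n_channels)
      stopf("layer amplitude vectors must have length n_channels")
    if (any(ld$amp0 < 0) || any(ld$amp1 < 0))
      stopf("layer amplitudes must be nonnegative")
  }
  shp <- utils::modifyList(list(
    center = (image_size + 1) / 2,
    radii = c(0.45, 0.40) * min(image_size),
    wobble_amp = 0.05, wobble_freq = 3L, wobble_phase = 0
  ), shape)
  nuc <- utils::modifyList(list(n = 60L, radius = 3L), nuclei)
  nz <- utils::modifyList(list(sd = 0.02, poisson = FALSE), noise)
  structure(list(
    image_size = image_size, pixel_size_um = pixel_size_um,
    n_channels = as.integer(n_channels), maturation_t = maturation_t,
    layer_defs = layer_defs, shape = shp, nuclei = nuc, noise = nz,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# three Gaussian layers; uniform at t = 0, one dominant channel per layer at
# t = 1 (extra channels get a depth-independent structural amplitude)
default_layer_defs <- function(n_channels) {
  centers <- c(0.2, 0.5, 0.8)
  lapply(seq_along(centers), function(l) {
    amp0 <- rep(0.5, n_channels)
    amp1 <- rep(0.05, n_channels)
    amp1[(l - 1L) %% n_channels + 1L] <- 1.0
    if (n_channels >= 4L) amp1[n_channels] <- 0.4  # structural channel
    list(center = centers[l], width = 0.12, amp0 = amp0, amp1 = amp1)
  })
}

# polar boundary radius of the generating shape at angle theta
phantom_radius <- function(shape, theta) {
  a <- shape$radii[1]; b <- shape$radii[2]
  re <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  re * (1 + shape$wobble_amp * sin(shape$wobble_freq * theta + shape$wobble_phase))
}

# amplitude matrix (layers x channels) at maturation t
layer_amplitudes <- function(layer_defs, t) {
  do.call(rbind, lapply(layer_defs, function(ld) (1 - t) * ld$amp0 + t * ld$amp1))
}

#' Generate a synthetic organoid section
#'
#' Deterministic given the spec (including its seed). The returned object
#' carries ground truth used by tests and oracles: the analytic contour,
#' normalized depth field, noise-free channel stack and pixel classes.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_section` with elements `channels`
#'   (H x W x C array, >= 0), `channels_clean` (noise-free), `mask` (0/1
#'   integer matrix), `depth` (normalized depth in [0, 1], 0 outside),
#'   `pixel_class` (integer ground-truth class image, 0 outside mask),
#'   `nuclei_centroids` (data.frame row/col), `nuclei_labels` (integer label
#'   image), `contour_truth` (closed polyline, columns row/col),
#'   `maturation_t`, `pixel_size_um`, `spec`.
#' @export
make_phantom_section <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ctr <- spec$shape$center
  rr <- matrix(seq_len(H), H, W) - ctr[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2]
  theta <- atan2(rr, cc)
  rho <- sqrt(rr^2 + cc^2)
  mask <- (rho <= phantom_radius(spec$shape, theta)) * 1L

  dpx <- as.numeric(EBImage::distmap(EBImage::Image(mask), metric = "euclidean"))
  dim(dpx) <- c(H, W)
  max_depth <- max(dpx)
  if (max_depth <= 0) stopf("degenerate phantom: empty mask")
  depth <- dpx / max_depth

  amps <- layer_amplitudes(spec$layer_defs, spec$maturation_t)  # L x C
  L <- nrow(amps)
  basis <- vapply(seq_len(L), function(l) {
    exp(-(depth - spec$layer_defs[[l]]$center)^2 /
          (2 * spec$layer_defs[[l]]$width^2))
  }, depth)                                                      # H x W x L
  dim(basis) <- c(H * W, L)

  clean <- basis %*% amps                                        # HW x C
  clean[mask == 0L, ] <- 0

  # ground-truth class: layer with the largest total (channel-summed)
  # contribution; 0 outside the mask
  contrib <- basis * rep(rowSums(amps), each = H * W)
  pixel_class <- max.col(contrib, ties.method = "first")
  pixel_class[mask == 0L] <- 0L
  dim(pixel_class) <- c(H, W)

  channels <- with_seed(spec$seed, {
    ch <- clean
    if (spec$noise$sd > 0)
      ch <- ch + stats::rnorm(length(ch), sd = spec$noise$sd)
    if (isTRUE(spec$noise$poisson))
      ch <- ch + stats::rnorm(length(ch), sd = sqrt(pmax(ch, 0)) * spec$noise$sd)
    ch[ch < 0] <- 0
    ch[mask == 0L, ] <- 0
    ch
  })
  dim(channels) <- c(H, W, spec$n_channels)
  dim(clean) <- c(H, W, spec$n_channels)

  nuc <- with_seed(spec$seed + 1L, place_phantom_nuclei(
    mask, dpx, n = spec$nuclei$n, radius = spec$nuclei$radius))

  th <- seq(0, 2 * pi, length.out = 2048L)
  R <- phantom_radius(spec$shape, th)
  contour_truth <- cbind(row = ctr[1] + R * sin(th), col = ctr[2] + R * cos(th))

  structure(list(
    channels = channels, channels_clean = clean, mask = mask,
    depth = depth, depth_px = dpx, max_depth_px = max_depth,
    pixel_class = pixel_class,
    nuclei_centroids = nuc$centroids, nuclei_labels = nuc$labels,
    contour_truth = contour_truth,
    maturation_t = spec$maturation_t, pixel_size_um = spec$pixel_size_um,
    channel_names = paste0("ch", seq_len(spec$n_channels)),
    spec = spec
  ), class = "phantom_section")
}

# rejection-sample non-overlapping nuclei disks fully inside the mask
place_phantom_nuclei <- function(mask, dpx, n, radius, max_attempts = 10000L) {
  H <- nrow(mask); W <- ncol(mask)
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centers) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stopf("could not place %d nuclei of radius %d in the mask after %d attempts",
            n, radius, max_attempts)
    r <- stats::runif(1, 1, H); c <- stats::runif(1, 1, W)
    ri <- round(r); ci <- round(c)
    if (dpx[ri, ci] <= radius) next           # disk would cross the boundary
    if (nrow(centers) > 0 &&
        min((centers[, 1] - r)^2 + (centers[, 2] - c)^2) <= (2 * radius)^2) next
    centers <- rbind(centers, c(r, c))
  }
  labels <- matrix(0L, H, W)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rs <- max(1L, floor(r0 - radius)):min(H, ceiling(r0 + radius))
    cs <- max(1L, floor(c0 - radius)):min(W, ceiling(c0 + radius))
    for (ci in cs) {
      inside <- (rs - r0)^2 + (ci - c0)^2 <= radius^2
      labels[rs[inside], ci] <- i
    }
  }
  list(centroids = data.frame(nucleus = seq_len(n),
                              row = centers[, 1], col = centers[, 2]),
       labels = labels)
}

#' Generate a maturation timecourse of phantom sections
#'
#' All specs must share layer definitions and have strictly increasing
#' `maturation_t`; each section receives an ordinal `timepoint` (0-based)
#' and a `timepoint_label`.
#'
#' @param specs list of [phantom_spec()] with strictly increasing
#'   `maturation_t` and identical `layer_defs`.
#' @return list of `phantom_section`, each with `$timepoint` set.
#' @export
make_phantom_timecourse <- function(specs) {
  if (inherits(specs, "phantom_spec")) specs <- list(specs)
  ts <- vapply(specs, function(s) s$maturation_t, numeric(1))
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stopf("maturation_t must be strictly increasing across the timecourse")
  ref <- specs[[1]]$layer_defs
  for (s in specs) if (!identical(s$layer_defs, ref))
    stopf("all specs in a timecourse must share layer_defs")
  sections <- lapply(seq_along(specs), function(i) {
    sec <- make_phantom_section(specs[[i]])
    sec$timepoint <- i - 1L
    sec$timepoint_label <- sprintf("t%02d", i - 1L)
    sec
  })
  sections
}

#' Analytic inward normal of the generating shape at a contour anchor
#'
#' Oracle for window orientation: finds the nearest point of the analytic
#' contour and returns the inward normal angle there (radians, measured from
#' the +col axis toward the +row axis).
#'
#' @param section a `phantom_section`.
#' @param anchor numeric (row, col); must lie within 5 px of the contour.
#' @return angle in radians.
#' @export
ground_truth_orientation <- function(section, anchor) {
  stopifnot(inherits(section, "phantom_section"))
  shape <- section$spec$shape
  ctr <- shape$center
  th0 <- atan2(anchor[1] - ctr[1], anchor[2] - ctr[2])
  # refine nearest contour point on a fine local angular grid
  th <- th0 + seq(-0.1, 0.1, length.out = 401L)
  R <- phantom_radius(shape, th)
  pr <- ctr[1] + R * sin(th); pc <- ctr[2] + R * cos(th)
  d2 <- (pr - anchor[1])^2 + (pc - anchor[2])^2
  i <- which.min(d2)
  if (sqrt(d2[i]) > 5) stopf("anchor is %.1f px from the contour (> 5 px)", sqrt(d2[i]))
  h <- 1e-5
  p <- function(t) {
    Rt <- phantom_radius(shape, t)
    c(ctr[1] + Rt * sin(t), ctr[2] + Rt * cos(t))
  }
  tang <- (p(th[i] + h) - p(th[i] - h)) / (2 * h)
  nrm <- c(-tang[2], tang[1])            # perpendicular
  to_center <- ctr - c(pr[i], pc[i])
  if (sum(nrm * to_center) < 0) nrm <- -nrm
  atan2(nrm[1], nrm[2])
}

#' @export
print.phantom_section <- function(x, ...) {
  cat(sprintf("phantom_section: %d x %d px, %d channels, t = %.2f, %d nuclei\n",
              nrow(x$mask), ncol(x$mask), dim(x$channels)[3],
              x$maturation_t, nrow(x$nuclei_centroids)))
  invisible(x)
}
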