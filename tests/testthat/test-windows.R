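# Laminar window machinery: tissue masking, contour extraction, distance
# maps, window placement/orientation, profile extraction and filtering.

disk_mask <- function(H, R, ctr = (H + 1) / 2) {
  rr <- matrix(seq_len(H), H, H); cc <- t(rr)
  ((rr - ctr)^2 + (cc - ctr)^2 <= R^2) * 1L
}

test_that("tissue mask recovers the phantom mask and is a single component", {
  sec <- small_section()
  m <- build_tissue_mask(sec$channels, dilation_radius = 2)
  jac <- sum(m & sec$mask) / sum(m | sec$mask)
  expect_gte(jac, 0.95)
  lab <- EBImage::bwlabel(EBImage::Image(m))
  expect_equal(max(lab), 1)
  expect_error(build_tissue_mask(array(0, c(64, 64, 1))), "constant")
})

test_that("contour length matches the closed form for a circle", {
  m <- disk_mask(512, 200)
  ct <- extract_contour(m, sigma = 10)
  arclen <- sum(sqrt(diff(ct[, 1])^2 + diff(ct[, 2])^2))
  expect_lt(abs(arclen - 2 * pi * 200) / (2 * pi * 200), 0.03)
  # closed and near the boundary: every point ~200 px from the centre
  expect_equal(ct[1, ], ct[nrow(ct), ])
  rad <- sqrt((ct[, 1] - 256.5)^2 + (ct[, 2] - 256.5)^2)
  expect_lt(max(abs(rad - 200)), 4)
  expect_error(extract_contour(m * 0L), "empty")
})

test_that("distance map matches the closed form on a disk", {
  m <- disk_mask(256, 100)
  raw <- distance_map(m, sigma = 0)
  # sigma = 0 reproduces the exact distance transform
  expect_equal(max(raw), 100, tolerance = 0.02)
  expect_true(all(raw[m == 0] == 0))
  # smoothing small relative to the disk shrinks the peak only slightly
  sm <- distance_map(m, sigma = 3)
  expect_lt(abs(max(sm) - 100) / 100, 0.05)
  # outside values below the centreline values
  expect_lt(max(sm[m == 0]), sm[128, 128])
})

test_that("windows are anchored on every stride-th contour coordinate", {
  sec <- small_section()
  ct <- extract_contour(sec$mask, sigma = 10)
  dm <- distance_map(sec$mask, sigma = 10)
  n <- nrow(ct) - 1
  ws <- place_windows(ct, dm, stride = 50, width_px = 20, length_px = 60)
  expect_equal(nrow(ws), length(seq(1, n, by = 50)))
  # anchors are contour coordinates
  expect_true(all(ws$anchor_row %in% ct[, 1]))
  expect_error(place_windows(ct, dm, stride = n + 10), "stride")
  # default geometry at the published pixel size spans 16.25 x 162.5 um
  ws_default <- place_windows(ct, dm, stride = 50)
  expect_equal(unname(window_extent_um(ws_default)),
               c(100 * 0.1625, 1000 * 0.1625))
})

test_that("orientation recovers analytic normals on circle and ellipse", {
  circ <- make_phantom_section(phantom_spec(
    image_size = c(192, 192), n_channels = 2, seed = 2,
    shape = list(radii = c(70, 70), wobble_amp = 0)))
  dm <- distance_map(circ$mask, sigma = 10)
  ct <- extract_contour(circ$mask, sigma = 10)
  ws <- place_windows(ct, dm, stride = 40, width_px = 20, length_px = 60)
  ws <- orient_windows(ws, dm)
  for (i in seq_len(nrow(ws))) {
    gt <- ground_truth_orientation(circ, c(ws$anchor_row[i], ws$anchor_col[i]))
    expect_lt(ang_diff(ws$angle[i], gt) * 180 / pi, 5)
  }
})

test_that("orientation equals an exhaustive scan and median error <= 3 deg", {
  sec <- small_section()
  dm <- distance_map(sec$mask, sigma = 10)
  ct <- extract_contour(sec$mask, sigma = 10)
  ws <- place_windows(ct, dm, stride = 60, width_px = 20, length_px = 60)
  ws_o <- orient_windows(ws, dm, full_circle = TRUE)
  errs <- numeric(nrow(ws))
  for (i in seq_len(nrow(ws))) {
    anchor <- c(ws$anchor_row[i], ws$anchor_col[i])
    # brute-force 0.5-degree scan over the full circle
    grid <- seq(-pi, pi, by = 0.5 * pi / 180)
    sc <- vapply(grid, function(a)
      laminator:::dt_score_at(dm, anchor, a, 20, 60), numeric(1))
    brute <- grid[which.max(sc)]
    expect_lt(ang_diff(ws_o$angle[i], brute) * 180 / pi, 0.51)
    gt <- ground_truth_orientation(sec, anchor)
    errs[i] <- ang_diff(ws_o$angle[i], gt) * 180 / pi
  }
  expect_lte(median(errs), 3)
})

test_that("rotating the section by 90 degrees rotates recovered angles", {
  sec <- small_section()
  dm0 <- distance_map(sec$mask, sigma = 10)
  ct0 <- extract_contour(sec$mask, sigma = 10)
  ws0 <- orient_windows(place_windows(ct0, dm0, stride = 80, width_px = 20,
                                      length_px = 60), dm0)
  mask_r <- rot90_mat(sec$mask)   # (r, c) -> (W - c + 1, r)
  dm_r <- distance_map(mask_r, sigma = 10)
  Wd <- ncol(sec$mask)
  for (i in seq_len(nrow(ws0))) {
    anchor_r <- c(Wd - ws0$anchor_col[i] + 1, ws0$anchor_row[i])
    ws_r <- ws0[i, , drop = FALSE]
    ws_r$anchor_row <- anchor_r[1]; ws_r$anchor_col <- anchor_r[2]
    ws_r$angle <- ws0$angle[i] - pi / 2
    for (a in c("width_px", "length_px")) attr(ws_r, a) <- attr(ws0, a)
    out <- orient_windows(ws_r, dm_r)
    expect_lt(ang_diff(out$angle, ws0$angle[i] - pi / 2) * 180 / pi, 1)
  }
})

test_that("profiles reproduce constant and depth-linear fields", {
  sec <- small_section_clean()
  dm <- distance_map(sec$mask, sigma = 10)
  ct <- extract_contour(sec$mask, sigma = 10)
  ws <- orient_windows(place_windows(ct, dm, stride = 40, width_px = 10,
                                     length_px = 40), dm)
  # constant image -> every profile position equals the constant
  const <- array(3.5, c(dim(sec$mask), 1))
  pm <- extract_profiles(ws, const, sec$mask)
  expect_equal(dim(pm$values)[2], 40)
  vals <- pm$values[, , 1]
  expect_lt(max(abs(vals[!is.na(vals)] - 3.5)), 1e-9)

  # depth-linear field: within the linear regime of the distance transform
  # (window ends before the medial axis) the profile is a unit-slope ramp
  lin <- array(sec$depth_px, c(dim(sec$mask), 1))
  pml <- extract_profiles(ws, lin, sec$mask)
  keep <- pml$windows$valid_fraction > 0.99
  expect_gt(sum(keep), 3)
  for (i in which(keep)) {
    prof <- pml$values[i, , 1]
    ramp <- seq(0, 39)            # depth increases 1 px per inward step
    rng <- max(prof) - min(prof)
    expect_lt(sqrt(mean((prof - (prof[1] + ramp))^2)) / rng, 0.02)
  }
})

test_that("one-hot MTU occupancy profiles sum to 1 where in-mask", {
  sec <- small_section()
  dm <- distance_map(sec$mask, sigma = 10)
  ct <- extract_contour(sec$mask, sigma = 10)
  ws <- orient_windows(place_windows(ct, dm, stride = 60, width_px = 10,
                                     length_px = 40), dm)
  lab <- (sec$pixel_class > 0) * sec$pixel_class  # integer labels
  pm <- extract_profiles(ws, channels = NULL, mask = sec$mask, mtu_labels = lab)
  occ <- pm$values
  sums <- apply(occ, c(1, 2), sum)
  full <- pm$windows$valid_fraction == 1
  expect_true(any(full))
  expect_lt(max(abs(sums[full, ] - 1)), 1e-9)
  expect_true(all(occ[!is.na(occ)] >= 0 & occ[!is.na(occ)] <= 1))
})

test_that("profile extraction is invariant to global translation", {
  sec <- small_section_clean()
  dm <- distance_map(sec$mask, sigma = 10)
  ct <- extract_contour(sec$mask, sigma = 10)
  ws <- orient_windows(place_windows(ct, dm, stride = 80, width_px = 10,
                                     length_px = 40), dm)
  img <- array(sec$channels[, , 1], c(dim(sec$mask), 1))
  pm0 <- extract_profiles(ws, img, sec$mask)
  # translate image, mask and anchors by (7, 11) on a larger canvas
  H <- nrow(sec$mask); W <- ncol(sec$mask)
  big_img <- array(0, c(H + 20, W + 20, 1))
  big_img[7 + seq_len(H), 11 + seq_len(W), 1] <- img[, , 1]
  big_mask <- matrix(0L, H + 20, W + 20)
  big_mask[7 + seq_len(H), 11 + seq_len(W)] <- sec$mask
  ws_t <- ws
  ws_t$anchor_row <- ws$anchor_row + 7
  ws_t$anchor_col <- ws$anchor_col + 11
  for (a in c("width_px", "length_px")) attr(ws_t, a) <- attr(ws, a)
  pm1 <- extract_profiles(ws_t, big_img, big_mask)
  expect_equal(pm0$values, pm1$values, tolerance = 1e-6)
})

test_that("window filtering applies the strict >99% coverage rule", {
  vf <- c(1, 1, 0.995, 0.99, 0.5, 0.2, 0)
  ws <- data.frame(window = 1:7, anchor_row = 1, anchor_col = 1, angle = 0,
                   contour_index = 1, valid_fraction = vf,
                   dt_score = 1, straight_contour = FALSE,
                   out_of_bounds = FALSE)
  attr(ws, "width_px") <- 10L; attr(ws, "length_px") <- 20L
  class(ws) <- c("window_set", "data.frame")
  pm <- laminator:::as_profile_matrix(array(1, c(7, 20, 1)), windows = ws)
  out <- filter_windows(pm)
  expect_equal(nrow(out$windows), 3)  # strictly greater than 0.99
  expect_equal(out$windows$valid_fraction, c(1, 1, 0.995))
  ws$valid_fraction <- rep(0.5, 7)
  pm_bad <- laminator:::as_profile_matrix(array(1, c(7, 20, 1)), windows = ws)
  expect_error(filter_windows(pm_bad), "all windows removed")
})

test_that("straightness filter drops windows on straight contour spans", {
  # a contour that is half straight line, half semicircle
  th <- seq(-pi / 2, pi / 2, length.out = 200)
  arc <- cbind(100 + 80 * sin(th), 100 + 80 * cos(th))
  line <- cbind(seq(180, 20, length.out = 200), 100 - 80)
  poly <- rbind(arc, line, arc[1, , drop = FALSE])
  straight_idx <- 300   # middle of the straight segment
  curved_idx <- 100     # middle of the arc
  expect_lt(laminator:::contour_straightness(poly, straight_idx, span = 40), 2)
  expect_gt(laminator:::contour_straightness(poly, curved_idx, span = 40), 2)
})
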