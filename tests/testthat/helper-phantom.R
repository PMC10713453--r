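# Shared phantom fixtures, built once per test run and cached. Sizes are
# kept small (192-256 px sections) so the whole suite stays fast while the
# geometry remains non-degenerate.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# a laminated wobbled-ellipse section (t = 1, default layers)
small_section <- function() fixture("small_section", {
  make_phantom_section(phantom_spec(
    image_size = c(192, 192), n_channels = 3, maturation_t = 1, seed = 7,
    shape = list(radii = c(80, 70), wobble_amp = 0.04)))
})

# the same section without noise (closed-form fields)
small_section_clean <- function() fixture("small_section_clean", {
  make_phantom_section(phantom_spec(
    image_size = c(192, 192), n_channels = 3, maturation_t = 1, seed = 7,
    noise = list(sd = 0), shape = list(radii = c(80, 70), wobble_amp = 0.04)))
})

# specs for a 5-point maturation timecourse at test scale
timecourse_specs <- function(n = 5, image_size = c(192, 192), seed0 = 100,
                             radii = c(80, 70)) {
  lapply(seq_len(n), function(i) phantom_spec(
    image_size = image_size, n_channels = 3,
    maturation_t = (i - 1) / max(n - 1, 1), seed = seed0 + i,
    shape = list(radii = radii, wobble_amp = 0.04)))
}

# per-section laminar profiles for the small timecourse (stride/window sized
# to the 192-px sections)
timecourse_profiles <- function() fixture("timecourse_profiles", {
  secs <- make_phantom_timecourse(timecourse_specs())
  pms <- lapply(secs, function(sec) {
    ct <- extract_contour(sec$mask, sigma = 10)
    dm <- distance_map(sec$mask, sigma = 10)
    ws <- place_windows(ct, dm, stride = 20, width_px = 20, length_px = 60)
    ws <- orient_windows(ws, dm)
    pm <- extract_profiles(ws, sec$channels, sec$mask,
                           channel_names = sec$channel_names)
    pm <- filter_windows(pm)
    pm$windows$section <- sprintf("s%d", sec$timepoint)
    pm$windows$timepoint <- sec$timepoint
    pm
  })
  list(sections = secs, pm = laminator:::bind_profile_matrices(pms))
})

# 4-class phantom: four ~equal-area depth bands, each tiled by overlapping
# same-signature sub-layers so pixel intensities are near-constant within a
# band; `class_of_layer` maps generator layer ids to the four bands
four_band_phantom <- function(seed = 11) {
  sig <- lapply(1:4, function(b) { s <- rep(0.05, 4); s[b] <- 1; s })
  bands <- list(seq(0.03, 0.11, by = 0.04), seq(0.17, 0.27, by = 0.05),
                seq(0.33, 0.47, by = 0.07), seq(0.54, 0.98, by = 0.11))
  layers <- list(); class_of_layer <- integer(0)
  for (b in 1:4) for (mu in bands[[b]]) {
    layers[[length(layers) + 1]] <- list(center = mu,
                                         width = 0.035 + 0.01 * (b - 1),
                                         amp0 = sig[[b]], amp1 = sig[[b]])
    class_of_layer <- c(class_of_layer, b)
  }
  spec <- phantom_spec(image_size = c(192, 192), n_channels = 4,
                       layer_defs = layers, noise = list(sd = 0.02),
                       seed = seed,
                       shape = list(radii = c(80, 70), wobble_amp = 0.04))
  sec <- make_phantom_section(spec)
  truth <- ifelse(sec$pixel_class > 0,
                  class_of_layer[pmax(sec$pixel_class, 1)], 0)
  dim(truth) <- dim(sec$pixel_class)
  list(section = sec, truth = truth)
}

# fitted MTU model on the four-band phantom (12 x 12 SOM at test scale)
four_band_model <- function() fixture("four_band_model", {
  ph <- four_band_phantom(seed = 11)
  px <- subsample_pixels(list(ph$section), factor = 6, seed = 12)
  cb <- fit_som(px, grid = c(12, 12), runs = 10, epochs = 20, seed = 13)
  model <- metacluster(cb, px, seed = 14)
  list(phantom = ph, px = px, codebook = cb, model = model)
})
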