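# Formats, manifests, configuration and the end-to-end pipeline. Images
# travel as TIFF (multi-page for channel stacks; 16-bit unsigned with a
# recorded intensity scale, so write -> read round trips are exact after the
# initial quantization), tables as UTF-8 delimited text, arrays as
# long-format TSV with a JSON sidecar describing the axes.

#' Write a section to disk as TIFFs plus a manifest row
#'
#' Channels are quantized to 16-bit with a per-stack intensity scale stored
#' in the manifest; mask, pixel-class and nuclei label images are written as
#' 16-bit label TIFFs; nuclei centroids as TSV.
#'
#' @param section a `phantom_section` (or compatible list).
#' @param dir output directory (created if needed).
#' @param section_id identifier used in file names.
#' @return data.frame with one manifest row (invisibly also writes
#'   `<id>_channels.tif`, `<id>_mask.tif`, `<id>_class.tif`,
#'   `<id>_nuclei.tif`, `<id>_centroids.tsv`).
#' @export
write_section <- function(section, dir, section_id = "s01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  C <- dim(section$channels)[3]
  scale <- max(section$channels, 1e-12)
  pages <- lapply(seq_len(C), function(ch)
    round(section$channels[, , ch] / scale * 65535) / 65535)
  p_ch <- file.path(dir, paste0(section_id, "_channels.tif"))
  tiff::writeTIFF(pages, p_ch, bits.per.sample = 16L)
  wlab <- function(m, suffix) {
    p <- file.path(dir, paste0(section_id, "_", suffix, ".tif"))
    if (max(m) > 65535) stopf("label image exceeds 16-bit range")
    tiff::writeTIFF(m / 65535, p, bits.per.sample = 16L)
    p
  }
  p_mask <- wlab(section$mask, "mask")
  p_class <- if (!is.null(section$pixel_class)) wlab(section$pixel_class, "class") else NA
  p_nuc <- if (!is.null(section$nuclei_labels)) wlab(section$nuclei_labels, "nuclei") else NA
  if (!is.null(section$nuclei_centroids))
    utils::write.table(section$nuclei_centroids,
                       file.path(dir, paste0(section_id, "_centroids.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  data.frame(
    section_id = section_id,
    sample_id = section_id,
    timepoint = if (!is.null(section$timepoint)) section$timepoint else 0L,
    timepoint_label = if (!is.null(section$timepoint_label))
      section$timepoint_label else "t00",
    pixel_size_um = section$pixel_size_um,
    intensity_scale = scale,
    channels_path = p_ch, mask_path = p_mask,
    class_path = p_class, nuclei_path = p_nuc,
    channel_names = paste(section$channel_names, collapse = ";"),
    maturation_t = if (!is.null(section$maturation_t)) section$maturation_t else NA,
    stringsAsFactors = FALSE
  )
}

#' Read a manifest table
#'
#' @param path TSV/CSV manifest with columns section_id, timepoint,
#'   pixel_size_um, channels_path, mask_path, channel_names (and optional
#'   intensity_scale, nuclei_path, class_path).
#' @return validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  req <- c("section_id", "timepoint", "pixel_size_um", "channels_path",
           "mask_path", "channel_names")
  miss <- setdiff(req, names(m))
  if (length(miss)) stopf("manifest lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(m$section_id)) stopf("duplicate section ids in manifest")
  if (any(m$pixel_size_um <= 0)) stopf("pixel_size_um must be positive")
  for (col in c("channels_path", "mask_path")) {
    bad <- m[[col]][!file.exists(m[[col]])]
    if (length(bad)) stopf("missing file(s): %s", paste(bad, collapse = ", "))
  }
  m
}

# read a 16-bit label TIFF back as an integer matrix
read_label_tiff <- function(path) {
  z <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(z), nrow(z), ncol(z))
}

#' Read one section from a manifest row
#'
#' @param row single-row data.frame (one manifest entry).
#' @return list with `channels` (H x W x C float array), `mask`,
#'   `nuclei_labels` / `pixel_class` (when present), `channel_names`,
#'   `section_id`, `timepoint`, `pixel_size_um`.
#' @export
read_section <- function(row) {
  pages <- tiff::readTIFF(row$channels_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- if (!is.null(row$intensity_scale)) row$intensity_scale else 1
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  channels <- array(NA_real_, c(H, W, length(pages)))
  for (ch in seq_along(pages)) channels[, , ch] <- pages[[ch]] * scale
  mask <- read_label_tiff(row$mask_path)
  if (!all(dim(mask) == c(H, W)))
    stopf("mask dimensions %dx%d do not match channels %dx%d in %s",
          nrow(mask), ncol(mask), H, W, row$section_id)
  out <- list(channels = channels, mask = mask,
              channel_names = strsplit(row$channel_names, ";")[[1]],
              section_id = row$section_id, timepoint = row$timepoint,
              pixel_size_um = row$pixel_size_um)
  for (fld in c("nuclei_path", "class_path")) {
    p <- row[[fld]]
    if (!is.null(p) && !is.na(p) && nzchar(p) && file.exists(p)) {
      lab <- read_label_tiff(p)
      if (!all(dim(lab) == c(H, W)))
        stopf("%s dimensions do not match channels in %s", fld, row$section_id)
      out[[sub("_path", "", fld)]] <- lab
    }
  }
  names(out)[names(out) == "nuclei"] <- "nuclei_labels"
  names(out)[names(out) == "class"] <- "pixel_class"
  out
}

#' Pipeline configuration with the published defaults
#'
#' Every tunable of the toolkit in one validated list: window geometry
#' (stride 100, 100 x 1000 px), mean-filter widths (20 profile / 15
#' trajectory / 25 average), downsample factor 2, 10 FFT components, SOM
#' 30 x 30 with 10 runs, Louvain k sweep, cluster-graph k = 4, maturation
#' quantile 0.05, KDE grid 200 with occupancy threshold 0.05, neighbourhood
#' radius 40 px, and the global seed that fans out to per-stage seeds.
#'
#' @param ... overrides of the defaults.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    subsample_factor = 1000L,
    som_grid = c(30L, 30L), som_runs = 10L, som_epochs = 20L,
    k_sweep = c(5L, 10L, 15L, 20L, 25L, 30L, 35L, 40L),
    louvain_resolution = 1,
    stride = 100L, width_px = 100L, length_px = 1000L,
    contour_sigma = 50, dmap_sigma = 25, dilation_radius = 5L,
    coarse_step = 2, refine_step = 0.5, search = 90, full_circle = FALSE,
    min_valid = 0.99, straightness_threshold = NULL,
    mean_window = 20L, downsample_factor = 2L, n_fft_components = 10L,
    n_dcs = 10L, k_local = 30L, k_umap = 15L,
    maturation_q = 0.05, graph_k = 4L,
    heatmap_low_q = 0.01, heatmap_high_q = 0.05,
    smooth_pt = 15L, smooth_avg = 25L,
    kde_grid = 200L, occupancy_threshold = 0.05,
    neighborhood_radius_px = 40L, density_kernel = c(100, 100)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$subsample_factor >= 1, cfg$stride >= 1,
            cfg$min_valid >= 0, cfg$min_valid <= 1)
  structure(cfg, class = "run_config")
}

# long-format TSV + JSON sidecar for a 3D profile array
write_profile_matrix <- function(pm, prefix) {
  d <- dim(pm$values)
  long <- data.frame(
    window = rep(seq_len(d[1]), times = d[2] * d[3]),
    position = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    feature = rep(pm$features, each = d[1] * d[2]),
    value = as.numeric(pm$values)
  )
  utils::write.table(long, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(axes = c("window", "position", "feature"), dim = d,
         features = pm$features,
         position_semantics = "1 = outer (contour) edge, increasing inward"),
    paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

write_matrix_tsv <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Run the full laminar phenotyping pipeline on a manifest
#'
#' Stages: reverse z-score normalization across sections (grouped by
#' timepoint), MTU model fit (reused from `mtu_model.json` in `out_dir` when
#' present) and per-section pixel assignment, contour / distance-map /
#' window placement and orientation, profile extraction and filtering,
#' profile normalization, smoothing, FFT distances, DISTATIS compromise and
#' aggregated log distance, diffusion pseudotime, per-timepoint clustering,
#' maturation scores and the timepoint-constrained cluster graph. All
#' numeric outputs are written as delimited text; the configuration and
#' per-stage seeds are echoed to the output directory.
#'
#' @param manifest data.frame (or path) as in [read_manifest()].
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(manifest, config = run_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = logf, append = TRUE)
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("pipeline start: %d sections, seed %d", nrow(manifest), config$seed)

  stage <- "read"
  res <- tryCatch({
    sections <- lapply(seq_len(nrow(manifest)),
                       function(i) read_section(manifest[i, ]))
    tps <- vapply(sections, function(s) as.character(s$timepoint), character(1))

    stage <- "normalize"
    norm <- reverse_zscore_normalize(lapply(sections, `[[`, "channels"), tps,
                                     masks = lapply(sections, `[[`, "mask"))
    for (i in seq_along(sections)) sections[[i]]$channels <- norm$images[[i]]
    log_line("normalized %d sections in %d timepoint groups",
             length(sections), length(unique(tps)))

    stage <- "mtu"
    model_path <- file.path(out_dir, "mtu_model.json")
    model <- load_mtu_model(model_path)
    if (is.null(model)) {
      px <- subsample_pixels(sections, factor = config$subsample_factor,
                             seed = stage_seed(config$seed, "subsample"))
      cb <- fit_som(px, grid = config$som_grid, runs = config$som_runs,
                    epochs = config$som_epochs,
                    seed = stage_seed(config$seed, "som"))
      model <- metacluster(cb, px, k_sweep = config$k_sweep,
                           resolution = config$louvain_resolution,
                           seed = stage_seed(config$seed, "metacluster"))
      save_mtu_model(model, model_path)
      log_line("fitted MTU model: %d MTUs, chosen k = %d (model saved)",
               model$n_mtus, model$chosen_k_neighbors)
    } else {
      log_line("reused MTU model from %s (%d MTUs)", model_path, model$n_mtus)
    }

    stage <- "windows"
    per_sec <- lapply(seq_along(sections), function(i) {
      sec <- sections[[i]]
      lab <- assign_pixels(sec$channels, model, sec$mask)
      dmap <- distance_map(sec$mask, sigma = config$dmap_sigma)
      contour <- extract_contour(sec$mask, sigma = config$contour_sigma)
      ws <- place_windows(contour, dmap, stride = config$stride,
                          width_px = config$width_px,
                          length_px = config$length_px,
                          pixel_size_um = sec$pixel_size_um)
      ws <- orient_windows(ws, dmap, coarse_step = config$coarse_step,
                           refine_step = config$refine_step,
                           search = config$search,
                           full_circle = config$full_circle)
      pm <- extract_profiles(ws, sec$channels, sec$mask, mtu_labels = lab,
                             channel_names = sec$channel_names)
      pm <- filter_windows(pm, min_valid = config$min_valid,
                           straightness_threshold = config$straightness_threshold)
      pm$windows$section <- sec$section_id
      pm$windows$timepoint <- sec$timepoint
      log_line("section %s: %d windows retained", sec$section_id,
               nrow(pm$windows))
      pm
    })

    stage <- "profiles"
    pm <- bind_profile_matrices(per_sec)
    pm <- normalize_profiles(pm)
    pm <- smooth_downsample(pm, mean_window = config$mean_window,
                            factor = config$downsample_factor)
    write_profile_matrix(pm, file.path(out_dir, "profiles"))

    stage <- "distances"
    ds <- fft_distance(pm, n_components = config$n_fft_components)
    cd <- distatis(ds)
    D_agg <- aggregate_log_distance(ds)
    write_matrix_tsv(cd$D_plus, file.path(out_dir, "compromise_distance.tsv"))

    stage <- "trajectory"
    dr <- diffusion_from_distance(D_agg, n_dcs = config$n_dcs,
                                  k_local = config$k_local)
    pt <- diffusion_pseudotime(dr, root = "auto",
                               timepoints = pm$windows$timepoint)
    cl <- cluster_windows_per_timepoint(dr, pm$windows$timepoint,
                                        k_umap = config$k_umap,
                                        resolution = config$louvain_resolution,
                                        seed = stage_seed(config$seed, "windows_cluster"))
    ms <- maturation_score(cd, pt, q = config$maturation_q)
    tp_order <- sort(unique(pm$windows$timepoint))
    cg <- build_cluster_graph(cl, tp_order, cd, k = config$graph_k,
                              seed = stage_seed(config$seed, "graph"))

    tab <- cbind(pm$windows[, c("section", "timepoint", "window",
                                "anchor_row", "anchor_col", "angle",
                                "valid_fraction")],
                 data.frame(pt = pt$pt, cluster = cl$labels,
                            maturation = ms$score,
                            umap1 = cl$embedding[, 1],
                            umap2 = cl$embedding[, 2]))
    dcs <- dr$components
    colnames(dcs) <- paste0("DC", seq_len(ncol(dcs)))
    utils::write.table(cbind(tab, dcs), file.path(out_dir, "windows.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cg$edges, file.path(out_dir, "cluster_graph_edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cg$nodes, file.path(out_dir, "cluster_graph_nodes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log_line("pipeline done: %d windows, %d clusters, root window %d",
             nrow(tab), nrow(cg$nodes), pt$root)
    list(model = model, profiles = pm, compromise = cd, diffusion = dr,
         pseudotime = pt, clustering = cl, maturation = ms, graph = cg,
         table = tab)
  }, error = function(e) {
    log_line("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}

# concatenate per-section profile matrices (shared features required)
bind_profile_matrices <- function(pms) {
  feats <- pms[[1]]$features
  P <- dim(pms[[1]]$values)[2]
  all_feats <- unique(unlist(lapply(pms, `[[`, "features")))
  vals <- array(0, c(sum(vapply(pms, function(p) dim(p$values)[1], integer(1))),
                     P, length(all_feats)),
                dimnames = list(NULL, NULL, all_feats))
  rows <- 0L
  meta <- list()
  for (p in pms) {
    n <- dim(p$values)[1]
    vals[rows + seq_len(n), , p$features] <- p$values
    w <- as.data.frame(p$windows)
    meta[[length(meta) + 1L]] <- w
    rows <- rows + n
  }
  common <- Reduce(intersect, lapply(meta, names))
  meta <- do.call(rbind, lapply(meta, function(w) w[common]))
  as_profile_matrix(vals, windows = meta, features = all_feats)
}

save_mtu_model <- function(model, path) {
  jsonlite::write_json(list(
    grid = model$codebook$grid,
    node_vectors = model$codebook$node_vectors,
    node_counts = model$codebook$node_counts,
    quantization_error = model$codebook$quantization_error,
    node_medians = model$node_medians,
    node_to_mtu = model$node_to_mtu,
    mtu_centroids = model$mtu_centroids,
    chosen_k_neighbors = model$chosen_k_neighbors,
    k_sweep = model$k_sweep,
    channel_names = model$channel_names
  ), path, digits = NA)
  invisible(path)
}

load_mtu_model <- function(path) {
  if (!file.exists(path)) return(NULL)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb <- structure(list(grid = j$grid, node_vectors = j$node_vectors,
                       node_counts = j$node_counts,
                       quantization_error = j$quantization_error,
                       channel_names = j$channel_names),
                  class = "som_codebook")
  structure(list(codebook = cb, node_medians = j$node_medians,
                 node_to_mtu = j$node_to_mtu,
                 n_mtus = max(j$node_to_mtu),
                 mtu_centroids = j$mtu_centroids,
                 chosen_k_neighbors = j$chosen_k_neighbors,
                 k_sweep = j$k_sweep, channel_names = j$channel_names),
            class = "mtu_model")
}
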