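# Nuclei features and radial cell-neighborhood analysis: per-nucleus
# intensity statistics, local density and radial distance, ring-wise radial
# intensity profiles around nuclei centroids (nuclear pixels masked out),
# and neighborhood clustering that reuses the profile-distance / diffusion /
# UMAP / Louvain chain.

#' Per-nucleus intensity and spatial features
#'
#' For every labelled nucleus: area, centroid, per-channel bottom 5th and
#' top 5th percentiles, median, mean and sum over member pixels; the mean
#' distance-map value under the nucleus (radial distance); and the local
#' density, i.e. the number of nuclei centroids (self included) inside an
#' axis-aligned ellipse kernel centred on the centroid.
#'
#' @param labels integer nuclei label matrix (0 = background).
#' @param channels H x W x C array co-registered with the labels.
#' @param dmap a [distance_map()] of the tissue mask (or any numeric matrix).
#' @param kernel ellipse bounding box in px, default c(100, 100) (semi-axes
#'   50 x 50).
#' @param channel_names optional channel names.
#' @return data.frame of class `nucleus_features`, one row per nucleus.
#' @export
nucleus_features <- function(labels, channels, dmap, kernel = c(100, 100),
                             channel_names = NULL) {
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  C <- dim(channels)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  if (length(ids) == 0) {
    out <- data.frame(nucleus = integer(0), row = numeric(0), col = numeric(0),
                      area = integer(0), radial_distance = numeric(0),
                      local_density = integer(0))
    return(structure(out, class = c("nucleus_features", "data.frame")))
  }
  idx <- which(labels > 0)
  l <- as.integer(labels[idx])
  rows <- ((idx - 1) %% nrow(labels)) + 1L
  cols <- ((idx - 1) %/% nrow(labels)) + 1L
  f <- factor(l, levels = ids)
  area <- as.integer(table(f))
  cen_r <- rowsum(rows, f) / area
  cen_c <- rowsum(cols, f) / area
  rad <- rowsum(as.numeric(dmap)[idx], f) / area

  out <- data.frame(nucleus = ids, row = as.numeric(cen_r),
                    col = as.numeric(cen_c), area = area,
                    radial_distance = as.numeric(rad),
                    local_density = NA_integer_)
  for (ch in seq_len(C)) {
    v <- channels[, , ch][idx]
    st <- vapply(split(v, f), function(x) {
      q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
      c(q[1], q[2], q[3], mean(x), sum(x))
    }, numeric(5))
    out[[paste0(channel_names[ch], "_p5")]] <- st[1, ]
    out[[paste0(channel_names[ch], "_median")]] <- st[2, ]
    out[[paste0(channel_names[ch], "_p95")]] <- st[3, ]
    out[[paste0(channel_names[ch], "_mean")]] <- st[4, ]
    out[[paste0(channel_names[ch], "_sum")]] <- st[5, ]
  }
  a <- kernel[1] / 2; b <- kernel[2] / 2
  for (i in seq_along(ids)) {
    out$local_density[i] <- sum(((out$row - out$row[i]) / a)^2 +
                                  ((out$col - out$col[i]) / b)^2 <= 1)
  }
  structure(out, class = c("nucleus_features", "data.frame"))
}

#' Radial intensity profiles around nuclei centroids
#'
#' For each nucleus and each ring r = 1..radius_px (rounded Euclidean pixel
#' distance from the centroid), the mean channel intensity over ring pixels
#' that are inside the image and do not belong to any nucleus (or, with
#' `exclude = "focal"`, only not to the focal nucleus). Rings with no
#' eligible pixels are missing (NA), not zero.
#'
#' @param nuclei a [nucleus_features()] result (or data.frame with `nucleus`,
#'   `row`, `col`).
#' @param channels H x W x C array.
#' @param labels integer nuclei label matrix used for masking.
#' @param radius_px neighbourhood radius in px (default 40; 6.5 um at
#'   0.1625 um/px).
#' @param exclude "all" (default) masks every nucleus, "focal" only the
#'   profiled one.
#' @return object of class `radial_profile_matrix` (also a
#'   `profile_matrix`): `values` is nuclei x rings x channels with NA for
#'   missing rings.
#' @export
radial_profiles <- function(nuclei, channels, labels, radius_px = 40L,
                            exclude = c("all", "focal"), channel_names = NULL) {
  exclude <- match.arg(exclude)
  stopifnot(radius_px >= 1)
  H <- dim(channels)[1]; W <- dim(channels)[2]; C <- dim(channels)[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  n <- nrow(nuclei)
  vals <- array(NA_real_, c(n, radius_px, C),
                dimnames = list(NULL, NULL, channel_names))
  off <- expand.grid(dr = -radius_px:radius_px, dc = -radius_px:radius_px)
  ring0 <- round(sqrt(off$dr^2 + off$dc^2))
  keep0 <- ring0 >= 1 & ring0 <= radius_px
  off <- off[keep0, ]; ring0 <- ring0[keep0]

  for (i in seq_len(n)) {
    r0 <- round(nuclei$row[i]); c0 <- round(nuclei$col[i])
    if (r0 < 1 || r0 > H || c0 < 1 || c0 > W)
      stopf("nucleus %d centroid lies outside the image", nuclei$nucleus[i])
    rr <- r0 + off$dr; cc <- c0 + off$dc
    inside <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    pix <- cbind(rr[inside], cc[inside])
    ring <- ring0[inside]
    lab <- labels[pix]
    ok <- if (exclude == "all") lab == 0L else lab != nuclei$nucleus[i]
    pix <- pix[ok, , drop = FALSE]; ring <- ring[ok]
    if (!length(ring)) next
    f <- factor(ring, levels = seq_len(radius_px))
    cnt <- as.integer(table(f))
    for (ch in seq_len(C)) {
      s <- tapply(channels[, , ch][pix], f, sum)   # NA for empty rings
      vals[i, , ch] <- ifelse(cnt > 0, as.numeric(s) / cnt, NA_real_)
    }
  }
  structure(list(values = vals,
                 windows = data.frame(window = seq_len(n),
                                      nucleus = nuclei$nucleus),
                 features = channel_names, positions = seq_len(radius_px),
                 radius_px = radius_px),
            class = c("radial_profile_matrix", "profile_matrix"))
}

#' Cluster radial neighbourhoods
#'
#' Chains the shared profile machinery: z-score / 0-1 normalization,
#' mean-filter smoothing and downsampling, per-channel FFT distances
#' averaged across channels, diffusion embedding, then a UMAP of the first
#' diffusion components and Louvain clustering of its kNN graph.
#'
#' @param rpm a [radial_profiles()] result.
#' @param mean_window,factor smoothing and downsampling (defaults 20, 2).
#' @param n_components FFT components (default 10).
#' @param n_dcs diffusion components (default 10).
#' @param k_umap UMAP / kNN neighbours (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param seed integer seed.
#' @return list of class `neighborhood_clustering`: `labels` (integer),
#'   `embedding` (n x 2), `distance` (aggregated), `diffusion`.
#' @export
neighborhood_clustering <- function(rpm, mean_window = 20L, factor = 2L,
                                    n_components = 10L, n_dcs = 10L,
                                    k_umap = 15L, resolution = 1, seed = 1L) {
  if (dim(rpm$values)[1] < 2) stopf("need at least 2 neighbourhoods")
  pm <- normalize_profiles(rpm, group_keys = character(0))
  pm <- smooth_downsample(pm, mean_window = mean_window, factor = factor)
  ds <- fft_distance(pm, n_components = n_components)
  D <- aggregate_mean_distance(ds)
  if (max(D) == 0) {                            # all profiles identical
    n <- nrow(D)
    return(structure(list(labels = rep(1L, n),
                          embedding = matrix(0, n, 2),
                          distance = D, diffusion = NULL),
                     class = "neighborhood_clustering"))
  }
  dr <- diffusion_from_distance(D, n_dcs = n_dcs, on_disconnected = "keep")
  n <- nrow(D)
  if (n < k_umap + 2L) {
    emb <- dr$components[, 1:2, drop = FALSE]
  } else {
    emb <- with_seed(stage_seed(seed, "nbhd_umap"),
                     uwot::umap(dr$components, n_neighbors = k_umap,
                                n_threads = 1, n_sgd_threads = 1))
  }
  g <- knn_graph(emb, k_umap)
  cm <- with_seed(stage_seed(seed, "nbhd_louvain"),
                  igraph::cluster_louvain(g, resolution = resolution))
  structure(list(labels = as.integer(igraph::membership(cm)),
                 embedding = emb, distance = D, diffusion = dr),
            class = "neighborhood_clustering")
}
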