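# Spatial correlation of nuclei-resolved features: weighted 2D kernel
# density estimation with an axis-aligned bivariate normal kernel on a fixed
# grid, an occupancy mask from the unweighted nuclei density, and Pearson
# correlations between masked density grids averaged across sections.

# normal-reference bandwidths per axis, matching the MASS::kde2d convention
# (bandwidth.nrd full width divided by 4 gives the kernel sd)
nrd_bandwidths <- function(rows, cols) {
  h <- c(MASS::bandwidth.nrd(rows), MASS::bandwidth.nrd(cols)) / 4
  if (any(h <= 0)) {
    fallback <- pmax(stats::sd(rows), stats::sd(cols), 1)
    h[h <= 0] <- fallback
  }
  h
}

#' Weighted 2D kernel density of a per-nucleus feature
#'
#' Each nucleus centroid contributes an axis-aligned bivariate normal kernel
#' scaled by its (nonnegative) feature value; negative features are shifted
#' to zero minimum (the shift is recorded). Bandwidths follow the normal
#' reference rule on the centroid coordinates. Each point kernel integrates
#' to its weight, so the grid Riemann sum approximates the total weight.
#'
#' @param centroids data.frame with `row`, `col` (>= 5 points).
#' @param weights per-nucleus feature values (default 1 = plain density).
#' @param grid_size grid resolution (default 200).
#' @param extent list(row = c(min, max), col = c(min, max)); default the
#'   centroid bounding box.
#' @param bandwidth optional c(row, col) kernel sds, overriding the normal
#'   reference rule.
#' @return object of class `density_grid`: `grid` (grid_size x grid_size),
#'   `row_at`, `col_at`, `bandwidth`, `extent`, `shift`.
#' @export
feature_density <- function(centroids, weights = NULL, grid_size = 200L,
                            extent = NULL, bandwidth = NULL) {
  n <- nrow(centroids)
  if (n < 5) stopf("need at least 5 nuclei for a density estimate")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  shift <- 0
  if (any(weights < 0)) {
    shift <- -min(weights)
    weights <- weights + shift
  }
  if (sum(weights) == 0) stopf("zero total weight")
  if (is.null(extent))
    extent <- list(row = range(centroids$row), col = range(centroids$col))
  if (is.null(bandwidth)) bandwidth <- nrd_bandwidths(centroids$row, centroids$col)
  gr <- seq(extent$row[1], extent$row[2], length.out = grid_size)
  gc <- seq(extent$col[1], extent$col[2], length.out = grid_size)
  ar <- outer(gr, centroids$row, function(g, p)
    stats::dnorm(g - p, sd = bandwidth[1]))        # grid x points
  ac <- outer(gc, centroids$col, function(g, p)
    stats::dnorm(g - p, sd = bandwidth[2]))
  grid <- ar %*% (weights * t(ac))                 # grid_size x grid_size
  structure(list(grid = grid, row_at = gr, col_at = gc,
                 bandwidth = bandwidth, extent = extent, shift = shift,
                 total_weight = sum(weights)),
            class = "density_grid")
}

#' Occupancy mask from nuclei positions
#'
#' Unweighted nuclei-position density on the same grid, rescaled to maximum
#' 1 and thresholded: cells with rescaled density strictly above `threshold`
#' are occupied.
#'
#' @param centroids data.frame with `row`, `col`.
#' @param grid_size,extent,bandwidth as in [feature_density()].
#' @param threshold occupancy threshold on the max-1 scale (default 0.05).
#' @return binary matrix (grid_size x grid_size) with attribute `density`.
#' @export
occupancy_mask <- function(centroids, grid_size = 200L, extent = NULL,
                           bandwidth = NULL, threshold = 0.05) {
  dg <- feature_density(centroids, weights = NULL, grid_size = grid_size,
                        extent = extent, bandwidth = bandwidth)
  dens <- dg$grid / max(dg$grid)
  mask <- (dens > threshold) * 1L
  attr(mask, "density") <- dens
  mask
}

#' Pearson correlation of two masked density grids
#'
#' Both grids are multiplied by the binary occupancy mask and correlated
#' over the masked cells.
#'
#' @param target,other [feature_density()] results on the same extent/grid.
#' @param mask binary occupancy grid.
#' @return Pearson r, or NA when a grid is constant under the mask.
#' @export
spatial_correlation <- function(target, other, mask) {
  a <- target$grid; b <- other$grid
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(mask)))
  cells <- mask > 0
  if (sum(cells) < 10) stopf("fewer than 10 masked grid cells")
  x <- (a * mask)[cells]; y <- (b * mask)[cells]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant density grid under the mask; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Rank features by mean spatial correlation with a target feature
#'
#' Computes per-section densities for every feature, correlates each with
#' the target feature's density under the section's occupancy mask, averages
#' r per feature across sections, and returns the ranking plus the top-n
#' positively and negatively correlated feature lists.
#'
#' @param sections list; each element a list with `centroids` (row/col
#'   data.frame) and `features` (named list or data.frame of per-nucleus
#'   values).
#' @param target name of the target feature.
#' @param grid_size,threshold KDE grid and occupancy threshold.
#' @param top_n list length (default 115).
#' @return object of class `spatial_correlation_table`: `per_section`
#'   (feature x section r), `mean_r` (sorted), `top_positive`,
#'   `top_negative`.
#' @export
rank_correlates <- function(sections, target, grid_size = 200L,
                            threshold = 0.05, top_n = 115L) {
  feat_names <- unique(unlist(lapply(sections, function(s) names(s$features))))
  if (!target %in% feat_names) stopf("target feature '%s' not found", target)
  rmat <- matrix(NA_real_, length(feat_names), length(sections),
                 dimnames = list(feat_names, NULL))
  for (si in seq_along(sections)) {
    s <- sections[[si]]
    if (!target %in% names(s$features)) next
    mask <- occupancy_mask(s$centroids, grid_size = grid_size,
                           threshold = threshold)
    tg <- feature_density(s$centroids, s$features[[target]],
                          grid_size = grid_size)
    for (f in names(s$features)) {
      og <- feature_density(s$centroids, s$features[[f]],
                            grid_size = grid_size)
      r <- tryCatch(spatial_correlation(tg, og, mask),
                    warning = function(w) NA_real_)
      rmat[f, si] <- r
    }
  }
  mean_r <- sort(rowMeans(rmat, na.rm = TRUE), decreasing = TRUE)
  pos <- names(mean_r)[mean_r > 0]
  neg <- rev(names(mean_r)[mean_r < 0])
  structure(list(per_section = rmat, mean_r = mean_r,
                 top_positive = utils::head(pos, top_n),
                 top_negative = utils::head(neg, top_n)),
            class = "spatial_correlation_table")
}
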