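# Multiplexed tissue units (MTUs): pixel-level clustering of multichannel
# intensity images. Normalized pixels are subsampled, summarised by a batch
# self-organizing map, the SOM node medians are metaclustered with a
# kNN-graph / Louvain sweep whose neighbourhood size is chosen at the knee
# of the (k, n_clusters) curve, and all pixels are assigned to the nearest
# metacluster centroid.

#' Reverse z-score normalization of channel stacks
#'
#' Harmonizes images within (timepoint, channel) groups while preserving
#' group-level differences: each image channel is z-scored by its own mean
#' and sd, then rescaled by the pooled group sd and recentred at the pooled
#' group mean ("reverse z-scoring"); finally every channel is scaled so the
#' global 1st percentile maps to 0 and the 99th to 1, clipped to [0, 1].
#'
#' @param images list of H x W x C numeric arrays (one per section).
#' @param timepoints vector of timepoint labels, one per image.
#' @param masks optional list of 0/1 matrices; when given, group statistics
#'   and percentiles are computed over in-mask pixels only.
#' @param channel_names optional channel names (default ch1..chC).
#' @return list with `images` (normalized stacks), `stats` (list of
#'   `groups` and `percentiles` data.frames), and `flagged` (images passed
#'   through unchanged because their sd was zero).
#' @export
reverse_zscore_normalize <- function(images, timepoints, masks = NULL,
                                     channel_names = NULL) {
  stopifnot(length(images) == length(timepoints))
  C <- dim(images[[1]])[3]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(C))
  pix <- function(i, ch) {
    v <- images[[i]][, , ch]
    if (!is.null(masks)) v <- v[masks[[i]] > 0]
    as.numeric(v)
  }
  tps <- unique(timepoints)
  groups <- expand.grid(timepoint = tps, channel = seq_len(C),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  groups$mean <- NA_real_; groups$sd <- NA_real_
  out <- lapply(images, function(x) array(NA_real_, dim(x)))
  flagged <- character(0)

  for (g in seq_len(nrow(groups))) {
    tp <- groups$timepoint[g]; ch <- groups$channel[g]
    idx <- which(timepoints == tp)
    pooled <- unlist(lapply(idx, pix, ch = ch))
    m_g <- mean(pooled); s_g <- stats::sd(pooled)
    if (!is.finite(s_g) || s_g == 0)
      stopf("zero pooled variance in group (timepoint=%s, channel=%s)",
            tp, channel_names[ch])
    groups$mean[g] <- m_g; groups$sd[g] <- s_g
    for (i in idx) {
      v <- images[[i]][, , ch]
      ref <- pix(i, ch)
      m_i <- mean(ref); s_i <- stats::sd(ref)
      if (!is.finite(s_i) || s_i == 0) {
        out[[i]][, , ch] <- v
        flagged <- c(flagged, sprintf("image %d channel %d", i, ch))
      } else {
        out[[i]][, , ch] <- (v - m_i) / s_i * s_g + m_g
      }
    }
  }

  pct <- data.frame(channel = channel_names, p1 = NA_real_, p99 = NA_real_)
  for (ch in seq_len(C)) {
    pooled <- unlist(lapply(seq_along(out), function(i) {
      v <- out[[i]][, , ch]
      if (!is.null(masks)) v <- v[masks[[i]] > 0]
      as.numeric(v)
    }))
    q <- stats::quantile(pooled, c(0.01, 0.99), names = FALSE)
    pct$p1[ch] <- q[1]; pct$p99[ch] <- q[2]
    span <- if (q[2] > q[1]) q[2] - q[1] else 1
    for (i in seq_along(out)) {
      v <- (out[[i]][, , ch] - q[1]) / span
      out[[i]][, , ch] <- pmin(pmax(v, 0), 1)
    }
  }
  list(images = out,
       stats = list(groups = groups, percentiles = pct),
       flagged = unique(flagged))
}

#' Subsample in-mask pixels into a training matrix
#'
#' Draws `floor(n_in_mask / factor)` pixels per section without replacement
#' (all of them, in scan order, when `factor = 1`) and concatenates them
#' into a pixels x channels matrix with per-row provenance.
#'
#' @param sections list; each element needs `channels` (H x W x C array),
#'   `mask` (0/1 matrix) and optionally `section_id`.
#' @param factor integer subsampling factor >= 1.
#' @param seed integer seed; the draw is deterministic per seed.
#' @param channel_names optional channel names.
#' @return object of class `pixel_matrix`: list with `values`, `provenance`
#'   (section, row, col) and `channel_names`.
#' @export
subsample_pixels <- function(sections, factor = 1000L, seed = 1L,
                             channel_names = NULL) {
  stopifnot(factor >= 1)
  vals <- list(); prov <- list()
  for (i in seq_along(sections)) {
    sec <- sections[[i]]
    id <- if (!is.null(sec$section_id)) sec$section_id else sprintf("s%02d", i)
    in_mask <- which(sec$mask > 0)
    if (length(in_mask) == 0) stopf("section %s has no in-mask pixels", id)
    n_take <- floor(length(in_mask) / factor)
    if (n_take < 1) stopf("section %s: factor %d leaves no pixels", id, factor)
    take <- if (factor == 1L) in_mask else
      with_seed(stage_seed(seed, paste0("subsample_", id)),
                sort(sample(in_mask, n_take)))
    H <- nrow(sec$mask)
    C <- dim(sec$channels)[3]
    m <- vapply(seq_len(C),
                function(ch) sec$channels[, , ch][take], numeric(length(take)))
    vals[[i]] <- matrix(m, ncol = C)
    prov[[i]] <- data.frame(section = id,
                            row = ((take - 1) %% H) + 1L,
                            col = ((take - 1) %/% H) + 1L)
  }
  values <- do.call(rbind, vals)
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(sections[[1]]$channel_names))
      sections[[1]]$channel_names else paste0("ch", seq_len(ncol(values)))
  }
  colnames(values) <- channel_names
  structure(list(values = values, provenance = do.call(rbind, prov),
                 channel_names = channel_names),
            class = "pixel_matrix")
}

# one batch-SOM training run; returns codebook and quantization error
som_single_run <- function(x, grid, epochs, seed) {
  m <- prod(grid)
  gpos <- cbind(rep(seq_len(grid[1]), grid[2]),
                rep(seq_len(grid[2]), each = grid[1]))
  gd2 <- cross_dist2(gpos, gpos)
  cb <- with_seed(seed, x[sample(nrow(x), m), , drop = FALSE])
  radii <- seq(max(grid) / 2, 0.5, length.out = epochs)
  bmu <- NULL
  for (e in seq_len(epochs)) {
    d2 <- cross_dist2(x, cb)
    bmu <- max.col(-d2, ties.method = "first")
    Hn <- exp(-gd2 / (2 * radii[e]^2))           # m x m neighbourhood kernel
    cnt <- tabulate(bmu, nbins = m)
    S <- matrix(0, m, ncol(x))
    sums <- rowsum(x, bmu)
    S[as.integer(rownames(sums)), ] <- sums
    num <- Hn %*% S
    den <- as.numeric(Hn %*% cnt)
    upd <- den > 0
    cb[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  d2 <- cross_dist2(x, cb)
  bmu <- max.col(-d2, ties.method = "first")
  qe <- mean(sqrt(d2[cbind(seq_len(nrow(x)), bmu)]))
  list(codebook = cb, bmu = bmu, qe = qe)
}

#' Fit a self-organizing map codebook to a pixel matrix
#'
#' Batch SOM on a rectangular grid with a Gaussian neighbourhood whose
#' radius decays linearly over epochs. `runs` independent initializations
#' (seeds `seed .. seed + runs - 1`) are trained and the codebook with the
#' lowest quantization error (mean Euclidean distance to the best-matching
#' node) is kept.
#'
#' @param x a [subsample_pixels()] result or plain numeric matrix.
#' @param grid SOM grid shape, default c(30, 30).
#' @param runs number of restarts, default 10.
#' @param epochs batch epochs per run, default 20.
#' @param seed integer seed.
#' @return object of class `som_codebook`: `grid`, `node_vectors`
#'   (nodes x channels), `node_counts`, `quantization_error`, `seed`.
#' @export
fit_som <- function(x, grid = c(30L, 30L), runs = 10L, epochs = 20L, seed = 1L) {
  mat <- if (inherits(x, "pixel_matrix")) x$values else as.matrix(x)
  m <- prod(grid)
  if (nrow(mat) < m)
    stopf("need at least %d training pixels for a %d x %d grid; use a smaller grid",
          m, grid[1], grid[2])
  best <- NULL
  for (r in seq_len(runs)) {
    fit <- som_single_run(mat, grid, epochs, seed + r - 1L)
    if (is.null(best) || fit$qe < best$qe) best <- fit
  }
  structure(list(grid = as.integer(grid),
                 node_vectors = best$codebook,
                 node_counts = tabulate(best$bmu, nbins = m),
                 quantization_error = best$qe,
                 channel_names = colnames(mat),
                 seed = as.integer(seed)),
            class = "som_codebook")
}

#' Kneedle knee/elbow locator for a decreasing convex curve
#'
#' Normalizes both axes to [0, 1], flips the decreasing convex curve to a
#' concave increasing one, and scans the difference-to-diagonal curve for
#' local maxima: the first local maximum followed by a drop below its
#' sensitivity threshold is the knee. A flat curve returns the first x; an
#' unconfirmed candidate falls back to the global maximum of the difference
#' curve.
#'
#' @param x,y numeric vectors (x increasing).
#' @param sensitivity Kneedle sensitivity S (default 1).
#' @return the x value at the knee.
#' @export
kneedle <- function(x, y, sensitivity = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  o <- order(x); x <- x[o]; y <- y[o]
  if (max(y) == min(y)) return(x[1])
  xn <- (x - min(x)) / (max(x) - min(x))
  yn <- (y - min(y)) / (max(y) - min(y))
  d <- (1 - yn) - xn
  n <- length(d)
  slack <- sensitivity * mean(diff(xn))
  for (i in 2:(n - 1)) {
    if (d[i] < d[i - 1] || d[i] < d[i + 1]) next   # not a local maximum
    threshold <- d[i] - slack
    for (j in (i + 1):n) {
      if (j < n && d[j] > d[j - 1]) break           # rising again: next candidate
      if (d[j] < threshold) return(x[i])            # knee confirmed
    }
  }
  x[which.max(d)]
}

#' Metacluster SOM nodes into multiplexed tissue units
#'
#' Per-node channel medians over assigned training pixels (empty nodes keep
#' their codebook vector) are clustered for each k in `k_sweep` with a
#' k-nearest-neighbour graph and Louvain community detection; the final k is
#' selected at the knee of the (k, n_clusters) curve. MTU ids are relabelled
#' in order of decreasing member pixel count (1 = largest).
#'
#' @param codebook a [fit_som()] result.
#' @param training the `pixel_matrix` used for training.
#' @param k_sweep integer vector of neighbourhood sizes (>= 3 values).
#' @param resolution Louvain resolution (default 1).
#' @param jaccard weight graph edges by Jaccard overlap of neighbour sets
#'   (default FALSE: unweighted).
#' @param seed integer seed (Louvain vertex-order randomization).
#' @return object of class `mtu_model`: `codebook`, `node_medians`,
#'   `node_to_mtu`, `n_mtus`, `mtu_centroids`, `chosen_k_neighbors`,
#'   `k_sweep` (data.frame k, n_clusters).
#' @export
metacluster <- function(codebook, training,
                        k_sweep = c(5L, 10L, 15L, 20L, 25L, 30L, 35L, 40L),
                        resolution = 1, jaccard = FALSE, seed = 1L) {
  if (length(k_sweep) < 3) stopf("k_sweep needs >= 3 values (knee undefined)")
  mat <- if (inherits(training, "pixel_matrix")) training$values else as.matrix(training)
  m <- nrow(codebook$node_vectors)
  d2 <- cross_dist2(mat, codebook$node_vectors)
  bmu <- max.col(-d2, ties.method = "first")
  med <- codebook$node_vectors
  counts <- tabulate(bmu, nbins = m)
  for (j in which(counts > 0))
    med[j, ] <- apply(mat[bmu == j, , drop = FALSE], 2, stats::median)

  cluster_at_k <- function(k) {
    k <- min(k, m - 1L)
    nn <- RANN::nn2(med, k = k + 1L)$nn.idx[, -1, drop = FALSE]
    el <- cbind(rep(seq_len(m), k), as.integer(nn))
    g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
    w <- NULL
    if (jaccard) {
      w <- igraph::similarity(g, method = "jaccard")
      e <- igraph::as_edgelist(g, names = FALSE)
      w <- w[cbind(e[, 1], e[, 2])]
    }
    with_seed(stage_seed(seed, paste0("louvain_k", k)),
              igraph::cluster_louvain(g, weights = w, resolution = resolution))
  }

  comms <- lapply(k_sweep, cluster_at_k)
  n_clusters <- vapply(comms, function(cm) length(unique(igraph::membership(cm))),
                       integer(1))
  chosen_k <- kneedle(k_sweep, n_clusters)
  membership <- igraph::membership(comms[[which(k_sweep == chosen_k)[1]]])
  membership <- as.integer(membership)

  # relabel by decreasing member pixel count
  sizes <- vapply(seq_len(max(membership)),
                  function(cl) sum(counts[membership == cl]), numeric(1))
  remap <- integer(max(membership))
  remap[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
  node_to_mtu <- remap[membership]
  n_mtus <- max(node_to_mtu)
  centroids <- do.call(rbind, lapply(seq_len(n_mtus), function(cl)
    colMeans(med[node_to_mtu == cl, , drop = FALSE])))
  colnames(centroids) <- colnames(codebook$node_vectors)

  structure(list(codebook = codebook, node_medians = med,
                 node_to_mtu = node_to_mtu, n_mtus = n_mtus,
                 mtu_centroids = centroids,
                 chosen_k_neighbors = chosen_k,
                 k_sweep = data.frame(k = k_sweep, n_clusters = n_clusters),
                 channel_names = codebook$channel_names),
            class = "mtu_model")
}

# nearest-centroid labels for a pixels x channels matrix; ties -> lowest id
assign_matrix <- function(model, x) {
  d2 <- cross_dist2(x, model$mtu_centroids)
  max.col(-d2, ties.method = "first")
}

#' Assign every in-mask pixel to its nearest MTU centroid
#'
#' @param channels H x W x C array (same channel order as the model).
#' @param model an [metacluster()] result.
#' @param mask 0/1 matrix; out-of-mask pixels get label 0.
#' @return object of class `mtu_label_image`: integer `labels` matrix plus
#'   `n_mtus`.
#' @export
assign_pixels <- function(channels, model, mask) {
  C <- dim(channels)[3]
  if (C != ncol(model$mtu_centroids))
    stopf("channel mismatch: image has %d channels, model expects %d",
          C, ncol(model$mtu_centroids))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask > 0)
  if (length(idx)) {
    x <- vapply(seq_len(C), function(ch) channels[, , ch][idx],
                numeric(length(idx)))
    labels[idx] <- assign_matrix(model, matrix(x, ncol = C))
  }
  structure(list(labels = labels, n_mtus = model$n_mtus),
            class = "mtu_label_image")
}

#' Per-MTU mean channel intensities and pixel counts
#'
#' @param label an [assign_pixels()] result (or integer label matrix).
#' @param channels H x W x C array co-registered with the labels.
#' @return data.frame: mtu, pixel count, one mean column per channel.
#' @export
mtu_summary <- function(label, channels) {
  labels <- if (inherits(label, "mtu_label_image")) label$labels else label
  stopifnot(all(dim(labels) == dim(channels)[1:2]))
  idx <- which(labels > 0)
  l <- labels[idx]
  C <- dim(channels)[3]
  x <- vapply(seq_len(C), function(ch) channels[, , ch][idx], numeric(length(idx)))
  f <- factor(l, levels = sort(unique(l)))
  sums <- rowsum(matrix(x, ncol = C), f)
  n <- as.integer(table(f))
  out <- data.frame(mtu = as.integer(levels(f)), count = n, sums / n)
  names(out)[-(1:2)] <- paste0("mean_ch", seq_len(C))
  out
}

#' @export
print.mtu_model <- function(x, ...) {
  cat(sprintf("mtu_model: %d MTUs from a %d x %d SOM (chosen k = %d)\n",
              x$n_mtus, x$codebook$grid[1], x$codebook$grid[2],
              x$chosen_k_neighbors))
  invisible(x)
}
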