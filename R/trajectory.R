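# Laminar windows, stage 3: diffusion embedding of the aggregated window
# distance, diffusion pseudotime from a root window, per-timepoint UMAP +
# Louvain clustering, the maturation score from compromise distances, and
# the timepoint-constrained cluster graph.

#' Diffusion embedding of a window distance matrix
#'
#' Gaussian kernel with local bandwidths (sigma_i = distance to the
#' `k_local`-th neighbour), density-normalized with alpha = 1, symmetrically
#' normalized and eigendecomposed. The trivial constant component is
#' dropped; returned components are the diffusion-map coordinates scaled by
#' their eigenvalues.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param n_dcs number of diffusion components (default 10).
#' @param k_local neighbour index for the local bandwidth (default 30,
#'   automatically reduced to floor(W/4) for small W).
#' @param on_disconnected "error" (default) aborts with the kernel-graph
#'   component sizes when the Gaussian kernel underflows to exact zeros
#'   between groups of items; "keep" proceeds anyway — the embedding still
#'   separates the components (used for pure clustering, where no pseudotime
#'   will be computed across components).
#' @return object of class `diffusion_result`: `eigenvalues` (descending,
#'   trivial one removed), `components` (W x n_dcs, eigenvalue-scaled),
#'   `psi` (unscaled coordinates), `k_local`.
#' @export
diffusion_from_distance <- function(D, n_dcs = 10L, k_local = 30L,
                                    on_disconnected = c("error", "keep")) {
  on_disconnected <- match.arg(on_disconnected)
  W <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stopf("distance matrix must be symmetric")
  k_local <- min(k_local, max(2L, floor(W / 4)))
  n_dcs <- min(n_dcs, W - 1L)
  sig <- apply(D, 1, function(r) sort(r)[k_local + 1L])  # k-th neighbour (excl. self)
  sig[sig <= 0] <- min(sig[sig > 0], 1e-12)
  K <- exp(-D^2 / tcrossprod(sig))
  q <- rowSums(K)
  K1 <- K / tcrossprod(q)                      # density normalization, alpha = 1
  d <- rowSums(K1)
  A <- K1 / tcrossprod(sqrt(d))                # symmetric normalized operator
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- eg$values
  # connectivity of the kernel support graph: tight but connected kernels
  # can push lambda_2 against 1, so disconnection is decided on the support,
  # not the spectrum
  g <- igraph::graph_from_adjacency_matrix(K > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1 && on_disconnected == "error")
    stopf("kernel graph is disconnected (component sizes: %s)",
          paste(comp$csize, collapse = ", "))
  phi <- eg$vectors / sqrt(d)                  # right eigenvectors of the kernel
  phi <- phi / rep(sqrt(colSums(phi^2)), each = W)
  keep <- 1L + seq_len(n_dcs)
  structure(list(eigenvalues = lam[keep],
                 components = phi[, keep, drop = FALSE] *
                   rep(lam[keep], each = W),
                 psi = phi[, keep, drop = FALSE],
                 k_local = k_local, n_dcs = n_dcs,
                 connected = comp$no == 1),
            class = "diffusion_result")
}

#' Diffusion pseudotime from a root window
#'
#' Euclidean distance from the root in the diffusion space rescaled by
#' lambda / (1 - lambda), min-max normalized to [0, 1] (so pt[root] = 0).
#' With `root = "auto"`, the root is the window of the earliest timepoint
#' with the most extreme first diffusion component.
#'
#' @param dr a [diffusion_from_distance()] result.
#' @param root window index, or "auto".
#' @param timepoints optional per-window timepoints (used by "auto").
#' @return object of class `pseudotime_result`: `pt` in [0, 1], `root`.
#' @export
diffusion_pseudotime <- function(dr, root = "auto", timepoints = NULL) {
  lam <- dr$eigenvalues
  if (isFALSE(dr$connected))
    stopf("unit eigenvalue in the non-trivial spectrum (disconnected kernel)")
  # eigenvalues numerically against 1 (tight, connected kernels) are clamped
  # so the rescaling weights stay finite
  lam <- pmin(lam, 1 - 1e-12)
  Z <- dr$psi * rep(lam / (1 - lam), each = nrow(dr$psi))
  W <- nrow(Z)
  if (identical(root, "auto")) {
    cand <- seq_len(W)
    if (!is.null(timepoints)) {
      tp0 <- sort(unique(timepoints))[1]
      cand <- which(timepoints == tp0)
    }
    dc1 <- Z[, 1]
    root <- cand[which.max(abs(dc1[cand] - stats::median(dc1)))]
  }
  stopifnot(root >= 1, root <= W)
  pt <- sqrt(rowSums((Z - rep(Z[root, ], each = W))^2))
  rng <- range(pt)
  pt <- if (diff(rng) > 0) (pt - rng[1]) / diff(rng) else pt * 0
  structure(list(pt = pt, root = as.integer(root), method = "diffusion distance"),
            class = "pseudotime_result")
}

# kNN graph (RANN) on an embedding -> igraph, for Louvain
knn_graph <- function(x, k) {
  n <- nrow(x)
  k <- min(k, n - 1L)
  nn <- RANN::nn2(x, k = k + 1L)$nn.idx[, -1, drop = FALSE]
  el <- cbind(rep(seq_len(n), k), as.integer(nn))
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}

#' Cluster laminar windows per timepoint on UMAP embeddings
#'
#' For each timepoint, a 2D UMAP of the first `n_dcs` diffusion components
#' of that timepoint's windows is computed and Louvain communities are found
#' on its `k_umap`-nearest-neighbour graph. Subsets smaller than
#' `k_umap + 1` windows get a single cluster (with a warning).
#'
#' @param dr a [diffusion_from_distance()] result.
#' @param timepoints per-window timepoint labels.
#' @param k_umap UMAP / kNN neighbours (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param seed integer seed.
#' @return object of class `window_clustering`: `labels` (character,
#'   "<tp>.<cluster>"), `embedding` (W x 2), `params`.
#' @export
cluster_windows_per_timepoint <- function(dr, timepoints, k_umap = 15L,
                                          resolution = 1, seed = 1L) {
  W <- nrow(dr$components)
  stopifnot(length(timepoints) == W)
  labels <- character(W)
  emb <- matrix(NA_real_, W, 2)
  for (tp in sort(unique(timepoints))) {
    idx <- which(timepoints == tp)
    if (length(idx) < k_umap + 1L) {
      warning(sprintf("timepoint %s has %d windows (< k_umap + 1); single cluster",
                      tp, length(idx)))
      labels[idx] <- paste0(tp, ".1")
      emb[idx, ] <- 0
      next
    }
    X <- dr$components[idx, , drop = FALSE]
    e <- with_seed(stage_seed(seed, paste0("umap_", tp)),
                   uwot::umap(X, n_neighbors = k_umap, n_threads = 1,
                              n_sgd_threads = 1))
    g <- knn_graph(e, k_umap)
    cm <- with_seed(stage_seed(seed, paste0("louvain_", tp)),
                    igraph::cluster_louvain(g, resolution = resolution))
    labels[idx] <- paste0(tp, ".", igraph::membership(cm))
    emb[idx, ] <- e
  }
  structure(list(labels = labels, embedding = emb,
                 timepoints = timepoints,
                 params = list(k_umap = k_umap, resolution = resolution,
                               seed = seed)),
            class = "window_clustering")
}

#' Maturation score from compromise distances and pseudotime
#'
#' The mean compromise distance of each window to the earliest pseudotime
#' quantile set minus its mean distance to the latest, min-max scaled to
#' [-1, 1]: -1 = most start-like, +1 = most end-like.
#'
#' @param cd a [distatis()] result (or a plain W x W distance matrix).
#' @param pt a [diffusion_pseudotime()] result (or numeric vector).
#' @param q quantile defining the start/end sets (default 0.05).
#' @param end_set optional explicit end-set indices (e.g. reference adult
#'   windows), overriding the upper quantile.
#' @return object of class `maturation_scores`: `score` in [-1, 1], `q`,
#'   `start_set`, `end_set`.
#' @export
maturation_score <- function(cd, pt, q = 0.05, end_set = NULL) {
  D <- if (inherits(cd, "compromise_distance")) cd$D_plus else as.matrix(cd)
  p <- if (inherits(pt, "pseudotime_result")) pt$pt else as.numeric(pt)
  stopifnot(length(p) == nrow(D))
  start_set <- which(p <= stats::quantile(p, q))
  if (is.null(end_set)) end_set <- which(p >= stats::quantile(p, 1 - q))
  raw <- rowMeans(D[, start_set, drop = FALSE]) -
    rowMeans(D[, end_set, drop = FALSE])
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("all windows equidistant from start and end sets; scores set to 0")
    score <- raw * 0
  } else {
    score <- 2 * (raw - rng[1]) / diff(rng) - 1
  }
  structure(list(score = score, q = q, start_set = start_set,
                 end_set = end_set),
            class = "maturation_scores")
}

#' Timepoint-constrained cluster graph with force-directed layout
#'
#' Candidate edges join cluster pairs from the same or adjacent timepoints
#' (in the declared order); edge weight is the mean compromise distance over
#' all inter-cluster window pairs. Each node keeps its `k` smallest-weight
#' allowed edges; the union is symmetrized and laid out force-directed with
#' attraction proportional to 1/weight.
#'
#' @param clustering a [cluster_windows_per_timepoint()] result.
#' @param timepoint_order vector giving the timepoint order.
#' @param cd a [distatis()] result or W x W distance matrix.
#' @param k edges kept per node (default 4).
#' @param seed layout seed.
#' @return object of class `cluster_graph`: `nodes` (timepoint, cluster,
#'   size, layout x/y), `edges` (from, to, weight).
#' @export
build_cluster_graph <- function(clustering, timepoint_order, cd, k = 4L,
                                seed = 1L) {
  D <- if (inherits(cd, "compromise_distance")) cd$D_plus else as.matrix(cd)
  labs <- clustering$labels
  tps <- clustering$timepoints
  nodes <- unique(data.frame(label = labs, timepoint = tps,
                             stringsAsFactors = FALSE))
  if (nrow(nodes) < 2) stopf("need at least 2 clusters to build a graph")
  nodes$size <- vapply(nodes$label, function(l) sum(labs == l), integer(1))
  nodes$tp_ord <- match(nodes$timepoint, timepoint_order)
  if (anyNA(nodes$tp_ord)) stopf("timepoint missing from timepoint_order")
  n <- nrow(nodes)

  wmat <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(nodes$tp_ord[i] - nodes$tp_ord[j]) > 1) next
    wi <- which(labs == nodes$label[i]); wj <- which(labs == nodes$label[j])
    wmat[i, j] <- wmat[j, i] <- mean(D[wi, wj])
  }
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- which(!is.na(wmat[i, ]))
    if (!length(cand)) next
    best <- cand[order(wmat[i, cand])][seq_len(min(k, length(cand)))]
    keep[i, best] <- TRUE
  }
  keep <- keep | t(keep)                       # symmetrize by union
  ii <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- data.frame(from = nodes$label[ii[, 1]], to = nodes$label[ii[, 2]],
                      weight = wmat[ii])
  stopifnot(all(abs(nodes$tp_ord[ii[, 1]] - nodes$tp_ord[ii[, 2]]) <= 1))

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$label)
  w_lay <- if (nrow(edges)) 1 / (edges$weight + 1e-12) else NULL
  lay <- with_seed(stage_seed(seed, "cluster_graph_layout"),
                   igraph::layout_with_fr(g, weights = w_lay))
  nodes$x <- lay[match(nodes$label, igraph::V(g)$name), 1]
  nodes$y <- lay[match(nodes$label, igraph::V(g)$name), 2]
  iso <- setdiff(nodes$label, unique(c(edges$from, edges$to)))
  if (length(iso))
    message(sprintf("%d isolated cluster node(s): %s", length(iso),
                    paste(iso, collapse = ", ")))
  structure(list(nodes = nodes[, c("label", "timepoint", "size", "x", "y")],
                 edges = edges, k = k),
            class = "cluster_graph")
}

#' Pseudotime-ordered, quantile-scaled trajectory heat map
#'
#' Windows are ordered by pseudotime; each feature is clipped and scaled
#' between its lower 1% and upper 5% quantiles across all values, then
#' mean-filtered along the pseudotime axis at every inner-outer position.
#'
#' @param pm a `profile_matrix`.
#' @param pt a [diffusion_pseudotime()] result or numeric vector.
#' @param feature feature name or index.
#' @param low_q,high_q scaling quantiles (defaults 0.01 and 0.05 upper, i.e.
#'   0.95 on the value scale).
#' @param smooth_pt mean-filter width along the pseudotime axis (default 15).
#' @return positions x windows matrix in [0, 1] (attribute `order` gives the
#'   pseudotime ordering of the columns).
#' @export
render_trajectory_heatmap <- function(pm, pt, feature = 1L,
                                      low_q = 0.01, high_q = 0.05,
                                      smooth_pt = 15L) {
  if (low_q < 0 || high_q < 0 || 1 - high_q <= low_q)
    stopf("invalid scaling quantiles: upper (1 - %.3f) must exceed lower (%.3f)",
          high_q, low_q)
  p <- if (inherits(pt, "pseudotime_result")) pt$pt else as.numeric(pt)
  f <- if (is.character(feature)) match(feature, pm$features) else feature
  x <- pm$values[, , f]                        # windows x positions
  lo <- stats::quantile(x, low_q, na.rm = TRUE)
  hi <- stats::quantile(x, 1 - high_q, na.rm = TRUE)
  x <- if (hi > lo) pmin(pmax((x - lo) / (hi - lo), 0), 1) else
    array(0.5, dim(x))                         # constant feature
  ord <- order(p)
  x <- x[ord, , drop = FALSE]
  sm <- apply(x, 2, moving_mean, width = smooth_pt)   # along pseudotime
  out <- t(sm)                                 # positions x windows
  attr(out, "order") <- ord
  out
}

#' Position-averaged trajectory profile
#'
#' Mean intensity across the inner-outer axis per window, ordered by
#' pseudotime and mean-filtered along the trajectory.
#'
#' @inheritParams render_trajectory_heatmap
#' @param smooth_avg mean-filter width along pseudotime (default 25).
#' @return numeric vector, one value per window in pseudotime order.
#' @export
trajectory_average_profile <- function(pm, pt, feature = 1L, smooth_avg = 25L) {
  p <- if (inherits(pt, "pseudotime_result")) pt$pt else as.numeric(pt)
  f <- if (is.character(feature)) match(feature, pm$features) else feature
  avg <- rowMeans(pm$values[, , f], na.rm = TRUE)
  moving_mean(avg[order(p)], smooth_avg)
}
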