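# Laminar windows, stage 2: profile normalization and smoothing, FFT-based
# per-feature window distances, the DISTATIS compromise across features, and
# the aggregated log-distance used for diffusion analysis.

# construct a bare profile_matrix from an array (used by tests and by the
# neighborhood module)
as_profile_matrix <- function(values, windows = NULL, features = NULL) {
  if (is.null(features)) features <- dimnames(values)[[3]]
  if (is.null(features)) features <- paste0("f", seq_len(dim(values)[3]))
  if (is.null(windows))
    windows <- data.frame(window = seq_len(dim(values)[1]))
  structure(list(values = values, windows = windows, features = features,
                 positions = seq_len(dim(values)[2])),
            class = "profile_matrix")
}

#' Reverse z-score and 0-1 scale window profiles
#'
#' Missing positions are first imputed from the nearest valid position of
#' the same profile. Per feature, each window profile is z-scored by its own
#' mean/sd and rescaled by the pooled sd/mean of its (section, timepoint)
#' group — the same reverse z-scoring contract as
#' [reverse_zscore_normalize()] with windows in place of images — then the
#' feature is min-max scaled to [0, 1] across all windows. A zero-variance
#' feature is set to 0.5 everywhere and flagged.
#'
#' @param pm a `profile_matrix`.
#' @param group_keys character vector of columns of `pm$windows` defining
#'   the normalization groups (default those of "section" and "timepoint"
#'   that exist; a single group if neither does).
#' @return normalized `profile_matrix` (attribute `constant_features` lists
#'   flagged features).
#' @export
normalize_profiles <- function(pm, group_keys = NULL) {
  v <- pm$values
  W <- dim(v)[1]; P <- dim(v)[2]; FF <- dim(v)[3]
  if (is.null(group_keys))
    group_keys <- intersect(c("section", "timepoint"), names(pm$windows))
  grp <- if (length(group_keys) == 0) rep(1L, W) else
    as.integer(interaction(pm$windows[group_keys], drop = TRUE))

  # impute missing positions from the nearest valid position
  for (i in seq_len(W)) for (f in seq_len(FF)) {
    x <- v[i, , f]
    na <- which(is.na(x))
    if (!length(na)) next
    ok <- which(!is.na(x))
    if (!length(ok)) stopf("window %d has no valid samples for feature %d", i, f)
    nearest <- vapply(na, function(p) ok[which.min(abs(ok - p))], integer(1))
    x[na] <- x[nearest]
    v[i, , f] <- x
  }

  constant <- character(0)
  for (f in seq_len(FF)) {
    xf <- v[, , f, drop = FALSE]
    dim(xf) <- c(W, P)
    for (g in unique(grp)) {
      rows <- which(grp == g)
      pooled <- as.numeric(xf[rows, ])
      m_g <- mean(pooled); s_g <- stats::sd(pooled)
      if (!is.finite(s_g) || s_g == 0) next   # group passed through
      for (i in rows) {
        m_i <- mean(xf[i, ]); s_i <- stats::sd(xf[i, ])
        if (is.finite(s_i) && s_i > 0)
          xf[i, ] <- (xf[i, ] - m_i) / s_i * s_g + m_g
      }
    }
    rng <- range(xf)
    if (diff(rng) == 0) {
      xf[] <- 0.5
      constant <- c(constant, pm$features[f])
    } else {
      xf <- (xf - rng[1]) / diff(rng)
    }
    v[, , f] <- xf
  }
  out <- pm
  out$values <- v
  attr(out, "constant_features") <- constant
  out
}

#' Smooth and downsample window profiles
#'
#' Centered moving mean along the inner-outer axis (windows shortened at the
#' edges) followed by keeping every `factor`-th position.
#'
#' @param pm a `profile_matrix` (no missing values).
#' @param mean_window moving-mean width in positions (default 20).
#' @param factor downsampling factor (default 2).
#' @return `profile_matrix` with `ceiling(P / factor)` positions.
#' @export
smooth_downsample <- function(pm, mean_window = 20L, factor = 2L) {
  P <- dim(pm$values)[2]
  if (mean_window > P)
    stopf("mean_window (%d) exceeds profile length (%d)", mean_window, P)
  keep <- seq(1L, P, by = factor)
  W <- dim(pm$values)[1]; FF <- dim(pm$values)[3]
  out <- array(NA_real_, c(W, length(keep), FF),
               dimnames = list(NULL, NULL, pm$features))
  for (i in seq_len(W)) for (f in seq_len(FF))
    out[i, , f] <- moving_mean(pm$values[i, , f], mean_window)[keep]
  res <- pm
  res$values <- out
  res$positions <- pm$positions[keep]
  res
}

#' Per-feature FFT distances between window profiles
#'
#' Profiles are discrete-Fourier transformed; the distance between two
#' windows for a feature is the Euclidean norm of the difference of their
#' first `n_components` complex coefficients (DC term included).
#'
#' @param pm a `profile_matrix` without missing values.
#' @param n_components number of frequency components compared (default 10).
#' @return object of class `feature_distance_set`: named list of symmetric
#'   W x W matrices, one per feature.
#' @export
fft_distance <- function(pm, n_components = 10L) {
  v <- pm$values
  W <- dim(v)[1]; P <- dim(v)[2]; FF <- dim(v)[3]
  if (anyNA(v)) stopf("profiles contain missing values; normalize first")
  if (n_components > P)
    stopf("n_components (%d) exceeds available components (%d)", n_components, P)
  out <- vector("list", FF)
  names(out) <- pm$features
  for (f in seq_len(FF)) {
    co <- stats::mvfft(t(matrix(v[, , f], W, P)))[seq_len(n_components), ,
                                                  drop = FALSE]
    reim <- rbind(Re(co), Im(co))              # 2k x W
    d <- as.matrix(stats::dist(t(reim)))
    dimnames(d) <- NULL
    out[[f]] <- d
  }
  structure(out, class = "feature_distance_set")
}

#' DISTATIS compromise of per-feature distance matrices
#'
#' Standard three-way MDS construction: each distance matrix is squared and
#' double-centred with uniform masses into a cross-product matrix, which is
#' normalized by its first eigenvalue; the RV-coefficient matrix between the
#' normalized cross-products is eigendecomposed and its first eigenvector
#' (rescaled to sum 1) weights the compromise cross-product, from which the
#' compromise distance is back-transformed.
#'
#' @param ds a [fft_distance()] result (or named list of symmetric
#'   nonnegative matrices of equal size).
#' @return object of class `compromise_distance`: `D_plus` (W x W),
#'   `S_plus`, `alpha` (per-feature weights summing to 1), `rv_matrix`.
#' @export
distatis <- function(ds) {
  mats <- unclass(ds)
  if (length(mats) < 2) stopf("DISTATIS needs at least 2 feature distance matrices")
  W <- nrow(mats[[1]])
  for (m in mats) {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stopf("distance matrices must be symmetric")
    if (nrow(m) != W) stopf("all distance matrices must share dimensions")
  }
  Cmat <- diag(W) - matrix(1 / W, W, W)
  S <- lapply(mats, function(D) {
    Sf <- -0.5 * Cmat %*% (D^2) %*% t(Cmat)
    l1 <- eigen((Sf + t(Sf)) / 2, symmetric = TRUE, only.values = TRUE)$values[1]
    if (l1 <= 0) stopf("degenerate cross-product matrix (first eigenvalue <= 0)")
    Sf / l1
  })
  K <- length(S)
  rv <- matrix(1, K, K, dimnames = list(names(mats), names(mats)))
  tr <- function(a, b) sum(a * b)              # trace(A B) for symmetric A, B
  for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
    rv[i, j] <- tr(S[[i]], S[[j]]) / sqrt(tr(S[[i]], S[[i]]) * tr(S[[j]], S[[j]]))
  ev <- eigen((rv + t(rv)) / 2, symmetric = TRUE)
  a <- ev$vectors[, 1]
  if (sum(a) < 0) a <- -a
  if (any(a < -1e-8))
    warning("first RV eigenvector has negative entries; clipping to 0")
  a <- pmax(a, 0)
  alpha <- a / sum(a)
  names(alpha) <- names(mats)
  S_plus <- Reduce(`+`, Map(`*`, S, alpha))
  d2 <- outer(diag(S_plus), diag(S_plus), "+") - 2 * S_plus
  if (any(d2 < -1e-8)) warning("negative squared compromise distances clamped at 0")
  D_plus <- sqrt(pmax(d2, 0))
  diag(D_plus) <- 0
  structure(list(D_plus = D_plus, S_plus = S_plus, alpha = alpha,
                 rv_matrix = rv),
            class = "compromise_distance")
}

#' Aggregate per-feature distances on a log scale
#'
#' Mean over features of `log10(D_f + 1)`; the input to diffusion analysis
#' of laminar-window heterogeneity.
#'
#' @param ds a [fft_distance()] result.
#' @return symmetric W x W matrix with zero diagonal.
#' @export
aggregate_log_distance <- function(ds) {
  mats <- unclass(ds)
  out <- Reduce(`+`, lapply(mats, function(D) log10(D + 1))) / length(mats)
  diag(out) <- 0
  out
}

#' Aggregate per-feature distances by their mean
#'
#' Plain mean of the per-feature distance matrices (used for radial
#' neighbourhood distances, where distances are averaged across features
#' without a log transform).
#'
#' @param ds a [fft_distance()] result.
#' @return symmetric W x W matrix with zero diagonal.
#' @export
aggregate_mean_distance <- function(ds) {
  mats <- unclass(ds)
  out <- Reduce(`+`, mats) / length(mats)
  diag(out) <- 0
  out
}

#' @export
print.compromise_distance <- function(x, ...) {
  cat(sprintf("compromise_distance: %d windows, %d features (alpha: %s)\n",
              nrow(x$D_plus), length(x$alpha),
              paste(sprintf("%.3f", x$alpha), collapse = ", ")))
  invisible(x)
}
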