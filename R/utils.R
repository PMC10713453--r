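# Shared low-level helpers: coordinate convention is 1-based (row, col) with
# pixel centres at integer coordinates; angles are measured from the +col
# axis toward the +row axis (radians).

#' Bilinear interpolation of an image at subpixel coordinates
#'
#' @param img numeric matrix.
#' @param r,c numeric vectors of row/col coordinates (1-based, equal length).
#' @param outside value returned for samples outside the image (default 0).
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(img, r, c, outside = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(as.numeric(outside), length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * nr
  v <- (1 - fr) * (1 - fc) * img[i00] +
    fr * (1 - fc) * img[i00 + 1] +
    (1 - fr) * fc * img[i00 + nr] +
    fr * fc * img[i00 + nr + 1]
  out[ok] <- v
  out
}

#' Nearest-neighbour sampling of an image at subpixel coordinates
#' @inheritParams bilinear_sample
#' @keywords internal
nearest_sample <- function(img, r, c, outside = 0) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- round(r); ci <- round(c)
  out <- rep(as.numeric(outside), length(r))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & is.finite(ri) & is.finite(ci)
  out[ok] <- img[cbind(ri[ok], ci[ok])]
  out
}

#' Centered moving mean with edge truncation
#'
#' Windows are shortened near the boundaries so no positions are lost.
#' @param x numeric vector.
#' @param width window size in samples.
#' @keywords internal
moving_mean <- function(x, width) {
  n <- length(x)
  if (width <= 1L) return(x)
  half_lo <- floor((width - 1) / 2)
  half_hi <- ceiling((width - 1) / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Pairwise squared Euclidean distances between rows of two matrices
#' @keywords internal
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stable string hash of the stage name folded into the global seed, kept
#' below 2^31 so it is a valid R integer.
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# internal assertion with sprintf-style message
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Otsu threshold of a numeric image
#'
#' Thin wrapper around [EBImage::otsu()] that tolerates arbitrary dynamic
#' range by rescaling to [0, 1] first.
#' @param img numeric matrix.
#' @param levels histogram resolution.
#' @return threshold on the original intensity scale.
#' @keywords internal
otsu_level <- function(img, levels = 256L) {
  rng <- range(img, finite = TRUE)
  if (diff(rng) == 0) stopf("cannot threshold a constant image")
  scaled <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = levels)
  rng[1] + th * diff(rng)
}

#' Spearman rank correlation
#' @keywords internal
spearman <- function(x, y) stats::cor(x, y, method = "spearman")
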