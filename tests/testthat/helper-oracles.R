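# Independent oracles used across tests. These deliberately use different
# code paths (explicit loops, naive formulas) than the implementation.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# naive O(n^2) discrete Fourier transform, first k complex components
naive_dft <- function(x, k) {
  n <- length(x)
  vapply(seq_len(k) - 1L, function(f) {
    sum(x * exp(-2i * pi * f * (seq_len(n) - 1L) / n))
  }, complex(1))
}

# brute-force per-pixel normalized depth histogram of a channel: mean
# intensity in depth bins (oracle for radial profile peaks)
depth_profile_oracle <- function(section, channel, n_bins = 50) {
  in_m <- section$mask > 0
  d <- section$depth[in_m]
  v <- section$channels[, , channel][in_m]
  bins <- cut(d, breaks = seq(0, 1, length.out = n_bins + 1), include.lowest = TRUE)
  tapply(v, bins, mean)
}

# angular difference folded to [0, pi]
ang_diff <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))

# brute-force weighted KDE: double loop over points x grid nodes
kde_oracle <- function(rows, cols, w, gr, gc, h) {
  out <- matrix(0, length(gr), length(gc))
  for (i in seq_along(gr)) for (j in seq_along(gc)) {
    out[i, j] <- sum(w * dnorm(gr[i] - rows, sd = h[1]) *
                       dnorm(gc[j] - cols, sd = h[2]))
  }
  out
}

# rotate a matrix by 90 degrees counter-clockwise in (row, col) axes
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]
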