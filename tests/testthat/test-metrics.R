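# Profile normalization, smoothing/downsampling, FFT distances, DISTATIS
# compromise and log-distance aggregation.

toy_pm <- function(values) laminator:::as_profile_matrix(values)

test_that("profile normalization preserves group stats and flags constants", {
  set.seed(5)
  v <- array(rnorm(6 * 40 * 2, 5, 2), c(6, 40, 2))
  v[, , 2] <- v[, , 2] + rep(c(0, 4), each = 3 * 40)  # group offset
  pm <- toy_pm(v)
  pm$windows$section <- rep(c("a", "b"), each = 3)
  pm$windows$timepoint <- 1
  out <- normalize_profiles(pm)
  expect_true(all(out$values >= 0 & out$values <= 1))
  # two identical windows stay identical
  v2 <- v; v2[2, , ] <- v2[1, , ]
  pm2 <- toy_pm(v2); pm2$windows$section <- "a"; pm2$windows$timepoint <- 1
  out2 <- normalize_profiles(pm2)
  expect_identical(out2$values[1, , ], out2$values[2, , ])
  # independent accumulation: per-window mean/sd of the reverse z-scored
  # profiles equal the pooled group stats (checked pre 0-1 scaling by
  # rebuilding the transform for one feature)
  f <- 1
  for (g in c("a", "b")) {
    rows <- which(pm$windows$section == g)
    pooled <- as.numeric(v[rows, , f])
    m_g <- mean(pooled); s_g <- sd(pooled)
    for (i in rows) {
      x <- v[i, , f]
      inter <- (x - mean(x)) / sd(x) * s_g + m_g
      expect_lt(abs(mean(inter) - m_g), 1e-9)
      expect_lt(abs(sd(inter) - s_g), 1e-9)
    }
  }
  # constant feature -> 0.5 and flagged
  vc <- v; vc[, , 1] <- 2
  outc <- normalize_profiles(toy_pm(vc))
  expect_true(all(outc$values[, , 1] == 0.5))
  expect_equal(attr(outc, "constant_features"), "f1")
  # missing values are imputed from the nearest valid position
  vm <- v; vm[1, 1:3, 1] <- NA
  outm <- normalize_profiles(toy_pm(vm))
  expect_false(anyNA(outm$values))
})

test_that("smoothing is a truncated moving mean and halves the length", {
  const <- toy_pm(array(2, c(3, 100, 1)))
  out <- smooth_downsample(const, mean_window = 20, factor = 2)
  expect_equal(dim(out$values)[2], 50)
  expect_true(all(out$values == 2))

  # impulse response matches direct convolution
  v <- array(0, c(1, 1000, 1)); v[1, 500, 1] <- 1
  out2 <- smooth_downsample(toy_pm(v), mean_window = 20, factor = 1)
  direct <- stats::filter(v[1, , 1], rep(1 / 20, 20), sides = 2)
  inner <- 30:970
  expect_equal(out2$values[1, inner, 1], as.numeric(direct[inner]),
               tolerance = 1e-12)
  expect_equal(max(out2$values), 1 / 20)
  expect_equal(sum(out2$values[1, , 1] == 1 / 20), 20)  # plateau width

  # 1000 positions downsampled by 2 -> 500
  out3 <- smooth_downsample(toy_pm(array(rnorm(1000), c(1, 1000, 1))),
                            mean_window = 20, factor = 2)
  expect_equal(dim(out3$values)[2], 500)
  expect_error(smooth_downsample(const, mean_window = 200), "exceeds")
})

test_that("FFT distances match a naive DFT oracle", {
  set.seed(8)
  v <- array(rnorm(5 * 500), c(5, 500, 1))
  ds <- fft_distance(toy_pm(v), n_components = 10)
  D <- ds[[1]]
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:4) for (j in (i + 1):5) {
    fi <- naive_dft(v[i, , 1], 10)
    fj <- naive_dft(v[j, , 1], 10)
    brute <- sqrt(sum(Mod(fi - fj)^2))
    expect_lt(abs(D[i, j] - brute) / brute, 1e-8)
  }
  # identical profiles -> zero distance
  v2 <- v; v2[2, , 1] <- v2[1, , 1]
  D2 <- fft_distance(toy_pm(v2), n_components = 10)[[1]]
  expect_equal(D2[1, 2], 0)
  # scaling a profile by c scales its distance to the zero profile by c
  v3 <- array(0, c(2, 100, 1)); v3[1, , 1] <- sin(1:100 / 7)
  d1 <- fft_distance(toy_pm(v3), 10)[[1]][1, 2]
  v3[1, , 1] <- 3 * v3[1, , 1]
  d3 <- fft_distance(toy_pm(v3), 10)[[1]][1, 2]
  expect_equal(d3, 3 * d1, tolerance = 1e-10)
  expect_error(fft_distance(toy_pm(v3), n_components = 200), "exceeds")
})

test_that("DISTATIS on identical tables gives uniform weights and a
           proportional compromise", {
  set.seed(3)
  p <- matrix(rnorm(20), 5, 4)
  D <- as.matrix(dist(p)); dimnames(D) <- NULL
  ds <- structure(list(a = D, b = D, c = D), class = "feature_distance_set")
  cd <- distatis(ds)
  expect_equal(unname(cd$alpha), rep(1 / 3, 3), tolerance = 1e-12)
  # undo the eigenvalue normalization analytically: D_plus * sqrt(l1) = D
  W <- nrow(D)
  Cmat <- diag(W) - matrix(1 / W, W, W)
  S <- -0.5 * Cmat %*% D^2 %*% t(Cmat)
  l1 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values[1]
  expect_equal(cd$D_plus * sqrt(l1), D, tolerance = 1e-9)
  expect_true(all(cd$rv_matrix >= 0 & cd$rv_matrix <= 1 + 1e-12))
  expect_equal(diag(cd$rv_matrix), c(a = 1, b = 1, c = 1))
})

test_that("DISTATIS matches an independent eigendecomposition oracle on a
           4 x 4 two-feature toy", {
  # two Euclidean distance tables over the same 4 items
  p1 <- matrix(c(0, 0, 1, 0, 1, 2, 3, 1), 4, 2, byrow = TRUE)
  p2 <- matrix(c(0, 1, 2, 0, 1, 1, 0, 3), 4, 2, byrow = TRUE)
  D1 <- as.matrix(dist(p1)); dimnames(D1) <- NULL
  D2 <- as.matrix(dist(p2)); dimnames(D2) <- NULL
  # spreadsheet-style oracle: explicit loops, svd() instead of eigen()
  center_sq <- function(D) {
    W <- nrow(D); S <- matrix(0, W, W)
    rm <- rowMeans(D^2); gm <- mean(D^2)
    for (i in 1:W) for (j in 1:W)
      S[i, j] <- -0.5 * (D[i, j]^2 - rm[i] - rm[j] + gm)
    S
  }
  norm1 <- function(S) S / svd(S)$d[1]
  S1 <- norm1(center_sq(D1)); S2 <- norm1(center_sq(D2))
  rv <- function(A, B) sum(A * B) / sqrt(sum(A * A) * sum(B * B))
  RV <- matrix(c(1, rv(S1, S2), rv(S2, S1), 1), 2, 2)
  sv <- svd(RV)
  a <- sv$u[, 1]; if (sum(a) < 0) a <- -a
  alpha <- a / sum(a)
  Sp <- alpha[1] * S1 + alpha[2] * S2
  Dp <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    Dp[i, j] <- sqrt(max(Sp[i, i] + Sp[j, j] - 2 * Sp[i, j], 0))

  cd <- distatis(structure(list(f1 = D1, f2 = D2),
                           class = "feature_distance_set"))
  expect_equal(unname(cd$alpha), alpha, tolerance = 1e-6)
  expect_equal(unname(cd$D_plus), Dp, tolerance = 1e-6)
  expect_error(distatis(structure(list(D1, D1 + upper.tri(D1)),
                                  class = "feature_distance_set")),
               "symmetric")
})

test_that("DISTATIS weights are equivariant to feature permutation and the
           compromise satisfies the triangle inequality", {
  set.seed(11)
  for (rep in 1:10) {
    mats <- lapply(1:4, function(k) {
      p <- matrix(rnorm(6 * 3), 6, 3)
      D <- as.matrix(dist(p)); dimnames(D) <- NULL; D
    })
    names(mats) <- paste0("f", 1:4)
    cd <- distatis(structure(mats, class = "feature_distance_set"))
    perm <- sample(4)
    cdp <- distatis(structure(mats[perm], class = "feature_distance_set"))
    expect_equal(unname(cdp$alpha), unname(cd$alpha[perm]), tolerance = 1e-9)
    expect_equal(cdp$D_plus, cd$D_plus, tolerance = 1e-9)
    # triangle inequality on the compromise distance
    D <- cd$D_plus
    n <- nrow(D)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
})

test_that("log-distance aggregation matches hand computation and is monotone", {
  D1 <- matrix(c(0, 9, 9, 0), 2, 2)
  D2 <- matrix(c(0, 99, 99, 0), 2, 2)
  ds <- structure(list(D1, D2), class = "feature_distance_set")
  agg <- aggregate_log_distance(ds)
  expect_equal(agg[1, 2], (log10(10) + log10(100)) / 2)
  # single zero feature -> zero matrix
  z <- structure(list(matrix(0, 3, 3)), class = "feature_distance_set")
  expect_true(all(aggregate_log_distance(z) == 0))
  # increasing any entry never decreases the aggregate
  D1b <- D1; D1b[1, 2] <- D1b[2, 1] <- 20
  aggb <- aggregate_log_distance(structure(list(D1b, D2),
                                           class = "feature_distance_set"))
  expect_gte(aggb[1, 2], agg[1, 2])
  # plain mean aggregation
  expect_equal(aggregate_mean_distance(ds)[1, 2], 54)
})
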