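# Orthogonalization, envelope correlation, connectivity matrices, masks,
# normalization and edge lengths.

test_that("windowed orthogonalization satisfies the least-squares contract", {
  fs <- 100
  set.seed(11)
  x <- apply_bandpass(rnorm(1000), 8, 13, fs)
  # collinear: residual vanishes in every complete window
  r <- orthogonalize_window(x, 2 * x, fs)
  expect_lt(max(abs(r)), 1e-10)
  # pre-orthogonalized windows: y untouched
  w <- 200
  y <- rnorm(1000)
  for (k in seq_len(5)) {
    sel <- ((k - 1) * w + 1):(k * w)
    y[sel] <- y[sel] - sum(y[sel] * x[sel]) / sum(x[sel]^2) * x[sel]
  }
  expect_equal(orthogonalize_window(x, y, fs), y, tolerance = 1e-12)
  # random pair: residual orthogonal to x within each window
  y2 <- rnorm(1000)
  r2 <- orthogonalize_window(x, y2, fs)
  for (k in seq_len(5)) {
    sel <- ((k - 1) * w + 1):(k * w)
    expect_lt(abs(sum(r2[sel] * x[sel])),
              1e-9 * sqrt(sum(r2[sel]^2) * sum(x[sel]^2)))
  }
  # all-zero x leaves y unchanged in that window
  x0 <- x; x0[1:200] <- 0
  r3 <- orthogonalize_window(x0, y2, fs)
  expect_equal(r3[1:200], y2[1:200])
  # trailing partial window dropped
  expect_length(orthogonalize_window(x[1:350], y2[1:350], fs), 200L)
})

test_that("envelope correlation: degenerate, null and coupled regimes", {
  fs <- 100; L <- 6000
  set.seed(12)
  x <- apply_bandpass(rnorm(L), 8, 13, fs)
  # collinear pair: both residuals vanish -> 0 by the degenerate contract
  expect_warning(v0 <- envelope_correlation(x, 2 * x, fs), "degenerate")
  expect_equal(v0, 0)
  # symmetry: direction-averaged estimator is exactly symmetric
  y <- apply_bandpass(rnorm(L), 8, 13, fs)
  expect_identical(envelope_correlation(x, y, fs),
                   envelope_correlation(y, x, fs))
  # shared slow modulator on independent carriers -> strong positive value
  tt <- (0:(30000 - 1)) / fs
  m <- 1 + 0.8 * cos(2 * pi * 0.1 * tt)
  s1 <- m * apply_bandpass(rnorm(30000), 8, 13, fs)
  s2 <- m * apply_bandpass(rnorm(30000), 8, 13, fs)
  sn <- sqrt(mean(s1^2)) / sqrt(10)  # SNR 10
  v <- envelope_correlation(s1 + sn * rnorm(30000), s2 + sn * rnorm(30000),
                            fs)
  # measured margin over replicate oracle runs: 0.36-0.40 (the windowed
  # orthogonalization shaves the shared-modulator coupling)
  expect_gt(v, 0.3)
})

test_that("null distribution of the estimator is centred near its
           small-sample bias", {
  # independent alpha-band noise at 300 s: the windowed-regression estimator
  # carries a small negative bias (~ -0.033); values concentrate around it
  fs <- 100
  set.seed(13)
  vals <- replicate(12, {
    x <- apply_bandpass(rnorm(30000), 8, 13, fs)
    y <- apply_bandpass(rnorm(30000), 8, 13, fs)
    envelope_correlation(x, y, fs)
  })
  expect_lt(mean(vals), 0)
  expect_gt(mean(vals), -0.08)
  expect_true(all(abs(vals) < 0.12))
})

test_that("orthogonalization suppresses zero-lag leakage mixing", {
  fs <- 100; L <- 30000
  set.seed(14)
  s1 <- apply_bandpass(rnorm(L), 8, 13, fs)
  s2 <- apply_bandpass(rnorm(L), 8, 13, fs)
  x <- s1 + 0.5 * s2
  y <- s2 + 0.5 * s1
  ex <- hilbert_envelope(x); ey <- hilbert_envelope(y)
  keep <- 201:(L - 200)
  expect_gt(cor(ex[keep], ey[keep]), 0.5)       # without orthogonalization
  expect_lt(abs(envelope_correlation(x, y, fs)), 0.08)  # with
})

test_that("connectivity matrix covers all 1653 edges and masks correctly", {
  pts <- fx_noise_pts(58, 30)
  C <- connectivity_matrix(pts, band = "alpha")
  expect_length(C$values, 58 * 57 / 2)
  expect_equal(C$weights, t(C$weights))
  expect_equal(diag(C$weights), rep(0, 58))
  # identical signals everywhere: orthogonalization kills all edges
  same <- matrix(rep(pts[1, ], 10), 10, byrow = TRUE)
  expect_warning(C0 <- connectivity_matrix(same, band = "alpha"))
  expect_equal(max(abs(C0$values)), 0)
  # masked computation restricted to the retained set
  mask <- full_edge_mask(58)
  mask$retained[1:100] <- FALSE
  mask$n_retained <- sum(mask$retained)
  Cm <- connectivity_matrix(pts, band = "alpha", mask = mask)
  expect_length(Cm$values, 1553)
  expect_true(all(is.na(Cm$weights[1, 2:51])))
})

test_that("normalization scales magnitudes to 1, preserves ratios and is
           idempotent and scale-invariant", {
  pts <- fx_noise_pts(20, 20, seed = 3)
  C <- connectivity_matrix(pts, band = "alpha")
  N1 <- normalize_connectivity(C)
  expect_equal(sum(abs(N1$values)), 1, tolerance = 1e-9)
  expect_equal(N1$values / N1$values[1], C$values / C$values[1],
               tolerance = 1e-9)
  # idempotent
  N2 <- normalize_connectivity(N1)
  expect_equal(N2$values, N1$values, tolerance = 1e-12)
  # scale invariance: 10 * C normalizes to the same network
  C10 <- C; C10$values <- 10 * C$values; C10$weights <- 10 * C$weights
  expect_equal(normalize_connectivity(C10)$values, N1$values,
               tolerance = 1e-12)
  # fixed point: weights already summing to 1 in magnitude
  Cfix <- C
  Cfix$values <- c(0.2, -0.3, 0.5, rep(0, length(C$values) - 3))
  expect_equal(normalize_connectivity(Cfix)$values[1:3], c(0.2, -0.3, 0.5))
  # all-zero matrix is an error
  Cz <- C; Cz$values <- rep(0, length(C$values))
  expect_error(normalize_connectivity(Cz), "all-zero")
})

test_that("edge mask: identity leak retains everything; mask reuse is
           identical across subjects", {
  parc <- fx_parc()
  leak0 <- make_toy_leakage_operator(parc, 0)
  mask <- derive_edge_mask(parc, leak0, n_iter = 3, seed = 5, duration = 20,
                           noise_sd = 0.05, n_surrogate = 30)
  expect_equal(mask$n_retained, 1653L)
  expect_error(derive_edge_mask(parc, leak0, n_iter = 1), "n_iter")
  # round trip
  stem <- tempfile()
  write_edge_mask(mask, stem)
  back <- read_edge_mask(stem)
  expect_equal(back$retained, mask$retained)
  expect_equal(back$threshold, mask$threshold, tolerance = 1e-12)
  unlink(paste0(stem, c(".tsv", ".json")))
})

test_that("mask retention shrinks as leakage spread grows", {
  # smaller parcellation + fast modulators keep the surrogate loop short
  parc <- make_symmetric_parcellation(fx_mesh(), 8)
  fracs <- vapply(c(5, 20, 60), function(spread) {
    leak <- make_toy_leakage_operator(parc, spread)
    m <- derive_edge_mask(parc, leak, n_iter = 6, seed = 6, duration = 30,
                          mod_freq = 1, noise_sd = 0.3, n_surrogate = 40)
    m$n_retained / length(m$retained)
  }, numeric(1))
  expect_lt(fracs[3], 1)
  expect_true(all(diff(fracs) <= 0))
  expect_gt(fracs[1], fracs[3])
})

test_that("edge length distributions integrate to one and order by range", {
  parc <- fx_parc()
  et <- sleepmodes:::edge_table(58)
  d_all <- sqrt(rowSums((parc$centroids[et[, 1], ] -
                         parc$centroids[et[, 2], ])^2))
  short <- which(d_all < quantile(d_all, 0.3))
  long <- which(d_all > quantile(d_all, 0.7))
  eshort <- edge_length_distribution(short, parc)
  elong <- edge_length_distribution(long, parc)
  expect_gt(mean(elong$lengths), mean(eshort$lengths))
  dens <- eshort$density
  area <- sum(dens$y) * diff(dens$x[1:2])
  expect_equal(area, 1, tolerance = 1e-3)
  # mirrored-pair edges all have identical length (pure x reflection)
  pr <- parc$parcel_pairs
  mirror_edges <- vapply(seq_len(nrow(pr)), function(k) {
    i <- min(pr[k, ]); j <- max(pr[k, ])
    which(et[, 1] == i & et[, 2] == j)
  }, integer(1))
  dm <- edge_length_distribution(mirror_edges, parc)$lengths
  expect_equal(dm, 2 * abs(parc$centroids[pr[, 1], 1]), tolerance = 1e-9)
  expect_error(edge_length_distribution(integer(0), parc), "empty")
})
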