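# Edge statistics, NBS components and permutation FWER, effect sizes.

test_that("edge t statistics match their contrast definitions", {
  cc <- synthetic_conn_cohort(n_parcels = 12, n_ep = 8, n_hc = 9, seed = 21)
  # oracle: per-edge t.test on the same data
  st <- edge_statistics(cc, "sleep_main")
  e <- 5
  d <- cc$W[e, , "AS"] - cc$W[e, , "QS"]
  expect_equal(st$t[e], unname(t.test(d)$statistic), tolerance = 1e-12)
  expect_equal(st$df, length(d) - 1)
  gm <- edge_statistics(cc, "group_main")
  avg <- (cc$W[e, , "AS"] + cc$W[e, , "QS"]) / 2
  tt <- t.test(avg[cc$groups == "EP"], avg[cc$groups == "HC"],
               var.equal = TRUE)
  expect_equal(gm$t[e], unname(tt$statistic), tolerance = 1e-12)
  ia <- edge_statistics(cc, "interaction")
  ti <- t.test(d[cc$groups == "EP"], d[cc$groups == "HC"], var.equal = TRUE)
  expect_equal(ia$t[e], unname(ti$statistic), tolerance = 1e-12)
  # AS == QS everywhere -> all sleep-main t are 0
  cc0 <- cc; cc0$W[, , "QS"] <- cc0$W[, , "AS"]
  expect_equal(max(abs(edge_statistics(cc0, "sleep_main")$t)), 0)
})

test_that("planted paired effect yields mean t near the noncentral-t
           location", {
  # oracle: a shift of size delta on one state gives paired differences
  # N(delta, 2 sd^2), so E[t] ~ delta / (sd sqrt(2)) * sqrt(n)
  n <- 40; delta <- 0.8
  set.seed(77)
  tvals <- replicate(40, {
    cc <- synthetic_conn_cohort(n_parcels = 8, n_ep = n / 2, n_hc = n / 2,
                                seed = sample.int(1e6, 1),
                                effect_edges = 1, effect_size = delta,
                                effect_on = "AS",
                                effect_group = c("EP", "HC"))
    edge_statistics(cc, "sleep_main")$t[1]
  })
  expect_equal(mean(tvals), delta / sqrt(2) * sqrt(n), tolerance = 0.12)
})

test_that("union-find component sizes agree with igraph", {
  set.seed(22)
  for (rep in 1:10) {
    n <- 15
    et <- sleepmodes:::edge_table(n)
    sel <- sample(nrow(et), 20)
    uf <- sleepmodes:::edge_components(et[sel, 1], et[sel, 2])
    g <- igraph::graph_from_edgelist(et[sel, ], directed = FALSE)
    memb <- igraph::components(g)$membership
    ig_sizes <- sort(as.integer(table(memb[et[sel, 1]])))
    expect_equal(sort(uf$sizes), ig_sizes)
  }
})

test_that("nbs finds planted components and respects thresholds", {
  # a 15-edge clique among parcels 1..6 (robust to single-edge dropouts),
  # strong paired effect
  et <- sleepmodes:::edge_table(16)
  planted <- which(et[, 1] <= 6 & et[, 2] <= 6)
  cc <- synthetic_conn_cohort(n_parcels = 16, n_ep = 15, n_hc = 15,
                              seed = 23, effect_edges = planted,
                              effect_size = 1.2, effect_on = "AS",
                              effect_group = c("EP", "HC"))
  res <- nbs(cc, contrast_spec("sleep_main", threshold = 3, n_perm = 200,
                               seed = 1))
  expect_gt(length(res$components), 0)
  big <- res$components[[which.max(vapply(res$components, `[[`, numeric(1),
                                          "size"))]]
  expect_equal(big$tail, "positive")
  expect_gte(length(intersect(big$edges, planted)), 12)
  expect_lt(big$p_fwer, 0.05)
  expect_true(res$any_significant)
  # threshold above max |t|: no components
  hi <- nbs(cc, contrast_spec("sleep_main", threshold = 1e6, n_perm = 100,
                              seed = 1))
  expect_length(hi$components, 0)
  expect_false(hi$any_significant)
  # p values are valid and deterministic under the seed
  res2 <- nbs(cc, contrast_spec("sleep_main", threshold = 3, n_perm = 200,
                                seed = 1))
  expect_identical(res$null_max_size, res2$null_max_size)
  ps <- vapply(res$components, `[[`, numeric(1), "p_fwer")
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("permutation null is exchangeable across independent draws", {
  cc <- synthetic_conn_cohort(n_parcels = 14, n_ep = 12, n_hc = 12,
                              seed = 24)
  r1 <- nbs(cc, contrast_spec("interaction", threshold = 2, n_perm = 400,
                              seed = 10))
  r2 <- nbs(cc, contrast_spec("interaction", threshold = 2, n_perm = 400,
                              seed = 20))
  ks <- suppressWarnings(ks.test(r1$null_max_size$positive,
                                 r2$null_max_size$positive))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohens_d follows the mean-t / sqrt(df) convention", {
  expect_equal(cohens_d(0, 92), 0)
  expect_equal(round(cohens_d(3.0, 92), 4), 0.3128)
  expect_equal(cohens_d(2.5, 25), 0.5)
  expect_error(cohens_d(1, 0), "df")
})

test_that("spectral fingerprint localizes a planted carrier/modulator
           effect", {
  # small cohort with an AS-only shared 0.1 Hz modulator on a 10 Hz carrier
  # in half the parcels; reduced banks around the planted bands
  fs <- 100; L <- 12000; n_parcels <- 10; n_subj <- 6
  carriers <- build_carrier_bank()[c(13, 17, 21)]  # ~4.6, 9.5, 19.2 Hz
  amplitudes <- build_amplitude_bank()[c(11, 15)]  # ~0.093, 0.19 Hz
  tt <- (0:(L - 1)) / fs
  set.seed(25)
  recs <- lapply(seq_len(n_subj), function(s) {
    mk <- function(coupled) {
      base <- apply_bandpass(matrix(rnorm(n_parcels * L), n_parcels), 2, 30,
                             fs)
      if (coupled) {
        m <- 1 + 0.9 * cos(2 * pi * 0.1 * tt + runif(1, 0, 2 * pi))
        for (p in 1:5) {
          carrier <- apply_bandpass(rnorm(L), 8.5, 11.5, fs)
          base[p, ] <- base[p, ] * 0.4 + 3 * m * carrier
        }
      }
      base
    }
    list(AS = mk(TRUE), QS = mk(FALSE))
  })
  groups <- factor(rep(c("EP", "HC"), each = n_subj / 2))
  grid <- spectral_fingerprint(recs, groups,
                               contrast_spec("sleep_main", threshold = 2.5,
                                             n_perm = 100, seed = 1),
                               carriers = carriers, amplitudes = amplitudes,
                               fs = fs)
  expect_equal(dim(grid), c(3L, 2L))
  best <- which(abs(grid) == max(abs(grid), na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(best[1, 1]), 2L)  # carrier band containing 10 Hz
  expect_equal(unname(best[1, 2]), 1L)  # amplitude band containing 0.1 Hz
  expect_gt(grid[2, 1], 0)              # AS > QS direction
})
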