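# Mixed ANOVA, partial correlations, FDR, asymmetry and brain-behavior.

test_that("mixed ANOVA matches hand-computed sums of squares on a balanced
           toy table", {
  # 2 groups x 2 subjects x 2 states, worked by hand:
  # values chosen so every SS is a simple fraction
  tab <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("A", "A", "B", "B"), each = 2),
    state = rep(c("AS", "QS"), 4),
    value = c(10, 12, 14, 18, 20, 26, 24, 32))
  out <- mixed_anova(tab)
  # manual decomposition (classic split-plot):
  y <- matrix(tab$value, nrow = 2)   # states x subjects
  subj_mean <- colMeans(y)
  grp <- c("A", "A", "B", "B")
  grand <- mean(y)
  ss_group <- 2 * sum(tapply(subj_mean, grp, function(v)
    length(v) * (mean(v) - grand)^2))
  ss_subj <- 2 * sum((subj_mean - tapply(subj_mean, grp, mean)[grp])^2)
  state_dev <- sweep(y, 2, subj_mean)
  state_mean <- rowMeans(state_dev)
  ss_state <- 4 * sum(state_mean^2)
  cell <- sapply(c("A", "B"), function(g) rowMeans(state_dev[, grp == g]))
  ss_inter <- 2 * sum(sweep(cell, 1, state_mean)^2)
  ss_err_w <- sum(state_dev^2) - ss_state - ss_inter
  expect_equal(out$F[out$effect == "group"],
               (ss_group / 1) / (ss_subj / 2), tolerance = 1e-12)
  expect_equal(out$F[out$effect == "state"],
               (ss_state / 1) / (ss_err_w / 2), tolerance = 1e-12)
  expect_equal(out$F[out$effect == "group:state"],
               (ss_inter / 1) / (ss_err_w / 2), tolerance = 1e-12)
  expect_equal(out$eta2[out$effect == "state"],
               ss_state / (ss_group + ss_subj + ss_state + ss_inter +
                           ss_err_w), tolerance = 1e-12)
})

test_that("mixed ANOVA degrees of freedom follow (N - g)(k - 1)", {
  set.seed(31)
  n <- c(42, 52)
  tab <- data.frame(
    subject = rep(sprintf("s%03d", 1:94), each = 2),
    group = rep(rep(c("EP", "HC"), n), each = 2),
    state = rep(c("AS", "QS"), 94),
    value = rnorm(188))
  out <- mixed_anova(tab)
  expect_equal(out$df2[out$effect == "state"], 92)
  expect_equal(out$df2[out$effect == "group:state"], 92)
  expect_equal(out$df1, c(1, 1, 1))
  expect_equal(out$df2[out$effect == "group"], 92)
  # identical state values per subject -> within-effect F = 0
  tab0 <- tab
  tab0$value <- rep(rnorm(94), each = 2)
  out0 <- mixed_anova(tab0)
  expect_equal(out0$F[out0$effect == "state"], 0, tolerance = 1e-20)
})

test_that("group-permuted data give uniform between-effect p-values", {
  set.seed(32)
  base <- data.frame(
    subject = rep(sprintf("s%02d", 1:30), each = 2),
    state = rep(c("AS", "QS"), 30),
    value = rnorm(60))
  pvals <- replicate(200, {
    g <- sample(rep(c("EP", "HC"), c(14, 16)))
    tab <- base
    tab$group <- rep(g, each = 2)
    mixed_anova(tab)$p[1]
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("partial correlation matches a brute-force two-stage regression
           oracle and the plain Pearson special case", {
  # worked 6-point table
  x <- c(1.2, 2.3, 0.7, 3.1, 2.0, 1.5)
  y <- c(2.0, 1.1, 2.8, 0.4, 1.3, 2.2)
  z <- c(0.5, 1.0, 0.2, 1.4, 0.9, 0.6)
  pc <- partial_pearson(x, y, z)
  rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
  expect_equal(pc$R, cor(rx, ry), tolerance = 1e-12)
  # z orthogonal to x and y: equals plain Pearson
  set.seed(33)
  x2 <- rnorm(40); y2 <- rnorm(40)
  z2 <- rnorm(40)
  z2 <- residuals(lm(z2 ~ x2 + y2))  # construct exact orthogonality
  pc2 <- partial_pearson(x2, y2, z2)
  expect_equal(pc2$R, cor(x2, y2), tolerance = 1e-10)
  # x = y: R = 1
  expect_equal(partial_pearson(x2, x2, rnorm(40))$R, 1, tolerance = 1e-12)
  # zero residual variance is an error
  expect_error(partial_pearson(z, y, z), "residual variance")
})

test_that("partial correlation p and CI reproduce the n = 32 printed-value
           conventions", {
  # R = -0.514 at n = 32 with one covariate: p = 0.003,
  # CI [-0.732, -0.202] under df = n - 3 and Fisher SE = 1/sqrt(df)
  R <- -0.514; n <- 32; df <- n - 3
  tval <- R * sqrt(df / (1 - R^2))
  expect_equal(round(2 * pt(-abs(tval), df), 3), 0.003)
  ci <- tanh(atanh(R) + c(-1, 1) * qnorm(0.975) / sqrt(df))
  # the upper bound lands at -0.2014 from the rounded R = -0.514; the
  # printed -0.202 reflects the unrounded correlation
  expect_equal(ci, c(-0.732, -0.202), tolerance = 2e-3)
})

test_that("Fisher-z CI covers the true partial correlation at nominal rate", {
  # x and y share bivariate-normal residuals with correlation -0.5 after the
  # common covariate z is removed, so the true partial correlation is -0.5
  set.seed(34)
  n <- 32; rho <- -0.5
  cover <- replicate(1000, {
    z <- rnorm(n)
    e1 <- rnorm(n)
    e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)
    pc <- partial_pearson(0.4 * z + e1, 0.4 * z + e2, z)
    pc$ci[1] <= rho && rho <= pc$ci[2]
  })
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("BH-FDR matches a brute-force step-up enumeration", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.99)
  out <- bh_fdr(p)
  # brute force: q_i = min over j >= i of m * p_(j) / j (sorted), then
  # mapped back
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  expect_equal(out[o], q, tolerance = 1e-12)
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # order invariance
  set.seed(35)
  p2 <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p2)[perm], bh_fdr(p2[perm]))
})

test_that("hemispheric asymmetry: mirrored matrices are null, planted boosts
           are detected", {
  parc <- fx_parc()
  # build a conn_cohort over all 1653 edges with mirror-symmetric weights
  et <- sleepmodes:::edge_table(58)
  hemi <- parc$hemisphere
  set.seed(36)
  n_subj <- 50
  base <- matrix(rnorm(nrow(et) * n_subj, 0.1, 0.05), nrow(et))
  # symmetrize: copy right-hemisphere edge weights onto mirrored left edges
  mirror_parcel <- integer(58)
  mirror_parcel[parc$parcel_pairs[, 1]] <- parc$parcel_pairs[, 2]
  mirror_parcel[parc$parcel_pairs[, 2]] <- parc$parcel_pairs[, 1]
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  idx_map <- match(key(mirror_parcel[et[, 1]], mirror_parcel[et[, 2]]),
                   key(et[, 1], et[, 2]))
  right_e <- which(hemi[et[, 1]] == "R" & hemi[et[, 2]] == "R")
  base[idx_map[right_e], ] <- base[right_e, ]
  W <- array(NA_real_, c(nrow(et), n_subj, 2),
             dimnames = list(NULL, NULL, c("AS", "QS")))
  W[, , "AS"] <- base
  W[, , "QS"] <- base
  groups <- factor(rep(c("EP", "HC"), each = n_subj / 2))
  cc <- structure(list(W = W, edge_idx = seq_len(nrow(et)), edges = et,
                       groups = groups, n_parcels = 58),
                  class = "conn_cohort")
  res <- hemispheric_asymmetry(cc, parc)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$p == 1))
  expect_true(all(res$p_fdr >= res$p))
  # planted 20% left boost
  W2 <- W
  left_e <- which(hemi[et[, 1]] == "L" & hemi[et[, 2]] == "L")
  W2[left_e, , ] <- W2[left_e, , ] * 1.2
  cc2 <- cc; cc2$W <- W2
  res2 <- hemispheric_asymmetry(cc2, parc)
  expect_true(any(res2$p_fdr < 0.05))
  expect_true(all(res2$left > res2$right))
})

test_that("brain-behavior couplings are recovered with FDR control", {
  cc <- synthetic_conn_cohort(n_parcels = 20, n_ep = 32, n_hc = 20,
                              seed = 37, sd = 0.1)
  cohort <- structure(list(
    subjects = lapply(seq_len(52), function(i)
      list(id = sprintf("S%03d", i),
           group = if (i <= 32) "EP" else "HC",
           age = rnorm(1, 41, 1.5))),
    groups = cc$groups), class = "cohort")
  edges <- 1:25
  ep <- which(cc$groups == "EP")
  change <- as.numeric(colMeans(cc$W[edges, ep, "AS"]) -
                       colMeans(cc$W[edges, ep, "QS"]))
  # exact negative outcome, no noise, no age effect -> R = -1
  out0 <- simulate_outcomes(cohort, change, coupling = -1, noise_sd = 0,
                            age_effect = 0, seed = 2)
  bb0 <- brain_behavior(cc, edges, out0, scores = "visual")
  expect_equal(bb0$R, -1, tolerance = 1e-10)
  # coupled visual score with noise, uncoupled social score
  out1 <- simulate_outcomes(cohort, change, coupling = -1,
                            noise_sd = 0.7 * sd(change), age_effect = 0.01,
                            seed = 3)
  bb1 <- brain_behavior(cc, edges, out1)
  expect_lt(bb1$R[bb1$score == "visual"], -0.4)
  expect_lt(bb1$p_fdr[bb1$score == "visual"], 0.05)
  expect_gt(bb1$p[bb1$score == "social_emotional"], 0.05)
  expect_error(brain_behavior(cc, integer(0), out1), "empty")
})

test_that("zero-coupling outcomes stay inside the null band", {
  cc <- synthetic_conn_cohort(n_parcels = 10, n_ep = 32, n_hc = 10,
                              seed = 38, sd = 0.1)
  cohort <- structure(list(
    subjects = lapply(seq_len(42), function(i)
      list(id = sprintf("S%03d", i),
           group = if (i <= 32) "EP" else "HC",
           age = rnorm(1, 41, 1.5))),
    groups = cc$groups), class = "cohort")
  ep <- which(cc$groups == "EP")
  change <- as.numeric(colMeans(cc$W[1:10, ep, "AS"]) -
                       colMeans(cc$W[1:10, ep, "QS"]))
  rs <- vapply(1:40, function(s) {
    outc <- simulate_outcomes(cohort, change, coupling = 0, noise_sd = 1,
                              seed = 100 + s)
    brain_behavior(cc, 1:10, outc, scores = "visual")$R
  }, numeric(1))
  # null width at n = 32: |R| < 0.35 for ~95% of draws
  expect_gt(mean(abs(rs) < 0.35), 0.85)
  expect_lt(abs(mean(rs)), 0.15)
})
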