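# Edge-wise contrasts, the network-based statistic (NBS) with permutation
# FWER control, and Cohen's d effect grids over the double filter bank.

#' Assemble a connectivity cohort
#'
#' Stacks per-subject, per-state connectivity values into an
#' edges x subjects x states array over a common retained edge set, the
#' structure the contrast and permutation machinery operates on.
#'
#' @param matrices nested list `subject -> state ("AS"/"QS") -> conn_matrix`
#'   (all with identical `edge_idx`).
#' @param groups factor of group labels (`EP`/`HC`), one per subject.
#' @return an object of class `conn_cohort`: list with `W` (edges x
#'   subjects x 2), `edge_idx`, `edges` (parcel index pairs), `groups`,
#'   `n_parcels`.
#' @export
conn_cohort <- function(matrices, groups) {
  stopifnot(length(matrices) == length(groups))
  first <- matrices[[1]][["AS"]]
  edge_idx <- first$edge_idx
  n_parcels <- first$n_parcels
  W <- array(NA_real_, c(length(edge_idx), length(matrices), 2),
             dimnames = list(NULL, NULL, c("AS", "QS")))
  for (s in seq_along(matrices)) {
    for (st in c("AS", "QS")) {
      C <- matrices[[s]][[st]]
      if (!identical(C$edge_idx, edge_idx))
        stop("subject ", s, " has a different edge set")
      W[, s, st] <- C$values
    }
  }
  structure(list(W = W, edge_idx = edge_idx,
                 edges = edge_table(n_parcels)[edge_idx, , drop = FALSE],
                 groups = factor(groups), n_parcels = n_parcels),
            class = "conn_cohort")
}

#' @export
print.conn_cohort <- function(x, ...) {
  cat(sprintf("conn_cohort: %d edges x %d subjects x 2 states (%s)\n",
              dim(x$W)[1], dim(x$W)[2],
              paste(sprintf("%s=%d", levels(x$groups),
                            tabulate(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Contrast specification for network statistics
#'
#' @param kind `"sleep_main"` (paired AS vs QS across all subjects),
#'   `"group_main"` (EP vs HC on state-averaged networks) or
#'   `"interaction"` (EP vs HC on the per-subject AS - QS differences).
#' @param threshold suprathreshold search height on |t| (default 3, the
#'   canonical-band setting; the fingerprint analyses use 2.5).
#' @param n_perm number of permutations (>= 100; paper-scale 5000).
#' @param alpha FWER level.
#' @param seed permutation seed.
#' @return an object of class `contrast_spec`.
#' @export
contrast_spec <- function(kind = c("sleep_main", "group_main", "interaction"),
                          threshold = 3, n_perm = 5000, alpha = 0.05,
                          seed = 1) {
  kind <- match.arg(kind)
  if (threshold <= 0) stop("threshold must be positive")
  if (n_perm < 100) stop("n_perm must be >= 100")
  structure(list(kind = kind, threshold = threshold, n_perm = n_perm,
                 alpha = alpha, seed = seed),
            class = "contrast_spec")
}

# per-edge data matrix (subjects x edges) the contrast's t-test runs on, and
# the grouping vector for two-sample contrasts
contrast_data <- function(cohort, kind) {
  W <- cohort$W
  switch(kind,
    sleep_main = list(X = t(W[, , "AS"] - W[, , "QS"]), paired = TRUE),
    group_main = list(X = t((W[, , "AS"] + W[, , "QS"]) / 2), paired = FALSE,
                      grp = cohort$groups),
    interaction = list(X = t(W[, , "AS"] - W[, , "QS"]), paired = FALSE,
                       grp = cohort$groups)
  )
}

# one-sample t per column (paired contrasts act on differences)
t_one_sample <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  list(t = m / sqrt(pmax(v, 1e-300) / n), df = n - 1)
}

# pooled-variance two-sample t per column (grp level 1 minus level 2)
t_two_sample <- function(X, grp) {
  gA <- grp == levels(grp)[1]
  nA <- sum(gA); nB <- sum(!gA)
  mA <- colMeans(X[gA, , drop = FALSE])
  mB <- colMeans(X[!gA, , drop = FALSE])
  ss <- colSums(X^2) - nA * mA^2 - nB * mB^2
  sp2 <- ss / (nA + nB - 2)
  list(t = (mA - mB) / sqrt(pmax(sp2, 1e-300) * (1 / nA + 1 / nB)),
       df = nA + nB - 2)
}

#' Per-edge contrast t statistics
#'
#' `sleep_main`: paired t on (AS - QS) across all subjects; `group_main`:
#' two-sample t (EP vs HC) on state-averaged matrices; `interaction`:
#' two-sample t on the per-subject (AS - QS) differences between groups.
#'
#' @param cohort a [conn_cohort()].
#' @param contrast a [contrast_spec()] (or a kind string).
#' @return list with `t` (per retained edge), `df`, and the contrast kind.
#' @export
edge_statistics <- function(cohort, contrast) {
  kind <- if (inherits(contrast, "contrast_spec")) contrast$kind else contrast
  cd <- contrast_data(cohort, kind)
  n_min <- if (cd$paired) nrow(cd$X) else min(tabulate(cd$grp))
  if (n_min < 3) stop("fewer than 3 subjects per cell")
  res <- if (cd$paired) t_one_sample(cd$X) else t_two_sample(cd$X, cd$grp)
  list(t = res$t, df = res$df, kind = kind)
}

# max suprathreshold component size (edge count) in one tail
max_component_size <- function(tvals, thr, ei, ej, positive = TRUE) {
  sel <- if (positive) tvals >= thr else tvals <= -thr
  if (!any(sel)) return(0L)
  comps <- edge_components(ei[sel], ej[sel])
  max(comps$sizes)
}

#' Network-based statistic
#'
#' Two-tailed NBS: edges with `t >= threshold` (positive tail) and
#' `t <= -threshold` (negative tail) are thresholded separately, connected
#' components are found in the parcel graph induced by the suprathreshold
#' edges, and each observed component's size (edge count) is compared with
#' the permutation null distribution of the maximum component size of its
#' own tail. Permutation schemes: `sleep_main` randomly swaps state labels
#' within subjects (sign flips of the paired differences); `group_main`
#' randomly reassigns subjects to groups preserving group sizes;
#' `interaction` applies the group reassignment to the per-subject difference
#' matrices. The FWER-corrected p-value uses the +1 correction,
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param cohort a [conn_cohort()].
#' @param contrast a [contrast_spec()].
#' @return an object of class `nbs_result`: per-component edge lists, sizes,
#'   tails and `p_fwer`; per-tail null distributions; per-edge `t` values;
#'   `any_significant` at the contrast alpha.
#' @export
nbs <- function(cohort, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  cd <- contrast_data(cohort, contrast$kind)
  obs <- if (cd$paired) t_one_sample(cd$X) else t_two_sample(cd$X, cd$grp)
  ei <- cohort$edges[, 1]; ej <- cohort$edges[, 2]
  thr <- contrast$threshold

  # observed components per tail
  comps <- list()
  for (tail in c("positive", "negative")) {
    sel <- if (tail == "positive") obs$t >= thr else obs$t <= -thr
    if (any(sel)) {
      cc <- edge_components(ei[sel], ej[sel])
      for (cid in seq_along(cc$sizes)) {
        eidx <- which(sel)[cc$edge_comp == cid]
        comps[[length(comps) + 1]] <-
          list(tail = tail, edges = eidx, size = length(eidx),
               mean_t = mean(obs$t[eidx]))
      }
    }
  }

  # permutation null of the max component size, per tail
  n <- nrow(cd$X)
  X <- cd$X
  null_pos <- integer(contrast$n_perm)
  null_neg <- integer(contrast$n_perm)
  with_seed(contrast$seed, {
    if (cd$paired) {
      SS2 <- colSums(X^2)
      for (p in seq_len(contrast$n_perm)) {
        sgn <- sample(c(-1, 1), n, replace = TRUE)
        m <- as.numeric(sgn %*% X) / n
        v <- (SS2 - n * m^2) / (n - 1)
        tp <- m / sqrt(pmax(v, 1e-300) / n)
        null_pos[p] <- max_component_size(tp, thr, ei, ej, TRUE)
        null_neg[p] <- max_component_size(tp, thr, ei, ej, FALSE)
      }
    } else {
      grp <- cd$grp
      nA <- sum(grp == levels(grp)[1]); nB <- n - nA
      SS2 <- colSums(X^2)
      for (p in seq_len(contrast$n_perm)) {
        pa <- sample(n, nA)
        mA <- colMeans(X[pa, , drop = FALSE])
        mB <- (colSums(X) - nA * mA) / nB
        sp2 <- (SS2 - nA * mA^2 - nB * mB^2) / (n - 2)
        tp <- (mA - mB) / sqrt(pmax(sp2, 1e-300) * (1 / nA + 1 / nB))
        null_pos[p] <- max_component_size(tp, thr, ei, ej, TRUE)
        null_neg[p] <- max_component_size(tp, thr, ei, ej, FALSE)
      }
    }
  })

  for (k in seq_along(comps)) {
    null <- if (comps[[k]]$tail == "positive") null_pos else null_neg
    comps[[k]]$p_fwer <- (1 + sum(null >= comps[[k]]$size)) /
      (1 + contrast$n_perm)
  }
  structure(list(components = comps,
                 null_max_size = list(positive = null_pos,
                                      negative = null_neg),
                 t = obs$t, df = obs$df, contrast = contrast,
                 any_significant = any(vapply(comps, function(cp)
                   cp$p_fwer < contrast$alpha, logical(1)))),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("nbs_result [%s, |t| >= %g, %d perms]: %d component(s)\n",
              x$contrast$kind, x$contrast$threshold, x$contrast$n_perm,
              length(x$components)))
  for (cp in x$components)
    cat(sprintf("  %s tail: %d edges, mean t = %.2f, p_FWER = %.4f\n",
                cp$tail, cp$size, cp$mean_t, cp$p_fwer))
  invisible(x)
}

#' Cohen's d from an NBS mean t statistic
#'
#' `d = mean_t / sqrt(df)`, the effect-size convention used for the spectral
#' fingerprint grids.
#'
#' @param mean_t mean t statistic over a component's edges.
#' @param df total degrees of freedom of the contrast.
#' @return scalar Cohen's d.
#' @export
cohens_d <- function(mean_t, df) {
  if (df <= 0) stop("df must be positive")
  mean_t / sqrt(df)
}

#' Spectral fingerprint of a contrast
#'
#' For every (carrier, amplitude) pair of the double filter bank, computes
#' per-subject connectivity matrices at that band pair, thresholds the
#' contrast at the fingerprint height (default 2.5), and records Cohen's d of
#' the largest suprathreshold component's mean t — or `NA` (null marker) when
#' no edge survives. With the full banks this is the 21 x 15 = 315-cell grid.
#'
#' @param recordings nested list `subject -> state -> parcels x time matrix`.
#' @param groups factor of group labels, one per subject.
#' @param contrast a [contrast_spec()] (threshold typically 2.5).
#' @param carriers list of carrier [band_spec()]s (default full 21-band bank).
#' @param amplitudes list of amplitude `band_spec`s (default full 15-band
#'   bank).
#' @param fs sampling rate (Hz).
#' @param mask optional `edge_mask` restricting the edge set.
#' @return an `effect_grid`: matrix carriers x amplitudes of signed Cohen's d
#'   (`NA` = no suprathreshold edge), with band centers as dimnames.
#' @export
spectral_fingerprint <- function(recordings, groups, contrast,
                                 carriers = build_carrier_bank(),
                                 amplitudes = build_amplitude_bank(),
                                 fs = 100, mask = NULL) {
  d_grid <- matrix(NA_real_, length(carriers), length(amplitudes),
                   dimnames = list(
                     sprintf("%.4g", vapply(carriers, `[[`, numeric(1),
                                            "center")),
                     sprintf("%.4g", vapply(amplitudes, `[[`, numeric(1),
                                            "center"))))
  for (ci in seq_along(carriers)) {
    for (ai in seq_along(amplitudes)) {
      mats <- lapply(recordings, function(states) {
        lapply(states, function(pts)
          connectivity_matrix(pts, fs = fs, band = carriers[[ci]],
                              amp_band = amplitudes[[ai]], mask = mask))
      })
      cohort <- conn_cohort(mats, groups)
      stats <- edge_statistics(cohort, contrast)
      sel_pos <- stats$t >= contrast$threshold
      sel_neg <- stats$t <= -contrast$threshold
      best <- NULL
      for (sel in list(sel_pos, sel_neg)) {
        if (any(sel)) {
          cc <- edge_components(cohort$edges[sel, 1], cohort$edges[sel, 2])
          cid <- which.max(cc$sizes)
          eidx <- which(sel)[cc$edge_comp == cid]
          if (is.null(best) || length(eidx) > best$size)
            best <- list(size = length(eidx), mean_t = mean(stats$t[eidx]))
        }
      }
      if (!is.null(best))
        d_grid[ci, ai] <- cohens_d(best$mean_t, stats$df)
    }
  }
  structure(d_grid, class = c("effect_grid", "matrix"))
}

#' Write NBS results as JSON + TSV edge list
#' @param res an `nbs_result`.
#' @param path output path stem.
#' @param cohort the `conn_cohort` (for parcel indices).
#' @return `path`, invisibly.
#' @export
write_nbs_result <- function(res, path, cohort) {
  jsonlite::write_json(
    list(contrast = unclass(res$contrast),
         components = lapply(res$components, function(cp)
           cp[c("tail", "size", "mean_t", "p_fwer")]),
         null_summary = lapply(res$null_max_size, function(nn)
           list(mean = mean(nn), q95 = unname(stats::quantile(nn, 0.95))))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  edges <- do.call(rbind, lapply(seq_along(res$components), function(k) {
    cp <- res$components[[k]]
    data.frame(component = k, tail = cp$tail,
               parcel_i = cohort$edges[cp$edges, 1],
               parcel_j = cohort$edges[cp$edges, 2],
               t = res$t[cp$edges])
  }))
  if (is.null(edges))
    edges <- data.frame(component = integer(), tail = character(),
                        parcel_i = integer(), parcel_j = integer(),
                        t = numeric())
  utils::write.table(edges, paste0(path, "_edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
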