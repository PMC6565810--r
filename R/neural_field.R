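# Stationary eigenmode-superposition model of cortical activity and the
# moment-matching fit of per-subject mode weights.
#
# The model:  Y(r, t) = sum_j a_j m_j(r) cos(2 pi nu t) cos(2 pi omega t)
#                       + sigma eta(r, t),
# a linear superposition of spatial eigenmodes carrying an amplitude-modulated
# carrier oscillation (a beat: each mode contributes pure tones at
# omega - nu and omega + nu) plus spatiotemporal white noise. Connectivity
# depends only on the ratios a_j / sigma, so fitting fixes sigma = 1,
# moment-matches the connectivity-weight distribution over a grid of the
# normalized weights a'_j, and rescales sigma afterwards to the empirical
# time-series SD (a_j = sigma a'_j).

#' Model parameters for the eigenmode superposition
#'
#' @param a mode weights `(a_1, a_2, a_3, a_4, ...)`; non-negative. The
#'   left-right antisymmetric second mode is fixed at 0 by default (the
#'   functional networks carry no significant hemispheric asymmetry); pass a
#'   nonzero `a[2]` explicitly to release it.
#' @param sigma white-noise standard deviation (> 0 unless explicitly
#'   noiseless).
#' @param nu amplitude-modulation frequency (Hz), default 0.1.
#' @param omega carrier frequency (Hz), default 10 (alpha band).
#' @param duration record length (s), default 300.
#' @param fs sampling rate (Hz), default 100; must exceed `2 * omega`.
#' @param seed integer seed for the noise.
#' @return an object of class `model_params`.
#' @export
model_params <- function(a = c(0.2, 0, 0.1, 0.1), sigma = 1, nu = 0.1,
                         omega = 10, duration = 300, fs = 100, seed = 1) {
  if (any(a < 0)) stop("mode weights must be non-negative")
  if (sigma < 0) stop("sigma must be >= 0")
  if (fs <= 2 * omega) stop("fs must exceed 2 * omega (carrier aliasing)")
  structure(list(a = a, sigma = sigma, nu = nu, omega = omega,
                 duration = duration, fs = fs, seed = seed),
            class = "model_params")
}

# the shared modulated-carrier waveform
carrier_wave <- function(nu, omega, duration, fs) {
  tt <- (seq_len(round(duration * fs)) - 1) / fs
  cos(2 * pi * nu * tt) * cos(2 * pi * omega * tt)
}

#' Simulate the vertex-level neural field
#'
#' Direct evaluation of the model on the mesh vertices:
#' `Y[v, t] = sum_j a_j m_j[v] c(t) + sigma eta[v, t]` with
#' `c(t) = cos(2 pi nu t) cos(2 pi omega t)` and i.i.d. standard normal
#' `eta`. Memory scales as vertices x samples; for cohort generation use the
#' statistically exact parcel-level path in [simulate_cohort()].
#'
#' @param params a [model_params()].
#' @param basis an `eigenmode_basis` with at least `length(params$a)` modes.
#' @param scaling `"rms"` (default) scales modes to unit mass-weighted RMS so
#'   the weights are oscillation-to-noise ratios (the convention of
#'   [parcel_mode_values()]); `"mass"` uses the raw mass-orthonormal modes.
#' @return an object of class `simulated_field`: list with `Y`
#'   (vertices x samples) and the generating `params`.
#' @export
simulate_field <- function(params, basis, scaling = c("rms", "mass")) {
  scaling <- match.arg(scaling)
  J <- length(params$a)
  if (ncol(basis$modes) < J) stop("basis has fewer modes than weights")
  cw <- carrier_wave(params$nu, params$omega, params$duration, params$fs)
  modes <- basis$modes[, seq_len(J), drop = FALSE]
  if (scaling == "rms") {
    if (is.null(basis$mass))
      stop("basis has no mass diagonal; use scaling = \"mass\"")
    modes <- modes * sqrt(sum(basis$mass))
  }
  b <- as.numeric(modes %*% params$a)
  Y <- outer(b, cw)
  if (params$sigma > 0) {
    with_seed(params$seed, {
      Y <- Y + params$sigma * matrix(stats::rnorm(length(Y)), nrow(Y))
    })
  }
  structure(list(Y = Y, params = params), class = "simulated_field")
}

#' Project a vertex field onto parcels
#'
#' Area-weighted mean over the vertices of each parcel.
#'
#' @param field a `simulated_field` (or vertices x time matrix).
#' @param parcellation a `parcellation`.
#' @param mesh the shared `surface_mesh`.
#' @return parcels x time matrix.
#' @export
project_to_parcels <- function(field, parcellation, mesh) {
  Y <- if (inherits(field, "simulated_field")) field$Y else field
  w <- vertex_areas(mesh)
  v2p <- parcellation$vertex_to_parcel
  out <- as.matrix(rowsum(Y * w, v2p) / as.numeric(rowsum(w, v2p)))
  dimnames(out) <- NULL
  out
}

# parcel-level sampler, statistically exact: the deterministic part of the
# parcel projection is (PM %*% a) c(t); the projected noise is independent
# across parcels (disjoint vertex supports) with per-parcel SD recorded on
# the parcel_mode_matrix
simulate_parcel_field <- function(params, pm) {
  J <- length(params$a)
  cw <- carrier_wave(params$nu, params$omega, params$duration, params$fs)
  b <- as.numeric(pm[, seq_len(J), drop = FALSE] %*% params$a)
  P <- outer(b, cw)
  if (params$sigma > 0) {
    nsd <- attr(pm, "noise_sd")
    with_seed(params$seed, {
      P <- P + params$sigma * nsd *
        matrix(stats::rnorm(length(P)), nrow(P))
    })
  }
  P
}

# mean and SD of (optionally magnitude-normalized) connectivity values
conn_summary_values <- function(vals, normalize = TRUE) {
  if (normalize) {
    s <- sum(abs(vals))
    if (s == 0) return(c(mu = 0, s = 0))
    vals <- vals / s
  }
  c(mu = mean(vals), s = stats::sd(vals))
}

#' Fit pipeline configuration and memoized model evaluator
#'
#' Bundles everything the moment-matching fit needs: the parcel mode matrix,
#' the edge set over which connectivity moments are computed, the band and
#' record geometry, and one shared noise realization (fixed seed) so the cost
#' surface over the weight grid is deterministic and smooth. Model
#' evaluations are memoized, so coarse-to-fine refinement across many
#' subjects reuses previously visited grid nodes.
#'
#' Evaluation is fast because the carrier filter is linear: the band-passed
#' parcel signal at weights `a'` is `outer(PM a', filt(c)) + filt(Z)`, with
#' `filt(c)` and the filtered noise `filt(Z)` precomputed once.
#'
#' @param pm a `parcel_mode_matrix` from [parcel_mode_values()].
#' @param mask an `edge_mask` (moments use retained edges).
#' @param summary_edges optional integer vector of canonical edge indices over
#'   which the moments are computed (defaults to all retained edges); the
#'   normalization is then taken within this set.
#' @param fs,duration record geometry (Hz, s).
#' @param band carrier band of the empirical pipeline (default `"alpha"`).
#' @param nu,omega model modulation and carrier frequencies (Hz).
#' @param window_s,trim_s orthogonalization window and edge trim (s).
#' @param normalize compute moments on magnitude-normalized weights?
#' @param noise_seed seed of the shared noise realization.
#' @param n_replicates average model moments over this many independent noise
#'   realizations (default 1).
#' @return an object of class `fit_pipeline`.
#' @export
fit_pipeline <- function(pm, mask, summary_edges = NULL, fs = 100,
                         duration = 300, band = "alpha", nu = 0.1,
                         omega = 10, window_s = 2, trim_s = 2,
                         normalize = TRUE, noise_seed = 424242,
                         n_replicates = 1, fast_envelope = TRUE) {
  n <- nrow(pm)
  env_band <- if (fast_envelope) band_limits(band) else NULL
  et <- edge_table(n)
  if (is.null(summary_edges)) summary_edges <- which(mask$retained)
  L <- as.integer(round(duration * fs))
  cw <- carrier_wave(nu, omega, duration, fs)
  fc <- as.numeric(filter_carrier(matrix(cw, 1), fs, band))
  nsd <- attr(pm, "noise_sd")
  fZ <- vector("list", n_replicates)
  with_seed(noise_seed, {
    for (r in seq_len(n_replicates)) {
      Z <- nsd * matrix(stats::rnorm(n * L), n, L)
      fZ[[r]] <- filter_carrier(Z, fs, band)
    }
  })
  pmw <- as.matrix(pm)
  pairs <- et[summary_edges, , drop = FALSE]
  memo <- new.env(parent = emptyenv())
  evaluate <- function(a1, a3, a4) {
    key <- paste(format(c(a1, a3, a4), digits = 12), collapse = "_")
    if (!is.null(memo[[key]])) return(memo[[key]])
    b <- pmw[, 1] * a1 + pmw[, 3] * a3 + pmw[, 4] * a4
    acc <- c(mu = 0, s = 0)
    for (r in seq_len(n_replicates)) {
      P <- outer(b, fc) + fZ[[r]]
      vals <- conn_core(P, fs, pairs, window_s = window_s, trim_s = trim_s,
                        env_band = env_band)
      acc <- acc + conn_summary_values(vals, normalize)
    }
    out <- acc / n_replicates
    memo[[key]] <- out
    out
  }
  structure(list(evaluate = evaluate, summary_edges = summary_edges,
                 n_parcels = n, fs = fs, duration = duration, band = band,
                 nu = nu, omega = omega, window_s = window_s,
                 trim_s = trim_s, normalize = normalize,
                 noise_seed = noise_seed, n_replicates = n_replicates,
                 env_band = env_band, memo = memo, pm = pm, mask = mask),
            class = "fit_pipeline")
}

#' @export
print.fit_pipeline <- function(x, ...) {
  cat(sprintf(paste0("fit_pipeline: %d parcels, %d summary edges, %g s @ %g",
                     " Hz [%s], %d noise replicate(s), %d nodes memoized\n"),
              x$n_parcels, length(x$summary_edges), x$duration, x$fs,
              band_label(x$band), x$n_replicates,
              length(ls(x$memo))))
  invisible(x)
}

#' Model functional connectivity at given weights
#'
#' Simulates the parcel-level model (`sigma = 1` unless given), runs the
#' identical empirical pipeline (carrier band-pass, windowed
#' orthogonalization, envelope correlation) over the pipeline's summary
#' edges, masks and normalizes.
#'
#' @param a_prime weights `(a'_1, a'_3, a'_4)` at unit noise.
#' @param pipeline a [fit_pipeline()].
#' @return a normalized `conn_matrix` over the summary edge set.
#' @export
model_connectivity <- function(a_prime, pipeline) {
  et <- edge_table(pipeline$n_parcels)
  b <- as.matrix(pipeline$pm)[, 1] * a_prime[1] +
    as.matrix(pipeline$pm)[, 3] * a_prime[2] +
    as.matrix(pipeline$pm)[, 4] * a_prime[3]
  params <- model_params(a = c(a_prime[1], 0, a_prime[2], a_prime[3]),
                         sigma = 1, nu = pipeline$nu, omega = pipeline$omega,
                         duration = pipeline$duration, fs = pipeline$fs,
                         seed = pipeline$noise_seed)
  P <- simulate_parcel_field(params, pipeline$pm)
  C <- connectivity_matrix(P, fs = pipeline$fs, band = pipeline$band,
                           edges = pipeline$summary_edges,
                           window_s = pipeline$window_s,
                           trim_s = pipeline$trim_s)
  if (pipeline$normalize) C <- normalize_connectivity(C)
  C
}

#' Connectivity moment summary of a subject recording
#'
#' Runs the pipeline's connectivity estimator on a parcel time series over
#' the pipeline's summary edge set and returns the first two moments of the
#' (normalized) weight distribution — the `(mu_data, sd_data)` pair the cost
#' function matches.
#'
#' @param pts parcels x time matrix.
#' @param pipeline a [fit_pipeline()].
#' @return named numeric `c(mu, s)`.
#' @export
subject_summary <- function(pts, pipeline) {
  filtered <- filter_carrier(pts, pipeline$fs, pipeline$band)
  et <- edge_table(pipeline$n_parcels)
  vals <- conn_core(filtered, pipeline$fs,
                    et[pipeline$summary_edges, , drop = FALSE],
                    window_s = pipeline$window_s, trim_s = pipeline$trim_s,
                    env_band = pipeline$env_band)
  conn_summary_values(vals, pipeline$normalize)
}

#' Precompute the model moment grid
#'
#' Evaluates the model connectivity moments at every node of a 3-D grid of
#' `(a'_1, a'_3, a'_4)`, with one shared noise realization across nodes so the
#' cost surface is deterministic.
#'
#' @param pipeline a [fit_pipeline()].
#' @param axes either a single numeric vector used for all three axes or a
#'   list of three vectors; values must lie in `[0, 0.5]` (the range the best
#'   fits fall into).
#' @return an object of class `fit_grid`: list with `axes`, arrays `mu` and
#'   `s`, and the pipeline.
#' @export
precompute_fit_grid <- function(pipeline, axes = seq(0, 0.5, by = 0.05)) {
  if (!is.list(axes)) axes <- list(a1 = axes, a3 = axes, a4 = axes)
  names(axes) <- c("a1", "a3", "a4")
  if (any(unlist(axes) < 0 | unlist(axes) > 0.5))
    stop("grid axes must lie within [0, 0.5]")
  if (any(lengths(axes) == 0)) stop("empty grid")
  dims <- lengths(axes)
  mu <- array(NA_real_, dims)
  s <- array(NA_real_, dims)
  for (k3 in seq_along(axes$a4))
    for (k2 in seq_along(axes$a3))
      for (k1 in seq_along(axes$a1)) {
        ms <- pipeline$evaluate(axes$a1[k1], axes$a3[k2], axes$a4[k3])
        mu[k1, k2, k3] <- ms["mu"]
        s[k1, k2, k3] <- ms["s"]
      }
  structure(list(axes = axes, mu = mu, s = s, pipeline = pipeline),
            class = "fit_grid")
}

#' @export
print.fit_grid <- function(x, ...) {
  cat(sprintf("fit_grid: %s nodes over [%g, %g]^3\n",
              paste(lengths(x$axes), collapse = " x "),
              min(unlist(x$axes)), max(unlist(x$axes))))
  invisible(x)
}

# argmin of J over a set of candidate nodes (matrix cols a1, a3, a4), with
# lexicographic tie-breaking
fit_cost <- function(mu_model, s_model, data_summary) {
  (data_summary["mu"] - mu_model)^2 + (data_summary["s"] - s_model)^2
}

#' Fit subject mode weights by moment matching
#'
#' Minimizes `J(a'_1, a'_3, a'_4) = (mu_data - mu_model)^2 +
#' (sd_data - sd_model)^2` over the precomputed grid, then (optionally)
#' refines with successively finer local grids around the running minimum.
#' Ties are broken lexicographically by `(a'_1, a'_3, a'_4)`; the boundary
#' flag is set when any coordinate of the solution sits on the edge of the
#' `[0, 0.5]` range.
#'
#' @param data either a named `c(mu, s)` summary (from [subject_summary()])
#'   or a `conn_matrix` computed over the pipeline's summary edges.
#' @param grid a `fit_grid`.
#' @param refine_steps numeric vector of successive local step sizes; each
#'   stage searches a `+-refine_span * step` box around the current minimum.
#'   The default `c(0.025, 0.0125)` refines a 0.1-step coarse grid down to
#'   0.0125 granularity; use `c(..., 0.0025)` to reach the exhaustive-grid
#'   granularity.
#' @param refine_span half-width of each refinement box in steps (default 2).
#' @return an object of class `fit_result`: `a_prime`, cost `J`, `summary`
#'   (model moments at the optimum), `data_summary`, `boundary` flag; `sigma`
#'   and `a` are `NA` until [estimate_sigma()].
#' @export
fit_subject <- function(data, grid, refine_steps = c(0.025, 0.0125),
                        refine_span = 2) {
  pipeline <- grid$pipeline
  data_summary <- if (inherits(data, "conn_matrix")) {
    conn_summary_values(data$values, pipeline$normalize)
  } else {
    data
  }
  if (!all(is.finite(data_summary))) stop("non-finite data summary")
  J <- fit_cost(grid$mu, grid$s, data_summary)
  best_idx <- arrayInd(lex_argmin(J), dim(J))
  best <- c(grid$axes$a1[best_idx[1]], grid$axes$a3[best_idx[2]],
            grid$axes$a4[best_idx[3]])
  best_J <- J[best_idx]
  for (step in refine_steps) {
    cand <- lapply(best, function(b) {
      v <- b + step * (-refine_span:refine_span)
      unique(pmin(pmax(v, 0), 0.5))
    })
    nodes <- as.matrix(expand.grid(a1 = cand[[1]], a3 = cand[[2]],
                                   a4 = cand[[3]]))
    # lexicographic order so ties resolve to the smallest (a1, a3, a4)
    nodes <- nodes[order(nodes[, 1], nodes[, 2], nodes[, 3]), , drop = FALSE]
    for (k in seq_len(nrow(nodes))) {
      ms <- pipeline$evaluate(nodes[k, 1], nodes[k, 2], nodes[k, 3])
      Jk <- fit_cost(ms["mu"], ms["s"], data_summary)
      if (Jk < best_J - 1e-18) {
        best_J <- Jk
        best <- nodes[k, ]
      }
    }
  }
  ms <- pipeline$evaluate(best[1], best[2], best[3])
  structure(list(a_prime = stats::setNames(as.numeric(best),
                                           c("a1", "a3", "a4")),
                 J = as.numeric(best_J),
                 summary = ms, data_summary = data_summary,
                 boundary = any(best <= 0) || any(best >= 0.5),
                 sigma = NA_real_, a = NULL),
            class = "fit_result")
}

# index of the minimum with lexicographic tie-breaking on (a1, a3, a4)
lex_argmin <- function(J) {
  ties <- which(J == min(J))
  if (length(ties) == 1) return(ties)
  idx <- arrayInd(ties, dim(J))
  ties[order(idx[, 1], idx[, 2], idx[, 3])][1]
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: a' = (%.4f, %.4f, %.4f), J = %.3g%s%s\n",
              x$a_prime[1], x$a_prime[2], x$a_prime[3], x$J,
              if (x$boundary) " [boundary]" else "",
              if (is.finite(x$sigma)) sprintf(", sigma = %.3f", x$sigma)
              else ""))
  invisible(x)
}

#' Two-step noise scale estimation
#'
#' Connectivity constrains only the ratios `a_j / sigma`; the absolute scale
#' is set afterwards by choosing `sigma` so that the model time series and
#' the empirical time series have the same pooled standard deviation across
#' time (and parcels). The model is linear in its overall scale, so
#' `sigma = sd_empirical / sd_model(sigma = 1)` and `a_j = sigma * a'_j`.
#'
#' @param fit a `fit_result`.
#' @param empirical_ts the subject's parcels x time matrix (same band-free
#'   raw parcel signals the summary was computed from).
#' @param pipeline the [fit_pipeline()] used for the fit.
#' @return the `fit_result` with `sigma` and `a` filled in.
#' @export
estimate_sigma <- function(fit, empirical_ts, pipeline) {
  sd_emp <- stats::sd(as.numeric(empirical_ts))
  if (sd_emp == 0) stop("zero-variance empirical input")
  params <- model_params(a = c(fit$a_prime[1], 0, fit$a_prime[2],
                               fit$a_prime[3]),
                         sigma = 1, nu = pipeline$nu, omega = pipeline$omega,
                         duration = pipeline$duration, fs = pipeline$fs,
                         seed = pipeline$noise_seed)
  P <- simulate_parcel_field(params, pipeline$pm)
  fit$sigma <- sd_emp / stats::sd(as.numeric(P))
  fit$a <- stats::setNames(fit$sigma * as.numeric(fit$a_prime),
                           c("a1", "a3", "a4"))
  fit
}

#' Persist a fit grid as a directory container
#' @param grid a `fit_grid`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fit_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- as.matrix(expand.grid(grid$axes))
  utils::write.table(
    data.frame(nodes, mu = as.numeric(grid$mu), s = as.numeric(grid$s)),
    file.path(dir, "grid.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  p <- grid$pipeline
  jsonlite::write_json(list(axes = grid$axes, fs = p$fs,
                            duration = p$duration,
                            band = band_label(p$band),
                            noise_seed = p$noise_seed,
                            n_replicates = p$n_replicates,
                            normalize = p$normalize,
                            summary_edges = p$summary_edges),
                       file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}
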