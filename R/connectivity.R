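# Orthogonalized amplitude-envelope correlation networks, edge-reliability
# masking, global normalization and edge-length distributions.
#
# The estimator: parcel signals are band-pass filtered into a carrier band,
# each pair is orthogonalized in 2 s non-overlapping windows (least-squares
# projection removed, both directions), amplitude envelopes are taken as the
# magnitude of the analytic signal, optionally band-passed into an amplitude
# band, and the two directed Pearson correlations are averaged.

# canonical unordered edge enumeration for n parcels: (1,2), (1,3), ...,
# (1,n), (2,3), ... — row-major upper triangle
edge_table <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i = i, j = j)
}

# vectorized Pearson correlation between matching columns of A and B;
# zero-variance columns yield 0 (degenerate contract) and are reported
col_pearson <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  va <- colSums(Ac^2); vb <- colSums(Bc^2)
  eps <- 1e-24
  bad <- va < eps | vb < eps
  r <- colSums(Ac * Bc) / sqrt(pmax(va, eps) * pmax(vb, eps))
  r[bad] <- 0
  if (any(bad))
    attr(r, "degenerate") <- sum(bad)
  r
}

# decimate envelope rows to amp_fs with an anti-alias low-pass
decimate_envelopes <- function(E, fs, amp_fs) {
  fac <- fs / amp_fs
  if (fac != round(fac)) stop("fs must be an integer multiple of amp_fs")
  if (fac == 1) return(E)
  lp <- design_butter(0.4 * amp_fs, 0.5 * amp_fs, fs, 20, "low")
  Ef <- t(apply(E, 1, function(x) signal::filtfilt(lp, x)))
  Ef[, seq(1, ncol(E), by = fac), drop = FALSE]
}

# Core batched estimator. P: channels x time (already carrier-filtered),
# pairs: K x 2 matrix of channel indices. Returns the direction-averaged
# envelope correlation per pair.
conn_core <- function(P, fs, pairs, window_s = 2, trim_s = 2,
                      amp_band = NULL, amp_fs = 2, chunk = 512L,
                      orthogonalize = TRUE, env_band = NULL,
                      env_fac = 4L) {
  w <- as.integer(round(window_s * fs))
  W <- floor(ncol(P) / w)
  if (W < 1) stop("record shorter than one orthogonalization window")
  L <- W * w
  if (!is.null(env_band)) {
    # subband envelopes at reduced rate: only valid without an amplitude band
    if (!is.null(amp_band)) stop("env_band and amp_band are exclusive")
    while (L %% env_fac != 0L) env_fac <- env_fac - 1L
    envelope_of <- function(M)
      envelope_subband_columns(M, fs, env_band[1], env_band[2],
                               fac = env_fac)
    env_rate <- fs / env_fac
  } else {
    envelope_of <- envelope_columns
    env_rate <- fs
  }
  # column orientation (time x channel) avoids repeated transposition
  Pt <- t(P[, seq_len(L), drop = FALSE])
  win_id <- rep(seq_len(W), each = w)
  env0 <- envelope_of(Pt)                       # L' x channels
  auto <- rowsum(Pt^2, win_id, reorder = TRUE)  # W x channels
  n_deg <- 0L

  post_env <- function(E) {
    # E: L' x K envelopes at env_rate; amplitude-band path decimates first
    if (!is.null(amp_band)) {
      E <- t(decimate_envelopes(t(E), fs, amp_fs))
      E <- apply(E, 2, function(x) {
        tryCatch(as.numeric(apply_band_spec(x, amp_band, amp_fs)),
                 error = function(e) rep(0, length(x)))
      })
      tr <- round(trim_s * amp_fs)
    } else {
      tr <- round(trim_s * env_rate)
    }
    keep <- (tr + 1):(nrow(E) - tr)
    if (length(keep) < 8) stop("record too short after edge trimming")
    E[keep, , drop = FALSE]
  }

  env0p <- post_env(env0)

  directed <- function(xi, yi) {
    # envelope correlation of env(x) with env(y orthogonalized to x)
    out <- numeric(length(xi))
    for (s in seq(1, length(xi), by = chunk)) {
      sel <- s:min(s + chunk - 1, length(xi))
      i <- xi[sel]; j <- yi[sel]
      if (orthogonalize) {
        cross <- rowsum(Pt[, i, drop = FALSE] * Pt[, j, drop = FALSE],
                        win_id, reorder = TRUE)           # W x K
        a <- auto[, i, drop = FALSE]
        cw <- ifelse(a < 1e-24, 0, cross / pmax(a, 1e-24))
        R <- Pt[, j, drop = FALSE] - cw[win_id, , drop = FALSE] *
          Pt[, i, drop = FALSE]
      } else {
        R <- Pt[, j, drop = FALSE]
      }
      ER <- post_env(envelope_of(R))
      r <- col_pearson(env0p[, i, drop = FALSE], ER)
      n_deg <<- n_deg + (attr(r, "degenerate") %||% 0L)
      out[sel] <- as.numeric(r)
    }
    out
  }

  r_xy <- directed(pairs[, 1], pairs[, 2])
  r_yx <- directed(pairs[, 2], pairs[, 1])
  if (n_deg > 0)
    warning(n_deg, " degenerate (constant-envelope) directions contributed 0")
  (r_xy + r_yx) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Windowed orthogonalization of one series against another
#'
#' Within each non-overlapping window of `window_s` seconds, the least-squares
#' projection of `y` on `x` is removed; the residual windows are concatenated
#' and a trailing partial window is dropped. Windows in which `x` is all zero
#' leave `y` unchanged (no projection defined).
#'
#' @param x,y equal-length numeric vectors.
#' @param fs sampling rate (Hz).
#' @param window_s window length (seconds), default 2.
#' @return the residual of `y`, of length `floor(length(y) / (window_s*fs)) *
#'   window_s*fs`.
#' @export
orthogonalize_window <- function(x, y, fs, window_s = 2) {
  stopifnot(length(x) == length(y))
  w <- as.integer(round(window_s * fs))
  W <- floor(length(x) / w)
  if (W < 1) stop("series shorter than one window")
  L <- W * w
  x <- x[seq_len(L)]; y <- y[seq_len(L)]
  win_id <- rep(seq_len(W), each = w)
  auto <- as.numeric(rowsum(x^2, win_id))
  cross <- as.numeric(rowsum(x * y, win_id))
  cw <- ifelse(auto < 1e-24, 0, cross / pmax(auto, 1e-24))
  y - cw[win_id] * x
}

#' Orthogonalized envelope correlation of two series
#'
#' Symmetric estimator: the mean of `corr(env(x), env(y | x removed))` and
#' `corr(env(y), env(x | y removed))`, with windowed orthogonalization,
#' analytic-signal envelopes, optional amplitude-band filtering of the
#' envelopes, and the first/last `trim_s` seconds excluded from the
#' correlation. Degenerate (zero-variance) directions contribute 0 with a
#' warning.
#'
#' @param x,y band-limited numeric vectors of equal length.
#' @param fs sampling rate (Hz).
#' @param amp_band optional [band_spec()]; when given, envelopes are
#'   band-passed into it (on a 2 Hz decimated grid) before correlating.
#' @param window_s orthogonalization window (s).
#' @param trim_s edge trim (s) excluded from the correlation.
#' @return a scalar in `[-1, 1]`.
#' @export
envelope_correlation <- function(x, y, fs, amp_band = NULL, window_s = 2,
                                 trim_s = 2) {
  P <- rbind(as.numeric(x), as.numeric(y))
  conn_core(P, fs, pairs = cbind(1L, 2L), window_s = window_s,
            trim_s = trim_s, amp_band = amp_band)
}

#' Functional connectivity matrix of a parcel recording
#'
#' Computes the orthogonalized envelope correlation for parcel pairs after
#' band-pass filtering into `band`. With 58 parcels and no mask this is the
#' full set of (58 x 57)/2 = 1653 unordered connections.
#'
#' @param pts parcels-by-time numeric matrix.
#' @param fs sampling rate (Hz), 100 in the standard pipeline.
#' @param band one of: a canonical band name (`"delta"`, `"theta"`,
#'   `"alpha"`, `"beta"`), a numeric `c(lo, hi)` in Hz, or a [band_spec()]
#'   (carrier filter of the fingerprint pipeline).
#' @param amp_band optional [band_spec()] applied to the envelopes
#'   (fingerprint pipeline).
#' @param mask optional `edge_mask`; only retained edges are computed, the
#'   rest are `NA`.
#' @param edges optional integer vector of canonical edge indices to compute
#'   (overrides `mask`'s edge set; used for moment summaries on a fixed edge
#'   subsample).
#' @param window_s,trim_s see [envelope_correlation()].
#' @return an object of class `conn_matrix`: list with `weights` (symmetric
#'   matrix, `NA` where not computed, zero diagonal), `values` (vector over
#'   `edge_idx`), `edge_idx` (canonical indices), `n_parcels`, `band` label
#'   and `masked`/`normalized` flags.
#' @export
connectivity_matrix <- function(pts, fs = 100, band = "alpha",
                                amp_band = NULL, mask = NULL, edges = NULL,
                                window_s = 2, trim_s = 2) {
  n <- nrow(pts)
  et <- edge_table(n)
  if (!is.null(edges)) {
    edge_idx <- as.integer(edges)
  } else if (!is.null(mask)) {
    if (length(mask$retained) != nrow(et))
      stop("mask edge count does not match parcel count")
    edge_idx <- which(mask$retained)
  } else {
    edge_idx <- seq_len(nrow(et))
  }
  filtered <- filter_carrier(pts, fs, band)
  vals <- conn_core(filtered, fs, et[edge_idx, , drop = FALSE],
                    window_s = window_s, trim_s = trim_s,
                    amp_band = amp_band)
  Wm <- matrix(NA_real_, n, n)
  Wm[cbind(et[edge_idx, 1], et[edge_idx, 2])] <- vals
  Wm[cbind(et[edge_idx, 2], et[edge_idx, 1])] <- vals
  diag(Wm) <- 0
  structure(list(weights = Wm, values = vals, edge_idx = edge_idx,
                 n_parcels = n, band = band_label(band),
                 masked = !is.null(mask) || !is.null(edges),
                 normalized = FALSE),
            class = "conn_matrix")
}

filter_carrier <- function(pts, fs, band) {
  if (inherits(band, "band_spec")) return(apply_band_spec(pts, band, fs))
  if (is.character(band)) {
    cb <- canonical_bands()
    row <- cb[cb$name == band, ]
    if (nrow(row) != 1) stop("unknown band name: ", band)
    return(apply_bandpass(pts, row$lo, row$hi, fs))
  }
  if (is.numeric(band) && length(band) == 2)
    return(apply_bandpass(pts, band[1], band[2], fs))
  stop("unsupported band specification")
}

# pass-band limits (Hz) of any band representation
band_limits <- function(band) {
  if (inherits(band, "band_spec")) return(c(band$pass_lo, band$pass_hi))
  if (is.character(band)) {
    cb <- canonical_bands()
    row <- cb[cb$name == band, ]
    if (nrow(row) != 1) stop("unknown band name: ", band)
    return(c(row$lo, row$hi))
  }
  if (is.numeric(band) && length(band) == 2) return(band)
  stop("unsupported band specification")
}

band_label <- function(band) {
  if (inherits(band, "band_spec")) sprintf("carrier %.3g Hz", band$center)
  else if (is.character(band)) band
  else sprintf("%.3g-%.3g Hz", band[1], band[2])
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("conn_matrix: %d parcels, %d edges [%s]%s%s\n",
              x$n_parcels, length(x$values), x$band,
              if (x$masked) ", masked" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize connectivity weights to unit total magnitude
#'
#' Divides every retained weight by the global sum of the magnitudes of the
#' weights, so that `sum(|w|) = 1`. Relative edge ratios are preserved; the
#' operation is idempotent.
#'
#' @param C a masked `conn_matrix`.
#' @return the normalized `conn_matrix`.
#' @export
normalize_connectivity <- function(C) {
  s <- sum(abs(C$values))
  if (s == 0) stop("all-zero connectivity matrix cannot be normalized")
  C$values <- C$values / s
  C$weights <- C$weights / s
  C$normalized <- TRUE
  C
}

#' Reliability mask for connectivity edges
#'
#' Emulates the surrogate procedure used to reject parcel pairs whose
#' connectivity cannot be distinguished from source-leakage cross-talk: in
#' each iteration, parcel-level carrier signals with independent slow
#' modulators are generated and mixed through the leakage operator; for every
#' parcel pair a synchronized version (shared modulator) is mixed in by a
#' rank-2 update and its recovered orthogonalized envelope correlation is
#' recorded, together with a pool of recovered values from non-synchronized
#' pairs. Edges whose mean recovered value exceeds the given percentile of
#' the pooled surrogate distribution are retained; the same mask is applied
#' to every subject.
#'
#' @param parcellation a `parcellation`.
#' @param leak a `leakage_operator` on the same parcellation.
#' @param n_iter number of iterations (paper-scale 500; >= 2).
#' @param percentile surrogate percentile for rejection (default 99).
#' @param seed integer seed.
#' @param duration simulated record length (s).
#' @param fs sampling rate (Hz).
#' @param carrier carrier frequency of the synthetic sources (Hz).
#' @param mod_freq upper frequency of the slow modulators (Hz).
#' @param noise_sd additive white-noise SD relative to unit carrier power.
#' @param n_surrogate non-synchronized pairs sampled into the surrogate pool
#'   per iteration.
#' @return an object of class `edge_mask`: list with logical `retained`
#'   (canonical edge order), `n_retained`, `threshold`, per-edge mean
#'   recovered values, and derivation metadata.
#' @export
derive_edge_mask <- function(parcellation, leak, n_iter = 500,
                             percentile = 99, seed = 1, duration = 60,
                             fs = 100, carrier = 10, mod_freq = 0.5,
                             noise_sd = 0.2, n_surrogate = 40) {
  if (n_iter < 2) stop("n_iter must be >= 2")
  n <- parcellation$n_parcels
  et <- edge_table(n)
  E <- nrow(et)
  L <- as.integer(round(duration * fs))
  tt <- (seq_len(L) - 1) / fs
  lp <- design_butter(mod_freq, 2 * mod_freq, fs, 20, "low")
  sync_sum <- numeric(E)
  surr <- vector("list", n_iter)
  Wmix <- leak$mixing
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      # independent modulated carriers per parcel
      mods <- t(apply(matrix(stats::rnorm(n * L), n, L), 1,
                      function(x) signal::filtfilt(lp, x)))
      mods <- 1 + 0.8 * mods / pmax(apply(mods, 1, stats::sd), 1e-12)
      phases <- stats::runif(n, 0, 2 * pi)
      S <- mods * cos(outer(phases, 2 * pi * carrier * tt, "+")) +
        noise_sd * matrix(stats::rnorm(n * L), n, L)
      M0 <- Wmix %*% S
      # shared-modulator replacement signals for the synchronized pair
      shared <- signal::filtfilt(lp, stats::rnorm(L))
      shared <- 1 + 0.8 * shared / max(stats::sd(shared), 1e-12)
      ph2 <- stats::runif(2, 0, 2 * pi)
      S12 <- rbind(shared, shared) *
        cos(outer(ph2, 2 * pi * carrier * tt, "+")) +
        noise_sd * matrix(stats::rnorm(2 * L), 2, L)
      # rows of the mixed matrix for each synchronized pair (rank-2 update)
      Pstack <- matrix(0, 2 * E, L)
      for (k in seq_len(E)) {
        i <- et[k, 1]; j <- et[k, 2]
        dS <- S12 - S[c(i, j), , drop = FALSE]
        Pstack[2 * k - 1, ] <- M0[i, ] + Wmix[i, c(i, j)] %*% dS
        Pstack[2 * k, ]     <- M0[j, ] + Wmix[j, c(i, j)] %*% dS
      }
      sync_sum <- sync_sum +
        conn_core(Pstack, fs, cbind(seq(1, 2 * E, 2), seq(2, 2 * E, 2)))
      sidx <- sample(E, min(n_surrogate, E))
      surr[[it]] <- conn_core(as.matrix(M0), fs,
                              et[sidx, , drop = FALSE])
    }
  })
  sync_mean <- sync_sum / n_iter
  thr <- stats::quantile(unlist(surr), percentile / 100, names = FALSE,
                         type = 7)
  retained <- sync_mean > thr
  structure(list(retained = retained, n_retained = sum(retained),
                 threshold = thr, sync_mean = sync_mean,
                 meta = list(n_iter = n_iter, percentile = percentile,
                             spread = leak$spread, seed = seed,
                             duration = duration, carrier = carrier)),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("edge_mask: %d / %d edges retained (surrogate %gth pct = %.4f)\n",
              x$n_retained, length(x$retained), x$meta$percentile,
              x$threshold))
  invisible(x)
}

#' Trivial all-edges mask
#'
#' @param n_parcels parcel count.
#' @return an `edge_mask` retaining every edge.
#' @export
full_edge_mask <- function(n_parcels) {
  E <- nrow(edge_table(n_parcels))
  structure(list(retained = rep(TRUE, E), n_retained = E,
                 threshold = -Inf, sync_mean = rep(NA_real_, E),
                 meta = list(n_iter = 0, percentile = NA, spread = 0)),
            class = "edge_mask")
}

#' Write / read an edge mask as TSV + JSON
#' @param mask an `edge_mask`.
#' @param path path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_edge_mask <- function(mask, path) {
  utils::write.table(data.frame(edge = seq_along(mask$retained),
                                retained = as.integer(mask$retained),
                                sync_mean = mask$sync_mean),
                     paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(c(mask$meta, list(threshold = mask$threshold)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_edge_mask
#' @export
read_edge_mask <- function(path) {
  tab <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(retained = tab$retained == 1L,
                 n_retained = sum(tab$retained == 1L),
                 threshold = meta$threshold,
                 sync_mean = tab$sync_mean,
                 meta = meta[setdiff(names(meta), "threshold")]),
            class = "edge_mask")
}

#' Euclidean edge-length distribution
#'
#' Centroid-to-centroid Euclidean distances for an edge set, with a Gaussian
#' kernel density estimate (Silverman's rule-of-thumb bandwidth) normalized
#' to integrate to one.
#'
#' @param edges integer vector of canonical edge indices, or a logical vector
#'   over all edges.
#' @param parcellation a `parcellation` (centroids used).
#' @return list with `lengths` (mm), `density` (a [stats::density()] object)
#'   and the edge index vector.
#' @export
edge_length_distribution <- function(edges, parcellation) {
  et <- edge_table(parcellation$n_parcels)
  if (is.logical(edges)) edges <- which(edges)
  if (length(edges) == 0) stop("empty edge set")
  d <- sqrt(rowSums((parcellation$centroids[et[edges, 1], , drop = FALSE] -
                     parcellation$centroids[et[edges, 2], , drop = FALSE])^2))
  dens <- if (length(d) > 1) {
    stats::density(d, bw = "nrd0")
  } else {
    stats::density(d, bw = max(d * 0.05, 1))
  }
  list(lengths = d, density = dens, edges = edges)
}

#' Write a connectivity matrix as edge-list TSV
#' @param C a `conn_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(C, path) {
  et <- edge_table(C$n_parcels)
  utils::write.table(
    data.frame(parcel_i = et[C$edge_idx, 1], parcel_j = et[C$edge_idx, 2],
               weight = C$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
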