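# Synthetic multi-subject cohorts with group-by-sleep-state mode-energy
# structure, and synthetic neurodevelopmental outcome scores.

#' Cohort specification
#'
#' Defines the generative structure of a synthetic cohort: subject counts for
#' the extremely-preterm (EP) and healthy-control (HC) groups, per
#' group-by-state mean mode weights `(a_1, a_3, a_4)`, between-subject
#' variation, noise level and record geometry. The defaults encode the study
#' conditions this package emulates: 42 EP and 52 HC subjects, 300 s records
#' at 100 Hz in active sleep (AS) and quiet sleep (QS), quiet sleep carrying
#' more energy in the uniform first mode and slightly less in the two
#' anteroposterior modes, with the state difference attenuated in the EP
#' group.
#'
#' @param n_ep,n_hc subject counts (> 0).
#' @param mode_weight_means nested list `group -> state -> c(a1, a3, a4)` of
#'   mean normalized mode weights.
#' @param mode_weight_sd between-subject SD of the weights (truncated at 0).
#' @param noise_sd white-noise SD `sigma` of the field model.
#' @param duration record length per state (s).
#' @param fs sampling rate (Hz).
#' @param age_mean,age_sd conceptional age at recording (weeks).
#' @param seed master seed; each subject uses `seed + subject index`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ep = 42, n_hc = 52,
                        mode_weight_means = list(
                          EP = list(AS = c(0.22, 0.11, 0.09),
                                    QS = c(0.30, 0.09, 0.08)),
                          HC = list(AS = c(0.20, 0.12, 0.10),
                                    QS = c(0.35, 0.09, 0.08))),
                        mode_weight_sd = 0.05, noise_sd = 1,
                        duration = 300, fs = 100,
                        age_mean = 41.1, age_sd = 1.5, seed = 1) {
  if (n_ep <= 0 || n_hc <= 0) stop("subject counts must be positive")
  if (round(duration * fs) != duration * fs)
    stop("duration x fs must be integral")
  w <- unlist(mode_weight_means)
  if (any(w < 0)) stop("mode weights must be non-negative")
  structure(list(n_ep = n_ep, n_hc = n_hc,
                 mode_weight_means = mode_weight_means,
                 mode_weight_sd = mode_weight_sd, noise_sd = noise_sd,
                 duration = duration, fs = fs, age_mean = age_mean,
                 age_sd = age_sd, seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d EP + %d HC, %g s @ %g Hz, seed %d\n",
              x$n_ep, x$n_hc, x$duration, x$fs, x$seed))
  invisible(x)
}

#' Simulate a synthetic cohort
#'
#' For every subject and sleep state, subject-level mode weights are drawn
#' from the group-by-state means (normal, truncated at zero: weights are
#' amplitudes) and the eigenmode field model is sampled and projected to
#' parcels. All randomness derives from the spec seed via per-subject seeds
#' (`seed + subject index`), so any subject is independently reproducible
#' and the whole cohort is bit-identical for a fixed seed.
#'
#' The default `method = "parcel"` samples the parcel projection of the
#' vertex field directly (identical distribution, no vertex-by-time arrays);
#' `method = "vertex"` runs [simulate_field()] on the mesh and projects,
#' which requires `basis`, `parcellation` and `mesh`.
#'
#' @param spec a [cohort_spec()].
#' @param pm a `parcel_mode_matrix` from [parcel_mode_values()].
#' @param method `"parcel"` (default) or `"vertex"`.
#' @param basis,parcellation,mesh required for `method = "vertex"`.
#' @return an object of class `cohort`: list of subjects, each with `id`,
#'   `group`, `age`, `ts` (named list `AS`/`QS` of parcels x time matrices)
#'   and `true_params` (generating weights and noise SD, recorded because
#'   the data are synthetic).
#' @export
simulate_cohort <- function(spec, pm, method = c("parcel", "vertex"),
                            basis = NULL, parcellation = NULL, mesh = NULL) {
  method <- match.arg(method)
  if (method == "vertex" &&
      (is.null(basis) || is.null(parcellation) || is.null(mesh)))
    stop("vertex method needs basis, parcellation and mesh")
  if (method == "vertex" &&
      length(parcellation$vertex_to_parcel) != nrow(basis$modes))
    stop("basis and parcellation come from different meshes")
  groups <- rep(c("EP", "HC"), c(spec$n_ep, spec$n_hc))
  subjects <- vector("list", length(groups))
  for (idx in seq_along(groups)) {
    g <- groups[idx]
    sseed <- spec$seed + idx
    subjects[[idx]] <- with_seed(sseed, {
      age <- stats::rnorm(1, spec$age_mean, spec$age_sd)
      ts <- list()
      true_w <- list()
      for (state in c("AS", "QS")) {
        mw <- spec$mode_weight_means[[g]][[state]]
        a <- rtrunc_norm0(3, mw, spec$mode_weight_sd)
        true_w[[state]] <- stats::setNames(a, c("a1", "a3", "a4"))
        params <- model_params(a = c(a[1], 0, a[2], a[3]),
                               sigma = spec$noise_sd,
                               duration = spec$duration, fs = spec$fs,
                               seed = NULL)  # RNG already positioned
        ts[[state]] <- if (method == "parcel") {
          simulate_parcel_field(params, pm)
        } else {
          project_to_parcels(simulate_field(params, basis), parcellation,
                             mesh)
        }
      }
      list(id = sprintf("S%03d", idx), group = g, age = age, ts = ts,
           true_params = list(weights = true_w, sigma = spec$noise_sd,
                              seed = sseed))
    })
  }
  structure(list(subjects = subjects, spec = spec,
                 groups = factor(groups, levels = c("EP", "HC"))),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%d EP, %d HC), 2 states each\n",
              length(x$subjects), sum(x$groups == "EP"),
              sum(x$groups == "HC")))
  invisible(x)
}

#' Synthetic neurodevelopmental outcome scores
#'
#' Generates per-EP-subject outcome scores linearly coupled to a
#' connectivity-change covariate:
#' `score = intercept + coupling * change + age_effect * (age - mean age) +
#' noise`. The default coupling sign is negative (stronger sleep-related
#' connectivity change predicting poorer scores is modelled with R < 0, as in
#' the visual-performance association this emulates). Generating parameters
#' are stored in the result for recovery tests.
#'
#' @param cohort a `cohort`.
#' @param connectivity_change numeric, one value per EP subject (AS minus QS
#'   mean connectivity, or any per-subject covariate).
#' @param coupling slope on `connectivity_change` for the visual score.
#' @param coupling_social slope for the social-emotional score (default 0:
#'   no true association).
#' @param noise_sd residual SD of the scores.
#' @param age_effect slope on (centred) conceptional age.
#' @param intercept score intercept.
#' @param seed integer seed.
#' @return an `outcome_table` data.frame with columns `subject`, `group`,
#'   `age`, `visual`, `social_emotional`; generating parameters in
#'   `attr(, "generating")`.
#' @export
simulate_outcomes <- function(cohort, connectivity_change, coupling = -0.5,
                              coupling_social = 0, noise_sd = 0.1,
                              age_effect = 0, intercept = 100, seed = 1) {
  ep <- which(cohort$groups == "EP")
  if (length(connectivity_change) != length(ep))
    stop("need one connectivity_change value per EP subject")
  ages <- vapply(cohort$subjects[ep], `[[`, numeric(1), "age")
  agec <- ages - mean(ages)
  out <- with_seed(seed, {
    visual <- intercept + coupling * connectivity_change +
      age_effect * agec + stats::rnorm(length(ep), 0, noise_sd)
    social <- intercept + coupling_social * connectivity_change +
      age_effect * agec + stats::rnorm(length(ep), 0, noise_sd)
    data.frame(subject = vapply(cohort$subjects[ep], `[[`, character(1),
                                "id"),
               group = "EP", age = ages, visual = visual,
               social_emotional = social)
  })
  attr(out, "generating") <- list(coupling = coupling,
                                  coupling_social = coupling_social,
                                  noise_sd = noise_sd,
                                  age_effect = age_effect,
                                  intercept = intercept, seed = seed)
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Write a cohort as array containers + manifest
#'
#' Each subject-state recording is written as a TSV array (parcels x time)
#' with a JSON sidecar (`fs`, channel names, units) under `dir`, plus a
#' cohort `manifest.tsv` (subject, group, state, file, age, true generating
#' weights).
#'
#' @param cohort a `cohort`.
#' @param dir output directory.
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in cohort$subjects) {
    for (state in names(s$ts)) {
      f <- sprintf("%s_%s.tsv", s$id, state)
      utils::write.table(s$ts[[state]], file.path(dir, f), sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(
        list(fs = cohort$spec$fs, units = "uV",
             channels = sprintf("parcel%02d", seq_len(nrow(s$ts[[state]])))),
        file.path(dir, paste0(f, ".json")), auto_unbox = TRUE)
      w <- s$true_params$weights[[state]]
      rows[[length(rows) + 1]] <-
        data.frame(subject = s$id, group = s$group, state = state, file = f,
                   age = s$age, a1 = w[1], a3 = w[2], a4 = w[3],
                   sigma = s$true_params$sigma)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory containing `manifest.tsv`.
#' @return a `cohort` (spec reduced to the recorded fields).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  ids <- unique(manifest$subject)
  fs <- jsonlite::read_json(file.path(dir, paste0(manifest$file[1], ".json")),
                            simplifyVector = TRUE)$fs
  subjects <- lapply(ids, function(id) {
    sub <- manifest[manifest$subject == id, ]
    ts <- lapply(stats::setNames(sub$state, sub$state), function(st) {
      as.matrix(utils::read.table(
        file.path(dir, sub$file[sub$state == st]), sep = "\t"))
    })
    ts <- lapply(ts, function(m) { dimnames(m) <- NULL; m })
    w <- lapply(stats::setNames(sub$state, sub$state), function(st) {
      r <- sub[sub$state == st, ]
      stats::setNames(c(r$a1, r$a3, r$a4), c("a1", "a3", "a4"))
    })
    list(id = id, group = sub$group[1], age = sub$age[1], ts = ts,
         true_params = list(weights = w, sigma = sub$sigma[1], seed = NA))
  })
  groups <- vapply(subjects, `[[`, character(1), "group")
  structure(list(subjects = subjects,
                 spec = list(fs = fs,
                             duration = ncol(subjects[[1]]$ts[[1]]) / fs),
                 groups = factor(groups, levels = c("EP", "HC"))),
            class = "cohort")
}
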