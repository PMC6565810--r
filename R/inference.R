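# Group-level inference: mixed-design ANOVA on fitted mode weights, partial
# correlations with FDR control for brain-behavior coupling, and hemispheric
# asymmetry tests.

#' Mixed-design (split-plot) ANOVA
#'
#' One between-subject factor (group) and one within-subject factor (state,
#' both states observed in every subject). Sums of squares come from the
#' standard two-stratum decomposition (`aov` with a subject error term);
#' the within-effect denominator df is `(N - g)(k - 1)` — 92 for 94 subjects
#' in two groups and two states. Effect sizes are reported both as classic
#' eta-squared (effect SS / total SS) and partial eta-squared
#' (effect SS / (effect SS + error SS)).
#'
#' @param values data.frame with columns `subject`, `group`, `state`, `value`
#'   (long format; two states per subject).
#' @return an `anova_table` data.frame, one row per effect (`group`,
#'   `state`, `group:state`) with `F`, `df1`, `df2`, `p`, `eta2`,
#'   `eta2_partial`.
#' @export
mixed_anova <- function(values) {
  req <- c("subject", "group", "state", "value")
  if (!all(req %in% names(values))) stop("need columns ", paste(req,
                                                                collapse = ", "))
  values$subject <- factor(values$subject)
  values$group <- factor(values$group)
  values$state <- factor(values$state)
  counts <- table(values$subject, values$state)
  if (any(counts != 1)) stop("every subject needs exactly one value per state")
  fit <- stats::aov(value ~ group * state + Error(subject / state),
                    data = values)
  sm <- summary(fit)
  # between stratum: group + residuals; within stratum: state, group:state,
  # residuals
  btw <- sm[["Error: subject"]][[1]]
  wth <- sm[["Error: subject:state"]][[1]]
  ss <- c(group = tab_get(btw, "group", "Sum Sq"),
          state = tab_get(wth, "state", "Sum Sq"),
          inter = tab_get(wth, "group:state", "Sum Sq"),
          err_b = tab_get(btw, "Residuals", "Sum Sq"),
          err_w = tab_get(wth, "Residuals", "Sum Sq"))
  ss_total <- sum(ss)
  out <- data.frame(
    effect = c("group", "state", "group:state"),
    F = c(tab_get(btw, "group", "F value"),
          tab_get(wth, "state", "F value"),
          tab_get(wth, "group:state", "F value")),
    df1 = c(tab_get(btw, "group", "Df"),
            tab_get(wth, "state", "Df"),
            tab_get(wth, "group:state", "Df")),
    df2 = c(tab_get(btw, "Residuals", "Df"),
            tab_get(wth, "Residuals", "Df"),
            tab_get(wth, "Residuals", "Df")),
    p = c(tab_get(btw, "group", "Pr(>F)"),
          tab_get(wth, "state", "Pr(>F)"),
          tab_get(wth, "group:state", "Pr(>F)")),
    eta2 = c(ss["group"], ss["state"], ss["inter"]) / ss_total,
    eta2_partial = c(ss["group"] / (ss["group"] + ss["err_b"]),
                     ss["state"] / (ss["state"] + ss["err_w"]),
                     ss["inter"] / (ss["inter"] + ss["err_w"]))
  )
  rownames(out) <- NULL
  # a literally absent effect (zero sum of squares, e.g. identical state
  # values in every subject) is 0/0 in the F ratio; report F = 0, p = 1
  zero <- c(ss["group"], ss["state"], ss["inter"]) < 1e-12 * max(ss_total,
                                                                 1e-300)
  out$F[zero] <- 0
  out$p[zero] <- 1
  class(out) <- c("anova_table", "data.frame")
  out
}

# pull one cell out of a summary.aov table by (trimmed) row name
tab_get <- function(tab, row, col) {
  i <- match(row, trimws(rownames(tab)))
  if (is.na(i)) return(NA_real_)
  as.numeric(tab[i, col])
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlation of the residuals of `x` and `y` after regressing each on `z`.
#' The p-value uses a t distribution with `n - k - 2` degrees of freedom
#' (`k` = number of covariates) and the confidence interval uses the Fisher
#' z transform with standard error `1 / sqrt(df)`.
#'
#' @param x,y numeric vectors.
#' @param z covariate vector or matrix (same number of rows).
#' @param conf confidence level (default 0.95).
#' @return a `partial_corr` list: `R`, `p` (two-tailed), `ci`, `df`, `n`,
#'   `n_covariates`.
#' @export
partial_pearson <- function(x, y, z, conf = 0.95) {
  z <- as.matrix(z)
  n <- length(x)
  stopifnot(length(y) == n, nrow(z) == n)
  k <- ncol(z)
  if (n < k + 4) stop("need at least k + 4 observations")
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  if (stats::sd(rx) < 1e-10 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) < 1e-10 * max(stats::sd(y), 1e-300))
    stop("zero residual variance")
  R <- stats::cor(rx, ry)
  df <- n - k - 2
  tval <- R * sqrt(df / (1 - R^2))
  p <- 2 * stats::pt(-abs(tval), df)
  zr <- atanh(R)
  zcrit <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(zr + c(-1, 1) * zcrit / sqrt(df))
  structure(list(R = R, p = p, ci = ci, df = df, n = n, n_covariates = k),
            class = "partial_corr")
}

#' @export
print.partial_corr <- function(x, ...) {
  cat(sprintf("partial R = %.3f, p = %.4g, 95%% CI [%.3f, %.3f] (n = %d)\n",
              x$R, x$p, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1), same order as input.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Hemispheric asymmetry of aggregate connectivity
#'
#' For every subject and state, the mean retained within-left-hemisphere and
#' within-right-hemisphere edge weight is computed; a paired two-tailed
#' Wilcoxon signed-rank test compares left vs right across subjects in each
#' of the four group-by-state cells, with BH-FDR over the four tests. A
#' Shapiro-Wilk normality prescreen of the left-right differences is
#' recorded (the rationale for the non-parametric test). All-zero difference
#' vectors yield p = 1.
#'
#' @param cohort a [conn_cohort()].
#' @param parcellation the `parcellation` (hemisphere labels used).
#' @return an `asymmetry_table` data.frame, one row per group x state:
#'   mean left / right aggregates, Wilcoxon `V`, `p`, `p_fdr`, `shapiro_p`.
#' @export
hemispheric_asymmetry <- function(cohort, parcellation) {
  hemi <- parcellation$hemisphere
  ei <- cohort$edges[, 1]; ej <- cohort$edges[, 2]
  left_edges <- hemi[ei] == "L" & hemi[ej] == "L"
  right_edges <- hemi[ei] == "R" & hemi[ej] == "R"
  if (!any(left_edges) || !any(right_edges))
    stop("no within-hemisphere edges in the retained set")
  rows <- list()
  for (g in levels(cohort$groups)) {
    for (st in c("AS", "QS")) {
      subj <- which(cohort$groups == g)
      lvals <- colMeans(cohort$W[left_edges, subj, st, drop = FALSE])
      rvals <- colMeans(cohort$W[right_edges, subj, st, drop = FALSE])
      d <- as.numeric(lvals) - as.numeric(rvals)
      if (all(d == 0)) {
        V <- 0; p <- 1; sh <- NA_real_
      } else {
        wt <- suppressWarnings(stats::wilcox.test(
          as.numeric(lvals), as.numeric(rvals), paired = TRUE,
          exact = length(d) <= 25))
        V <- unname(wt$statistic); p <- wt$p.value
        sh <- if (length(d) >= 3 && stats::sd(d) > 0)
          stats::shapiro.test(d)$p.value else NA_real_
      }
      rows[[length(rows) + 1]] <-
        data.frame(group = g, state = st, left = mean(lvals),
                   right = mean(rvals), V = V, p = p, shapiro_p = sh)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  class(out) <- c("asymmetry_table", "data.frame")
  out
}

#' Brain-behavior partial correlations over an interaction network
#'
#' Per EP subject, the mean retained weight over the given edge set is
#' computed in AS and in QS; the AS - QS difference is correlated with each
#' outcome score (partial Pearson controlling for conceptional age at
#' recording), and all tests are BH-FDR adjusted jointly.
#'
#' @param cohort a [conn_cohort()] (EP subjects must match `outcomes`).
#' @param interaction_edges integer indices into the cohort's retained edge
#'   set (e.g. the edges of a significant interaction component), or a
#'   logical vector over retained edges.
#' @param outcomes an `outcome_table` from [simulate_outcomes()] (or any
#'   data.frame with `age` and score columns).
#' @param scores names of the outcome columns to test.
#' @return a `brain_behavior_table` data.frame: one row per score with `R`,
#'   `p`, `ci_lo`, `ci_hi`, `p_fdr`, `n`; the per-subject connectivity
#'   change is attached as `attr(, "change")`.
#' @export
brain_behavior <- function(cohort, interaction_edges, outcomes,
                           scores = c("visual", "social_emotional")) {
  if (is.logical(interaction_edges)) interaction_edges <-
      which(interaction_edges)
  if (length(interaction_edges) == 0) stop("empty edge set")
  ep <- which(cohort$groups == "EP")
  if (nrow(outcomes) != length(ep))
    stop("outcomes must have one row per EP subject")
  change <- colMeans(cohort$W[interaction_edges, ep, "AS", drop = FALSE]) -
    colMeans(cohort$W[interaction_edges, ep, "QS", drop = FALSE])
  change <- as.numeric(change)
  rows <- lapply(scores, function(sc) {
    pc <- partial_pearson(change, outcomes[[sc]], outcomes$age)
    data.frame(score = sc, R = pc$R, p = pc$p, ci_lo = pc$ci[1],
               ci_hi = pc$ci[2], n = pc$n)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  attr(out, "change") <- change
  class(out) <- c("brain_behavior_table", "data.frame")
  out
}
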