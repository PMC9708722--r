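#' Group comparison table
#'
#' Reproduces the demographics/clinical comparison layout: approximately
#' normal continuous variables via the pooled t test, binary variables via
#' the uncorrected Pearson chi-square, and skewed counts/scores via
#' Mann-Whitney with median (IQR) summaries. Variable routing is
#' configurable and defaults to the conventional assignment (t: age,
#' education, FSRP, MoCA, ALPS, Eg; chi2: sex and vascular risk factors;
#' Mann-Whitney: lacune count, WMH volume, EPVS scores).
#'
#' @param cohort cohort data.frame (see [simulate_cohort()]).
#' @param grouping name of the 2-level grouping column (default "group").
#' @param routing named list with character vectors `t`, `chi2`, `mw`;
#'   entries absent from the data are skipped.
#' @return data.frame: `variable`, `test`, `summary_1`, `summary_2`,
#'   `statistic`, `p`, with attribute `groups`.
#' @export
group_compare_table <- function(cohort, grouping = "group",
                                routing = list(
                                  t = c("age", "education", "FSRP", "MoCA",
                                        "mean_alps", "Eg"),
                                  chi2 = c("sex", "hypertension", "diabetes",
                                           "hyperlipemia", "smoking"),
                                  mw = c("lacune", "WMH", "EPVS_bg", "EPVS_cso"))) {
  g <- cohort[[grouping]]
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 groups")
  if (length(lev) > 2) stop("group comparison is defined for 2 groups")
  i1 <- g == lev[1]; i2 <- g == lev[2]
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)

  for (v in intersect(routing$t, names(cohort))) {
    x1 <- cohort[[v]][i1]; x2 <- cohort[[v]][i2]
    if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
      add(variable = v, test = "t", summary_1 = sprintf("%.2f", mean(x1)),
          summary_2 = sprintf("%.2f", mean(x2)), statistic = NA_real_, p = NA_real_)
      next
    }
    r <- t_from_summary(mean(x1), stats::sd(x1), length(x1),
                        mean(x2), stats::sd(x2), length(x2))
    add(variable = v, test = "t",
        summary_1 = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
        summary_2 = sprintf("%.2f ± %.2f", mean(x2), stats::sd(x2)),
        statistic = r$t, p = r$p)
  }
  for (v in intersect(routing$chi2, names(cohort))) {
    a <- sum(cohort[[v]][i1] == 1); b <- sum(i1) - a
    cc <- sum(cohort[[v]][i2] == 1); d <- sum(i2) - cc
    res <- tryCatch(chi2_2x2(a, b, cc, d), error = function(e) NULL)
    add(variable = v, test = "chi2",
        summary_1 = sprintf("%d (%.1f%%)", a, 100 * a / sum(i1)),
        summary_2 = sprintf("%d (%.1f%%)", cc, 100 * cc / sum(i2)),
        statistic = if (is.null(res)) NA_real_ else res$chi2,
        p = if (is.null(res)) NA_real_ else res$p)
  }
  iqr_fmt <- function(x) sprintf("%.2g (%.2g–%.2g)", stats::median(x),
                                 stats::quantile(x, 0.25), stats::quantile(x, 0.75))
  for (v in intersect(routing$mw, names(cohort))) {
    x1 <- cohort[[v]][i1]; x2 <- cohort[[v]][i2]
    if (length(unique(c(x1, x2))) == 1) {
      add(variable = v, test = "mann_whitney", summary_1 = iqr_fmt(x1),
          summary_2 = iqr_fmt(x2), statistic = NA_real_, p = NA_real_)
      next
    }
    r <- mann_whitney(x1, x2)
    add(variable = v, test = "mann_whitney", summary_1 = iqr_fmt(x1),
        summary_2 = iqr_fmt(x2), statistic = r$Z, p = r$p)
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lev
  out
}

#' Empirical type-I error calibration of the comparison tests
#'
#' Simulates null two-group data and records the rejection rate of each
#' test at the nominal level: the pooled t on Normal samples, the Pearson
#' chi-square on balanced Bernoulli counts, and Mann-Whitney on Normal
#' samples.
#'
#' @param n_sims simulated datasets per test (default 2000).
#' @param n_per_group group size (default 30).
#' @param alpha nominal level (default 0.05).
#' @param seed RNG seed.
#' @return named numeric: rejection rates for `t`, `chi2`, `mann_whitney`.
#' @export
calibrate_type1 <- function(n_sims = 2000L, n_per_group = 30L, alpha = 0.05,
                            seed = 1L) {
  set.seed(seed)
  rej <- c(t = 0L, chi2 = 0L, mann_whitney = 0L)
  n_chi2 <- 0L
  for (i in seq_len(n_sims)) {
    x <- stats::rnorm(n_per_group); y <- stats::rnorm(n_per_group)
    r <- t_from_summary(mean(x), stats::sd(x), n_per_group,
                        mean(y), stats::sd(y), n_per_group)
    if (r$p < alpha) rej["t"] <- rej["t"] + 1L
    a <- stats::rbinom(1, n_per_group, 0.5)
    cc <- stats::rbinom(1, n_per_group, 0.5)
    res <- tryCatch(chi2_2x2(a, n_per_group - a, cc, n_per_group - cc),
                    error = function(e) NULL)
    if (!is.null(res)) {
      n_chi2 <- n_chi2 + 1L
      if (res$p < alpha) rej["chi2"] <- rej["chi2"] + 1L
    }
    mw <- mann_whitney(stats::rnorm(n_per_group), stats::rnorm(n_per_group))
    if (mw$p < alpha) rej["mann_whitney"] <- rej["mann_whitney"] + 1L
  }
  c(t = rej[["t"]] / n_sims, chi2 = rej[["chi2"]] / max(n_chi2, 1L),
    mann_whitney = rej[["mann_whitney"]] / n_sims)
}
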