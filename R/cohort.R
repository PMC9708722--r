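#' Cohort simulation parameters
#'
#' Defaults emulate the study cohort: 77 normal-cognition (NC) and 79
#' vascular cognitive impairment (VCI) subjects; per-group ALPS-index
#' distributions Normal(1.95, 0.11) and Normal(1.80, 0.16); demographics and
#' vascular-risk-factor prevalences matching the published group summaries.
#' The structural model is the mediation diagram: global efficiency
#' `Eg = eg_intercept + a * ALPS + e1`, and
#' `MoCA = moca_intercept + c_prime * ALPS + b * Eg + covariate terms +
#' group shift + e2`, clipped to [0, 30]. Default paths are chosen so the
#' implied indirect effect `a * b` equals 7.46 with a mediation ratio of
#' about 1/3 of the total ALPS effect, and so group means of Eg (~0.20) and
#' MoCA (~26 vs ~16) land in the published range.
#'
#' @param n named integer vector `c(NC = , VCI = )` (each >= 3).
#' @param alps_mean,alps_sd named numeric `c(NC = , VCI = )`.
#' @param a ALPS -> Eg path.
#' @param b Eg -> MoCA path.
#' @param c_prime direct ALPS -> MoCA path.
#' @param eg_intercept,eg_sd intercept and residual SD of the Eg equation.
#' @param moca_intercept,moca_sd intercept and residual SD of the MoCA
#'   equation.
#' @param group_moca_shift additional MoCA shift applied to the VCI group
#'   (non-glymphatic injury not routed through ALPS or Eg).
#' @param beta_age,beta_edu MoCA covariate coefficients (age and education
#'   enter centered at 61 y and 12.6 y).
#' @param seed RNG seed.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n = c(NC = 77L, VCI = 79L),
                          alps_mean = c(NC = 1.95, VCI = 1.80),
                          alps_sd = c(NC = 0.11, VCI = 0.16),
                          a = 0.02, b = 373, c_prime = 15.14,
                          eg_intercept = 0.1625, eg_sd = 0.006,
                          moca_intercept = -78.3, moca_sd = 2.5,
                          group_moca_shift = -7,
                          beta_age = -0.03, beta_edu = 0.15,
                          seed = 1L) {
  stopifnot(all(n >= 3), all(alps_sd >= 0), eg_sd >= 0, moca_sd >= 0)
  structure(as.list(environment()), class = "cohort_params")
}

# per-group marginal distributions of covariates (published group summaries)
cohort_covariate_spec <- function() {
  list(
    age = list(NC = c(60.48, 4.51), VCI = c(61.65, 5.35)),
    education = list(NC = c(12.84, 2.52), VCI = c(12.47, 2.71)),
    sex_female_p = c(NC = 25 / 77, VCI = 20 / 79),
    hypertension_p = c(NC = 32 / 77, VCI = 56 / 79),
    hyperlipemia_p = c(NC = 46 / 77, VCI = 32 / 79),
    diabetes_p = c(NC = 22 / 77, VCI = 35 / 79),
    smoking_p = c(NC = 25 / 77, VCI = 47 / 79),
    fsrp = list(NC = c(6.69, 3.65), VCI = c(10.46, 4.30)),
    lacune_nb = list(NC = c(size = 0.5, mu = 0.6), VCI = c(size = 1.2, mu = 5)),
    wmh_lnorm = list(NC = c(meanlog = log(0.45), sdlog = 1.1),
                     VCI = c(meanlog = log(4.25), sdlog = 1.1)),
    epvs_bg = list(NC = c(0.10, 0.30, 0.45, 0.10, 0.05),
                   VCI = c(0.05, 0.15, 0.60, 0.15, 0.05)),
    epvs_cso = list(NC = c(0.30, 0.45, 0.20, 0.04, 0.01),
                    VCI = c(0.25, 0.45, 0.25, 0.04, 0.01))
  )
}

#' Simulate a cohort table under the mediation structural model
#'
#' Generates per-subject covariates, ALPS index, global efficiency and MoCA
#' following [cohort_params()]. Deterministic under a fixed seed.
#'
#' @param params a [cohort_params()].
#' @return data.frame with columns `id`, `group`, `subgroup`, `age`, `sex`
#'   (1 = female), `education`, `hypertension`, `diabetes`, `hyperlipemia`,
#'   `smoking`, `FSRP`, `lacune`, `WMH`, `EPVS_bg`, `EPVS_cso`,
#'   `mean_alps`, `Eg`, `MoCA`.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  spec <- cohort_covariate_spec()
  groups <- rep(names(params$n), params$n)
  ntot <- length(groups)

  draw_norm <- function(sp) {
    out <- numeric(ntot)
    for (g in unique(groups)) {
      i <- groups == g
      out[i] <- stats::rnorm(sum(i), sp[[g]][1], sp[[g]][2])
    }
    out
  }
  draw_bin <- function(p) {
    out <- integer(ntot)
    for (g in unique(groups)) {
      i <- groups == g
      out[i] <- stats::rbinom(sum(i), 1, p[[g]])
    }
    out
  }
  draw_epvs <- function(sp) {
    out <- integer(ntot)
    for (g in unique(groups)) {
      i <- groups == g
      out[i] <- sample(0:4, sum(i), replace = TRUE, prob = sp[[g]])
    }
    out
  }

  age <- draw_norm(spec$age)
  education <- pmax(6, draw_norm(spec$education))
  sex <- draw_bin(spec$sex_female_p)
  hypertension <- draw_bin(spec$hypertension_p)
  hyperlipemia <- draw_bin(spec$hyperlipemia_p)
  diabetes <- draw_bin(spec$diabetes_p)
  smoking <- draw_bin(spec$smoking_p)
  fsrp <- pmax(0, draw_norm(spec$fsrp))
  lacune <- integer(ntot); wmh <- numeric(ntot)
  for (g in unique(groups)) {
    i <- groups == g
    nb <- spec$lacune_nb[[g]]
    lacune[i] <- stats::rnbinom(sum(i), size = nb["size"], mu = nb["mu"])
    ln <- spec$wmh_lnorm[[g]]
    wmh[i] <- stats::rlnorm(sum(i), ln["meanlog"], ln["sdlog"])
  }
  epvs_bg <- draw_epvs(spec$epvs_bg)
  epvs_cso <- draw_epvs(spec$epvs_cso)

  alps <- numeric(ntot)
  for (g in unique(groups)) {
    i <- groups == g
    alps[i] <- stats::rnorm(sum(i), params$alps_mean[[g]], params$alps_sd[[g]])
  }
  alps <- pmax(alps, 0.1)

  eg <- params$eg_intercept + params$a * alps + stats::rnorm(ntot, 0, params$eg_sd)
  moca <- params$moca_intercept + params$c_prime * alps + params$b * eg +
    params$beta_age * (age - 61) + params$beta_edu * (education - 12.6) +
    ifelse(groups == "VCI", params$group_moca_shift, 0) +
    stats::rnorm(ntot, 0, params$moca_sd)
  moca <- pmin(pmax(moca, 0), 30)

  subgroup <- character(ntot)
  nc_sub <- c("HC", "SVDN", "PSCN"); nc_w <- c(30, 33, 14)
  vci_sub <- c("SVCI", "PSCI"); vci_w <- c(40, 39)
  i_nc <- which(groups == "NC"); i_vci <- which(groups == "VCI")
  subgroup[i_nc] <- rep(nc_sub, length.out = length(i_nc),
                        times = pmax(1, round(nc_w / sum(nc_w) * length(i_nc))))[seq_along(i_nc)]
  subgroup[i_vci] <- rep(vci_sub, length.out = length(i_vci),
                         times = pmax(1, round(vci_w / sum(vci_w) * length(i_vci))))[seq_along(i_vci)]

  data.frame(id = sprintf("S%03d", seq_len(ntot)), group = groups,
             subgroup = subgroup, age = age, sex = sex,
             education = education, hypertension = hypertension,
             diabetes = diabetes, hyperlipemia = hyperlipemia,
             smoking = smoking, FSRP = fsrp, lacune = lacune, WMH = wmh,
             EPVS_bg = epvs_bg, EPVS_cso = epvs_cso,
             mean_alps = alps, Eg = eg, MoCA = moca,
             stringsAsFactors = FALSE)
}
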