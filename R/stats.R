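#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t with pooled variance (the form that reproduces published
#' group-comparison tables computed in SPSS), computable from means, SDs and
#' group sizes alone.
#'
#' @param m1,s1,n1 mean, SD, n of group 1.
#' @param m2,s2,n2 mean, SD, n of group 2.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) stop("both group variances are zero")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction):
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1, with the odds
#' ratio `ad / bc`.
#'
#' @param a,b,c,d cell counts; rows are groups, columns outcome
#'   (present/absent).
#' @return list with `chi2`, `df = 1`, `p`, `odds_ratio`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in 2x2 table")
  N <- sum(cells)
  chi2 <- N * (a * d - b * c)^2 / prod(margins)
  or <- if (b > 0 && c > 0) (a * d) / (b * c) else NA_real_
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       odds_ratio = or)
}

#' Mann-Whitney U with tie-corrected normal approximation
#'
#' `U` is computed for the first sample (`U = 0` when all `x` fall below all
#' `y`), using midranks for ties. `Z = (U - n1 n2 / 2) / sigma_U` with the
#' tie-corrected variance; two-sided p from the normal approximation (no
#' continuity correction, the SPSS convention).
#'
#' @param x,y numeric samples.
#' @return list with `U`, `Z`, `p`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  var_u <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (var_u <= 0) {
    warning("all values tied across both samples")
    return(list(U = U, Z = 0, p = 1))
  }
  Z <- (U - mu) / sqrt(var_u)
  list(U = U, Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}

#' Pearson or Spearman correlation with t-approximation p-value
#'
#' @param x,y numeric vectors, `n >= 3`, finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p` (two-sided), `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y, method = method)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Binary logistic regression with odds ratios and Wald intervals
#'
#' Maximum likelihood via IRLS (`stats::glm`), Wald confidence intervals,
#' odds ratios per coefficient. A designated predictor can be rescaled to
#' percentage form (multiplied by 100 before fitting), the convention used
#' for reporting the ALPS index so that the OR refers to a one-percentage-
#' point change.
#'
#' @param X data.frame or matrix of predictors.
#' @param y binary response (0/1 or logical).
#' @param alpha 1 - confidence level for the Wald CI.
#' @param percent optional name(s) of predictors to multiply by 100.
#' @return data.frame per predictor: `estimate`, `OR`, `ci_lo`, `ci_hi`,
#'   `p`; intercept included.
#' @export
logistic_fit <- function(X, y, alpha = 0.05, percent = NULL) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (nrow(X) <= ncol(X)) stop("more predictors than observations")
  for (p in percent) X[[p]] <- X[[p]] * 100
  mm <- stats::model.matrix(~ ., X)
  if (qr(mm)$rank < ncol(mm)) stop("rank-deficient design (constant or collinear predictor)")
  fit <- suppressWarnings(stats::glm.fit(mm, y, family = stats::binomial()))
  beta <- fit$coefficients
  if (!fit$converged || any(abs(beta[-1]) > 15))
    stop("complete or quasi-complete separation detected")
  w <- fit$weights
  cov <- solve(crossprod(mm * sqrt(w)))
  se <- sqrt(diag(cov))
  z <- stats::qnorm(1 - alpha / 2)
  data.frame(term = names(beta), estimate = unname(beta),
             OR = exp(unname(beta)),
             ci_lo = exp(unname(beta) - z * se), ci_hi = exp(unname(beta) + z * se),
             p = 2 * stats::pnorm(-abs(unname(beta) / se)),
             row.names = NULL)
}

#' Standardized multiple linear regression with VIF
#'
#' OLS on z-scored response and predictors (standardized betas), plus the
#' variance inflation factor `VIF_j = 1 / (1 - R^2_j)` from regressing each
#' predictor on the others.
#'
#' @param X data.frame or matrix of predictors.
#' @param y numeric response.
#' @return data.frame per predictor: `beta_std`, `p`, `VIF`.
#' @export
linear_fit_standardized <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) > ncol(X) + 1)
  Z <- scale(as.matrix(X))
  if (any(!is.finite(Z))) stop("constant predictor")
  zy <- as.vector(scale(y))
  mm <- cbind(1, Z)
  if (qr(mm)$rank < ncol(mm)) stop("perfect collinearity among predictors (VIF = Inf)")
  fit <- stats::lm.fit(mm, zy)
  beta <- fit$coefficients[-1]
  res <- fit$residuals
  df <- nrow(X) - ncol(mm)
  s2 <- sum(res^2) / df
  cov <- s2 * solve(crossprod(mm))
  se <- sqrt(diag(cov))[-1]
  vif <- vapply(seq_len(ncol(Z)), function(j) {
    fj <- stats::lm.fit(cbind(1, Z[, -j, drop = FALSE]), Z[, j])
    r2 <- 1 - sum(fj$residuals^2) / sum((Z[, j])^2)
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
  data.frame(term = colnames(X), beta_std = unname(beta),
             p = 2 * stats::pt(-abs(beta / se), df), VIF = vif,
             row.names = NULL)
}
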