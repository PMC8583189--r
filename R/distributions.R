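# Lognormal parameter estimation (plotting-position CDF fits and quantile
# fits), the IR-BW power-law regression, and BMR-based inhalation-rate
# estimation. All lognormal parameters are on the natural-log scale.

#' Lognormal parameter set
#'
#' The currency of all distribution fitting: `meanlog` and `sdlog` of the
#' natural-log-transformed variable, plus the R^2 of the CDF fit and a tag
#' recording how the parameters were obtained.
#'
#' @param meanlog Mean of the log-transformed variable.
#' @param sdlog Standard deviation of the log-transformed variable (>= 0;
#'   fitted parameter sets are strictly positive, but a zero-variance set is
#'   accepted so simulations can collapse to deterministic point estimates).
#' @param r2 Coefficient of determination of the CDF fit, in [0, 1], or `NA`
#'   when the parameters were specified rather than fitted.
#' @param method One of `"samples"`, `"quantiles"`, `"specified"`, `"mle"`.
#' @return An object of class `lognormal_params`.
#' @examples
#' lognormal_params(2.21, 1.01)   # site-level BaP_eq concentration
#' @export
lognormal_params <- function(meanlog, sdlog, r2 = NA_real_,
                             method = "specified") {
  check_number(meanlog, "meanlog")
  check_number(sdlog, "sdlog", nonneg = TRUE)
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop_("r2 must be in [0, 1]")
  structure(list(meanlog = meanlog, sdlog = sdlog, r2 = r2,
                 method = method, log_base = "natural"),
            class = "lognormal_params")
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf("<lognormal_params> LN(%.4g, %.4g)%s [%s]\n",
              x$meanlog, x$sdlog,
              if (is.na(x$r2)) "" else sprintf(", R2 = %.4f", x$r2),
              x$method))
  invisible(x)
}

#' Plotting positions for empirical CDF fitting
#'
#' Assigns each sample its empirical cumulative probability
#' `rank / (n + 1)`, with averaged ranks for ties. Positions are returned in
#' the input order of `values`.
#'
#' @param values Numeric vector, n >= 1.
#' @return Proportions strictly inside (0, 1), same length as `values`.
#' @examples
#' plotting_positions(c(5, 1, 3))   # 0.75 0.25 0.50
#' @export
plotting_positions <- function(values) {
  check_number(values, "values")
  n <- length(values)
  if (n == 0) stop_("at least one value is required")
  rank(values, ties.method = "average") / (n + 1)
}

#' Fit a lognormal by Gaussian-CDF regression on plotting positions
#'
#' Log-transforms the samples, assigns plotting positions, and least-squares
#' fits the Gaussian CDF `pnorm((log x - a) / b)` to the (log value,
#' plotting position) pairs. This is the fit used for site-level monitoring
#' data; for large n it agrees with the log-moment estimates.
#'
#' @param values Strictly positive samples, n >= 5, not all equal.
#' @param method `"cdf"` (default, plotting-position CDF least squares) or
#'   `"mle"` (mean/SD of the log data).
#' @return A [lognormal_params()] with the R^2 of the CDF fit.
#' @examples
#' set.seed(1)
#' fit_lognormal_samples(rlnorm(100, 2.21, 1.01))
#' @export
fit_lognormal_samples <- function(values, method = c("cdf", "mle")) {
  method <- match.arg(method)
  check_number(values, "values", positive = TRUE)
  if (length(values) < 5) stop_("at least 5 samples are required")
  lx <- log(values)
  if (max(lx) - min(lx) < .Machine$double.eps^0.5) {
    stop_("degenerate sample: all values are (numerically) equal")
  }
  p <- plotting_positions(values)
  if (method == "mle") {
    fit <- lognormal_params(mean(lx), stats::sd(lx), method = "mle")
    fit$r2 <- cdf_r2(lx, p, fit$meanlog, fit$sdlog)
    return(fit)
  }
  start <- c(mean(lx), max(stats::sd(lx), 1e-3))
  obj <- function(par) {
    if (par[2] <= 0) return(Inf)
    sum((stats::pnorm(lx, par[1], par[2]) - p)^2)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  fit <- lognormal_params(opt$par[1], opt$par[2], method = "samples")
  fit$r2 <- cdf_r2(lx, p, fit$meanlog, fit$sdlog)
  fit
}

# R^2 of the fitted CDF against the plotting positions
cdf_r2 <- function(lx, p, meanlog, sdlog) {
  fitted <- stats::pnorm(lx, meanlog, sdlog)
  1 - sum((p - fitted)^2) / sum((p - mean(p))^2)
}

#' Ordered (probability, value) quantile pairs
#'
#' Handbook-style quantile summaries (quartiles and medians) of an exposure
#' parameter, used to fit lognormal distributions when raw samples are not
#' available.
#'
#' @param p Probabilities strictly inside (0, 1), strictly increasing.
#' @param value Matching quantile values, strictly increasing and positive.
#' @return A data.frame of class `quantile_set` with columns `p`, `value`.
#' @export
quantile_set <- function(p, value) {
  check_number(p, "p")
  check_number(value, "value", positive = TRUE)
  if (length(p) != length(value)) stop_("p and value must have equal length")
  if (any(p <= 0) || any(p >= 1)) stop_("probabilities must lie strictly in (0, 1)")
  if (is.unsorted(p, strictly = TRUE)) stop_("probabilities must be strictly increasing")
  if (is.unsorted(value, strictly = TRUE)) stop_("quantile values must be strictly increasing")
  structure(data.frame(p = p, value = value),
            class = c("quantile_set", "data.frame"))
}

#' Fit a lognormal from handbook quantiles
#'
#' Regresses log value on the standard-normal quantile of the probability:
#' for a lognormal, `log q_p = meanlog + sdlog * qnorm(p)`, so an ordinary
#' least-squares line through the (qnorm(p), log value) pairs recovers the
#' parameters exactly when the pairs lie on a lognormal.
#'
#' @param qs A [quantile_set()] (or data.frame with columns `p`, `value`)
#'   with at least two pairs.
#' @return A [lognormal_params()] with the R^2 of the quantile regression.
#' @examples
#' qs <- quantile_set(c(0.25, 0.5, 0.75), qlnorm(c(0.25, 0.5, 0.75), 4.169, 0.218))
#' fit_lognormal_quantiles(qs)
#' @export
fit_lognormal_quantiles <- function(qs) {
  if (!inherits(qs, "quantile_set")) {
    check_columns(qs, c("p", "value"), "qs")
    qs <- quantile_set(qs$p, qs$value)
  }
  if (nrow(qs) < 2) stop_("at least two quantile pairs are required")
  z <- stats::qnorm(qs$p)
  fit <- stats::lm(log(qs$value) ~ z)
  out <- lognormal_params(unname(stats::coef(fit)[1]),
                          unname(stats::coef(fit)[2]),
                          method = "quantiles")
  ly <- log(qs$value)
  ss_tot <- sum((ly - mean(ly))^2)
  out$r2 <- max(0, min(1, 1 - sum(stats::residuals(fit)^2) / ss_tot))
  out
}

#' Shapiro-Wilk normality gate on the log scale
#'
#' Tests whether log-transformed samples are consistent with a normal
#' distribution, gating the use of a lognormal model.
#'
#' @param values Strictly positive samples, 3 <= n <= 5000.
#' @param alpha Significance level for the pass flag (default 0.05).
#' @return List of class `normality_report`: `statistic`, `p_value`, `pass`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  check_number(values, "values", positive = TRUE)
  n <- length(values)
  if (n < 3 || n > 5000) stop_("Shapiro-Wilk requires 3 <= n <= 5000")
  lx <- log(values)
  if (max(lx) - min(lx) < .Machine$double.eps^0.5) {
    stop_("degenerate sample: all values are (numerically) equal")
  }
  sw <- stats::shapiro.test(lx)
  structure(list(statistic = unname(sw$statistic),
                 p_value = sw$p.value,
                 pass = sw$p.value > alpha),
            class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("<normality_report> W = %.4f, p = %.4g, lognormal %s\n",
              x$statistic, x$p_value,
              if (x$pass) "accepted" else "rejected"))
  invisible(x)
}

#' Power-law relationship between two positive variables
#'
#' Container for a log-log linear model `log y = slope * log x + intercept`,
#' as used for the inhalation-rate vs body-weight dependence. The intercept
#' is on the natural-log scale with y in m^3 day^-1 and x in kg.
#'
#' @param slope Dimensionless exponent.
#' @param intercept Intercept in natural-log units.
#' @param residual_sd Residual SD of the log-scale fit (>= 0).
#' @param n Number of observations used (>= 3 for a fitted model).
#' @return An object of class `power_law_model`.
#' @export
power_law_model <- function(slope, intercept, residual_sd = 0, n = NA_integer_) {
  check_number(slope, "slope")
  check_number(intercept, "intercept")
  check_number(residual_sd, "residual_sd", nonneg = TRUE)
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = residual_sd, n = n,
                 log_base = "natural"),
            class = "power_law_model")
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf(
    "<power_law_model> log y = %.4g log x + %.4g (resid SD %.4g, n = %s)\n",
    x$slope, x$intercept, x$residual_sd, x$n))
  invisible(x)
}

#' Fit the IR-BW power law by log-log least squares
#'
#' Ordinary least squares of log IR on log BW. The slope (the power-law
#' exponent) is invariant to the log base; the stored intercept is natural-
#' log with IR in m^3 day^-1.
#'
#' @param bw Body weights (kg), strictly positive, n >= 3.
#' @param ir Inhalation rates (m^3 day^-1), strictly positive.
#' @return A [power_law_model()].
#' @export
fit_ir_bw_regression <- function(bw, ir) {
  check_number(bw, "bw", positive = TRUE)
  check_number(ir, "ir", positive = TRUE)
  if (length(bw) != length(ir)) stop_("bw and ir must have equal length")
  if (length(bw) < 3) stop_("at least 3 observations are required")
  lb <- log(bw)
  if (stats::var(lb) < .Machine$double.eps) stop_("zero variance in log(bw)")
  fit <- stats::lm(log(ir) ~ lb)
  res_sd <- sqrt(sum(stats::residuals(fit)^2) / (length(bw) - 2))
  power_law_model(unname(stats::coef(fit)[2]), unname(stats::coef(fit)[1]),
                  residual_sd = res_sd, n = length(bw))
}

#' Predict inhalation rate from body weight under a power law
#'
#' @param model A [power_law_model()].
#' @param bw Body weights (kg).
#' @return Predicted IR in m^3 day^-1 (deterministic; no residual term).
#' @export
predict_ir <- function(model, bw) {
  stopifnot(inherits(model, "power_law_model"))
  check_number(bw, "bw", positive = TRUE)
  exp(model$intercept + model$slope * log(bw))
}

# Schofield-type weight-based BMR bands (MJ/day): intercept + coef_bw * BW.
# Band boundaries: [16, 30), [30, 60), [60, 100].
bmr_bands <- function() {
  data.frame(
    sex   = rep(c("male", "female"), each = 3),
    lower = rep(c(16, 30, 60), 2),
    upper = rep(c(30, 60, 100), 2),
    coef_bw   = c(0.063, 0.048, 0.049, 0.062, 0.034, 0.038),
    intercept = c(2.896, 3.653, 2.459, 2.036, 3.538, 2.755)
  )
}

#' Estimate inhalation rate from basal metabolic rate
#'
#' Estimates the daily basal metabolic rate (BMR, MJ day^-1) from sex-, age-
#' banded linear equations in body weight (Schofield-type coefficients),
#' scales it by a physical activity level (PAL) to total energy expenditure,
#' and converts energy to ventilation via the oxygen-uptake coefficient `h`
#' (L O2 per kJ) and the ventilatory equivalent `vq` (L air per L O2):
#' `IR = BMR * PAL * h * vq`. Defaults (PAL 2.0, h 0.05, vq 30) describe an
#' occupationally active adult population.
#'
#' @param bw Body weight in kg (20-200).
#' @param height Height in cm (100-230); accepted for band schemes that use
#'   it (the default weight-only bands do not).
#' @param age Age in years (16-100).
#' @param sex `"male"` or `"female"` (vectorized alongside the others).
#' @param pal Physical activity level multiplier.
#' @param h Oxygen uptake per unit energy expenditure (L O2 / kJ).
#' @param vq Ventilatory equivalent (L air ventilated per L O2).
#' @return Inhalation rate in L min^-1.
#' @examples
#' estimate_ir_from_bmr(67.7, 171, 30, "male")   # ~14 L/min
#' @export
estimate_ir_from_bmr <- function(bw, height, age, sex,
                                 pal = 2.0, h = 0.05, vq = 30) {
  check_number(bw, "bw")
  check_number(height, "height")
  check_number(age, "age")
  if (any(bw < 20 | bw > 200)) stop_("bw outside plausible range 20-200 kg")
  if (any(height < 100 | height > 230)) stop_("height outside plausible range 100-230 cm")
  if (any(age < 16 | age > 100)) stop_("age outside plausible range 16-100 years")
  if (!all(sex %in% c("male", "female"))) stop_("sex must be 'male' or 'female'")
  check_number(pal, "pal", positive = TRUE)
  check_number(h, "h", positive = TRUE)
  check_number(vq, "vq", positive = TRUE)
  n <- max(length(bw), length(height), length(age), length(sex))
  bw <- rep_len(bw, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  bands <- bmr_bands()
  bmr <- numeric(n)
  age_band <- pmin(age, 99.999)
  for (i in seq_len(n)) {
    row <- bands[bands$sex == sex[i] & bands$lower <= age_band[i] &
                   age_band[i] < bands$upper, ]
    bmr[i] <- row$intercept + row$coef_bw * bw[i]
  }
  # MJ/day -> kJ/day -> L air/day -> L/min
  bmr * 1000 * pal * h * vq / 1440
}
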