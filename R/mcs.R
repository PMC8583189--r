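# Monte Carlo simulation engine: the four simulation variants, iteration
# allocation, convergence checking, and Spearman sensitivity analysis.

mcs_variants <- c("traditional", "concentration_adjusted",
                  "age_stratified", "correlated")

# Deterministic substream seed for stratum k of a master seed; kept inside
# the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 48611 * k) %% 2147483647L)
}

#' Configuration of a Monte Carlo risk simulation
#'
#' Bundles everything one simulation run needs: the variant, the iteration
#' budget, the seed, the input distributions and the exposure constants.
#'
#' Variants:
#' \describe{
#'   \item{traditional}{Concentration, body weight and inhalation rate drawn
#'     independently from whole-population lognormals.}
#'   \item{concentration_adjusted}{Identical mechanics, but `conc` is the
#'     population-weighted individual-exposure lognormal rather than the
#'     site-fitted one.}
#'   \item{age_stratified}{Iterations split across age strata in proportion
#'     to their population weights; each stratum samples its own BW and IR
#'     lognormals; outputs are pooled.}
#'   \item{correlated}{Only concentration and body weight are drawn; IR is
#'     computed from BW through the power-law model (optionally with
#'     lognormal residual scatter, off by default).}
#' }
#'
#' @param variant One of `"traditional"`, `"concentration_adjusted"`,
#'   `"age_stratified"`, `"correlated"`.
#' @param conc [lognormal_params()] for the BaP_eq concentration (ng m^-3).
#' @param bw,ir [lognormal_params()] for body weight (kg) and inhalation
#'   rate (m^3 day^-1); required except for `age_stratified` (`bw`, `ir`
#'   come from `strata`) and `correlated` (`ir` comes from `power_law`).
#' @param strata For `age_stratified`: a named list of strata, each a list
#'   with elements `weight` (> 0, weights summing to 1), `bw` and `ir`
#'   ([lognormal_params()]).
#' @param power_law For `correlated`: a [power_law_model()] giving IR as a
#'   power law of BW.
#' @param residual_sd Log-scale residual SD added to the power-law IR in the
#'   correlated variant (default 0: deterministic substitution).
#' @param iterations Total iteration budget (>= 1).
#' @param seed Master RNG seed.
#' @param constants [exposure_constants()].
#' @param percentiles Summary percentiles, in (0, 1).
#' @return An object of class `mcs_config`.
#' @export
mcs_config <- function(variant, conc, bw = NULL, ir = NULL, strata = NULL,
                       power_law = NULL, residual_sd = 0,
                       iterations = 30000, seed = 1,
                       constants = exposure_constants(),
                       percentiles = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  variant <- match.arg(variant, mcs_variants)
  stopifnot(inherits(conc, "lognormal_params"),
            inherits(constants, "exposure_constants"))
  if (iterations < 1) stop_("iterations must be >= 1")
  if (variant %in% c("traditional", "concentration_adjusted")) {
    if (!inherits(bw, "lognormal_params") || !inherits(ir, "lognormal_params")) {
      stop_(variant, " variant requires `bw` and `ir` lognormal parameters")
    }
  } else if (variant == "age_stratified") {
    if (is.null(strata) || length(strata) < 1 || is.null(names(strata))) {
      stop_("age_stratified variant requires a named list of strata")
    }
    w <- vapply(strata, function(s) s$weight, numeric(1))
    if (any(w <= 0)) stop_("stratum weights must be strictly positive")
    if (abs(sum(w) - 1) > 1e-9) stop_("stratum weights must sum to 1")
    ok <- vapply(strata, function(s) {
      inherits(s$bw, "lognormal_params") && inherits(s$ir, "lognormal_params")
    }, logical(1))
    if (!all(ok)) stop_("each stratum needs `bw` and `ir` lognormal parameters")
  } else if (variant == "correlated") {
    if (!inherits(bw, "lognormal_params")) {
      stop_("correlated variant requires `bw` lognormal parameters")
    }
    if (!inherits(power_law, "power_law_model")) {
      stop_("correlated variant requires a power_law_model for IR")
    }
  }
  check_number(residual_sd, "residual_sd", nonneg = TRUE)
  if (any(percentiles <= 0 | percentiles >= 1)) {
    stop_("percentiles must lie strictly in (0, 1)")
  }
  structure(list(variant = variant, conc = conc, bw = bw, ir = ir,
                 strata = strata, power_law = power_law,
                 residual_sd = residual_sd,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 constants = constants, percentiles = percentiles),
            class = "mcs_config")
}

#' @export
print.mcs_config <- function(x, ...) {
  cat(sprintf("<mcs_config> %s, %d iterations, seed %d\n",
              x$variant, x$iterations, x$seed))
  invisible(x)
}

draw_lognormal <- function(n, params) {
  stats::rlnorm(n, params$meanlog, params$sdlog)
}

#' Run a Monte Carlo risk simulation
#'
#' Draws the configured input distributions, computes the ILCR for every
#' iteration through [compute_ilcr()], and returns the per-iteration draws
#' together with summary statistics. Identical configurations and seeds give
#' bit-identical results; in the age-stratified variant each stratum uses a
#' substream seed derived from the master seed, so changing one stratum's
#' allocation does not reshuffle the others.
#'
#' @param config An [mcs_config()].
#' @return An object of class `simulation_result`: list with `draws` (a
#'   data.frame with columns `conc`, `bw`, `ir`, `ilcr`, `stratum`),
#'   `summary` (mean, sd, median, min, max, percentiles, n), `variant`,
#'   `seed` and the `config` echo.
#' @export
run_mcs <- function(config) {
  stopifnot(inherits(config, "mcs_config"))
  variant <- config$variant
  n <- config$iterations
  if (variant %in% c("traditional", "concentration_adjusted")) {
    set.seed(config$seed)
    conc <- draw_lognormal(n, config$conc)
    bw <- draw_lognormal(n, config$bw)
    ir <- draw_lognormal(n, config$ir)
    stratum <- rep("whole_population", n)
  } else if (variant == "correlated") {
    set.seed(config$seed)
    conc <- draw_lognormal(n, config$conc)
    bw <- draw_lognormal(n, config$bw)
    ir <- predict_ir(config$power_law, bw)
    if (config$residual_sd > 0) {
      ir <- ir * exp(stats::rnorm(n, 0, config$residual_sd))
    }
    stratum <- rep("whole_population", n)
  } else { # age_stratified
    weights <- vapply(config$strata, function(s) s$weight, numeric(1))
    counts <- allocate_iterations(n, weights)
    parts <- vector("list", length(config$strata))
    for (k in seq_along(config$strata)) {
      s <- config$strata[[k]]
      nk <- counts[k]
      set.seed(derive_seed(config$seed, k))
      parts[[k]] <- data.frame(
        conc = draw_lognormal(nk, config$conc),
        bw = draw_lognormal(nk, s$bw),
        ir = draw_lognormal(nk, s$ir),
        stratum = rep(names(config$strata)[k], nk)
      )
    }
    pooled <- do.call(rbind, parts)
    conc <- pooled$conc; bw <- pooled$bw; ir <- pooled$ir
    stratum <- pooled$stratum
  }
  ilcr <- compute_ilcr(conc, ir, bw, config$constants)
  draws <- data.frame(conc = conc, bw = bw, ir = ir, ilcr = ilcr,
                      stratum = stratum)
  structure(list(draws = draws,
                 summary = summarize_risks(ilcr, config$percentiles),
                 variant = variant, seed = config$seed, config = config),
            class = "simulation_result")
}

summarize_risks <- function(x, percentiles = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  q <- stats::quantile(x, percentiles, names = FALSE)
  names(q) <- paste0("p", formatC(100 * percentiles, format = "g"))
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       median = stats::median(x), min = min(x), max = max(x),
       percentiles = q)
}

#' @export
print.simulation_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<simulation_result> %s, %d iterations (seed %d)\n",
              x$variant, s$n, x$seed))
  cat(sprintf("  ILCR mean %.3e, sd %.3e, median %.3e, range [%.3e, %.3e]\n",
              s$mean, s$sd, s$median, s$min, s$max))
  invisible(x)
}

#' Allocate iterations to strata by largest-remainder rounding
#'
#' Splits a total iteration budget across strata proportionally to their
#' population weights, rounding so the counts sum exactly to the total:
#' each stratum gets `floor(weight * total)` and the leftover iterations go
#' to the largest fractional remainders.
#'
#' @param total Total iterations, >= number of strata.
#' @param weights Strictly positive weights summing to 1.
#' @return Integer vector of per-stratum counts summing to `total`.
#' @examples
#' allocate_iterations(9, c(0.5, 0.3, 0.2))   # 4 3 2
#' @export
allocate_iterations <- function(total, weights) {
  check_number(weights, "weights", positive = TRUE)
  if (abs(sum(weights) - 1) > 1e-9) stop_("weights must sum to 1")
  if (total < length(weights)) stop_("total must be >= number of strata")
  exact <- weights * total
  counts <- floor(exact)
  leftover <- as.integer(round(total - sum(counts)))
  if (leftover > 0) {
    top <- order(exact - counts, decreasing = TRUE)[seq_len(leftover)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Convergence of the simulated mean over an iteration grid
#'
#' Runs the configured variant at each grid size with the same master seed
#' and flags convergence when the relative change of the mean between
#' successive grid points drops below `tol` (and stays below it).
#'
#' @param config An [mcs_config()]; its `iterations` field is overridden by
#'   the grid.
#' @param grid Ascending iteration counts, at least two.
#' @param tol Relative tolerance on successive means (default 0.02).
#' @return A data.frame with columns `iterations`, `mean`, `sd`,
#'   `rel_change`, `within_tol`, with attribute `converged` (also returned
#'   in the `converged` column of the last row's sense): TRUE when every
#'   successive change from some grid point onward is below `tol`.
#' @export
convergence_check <- function(config, grid = seq(5000, 50000, by = 5000),
                              tol = 0.02) {
  stopifnot(inherits(config, "mcs_config"))
  if (length(grid) < 2) stop_("the iteration grid needs at least two points")
  if (is.unsorted(grid, strictly = TRUE)) stop_("the grid must be strictly ascending")
  check_number(tol, "tol", nonneg = TRUE)
  means <- sds <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cfg <- config
    cfg$iterations <- as.integer(grid[i])
    res <- run_mcs(cfg)
    means[i] <- res$summary$mean
    sds[i] <- res$summary$sd
  }
  rel <- c(NA, abs(diff(means)) / abs(means[-length(means)]))
  within <- rel < tol
  # zero-variance configs produce identical means: rel change 0 everywhere
  converged <- isTRUE(all(within[-1]))
  out <- data.frame(iterations = grid, mean = means, sd = sds,
                    rel_change = rel, within_tol = within)
  attr(out, "converged") <- converged
  out
}

#' Spearman rank-correlation sensitivity of the simulated risk
#'
#' Correlates each per-iteration input (concentration, body weight,
#' inhalation rate) with the per-iteration ILCR using Spearman rank
#' correlation (averaged ranks on ties) and ranks the inputs by absolute
#' correlation. A constant input has no defined rank correlation and is
#' reported as `NA`, ranked last.
#'
#' @param result A [run_mcs()] result.
#' @return An object of class `sensitivity_result`: data.frame with columns
#'   `input`, `rho`, `rank`.
#' @export
sensitivity_spearman <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  d <- result$draws
  inputs <- c("conc", "bw", "ir")
  rho <- vapply(inputs, function(v) {
    x <- d[[v]]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, d$ilcr, method = "spearman")
  }, numeric(1))
  ord <- order(abs(rho), decreasing = TRUE, na.last = TRUE)
  out <- data.frame(input = inputs, rho = rho, row.names = NULL)
  out$rank <- match(seq_along(inputs), ord)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  structure(out, class = c("sensitivity_result", "data.frame"))
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> Spearman rank correlation with ILCR\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
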