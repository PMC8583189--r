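# Individual ("actual") risk assessment from nearest-site exposure, subgroup
# contrasts, IDW concentration surfaces, and goodness-of-fit grading of
# simulated risk distributions against the empirical one.

#' Assign each participant to its nearest sampling site
#'
#' Euclidean nearest-neighbour assignment in projected planar coordinates,
#' with a deterministic tie-break by the lexicographically smallest site id.
#' Participants carrying a pre-assigned `site_id` keep it.
#'
#' @param participants data.frame with columns `x`, `y` (projected metres or
#'   any consistent planar unit) and optionally `site_id`.
#' @param sites data.frame with columns `site_id`, `x`, `y`, `bap_eq`
#'   (annual total BaP_eq, ng m^-3).
#' @return `participants` with columns `site_id` and `bap_eq` filled in.
#' @export
assign_nearest_site <- function(participants, sites) {
  check_columns(sites, c("site_id", "x", "y", "bap_eq"), "sites")
  if (nrow(sites) == 0) stop_("at least one site is required")
  if (anyDuplicated(sites$site_id)) stop_("site ids must be unique")
  has_site <- if ("site_id" %in% names(participants)) {
    !is.na(participants$site_id)
  } else {
    participants$site_id <- NA_character_
    rep(FALSE, nrow(participants))
  }
  if (!all(has_site)) {
    check_columns(participants, c("x", "y"), "participants")
    # stable tie-break: scan sites in id order, strict improvement required
    ord <- order(as.character(sites$site_id))
    sx <- sites$x[ord]; sy <- sites$y[ord]; sid <- sites$site_id[ord]
    px <- participants$x[!has_site]; py <- participants$y[!has_site]
    d2 <- outer(px, sx, function(a, b) (a - b)^2) +
      outer(py, sy, function(a, b) (a - b)^2)
    nearest <- apply(d2, 1, which.min)  # which.min takes the first minimum
    participants$site_id[!has_site] <- sid[nearest]
  }
  idx <- match(participants$site_id, sites$site_id)
  if (anyNA(idx)) stop_("participant assigned to unknown site id")
  participants$bap_eq <- sites$bap_eq[idx]
  participants
}

#' Assess individual ILCRs from measured parameters and nearest-site exposure
#'
#' Computes the "actual" incremental lifetime cancer risk of every
#' participant: exposure is the annual BaP_eq of the nearest sampling site,
#' body weight is as measured, and the inhalation rate is the measured
#' `ir_lpm` (L min^-1) where present, otherwise estimated from body metrics
#' through [estimate_ir_from_bmr()].
#'
#' @param participants data.frame with columns `id`, `age`, `sex`, `area`,
#'   `height_cm`, `bw_kg`, optionally `ir_lpm`, and either `x`/`y`
#'   coordinates or `site_id`.
#' @param sites Site table as in [assign_nearest_site()].
#' @param constants [exposure_constants()].
#' @param strict Error on unresolvable participants instead of dropping them
#'   into the attached error report (default FALSE).
#' @return `participants` with columns `site_id`, `bap_eq`, `ir_m3d`,
#'   `ilcr` and `risk_class` added; attributes `summary` (mean, sd, median,
#'   min, max, percentiles, n) and `errors` (ids skipped, with reasons).
#' @export
assess_individuals <- function(participants, sites,
                               constants = exposure_constants(),
                               strict = FALSE) {
  check_columns(participants, c("id", "age", "sex", "bw_kg"), "participants")
  if (nrow(participants) == 0) stop_("participant table is empty")
  participants <- assign_nearest_site(participants, sites)
  ir_lpm <- if ("ir_lpm" %in% names(participants)) {
    participants$ir_lpm
  } else {
    rep(NA_real_, nrow(participants))
  }
  errors <- character(0)
  need <- is.na(ir_lpm)
  if (any(need)) {
    check_columns(participants, "height_cm", "participants")
    est <- try(estimate_ir_from_bmr(participants$bw_kg[need],
                                    participants$height_cm[need],
                                    participants$age[need],
                                    participants$sex[need]),
               silent = TRUE)
    if (inherits(est, "try-error")) {
      msg <- attr(est, "condition")$message
      if (strict) stop_("IR estimation failed: ", msg)
      errors <- c(errors, paste0("IR estimation failed: ", msg))
      participants <- participants[!need, , drop = FALSE]
      ir_lpm <- ir_lpm[!need]
    } else {
      ir_lpm[need] <- est
    }
  }
  if (nrow(participants) == 0) stop_("no assessable participants remain")
  participants$ir_m3d <- convert_ir(ir_lpm, "L/min", "m3/day")
  participants$ilcr <- compute_ilcr(participants$bap_eq,
                                    participants$ir_m3d,
                                    participants$bw_kg, constants)
  participants$risk_class <- classify_risk(participants$ilcr)
  attr(participants, "summary") <- summarize_risks(participants$ilcr)
  attr(participants, "errors") <- errors
  participants
}

#' Kruskal-Wallis subgroup contrast of individual risks
#'
#' Rank-based comparison of ILCR across the levels of a grouping factor
#' (sex, urban/rural area, age group, ...), with per-group sample sizes and
#' geometric means.
#'
#' @param participants Output of [assess_individuals()] (needs an `ilcr`
#'   column).
#' @param by Name of the grouping column.
#' @return Object of class `subgroup_comparison`: list with `factor`,
#'   `groups` (data.frame: group, n, geomean), `statistic`, `df`, `p_value`.
#' @export
compare_subgroups <- function(participants, by) {
  check_columns(participants, c("ilcr", by), "participants")
  g <- factor(participants[[by]])
  if (nlevels(g) < 2) stop_("at least two groups are required")
  if (any(table(g) < 2)) stop_("each group needs at least two members")
  kw <- stats::kruskal.test(participants$ilcr, g)
  groups <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    geomean = vapply(levels(g),
                     function(l) geomean(participants$ilcr[g == l]),
                     numeric(1)),
    row.names = NULL
  )
  structure(list(factor = by, groups = groups,
                 statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p_value = kw$p.value),
            class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf("<subgroup_comparison> ILCR by %s: H = %.4g (df %d), p = %.4g\n",
              x$factor, x$statistic, x$df, x$p_value))
  print.data.frame(x$groups, digits = 4)
  invisible(x)
}

#' Inverse-distance-weighted concentration surface
#'
#' Interpolates site BaP_eq values onto a regular grid with weights
#' `d^-power`; a node coinciding with a site takes that site's value
#' exactly.
#'
#' @param sites Site table with `x`, `y`, `bap_eq`.
#' @param grid Either a data.frame of nodes with columns `x`, `y`, or a list
#'   with `xlim`, `ylim`, `nx`, `ny` describing a regular grid.
#' @param power IDW exponent (> 0), default 2.
#' @return data.frame with columns `x`, `y`, `value`.
#' @export
idw_surface <- function(sites, grid, power = 2) {
  check_columns(sites, c("x", "y", "bap_eq"), "sites")
  if (nrow(sites) == 0) stop_("at least one site is required")
  check_number(power, "power", positive = TRUE)
  if (is.data.frame(grid)) {
    check_columns(grid, c("x", "y"), "grid")
    nodes <- grid[, c("x", "y")]
  } else {
    nodes <- expand.grid(
      x = seq(grid$xlim[1], grid$xlim[2], length.out = grid$nx),
      y = seq(grid$ylim[1], grid$ylim[2], length.out = grid$ny)
    )
  }
  if (nrow(nodes) == 0) stop_("the interpolation grid is empty")
  value <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    d <- sqrt((sites$x - nodes$x[i])^2 + (sites$y - nodes$y[i])^2)
    hit <- which(d == 0)
    if (length(hit) > 0) {
      value[i] <- sites$bap_eq[hit[1]]
    } else {
      w <- d^(-power)
      value[i] <- sum(w * sites$bap_eq) / sum(w)
    }
  }
  cbind(nodes, value = value)
}

#' Grade a simulated risk distribution against the empirical one
#'
#' Quantifies simulation accuracy by the ratios (simulated / actual) of the
#' arithmetic mean, median and standard deviation, and variation by the
#' difference in range span, expressed in orders of magnitude:
#' `log10(max/min)_simulated - log10(max/min)_actual`.
#'
#' @param actual,simulated Non-empty numeric vectors of strictly positive
#'   risks.
#' @return Object of class `gof_report`: list with `mean_ratio`,
#'   `median_ratio`, `sd_ratio`, `span_difference` and the two summaries.
#' @examples
#' goodness_of_fit(c(1e-6, 2e-6, 4e-6), c(2e-6, 4e-6, 8e-6))
#' @export
goodness_of_fit <- function(actual, simulated) {
  check_number(actual, "actual", positive = TRUE)
  check_number(simulated, "simulated", positive = TRUE)
  if (length(actual) == 0 || length(simulated) == 0) {
    stop_("both samples must be non-empty")
  }
  structure(list(
    mean_ratio = mean(simulated) / mean(actual),
    median_ratio = stats::median(simulated) / stats::median(actual),
    sd_ratio = stats::sd(simulated) / stats::sd(actual),
    span_difference = log10(max(simulated) / min(simulated)) -
      log10(max(actual) / min(actual)),
    actual = summarize_risks(actual),
    simulated = summarize_risks(simulated)
  ), class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat("<gof_report> simulated vs actual risk distribution\n")
  cat(sprintf("  mean ratio %.3g, median ratio %.3g, SD ratio %.3g\n",
              x$mean_ratio, x$median_ratio, x$sd_ratio))
  cat(sprintf("  range span difference %.3g orders of magnitude\n",
              x$span_difference))
  invisible(x)
}

#' Kernel-density description of a risk distribution
#'
#' Descriptive report of the empirical risk density on the log10 scale,
#' including the local maxima (candidate modes). Intended for inspecting
#' multimodality induced by spatially clustered exposure; it is not a formal
#' mode test.
#'
#' @param ilcr Strictly positive risks.
#' @param bw Kernel bandwidth passed to [stats::density()] (default `"SJ"`).
#' @return List with the `density` object (on log10(ILCR)) and `modes`, the
#'   ILCR values at local density maxima.
#' @export
risk_density <- function(ilcr, bw = "SJ") {
  check_number(ilcr, "ilcr", positive = TRUE)
  d <- stats::density(log10(ilcr), bw = bw)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  list(density = d, modes = 10^d$x[peaks])
}
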