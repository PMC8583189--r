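# Synthetic site networks and participant populations with the statistical
# structure the assessment assumes: lognormal site concentrations with
# spatially clustered exposure, stratified body weights, and a power-law
# IR-BW dependence. Everything is a pure function of (spec, seed).

#' Reference exposure-parameter bundle
#'
#' The packaged urban-industrial reference scenario: natural-log lognormal
#' parameters for the site-level BaP_eq concentration LN(2.21, 1.01) and the
#' population-weighted individual exposure LN(2.419, 1.317); body-weight and
#' inhalation-rate lognormals per age stratum (18-44, 45-59, 60-70) and for
#' the whole population; census-proportional stratum weights; and the IR-BW
#' power law with exponent 0.679 (intercept calibrated so the median body
#' weight maps to the median inhalation rate).
#'
#' @return List with elements `site_conc`, `exposure`, `bw`, `ir` (each of
#'   the latter two a list `whole`, `s18_44`, `s45_59`, `s60_70`),
#'   `stratum_weights`, `power_law` and `strata` (ready for
#'   [mcs_config()]'s `strata` argument).
#' @export
default_exposure_params <- function() {
  bw <- list(
    whole  = lognormal_params(4.169, 0.218),
    s18_44 = lognormal_params(4.169, 0.225),
    s45_59 = lognormal_params(4.192, 0.204),
    s60_70 = lognormal_params(4.142, 0.216)
  )
  ir <- list(
    whole  = lognormal_params(2.788, 0.195),
    s18_44 = lognormal_params(2.823, 0.175),
    s45_59 = lognormal_params(2.816, 0.150),
    s60_70 = lognormal_params(2.660, 0.157)
  )
  weights <- c(s18_44 = 19379, s45_59 = 8172, s60_70 = 2449) / 30000
  slope <- 0.679
  # intercept calibrated so median BW maps to median IR on the log scale
  pl <- power_law_model(slope, ir$whole$meanlog - slope * bw$whole$meanlog,
                        residual_sd = 0.1)
  strata <- lapply(names(weights), function(s) {
    list(weight = unname(weights[s]), bw = bw[[s]], ir = ir[[s]])
  })
  names(strata) <- names(weights)
  list(site_conc = lognormal_params(2.21, 1.01),
       exposure = lognormal_params(2.419, 1.317),
       bw = bw, ir = ir, stratum_weights = weights,
       power_law = pl, strata = strata)
}

#' Scenario specification for the synthetic generators
#'
#' Describes a synthetic study area: a clustered network of monitoring sites
#' whose annual BaP_eq concentrations have a prescribed lognormal marginal,
#' and a participant population with stratified ages, sex-structured body
#' weights and an IR model. The defaults are the packaged reference
#' scenario: 25 sites in 3 exposure clusters whose mixture reproduces
#' LN(2.21, 1.01), 2740 participants distributed over the clusters in the
#' proportions 741/1594/405, stratum weights 19379/8172/2449 of 30000, and
#' the power-law IR model with exponent 0.679 and residual SD 0.1.
#'
#' The site log-concentration is decomposed as cluster offset + within-
#' cluster noise: offsets are equally spaced and scaled so that, with the
#' chosen within-cluster SD, the site marginal matches `site_conc`. The
#' lowest-exposure cluster is labelled urban, the highest rural, and
#' middle-cluster sites alternate, so urban/rural contrasts have signal.
#'
#' @param n_sites Number of monitoring sites.
#' @param n_participants Number of participants.
#' @param site_conc [lognormal_params()] of the site concentration marginal.
#' @param within_sdlog Within-cluster log-concentration SD (must be smaller
#'   than `site_conc$sdlog`).
#' @param n_clusters Number of spatial exposure clusters.
#' @param participant_cluster_weights Participant allocation over clusters
#'   (summing to 1), ordered from the lowest- to the highest-exposure
#'   cluster.
#' @param stratum_weights Named age-stratum weights (strata `s18_44`,
#'   `s45_59`, `s60_70`), summing to 1.
#' @param bw Named list of per-stratum body-weight [lognormal_params()].
#' @param sex_bw_log_offset Male-female difference of mean log body weight;
#'   within-sex SD is shrunk so the pooled log-BW SD still matches the
#'   stratum parameter.
#' @param ir_model `"power_law"` (IR from BW via `power_law` plus lognormal
#'   residual) or `"independent"` (per-stratum `ir` lognormals).
#' @param power_law [power_law_model()] used when `ir_model = "power_law"`;
#'   its `residual_sd` supplies the log-residual scatter.
#' @param ir Named list of per-stratum IR [lognormal_params()], used when
#'   `ir_model = "independent"`.
#' @param cluster_spacing Distance between neighbouring cluster centres
#'   (planar units).
#' @param site_spread SD of site coordinates around their cluster centre.
#' @param participant_spread SD of participant coordinates around their home
#'   site.
#' @param seed Master seed of the generators.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_sites = 25,
                          n_participants = 2740,
                          site_conc = default_exposure_params()$site_conc,
                          within_sdlog = 0.5,
                          n_clusters = 3,
                          participant_cluster_weights = c(741, 1594, 405) / 2740,
                          stratum_weights = default_exposure_params()$stratum_weights,
                          bw = default_exposure_params()$bw,
                          sex_bw_log_offset = log(67.7 / 56.9),
                          ir_model = c("power_law", "independent"),
                          power_law = default_exposure_params()$power_law,
                          ir = default_exposure_params()$ir,
                          cluster_spacing = 10,
                          site_spread = 1,
                          participant_spread = 0.2,
                          seed = 1) {
  ir_model <- match.arg(ir_model)
  stopifnot(inherits(site_conc, "lognormal_params"))
  if (n_sites < 1 || n_participants < 1) stop_("counts must be >= 1")
  if (n_clusters < 1) stop_("at least one cluster is required")
  if (length(participant_cluster_weights) != n_clusters) {
    stop_("one participant weight per cluster is required")
  }
  check_number(participant_cluster_weights, "participant_cluster_weights",
               positive = TRUE)
  if (abs(sum(participant_cluster_weights) - 1) > 1e-9) {
    stop_("participant cluster weights must sum to 1")
  }
  check_number(stratum_weights, "stratum_weights", nonneg = TRUE)
  if (abs(sum(stratum_weights) - 1) > 1e-9) stop_("stratum weights must sum to 1")
  if (within_sdlog > site_conc$sdlog) {
    stop_("within-cluster SD cannot exceed the marginal log-SD")
  }
  if (ir_model == "power_law") stopifnot(inherits(power_law, "power_law_model"))
  structure(list(
    n_sites = as.integer(n_sites),
    n_participants = as.integer(n_participants),
    site_conc = site_conc, within_sdlog = within_sdlog,
    n_clusters = as.integer(n_clusters),
    participant_cluster_weights = participant_cluster_weights,
    stratum_weights = stratum_weights, bw = bw,
    sex_bw_log_offset = sex_bw_log_offset,
    ir_model = ir_model, power_law = power_law, ir = ir,
    cluster_spacing = cluster_spacing, site_spread = site_spread,
    participant_spread = participant_spread,
    seed = as.integer(seed)
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %d sites in %d clusters, %d participants, IR model %s, seed %d\n",
    x$n_sites, x$n_clusters, x$n_participants, x$ir_model, x$seed))
  invisible(x)
}

# Equally spaced cluster log-offsets scaled so that the equal-weight site
# mixture reproduces the marginal log-SD given the within-cluster SD.
cluster_offsets <- function(spec) {
  k <- spec$n_clusters
  if (k == 1) return(0)
  unit <- seq(-1, 1, length.out = k)
  unit <- unit - mean(unit)
  target_var <- spec$site_conc$sdlog^2 - spec$within_sdlog^2
  unit * sqrt(target_var / mean(unit^2))
}

age_strata <- function() {
  data.frame(stratum = c("s18_44", "s45_59", "s60_70"),
             lower = c(18, 45, 60), upper = c(44, 59, 70))
}

#' Generate a synthetic monitoring-site network
#'
#' Sites are placed around cluster centres laid out on a line; each cluster
#' carries a log-concentration offset so the pooled site concentrations
#' follow the configured lognormal marginal while exposure is spatially
#' clustered. Clusters are ordered from lowest to highest exposure; the
#' lowest is labelled urban, the highest rural, middle clusters alternate
#' site-by-site.
#'
#' @param spec A [scenario_spec()].
#' @param seed Override of `spec$seed`.
#' @return data.frame with columns `site_id`, `cluster`, `area`, `x`, `y`,
#'   `bap_eq`.
#' @export
gen_sites <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(derive_seed(seed, 1))
  k <- spec$n_clusters
  offsets <- cluster_offsets(spec)
  counts <- allocate_iterations(spec$n_sites, rep(1 / k, k))
  cluster <- rep(seq_len(k), counts)
  centre_x <- (seq_len(k) - (k + 1) / 2) * spec$cluster_spacing
  x <- centre_x[cluster] + stats::rnorm(spec$n_sites, 0, spec$site_spread)
  y <- stats::rnorm(spec$n_sites, 0, spec$site_spread)
  log_conc <- spec$site_conc$meanlog + offsets[cluster] +
    stats::rnorm(spec$n_sites, 0, spec$within_sdlog)
  area <- character(spec$n_sites)
  for (cl in seq_len(k)) {
    idx <- which(cluster == cl)
    area[idx] <- if (cl == 1 && k > 1) {
      "urban"
    } else if (cl == k && k > 1) {
      "rural"
    } else {
      rep(c("urban", "rural"), length.out = length(idx))
    }
  }
  data.frame(
    site_id = sprintf("S%02d", seq_len(spec$n_sites)),
    cluster = cluster, area = area, x = x, y = y,
    bap_eq = exp(log_conc)
  )
}

#' Generate a synthetic participant population
#'
#' Participants live near a randomly chosen site of their exposure cluster
#' (cluster membership drawn from the configured participant weights, so
#' nearest-site assignment induces clustered, multimodal exposure). Ages are
#' drawn by stratum weights; log body weight is the stratum lognormal
#' decomposed into a male/female location shift plus within-sex noise;
#' heights are sex-specific normals; IR follows either the power-law model
#' of BW (with lognormal residual) or independent per-stratum lognormals.
#'
#' @param spec A [scenario_spec()].
#' @param sites Output of [gen_sites()].
#' @param seed Override of `spec$seed`.
#' @return data.frame with columns `id`, `age`, `sex`, `area`, `height_cm`,
#'   `bw_kg`, `ir_lpm`, `x`, `y`, `cluster`, `home_site`.
#' @export
gen_participants <- function(spec, sites, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(sites) || nrow(sites) == 0) stop_("site table is empty")
  check_columns(sites, c("site_id", "cluster", "area", "x", "y"), "sites")
  set.seed(derive_seed(seed, 2))
  n <- spec$n_participants
  cluster <- sample.int(spec$n_clusters, n, replace = TRUE,
                        prob = spec$participant_cluster_weights)
  home <- integer(n)
  for (cl in unique(cluster)) {
    pool <- which(sites$cluster == cl)
    if (length(pool) == 0) stop_("cluster ", cl, " has no sites")
    sel <- cluster == cl
    home[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
  }
  x <- sites$x[home] + stats::rnorm(n, 0, spec$participant_spread)
  y <- sites$y[home] + stats::rnorm(n, 0, spec$participant_spread)

  strata <- age_strata()
  s_idx <- sample.int(nrow(strata), n, replace = TRUE,
                      prob = spec$stratum_weights[strata$stratum])
  age <- strata$lower[s_idx] +
    floor(stats::runif(n) * (strata$upper[s_idx] - strata$lower[s_idx] + 1))

  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  d <- spec$sex_bw_log_offset
  log_bw <- numeric(n)
  for (i in seq_len(nrow(strata))) {
    p <- spec$bw[[strata$stratum[i]]]
    if (p$sdlog^2 <= (d / 2)^2) {
      stop_("sex BW offset too large for the stratum log-SD")
    }
    within <- sqrt(p$sdlog^2 - (d / 2)^2)
    sel <- s_idx == i
    shift <- ifelse(sex[sel] == "male", d / 2, -d / 2)
    log_bw[sel] <- p$meanlog + shift + stats::rnorm(sum(sel), 0, within)
  }
  bw_kg <- exp(log_bw)
  height_cm <- ifelse(sex == "male",
                      stats::rnorm(n, 171, 5.41),
                      stats::rnorm(n, 160, 5.80))
  height_cm <- pmin(pmax(height_cm, 130), 220)

  if (spec$ir_model == "power_law") {
    pl <- spec$power_law
    log_ir <- pl$intercept + pl$slope * log_bw
    if (pl$residual_sd > 0) log_ir <- log_ir + stats::rnorm(n, 0, pl$residual_sd)
    ir_m3d <- exp(log_ir)
  } else {
    ir_m3d <- numeric(n)
    for (i in seq_len(nrow(strata))) {
      p <- spec$ir[[strata$stratum[i]]]
      sel <- s_idx == i
      ir_m3d[sel] <- stats::rlnorm(sum(sel), p$meanlog, p$sdlog)
    }
  }

  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = age, sex = sex,
    area = sites$area[home],
    height_cm = height_cm, bw_kg = bw_kg,
    ir_lpm = convert_ir(ir_m3d, "m3/day", "L/min"),
    x = x, y = y,
    cluster = cluster, home_site = sites$site_id[home]
  )
}

#' Exact handbook-style quantile tables from lognormal parameters
#'
#' Evaluates the lognormal quantile function at the quartiles and median,
#' formatted as the long quantile CSV schema consumed by
#' [fit_lognormal_quantiles()]. Round-tripping through the quantile fit
#' returns the generating parameters exactly.
#'
#' @param params Named list of strata, each a list with [lognormal_params()]
#'   elements named by parameter (e.g. `bw`, `ir`).
#' @param probs Probabilities to tabulate (default quartiles and median).
#' @return data.frame with columns `stratum`, `parameter`, `p`, `value`.
#' @export
gen_handbook_quantiles <- function(params,
                                   probs = c(0.25, 0.5, 0.75)) {
  if (is.null(names(params))) stop_("strata must be named")
  rows <- list()
  for (s in names(params)) {
    for (par in names(params[[s]])) {
      lp <- params[[s]][[par]]
      stopifnot(inherits(lp, "lognormal_params"))
      rows[[length(rows) + 1]] <- data.frame(
        stratum = s, parameter = par, p = probs,
        value = stats::qlnorm(probs, lp$meanlog, lp$sdlog)
      )
    }
  }
  do.call(rbind, rows)
}
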