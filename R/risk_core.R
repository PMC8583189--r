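# Deterministic exposure arithmetic: TEF-weighted BaP equivalents, the ILCR
# equation, unit conversions, annual averaging, and risk classification.

#' The fifteen priority PAH congeners
#'
#' Abbreviated names of the fifteen priority-controlled PAH congeners handled
#' by the default TEF table: acenaphthene (Ace), acenaphthylene (Acy),
#' fluorene (Flo), phenanthrene (Phe), anthracene (Ant), fluoranthene (Fla),
#' pyrene (Pyr), benz(a)anthracene (BaA), chrysene (Chr),
#' benzo(b)fluoranthene (BbF), benzo(k)fluoranthene (BkF), benzo(a)pyrene
#' (BaP), dibenz(a,h)anthracene (DahA), indeno(1,2,3-cd)pyrene (IcdP) and
#' benzo(ghi)perylene (BghiP).
#'
#' @return Character vector of length 15.
#' @export
pah_congeners <- function() {
  c("Ace", "Acy", "Flo", "Phe", "Ant", "Fla", "Pyr", "BaA", "Chr",
    "BbF", "BkF", "BaP", "DahA", "IcdP", "BghiP")
}

#' Toxic equivalency factor (TEF) table
#'
#' A TEF table maps congener names to their carcinogenic potency relative to
#' benzo(a)pyrene (BaP, TEF = 1 by definition). `default_tef_table()` returns
#' a Nisbet-LaGoy-style scheme with dibenz(a,h)anthracene capped at 1; site-
#' or study-specific tables can be supplied wherever a TEF table is accepted.
#'
#' @param tefs Named numeric vector of strictly positive TEFs. Must contain a
#'   `BaP` entry equal to 1. Names outside [pah_congeners()] are rejected
#'   unless `allow_extra = TRUE`.
#' @param allow_extra Accept congener names beyond the default fifteen.
#' @return A named numeric vector of class `tef_table`.
#' @examples
#' tefs <- default_tef_table()
#' tefs[["BaP"]]
#' @export
tef_table <- function(tefs, allow_extra = FALSE) {
  if (is.null(names(tefs)) || any(names(tefs) == "")) {
    stop_("TEFs must be a fully named numeric vector")
  }
  check_number(tefs, "tefs", positive = TRUE)
  if (!"BaP" %in% names(tefs)) stop_("TEF table must contain a BaP entry")
  if (tefs[["BaP"]] != 1) stop_("the BaP TEF must be exactly 1")
  if (anyDuplicated(names(tefs))) stop_("duplicate congener names in TEF table")
  if (!allow_extra) {
    unknown <- setdiff(names(tefs), pah_congeners())
    if (length(unknown) > 0) {
      stop_("unknown congener name(s): ", paste(unknown, collapse = ", "))
    }
  }
  structure(tefs, class = c("tef_table", "numeric"))
}

#' @rdname tef_table
#' @export
default_tef_table <- function() {
  tef_table(c(
    Ace = 0.001, Acy = 0.001, Flo = 0.001, Phe = 0.001, Ant = 0.01,
    Fla = 0.001, Pyr = 0.001, BaA = 0.1, Chr = 0.01, BbF = 0.1,
    BkF = 0.1, BaP = 1, DahA = 1, IcdP = 0.1, BghiP = 0.01
  ))
}

#' Per-congener concentration profile
#'
#' One phase of atmospheric PAH concentrations measured at one site during
#' one sampling period.
#'
#' @param site_id Site identifier.
#' @param phase `"gaseous"` or `"particulate"`.
#' @param period Sampling-period label (e.g. `"winter"`, `"annual"`).
#' @param concentrations Named numeric vector of congener concentrations in
#'   ng m^-3; all values must be non-negative.
#' @return An object of class `pah_profile`.
#' @examples
#' pah_profile("S1", "particulate", "winter", c(BaP = 2.1, BaA = 5.0))
#' @export
pah_profile <- function(site_id, phase = c("gaseous", "particulate"),
                        period = "annual", concentrations = numeric()) {
  phase <- match.arg(phase)
  if (is.null(names(concentrations)) ||
      (length(concentrations) > 0 && any(names(concentrations) == ""))) {
    stop_("concentrations must be a named numeric vector")
  }
  check_number(concentrations, "concentrations", nonneg = TRUE)
  structure(
    list(site_id = site_id, phase = phase, period = period,
         concentrations = concentrations),
    class = "pah_profile"
  )
}

#' @export
print.pah_profile <- function(x, ...) {
  cat(sprintf("<pah_profile> site %s, %s phase, period %s: %d congener(s)\n",
              x$site_id, x$phase, x$period, length(x$concentrations)))
  invisible(x)
}

#' Exposure constants for the ILCR equation
#'
#' Bundles the deterministic constants of the inhalation risk equation:
#' exposure frequency `ef` (day yr^-1), exposure duration `ed` (yr),
#' averaging time `at` (day), the BaP inhalation cancer slope factor `csf`
#' (per mg kg^-1 day^-1) and the ng-to-mg mass scale factor. Defaults are the
#' adult-resident scenario: EF 365, ED 53 yr, AT 70 x 365 day, CSF 3.14.
#'
#' @param ef,ed,at,csf,unit_factor Strictly positive scalars.
#' @return An object of class `exposure_constants`.
#' @export
exposure_constants <- function(ef = 365, ed = 53, at = 70 * 365,
                               csf = 3.14, unit_factor = 1e-6) {
  for (nm in c("ef", "ed", "at", "csf", "unit_factor")) {
    v <- get(nm)
    if (length(v) != 1) stop_(sprintf("`%s` must be a single number", nm))
    check_number(v, nm, positive = TRUE)
  }
  structure(list(ef = ef, ed = ed, at = at, csf = csf,
                 unit_factor = unit_factor),
            class = "exposure_constants")
}

#' @export
print.exposure_constants <- function(x, ...) {
  cat(sprintf(
    "<exposure_constants> EF %g d/yr, ED %g yr, AT %g d, CSF %g, ng->mg %g\n",
    x$ef, x$ed, x$at, x$csf, x$unit_factor))
  invisible(x)
}

#' TEF-weighted BaP-equivalent concentration
#'
#' Computes the benzo(a)pyrene-equivalent concentration
#' BaP_eq = sum_i C_i * TEF_i over all congeners in the supplied profiles,
#' and over phases when profiles for both phases are given.
#'
#' @param profiles A single [pah_profile()] or a list of them.
#' @param tefs A [tef_table()].
#' @return BaP_eq in ng m^-3 (single non-negative number).
#' @examples
#' p <- pah_profile("S1", "gaseous", "annual", c(BaP = 2, DahA = 1, Chr = 10))
#' compute_bap_eq(p)   # 2*1 + 1*1 + 10*0.01 = 3.1
#' @export
compute_bap_eq <- function(profiles, tefs = default_tef_table()) {
  if (inherits(profiles, "pah_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop_("at least one profile is required")
  total <- 0
  for (p in profiles) {
    if (!inherits(p, "pah_profile")) stop_("profiles must be pah_profile objects")
    conc <- p$concentrations
    missing <- setdiff(names(conc), names(tefs))
    if (length(missing) > 0) {
      stop_("no TEF entry for congener(s): ", paste(missing, collapse = ", "))
    }
    total <- total + sum(conc * unclass(tefs)[names(conc)])
  }
  total
}

#' Incremental lifetime cancer risk from inhalation
#'
#' Evaluates the inhalation ILCR equation
#' `ILCR = BaP_eq * 1e-6 * IR * EF * ED * CSF / (BW * AT)`,
#' where the 1e-6 factor converts ng to mg so the dose entering the slope
#' factor is in mg kg^-1 day^-1. Vectorized over `bap_eq`, `ir` and `bw`.
#'
#' @param bap_eq BaP-equivalent concentration (ng m^-3), non-negative.
#' @param ir Inhalation rate (m^3 day^-1), strictly positive.
#' @param bw Body weight (kg), strictly positive.
#' @param constants An [exposure_constants()] object.
#' @return Dimensionless lifetime risk, same length as the longest input.
#' @examples
#' compute_ilcr(10, 16, 64)  # 5.944e-06
#' @export
compute_ilcr <- function(bap_eq, ir, bw, constants = exposure_constants()) {
  check_number(bap_eq, "bap_eq", nonneg = TRUE)
  check_number(ir, "ir", positive = TRUE)
  check_number(bw, "bw", positive = TRUE)
  stopifnot(inherits(constants, "exposure_constants"))
  bap_eq * constants$unit_factor * ir * constants$ef * constants$ed *
    constants$csf / (bw * constants$at)
}

#' Classify lifetime cancer risk against EPA thresholds
#'
#' Risks below one-in-a-million (1e-6) are conventionally acceptable; risks of
#' one-in-ten-thousand (1e-4) or greater are serious. The 1e-6 boundary falls
#' in `exceeds_acceptable`, the 1e-4 boundary in `serious`.
#'
#' @param ilcr Non-negative numeric vector of risks.
#' @param acceptable,serious Ordered thresholds (defaults 1e-6 and 1e-4).
#' @return Factor with levels `below_acceptable`, `exceeds_acceptable`,
#'   `serious`.
#' @examples
#' classify_risk(c(5e-7, 4.83e-6, 1e-4))
#' @export
classify_risk <- function(ilcr, acceptable = 1e-6, serious = 1e-4) {
  check_number(ilcr, "ilcr", nonneg = TRUE)
  if (!(acceptable < serious)) stop_("thresholds must satisfy acceptable < serious")
  cut(ilcr, breaks = c(-Inf, acceptable, serious, Inf), right = FALSE,
      labels = c("below_acceptable", "exceeds_acceptable", "serious"))
}

#' Convert inhalation rates between L/min and m^3/day
#'
#' 1 L min^-1 = 60 * 24 / 1000 = 1.44 m^3 day^-1.
#'
#' @param value Numeric vector of rates.
#' @param from,to One of `"L/min"`, `"m3/day"`.
#' @return `value` expressed in `to` units.
#' @examples
#' convert_ir(10, "L/min", "m3/day")  # 14.4
#' @export
convert_ir <- function(value, from, to) {
  units <- c("L/min", "m3/day")
  if (!from %in% units || !to %in% units) {
    stop_("units must be one of: ", paste(units, collapse = ", "))
  }
  check_number(value, "value")
  if (from == to) return(value)
  if (from == "L/min") value * 1.44 else value / 1.44
}

#' Annual average concentration profile
#'
#' Averages per-period profiles (same site and phase) congener-by-congener
#' into an annual profile. By default all periods get equal weight; explicit
#' weights must sum to 1.
#'
#' @param profiles List of [pah_profile()] objects covering the sampling
#'   periods; all must share the congener set.
#' @param weights Optional per-period fractions summing to 1.
#' @return A [pah_profile()] with `period = "annual"`.
#' @export
annualize <- function(profiles, weights = NULL) {
  if (inherits(profiles, "pah_profile")) profiles <- list(profiles)
  n <- length(profiles)
  if (n == 0) stop_("at least one period profile is required")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop_("one weight per profile is required")
  check_number(weights, "weights", positive = TRUE)
  if (abs(sum(weights) - 1) > 1e-9) stop_("weights must sum to 1")
  congeners <- names(profiles[[1]]$concentrations)
  acc <- numeric(length(congeners))
  names(acc) <- congeners
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    if (!setequal(names(p$concentrations), congeners)) {
      stop_("all period profiles must share the same congener set")
    }
    acc <- acc + weights[i] * p$concentrations[congeners]
  }
  pah_profile(profiles[[1]]$site_id, profiles[[1]]$phase, "annual", acc)
}
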