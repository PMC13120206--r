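#' Default exposure profiles for the three population groups
#'
#' Exposure-parameter distributions for adult males, adult females and
#' children, as used by the USEPA-style two-pathway dose model:
#' * `ir_ing` — sediment ingestion rate, mg/d (point: 114 adults, 200 children);
#' * `ed` — exposure duration, years (point: 70 adults, 18 children);
#' * `ef_freq` — exposure frequency, d/year (triangular 345 (180-365); named
#'   `ef_freq` to avoid any collision with the enrichment factor);
#' * `bw` — body weight, kg (lognormal 67.55 +/- 8.72 adult males,
#'   57.59 +/- 8.03 adult females; triangular 29.30 (5.20-56.80) children);
#' * `sa` — exposed skin surface area, m^2 (triangular);
#' * `af` — skin adherence factor, mg/(cm^2 d) (lognormal, arithmetic
#'   mean +/- sd 0.49 +/- 0.54 adults, 0.65 +/- 1.2 children; heavy-tailed,
#'   naturally truncated below at 0 by lognormality);
#' * `cf_unit` — unit conversion, point 1e-6 kg/mg.
#'
#' Averaging time is a rule, not a distribution: `365 * ED` days for
#' non-carcinogenic doses (so ED cancels), `365 * 70` days for carcinogenic
#' doses. Lognormal entries are parameterized from their arithmetic mean and
#' sd via the same moment bridge as the concentration models
#' ([fit_by_moments()]).
#'
#' @param group One of `"adult_male"`, `"adult_female"`, `"child"`.
#' @return An `exposure_profile`: a list of [dist_spec()] objects plus the
#'   group tag.
#' @export
default_exposure_profile <- function(group = c("adult_male", "adult_female",
                                               "child")) {
  group <- match.arg(group)
  lnorm <- function(mean, sd) fit_by_moments("lognormal",
                                             list(mean = mean, sd = sd))
  tri <- function(lower, mode, upper)
    dist_spec("triangular", lower = lower, mode = mode, upper = upper)
  pt <- function(v) dist_spec("point", value = v)
  common <- list(ef_freq = tri(180, 345, 365), cf_unit = pt(1e-6))
  p <- switch(group,
    adult_male = list(ir_ing = pt(114), ed = pt(70),
                      bw = lnorm(67.55, 8.72),
                      sa = tri(0.085, 0.169, 0.422),
                      af = lnorm(0.49, 0.54)),
    adult_female = list(ir_ing = pt(114), ed = pt(70),
                        bw = lnorm(57.59, 8.03),
                        sa = tri(0.076, 0.153, 0.382),
                        af = lnorm(0.49, 0.54)),
    child = list(ir_ing = pt(200), ed = pt(18),
                 bw = tri(5.20, 29.30, 56.80),
                 sa = tri(0.043, 0.086, 0.216),
                 af = lnorm(0.65, 1.2))
  )
  structure(c(list(group = group), p, common), class = "exposure_profile")
}

#' Average daily dose via incidental ingestion
#'
#' `CDD_ing = ck * IR * ED * EF * CF / (BW * AT)`, mg/(kg d). With the
#' non-carcinogenic averaging time `AT = 365 * ED` the exposure duration
#' cancels; with the carcinogenic `AT = 365 * 70` it does not.
#'
#' @param ck Sediment concentration, mg/kg (>= 0).
#' @param ir_ing Ingestion rate, mg/d.
#' @param ed Exposure duration, years.
#' @param ef_freq Exposure frequency, d/year.
#' @param bw Body weight, kg (> 0).
#' @param at Averaging time, days (> 0).
#' @param cf Unit conversion factor, kg/mg.
#' @return Dose in mg/(kg d). Vectorized with recycling.
#' @export
cdd_ingestion <- function(ck, ir_ing, ed, ef_freq, bw, at, cf = 1e-6) {
  if (any(bw <= 0) || any(at <= 0))
    stop("bw and at must be > 0", call. = FALSE)
  if (any(ck < 0)) stop("ck must be non-negative", call. = FALSE)
  ck * ir_ing * ed * ef_freq * cf / (bw * at)
}

#' Average daily dose via dermal contact
#'
#' `CDD_derm = ck * SA * AF * ABS * ED * EF * CF / (BW * AT)`, mg/(kg d).
#' `sa` is supplied in m^2 (as in the exposure tables) and converted to cm^2
#' (factor 1e4) before multiplying by the adherence factor `af`, whose units
#' are mg/(cm^2 d).
#'
#' @param ck Sediment concentration, mg/kg (>= 0).
#' @param sa Exposed skin surface area, m^2.
#' @param af Skin adherence factor, mg/(cm^2 d).
#' @param abs_frac Dermal absorption fraction in (0, 1].
#' @param ed Exposure duration, years.
#' @param ef_freq Exposure frequency, d/year.
#' @param bw Body weight, kg (> 0).
#' @param at Averaging time, days (> 0).
#' @param cf Unit conversion factor, kg/mg.
#' @return Dose in mg/(kg d). Vectorized with recycling.
#' @export
cdd_dermal <- function(ck, sa, af, abs_frac, ed, ef_freq, bw, at, cf = 1e-6) {
  if (any(bw <= 0) || any(at <= 0))
    stop("bw and at must be > 0", call. = FALSE)
  if (any(ck < 0)) stop("ck must be non-negative", call. = FALSE)
  ck * (sa * 1e4) * af * abs_frac * ed * ef_freq * cf / (bw * at)
}

#' Hazard quotient and hazard index
#'
#' `HQ = CDD / RfD` for one metal and route; `HI` is the sum of the nine
#' hazard quotients for one group and route, flagged `"potential"` when
#' strictly above 1 and `"negligible"` otherwise.
#'
#' @param cdd Non-carcinogenic average daily dose, mg/(kg d).
#' @param rfd Route-specific reference dose, mg/(kg d) (> 0).
#' @return `hazard_quotient()` returns the dimensionless ratio.
#' @export
hazard_quotient <- function(cdd, rfd) {
  if (anyNA(rfd) || any(rfd <= 0))
    stop("rfd must be present and > 0 for every metal and route", call. = FALSE)
  cdd / rfd
}

#' @rdname hazard_quotient
#' @param hqs Named numeric vector with one hazard quotient per metal.
#' @return `hazard_index()` returns a one-row tibble `hi`/`flag`.
#' @export
hazard_index <- function(hqs) {
  missing <- setdiff(metal_names(), names(hqs))
  if (length(missing) > 0)
    stop(sprintf("missing HQ for metal(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  hi <- sum(hqs[metal_names()])
  tibble::tibble(hi = hi, flag = if (hi > 1) "potential" else "negligible")
}

#' Carcinogenic risk
#'
#' `CR = CDD_carc * SF` where a route-specific slope factor exists; `NA`
#' (risk not computed) where it does not. The carcinogenic dose uses
#' `AT = 365 * 70` days, so exposure duration no longer cancels.
#' `total_carcinogenic_risk()` sums the available CRs.
#'
#' @param cdd_carc Carcinogenic average daily dose, mg/(kg d).
#' @param sf Slope factor, (mg/(kg d))^-1, or `NA` where not established.
#' @return `carcinogenic_risk()`: CR, with `NA` propagated where `sf` is
#'   absent.
#' @export
carcinogenic_risk <- function(cdd_carc, sf) {
  cdd_carc * sf # NA slope factors propagate to NA risk
}

#' @rdname carcinogenic_risk
#' @param cr Numeric vector of per-metal CRs (may contain `NA`).
#' @return `total_carcinogenic_risk()`: the sum over available entries.
#' @export
total_carcinogenic_risk <- function(cr) sum(cr, na.rm = TRUE)

#' @rdname carcinogenic_risk
#' @param tcr Total carcinogenic risk (>= 0).
#' @return `classify_tcr()`: `"negligible"` below 1e-6, `"acceptable"` in
#'   [1e-6, 1e-4), `"unacceptable"` at or above 1e-4.
#' @export
classify_tcr <- function(tcr) {
  if (any(tcr < 0)) stop("tcr must be non-negative", call. = FALSE)
  ifelse(tcr < 1e-6, "negligible",
         ifelse(tcr < 1e-4, "acceptable", "unacceptable"))
}

# shared plumbing: exposure inputs + concentration constants for one route
.exposure_inputs <- function(profile, route) {
  inputs <- list(ef_freq = profile$ef_freq, bw = profile$bw)
  if (route == "dermal") {
    inputs$sa <- profile$sa
    inputs$af <- profile$af
  }
  inputs
}

#' Monte Carlo hazard index for one group and route
#'
#' Propagates the stochastic exposure parameters (exposure frequency, body
#' weight and, for the dermal route, skin area and adherence factor) through
#' the dose model at fixed metal concentrations, and summarizes the resulting
#' hazard-index draws. Point-valued profile entries (ingestion rate, exposure
#' duration, unit conversion) enter as constants. The non-carcinogenic
#' averaging time `365 * ED` is applied, so ED cancels.
#'
#' @param conc Named numeric vector of metal concentrations, mg/kg.
#' @param profile An [default_exposure_profile()].
#' @param route `"ingestion"` or `"dermal"`.
#' @param toxicology A [default_toxicology()] table.
#' @param config An [mc_config()].
#' @return An [mc_result] of hazard-index draws, with the input draws
#'   attached for sensitivity analysis.
#' @export
simulate_hazard_index <- function(conc, profile,
                                  route = c("ingestion", "dermal"),
                                  toxicology = default_toxicology(),
                                  config = mc_config()) {
  route <- match.arg(route)
  missing <- setdiff(metal_names(), names(conc))
  if (length(missing) > 0)
    stop(sprintf("missing concentration for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ir <- profile$ir_ing$params$value
  cf <- profile$cf_unit$params$value
  ed <- profile$ed$params$value
  model <- if (route == "ingestion") {
    function(x) {
      hq_sum <- 0
      for (m in metal_names()) {
        cdd <- cdd_ingestion(conc[[m]], ir, ed, x$ef_freq, x$bw,
                             at = 365 * ed, cf = cf)
        hq_sum <- hq_sum + hazard_quotient(cdd, toxicology$rfd_ing[[m]])
      }
      hq_sum
    }
  } else {
    function(x) {
      hq_sum <- 0
      for (m in metal_names()) {
        cdd <- cdd_dermal(conc[[m]], x$sa, x$af, toxicology$abs_dermal[[m]],
                          ed, x$ef_freq, x$bw, at = 365 * ed, cf = cf)
        hq_sum <- hq_sum + hazard_quotient(cdd, toxicology$rfd_derm[[m]])
      }
      hq_sum
    }
  }
  run_mc(model, .exposure_inputs(profile, route), config)
}

#' Monte Carlo total carcinogenic risk for one group and route
#'
#' As [simulate_hazard_index()], but with the carcinogenic averaging time
#' `365 * 70` days (so the dose scales with ED/70) and summing
#' `CDD * SF` only over the metals with an established slope factor on the
#' route (ingestion: As, Cd, Cr, Pb; dermal: As, Cd).
#'
#' @inheritParams simulate_hazard_index
#' @return An [mc_result] of TCR draws.
#' @export
simulate_carcinogenic_risk <- function(conc, profile,
                                       route = c("ingestion", "dermal"),
                                       toxicology = default_toxicology(),
                                       config = mc_config()) {
  route <- match.arg(route)
  ir <- profile$ir_ing$params$value
  cf <- profile$cf_unit$params$value
  ed <- profile$ed$params$value
  at <- 365 * 70
  sf <- if (route == "ingestion") toxicology$sf_ing else toxicology$sf_derm
  with_sf <- metal_names()[!is.na(sf[metal_names()])]
  model <- function(x) {
    cr_sum <- 0
    for (m in with_sf) {
      cdd <- if (route == "ingestion") {
        cdd_ingestion(conc[[m]], ir, ed, x$ef_freq, x$bw, at = at, cf = cf)
      } else {
        cdd_dermal(conc[[m]], x$sa, x$af, toxicology$abs_dermal[[m]],
                   ed, x$ef_freq, x$bw, at = at, cf = cf)
      }
      cr_sum <- cr_sum + carcinogenic_risk(cdd, sf[[m]])
    }
    cr_sum
  }
  run_mc(model, .exposure_inputs(profile, route), config)
}
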