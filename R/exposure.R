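# Consumer exposure scenarios, bioactivity-exposure ratios and traditional
# margins of safety.

#' Default body surface area treated by a body lotion (cm^2)
#'
#' SCCS Notes of Guidance default whole-body surface area used to convert a
#' daily applied product amount into a dose per unit skin area.
#' @export
SCCS_BODY_SURFACE_CM2 <- 15670

#' Construct a consumer exposure scenario
#'
#' @param product_type label, e.g. `"body lotion"`.
#' @param daily_amount product applied or ingested, g/day.
#' @param concentration ingredient mass fraction in the product (0-1);
#'   0.1\% is 0.001.
#' @param body_weight consumer body weight, kg (default 60).
#' @param surface_area treated skin area, cm^2 (dermal route; defaults to the
#'   SCCS whole-body figure).
#' @param route `"dermal"` or `"oral"`.
#' @param product_amount_per_bw optional product amount relative to body
#'   weight, mg/kg bw/day. This is a distribution-based figure taken from
#'   exposure guidance, carried as an independent input and never recomputed
#'   from `daily_amount / body_weight`.
#' @return object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(product_type, daily_amount, concentration,
                              body_weight = 60,
                              surface_area = SCCS_BODY_SURFACE_CM2,
                              route = c("dermal", "oral"),
                              product_amount_per_bw = NULL) {
  route <- match.arg(route)
  check_number(daily_amount, "daily_amount", positive = TRUE)
  check_fraction(concentration, "concentration", allow_zero = TRUE)
  check_number(body_weight, "body_weight", positive = TRUE)
  check_number(surface_area, "surface_area", positive = TRUE)
  if (!is.null(product_amount_per_bw)) {
    check_number(product_amount_per_bw, "product_amount_per_bw", positive = TRUE)
  }
  structure(list(
    product_type = product_type,
    daily_amount_g = daily_amount,
    concentration = concentration,
    body_weight_kg = body_weight,
    surface_area_cm2 = surface_area,
    route = route,
    product_amount_per_bw_mg_kg = product_amount_per_bw %||%
      (daily_amount * 1000 / body_weight)
  ), class = "exposure_scenario")
}

#' Applied ingredient dose per unit skin area
#'
#' For a dermal scenario, converts the daily product amount and ingredient
#' concentration into micrograms of ingredient per cm^2 of treated skin:
#' `daily_amount * concentration / surface_area`.
#'
#' @param scenario an [exposure_scenario()] with `route = "dermal"`.
#' @return dose in ug/cm^2 per day.
#' @export
applied_dose_per_area <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (scenario$route != "dermal") {
    stop_ngra("applied dose per area is defined for the dermal route only",
              class = "ngra_route_error")
  }
  scenario$daily_amount_g * 1e6 * scenario$concentration / scenario$surface_area_cm2
}

#' Systemic exposure dose
#'
#' Daily amount of ingredient reaching the systemic circulation per kg body
#' weight: `product_amount_per_bw * concentration * absorbed_fraction`
#' (mg/kg bw/day).
#'
#' @param scenario an [exposure_scenario()].
#' @param absorbed_fraction fraction of the applied ingredient absorbed as
#'   parent into the systemic circulation (0-1).
#' @return SED in mg/kg bw/day.
#' @export
systemic_exposure_dose <- function(scenario, absorbed_fraction) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  check_fraction(absorbed_fraction, "absorbed_fraction", allow_zero = TRUE)
  scenario$product_amount_per_bw_mg_kg * scenario$concentration * absorbed_fraction
}

#' Bioactivity-exposure ratio
#'
#' The BER divides an internal (plasma) point of departure by an internal
#' exposure metric from the same unit system; a ratio substantially greater
#' than 1 indicates that estimated exposure is below concentrations causing
#' bioactivity, while a ratio near or below 1 flags the assessment for
#' refinement.
#'
#' @param pod_internal internal PoD, nM.
#' @param exposure_value internal exposure metric (e.g. a Cmax), nM.
#' @param exposure_metric label of the metric used, e.g. `"cmax_total_mean"`.
#' @return object of class `ber_result` with full-precision `ber`, the
#'   display-rounded `ber_display` (see [display_ber()]) and an
#'   `interpretation` of `"acceptable_margin"` (BER > 1) or
#'   `"refine_assessment"`.
#' @export
compute_ber <- function(pod_internal, exposure_value,
                        exposure_metric = "cmax_total_mean") {
  check_number(pod_internal, "pod_internal", positive = TRUE)
  check_number(exposure_value, "exposure_value", positive = TRUE)
  ber <- pod_internal / exposure_value
  structure(list(
    pod_internal_nM = pod_internal,
    exposure_metric = exposure_metric,
    exposure_value_nM = exposure_value,
    ber = ber,
    ber_display = display_ber(ber),
    interpretation = if (ber > 1) "acceptable_margin" else "refine_assessment"
  ), class = "ber_result")
}

#' @export
print.ber_result <- function(x, ...) {
  cat(sprintf("BER = %g / %g nM = %g (%s)\n", x$pod_internal_nM,
              x$exposure_value_nM, x$ber_display, x$interpretation))
  invisible(x)
}

#' Traditional margin of safety
#'
#' `MoS = pod_external * absorption_adjustment / sed`, where the external PoD
#' is a NOAEL in mg/kg bw/day, the adjustment converts it to a systemically
#' available dose (e.g. 0.25 for 25\% oral bioavailability) and the SED is
#' the systemic exposure dose of the scenario under assessment.
#'
#' @param pod_external external PoD, mg/kg bw/day.
#' @param absorption_adjustment bioavailability fraction applied to the PoD.
#' @param sed systemic exposure dose, mg/kg bw/day (> 0).
#' @return object of class `mos_result`.
#' @export
margin_of_safety <- function(pod_external, absorption_adjustment, sed) {
  check_number(pod_external, "pod_external", positive = TRUE)
  check_fraction(absorption_adjustment, "absorption_adjustment")
  check_number(sed, "sed", positive = TRUE)
  structure(list(
    pod_external_mg_kg = pod_external,
    absorption_adjustment = absorption_adjustment,
    sed_mg_kg = sed,
    mos = pod_external * absorption_adjustment / sed
  ), class = "mos_result")
}

#' @export
print.mos_result <- function(x, ...) {
  cat(sprintf("MoS = %g x %g / %g = %g\n", x$pod_external_mg_kg,
              x$absorption_adjustment, x$sed_mg_kg, round_half_up(x$mos, 1)))
  invisible(x)
}

#' BER table in Markdown
#'
#' Renders a list of [compute_ber()] results as a Markdown table
#' (PoD, exposure metric, exposure value, BER, interpretation).
#'
#' @param bers list of `ber_result` objects.
#' @return character vector of Markdown lines.
#' @export
ber_markdown <- function(bers) {
  stopifnot(all(vapply(bers, inherits, logical(1), "ber_result")))
  rows <- vapply(bers, function(b) {
    sprintf("| %g | %s | %g | %g | %s |", b$pod_internal_nM, b$exposure_metric,
            b$exposure_value_nM, b$ber_display, b$interpretation)
  }, character(1))
  c("| PoD (nM) | Exposure metric | Exposure value (nM) | BER | Interpretation |",
    "|---|---|---|---|---|", rows)
}
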