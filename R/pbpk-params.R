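# PBPK parameterization: whole-body perfusion-limited compartment sets,
# dosing schedules, population-variability specs and YAML/JSON config I/O.

#' Construct a PBPK parameter set
#'
#' A generic calibratable perfusion-limited whole-body model. Tissues
#' exchange with a central plasma pool at their blood flow; a gut
#' compartment (when present) drains through the liver (portal routing);
#' hepatic intrinsic clearance acts on the unbound liver concentration (or
#' on plasma when no liver compartment is configured, which gives the
#' classical one-compartment limit). Oral dosing passes through a gut-lumen
#' depot with first-order absorption; dermal dosing passes through a skin
#' surface depot where first-order permeation into the skin competes with
#' first-order cutaneous metabolism (dermal first-pass).
#'
#' @param body_weight kg.
#' @param compartments data frame with columns `name`, `volume_L_kg`
#'   (L per kg body weight), `flow_L_h_kg` (blood flow, L/h per kg body
#'   weight) and `kp` (tissue:plasma partition coefficient). May be empty
#'   for the one-compartment limit.
#' @param plasma_volume_L_kg central plasma volume, L/kg.
#' @param fu_plasma fraction unbound in plasma, (0, 1].
#' @param hepatic_clint_L_h_kg unbound intrinsic hepatic clearance, L/h/kg.
#' @param ka_oral_per_h first-order oral absorption rate, 1/h. `Inf` means
#'   instantaneous absorption (dose bolused into the absorption target).
#' @param f_abs_oral oral absorbed fraction, (0, 1].
#' @param f_abs_dermal dermal absorbed fraction (fraction of the applied
#'   dose entering the skin depot), [0, 1].
#' @param k_perm_skin_per_h skin-depot-to-tissue transfer rate, 1/h.
#' @param k_met_skin_per_h first-order cutaneous metabolism rate in the
#'   skin depot, 1/h (0 disables skin first-pass metabolism).
#' @param molecular_weight g/mol, used for mg/ug to nmol conversion.
#' @param chemical_id,species optional labels carried through reports.
#' @return object of class `pbpk_parameters`.
#' @export
pbpk_parameters <- function(body_weight,
                            compartments,
                            plasma_volume_L_kg,
                            fu_plasma,
                            hepatic_clint_L_h_kg,
                            ka_oral_per_h = 1,
                            f_abs_oral = 1,
                            f_abs_dermal = 1,
                            k_perm_skin_per_h = 0.1,
                            k_met_skin_per_h = 0,
                            molecular_weight = 100,
                            chemical_id = NA_character_,
                            species = NA_character_) {
  check_number(body_weight, "body_weight", positive = TRUE)
  check_number(plasma_volume_L_kg, "plasma_volume_L_kg", positive = TRUE)
  check_fraction(fu_plasma, "fu_plasma")
  check_number(hepatic_clint_L_h_kg, "hepatic_clint_L_h_kg", nonneg = TRUE)
  if (!(is.numeric(ka_oral_per_h) && length(ka_oral_per_h) == 1 &&
        (is.infinite(ka_oral_per_h) || ka_oral_per_h > 0))) {
    stop_ngra("`ka_oral_per_h` must be > 0 (or Inf for instantaneous absorption)",
              class = "ngra_validation_error")
  }
  check_fraction(f_abs_oral, "f_abs_oral")
  check_fraction(f_abs_dermal, "f_abs_dermal", allow_zero = TRUE)
  check_number(k_perm_skin_per_h, "k_perm_skin_per_h", nonneg = TRUE)
  check_number(k_met_skin_per_h, "k_met_skin_per_h", nonneg = TRUE)
  check_number(molecular_weight, "molecular_weight", positive = TRUE)

  compartments <- as.data.frame(compartments)
  if (nrow(compartments)) {
    req <- c("name", "volume_L_kg", "flow_L_h_kg", "kp")
    if (!all(req %in% names(compartments))) {
      stop_ngra("compartments need columns name, volume_L_kg, flow_L_h_kg, kp",
                class = "ngra_validation_error")
    }
    if (anyDuplicated(compartments$name)) {
      stop_ngra("duplicate compartment names", class = "ngra_validation_error")
    }
    num <- c("volume_L_kg", "flow_L_h_kg", "kp")
    if (any(!is.finite(as.matrix(compartments[num]))) ||
        any(as.matrix(compartments[num]) <= 0)) {
      stop_ngra("compartment volumes, flows and partition coefficients must be > 0",
                class = "ngra_validation_error")
    }
    if ("gut" %in% compartments$name && !"liver" %in% compartments$name) {
      stop_ngra("a gut compartment requires a liver compartment (portal routing)",
                class = "ngra_validation_error")
    }
  }
  structure(list(
    body_weight = body_weight,
    compartments = compartments,
    plasma_volume_L_kg = plasma_volume_L_kg,
    fu_plasma = fu_plasma,
    hepatic_clint_L_h_kg = hepatic_clint_L_h_kg,
    ka_oral_per_h = ka_oral_per_h,
    f_abs_oral = f_abs_oral,
    f_abs_dermal = f_abs_dermal,
    k_perm_skin_per_h = k_perm_skin_per_h,
    k_met_skin_per_h = k_met_skin_per_h,
    molecular_weight = molecular_weight,
    chemical_id = chemical_id,
    species = species
  ), class = "pbpk_parameters")
}

#' Default perfusion-limited compartment set
#'
#' Gut, liver, kidney, skin and rest-of-body with species-typical fractional
#' volumes and blood flows (all per kg body weight) and unit partition
#' coefficients; intended as a starting point for calibration.
#'
#' @param species `"rat"` or `"human"`.
#' @return compartment data frame for [pbpk_parameters()].
#' @export
default_compartments <- function(species = c("human", "rat")) {
  species <- match.arg(species)
  if (species == "rat") {
    data.frame(
      name         = c("gut", "liver", "kidney", "skin", "rest"),
      volume_L_kg  = c(0.027, 0.034, 0.007, 0.190, 0.500),
      flow_L_h_kg  = c(2.67, 0.36, 2.49, 1.03, 8.90),
      kp           = c(1, 1, 1, 1, 1),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      name         = c("gut", "liver", "kidney", "skin", "rest"),
      volume_L_kg  = c(0.017, 0.026, 0.004, 0.037, 0.600),
      flow_L_h_kg  = c(0.98, 0.28, 1.13, 0.32, 2.90),
      kp           = c(1, 1, 1, 1, 1),
      stringsAsFactors = FALSE
    )
  }
}

#' Construct a dosing schedule
#'
#' @param route `"oral"` (dose in mg/kg per administration) or `"dermal"`
#'   (dose in ug/cm^2 per administration; `area_cm2` required).
#' @param dose external dose per administration, >= 0, in route-native units.
#' @param interval_h hours between doses (default 24, once daily).
#' @param n_doses number of administrations (default 7).
#' @param duration_days simulated duration (default spans the dosing series
#'   plus one full interval, i.e. 7 days for the default schedule).
#' @param area_cm2 treated skin area for dermal dosing.
#' @return object of class `dosing_schedule`.
#' @export
dosing_schedule <- function(route = c("oral", "dermal"), dose,
                            interval_h = 24, n_doses = 7,
                            duration_days = n_doses * interval_h / 24,
                            area_cm2 = NULL) {
  route <- match.arg(route)
  check_number(dose, "dose", nonneg = TRUE)
  check_number(interval_h, "interval_h", positive = TRUE)
  check_number(n_doses, "n_doses", positive = TRUE)
  if (n_doses < 1 || n_doses != round(n_doses)) {
    stop_ngra("n_doses must be a positive integer", class = "ngra_validation_error")
  }
  check_number(duration_days, "duration_days", positive = TRUE)
  if (duration_days * 24 < (n_doses - 1) * interval_h) {
    stop_ngra("duration shorter than the dosing series",
              class = "ngra_validation_error")
  }
  if (route == "dermal") {
    if (is.null(area_cm2)) {
      stop_ngra("dermal dosing requires `area_cm2`", class = "ngra_validation_error")
    }
    check_number(area_cm2, "area_cm2", positive = TRUE)
  }
  structure(list(route = route, dose = dose, interval_h = interval_h,
                 n_doses = as.integer(n_doses), duration_days = duration_days,
                 area_cm2 = area_cm2), class = "dosing_schedule")
}

#' Construct a population-variability specification
#'
#' Inter-individual variability is modelled as independent median-preserving
#' lognormal multipliers on named parameters. Recognized names:
#' `hepatic_clint`, `fu_plasma` (resampled values are capped at 1),
#' `ka_oral`, `k_perm_skin`, `k_met_skin`, `f_abs_oral`, `f_abs_dermal`
#' (capped at 1), `volume_scalar` (scales plasma and all tissue volumes),
#' `flow_scalar` (all tissue flows) and `kp_scalar` (all partition
#' coefficients).
#'
#' @param cv named list/vector of lognormal coefficients of variation >= 0.
#' @param n_individuals number of Monte Carlo individuals (>= 1).
#' @param seed integer seed; fixed seed gives bit-identical results.
#' @return object of class `variability_spec`.
#' @export
variability_spec <- function(cv = list(), n_individuals = 1000, seed = 1L) {
  cv <- as.list(cv)
  allowed <- c("hepatic_clint", "fu_plasma", "ka_oral", "k_perm_skin",
               "k_met_skin", "f_abs_oral", "f_abs_dermal", "volume_scalar",
               "flow_scalar", "kp_scalar")
  bad <- setdiff(names(cv), allowed)
  if (length(bad)) {
    stop_ngra("unknown variability parameters: ", paste(bad, collapse = ", "),
              class = "ngra_validation_error")
  }
  for (nm in names(cv)) check_number(cv[[nm]], nm, nonneg = TRUE)
  check_number(n_individuals, "n_individuals", positive = TRUE)
  if (n_individuals != round(n_individuals)) {
    stop_ngra("n_individuals must be an integer", class = "ngra_validation_error")
  }
  structure(list(cv = cv, n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed)), class = "variability_spec")
}

#' Read a PBPK configuration from YAML or JSON
#'
#' The document may contain blocks `parameters`, `schedule` and
#' `variability`; each present block is validated through its constructor.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return list with elements `parameters` (`pbpk_parameters`), `schedule`
#'   (`dosing_schedule` or NULL) and `variability` (`variability_spec` or
#'   NULL).
#' @export
read_pbpk_config <- function(path) {
  if (!file.exists(path)) stop_ngra("config not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  p <- doc$parameters
  if (is.null(p)) stop_ngra("config has no `parameters` block")
  comp <- if (is.data.frame(p$compartments)) p$compartments else {
    do.call(rbind, lapply(p$compartments, function(cc) {
      data.frame(name = cc$name, volume_L_kg = cc$volume_L_kg,
                 flow_L_h_kg = cc$flow_L_h_kg, kp = cc$kp,
                 stringsAsFactors = FALSE)
    }))
  }
  ka <- p$ka_oral_per_h %||% 1
  if (identical(ka, "Inf") || identical(ka, ".inf")) ka <- Inf
  params <- pbpk_parameters(
    body_weight = p$body_weight,
    compartments = comp %||% data.frame(),
    plasma_volume_L_kg = p$plasma_volume_L_kg,
    fu_plasma = p$fu_plasma,
    hepatic_clint_L_h_kg = p$hepatic_clint_L_h_kg,
    ka_oral_per_h = ka,
    f_abs_oral = p$f_abs_oral %||% 1,
    f_abs_dermal = p$f_abs_dermal %||% 1,
    k_perm_skin_per_h = p$k_perm_skin_per_h %||% 0.1,
    k_met_skin_per_h = p$k_met_skin_per_h %||% 0,
    molecular_weight = p$molecular_weight,
    chemical_id = p$chemical_id %||% NA_character_,
    species = p$species %||% NA_character_
  )
  sched <- NULL
  if (!is.null(doc$schedule)) {
    s <- doc$schedule
    sched <- dosing_schedule(route = s$route, dose = s$dose,
                             interval_h = s$interval_h %||% 24,
                             n_doses = s$n_doses %||% 7,
                             duration_days = s$duration_days %||%
                               ((s$n_doses %||% 7) * (s$interval_h %||% 24) / 24),
                             area_cm2 = s$area_cm2)
  }
  vs <- NULL
  if (!is.null(doc$variability)) {
    v <- doc$variability
    vs <- variability_spec(cv = v$cv %||% list(),
                           n_individuals = v$n_individuals %||% 1000,
                           seed = v$seed %||% 1L)
  }
  list(parameters = params, schedule = sched, variability = vs)
}

#' Path to a PBPK configuration shipped with the package
#'
#' Shipped calibrated configurations are regression anchors fitted to the
#' printed case-study values (see the methods vignette); they are not claims
#' of equivalence to any external model. Available names:
#' `genistein-rat-oral`, `daidzein-rat-oral`, `daidzein-human-dermal`.
#'
#' @param name configuration name (without extension).
#' @return file path.
#' @export
pbpk_config_path <- function(name) {
  p <- system.file("extdata", "pbpk", paste0(name, ".yaml"), package = "ngra")
  if (p == "") stop_ngra("no shipped PBPK config named '", name, "'")
  p
}
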