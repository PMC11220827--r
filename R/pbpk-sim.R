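# Whole-body PBPK simulation, steady-state Cmax metrics, Monte Carlo
# population variability and reverse dosimetry.

# state-vector layout helpers --------------------------------------------

pbpk_state_names <- function(params) {
  c("gut_lumen", "skin_depot",
    if (nrow(params$compartments)) params$compartments$name,
    "plasma", "eliminated", "skin_metabolized", "unabsorbed")
}

# The model is linear and time-invariant between dose events, so the whole
# right-hand side is one constant rate matrix M with dA/dt = M A. Building M
# once per simulation keeps the stiff integrator fast (constant analytic
# Jacobian) without changing the model.
pbpk_rate_matrix <- function(params) {
  nms <- pbpk_state_names(params)
  n <- length(nms)
  M <- matrix(0, n, n, dimnames = list(nms, nms))
  comp <- params$compartments
  bw <- params$body_weight
  V_pl <- params$plasma_volume_L_kg * bw
  fu <- params$fu_plasma
  CL <- params$hepatic_clint_L_h_kg * bw
  ka <- params$ka_oral_per_h
  k_perm <- params$k_perm_skin_per_h
  k_met <- params$k_met_skin_per_h
  has <- function(x) x %in% comp$name

  # skin surface depot: permeation vs cutaneous metabolism
  M["skin_depot", "skin_depot"] <- -(k_perm + k_met)
  M["skin_metabolized", "skin_depot"] <- k_met
  perm_target <- if (has("skin")) "skin" else "plasma"
  M[perm_target, "skin_depot"] <- M[perm_target, "skin_depot"] + k_perm

  # gut lumen depot (finite ka; Inf means events bolus the target directly)
  abs_target <- if (has("gut")) "gut" else "plasma"
  if (is.finite(ka)) {
    M["gut_lumen", "gut_lumen"] <- -ka
    M[abs_target, "gut_lumen"] <- M[abs_target, "gut_lumen"] + ka
  }

  if (nrow(comp)) {
    V <- comp$volume_L_kg * bw
    Q <- comp$flow_L_h_kg * bw
    kel <- Q / (V * comp$kp)     # venous outflow rate constants
    names(V) <- names(Q) <- names(kel) <- comp$name
    for (nm in comp$name) {
      M[nm, "plasma"] <- M[nm, "plasma"] + Q[nm] / V_pl       # arterial inflow
      M["plasma", "plasma"] <- M["plasma", "plasma"] - Q[nm] / V_pl
      if (nm == "gut") {
        # portal routing: gut venous blood drains through the liver
        M["gut", "gut"] <- M["gut", "gut"] - kel["gut"]
        M["liver", "gut"] <- M["liver", "gut"] + kel["gut"]
      } else if (nm == "liver") {
        out <- (Q["liver"] + if (has("gut")) Q["gut"] else 0) /
          (V["liver"] * comp$kp[comp$name == "liver"])
        clr <- CL * fu / (V["liver"] * comp$kp[comp$name == "liver"])
        M["liver", "liver"] <- M["liver", "liver"] - out - clr
        M["plasma", "liver"] <- M["plasma", "liver"] + out
        M["eliminated", "liver"] <- M["eliminated", "liver"] + clr
      } else {
        M[nm, nm] <- M[nm, nm] - kel[nm]
        M["plasma", nm] <- M["plasma", nm] + kel[nm]
      }
    }
    if (!has("liver")) {
      M["plasma", "plasma"] <- M["plasma", "plasma"] - CL * fu / V_pl
      M["eliminated", "plasma"] <- M["eliminated", "plasma"] + CL * fu / V_pl
    }
  } else {
    M["plasma", "plasma"] <- M["plasma", "plasma"] - CL * fu / V_pl
    M["eliminated", "plasma"] <- M["eliminated", "plasma"] + CL * fu / V_pl
  }
  M
}

pbpk_derivs <- function(t, state, M) {
  list(as.vector(M %*% state))
}

dose_to_nmol <- function(schedule, params) {
  if (schedule$route == "oral") {
    # mg/kg -> nmol
    schedule$dose * params$body_weight * 1e6 / params$molecular_weight
  } else {
    # ug/cm2 * cm2 -> nmol
    schedule$dose * schedule$area_cm2 * 1e3 / params$molecular_weight
  }
}

#' Simulate plasma and tissue kinetics under repeated dosing
#'
#' Integrates the perfusion-limited model (stiff-capable `lsoda`) over the
#' scheduled dosing series. Oral doses enter a gut-lumen depot (absorbed
#' fraction `f_abs_oral`; the rest is tracked as unabsorbed mass); dermal
#' doses enter the skin surface depot (absorbed fraction `f_abs_dermal`)
#' where permeation and cutaneous metabolism compete. Internal state is in
#' nmol; plasma concentration is reported in nM.
#'
#' @param params a [pbpk_parameters()] object.
#' @param schedule a [dosing_schedule()] object.
#' @param dt coarse output resolution (h) before the final dosing interval.
#' @param dt_fine output resolution (h) over the final dosing interval, from
#'   which Cmax is read.
#' @param rtol,atol solver tolerances.
#' @return object of class `pbpk_timeseries` with `times` (h), `plasma_nM`,
#'   an `amounts` matrix (nmol per state), cumulative `eliminated`,
#'   `skin_metabolized` and `unabsorbed` mass, and the administered total.
#' @export
simulate_plasma <- function(params, schedule, dt = 0.5, dt_fine = 0.05,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "pbpk_parameters"),
            inherits(schedule, "dosing_schedule"))
  if (schedule$route == "dermal" && params$f_abs_dermal > 0 &&
      params$k_perm_skin_per_h == 0 && schedule$dose > 0) {
    stop_ngra("dermal dosing requires k_perm_skin_per_h > 0",
              class = "ngra_validation_error")
  }
  M <- pbpk_rate_matrix(params)
  V_pl <- params$plasma_volume_L_kg * params$body_weight
  state <- stats::setNames(numeric(length(pbpk_state_names(params))),
                           pbpk_state_names(params))

  dose_times <- (seq_len(schedule$n_doses) - 1) * schedule$interval_h
  total_nmol <- dose_to_nmol(schedule, params)
  if (schedule$route == "oral") {
    f_abs <- params$f_abs_oral
    target <- if (is.finite(params$ka_oral_per_h)) "gut_lumen"
              else if ("gut" %in% params$compartments$name) "gut" else "plasma"
  } else {
    f_abs <- params$f_abs_dermal
    target <- "skin_depot"
  }
  events <- rbind(
    data.frame(var = target, time = dose_times, value = total_nmol * f_abs,
               method = "add", stringsAsFactors = FALSE),
    data.frame(var = "unabsorbed", time = dose_times,
               value = total_nmol * (1 - f_abs), method = "add",
               stringsAsFactors = FALSE)
  )
  events <- events[order(events$time, events$var), , drop = FALSE]
  t_end <- schedule$duration_days * 24
  t_last <- max(dose_times)
  fine_from <- if (t_end > t_last) t_last else max(0, t_end - schedule$interval_h)
  times <- sort(unique(c(seq(0, fine_from, by = dt),
                         seq(fine_from, t_end, by = dt_fine),
                         t_end, dose_times)))

  out <- deSolve::lsoda(y = state, times = times, func = pbpk_derivs,
                        parms = M, rtol = rtol, atol = atol,
                        jacfunc = function(t, y, M) M, jactype = "fullusr",
                        events = list(data = events), maxsteps = 50000)
  if (any(!is.finite(out))) {
    stop_ngra("PBPK integration produced non-finite state",
              class = "ngra_integration_failure")
  }
  amounts <- out[, -1, drop = FALSE]
  plasma_nM <- amounts[, "plasma"] / V_pl
  if (min(plasma_nM) < -1e-9 * max(abs(plasma_nM), 1)) {
    stop_ngra("PBPK integration produced negative plasma concentrations",
              class = "ngra_integration_failure")
  }
  structure(list(
    times = out[, 1],
    plasma_nM = pmax(plasma_nM, 0),
    amounts = amounts,
    eliminated = amounts[, "eliminated"],
    skin_metabolized = amounts[, "skin_metabolized"],
    unabsorbed = amounts[, "unabsorbed"],
    administered_nmol = total_nmol * schedule$n_doses,
    params = params,
    schedule = schedule
  ), class = "pbpk_timeseries")
}

#' Mass-balance error of a simulation
#'
#' Relative difference between administered mass and the sum of mass in the
#' body (tissues, plasma, depots), unabsorbed, skin-metabolized and
#' eliminated mass at the final timepoint.
#'
#' @param series a `pbpk_timeseries`.
#' @return relative error (0 for a zero-dose series).
#' @export
mass_balance_error <- function(series) {
  stopifnot(inherits(series, "pbpk_timeseries"))
  if (series$administered_nmol == 0) return(0)
  last <- nrow(series$amounts)
  accounted <- sum(series$amounts[last, ])
  abs(series$administered_nmol - accounted) / series$administered_nmol
}

#' Tidy export of a simulated time series
#'
#' @param x a `pbpk_timeseries`.
#' @param ... unused.
#' @return long data frame with columns `time_h`, `compartment`,
#'   `amount_nmol` and `plasma_nM` (populated on plasma rows).
#' @export
as.data.frame.pbpk_timeseries <- function(x, ...) {
  comps <- colnames(x$amounts)
  out <- do.call(rbind, lapply(comps, function(cn) {
    data.frame(time_h = x$times, compartment = cn,
               amount_nmol = x$amounts[, cn],
               plasma_nM = if (cn == "plasma") x$plasma_nM else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.pbpk_timeseries <- function(x, ...) {
  cat(sprintf("PBPK time series: %s, %s route, %d x %g %s, %g days\n",
              x$params$chemical_id, x$schedule$route, x$schedule$n_doses,
              x$schedule$dose,
              ifelse(x$schedule$route == "oral", "mg/kg", "ug/cm2"),
              x$schedule$duration_days))
  cat(sprintf("  final plasma: %.4g nM; mass-balance error %.2e\n",
              x$plasma_nM[length(x$plasma_nM)], mass_balance_error(x)))
  invisible(x)
}

#' Steady-state Cmax metrics from a simulated series
#'
#' Reads the maximum total plasma concentration over the final dosing
#' interval (taken as steady state for the default 7-day once-daily
#' schedule) and scales it by the fraction unbound.
#'
#' @param series a `pbpk_timeseries`.
#' @param fu fraction unbound; defaults to the simulation's `fu_plasma`.
#' @return list with `cmax_total_nM`, `cmax_fu_nM` and `tmax_h`.
#' @export
cmax_metrics <- function(series, fu = series$params$fu_plasma) {
  stopifnot(inherits(series, "pbpk_timeseries"))
  check_fraction(fu, "fu")
  sch <- series$schedule
  t_last <- (sch$n_doses - 1) * sch$interval_h
  t_end <- max(series$times)
  if (t_end - t_last < sch$interval_h - 1e-9) {
    if (sch$n_doses > 1 || t_end < sch$interval_h - 1e-9) {
      stop_ngra("series does not cover a full dosing interval after the last dose",
                class = "ngra_validation_error")
    }
  }
  win <- series$times >= t_last
  cmax <- max(series$plasma_nM[win])
  tmax <- series$times[win][which.max(series$plasma_nM[win])]
  list(cmax_total_nM = cmax, cmax_fu_nM = fu * cmax, tmax_h = tmax)
}

# draw the per-individual multiplier matrix for a variability spec
draw_multipliers <- function(variability) {
  nms <- sort(names(variability$cv))
  n <- variability$n_individuals
  set.seed(variability$seed)
  m <- matrix(1, nrow = n, ncol = length(nms), dimnames = list(NULL, nms))
  for (nm in nms) {
    cv <- variability$cv[[nm]]
    if (cv > 0) {
      sigma <- sqrt(log(1 + cv^2))
      m[, nm] <- exp(stats::rnorm(n, 0, sigma))  # median-preserving
    }
  }
  m
}

perturb_params <- function(params, mult) {
  p <- params
  g <- function(nm) if (nm %in% names(mult)) mult[[nm]] else 1
  p$hepatic_clint_L_h_kg <- p$hepatic_clint_L_h_kg * g("hepatic_clint")
  p$fu_plasma <- min(1, p$fu_plasma * g("fu_plasma"))
  if (is.finite(p$ka_oral_per_h)) p$ka_oral_per_h <- p$ka_oral_per_h * g("ka_oral")
  p$k_perm_skin_per_h <- p$k_perm_skin_per_h * g("k_perm_skin")
  p$k_met_skin_per_h <- p$k_met_skin_per_h * g("k_met_skin")
  p$f_abs_oral <- min(1, p$f_abs_oral * g("f_abs_oral"))
  p$f_abs_dermal <- min(1, p$f_abs_dermal * g("f_abs_dermal"))
  p$plasma_volume_L_kg <- p$plasma_volume_L_kg * g("volume_scalar")
  if (nrow(p$compartments)) {
    p$compartments$volume_L_kg <- p$compartments$volume_L_kg * g("volume_scalar")
    p$compartments$flow_L_h_kg <- p$compartments$flow_L_h_kg * g("flow_scalar")
    p$compartments$kp <- p$compartments$kp * g("kp_scalar")
  }
  p
}

#' Monte Carlo population simulation of steady-state Cmax
#'
#' Simulates `n_individuals` virtual individuals whose parameters are
#' perturbed by median-preserving lognormal multipliers (see
#' [variability_spec()]) and summarizes the per-individual steady-state
#' Cmax as the mean and empirical 5th/95th percentiles. The unbound metrics
#' use each individual's own fraction unbound, so `cmax_fu = fu *
#' cmax_total` holds exactly per individual. Individual simulation failures
#' are excluded and counted; more than 10\% failures aborts.
#'
#' @param params a [pbpk_parameters()] object (typical individual).
#' @param schedule a [dosing_schedule()].
#' @param variability a [variability_spec()].
#' @param dt,dt_fine output grids passed to [simulate_plasma()].
#' @return object of class `plasma_metrics` with fields
#'   `cmax_total_mean/ci5/ci95`, `cmax_fu_mean/ci5/ci95` (nM), the
#'   per-individual vectors and the failure count. Fixed seed gives
#'   bit-identical results.
#' @export
population_simulate <- function(params, schedule, variability,
                                dt = 0.5, dt_fine = 0.05) {
  stopifnot(inherits(variability, "variability_spec"))
  mult <- draw_multipliers(variability)
  n <- variability$n_individuals
  cmax_total <- rep(NA_real_, n)
  fu_i <- rep(NA_real_, n)
  failures <- 0L
  for (i in seq_len(n)) {
    pi <- perturb_params(params, as.list(mult[i, , drop = TRUE]))
    res <- tryCatch({
      s <- simulate_plasma(pi, schedule, dt = dt, dt_fine = dt_fine)
      cmax_metrics(s)$cmax_total_nM
    }, error = function(e) NA_real_)
    if (is.na(res)) failures <- failures + 1L else {
      cmax_total[i] <- res
      fu_i[i] <- pi$fu_plasma
    }
  }
  if (failures > 0.1 * n) {
    stop_ngra(sprintf("%d/%d population simulations failed", failures, n),
              class = "ngra_integration_failure")
  }
  ok <- !is.na(cmax_total)
  ct <- cmax_total[ok]
  cf <- fu_i[ok] * ct
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  structure(list(
    cmax_total_mean = mean(ct),
    cmax_total_ci5 = q(ct, 0.05),
    cmax_total_ci95 = q(ct, 0.95),
    cmax_fu_mean = mean(cf),
    cmax_fu_ci5 = q(cf, 0.05),
    cmax_fu_ci95 = q(cf, 0.95),
    cmax_total_individual = ct,
    cmax_fu_individual = cf,
    n_individuals = n,
    n_failed = failures,
    seed = variability$seed
  ), class = "plasma_metrics")
}

#' @export
print.plasma_metrics <- function(x, ...) {
  cat(sprintf("Cmax,total: mean %.3g nM (CI5-95%% %.3g-%.3g)\n",
              x$cmax_total_mean, x$cmax_total_ci5, x$cmax_total_ci95))
  cat(sprintf("Cmax,fu:    mean %.3g nM (CI5-95%% %.3g-%.3g)  [n = %d, %d failed]\n",
              x$cmax_fu_mean, x$cmax_fu_ci5, x$cmax_fu_ci95,
              x$n_individuals, x$n_failed))
  invisible(x)
}

#' Reverse dosimetry: external dose for a target plasma concentration
#'
#' Inverts the forward model by bisection on the external dose until the
#' chosen steady-state plasma metric matches `target_cmax` to a relative
#' tolerance. Monotonicity of the forward model in dose is asserted by
#' probing before the search; the initial bracket is centred on the
#' dose-proportional guess and expanded up to a factor 1000 each way.
#'
#' @param params a [pbpk_parameters()] object.
#' @param schedule a [dosing_schedule()] whose `dose` field is ignored.
#' @param target_cmax target plasma concentration, nM (> 0).
#' @param metric `"total"` or `"fu"` (unbound).
#' @param statistic `"deterministic"` (typical individual) or `"mean"`,
#'   `"ci5"`, `"ci95"` of a population simulation (requires `variability`;
#'   the same seed is reused at every bisection step so the objective is
#'   smooth in dose).
#' @param variability a [variability_spec()] when a population statistic is
#'   requested.
#' @param tol relative tolerance on the matched concentration.
#' @param dt,dt_fine output grids passed to [simulate_plasma()].
#' @return external dose in route-native units (mg/kg per administration
#'   for oral; ug/cm^2 for dermal), with attribute `achieved_nM`.
#' @export
reverse_dosimetry <- function(params, schedule, target_cmax,
                              metric = c("total", "fu"),
                              statistic = c("deterministic", "mean", "ci5", "ci95"),
                              variability = NULL, tol = 1e-3,
                              dt = 0.5, dt_fine = 0.05) {
  metric <- match.arg(metric)
  statistic <- match.arg(statistic)
  check_number(target_cmax, "target_cmax", positive = TRUE)
  if (statistic != "deterministic" && is.null(variability)) {
    stop_ngra("population statistic requested without a variability spec",
              class = "ngra_validation_error")
  }
  f <- function(dose) {
    sch <- schedule
    sch$dose <- dose
    if (statistic == "deterministic") {
      m <- cmax_metrics(simulate_plasma(params, sch, dt = dt, dt_fine = dt_fine))
      if (metric == "total") m$cmax_total_nM else m$cmax_fu_nM
    } else {
      pm <- population_simulate(params, sch, variability, dt = dt, dt_fine = dt_fine)
      pm[[paste0("cmax_", if (metric == "total") "total" else "fu", "_",
                 statistic)]]
    }
  }
  d0 <- 1
  f0 <- f(d0)
  if (!is.finite(f0) || f0 <= 0) {
    stop_ngra("forward model gives no exposure at the probe dose",
              class = "ngra_reverse_dosimetry_error")
  }
  # monotonicity probe
  if (f(2 * d0) <= f0) {
    stop_ngra("forward model is not increasing in dose",
              class = "ngra_reverse_dosimetry_error")
  }
  guess <- d0 * target_cmax / f0
  lo <- guess / 2; hi <- guess * 2
  flo <- f(lo); fhi <- f(hi)
  expand <- 0
  while (flo > target_cmax && expand < 4) {
    lo <- lo / 10; flo <- f(lo); expand <- expand + 1
  }
  expand <- 0
  while (fhi < target_cmax && expand < 4) {
    hi <- hi * 10; fhi <- f(hi); expand <- expand + 1
  }
  if (flo > target_cmax || fhi < target_cmax) {
    stop_ngra("target concentration unreachable within the dose bracket",
              class = "ngra_reverse_dosimetry_error")
  }
  dose <- NA_real_
  for (it in seq_len(200)) {
    mid <- sqrt(lo * hi)
    fm <- f(mid)
    if (abs(fm - target_cmax) / target_cmax < tol) {
      dose <- mid
      break
    }
    if (fm < target_cmax) lo <- mid else hi <- mid
  }
  if (is.na(dose)) {
    stop_ngra("reverse dosimetry did not converge",
              class = "ngra_reverse_dosimetry_error")
  }
  attr(dose, "achieved_nM") <- f(dose)
  dose
}

#' Fold effect of cutaneous first-pass metabolism on parent Cmax
#'
#' Ratio of the steady-state parent Cmax without skin metabolism
#' (`k_met_skin = 0`) to the Cmax with the configured rate; at least 1, and
#' strictly increasing in the configured metabolism rate.
#'
#' @param params a [pbpk_parameters()] object.
#' @param schedule a dermal [dosing_schedule()].
#' @return fold ratio (>= 1).
#' @export
skin_firstpass_effect <- function(params, schedule) {
  stopifnot(inherits(params, "pbpk_parameters"),
            inherits(schedule, "dosing_schedule"))
  if (schedule$route != "dermal") {
    stop_ngra("skin first-pass effect is defined for the dermal route only",
              class = "ngra_route_error")
  }
  p0 <- params
  p0$k_met_skin_per_h <- 0
  c_with <- cmax_metrics(simulate_plasma(params, schedule))$cmax_total_nM
  c_without <- cmax_metrics(simulate_plasma(p0, schedule))$cmax_total_nM
  c_without / c_with
}
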