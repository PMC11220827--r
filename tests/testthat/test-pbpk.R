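# PBPK engine: analytic limits, conservation properties, population
# variability and reverse dosimetry.

test_that("the one-compartment limit matches the closed-form decay pointwise", {
  p <- one_comp_params(V = 5, k = 0.2)
  sch <- dosing_schedule("oral", dose = 1, n_doses = 1, duration_days = 1)
  s <- simulate_plasma(p, sch, dt = 0.1, dt_fine = 0.1)
  D <- 1 * 1e6 / 100  # nmol for 1 mg/kg at MW 100, BW 1 kg
  idx <- s$times > 0  # the t = 0 row precedes the bolus event
  analytic <- (D / 5) * exp(-0.2 * s$times[idx])
  expect_lt(max(abs(s$plasma_nM[idx] - analytic) / analytic), 1e-3)
  # Cmax after a single dose is D/V (read on a grid fine enough for k*dt ~ 1e-3)
  s_fine <- simulate_plasma(p, sch, dt = 0.1, dt_fine = 0.005)
  expect_equal(cmax_metrics(s_fine)$cmax_total_nM, D / 5, tolerance = 0.002)
})

test_that("zero dose gives a flat zero series and exact mass balance", {
  s <- simulate_plasma(full_params(), dosing_schedule("oral", dose = 0))
  expect_true(all(s$plasma_nM == 0))
  expect_equal(mass_balance_error(s), 0)
})

test_that("mass balance closes within solver tolerance for both routes", {
  oral <- simulate_plasma(full_params(), dosing_schedule("oral", dose = 0.3))
  expect_lt(mass_balance_error(oral), 1e-6)
  dermal <- simulate_plasma(full_params("human"),
                            dosing_schedule("dermal", dose = 0.5, area_cm2 = 15670))
  expect_lt(mass_balance_error(dermal), 1e-6)
  # unabsorbed and skin-metabolized mass are tracked explicitly
  expect_gt(max(dermal$unabsorbed), 0)
  expect_gt(max(dermal$skin_metabolized), 0)
})

test_that("Cmax is linear in dose for the first-order model", {
  p <- full_params()
  c1 <- cmax_metrics(simulate_plasma(p, dosing_schedule("oral", dose = 0.3)))
  c2 <- cmax_metrics(simulate_plasma(p, dosing_schedule("oral", dose = 0.6)))
  expect_equal(c2$cmax_total_nM / c1$cmax_total_nM, 2, tolerance = 1e-6)
})

test_that("cmax metrics read the final dosing interval and scale by fu", {
  p <- full_params(fu = 0.0504202)
  s <- simulate_plasma(p, dosing_schedule("oral", dose = 0.3))
  m <- cmax_metrics(s)
  expect_equal(m$cmax_fu_nM, 0.0504202 * m$cmax_total_nM)
  expect_gte(m$tmax_h, 144)
  expect_equal(cmax_metrics(s, fu = 1)$cmax_fu_nM, m$cmax_total_nM)
  # a series not covering a full interval after the last dose errors
  short <- simulate_plasma(p, dosing_schedule("oral", dose = 0.3, n_doses = 2,
                                              duration_days = 1.2))
  expect_error(cmax_metrics(short), class = "ngra_validation_error")
})

test_that("parameter validation rejects non-physical inputs", {
  expect_error(pbpk_parameters(body_weight = -1, compartments = data.frame(),
                               plasma_volume_L_kg = 1, fu_plasma = 0.5,
                               hepatic_clint_L_h_kg = 1),
               class = "ngra_validation_error")
  expect_error(one_comp_params(fu = 1.5), class = "ngra_validation_error")
  comp <- default_compartments("rat")
  comp$volume_L_kg[2] <- 0
  expect_error(pbpk_parameters(0.25, comp, 0.03, 0.5, 1),
               class = "ngra_validation_error")
  # gut without liver has no portal target
  expect_error(pbpk_parameters(0.25, default_compartments("rat")[-2, ],
                               0.03, 0.5, 1), class = "ngra_validation_error")
})

test_that("population metrics are bit-identical for a fixed seed", {
  p <- full_params()
  sch <- dosing_schedule("oral", dose = 0.3)
  vs <- variability_spec(cv = list(hepatic_clint = 0.5, fu_plasma = 0.2),
                         n_individuals = 25, seed = 42)
  a <- population_simulate(p, sch, vs)
  b <- population_simulate(p, sch, vs)
  expect_identical(a$cmax_total_individual, b$cmax_total_individual)
  expect_identical(a$cmax_total_ci95, b$cmax_total_ci95)
  # per-individual unbound metric is fu_i * total_i exactly
  expect_equal(a$cmax_fu_individual / a$cmax_total_individual <= 1, rep(TRUE, 25))
})

test_that("degenerate variability collapses the population spread", {
  p <- full_params()
  sch <- dosing_schedule("oral", dose = 0.3)
  zero <- population_simulate(p, sch, variability_spec(cv = list(),
                                                       n_individuals = 5, seed = 1))
  expect_equal(zero$cmax_total_ci5, zero$cmax_total_mean)
  expect_equal(zero$cmax_total_ci95, zero$cmax_total_mean)
  one <- population_simulate(p, sch,
                             variability_spec(cv = list(hepatic_clint = 0.5),
                                              n_individuals = 1, seed = 3))
  expect_equal(one$cmax_total_ci5, one$cmax_total_mean)
  expect_equal(one$cmax_total_ci95, one$cmax_total_mean)
})

test_that("population CI ratio matches a brute-force resampling oracle", {
  # CV 0.5 lognormal on clearance; oracle: dense interpolation of the
  # dose-response of Cmax to the clearance multiplier, resampled at n = 1e5
  p <- full_params()
  sch <- dosing_schedule("oral", dose = 0.3)
  cv <- 0.5
  sigma <- sqrt(log(1 + cv^2))
  lm_grid <- seq(-3.8 * sigma, 3.8 * sigma, length.out = 21)
  cmax_grid <- vapply(lm_grid, function(lm) {
    pi <- p
    pi$hepatic_clint_L_h_kg <- p$hepatic_clint_L_h_kg * exp(lm)
    cmax_metrics(simulate_plasma(pi, sch))$cmax_total_nM
  }, numeric(1))
  f <- splinefun(lm_grid, log(cmax_grid), method = "hyman")
  set.seed(99)
  oracle_cmax <- exp(f(rnorm(1e5, 0, sigma)))
  oracle_ratio <- unname(quantile(oracle_cmax, 0.95) / quantile(oracle_cmax, 0.05))

  vs <- variability_spec(cv = list(hepatic_clint = cv), n_individuals = 1000,
                         seed = 7)
  pm <- population_simulate(p, sch, vs)
  expect_equal(pm$cmax_total_ci95 / pm$cmax_total_ci5, oracle_ratio,
               tolerance = 0.1)
})

test_that("reverse dosimetry inverts the forward model over three dose decades", {
  p <- full_params()
  for (d in c(0.01, 1, 100)) {
    sch <- dosing_schedule("oral", dose = d)
    target <- cmax_metrics(simulate_plasma(p, sch))$cmax_total_nM
    est <- reverse_dosimetry(p, sch, target)
    expect_equal(as.numeric(est), d, tolerance = 0.01)
  }
})

test_that("reverse dosimetry solves the one-compartment closed form", {
  p <- one_comp_params(V = 5, k = 0.2)
  sch <- dosing_schedule("oral", dose = 1, n_doses = 1, duration_days = 1)
  est <- reverse_dosimetry(p, sch, target_cmax = 10, dt_fine = 0.005)
  # Cmax = D/V with D = dose * 1e6 / MW nmol: dose = 10 nM * 5 L * 100 / 1e6
  expect_equal(as.numeric(est), 10 * 5 * 100 / 1e6, tolerance = 0.01)
})

test_that("skin first-pass fold is 1 without metabolism and increases with it", {
  sch <- dosing_schedule("dermal", dose = 0.5, area_cm2 = 15670)
  p0 <- full_params("human", k_met = 0)
  expect_equal(skin_firstpass_effect(p0, sch), 1, tolerance = 1e-8)
  folds <- vapply(c(0.05, 0.1, 0.2, 0.4), function(km) {
    skin_firstpass_effect(full_params("human", k_met = km), sch)
  }, numeric(1))
  expect_true(all(diff(folds) > 0))
  expect_true(all(folds >= 1))
  expect_error(skin_firstpass_effect(p0, dosing_schedule("oral", dose = 1)),
               class = "ngra_route_error")
})

test_that("tidy export is long-format with plasma concentrations attached", {
  s <- simulate_plasma(full_params(), dosing_schedule("oral", dose = 0.3,
                                                      n_doses = 2,
                                                      duration_days = 2))
  df <- as.data.frame(s)
  expect_true(all(c("time_h", "compartment", "amount_nmol", "plasma_nM") %in%
                    names(df)))
  expect_true("liver" %in% df$compartment)
  pl <- df[df$compartment == "plasma", ]
  expect_equal(pl$plasma_nM, s$plasma_nM)
})
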