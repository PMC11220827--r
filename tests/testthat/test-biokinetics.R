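# In vitro biokinetics metrics.

test_that("trapezoidal AUC matches an independent summation oracle", {
  expect_equal(trapezoid_auc(c(0, 24), c(2, 2)), 48)
  expect_equal(trapezoid_auc(c(0, 24), c(0, 2)), 24)
  set.seed(9)
  for (i in 1:10) {
    t <- sort(runif(5, 0, 24)); c <- runif(5, 0, 10)
    oracle <- 0
    for (j in 1:4) oracle <- oracle + (t[j + 1] - t[j]) * (c[j] + c[j + 1]) / 2
    expect_equal(trapezoid_auc(t, c), oracle)
  }
  expect_error(trapezoid_auc(1, 2), class = "ngra_validation_error")
  expect_error(trapezoid_auc(c(1, 1), c(2, 2)), class = "ngra_validation_error")
})

test_that("AUC is additive over adjacent intervals and ignores collinear points", {
  t <- c(0, 4, 10, 24); c <- c(1, 3, 2, 0)
  expect_equal(trapezoid_auc(t, c),
               trapezoid_auc(t[1:2], c[1:2]) + trapezoid_auc(t[2:4], c[2:4]))
  # inserting a collinear midpoint leaves the AUC unchanged
  expect_equal(trapezoid_auc(c(0, 2, 4), c(1, 2, 3)), trapezoid_auc(c(0, 4), c(1, 3)))
})

test_that("nominal fold is symmetric with the 1.3-fold acceptance rule", {
  r <- nominal_fold(1.26, 1.3)
  expect_equal(round(r$fold, 2), 1.03)
  expect_true(r$within)
  expect_equal(nominal_fold(2, 2)$fold, 1)
  expect_false(nominal_fold(2, 1)$within)
  expect_equal(nominal_fold(2, 1)$fold, nominal_fold(1, 2)$fold)
  expect_error(nominal_fold(0, 1), class = "ngra_validation_error")
})

test_that("intracellular concentration converts amounts through total cell volume", {
  expect_equal(intracellular_concentration(2, 1e6, 2), 1)  # 2 nmol / 2 uL = 1 mM
  expect_equal(intracellular_concentration(2, 1e6, 4),
               intracellular_concentration(2, 1e6, 2) / 2)
  expect_error(intracellular_concentration(2, 0, 2), class = "ngra_validation_error")
})

test_that("no-cell stability check uses both timepoints", {
  ok <- stability_check(list(conc_0h = 1.33, conc_24h = 1.26), nominal = 1.3)
  expect_true(ok$stable)
  half <- stability_check(list(conc_0h = 1.3, conc_24h = 0.65), nominal = 1.3)
  expect_false(half$stable)
  expect_equal(half$fold_0h, 1)
  expect_error(stability_check(list(conc_0h = 1.3), 1.3),
               class = "ngra_validation_error")
})

test_that("tidy biokinetics tables yield per-cell-line metrics", {
  bk <- generate_biokinetics(synthetic_spec(seed = 4))
  m <- biokinetics_metrics(bk$measurements)
  expect_equal(nrow(m), 1)
  expect_true(m$within_nominal)
  # concentrative uptake: intracellular (mM) exceeds nominal (uM) >1000-fold
  expect_gt(m$intracellular_mM * 1000 / m$nominal_uM, 1000)
  expect_gt(m$auc_medium_uM_h, 0)
})

test_that("lysate measurements are accepted as amounts or as concentrations", {
  bk <- generate_biokinetics(synthetic_spec(seed = 6))
  m_amount <- biokinetics_metrics(bk$measurements)
  conc <- bk$measurements
  lys <- conc$compartment == "lysate"
  conc$value[lys] <- intracellular_concentration(
    conc$value[lys], conc$n_cells[1], conc$cell_volume_pL[1])
  conc$unit[lys] <- "mM"
  m_conc <- biokinetics_metrics(conc)
  expect_equal(m_conc$intracellular_mM, m_amount$intracellular_mM)
})
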