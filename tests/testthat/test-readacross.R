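# Analogue-suitability evidence: physicochemical comparison, profiler
# concordance and potency ratios.

test_that("physicochemical comparison applies per-property modes and tolerances", {
  pr <- fixture_physchem()
  v <- compare_physchem(pr$target, pr$source)
  expect_true(v$similar[v$property == "log_pow"])          # |3.3 - 3.04| <= 1
  mw <- v[v$property == "molecular_weight", ]
  expect_true(mw$similar)                                   # 270.24/254.23 = 1.063
  expect_equal(max(mw$target_value, mw$source_value) /
                 min(mw$target_value, mw$source_value), 270.24 / 254.23)
  # identical profiles are similar throughout
  self <- compare_physchem(pr$source, pr$source)
  expect_true(all(self$similar))
})

test_that("physicochemical verdicts are symmetric under target/source swap", {
  pr <- fixture_physchem()
  a <- compare_physchem(pr$target, pr$source)
  b <- compare_physchem(pr$source, pr$target)
  expect_equal(a$similar, b$similar)
  # missing mandatory property errors
  incomplete <- physchem_profile("x", molecular_weight = 250,
                                 water_solubility = 0.1)
  expect_error(compare_physchem(incomplete, pr$source),
               class = "ngra_validation_error")
})

test_that("categorical concordance counts matched profiler calls", {
  calls <- case_study_fixtures()$profiler_calls
  cc <- categorical_concordance(calls)
  expect_equal(cc$n_concordant, 4L)
  expect_equal(cc$fraction_concordant, 1)
  calls$target_call[2] <- "weak binder"
  cc2 <- categorical_concordance(calls)
  expect_equal(cc2$n_concordant, 3L)
  expect_false(cc2$calls$concordant[2])
  expect_error(categorical_concordance(calls[0, ]), class = "ngra_validation_error")
  calls$source_call[1] <- NA
  expect_error(categorical_concordance(calls), class = "ngra_validation_error")
})

test_that("potency ratios match endpoints by assay, measure and S9", {
  tab <- potency_ratio_table(fixture_panel("daidzein"), fixture_panel("genistein"))
  r <- tab$ratios
  calux_minus <- r[r$assay_id == "calux_eralpha" & r$s9 == "minus", ]
  expect_equal(calux_minus$ratio, 110 / 6.5)
  erb <- r[r$assay_id == "pharmacology_erbeta", ]
  expect_equal(erb$ratio, 3.2 / 0.52)
  # chemical against itself gives unit ratios
  self <- potency_ratio_table(fixture_panel("genistein"), fixture_panel("genistein"))
  expect_true(all(self$ratios$ratio == 1))
  expect_equal(nrow(self$unmatched), 0)
})

test_that("dossier conclusion requires mandatory similarity and full concordance", {
  pr <- fixture_physchem()
  v <- compare_physchem(pr$target, pr$source)
  cc <- categorical_concordance(case_study_fixtures()$profiler_calls)
  d <- readacross_dossier("daidzein", "genistein", v, cc)
  expect_equal(d$conclusion, "supported")
  expect_true(length(d$narrative_log) >= nrow(v) + 2)
  # a discordant profiler call blocks the conclusion
  calls <- case_study_fixtures()$profiler_calls
  calls$target_call[1] <- "different"
  d2 <- readacross_dossier("daidzein", "genistein", v,
                           categorical_concordance(calls))
  expect_equal(d2$conclusion, "not_supported")
})
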