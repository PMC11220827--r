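# Tiered workflow orchestration.

fast_config <- function(...) {
  cfg <- ngra_case_config(n_individuals = 20, n_individuals_reverse = 10,
                          seed = 7, reverse_statistic = "deterministic", ...)
  cfg
}

test_that("the full case-study workflow derives the safety-factor chain and BER table", {
  rep <- run_ngra(fast_config())
  expect_s3_class(rep, "ngra_report")
  expect_null(rep$aborted_at)
  # every step 1-10 is populated
  expect_true(all(!vapply(rep$steps, is.null, logical(1))))
  expect_equal(display_conc(rep$pod$loec_nM), 100)
  expect_equal(display_conc(rep$pod$noec_nM), 33)
  expect_equal(display_conc(rep$safe_internal_nM), 10)
  # BER table reproduces the fixture roundings
  expect_equal(rep$ber_table$ber_display,
               c(1.7, 3.0, 1.0, 33, 56, 20, 8.5, 14.7, 5.1, 167, 250, 100))
  expect_true(all(rep$ber_table$interpretation == "acceptable_margin"))
  expect_match(rep$conclusion, "daidzein")
  # consistency check lands near the in vivo PoD (regression-calibrated)
  expect_equal(rep$steps$step9$consistency$external_noael_mg_kg, 4.1,
               tolerance = 0.02)
})

test_that("reports are deterministic given the config seeds", {
  r1 <- run_ngra(fast_config())
  r2 <- run_ngra(fast_config())
  expect_identical(report_to_json(r1), report_to_json(r2))
})

test_that("discordant categorical alerts abort the workflow at tier 0", {
  cfg <- fast_config()
  cfg$profiler_calls$target_call[1] <- "different call"
  rep <- run_ngra(cfg)
  expect_equal(rep$aborted_at, "tier0")
  expect_null(rep$conclusion)
  expect_match(paste(rep$decision_log, collapse = " "), "not supported")
  md <- report_to_markdown(rep)
  expect_match(paste(md, collapse = "\n"), "Aborted")
})

test_that("consistency check inverts the rat model without extra factors", {
  cfg <- read_pbpk_config(pbpk_config_path("daidzein-rat-oral"))
  cc <- consistency_check(33, cfg, in_vivo_noael_mg_kg = 5)
  expect_equal(cc$external_noael_mg_kg, 4.1, tolerance = 0.02)
  expect_equal(cc$fold_vs_in_vivo, 5 / cc$external_noael_mg_kg)
  # an estimate equal to the in vivo NOAEL gives fold 1
  cc2 <- consistency_check(33, cfg, in_vivo_noael_mg_kg = cc$external_noael_mg_kg)
  expect_equal(cc2$fold_vs_in_vivo, 1)
})

test_that("in vitro / in vivo concordance fold matches the printed comparison", {
  cf <- invitro_invivo_concordance(24.1, 5.2 / 3)
  expect_equal(cf$fold_rounded, 14)
  expect_equal(cf$fold, 24.1 / (5.2 / 3))
})

test_that("report serializations carry the headline numbers", {
  rep <- run_ngra(fast_config())
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(js$safe_internal_nM, rep$safe_internal_nM)
  md <- report_to_markdown(rep)
  expect_match(paste(md, collapse = "\n"), "Safe internal concentration")
  tmp <- tempfile(fileext = ".json")
  report_to_json(rep, tmp)
  expect_true(file.exists(tmp))
})

test_that("synthetic pairs flow through the workflow PoD chain consistently", {
  pair <- generate_chemical_pair(synthetic_spec(seed = 31, potency_ratio = 1,
                                                assay_noise_cv = 0))
  tgt <- derive_pod(select_pod(pair$target))
  src <- derive_pod(select_pod(pair$source))
  expect_equal(tgt$safe_internal_nM, src$safe_internal_nM)
})
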