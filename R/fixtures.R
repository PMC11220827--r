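# Packaged case-study fixtures: transcriptions of the isoflavone
# (daidzein/genistein) read-across data tables, checksummed on load.

FIXTURE_FILES <- c(
  physchem            = "physchem.csv",
  profiler_calls      = "profiler_calls.csv",
  pharmacology_screen = "pharmacology_screen.csv",
  er_binding          = "er_binding.csv",
  pathway_bmd         = "pathway_bmd.csv",
  eats_loec           = "eats_loec.csv",
  assay_summary       = "assay_summary.csv",
  daidzein_panel      = "daidzein_panel.csv",
  genistein_panel     = "genistein_panel.csv",
  ber_exposure        = "ber_exposure.csv"
)

fixture_dir <- function() system.file("extdata", "tables", package = "ngra")

#' Load the packaged case-study tables
#'
#' Returns the versioned fixture tables of the daidzein/genistein case study
#' (physicochemical properties, in silico profiler calls, pharmacology
#' screen, ER binding parameters, pathway-median BMDs, EATS LOECs, the
#' cross-assay summary, ingest-ready assay panels in nM, and the BER
#' exposure inputs). File integrity is verified against a packaged MD5
#' manifest; units follow the original tables, with concentrations in the
#' assay panels pre-converted to nM (a `value_nM` column).
#'
#' @param check_md5 verify checksums (default TRUE).
#' @return named list of data frames.
#' @export
case_study_fixtures <- function(check_md5 = TRUE) {
  dir <- fixture_dir()
  if (check_md5) {
    manifest <- utils::read.csv(file.path(dir, "MANIFEST.csv"),
                                stringsAsFactors = FALSE)
    for (i in seq_len(nrow(manifest))) {
      f <- file.path(dir, manifest$file[i])
      got <- unname(tools::md5sum(f))
      if (!identical(got, manifest$md5[i])) {
        stop_ngra("fixture checksum mismatch for ", manifest$file[i],
                  class = "ngra_checksum_error")
      }
    }
  }
  out <- lapply(FIXTURE_FILES, function(f) {
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  })
  names(out) <- names(FIXTURE_FILES)
  out
}

#' Assay panel for a case-study chemical
#'
#' @param chemical `"daidzein"` or `"genistein"`.
#' @return an [assay_panel()].
#' @export
fixture_panel <- function(chemical = c("daidzein", "genistein")) {
  chemical <- match.arg(chemical)
  fx <- case_study_fixtures()
  assay_panel(fx[[paste0(chemical, "_panel")]])
}

#' Physicochemical profiles for the case-study pair
#'
#' @return list with `target` (daidzein) and `source` (genistein)
#'   [physchem_profile()] objects.
#' @export
fixture_physchem <- function() {
  tab <- case_study_fixtures()$physchem
  get <- function(col, prop) {
    v <- tab[[col]][tab$property == prop]
    if (!length(v) || is.na(v)) NULL else as.numeric(v)
  }
  mk <- function(id, col) {
    physchem_profile(id,
      log_pow = get(col, "log_pow"),
      boiling_point = get(col, "boiling_point"),
      melting_point = get(col, "melting_point"),
      vapor_pressure = get(col, "vapor_pressure"),
      molecular_weight = get(col, "molecular_weight"),
      water_solubility = get(col, "water_solubility"),
      density = get(col, "density"))
  }
  list(target = mk("daidzein", "daidzein"),
       source = mk("genistein", "genistein"))
}
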