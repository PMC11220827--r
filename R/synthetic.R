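# Synthetic-data generators: chemical pairs with a configurable potency
# ratio, pathway-structured gene-level BMD tables and in vitro
# concentration-time courses, all pure functions of (spec, seed).

#' Specification for synthetic pipeline inputs
#'
#' Defaults mirror the structure of the packaged case study: a source/target
#' pair roughly an order of magnitude apart in potency, multiplicative
#' (lognormal) assay noise, gene-level BMDs clustered into pathways with one
#' designated lowest-median pathway, and steady medium concentrations with
#' strong intracellular accumulation.
#'
#' @param seed integer; fixed seed gives byte-identical output.
#' @param potency_ratio target/source LOEC ratio (> 0, default 15).
#' @param assay_noise_cv lognormal CV of assay noise (default 0.3).
#' @param n_pathways number of pathways (default 20).
#' @param genes_per_pathway genes per pathway (default 10).
#' @param lowest_pathway_median designated lowest pathway-median BMD, uM
#'   (default 0.038).
#' @param frac_pass fraction of genes passing upstream filters in
#'   non-designated pathways (default 0.8).
#' @param pk_cv named list of PK parameter CVs for [variability_spec()].
#' @param n_individuals,timepoints_h,nominal_uM,n_cells,cell_volume_pL
#'   population size and biokinetics time-course shape parameters.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, potency_ratio = 15, assay_noise_cv = 0.3,
                           n_pathways = 20, genes_per_pathway = 10,
                           lowest_pathway_median = 0.038, frac_pass = 0.8,
                           pk_cv = list(volume_scalar = 0.34),
                           n_individuals = 200,
                           timepoints_h = c(0, 2, 4, 8, 24),
                           nominal_uM = 1.3, n_cells = 51000,
                           cell_volume_pL = 2) {
  check_number(potency_ratio, "potency_ratio", positive = TRUE)
  check_number(assay_noise_cv, "assay_noise_cv", nonneg = TRUE)
  check_number(n_pathways, "n_pathways", positive = TRUE)
  check_number(genes_per_pathway, "genes_per_pathway", positive = TRUE)
  check_number(lowest_pathway_median, "lowest_pathway_median", positive = TRUE)
  check_fraction(frac_pass, "frac_pass")
  structure(list(seed = as.integer(seed), potency_ratio = potency_ratio,
                 assay_noise_cv = assay_noise_cv, n_pathways = n_pathways,
                 genes_per_pathway = genes_per_pathway,
                 lowest_pathway_median = lowest_pathway_median,
                 frac_pass = frac_pass, pk_cv = pk_cv,
                 n_individuals = n_individuals, timepoints_h = timepoints_h,
                 nominal_uM = nominal_uM, n_cells = n_cells,
                 cell_volume_pL = cell_volume_pL),
            class = "synthetic_spec")
}

rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sigma))  # median-preserving multiplier
}

# baseline source-chemical panel: endpoint classes and potencies modelled on
# the packaged genistein panel (values in nM). Each assay appears once:
# collapsing a noised +/-S9 pair by minimum would bias the recovered potency
# ratio downward (a property of min-selection, not of the pipeline), so the
# pair-collapse rule is exercised on the fixture panels instead.
synthetic_base_panel <- function() {
  data.frame(
    assay_id = c("cell_stress_mmp", "calux_eralpha", "htpo_inhibition",
                 "ttr_binding", "steroidogenesis_androgen",
                 "pharmacology_eralpha", "pharmacology_erbeta"),
    endpoint_class = c("cell_stress", "functional_transactivation",
                       "enzyme_inhibition", "enzyme_inhibition",
                       "steroidogenesis", "receptor_binding",
                       "receptor_binding"),
    measure = "LOEC",
    base_nM = c(11600, 5.2, 19000, 210, 3200, 44, 0.52),
    s9 = c("n/a", "plus", "n/a", "n/a", "n/a", "n/a", "n/a"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic source/target chemical pair
#'
#' Draws a source assay panel around the baseline potencies with lognormal
#' noise and a target panel whose LOECs are `potency_ratio` times the source
#' LOECs times independent lognormal noise, together with near-identical
#' physicochemical profiles.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `source` and `target` [assay_panel()]s, the matching
#'   [physchem_profile()]s and the realized per-assay ratio table.
#' @export
generate_chemical_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  base <- synthetic_base_panel()
  n <- nrow(base)
  src_val <- base$base_nM * rlnorm_cv(n, spec$assay_noise_cv)
  tgt_val <- spec$potency_ratio * src_val * rlnorm_cv(n, spec$assay_noise_cv)
  mk <- function(id, val) {
    assay_panel(data.frame(chemical_id = id, assay_id = base$assay_id,
                           endpoint_class = base$endpoint_class,
                           measure = base$measure, value_nM = val,
                           sd_nM = NA_real_, s9 = base$s9, direction = "n/a",
                           stringsAsFactors = FALSE))
  }
  source_panel <- mk("synthetic_source", src_val)
  target_panel <- mk("synthetic_target", tgt_val)
  profiles <- list(
    source = physchem_profile("synthetic_source", log_pow = 3.0,
                              molecular_weight = 270, water_solubility = 0.12),
    target = physchem_profile("synthetic_target", log_pow = 3.3,
                              molecular_weight = 254, water_solubility = 0.053)
  )
  list(source = source_panel, target = target_panel, profiles = profiles,
       ratios = data.frame(assay_id = base$assay_id, s9 = base$s9,
                           ratio = tgt_val / src_val, stringsAsFactors = FALSE))
}

#' Generate a pathway-structured gene-level BMD table
#'
#' Produces `n_pathways * genes_per_pathway` gene BMDs with one designated
#' pathway (`PW01`) whose passing-gene median equals
#' `lowest_pathway_median` (exactly, by construction) and all other pathway
#' medians strictly higher. All genes in the designated pathway pass the
#' upstream filters; elsewhere genes pass independently with probability
#' `frac_pass`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `gene_bmds` (gene_id, bmd_uM, passes_filters) and
#'   `pathway_map` (gene_id, pathway_id).
#' @export
generate_gene_bmds <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  npw <- spec$n_pathways
  gpp <- spec$genes_per_pathway
  if (npw < 1 || gpp < 1) {
    stop_ngra("need at least one pathway and one gene per pathway",
              class = "ngra_validation_error")
  }
  set.seed(spec$seed + 1L)
  pw_ids <- sprintf("PW%02d", seq_len(npw))
  # non-designated pathway medians at least 2-fold above the designated one
  other_medians <- spec$lowest_pathway_median *
    stats::runif(npw - 1, min = 2, max = 1000)
  medians <- c(spec$lowest_pathway_median, other_medians)
  rows <- lapply(seq_len(npw), function(i) {
    bmd <- medians[i] * rlnorm_cv(gpp, 0.5)
    pass <- if (i == 1) rep(TRUE, gpp)
            else stats::runif(gpp) < spec$frac_pass
    if (i == 1) {
      # rescale so the passing median is exact
      bmd <- bmd * medians[i] / stats::median(bmd)
    }
    data.frame(gene_id = sprintf("G_%s_%03d", pw_ids[i], seq_len(gpp)),
               bmd_uM = bmd, passes_filters = pass, pathway_id = pw_ids[i],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # guard: other pathways' PASSING medians must stay above the designated one
  summaries <- pathway_median_bmd(tab[c("gene_id", "bmd_uM", "passes_filters")],
                                  tab[c("gene_id", "pathway_id")], min_genes = 1)
  others <- summaries[summaries$pathway_id != "PW01", , drop = FALSE]
  if (nrow(others) && min(others$median_bmd_uM) <= spec$lowest_pathway_median) {
    stop_ngra("infeasible synthetic constraints: a non-designated pathway ",
              "median fell at or below the designated lowest median",
              class = "ngra_validation_error")
  }
  list(gene_bmds = tab[c("gene_id", "bmd_uM", "passes_filters")],
       pathway_map = tab[c("gene_id", "pathway_id")])
}

#' Generate a synthetic in vitro biokinetics time course
#'
#' Medium concentrations stay near nominal with mild first-order loss and
#' measurement noise; lysate-associated amounts accumulate toward a plateau
#' chosen so that the intracellular concentration exceeds nominal more than
#' a thousandfold (concentrative uptake), plus stable no-cell controls.
#'
#' @param spec a [synthetic_spec()].
#' @param chemical_id,cell_line labels for the output table.
#' @return list with `measurements` (tidy data frame for
#'   [biokinetics_metrics()]) and `no_cell_control`.
#' @export
generate_biokinetics <- function(spec, chemical_id = "synthetic_target",
                                 cell_line = "HepG2") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  tp <- spec$timepoints_h
  noise <- function(n) rlnorm_cv(n, 0.05)
  medium <- spec$nominal_uM * exp(-0.005 * tp) * noise(length(tp))
  # plateau amount giving ~1500x nominal intracellularly
  target_mM <- spec$nominal_uM * 1.5  # uM * 1500 = mM numerically
  plateau_nmol <- target_mM * 1e-3 * spec$n_cells * spec$cell_volume_pL * 1e-12 * 1e9
  lysate <- plateau_nmol * (1 - exp(-0.5 * tp)) * noise(length(tp))
  meas <- rbind(
    data.frame(chemical_id = chemical_id, cell_line = cell_line,
               compartment = "medium", time_h = tp, value = medium,
               unit = "uM", nominal_uM = spec$nominal_uM,
               n_cells = spec$n_cells, cell_volume_pL = spec$cell_volume_pL,
               stringsAsFactors = FALSE),
    data.frame(chemical_id = chemical_id, cell_line = cell_line,
               compartment = "lysate", time_h = tp, value = lysate,
               unit = "nmol", nominal_uM = spec$nominal_uM,
               n_cells = spec$n_cells, cell_volume_pL = spec$cell_volume_pL,
               stringsAsFactors = FALSE)
  )
  ctrl <- list(conc_0h = spec$nominal_uM * noise(1),
               conc_24h = spec$nominal_uM * noise(1))
  list(measurements = meas, no_cell_control = ctrl)
}
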