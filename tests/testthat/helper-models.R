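# Shared model factories for the test suite.

# one-compartment limit: plasma only, clearance from plasma
one_comp_params <- function(V = 5, k = 0.2, fu = 1, ka = Inf, mw = 100) {
  pbpk_parameters(body_weight = 1, compartments = data.frame(),
                  plasma_volume_L_kg = V, fu_plasma = fu,
                  hepatic_clint_L_h_kg = k * V / fu, ka_oral_per_h = ka,
                  molecular_weight = mw)
}

# small full-body test configuration (not a calibrated fixture)
full_params <- function(species = "rat", fu = 0.05, clint = 20, ka = 0.5,
                        f_abs_oral = 0.3, f_abs_dermal = 0.25,
                        k_perm = 0.05, k_met = 0.1, mw = 254.23) {
  pbpk_parameters(
    body_weight = if (species == "rat") 0.25 else 60,
    compartments = default_compartments(species),
    plasma_volume_L_kg = if (species == "rat") 0.0312 else 0.0435,
    fu_plasma = fu, hepatic_clint_L_h_kg = clint, ka_oral_per_h = ka,
    f_abs_oral = f_abs_oral, f_abs_dermal = f_abs_dermal,
    k_perm_skin_per_h = k_perm, k_met_skin_per_h = k_met,
    molecular_weight = mw)
}

tiny_panel <- function(chem = "chemA", loec = 100) {
  assay_panel(data.frame(
    chemical_id = chem, assay_id = "transactivation_1",
    endpoint_class = "functional_transactivation", measure = "LOEC",
    value_nM = loec, stringsAsFactors = FALSE))
}
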