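# In vitro biokinetics: exposure metrics from measured medium and lysate
# concentrations in cell-based assays.

#' Trapezoidal area under a concentration-time curve
#'
#' @param timepoints hours, strictly increasing, length >= 2.
#' @param concentrations concentrations (uM) at `timepoints`, >= 0.
#' @return AUC in uM.h over `[first, last]` timepoint.
#' @export
trapezoid_auc <- function(timepoints, concentrations) {
  if (length(timepoints) < 2) {
    stop_ngra("AUC needs at least two timepoints", class = "ngra_validation_error")
  }
  if (length(concentrations) != length(timepoints)) {
    stop_ngra("timepoints and concentrations differ in length",
              class = "ngra_validation_error")
  }
  if (any(diff(timepoints) <= 0)) {
    stop_ngra("timepoints must be strictly increasing",
              class = "ngra_validation_error")
  }
  check_number(concentrations, "concentrations", nonneg = TRUE,
               len = length(concentrations))
  sum(diff(timepoints) * (utils::head(concentrations, -1) +
                            utils::tail(concentrations, -1)) / 2)
}

#' Fold difference between measured and nominal concentration
#'
#' Symmetric fold `max(m, n) / min(m, n)`; a measured value is considered
#' consistent with nominal dosing when the fold is at most `threshold`
#' (default 1.3).
#'
#' @param measured_cmax,nominal positive concentrations, uM.
#' @param threshold acceptance fold.
#' @return list with `fold` and logical `within`.
#' @export
nominal_fold <- function(measured_cmax, nominal, threshold = 1.3) {
  check_number(measured_cmax, "measured_cmax", positive = TRUE)
  check_number(nominal, "nominal", positive = TRUE)
  check_number(threshold, "threshold", positive = TRUE)
  fold <- max(measured_cmax, nominal) / min(measured_cmax, nominal)
  list(fold = fold, within = fold <= threshold)
}

#' Intracellular concentration from a lysate amount
#'
#' Divides the chemical amount associated with the cell lysate by the total
#' cell volume (`n_cells * cell_volume`), giving the average (free plus
#' bound) intracellular concentration in mM.
#'
#' @param lysate_amount amount in the lysate, nmol.
#' @param n_cells number of cells in the well.
#' @param cell_volume single-cell volume, pL.
#' @return concentration in mM.
#' @export
intracellular_concentration <- function(lysate_amount, n_cells, cell_volume) {
  check_number(lysate_amount, "lysate_amount", nonneg = TRUE,
               len = length(lysate_amount))
  check_number(n_cells, "n_cells", positive = TRUE)
  check_number(cell_volume, "cell_volume", positive = TRUE)
  # nmol -> mol (1e-9); n_cells * pL -> L (1e-12); mol/L -> mM (1e3)
  (lysate_amount * 1e-9) / (n_cells * cell_volume * 1e-12) * 1e3
}

#' No-cell stability check
#'
#' A chemical is considered stable in the incubation system (no degradation,
#' evaporation or binding to plastic) when its concentration in cell-free
#' control wells at 0 h and 24 h is within `threshold`-fold of nominal.
#'
#' @param no_cell_control list or named vector with `conc_0h` and `conc_24h`
#'   (uM, > 0).
#' @param nominal nominal concentration, uM.
#' @param threshold acceptance fold (default 1.3).
#' @return list with `stable`, `fold_0h`, `fold_24h`.
#' @export
stability_check <- function(no_cell_control, nominal, threshold = 1.3) {
  nc <- as.list(no_cell_control)
  if (is.null(nc$conc_0h) || is.null(nc$conc_24h)) {
    stop_ngra("no-cell control needs conc_0h and conc_24h",
              class = "ngra_validation_error")
  }
  f0 <- nominal_fold(nc$conc_0h, nominal, threshold)
  f24 <- nominal_fold(nc$conc_24h, nominal, threshold)
  list(stable = f0$within && f24$within, fold_0h = f0$fold, fold_24h = f24$fold)
}

#' Biokinetics metrics from a tidy measurement table
#'
#' Convenience wrapper computing, per chemical and cell line, the medium
#' AUC0-24, the medium Cmax and its fold versus nominal, and (when cell
#' counts and volumes are available) the peak intracellular concentration.
#'
#' @param df tidy data frame with columns `chemical_id`, `cell_line`,
#'   `compartment` (`"medium"` or `"lysate"`), `time_h`, `value`, `unit`
#'   plus `nominal_uM`, and optionally `n_cells`, `cell_volume_pL`. Medium
#'   values are uM. Lysate values may arrive as amounts (`unit = "nmol"`,
#'   converted through `n_cells * cell_volume_pL`) or directly as
#'   cell-volume concentrations (`unit = "mM"`).
#' @param threshold nominal-fold acceptance threshold.
#' @return data frame with one row per chemical x cell line.
#' @export
biokinetics_metrics <- function(df, threshold = 1.3) {
  req <- c("chemical_id", "cell_line", "compartment", "time_h", "value",
           "nominal_uM")
  if (!all(req %in% names(df))) {
    stop_ngra("need columns ", paste(req, collapse = ", "),
              class = "ngra_validation_error")
  }
  groups <- split(df, list(df$chemical_id, df$cell_line), drop = TRUE)
  out <- lapply(groups, function(g) {
    med <- g[g$compartment == "medium", , drop = FALSE]
    med <- med[order(med$time_h), , drop = FALSE]
    auc <- if (nrow(med) >= 2) trapezoid_auc(med$time_h, med$value) else NA_real_
    cmax <- if (nrow(med)) max(med$value) else NA_real_
    nf <- if (is.finite(cmax)) nominal_fold(cmax, med$nominal_uM[1], threshold)
          else list(fold = NA_real_, within = NA)
    lys <- g[g$compartment == "lysate", , drop = FALSE]
    ic <- NA_real_
    if (nrow(lys)) {
      if (!is.null(lys$unit) && all(lys$unit == "mM")) {
        ic <- max(lys$value)
      } else if (!is.null(lys$n_cells) && all(is.finite(lys$n_cells))) {
        ic <- max(intracellular_concentration(lys$value, lys$n_cells[1],
                                              lys$cell_volume_pL[1]))
      }
    }
    data.frame(chemical_id = g$chemical_id[1], cell_line = g$cell_line[1],
               nominal_uM = g$nominal_uM[1], auc_medium_uM_h = auc,
               cmax_medium_uM = cmax, fold_vs_nominal = nf$fold,
               within_nominal = nf$within, intracellular_mM = ic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
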