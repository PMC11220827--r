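# Point-of-departure derivation: assay panels, pathway-level BMD aggregation,
# governing-endpoint selection and the safety-factor chain.

ENDPOINT_CLASSES <- c("functional_transactivation", "receptor_binding",
                      "enzyme_inhibition", "cell_stress",
                      "transcriptomic_pathway", "steroidogenesis")

MEASURES <- c("LOEC", "NOEC", "IC50", "Ki", "PC50", "BMD_median")

# measure/endpoint-class combinations accepted in a panel
MEASURE_MATRIX <- list(
  functional_transactivation = c("LOEC", "NOEC", "PC50", "IC50"),
  receptor_binding           = c("LOEC", "NOEC", "IC50", "Ki"),
  enzyme_inhibition          = c("LOEC", "NOEC", "IC50"),
  cell_stress                = c("LOEC", "NOEC"),
  transcriptomic_pathway     = c("BMD_median", "NOEC"),
  steroidogenesis            = c("LOEC", "NOEC")
)

# endpoint classes whose results may govern the PoD, in priority order;
# receptor binding and transcriptomics are supporting evidence only (they
# flag targets but do not define a biological potency)
GOVERNING_CLASSES <- c("functional_transactivation", "enzyme_inhibition",
                       "steroidogenesis", "cell_stress")

#' Construct and validate an in vitro assay panel
#'
#' An assay panel is a data frame with one row per assay result for one or
#' more chemicals. Values are concentrations in nM throughout; tables
#' reported in other units must be converted on ingestion.
#'
#' @param df data frame with columns `chemical_id`, `assay_id`,
#'   `endpoint_class`, `measure`, `value_nM`, and optionally `sd_nM`
#'   (NA when not reported), `s9` (`"plus"`, `"minus"` or `"n/a"`) and
#'   `direction`.
#' @return the validated data frame with class `assay_panel`.
#' @export
assay_panel <- function(df) {
  req <- c("chemical_id", "assay_id", "endpoint_class", "measure", "value_nM")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop_ngra("assay panel missing columns: ", paste(missing_cols, collapse = ", "),
              class = "ngra_validation_error")
  }
  if (!nrow(df)) stop_ngra("assay panel is empty", class = "ngra_validation_error")
  if (!all(df$endpoint_class %in% ENDPOINT_CLASSES)) {
    stop_ngra("unknown endpoint_class", class = "ngra_validation_error")
  }
  if (!all(df$measure %in% MEASURES)) {
    stop_ngra("unknown measure", class = "ngra_validation_error")
  }
  ok <- mapply(function(cls, m) m %in% MEASURE_MATRIX[[cls]],
               df$endpoint_class, df$measure)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop_ngra(sprintf("measure %s not allowed for endpoint class %s",
                      df$measure[bad], df$endpoint_class[bad]),
              class = "ngra_validation_error")
  }
  if (any(!is.finite(df$value_nM)) || any(df$value_nM <= 0)) {
    stop_ngra("assay values must be positive and finite",
              class = "ngra_validation_error")
  }
  if (is.null(df$sd_nM)) df$sd_nM <- NA_real_
  if (is.null(df$s9)) df$s9 <- "n/a"
  if (is.null(df$direction)) df$direction <- "n/a"
  if (!all(df$s9 %in% c("plus", "minus", "n/a"))) {
    stop_ngra("s9 must be 'plus', 'minus' or 'n/a'", class = "ngra_validation_error")
  }
  class(df) <- c("assay_panel", "data.frame")
  df
}

#' Aggregate gene-level benchmark doses into pathway medians
#'
#' Gene-level BMDs (from an upstream transcriptomic dose-response analysis)
#' are grouped into pathways; a pathway is retained when at least
#' `min_genes` of its member genes pass all upstream filters, and its summary
#' BMD is the median over those passing genes only. A stricter gene count
#' (5) gives higher confidence in the biological relevance of the pathway
#' call; a looser one (3) gives a lower, more conservative PoD.
#'
#' @param gene_bmds data frame with columns `gene_id`, `bmd_uM` (> 0) and
#'   logical `passes_filters`.
#' @param pathway_map data frame with columns `gene_id`, `pathway_id`
#'   (a gene may map to several pathways).
#' @param min_genes minimum number of passing genes per pathway (typically 3
#'   or 5).
#' @return data frame with columns `pathway_id`, `n_genes_passing`,
#'   `median_bmd_uM`, ordered by `median_bmd_uM`. Empty input gives an empty
#'   summary, not an error.
#' @export
pathway_median_bmd <- function(gene_bmds, pathway_map, min_genes = 3) {
  check_number(min_genes, "min_genes", positive = TRUE)
  empty <- data.frame(pathway_id = character(), n_genes_passing = integer(),
                      median_bmd_uM = numeric(), stringsAsFactors = FALSE)
  if (is.null(gene_bmds) || !nrow(gene_bmds)) return(empty)
  req <- c("gene_id", "bmd_uM", "passes_filters")
  if (!all(req %in% names(gene_bmds))) {
    stop_ngra("gene_bmds needs columns gene_id, bmd_uM, passes_filters",
              class = "ngra_validation_error")
  }
  if (any(gene_bmds$bmd_uM <= 0)) {
    stop_ngra("gene BMDs must be > 0", class = "ngra_validation_error")
  }
  unmapped <- setdiff(gene_bmds$gene_id, pathway_map$gene_id)
  if (length(unmapped)) {
    stop_ngra("genes without pathway membership: ",
              paste(utils::head(unmapped, 5), collapse = ", "),
              class = "ngra_validation_error")
  }
  passing <- gene_bmds[gene_bmds$passes_filters, , drop = FALSE]
  if (!nrow(passing)) return(empty)
  merged <- merge(passing, pathway_map, by = "gene_id")
  agg <- do.call(rbind, lapply(split(merged, merged$pathway_id), function(g) {
    data.frame(pathway_id = g$pathway_id[1],
               n_genes_passing = nrow(g),
               median_bmd_uM = stats::median(g$bmd_uM),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[agg$n_genes_passing >= min_genes, , drop = FALSE]
  agg <- agg[order(agg$median_bmd_uM, agg$pathway_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Lowest pathway-median BMD
#'
#' Returns the pathway summary with the smallest median BMD; ties are broken
#' by lexicographic pathway id and recorded in a `tie` attribute.
#'
#' @param summaries output of [pathway_median_bmd()], non-empty.
#' @return single-row data frame; attribute `tie` is TRUE when several
#'   pathways share the minimum.
#' @export
lowest_median_bmd <- function(summaries) {
  if (is.null(summaries) || !nrow(summaries)) {
    stop_ngra("no pathway summaries to rank", class = "ngra_validation_error")
  }
  lo <- summaries[summaries$median_bmd_uM == min(summaries$median_bmd_uM), ,
                  drop = FALSE]
  tie <- nrow(lo) > 1
  lo <- lo[order(lo$pathway_id), , drop = FALSE][1, , drop = FALSE]
  rownames(lo) <- NULL
  attr(lo, "tie") <- tie
  lo
}

#' Fold ratio between two benchmark doses
#'
#' Ratio `bmd_a / bmd_b`, rounded half-up to the nearest integer when the
#' rounded value is at least 2 (the convention used when quoting "n-fold
#' lower" potency differences); smaller ratios are returned at full
#' precision.
#'
#' @param bmd_a,bmd_b positive concentrations in the same unit.
#' @return numeric fold ratio.
#' @export
bmd_fold_ratio <- function(bmd_a, bmd_b) {
  check_number(bmd_a, "bmd_a", positive = TRUE)
  check_number(bmd_b, "bmd_b", positive = TRUE)
  r <- bmd_a / bmd_b
  rr <- round_half_up(r)
  if (rr >= 2) rr else r
}

#' Select the governing point of departure from an assay panel
#'
#' The governing PoD is based on biological functional activity, not binding
#' affinity: receptor-binding and transcriptomic-pathway results are treated
#' as supporting evidence that flags targets but never governs. Among
#' functional endpoint classes (transactivation, enzyme inhibition,
#' steroidogenesis, cell stress) the lowest LOEC wins. When the same assay
#' was run with and without a metabolic S9 fraction, the pair is collapsed
#' to its minimum and the log records whether the two values overlap within
#' their reported standard deviations. Every exclusion is appended to the
#' selection log.
#'
#' @param panel an [assay_panel()] (rows for a single chemical).
#' @param governing_classes endpoint classes allowed to govern the PoD, in
#'   priority order (used only to break exact value ties); defaults to the
#'   functional classes.
#' @return single-row data frame of the selected result, with attribute
#'   `selection_log` (character vector).
#' @export
select_pod <- function(panel, governing_classes = GOVERNING_CLASSES) {
  stopifnot(all(governing_classes %in% ENDPOINT_CLASSES))
  panel <- assay_panel(as.data.frame(panel))
  if (length(unique(panel$chemical_id)) != 1) {
    stop_ngra("select_pod expects a panel for a single chemical",
              class = "ngra_validation_error")
  }
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  drop <- !(panel$endpoint_class %in% governing_classes)
  for (i in which(drop)) {
    note("excluded %s (%s %s = %.4g nM): endpoint class '%s' is supporting evidence only",
         panel$assay_id[i], panel$measure[i], panel$s9[i], panel$value_nM[i],
         panel$endpoint_class[i])
  }
  cand <- panel[!drop, , drop = FALSE]

  non_loec <- cand$measure != "LOEC"
  for (i in which(non_loec)) {
    note("excluded %s: measure %s is not a LOEC", cand$assay_id[i], cand$measure[i])
  }
  cand <- cand[!non_loec, , drop = FALSE]
  if (!nrow(cand)) {
    stop_ngra("no functional LOEC in panel; broaden the assay panel before deriving a PoD",
              class = "ngra_no_functional_result")
  }

  # collapse +/- S9 pairs per assay to the minimum
  cand <- cand[order(cand$assay_id, cand$value_nM, cand$s9), , drop = FALSE]
  collapsed <- do.call(rbind, lapply(split(cand, cand$assay_id), function(g) {
    if (nrow(g) > 1 && all(c("plus", "minus") %in% g$s9)) {
      g <- g[order(g$value_nM), , drop = FALSE]
      keep <- g[1, , drop = FALSE]
      other <- g[2, , drop = FALSE]
      sds <- c(keep$sd_nM, other$sd_nM)
      overlap <- if (all(is.finite(sds))) {
        abs(other$value_nM - keep$value_nM) <= sum(sds)
      } else NA
      note("S9 pair for %s: kept %s S9 (%.4g nM) over %s S9 (%.4g nM); difference within reported SDs: %s",
           keep$assay_id, keep$s9, keep$value_nM, other$s9, other$value_nM,
           ifelse(is.na(overlap), "unknown (SD not reported)", overlap))
      keep
    } else g
  }))

  collapsed$.rank <- match(collapsed$endpoint_class, governing_classes)
  collapsed <- collapsed[order(collapsed$value_nM, collapsed$.rank,
                               collapsed$assay_id), , drop = FALSE]
  sel <- collapsed[1, , drop = FALSE]
  for (i in seq_len(nrow(collapsed))[-1]) {
    note("excluded %s (LOEC %.4g nM): higher than selected %s (%.4g nM)",
         collapsed$assay_id[i], collapsed$value_nM[i], sel$assay_id, sel$value_nM)
  }
  sel$.rank <- NULL
  rownames(sel) <- NULL
  attr(sel, "selection_log") <- log
  sel
}

#' Apply the safety-factor chain to a selected LOEC
#'
#' Converts a LOEC into a NOEC estimate by a factor of `sf_loec_to_noec`
#' (default 3) and then into a safe internal concentration by an additional
#' factor `sf_intraindividual` (default 3.3) accounting for intra-individual
#' variability. All values are carried at full precision; use
#' [display_conc()] for reporting.
#'
#' @param selected single-row assay result (e.g. from [select_pod()]) with
#'   `measure == "LOEC"`, or a bare positive LOEC in nM.
#' @param sf_loec_to_noec,sf_intraindividual positive safety factors; set
#'   `sf_intraindividual = 1` to stop at the NOEC.
#' @return object of class `pod_derivation`: a list with `chemical_id`,
#'   `selected_assay`, `loec_nM`, `noec_nM`, `safe_internal_nM`, the factors
#'   and the selection log.
#' @export
derive_pod <- function(selected, sf_loec_to_noec = 3, sf_intraindividual = 3.3) {
  check_number(sf_loec_to_noec, "sf_loec_to_noec", positive = TRUE)
  check_number(sf_intraindividual, "sf_intraindividual", positive = TRUE)
  if (is.numeric(selected)) {
    check_number(selected, "selected", positive = TRUE)
    selected <- data.frame(chemical_id = NA_character_, assay_id = NA_character_,
                           endpoint_class = NA_character_, measure = "LOEC",
                           value_nM = selected, stringsAsFactors = FALSE)
  }
  if (selected$measure != "LOEC") {
    stop_ngra("derive_pod expects a LOEC", class = "ngra_validation_error")
  }
  loec <- selected$value_nM
  check_number(loec, "loec", positive = TRUE)
  noec <- loec / sf_loec_to_noec
  safe <- noec / sf_intraindividual
  structure(list(
    chemical_id = selected$chemical_id,
    selected_assay = selected,
    loec_nM = loec,
    noec_nM = noec,
    safe_internal_nM = safe,
    sf_loec_to_noec = sf_loec_to_noec,
    sf_intraindividual = sf_intraindividual,
    selection_log = attr(selected, "selection_log") %||% character()
  ), class = "pod_derivation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pod_derivation <- function(x, ...) {
  cat("Point-of-departure derivation\n")
  cat(sprintf("  chemical:        %s\n", x$chemical_id))
  cat(sprintf("  selected assay:  %s (%s)\n", x$selected_assay$assay_id,
              x$selected_assay$endpoint_class))
  cat(sprintf("  LOEC:            %g nM\n", display_conc(x$loec_nM)))
  cat(sprintf("  NOEC (LOEC/%g):  %g nM\n", x$sf_loec_to_noec,
              display_conc(x$noec_nM)))
  cat(sprintf("  safe internal (NOEC/%g): %g nM\n", x$sf_intraindividual,
              display_conc(x$safe_internal_nM)))
  invisible(x)
}

#' Serialize a PoD derivation to JSON
#'
#' @param pod a `pod_derivation` object.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
pod_to_json <- function(pod, path = NULL) {
  stopifnot(inherits(pod, "pod_derivation"))
  x <- unclass(pod)
  x$selected_assay <- as.list(x$selected_assay)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
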