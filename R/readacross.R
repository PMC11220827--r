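# Read-across analogue suitability: physicochemical similarity, categorical
# in silico concordance and cross-assay potency ratios.

#' Construct a physicochemical profile
#'
#' @param chemical_id chemical label.
#' @param ... named numeric properties (e.g. `log_pow`, `molecular_weight`,
#'   `water_solubility`, `melting_point`, `boiling_point`, `vapor_pressure`,
#'   `density`). `pka` may be a numeric vector (polyprotic chemicals).
#' @return object of class `physchem_profile` (named list).
#' @export
physchem_profile <- function(chemical_id, ...) {
  props <- list(...)
  if (!is.null(props$molecular_weight)) {
    check_number(props$molecular_weight, "molecular_weight", positive = TRUE)
  }
  if (!is.null(props$water_solubility)) {
    check_number(props$water_solubility, "water_solubility", nonneg = TRUE)
  }
  structure(c(list(chemical_id = chemical_id), props),
            class = "physchem_profile")
}

#' Default similarity tolerances for physicochemical comparison
#'
#' Per-property comparison mode and tolerance. `abs_diff` passes when
#' `|target - source| <= tolerance`; `fold` passes when
#' `max(x, y) / min(x, y) <= tolerance`. These thresholds are pragmatic
#' conventions of this package, not regulatory criteria.
#'
#' @return named list of `list(mode=, tolerance=, mandatory=)` entries.
#' @export
default_physchem_tolerances <- function() {
  list(
    log_pow          = list(mode = "abs_diff", tolerance = 1.0,  mandatory = TRUE),
    molecular_weight = list(mode = "fold",     tolerance = 1.25, mandatory = TRUE),
    water_solubility = list(mode = "fold",     tolerance = 10,   mandatory = TRUE),
    melting_point    = list(mode = "abs_diff", tolerance = 50,   mandatory = FALSE),
    boiling_point    = list(mode = "abs_diff", tolerance = 100,  mandatory = FALSE),
    vapor_pressure   = list(mode = "fold",     tolerance = 100,  mandatory = FALSE),
    density          = list(mode = "abs_diff", tolerance = 0.3,  mandatory = FALSE)
  )
}

#' Compare physicochemical profiles of target and source chemicals
#'
#' One similarity verdict per configured property. Missing mandatory
#' properties raise an error; missing optional ones are skipped.
#'
#' @param target,source [physchem_profile()] objects.
#' @param tolerances per-property configuration, see
#'   [default_physchem_tolerances()].
#' @return data frame with columns `property`, `target_value`,
#'   `source_value`, `comparison_mode`, `tolerance`, `mandatory`, `similar`.
#' @export
compare_physchem <- function(target, source,
                             tolerances = default_physchem_tolerances()) {
  stopifnot(inherits(target, "physchem_profile"),
            inherits(source, "physchem_profile"))
  rows <- lapply(names(tolerances), function(p) {
    tv <- target[[p]]; sv <- source[[p]]
    cfg <- tolerances[[p]]
    if (is.null(tv) || is.null(sv)) {
      if (isTRUE(cfg$mandatory)) {
        stop_ngra("mandatory physicochemical property missing: ", p,
                  class = "ngra_validation_error")
      }
      return(NULL)
    }
    similar <- switch(cfg$mode,
      abs_diff = abs(tv - sv) <= cfg$tolerance,
      fold = {
        check_number(tv, p, positive = TRUE)
        check_number(sv, p, positive = TRUE)
        max(tv, sv) / min(tv, sv) <= cfg$tolerance
      },
      stop_ngra("unknown comparison mode: ", cfg$mode)
    )
    data.frame(property = p, target_value = tv, source_value = sv,
               comparison_mode = cfg$mode, tolerance = cfg$tolerance,
               mandatory = isTRUE(cfg$mandatory), similar = similar,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance of categorical in silico profiler calls
#'
#' @param alert_calls data frame with columns `profiler`, `target_call`,
#'   `source_call` (one row per profiler; every profiler must have both
#'   calls).
#' @return list with per-profiler data frame (`concordant` column), the
#'   overall fraction concordant, and counts.
#' @export
categorical_concordance <- function(alert_calls) {
  if (is.null(alert_calls) || !nrow(alert_calls)) {
    stop_ngra("no profiler calls supplied", class = "ngra_validation_error")
  }
  req <- c("profiler", "target_call", "source_call")
  if (!all(req %in% names(alert_calls))) {
    stop_ngra("alert calls need columns profiler, target_call, source_call",
              class = "ngra_validation_error")
  }
  if (any(is.na(alert_calls$target_call)) || any(is.na(alert_calls$source_call))) {
    stop_ngra("unpaired profiler call", class = "ngra_validation_error")
  }
  ac <- alert_calls
  ac$concordant <- trimws(ac$target_call) == trimws(ac$source_call)
  list(calls = ac,
       n_concordant = sum(ac$concordant),
       n_profilers = nrow(ac),
       fraction_concordant = mean(ac$concordant))
}

#' Cross-assay potency ratio table
#'
#' For every endpoint shared between the two panels (matched by `assay_id`
#' and `measure`), the ratio of target to source value; endpoints present in
#' only one panel are listed separately rather than raising an error.
#'
#' @param target_panel,source_panel [assay_panel()] objects.
#' @return list with `ratios` (data frame: assay_id, measure, target_nM,
#'   source_nM, ratio) and `unmatched` (data frame of one-sided endpoints).
#' @export
potency_ratio_table <- function(target_panel, source_panel) {
  t <- as.data.frame(assay_panel(as.data.frame(target_panel)))
  s <- as.data.frame(assay_panel(as.data.frame(source_panel)))
  key <- function(d) paste(d$assay_id, d$measure, d$s9, sep = "||")
  t$key <- key(t); s$key <- key(s)
  shared <- intersect(t$key, s$key)
  m <- merge(t[t$key %in% shared, c("key", "assay_id", "measure", "s9", "value_nM")],
             s[s$key %in% shared, c("key", "value_nM")],
             by = "key", suffixes = c("_target", "_source"))
  ratios <- data.frame(assay_id = m$assay_id, measure = m$measure, s9 = m$s9,
                       target_nM = m$value_nM_target,
                       source_nM = m$value_nM_source,
                       ratio = m$value_nM_target / m$value_nM_source,
                       stringsAsFactors = FALSE)
  ratios <- ratios[order(ratios$assay_id, ratios$s9), , drop = FALSE]
  rownames(ratios) <- NULL
  un_t <- t[!t$key %in% shared, c("assay_id", "measure", "s9", "value_nM")]
  un_s <- s[!s$key %in% shared, c("assay_id", "measure", "s9", "value_nM")]
  unmatched <- rbind(cbind(panel = rep("target", nrow(un_t)), un_t),
                     cbind(panel = rep("source", nrow(un_s)), un_s))
  rownames(unmatched) <- NULL
  list(ratios = ratios, unmatched = unmatched)
}

#' Assemble a read-across dossier
#'
#' Combines physicochemical verdicts, categorical concordance and potency
#' ratios into a weight-of-evidence dossier. The conclusion is `"supported"`
#' only when every mandatory physicochemical verdict is similar and all
#' profiler calls are concordant; every rule firing is appended to the
#' narrative log. A simple fraction-similar summary is included as
#' descriptive plumbing; it is not a validated analogue-quality score.
#'
#' @param target_id,source_id chemical labels.
#' @param physchem_verdicts output of [compare_physchem()].
#' @param concordance output of [categorical_concordance()].
#' @param potency output of [potency_ratio_table()] (optional).
#' @return object of class `readacross_dossier`.
#' @export
readacross_dossier <- function(target_id, source_id, physchem_verdicts,
                               concordance, potency = NULL) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  mand <- physchem_verdicts[physchem_verdicts$mandatory, , drop = FALSE]
  phys_ok <- all(mand$similar)
  for (i in seq_len(nrow(physchem_verdicts))) {
    v <- physchem_verdicts[i, ]
    note("physchem %s: target %.4g vs source %.4g (%s, tol %.4g) -> %s%s",
         v$property, v$target_value, v$source_value, v$comparison_mode,
         v$tolerance, ifelse(v$similar, "similar", "NOT similar"),
         ifelse(v$mandatory, " [mandatory]", ""))
  }
  alert_ok <- concordance$fraction_concordant == 1
  note("profiler concordance: %d/%d concordant", concordance$n_concordant,
       concordance$n_profilers)
  conclusion <- if (phys_ok && alert_ok) "supported" else "not_supported"
  note("conclusion: %s", conclusion)
  structure(list(
    target_id = target_id,
    source_id = source_id,
    physchem_verdicts = physchem_verdicts,
    concordance = concordance,
    potency = potency,
    fraction_similar = mean(physchem_verdicts$similar),
    conclusion = conclusion,
    narrative_log = log
  ), class = "readacross_dossier")
}

#' @export
print.readacross_dossier <- function(x, ...) {
  cat(sprintf("Read-across dossier: %s (target) <- %s (source)\n",
              x$target_id, x$source_id))
  cat(sprintf("  physchem verdicts similar: %d/%d\n",
              sum(x$physchem_verdicts$similar), nrow(x$physchem_verdicts)))
  cat(sprintf("  profiler concordance:      %d/%d\n",
              x$concordance$n_concordant, x$concordance$n_profilers))
  cat(sprintf("  conclusion: %s\n", x$conclusion))
  invisible(x)
}
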