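#' Meta-models of receptive-field fit quality
#'
#' Fits a declared family of mixed-effects models on per-channel
#' Fisher-Z predicted-recorded correlations and ranks them by AIC.
#'
#' The `"main"` family (five members) asks whether model order
#' (linear vs. quadratic) and the availability of phone-label
#' information explain fit quality beyond weight shuffling:
#' z ~ shuffle (baseline); + model; + label; + model + label;
#' + model + label + model:label. The `"language"` family (six
#' members) starts from z ~ model + label + model:label and adds the
#' excerpt-language factor and its interactions up to the full
#' three-way model * label * lang crossing. All models include the
#' response band (when more than one is present) and subject and
#' channel random intercepts.
#'
#' @param records data frame with columns z, model, label, shuffle,
#'   band, subject, channel (and lang for the language family).
#' @param family "main" or "language".
#' @return list with `fits` (named `lme_fit` list) and `ranking` (a
#'   `model_ranking`).
#' @export
fit_quality_meta <- function(records, family = c("main", "language")) {
  family <- match.arg(family)
  need <- c("z", "model", "label", "band", "subject", "channel",
            if (family == "main") "shuffle" else "lang")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  for (f in intersect(c("model", "label", "shuffle", "band", "lang"),
                      names(records))) {
    if (length(unique(records[[f]])) < 2 && f != "band") {
      stop("factor '", f, "' needs both levels in the records")
    }
  }
  band <- if (length(unique(records$band)) > 1) "band" else NULL
  if (family == "main") {
    formulas <- list(
      baseline = c("shuffle", band),
      add_model = c("shuffle", "model", band),
      add_label = c("shuffle", "label", band),
      add_both = c("shuffle", "model", "label", band),
      interaction = c("shuffle", "model", "label", "model:label", band))
  } else {
    base <- c("model", "label", "model:label", band)
    formulas <- list(
      baseline = base,
      lang = c(base, "lang"),
      lang_x_model = c(base, "lang", "lang:model"),
      lang_x_label = c(base, "lang", "lang:label"),
      lang_x_both = c(base, "lang", "lang:model", "lang:label"),
      full = c("model * label * lang", band))
  }
  fit_meta_family(records, formulas)
}
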