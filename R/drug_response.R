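# Drug-response layer: control-% normalization of plate/assay readouts,
# averaging across assays, combination-index synergy calls, four-band
# sensitivity classification and cross-model concordance.

#' Normalize treated readouts to control percent
#'
#' `mean_percent = 100 * mean(treated) / mean(control)`; the per-replicate
#' percentages (each treated replicate against the control mean) supply the
#' standard deviation. The control normalized against itself is exactly 100.
#'
#' @param treated,control Numeric vectors of raw replicate signals from the
#'   same model and assay.
#' @return One-row tibble: `mean_percent`, `sd_percent`, `n`.
#' @export
#' @examples
#' normalize_to_control(c(0.55, 0.6, 0.65), c(0.8, 0.8, 0.8)) # 75%
normalize_to_control <- function(treated, control) {
  if (length(treated) < 1L || length(control) < 1L) {
    stop_input("need at least one replicate in both treated and control.")
  }
  if (any(treated < 0) || any(control < 0)) {
    stop_input("raw signals must be nonnegative.")
  }
  cm <- mean(control)
  if (cm <= 0) stop_input("control mean is zero; control percent is undefined.")
  pct <- 100 * treated / cm
  tibble::tibble(
    mean_percent = mean(pct),
    sd_percent = if (length(pct) > 1L) stats::sd(pct) else NA_real_,
    n = length(treated)
  )
}

#' Viability table from a raw assay readout table
#'
#' Normalizes every model x arm x assay cell of a long readout table against
#' the control arm of the same model and assay.
#'
#' @param assays Tibble with columns `model, arm, assay, replicate, signal`.
#' @param control_arm Name of the control arm (default `"Co"`).
#' @return Tibble: `model, arm, assay, mean_percent, sd_percent, n`.
#' @export
viability_table <- function(assays, control_arm = "Co") {
  if (nrow(assays) == 0) stop_input("empty assay table.")
  assays |>
    dplyr::group_by(.data$model, .data$assay) |>
    dplyr::group_modify(function(d, key) {
      ctrl <- d$signal[d$arm == control_arm]
      if (length(ctrl) == 0) {
        stop_input("no `%s` arm for model/assay %s/%s.", control_arm,
                   key$model, key$assay)
      }
      d |>
        dplyr::group_by(.data$arm) |>
        dplyr::group_modify(~ normalize_to_control(.x$signal, ctrl)) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()
}

#' Average viability across assays
#'
#' Unweighted arithmetic mean of the per-assay control percentages for each
#' model x arm, mirroring the convention of averaging the results of the
#' different proliferation tests. The `assay` field becomes `"average"`;
#' `sd_percent` is the spread of the per-assay means (NA for a single assay).
#'
#' @param viability Tibble from [viability_table()].
#' @return Tibble: `model, arm, assay = "average", mean_percent, sd_percent, n`.
#' @export
average_across_assays <- function(viability) {
  if (nrow(viability) == 0) stop_input("empty viability table.")
  viability |>
    dplyr::group_by(.data$model, .data$arm) |>
    dplyr::summarise(
      assay = "average",
      sd_percent = if (dplyr::n() > 1L) stats::sd(.data$mean_percent) else NA_real_,
      n = dplyr::n(),
      mean_percent = mean(.data$mean_percent),
      .groups = "drop"
    ) |>
    dplyr::select("model", "arm", "assay", "mean_percent", "sd_percent", "n")
}

#' Effect fraction of a treatment
#'
#' Fractional inhibition `E = 1 - viability/100`, clipped to \[0, 1\]:
#' viability above control (growth stimulation) maps to zero effect rather
#' than a negative one.
#'
#' @param mean_percent Viability in control % (vectorized).
#' @return Effect fraction(s) in \[0, 1\].
#' @export
effect_fraction <- function(mean_percent) {
  if (any(mean_percent < 0, na.rm = TRUE)) stop_input("viability percent must be >= 0.")
  pmin(1, pmax(0, 1 - mean_percent / 100))
}

#' Combination index and interaction class
#'
#' `CI = (Ea + Eb) / Eab`, where `Ea` and `Eb` are the effect fractions of
#' the single monotreatments and `Eab` the effect of their combination.
#' Interactions: synergistic (`CI < 1`), additive (`CI = 1`), no additional
#' effect (`CI > 1`). Because exact equality has measure zero on noisy data,
#' additivity is declared inside a tolerance band `|CI - 1| <= tolerance`.
#'
#' @param ea,eb,eab Effect fractions in \[0, 1\] (vectorized); `eab` must be
#'   strictly positive.
#' @param tolerance Half-width of the additivity band around 1 (default 0.05).
#' @return Tibble: `ea, eb, eab, ci, interaction` with `interaction` a
#'   factor in `synergistic < additive < no_additional_effect`.
#' @export
#' @examples
#' combination_index(0.2, 0.3, 0.6) # ci ~ 0.83, synergistic
combination_index <- function(ea, eb, eab, tolerance = 0.05) {
  if (any(c(ea, eb) < 0) || any(c(ea, eb) > 1)) {
    stop_input("monotreatment effects must lie in [0, 1].")
  }
  if (any(eab <= 0)) {
    stop_input("combination effect is zero: the combination index is undefined.")
  }
  if (tolerance < 0) stop_input("`tolerance` must be nonnegative.")
  ci <- (ea + eb) / eab
  interaction <- dplyr::case_when(
    ci < 1 - tolerance ~ "synergistic",
    ci > 1 + tolerance ~ "no_additional_effect",
    .default = "additive"
  )
  tibble::tibble(
    ea = ea, eb = eb, eab = eab, ci = ci,
    interaction = factor(interaction,
                         levels = c("synergistic", "additive", "no_additional_effect"))
  )
}

# Sensitivity class boundaries (viability in control %): resistant >= 90,
# minimal sensitivity [80, 90), sensitive [60, 80), highly sensitive < 60.
sensitivity_levels <- c("highly_sensitive", "sensitive", "minimal_sensitivity", "resistant")

#' Classify drug sensitivity from average viability
#'
#' Four-band classification of the altered proliferation: resistant
#' (viability >= 90% of control), minimal sensitivity (80-90%), sensitive
#' (60-80%), highly sensitive (< 60%). Lower viability never yields a less
#' sensitive class.
#'
#' @param mean_percent Viability in control % (vectorized).
#' @return Ordered factor of categories.
#' @export
#' @examples
#' classify_sensitivity(c(95, 85, 70, 45))
classify_sensitivity <- function(mean_percent) {
  if (any(mean_percent < 0, na.rm = TRUE)) stop_input("viability percent must be >= 0.")
  cut(mean_percent,
      breaks = c(-Inf, 60, 80, 90, Inf),
      labels = sensitivity_levels,
      right = FALSE, ordered_result = TRUE)
}

#' Sensitivity calls for every model and arm
#'
#' @param viability Averaged viability table (see [average_across_assays()]).
#' @return The input with a `category` column appended.
#' @export
sensitivity_calls <- function(viability) {
  dplyr::mutate(viability, category = classify_sensitivity(.data$mean_percent))
}

#' Concordance of sensitivity calls between two model systems
#'
#' Fraction of treatment arms on which two model systems receive the same
#' sensitivity category, plus a per-arm match table. Both call sets must
#' cover exactly the same arms.
#'
#' @param calls_a,calls_b Tibbles with columns `arm`, `category` and
#'   `mean_percent` (from [sensitivity_calls()]).
#' @return List: `agreement` (fraction in \[0, 1\]), `mean_abs_diff`
#'   (mean absolute viability difference, the ranking tie-breaker), and
#'   `table` (per-arm categories and match flag).
#' @export
model_concordance <- function(calls_a, calls_b) {
  if (!setequal(calls_a$arm, calls_b$arm) ||
      anyDuplicated(calls_a$arm) || anyDuplicated(calls_b$arm)) {
    stop_input("the two call sets must cover exactly the same arms, once each.")
  }
  tab <- dplyr::inner_join(
    calls_a[, c("arm", "category", "mean_percent")],
    calls_b[, c("arm", "category", "mean_percent")],
    by = "arm", suffix = c("_a", "_b")
  ) |>
    dplyr::mutate(match = .data$category_a == .data$category_b)
  list(
    agreement = mean(tab$match),
    mean_abs_diff = mean(abs(tab$mean_percent_a - tab$mean_percent_b)),
    table = tab
  )
}

#' Rank model systems by concordance with a reference system
#'
#' Orders candidate model systems by their agreement fraction with the
#' reference (typically the in vivo xenograft); ties are broken by the
#' smaller mean absolute viability difference.
#'
#' @param calls Sensitivity-call table covering several models
#'   (from [sensitivity_calls()]).
#' @param reference Model label to rank the others against.
#' @return Tibble of candidate models sorted from most to least concordant.
#' @export
rank_model_concordance <- function(calls, reference) {
  ref <- calls[calls$model == reference, ]
  if (nrow(ref) == 0) stop_input("reference model `%s` absent from calls.", reference)
  others <- setdiff(unique(calls$model), reference)
  rows <- lapply(others, function(m) {
    cc <- model_concordance(calls[calls$model == m, ], ref)
    tibble::tibble(model = m, agreement = cc$agreement, mean_abs_diff = cc$mean_abs_diff)
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$agreement), .data$mean_abs_diff)
}

#' Combination assessments for every combination arm of every model
#'
#' Splits combination arm names of the form `"a+b"` into their monotherapy
#' components, converts average viabilities to effect fractions, and
#' computes the combination index and interaction class per model.
#'
#' @param viability Averaged viability table (model x arm).
#' @inheritParams combination_index
#' @return Tibble: `model, arm, ea, eb, eab, ci, interaction`.
#' @export
combination_assessments <- function(viability, tolerance = 0.05) {
  combos <- viability[grepl("+", viability$arm, fixed = TRUE), ]
  if (nrow(combos) == 0) return(tibble::tibble())
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    m <- combos$model[i]
    parts <- strsplit(combos$arm[i], "+", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop_input("combination arm `%s` does not name exactly two components.", combos$arm[i])
    }
    mono <- viability[viability$model == m & viability$arm %in% parts, ]
    if (nrow(mono) != 2L) {
      stop_input("model `%s`: monotherapy arms for `%s` are missing.", m, combos$arm[i])
    }
    ef <- effect_fraction(mono$mean_percent)
    dplyr::bind_cols(
      tibble::tibble(model = m, arm = combos$arm[i]),
      combination_index(ef[1L], ef[2L],
                        effect_fraction(combos$mean_percent[i]),
                        tolerance = tolerance)
    )
  })
  dplyr::bind_rows(rows)
}

#' Model x arm sensitivity matrix with synergy flags
#'
#' The compact comparison grid: average viability, sensitivity category and,
#' for combination arms, whether the combination index calls the interaction
#' synergistic.
#'
#' @param viability Averaged viability table (model x arm).
#' @inheritParams combination_index
#' @return Tibble: `model, arm, mean_percent, category, ci, synergistic`.
#' @export
sensitivity_matrix <- function(viability, tolerance = 0.05) {
  calls <- sensitivity_calls(viability)
  combos <- combination_assessments(viability, tolerance = tolerance)
  out <- calls[, c("model", "arm", "mean_percent", "category")]
  if (nrow(combos) > 0) {
    out <- dplyr::left_join(out, combos[, c("model", "arm", "ci", "interaction")],
                            by = c("model", "arm"))
  } else {
    out$ci <- NA_real_
    out$interaction <- NA_character_
  }
  dplyr::mutate(out, synergistic = !is.na(.data$ci) & .data$interaction == "synergistic")
}
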