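# Cohort-level heterogeneity scoring: per-sample scores from observer
# profiles, per-marker pooling with the >40% rule, and cross-model SDI
# comparison tables.

#' Read a cohort of observer intensity profiles from CSV
#'
#' Expects columns `sample_id, marker, subtype, observer, p0, p1, p2, p3`
#' and optionally `n_cells` (fractions as decimals, '.' separator, header
#' row).
#'
#' @param path Path to the CSV file.
#' @return A tibble of observer profiles.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "marker", "subtype", "observer", "p0", "p1", "p2", "p3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_input("cohort file `%s` is missing columns: %s", path, paste(miss, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Score a cohort: consensus profiles, H-score, SDI and heterogeneity call
#'
#' Collapses observer replicates to a consensus profile per sample and
#' marker (element-wise mean of fraction vectors), then computes the
#' H-score, the Shannon Diversity Index, and the per-sample heterogeneity
#' call for each consensus profile.
#'
#' @param cohort Tibble of observer profiles as returned by [read_cohort()]
#'   or [simulate_cohort()].
#' @param min_minor_fraction Per-sample heterogeneity threshold, see
#'   [call_sample_heterogeneity()].
#' @return A tibble with one row per sample x marker: the consensus
#'   fractions `p0..p3`, `h_score`, `sdi` and `heterogeneous`.
#' @export
score_cohort <- function(cohort, min_minor_fraction = 0.10) {
  if (nrow(cohort) == 0) stop_input("empty cohort: nothing to score.")
  cohort |>
    dplyr::group_by(.data$sample_id, .data$marker, .data$subtype) |>
    dplyr::summarise(
      p = list(consensus_profile(cbind(.data$p0, .data$p1, .data$p2, .data$p3))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p0 = vapply(.data$p, `[`, numeric(1), 1L),
      p1 = vapply(.data$p, `[`, numeric(1), 2L),
      p2 = vapply(.data$p, `[`, numeric(1), 3L),
      p3 = vapply(.data$p, `[`, numeric(1), 4L),
      h_score = vapply(.data$p, h_score, numeric(1)),
      sdi = vapply(.data$p, shannon_diversity, numeric(1)),
      heterogeneous = vapply(
        .data$p, call_sample_heterogeneity, logical(1),
        min_minor_fraction = min_minor_fraction
      )
    ) |>
    dplyr::select(-"p")
}

#' Pooled heterogeneity percentage over subtypes
#'
#' Pools heterogeneous/evaluated counts across subtypes (subtypes with zero
#' evaluated samples are dropped, not treated as 0/0) and returns the
#' percentage rounded half away from zero to the nearest integer.
#'
#' @param n_het,n_eval Integer vectors of per-subtype heterogeneous and
#'   evaluated sample counts.
#' @return Pooled percentage on the 0-100 scale (integer-valued).
#' @export
#' @examples
#' pooled_heterogeneity_percent(c(8, 10, 8, 9), c(10, 10, 8, 10)) # 92
pooled_heterogeneity_percent <- function(n_het, n_eval) {
  if (length(n_het) != length(n_eval)) {
    stop_input("`n_het` and `n_eval` must have the same length.")
  }
  if (any(n_het < 0) || any(n_eval < 0) || any(n_het > n_eval)) {
    stop_input("counts must satisfy 0 <= n_het <= n_eval for every subtype.")
  }
  keep <- n_eval > 0
  if (!any(keep)) stop_input("no subtype has any evaluated sample.")
  round_half_away(100 * sum(n_het[keep]) / sum(n_eval[keep]))
}

#' Cohort-level heterogeneity summary for one marker
#'
#' Aggregates per-sample heterogeneity calls into per-subtype
#' heterogeneous/evaluated counts, the pooled percentage, and the
#' cohort-level flag: a marker is heterogeneous when strictly more than 40%
#' of the evaluated samples are heterogeneous.
#'
#' @param calls Tibble with columns `subtype` and `heterogeneous` (one row
#'   per evaluated sample), or a named list mapping subtype to a logical
#'   vector of per-sample calls.
#' @param marker Marker name carried into the output.
#' @param cohort_percent_cutoff Strict lower bound (percent) for the
#'   marker-level flag; default 40.
#' @return One-row tibble: `marker`, nested `per_subtype` counts,
#'   `pooled_percent`, `is_heterogeneous_marker`.
#' @export
summarize_marker <- function(calls, marker = "marker", cohort_percent_cutoff = 40) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- tibble::tibble(
      subtype = rep(names(calls), lengths(calls)),
      heterogeneous = unlist(calls, use.names = FALSE)
    )
  }
  if (nrow(calls) == 0) stop_input("no heterogeneity calls supplied for `%s`.", marker)
  counts <- calls |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(
      n_heterogeneous = sum(.data$heterogeneous),
      n_evaluated = dplyr::n(),
      .groups = "drop"
    )
  pooled <- pooled_heterogeneity_percent(counts$n_heterogeneous, counts$n_evaluated)
  tibble::tibble(
    marker = marker,
    per_subtype = list(counts),
    pooled_percent = pooled,
    is_heterogeneous_marker = pooled > cohort_percent_cutoff
  )
}

#' Cohort heterogeneity table across markers
#'
#' Applies [summarize_marker()] to every marker in a scored cohort and lays
#' the result out like a published heterogeneity survey: one row per marker,
#' per-subtype "k/n" strings, pooled percent and flag.
#'
#' @param scores Scored cohort from [score_cohort()].
#' @inheritParams summarize_marker
#' @return Tibble with one row per marker.
#' @export
marker_heterogeneity_table <- function(scores, cohort_percent_cutoff = 40) {
  if (nrow(scores) == 0) stop_input("empty scored cohort.")
  out <- scores |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(~ summarize_marker(.x, marker = .y$marker,
                                           cohort_percent_cutoff = cohort_percent_cutoff)[, -1]) |>
    dplyr::ungroup()
  wide <- lapply(seq_len(nrow(out)), function(i) {
    cts <- out$per_subtype[[i]]
    stats::setNames(
      as.list(sprintf("%d/%d", cts$n_heterogeneous, cts$n_evaluated)),
      cts$subtype
    )
  })
  dplyr::bind_cols(
    out["marker"],
    dplyr::bind_rows(lapply(wide, tibble::as_tibble)),
    out[c("pooled_percent", "is_heterogeneous_marker")]
  )
}

#' Reference per-subtype heterogeneity counts for the 14-marker breast panel
#'
#' Per-subtype heterogeneous/evaluated staining counts for 14 metabolic
#' markers from a published immunohistochemistry survey of breast cancer
#' (Luminal A/B, HER2+ and triple-negative subtypes, 7-10 cases each),
#' together with the percentage printed alongside them. Shipped as a plain
#' CSV fixture and used to validate the pooling rule.
#'
#' @return Long tibble: `marker`, `subtype`, `n_heterogeneous`,
#'   `n_evaluated`, `published_percent`.
#' @export
reference_marker_counts <- function() {
  path <- system.file("extdata", "breast_marker_heterogeneity_counts.csv",
                      package = "tmshet", mustWork = TRUE)
  wide <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                            check.names = FALSE))
  subtypes <- c("LumA", "LumB", "HER2+", "TNBC")
  long <- lapply(subtypes, function(s) {
    tibble::tibble(
      marker = wide$marker,
      subtype = s,
      n_heterogeneous = wide[[paste0(s, "_het")]],
      n_evaluated = wide[[paste0(s, "_n")]],
      published_percent = wide$published_percent
    )
  })
  dplyr::bind_rows(long)
}

#' Recompute pooled percentages for the reference panel and flag mismatches
#'
#' Recomputes each marker's pooled heterogeneity percentage from the
#' per-subtype counts and compares it with the percentage published next to
#' them. Internally consistent rows match exactly; the remaining rows are
#' flagged as discrepant (`consistent = FALSE`), not forced to agree.
#'
#' @param counts Long counts tibble, defaults to [reference_marker_counts()].
#' @inheritParams summarize_marker
#' @return Tibble: `marker`, `pooled_percent`, `published_percent`,
#'   `consistent`, `is_heterogeneous_marker`.
#' @export
reference_marker_consistency <- function(counts = reference_marker_counts(),
                                         cohort_percent_cutoff = 40) {
  counts |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      pooled_percent = pooled_heterogeneity_percent(.data$n_heterogeneous, .data$n_evaluated),
      published_percent = .data$published_percent[1L],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      consistent = .data$pooled_percent == .data$published_percent,
      is_heterogeneous_marker = .data$pooled_percent > cohort_percent_cutoff
    )
}

#' Mean SDI per marker and model system
#'
#' Tabulates the arithmetic mean Shannon Diversity Index per marker x model
#' cell (the `subtype` column of a scored cohort carries the model label
#' when profiles come from experimental models rather than patient tissue).
#' Cells with no scores are absent from the table, never reported as zero.
#'
#' @param scores Scored cohort from [score_cohort()].
#' @return Tibble: `marker`, `model`, `mean_sdi`, `n`.
#' @export
sdi_model_table <- function(scores) {
  if (nrow(scores) == 0) stop_input("empty scored cohort.")
  scores |>
    dplyr::group_by(marker = .data$marker, model = .data$subtype) |>
    dplyr::summarise(mean_sdi = mean(.data$sdi), n = dplyr::n(), .groups = "drop")
}

#' Per-marker SDI contrast between two model systems
#'
#' @param sdi_table Output of [sdi_model_table()].
#' @param model_a,model_b Model labels to contrast.
#' @return Tibble: `marker`, mean SDI under each model, and the absolute
#'   difference; markers missing from either model are dropped.
#' @export
sdi_model_contrast <- function(sdi_table, model_a, model_b) {
  a <- sdi_table[sdi_table$model == model_a, c("marker", "mean_sdi")]
  b <- sdi_table[sdi_table$model == model_b, c("marker", "mean_sdi")]
  names(a)[2] <- "sdi_a"
  names(b)[2] <- "sdi_b"
  dplyr::inner_join(a, b, by = "marker") |>
    dplyr::mutate(abs_diff = abs(.data$sdi_a - .data$sdi_b))
}
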