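# Reporting layer: one call that ties cohort scoring, drug response and
# xenograft summaries together, writes the report tables as plain CSV, and
# records a manifest with the configuration hash and seed.

#' Pipeline run configuration
#'
#' @param cohort Path to a cohort CSV (`sample_id, marker, subtype,
#'   observer, p0..p3`), or NULL to skip the heterogeneity tables.
#' @param assays Path to an assay CSV (`model, arm, assay, replicate,
#'   signal`), or NULL to skip the sensitivity matrix.
#' @param calipers Path to a caliper CSV (`animal_id, group, day,
#'   shorter_mm, longer_mm[, weight_g]`), or NULL to skip growth tables.
#' @param out_dir Output directory for the report bundle.
#' @param min_minor_fraction Per-sample heterogeneity threshold (0, 0.5].
#' @param cohort_percent_cutoff Cohort-level percentage cutoff (strict),
#'   default 40.
#' @param ci_tolerance Additivity band half-width for the combination index.
#' @param seed Seed recorded in the manifest (the scoring itself is
#'   deterministic; the seed matters when inputs were simulated).
#' @return A `tmshet_run_config` list.
#' @export
run_config <- function(cohort = NULL, assays = NULL, calipers = NULL,
                       out_dir = ".", min_minor_fraction = 0.10,
                       cohort_percent_cutoff = 40, ci_tolerance = 0.05,
                       seed = NULL) {
  if (min_minor_fraction <= 0 || min_minor_fraction > 0.5) {
    stop_input("`min_minor_fraction` must lie in (0, 0.5].")
  }
  if (cohort_percent_cutoff < 0 || cohort_percent_cutoff > 100) {
    stop_input("`cohort_percent_cutoff` must lie in [0, 100].")
  }
  if (ci_tolerance < 0) stop_input("`ci_tolerance` must be nonnegative.")
  structure(
    list(cohort = cohort, assays = assays, calipers = calipers,
         out_dir = out_dir, min_minor_fraction = min_minor_fraction,
         cohort_percent_cutoff = cohort_percent_cutoff,
         ci_tolerance = ci_tolerance, seed = seed),
    class = "tmshet_run_config"
  )
}

write_report_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full scoring pipeline and write the report bundle
#'
#' Reads whichever inputs the configuration names, scores them, and writes:
#' `heterogeneity_table.csv` (marker-level cohort heterogeneity),
#' `sdi_comparison.csv` (mean SDI per marker and model),
#' `sensitivity_matrix.csv` (model x arm viability, class and synergy),
#' `growth_curves.csv` (per-group tumour-volume curves), and
#' `manifest.json` (configuration, its hash, seed, and the files written).
#' Optional inputs that are absent are simply omitted from the report; on
#' failure, partially written outputs are removed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed tables, output paths and the
#'   configuration hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tmshet_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    rlang::abort(sprintf("pipeline failed (%s); partial outputs removed.",
                         conditionMessage(e)), parent = e)
  }
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  result <- list(config_hash = cfg_hash)
  tryCatch({
    if (!is.null(config$cohort)) {
      scores <- score_cohort(read_cohort(config$cohort),
                             min_minor_fraction = config$min_minor_fraction)
      het <- marker_heterogeneity_table(
        scores, cohort_percent_cutoff = config$cohort_percent_cutoff)
      het$config_hash <- cfg_hash
      sdi <- sdi_model_table(scores)
      sdi$config_hash <- cfg_hash
      written <- c(written,
                   write_report_csv(het, config$out_dir, "heterogeneity_table.csv"),
                   write_report_csv(sdi, config$out_dir, "sdi_comparison.csv"))
      result$heterogeneity <- het
      result$sdi <- sdi
    }
    if (!is.null(config$assays)) {
      readouts <- tibble::as_tibble(utils::read.csv(config$assays,
                                                    stringsAsFactors = FALSE))
      viab <- average_across_assays(viability_table(readouts))
      mat <- sensitivity_matrix(viab, tolerance = config$ci_tolerance)
      mat$config_hash <- cfg_hash
      written <- c(written,
                   write_report_csv(mat, config$out_dir, "sensitivity_matrix.csv"))
      result$sensitivity <- mat
      result$annotations <- significance_annotations(readouts)
    }
    if (!is.null(config$calipers)) {
      growth <- growth_summary(read_calipers(config$calipers))
      curves <- growth$curves
      curves$config_hash <- cfg_hash
      written <- c(written,
                   write_report_csv(curves, config$out_dir, "growth_curves.csv"))
      result$growth <- growth
    }
    manifest <- list(
      config = config[setdiff(names(config), "out_dir")],
      config_hash = cfg_hash,
      seed = config$seed,
      outputs = basename(written)
    )
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         null = "null", digits = NA)
    written <- c(written, manifest_path)
    result$outputs <- written
    invisible(result)
  }, error = on_fail)
}

#' Per-arm significance annotations for replicate viability sets
#'
#' Within each model and assay, a one-way ANOVA of signal on treatment arm
#' followed by Tukey's honest-significant-difference comparisons against the
#' control arm; arms with adjusted p <= 0.05 are flagged. Degenerate groups
#' (all replicates identical in every arm) are reported as untestable, with
#' the flag set when arm means differ anyway.
#'
#' @param assays Long readout tibble (`model, arm, assay, replicate,
#'   signal`).
#' @param control_arm Control arm name, default `"Co"`.
#' @param alpha Significance level, default 0.05.
#' @return Tibble: `model, assay, arm, p_adj, significant, test`.
#' @export
significance_annotations <- function(assays, control_arm = "Co", alpha = 0.05) {
  assays |>
    dplyr::group_by(.data$model, .data$assay) |>
    dplyr::group_modify(function(d, key) {
      arms <- setdiff(unique(d$arm), control_arm)
      if (length(arms) == 0 || !control_arm %in% d$arm) {
        return(tibble::tibble(arm = arms, p_adj = NA_real_,
                              significant = NA, test = "untestable"))
      }
      ctrl_mean <- mean(d$signal[d$arm == control_arm])
      resid_var <- sum(tapply(d$signal, d$arm, function(x) sum((x - mean(x))^2)))
      if (resid_var < 1e-12) {
        means <- tapply(d$signal, d$arm, mean)
        return(tibble::tibble(
          arm = arms, p_adj = NA_real_,
          significant = abs(means[arms] - ctrl_mean) > 1e-12,
          test = "degenerate"
        ))
      }
      d$arm_f <- factor(d$arm)
      tk <- stats::TukeyHSD(stats::aov(signal ~ arm_f, data = d))$arm_f
      lab_a <- sprintf("%s-%s", arms, control_arm)
      lab_b <- sprintf("%s-%s", control_arm, arms)
      p <- vapply(seq_along(arms), function(i) {
        hit <- rownames(tk) %in% c(lab_a[i], lab_b[i])
        if (any(hit)) tk[hit, "p adj"][1L] else NA_real_
      }, numeric(1))
      tibble::tibble(arm = arms, p_adj = p,
                     significant = !is.na(p) & p <= alpha,
                     test = "one-way ANOVA + Tukey HSD")
    }) |>
    dplyr::ungroup()
}
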