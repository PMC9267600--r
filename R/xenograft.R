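# Caliper-based xenograft summaries: the tumour-volume formula, per-group
# growth curves, and the endpoint effect fraction that feeds the
# combination-index calculation for in vivo arms.

#' Tumour volume from two caliper diameters
#'
#' Geometric-mean-diameter convention: the two caliper readings are combined
#' into an effective diameter `(2*shorter + longer)/3` (the shorter diameter
#' is counted twice because the depth of a subcutaneous tumour is closer to
#' its width than its length) and the sphere volume of that diameter is
#' returned: `V = (pi/6) * ((2*shorter + longer)/3)^3`. Equal diameters
#' reduce exactly to the sphere formula.
#'
#' @param shorter_mm,longer_mm Caliper diameters in mm (vectorized); both
#'   must be positive. Readings are used as given; see [read_calipers()] for
#'   swap correction on ingest.
#' @return Volume(s) in mm^3.
#' @export
#' @examples
#' tumour_volume(3, 3)  # sphere of diameter 3 ~ 14.14 mm^3
#' tumour_volume(4, 6)  # ~ 53.22 mm^3
tumour_volume <- function(shorter_mm, longer_mm) {
  if (any(shorter_mm <= 0) || any(longer_mm <= 0)) {
    stop_input("caliper diameters must be positive.")
  }
  (pi / 6) * ((2 * shorter_mm + longer_mm) / 3)^3
}

#' Read caliper measurements from CSV
#'
#' Expects columns `animal_id, group, day, shorter_mm, longer_mm` and
#' optionally `weight_g`. Swapped diameter pairs (shorter recorded larger
#' than longer) are corrected on ingest, and the derived `volume_mm3`
#' column is appended.
#'
#' @param path Path to the CSV file.
#' @return Tibble of measurements with `volume_mm3`.
#' @export
read_calipers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day", "shorter_mm", "longer_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_input("caliper file `%s` is missing columns: %s", path, paste(miss, collapse = ", "))
  }
  prepare_calipers(tibble::as_tibble(df))
}

#' Swap-correct diameters and derive volumes
#'
#' @param measurements Tibble with `shorter_mm` and `longer_mm` columns.
#' @return The input with diameters ordered and `volume_mm3` appended.
#' @export
prepare_calipers <- function(measurements) {
  s <- pmin(measurements$shorter_mm, measurements$longer_mm)
  l <- pmax(measurements$shorter_mm, measurements$longer_mm)
  measurements$shorter_mm <- s
  measurements$longer_mm <- l
  measurements$volume_mm3 <- tumour_volume(s, l)
  measurements
}

#' Per-group growth curves and endpoint summaries
#'
#' Day-aligned mean and standard deviation of tumour volume per treatment
#' group, plus the endpoint (final-day) mean volume and, when recorded, the
#' endpoint mean weight. Days missing for a group are simply absent.
#'
#' @param measurements Caliper tibble with `volume_mm3` (see
#'   [prepare_calipers()]).
#' @return List: `curves` (group, day, mean_volume, sd_volume, n) and
#'   `endpoint` (group, day, mean_volume, mean_weight_g, n).
#' @export
growth_summary <- function(measurements) {
  if (nrow(measurements) == 0) stop_input("no caliper measurements supplied.")
  curves <- measurements |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      mean_volume = mean(.data$volume_mm3),
      sd_volume = if (dplyr::n() > 1L) stats::sd(.data$volume_mm3) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  endpoint <- measurements |>
    dplyr::group_by(.data$group) |>
    dplyr::filter(.data$day == max(.data$day)) |>
    dplyr::summarise(
      day = .data$day[1L],
      mean_volume = mean(.data$volume_mm3),
      mean_weight_g = if ("weight_g" %in% names(measurements))
        mean(.data$weight_g) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  list(curves = curves, endpoint = endpoint)
}

#' In vivo effect fraction from endpoint summaries
#'
#' Treatment effect on the final tumour burden,
#' `E = 1 - treated_endpoint / control_endpoint`, clipped to \[0, 1\]. The
#' endpoint basis is the final mean volume by default; the final mean weight
#' is available as an alternative.
#'
#' @param control_summary,treated_summary One-row endpoint tibbles for the
#'   control and treated groups (rows of `growth_summary()$endpoint`).
#' @param basis `"volume"` or `"weight"`.
#' @return Effect fraction in \[0, 1\], ready for [combination_index()].
#' @export
in_vivo_effect <- function(control_summary, treated_summary,
                           basis = c("volume", "weight")) {
  basis <- match.arg(basis)
  col <- if (basis == "volume") "mean_volume" else "mean_weight_g"
  ctrl <- control_summary[[col]]
  trt <- treated_summary[[col]]
  if (length(ctrl) != 1L || length(trt) != 1L || is.na(ctrl) || is.na(trt)) {
    stop_input("endpoint `%s` must be present in both summaries.", basis)
  }
  if (ctrl <= 0) stop_input("control endpoint is zero; the effect fraction is undefined.")
  min(1, max(0, 1 - trt / ctrl))
}
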