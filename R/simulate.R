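# Synthetic-data generators. They emulate the study conditions the scoring
# modules assume — staining-intensity cohorts with marker-specific
# heterogeneity prevalence, 72-h treatment plates with a controllable true
# combination index, and 21-day xenograft diameter time courses — so that
# every pipeline stage can be exercised and its parameter recovery checked
# without any raw measurements.

second_largest <- function(p) sort(p, decreasing = TRUE)[2L]

# Draw one true intensity profile of the requested class. Heterogeneous
# profiles are symmetric Dirichlet(concentration_het) draws conditioned on
# the per-sample heterogeneity rule holding with a safety margin
# (second-largest fraction >= threshold * (1 + margin)); homogeneous
# profiles put concentration_homog on a uniformly chosen dominant bin and
# are conditioned on the rule failing with the same margin (second-largest
# < threshold * (1 - margin)). The margin keeps the generator's ground
# truth recoverable: profiles sitting exactly on the call boundary would
# otherwise be misclassified from finite cell counts at a material rate.
draw_true_profile <- function(heterogeneous, concentration_het, concentration_homog,
                              threshold, margin) {
  hi <- threshold * (1 + margin)
  lo <- threshold * (1 - margin)
  repeat {
    if (heterogeneous) {
      p <- rdirichlet(1L, rep(concentration_het, 4L))[1L, ]
      if (second_largest(p) >= hi) return(p)
    } else {
      alpha <- rep(concentration_het, 4L)
      alpha[sample.int(4L, 1L)] <- concentration_homog
      p <- rdirichlet(1L, alpha)[1L, ]
      if (second_largest(p) < lo) return(p)
    }
  }
}

#' Configuration for the synthetic staining cohort
#'
#' @param markers Named numeric vector of per-marker heterogeneity
#'   prevalences in \[0, 1\]. Defaults to the 14-marker breast panel with
#'   prevalences equal to the pooled percentages recomputed from the
#'   reference counts.
#' @param n_per_subtype Named integer vector of samples per subtype
#'   (default 10 for each of LumA, LumB, HER2+, TNBC).
#' @param concentration_het Per-bin Dirichlet concentration of heterogeneous
#'   profiles (default 1: uniform on the simplex, median SDI ~ 1.1).
#' @param concentration_homog Dominant-bin concentration of homogeneous,
#'   near-degenerate profiles (default 10: mean SDI ~ 0.4).
#' @param n_cells Cells evaluated per sample and observer (default 300);
#'   `Inf` means observers read the true fractions exactly.
#' @param n_observers Independent observers per sample (default 2).
#' @param threshold Per-sample heterogeneity call threshold the cohort is
#'   generated to be scored with (default 0.10).
#' @param margin Truth-separation margin as a fraction of `threshold`
#'   (default 0.25).
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(markers = NULL,
                              n_per_subtype = c(LumA = 10L, LumB = 10L,
                                                `HER2+` = 10L, TNBC = 10L),
                              concentration_het = 1,
                              concentration_homog = 10,
                              n_cells = 300L,
                              n_observers = 2L,
                              threshold = 0.10,
                              margin = 0.25) {
  if (is.null(markers)) {
    ref <- reference_marker_consistency()
    markers <- stats::setNames(ref$pooled_percent / 100, ref$marker)
  }
  if (is.null(names(markers)) || any(markers < 0) || any(markers > 1)) {
    stop_input("`markers` must be a named vector of prevalences in [0, 1].")
  }
  if (concentration_het <= 0 || concentration_homog <= 0) {
    stop_input("Dirichlet concentrations must be positive.")
  }
  if (any(n_per_subtype < 0) || is.null(names(n_per_subtype))) {
    stop_input("`n_per_subtype` must be a named vector of nonnegative counts.")
  }
  structure(
    list(markers = markers, n_per_subtype = n_per_subtype,
         concentration_het = concentration_het,
         concentration_homog = concentration_homog,
         n_cells = n_cells, n_observers = n_observers,
         threshold = threshold, margin = margin),
    class = "cohort_sim_config"
  )
}

#' Simulate a staining-intensity cohort
#'
#' For each marker and sample, the sample is truly heterogeneous with the
#' marker's prevalence; its intensity profile is drawn from the matching
#' Dirichlet family (see [cohort_sim_config()]); and each observer reads the
#' sample by multinomial sampling of `n_cells` cells from the true profile.
#'
#' @param config A [cohort_sim_config()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @return List with `profiles` (observer rows: `sample_id, marker, subtype,
#'   observer, p0..p3, n_cells`) and `truth` (one row per sample x marker
#'   with the true fractions and heterogeneity label).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  subtypes <- names(config$n_per_subtype)
  profiles <- list()
  truth <- list()
  for (mk in names(config$markers)) {
    theta <- config$markers[[mk]]
    for (st in subtypes) {
      n <- config$n_per_subtype[[st]]
      if (n == 0) next
      for (i in seq_len(n)) {
        sid <- sprintf("%s_%02d", st, i)
        het <- stats::runif(1L) < theta
        p <- draw_true_profile(het, config$concentration_het,
                               config$concentration_homog,
                               config$threshold, config$margin)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          sample_id = sid, marker = mk, subtype = st,
          heterogeneous = het,
          p0 = p[1L], p1 = p[2L], p2 = p[3L], p3 = p[4L]
        )
        for (ob in seq_len(config$n_observers)) {
          q <- if (is.infinite(config$n_cells)) p else
            stats::rmultinom(1L, config$n_cells, p)[, 1L] / config$n_cells
          profiles[[length(profiles) + 1L]] <- tibble::tibble(
            sample_id = sid, marker = mk, subtype = st,
            observer = sprintf("obs%d", ob),
            p0 = q[1L], p1 = q[2L], p2 = q[3L], p3 = q[4L],
            n_cells = config$n_cells
          )
        }
      }
    }
  }
  list(profiles = dplyr::bind_rows(profiles), truth = dplyr::bind_rows(truth))
}

#' Default treatment-arm layout for the plate simulator
#'
#' True viabilities (control %) and true combination indices reproducing
#' the qualitative cross-model pattern of the study systems: monolayer (2D)
#' cultures sensitive to every arm, 3D spheroids sensitive to rapamycin and
#' doxorubicin only, and the bioprinted scaffold (3D-TMS) and xenograft
#' models resistant to every monotherapy with strongly synergistic
#' combinations that drop viability below 60%.
#'
#' @return Tibble: `model, arm, viability, ci` (`viability` is NA for
#'   combination arms, whose effect derives from `ci`; `ci` is NA for
#'   monotherapies).
#' @export
default_plate_arms <- function() {
  tibble::tribble(
    ~model,         ~arm,      ~viability, ~ci,
    "2D",           "Co",      100,        NA,
    "2D",           "R",       70,         NA,
    "2D",           "doxy",    75,         NA,
    "2D",           "doxo",    65,         NA,
    "2D",           "R+doxy",  NA,         0.85,
    "2D",           "R+doxo",  NA,         0.85,
    "3D-spheroid",  "Co",      100,        NA,
    "3D-spheroid",  "R",       70,         NA,
    "3D-spheroid",  "doxy",    88,         NA,
    "3D-spheroid",  "doxo",    72,         NA,
    "3D-spheroid",  "R+doxy",  NA,         0.90,
    "3D-spheroid",  "R+doxo",  NA,         0.90,
    "3D-TMS",       "Co",      100,        NA,
    "3D-TMS",       "R",       94,         NA,
    "3D-TMS",       "doxy",    96,         NA,
    "3D-TMS",       "doxo",    95,         NA,
    "3D-TMS",       "R+doxy",  NA,         0.22,
    "3D-TMS",       "R+doxo",  NA,         0.22,
    "Xeno",         "Co",      100,        NA,
    "Xeno",         "R",       94,         NA,
    "Xeno",         "doxy",    96,         NA,
    "Xeno",         "doxo",    95,         NA,
    "Xeno",         "R+doxy",  NA,         0.20,
    "Xeno",         "R+doxo",  NA,         0.20
  )
}

# Assays read out per model system: metabolic (AB), protein (SRB/mSRB),
# direct counting, and the caliper-volume "assay" for the in vivo arm.
default_plate_assays <- function() {
  tibble::tribble(
    ~model,        ~assay,
    "2D",          "AB",
    "2D",          "SRB",
    "2D",          "cell_count",
    "3D-spheroid", "AB",
    "3D-spheroid", "cell_count",
    "3D-TMS",      "AB",
    "3D-TMS",      "mSRB",
    "Xeno",        "volume"
  )
}

#' Configuration for the synthetic treatment plate
#'
#' @param arms Tibble of true arm-level conditions (see
#'   [default_plate_arms()]).
#' @param assays Tibble mapping each model to the assays read out on it.
#' @param cv Multiplicative assay noise (coefficient of variation,
#'   default 0.10).
#' @param replicates Replicates per model x arm x assay (default 6).
#' @return A `plate_sim_config` list.
#' @export
plate_sim_config <- function(arms = default_plate_arms(),
                             assays = default_plate_assays(),
                             cv = 0.10, replicates = 6L) {
  if (any(arms$viability < 0, na.rm = TRUE)) stop_input("true viabilities must be >= 0.")
  if (any(arms$ci <= 0, na.rm = TRUE)) stop_input("true combination indices must be > 0.")
  if (cv < 0) stop_input("`cv` must be nonnegative.")
  if (replicates < 1L) stop_input("need at least one replicate.")
  structure(list(arms = arms, assays = assays, cv = cv, replicates = replicates),
            class = "plate_sim_config")
}

# Resolve combination-arm viabilities from monotherapy effects and the true
# combination index: Eab = (Ea + Eb) / ci, truncated to [0, 1].
resolve_plate_truth <- function(arms) {
  out <- arms
  for (i in which(is.na(arms$viability))) {
    m <- arms$model[i]
    parts <- strsplit(arms$arm[i], "+", fixed = TRUE)[[1L]]
    mono <- arms[arms$model == m & arms$arm %in% parts & !is.na(arms$viability), ]
    if (nrow(mono) != length(parts)) {
      stop_input("model `%s`: combination `%s` lacks monotherapy viabilities.",
                 m, arms$arm[i])
    }
    if (is.na(arms$ci[i]) || arms$ci[i] <= 0) {
      stop_input("model `%s`: combination `%s` needs a positive true ci.", m, arms$arm[i])
    }
    eab <- min(1, sum(effect_fraction(mono$viability)) / arms$ci[i])
    out$viability[i] <- 100 * (1 - eab)
  }
  out
}

#' Simulate raw assay readouts for a treatment plate
#'
#' Replicate signals are `v_true * (1 + e)` with `e ~ Normal(0, cv)`,
#' truncated at zero; the control arm's true level is fixed at 100 on the
#' signal scale, so noiseless plates normalize back to the true viabilities
#' exactly.
#'
#' @param config A [plate_sim_config()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @return List with `readouts` (`model, arm, assay, replicate, signal`) and
#'   `truth` (arm-level true viabilities with combination viabilities
#'   resolved from the true combination indices).
#' @export
simulate_assay_plate <- function(config, seed = NULL) {
  stopifnot(inherits(config, "plate_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  truth <- resolve_plate_truth(config$arms)
  grid <- dplyr::inner_join(truth, config$assays, by = "model",
                            relationship = "many-to-many")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    eps <- stats::rnorm(config$replicates, 0, config$cv)
    tibble::tibble(
      model = grid$model[i], arm = grid$arm[i], assay = grid$assay[i],
      replicate = seq_len(config$replicates),
      signal = pmax(0, grid$viability[i] * (1 + eps))
    )
  })
  list(readouts = dplyr::bind_rows(rows), truth = truth)
}

#' Configuration for the synthetic xenograft study
#'
#' Control tumours grow exponentially from `v0` to `v0 * growth_fold` over
#' the study; a treated group's burden at the final day is its control-level
#' burden scaled by the group multiplier, applied as a proportional rate
#' reduction so the multiplier is exact at the endpoint. Diameters are
#' back-computed from the sphere volume and jittered with measurement noise.
#'
#' @param groups Tibble `group, multiplier`; default mirrors the in vivo
#'   arm pattern (combinations roughly halve the final burden).
#' @param v0 Initial (palpable) tumour volume in mm^3, default 50.
#' @param growth_fold Fold growth of the control group over the study,
#'   default 8.
#' @param days Measurement days (default thrice weekly over 21 days).
#' @param n_animals Animals per group, default 6.
#' @param noise_sd_mm Gaussian measurement noise on each diameter in mm,
#'   default 0.3.
#' @param weight_per_mm3 Endpoint tumour density in g/mm^3, default 0.001.
#' @return A `xeno_sim_config` list.
#' @export
xeno_sim_config <- function(groups = tibble::tibble(
                              group = c("Co", "R", "doxy", "doxo", "R+doxy", "R+doxo"),
                              multiplier = c(1, 0.94, 0.96, 0.95, 0.50, 0.45)),
                            v0 = 50, growth_fold = 8,
                            days = c(0, 2, 4, 7, 9, 11, 14, 16, 18, 21),
                            n_animals = 6L, noise_sd_mm = 0.3,
                            weight_per_mm3 = 0.001) {
  if (v0 <= 0 || growth_fold <= 0) stop_input("volumes and growth must be positive.")
  if (any(groups$multiplier <= 0)) stop_input("treatment multipliers must be positive.")
  if (noise_sd_mm < 0) stop_input("`noise_sd_mm` must be nonnegative.")
  structure(list(groups = groups, v0 = v0, growth_fold = growth_fold,
                 days = days, n_animals = n_animals,
                 noise_sd_mm = noise_sd_mm, weight_per_mm3 = weight_per_mm3),
            class = "xeno_sim_config")
}

#' Simulate a caliper-measured xenograft study
#'
#' @param config A [xeno_sim_config()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @return List with `measurements` (`animal_id, group, day, shorter_mm,
#'   longer_mm, weight_g`; weight only on the final day) and `truth`
#'   (per-group true endpoint volumes and effect fractions).
#' @export
simulate_xenograft_study <- function(config, seed = NULL) {
  stopifnot(inherits(config, "xeno_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  t_end <- max(config$days)
  rate <- log(config$growth_fold) / t_end
  rows <- list()
  for (g in seq_len(nrow(config$groups))) {
    grp <- config$groups$group[g]
    mult <- config$groups$multiplier[g]
    for (a in seq_len(config$n_animals)) {
      aid <- sprintf("%s_%02d", grp, a)
      for (d in config$days) {
        v_true <- config$v0 * exp(rate * d) * mult^(d / t_end)
        diam <- (6 * v_true / pi)^(1 / 3)
        s <- pmax(0.1, diam + stats::rnorm(1L, 0, config$noise_sd_mm))
        l <- pmax(0.1, diam + stats::rnorm(1L, 0, config$noise_sd_mm))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          animal_id = aid, group = grp, day = d,
          shorter_mm = min(s, l), longer_mm = max(s, l),
          weight_g = if (d == t_end)
            tumour_volume(min(s, l), max(s, l)) * config$weight_per_mm3
          else NA_real_
        )
      }
    }
  }
  ctrl_end <- config$v0 * config$growth_fold
  truth <- dplyr::mutate(
    config$groups,
    endpoint_volume = ctrl_end * .data$multiplier,
    effect = pmin(1, pmax(0, 1 - .data$multiplier))
  )
  list(measurements = prepare_calipers(dplyr::bind_rows(rows)), truth = truth)
}
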