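test_that("cohort generator is deterministic and honours degenerate prevalences", {
  cfg0 <- cohort_sim_config(markers = c(M = 0),
                            n_per_subtype = c(A = 5L, B = 5L))
  sim0 <- simulate_cohort(cfg0, seed = 1)
  sc0 <- score_cohort(sim0$profiles)
  expect_false(any(sc0$heterogeneous))
  expect_false(summarize_marker(sc0)$is_heterogeneous_marker)

  cfg1 <- cohort_sim_config(markers = c(M = 1),
                            n_per_subtype = c(A = 5L, B = 5L),
                            n_cells = Inf)
  sc1 <- score_cohort(simulate_cohort(cfg1, seed = 1)$profiles)
  expect_true(all(sc1$heterogeneous))
  expect_equal(summarize_marker(sc1)$pooled_percent, 100)

  rerun <- simulate_cohort(cfg0, seed = 1)
  expect_identical(sim0$profiles, rerun$profiles)
  expect_identical(sim0$truth, rerun$truth)
  expect_error(cohort_sim_config(markers = c(M = 0.5), concentration_het = 0),
               "positive")
  expect_error(cohort_sim_config(markers = c(1.2)), "named")
})

test_that("cohort generator recovers a 90% prevalence within the binomial band", {
  cfg <- cohort_sim_config(markers = c(M = 0.9),
                           n_per_subtype = c(LumA = 9L, LumB = 10L,
                                             `HER2+` = 8L, TNBC = 10L))
  sc <- score_cohort(simulate_cohort(cfg, seed = 99)$profiles)
  k <- sum(sc$heterogeneous)
  expect_gte(k, qbinom(0.025, 37, 0.9))
  expect_lte(k, qbinom(0.975, 37, 0.9))
})

test_that("observer fractions are multinomial reads of the true profile", {
  cfg <- cohort_sim_config(markers = c(M = 0.5), n_per_subtype = c(A = 20L),
                           n_cells = 400L)
  sim <- simulate_cohort(cfg, seed = 3)
  expect_equal(nrow(sim$profiles), 2 * nrow(sim$truth))
  joined <- dplyr::inner_join(sim$profiles, sim$truth,
                              by = c("sample_id", "marker", "subtype"),
                              suffix = c("", "_true"))
  expect_true(all(abs(joined$p0 - joined$p0_true) < 0.15))
  # fractions are integer cell counts over n_cells
  expect_true(all(abs(joined$p0 * 400 - round(joined$p0 * 400)) < 1e-9))
})

test_that("noiseless plates normalize back to the true viabilities exactly", {
  cfg <- plate_sim_config(cv = 0)
  sim <- simulate_assay_plate(cfg, seed = 1)
  viab <- average_across_assays(viability_table(sim$readouts))
  merged <- dplyr::inner_join(viab, sim$truth, by = c("model", "arm"))
  expect_equal(merged$mean_percent, merged$viability)
  # a noiseless additive combination scores as exactly additive
  arms <- tibble::tibble(model = "m",
                         arm = c("Co", "a", "b", "a+b"),
                         viability = c(100, 70, 80, NA),
                         ci = c(NA, NA, NA, 1))
  assays <- tibble::tibble(model = "m", assay = "AB")
  v <- average_across_assays(viability_table(
    simulate_assay_plate(plate_sim_config(arms, assays, cv = 0), seed = 1)$readouts))
  out <- combination_assessments(v)
  expect_equal(out$ci, 1)
  expect_equal(as.character(out$interaction), "additive")
})

test_that("plate generator validates its truth table and is reproducible", {
  bad <- tibble::tibble(model = "m", arm = c("Co", "a", "b", "a+b"),
                        viability = c(100, 70, 80, NA), ci = c(NA, NA, NA, -1))
  expect_error(plate_sim_config(bad, tibble::tibble(model = "m", assay = "AB")),
               "> 0")
  cfg <- plate_sim_config()
  expect_identical(simulate_assay_plate(cfg, seed = 5)$readouts,
                   simulate_assay_plate(cfg, seed = 5)$readouts)
})

test_that("xenograft generator hits treatment multipliers exactly without noise", {
  cfg <- xeno_sim_config(groups = tibble::tibble(group = c("Co", "T1", "T0.5"),
                                                 multiplier = c(1, 1, 0.5)),
                         n_animals = 2L, noise_sd_mm = 0)
  gs <- growth_summary(simulate_xenograft_study(cfg, seed = 1)$measurements)
  ep <- gs$endpoint
  ctrl <- ep[ep$group == "Co", ]
  expect_equal(in_vivo_effect(ctrl, ep[ep$group == "T1", ]), 0)
  expect_equal(in_vivo_effect(ctrl, ep[ep$group == "T0.5", ]), 0.5)
  expect_equal(ctrl$mean_volume, 50 * 8)
})

test_that("stochastic xenograft effects are recovered within 3 standard errors", {
  cfg <- xeno_sim_config(groups = tibble::tibble(group = c("Co", "T"),
                                                 multiplier = c(1, 0.6)),
                         n_animals = 8L)
  reps <- vapply(1:30, function(s) {
    gs <- growth_summary(simulate_xenograft_study(cfg, seed = s)$measurements)
    in_vivo_effect(gs$endpoint[gs$endpoint$group == "Co", ],
                   gs$endpoint[gs$endpoint$group == "T", ])
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.4), 3 * se + 1e-3)
})
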