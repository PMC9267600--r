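test_that("normalize_to_control reports control % with replicate spread", {
  expect_equal(normalize_to_control(c(0.8, 0.8), c(0.8, 0.8))$mean_percent, 100)
  expect_equal(normalize_to_control(c(0, 0, 0), c(1, 1, 1))$mean_percent, 0)
  out <- normalize_to_control(c(0.55, 0.60, 0.65), c(0.8, 0.8, 0.8))
  expect_equal(out$mean_percent, 75)
  expect_equal(out$sd_percent, sd(100 * c(0.55, 0.60, 0.65) / 0.8))
  expect_error(normalize_to_control(c(1, 2), c(0, 0)), "control mean")
})

test_that("viability_table normalizes every arm against its own model/assay control", {
  readouts <- tibble::tibble(
    model = "2D", assay = "AB",
    arm = rep(c("Co", "R"), each = 3),
    replicate = rep(1:3, 2),
    signal = c(100, 100, 100, 60, 70, 80)
  )
  viab <- viability_table(readouts)
  expect_equal(viab$mean_percent[viab$arm == "Co"], 100)
  expect_equal(viab$mean_percent[viab$arm == "R"], 70)
  expect_error(viability_table(dplyr::filter(readouts, arm != "Co")), "no `Co` arm")
})

test_that("average_across_assays is the unweighted mean of assay results", {
  viab <- tibble::tibble(
    model = "2D", arm = "R",
    assay = c("AB", "SRB", "cell_count"),
    mean_percent = c(72, 81, 90), sd_percent = 1, n = 6
  )
  expect_equal(average_across_assays(viab)$mean_percent, 81)
  expect_equal(average_across_assays(viab[1:2, ])$mean_percent, 76.5)
  one <- average_across_assays(viab[1, ])
  expect_equal(one$mean_percent, 72)
  expect_equal(one$assay, "average")
  expect_error(average_across_assays(viab[0, ]), "empty")
})

test_that("effect_fraction is clipped fractional inhibition", {
  expect_equal(effect_fraction(100), 0)
  expect_equal(effect_fraction(0), 1)
  expect_equal(effect_fraction(75), 0.25)
  expect_equal(effect_fraction(130), 0) # stimulation clips to zero effect
  expect_error(effect_fraction(-5), ">= 0")
})

test_that("combination_index classifies synergy around the additivity band", {
  add <- combination_index(0.2, 0.3, 0.5)
  expect_equal(add$ci, 1)
  expect_equal(as.character(add$interaction), "additive")
  syn <- combination_index(0.2, 0.3, 0.6)
  expect_equal(syn$ci, 5 / 6, tolerance = 1e-12)
  expect_equal(as.character(syn$interaction), "synergistic")
  ant <- combination_index(0.3, 0.3, 0.4)
  expect_equal(ant$ci, 1.5)
  expect_equal(as.character(ant$interaction), "no_additional_effect")
  # tolerance band edges are additive inclusively
  expect_equal(as.character(combination_index(0.21, 0.21, 0.4)$interaction),
               "additive") # ci = 1.05
  expect_error(combination_index(0.2, 0.3, 0), "undefined")
  expect_error(combination_index(1.2, 0.3, 0.5), "\\[0, 1\\]")
})

test_that("combination_index is invariant under common rescaling of effects", {
  set.seed(5)
  for (i in 1:25) {
    e <- runif(3, 0.05, 0.6)
    k <- runif(1, 0.2, 1 / max(e))
    expect_equal(combination_index(e[1], e[2], e[3])$ci,
                 combination_index(k * e[1], k * e[2], k * e[3])$ci)
  }
})

test_that("sensitivity classes follow the four viability bands, monotonically", {
  expect_equal(as.character(classify_sensitivity(95)), "resistant")
  expect_equal(as.character(classify_sensitivity(70)), "sensitive")
  expect_equal(as.character(classify_sensitivity(59.999)), "highly_sensitive")
  # band boundaries: 90 resistant, 80 minimal, 60 sensitive
  expect_equal(as.character(classify_sensitivity(c(90, 89.99, 80, 79.99, 60))),
               c("resistant", "minimal_sensitivity", "minimal_sensitivity",
                 "sensitive", "sensitive"))
  v <- sort(runif(100, 0, 120))
  cls <- classify_sensitivity(v)
  expect_true(all(diff(as.integer(cls)) >= 0)) # lower viability never less sensitive
})

test_that("model_concordance counts matching arms and rejects arm mismatches", {
  a <- tibble::tibble(arm = c("Co", "R", "doxy", "doxo"),
                      category = classify_sensitivity(c(95, 85, 70, 50)),
                      mean_percent = c(95, 85, 70, 50))
  expect_equal(model_concordance(a, a)$agreement, 1)
  b <- a
  b$category <- classify_sensitivity(c(70, 50, 95, 85))
  expect_equal(model_concordance(a, b)$agreement, 0)
  c5 <- tibble::tibble(arm = letters[1:5],
                       category = classify_sensitivity(c(95, 95, 70, 50, 50)),
                       mean_percent = c(95, 95, 70, 50, 50))
  d5 <- c5
  d5$category <- classify_sensitivity(c(95, 95, 70, 85, 85))
  expect_equal(model_concordance(c5, d5)$agreement, 0.6)
  expect_error(model_concordance(a, c5), "same arms")
})

test_that("combination assessments resolve monotherapy components by arm name", {
  viab <- tibble::tibble(
    model = "2D",
    arm = c("Co", "R", "doxo", "R+doxo"),
    mean_percent = c(100, 80, 70, 50),
    sd_percent = NA, n = 1
  )
  out <- combination_assessments(viab)
  expect_equal(out$ci, (0.2 + 0.3) / 0.5)
  expect_equal(as.character(out$interaction), "additive")
  mat <- sensitivity_matrix(viab)
  expect_equal(nrow(mat), 4)
  expect_false(any(mat$synergistic[mat$arm != "R+doxo"]))
})
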