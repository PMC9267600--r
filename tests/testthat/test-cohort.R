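test_that("round_half_away rounds ties away from zero", {
  expect_equal(round_half_away(c(86.49, 86.5, 40.5, 0.5, -0.5)),
               c(86, 87, 41, 1, -1))
})

test_that("pooled percentage pools counts over subtypes and drops empty ones", {
  # pooled counts, not mean of per-subtype percentages
  expect_equal(pooled_heterogeneity_percent(c(8, 8, 8, 8), c(9, 10, 8, 10)), 86)
  expect_equal(pooled_heterogeneity_percent(c(8, 10, 8, 9), c(10, 10, 8, 10)), 92)
  expect_equal(pooled_heterogeneity_percent(c(1, 2, 3, 4), c(7, 9, 7, 8)), 32)
  # a subtype with no evaluated samples is excluded, not counted as 0/0
  expect_equal(pooled_heterogeneity_percent(c(5, 0), c(10, 0)), 50)
  expect_error(pooled_heterogeneity_percent(c(0, 0), c(0, 0)), "no subtype")
  expect_error(pooled_heterogeneity_percent(c(5), c(4)), "n_het <= n_eval")
})

test_that("summarize_marker aggregates calls with the strict >40% rule", {
  calls <- list(LumA = calls_of(8, 9), LumB = calls_of(8, 10),
                `HER2+` = calls_of(8, 8), TNBC = calls_of(8, 10))
  out <- summarize_marker(calls, marker = "pS6-like")
  expect_equal(out$pooled_percent, 86)
  expect_true(out$is_heterogeneous_marker)
  cts <- out$per_subtype[[1]]
  expect_equal(sum(cts$n_heterogeneous), 32)
  expect_equal(sum(cts$n_evaluated), 37)

  low <- summarize_marker(list(A = calls_of(1, 7), B = calls_of(2, 9),
                               C = calls_of(3, 7), D = calls_of(4, 8)))
  expect_equal(low$pooled_percent, 32)
  expect_false(low$is_heterogeneous_marker)

  # strict inequality: exactly 40% is not a heterogeneous marker
  expect_false(summarize_marker(list(A = calls_of(2, 5)))$is_heterogeneous_marker)
  expect_error(summarize_marker(tibble::tibble(subtype = character(),
                                               heterogeneous = logical())),
               "no heterogeneity calls")
})

test_that("score_cohort builds consensus profiles and scores them", {
  sc <- score_cohort(toy_cohort())
  expect_equal(nrow(sc), 2)
  s1 <- sc[sc$sample_id == "s1", ]
  expect_equal(unlist(s1[, c("p0", "p1", "p2", "p3")], use.names = FALSE),
               c(0.5, 0.4, 0.1, 0))
  expect_equal(s1$h_score, 100 * (0.4 + 0.2))
  expect_equal(s1$sdi, entropy_oracle(c(0.5, 0.4, 0.1, 0)))
  expect_true(s1$heterogeneous)
  s2 <- sc[sc$sample_id == "s2", ]
  expect_equal(s2$sdi, 0)
  expect_false(s2$heterogeneous)
})

test_that("marker heterogeneity table mirrors the k/n survey layout", {
  sc <- score_cohort(toy_cohort())
  tab <- marker_heterogeneity_table(sc)
  expect_equal(tab$LumA, "1/1")
  expect_equal(tab$LumB, "0/1")
  expect_equal(tab$pooled_percent, 50)
  expect_true(tab$is_heterogeneous_marker)
})

test_that("sdi_model_table averages per cell and keeps missing cells absent", {
  scores <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    marker = c("GLS", "GLS", "FASN"),
    subtype = c("Xeno", "Xeno", "3D-TMS"),
    sdi = c(0, log(4), 0.8)
  )
  tab <- sdi_model_table(scores)
  expect_equal(tab$mean_sdi[tab$marker == "GLS" & tab$model == "Xeno"],
               log(4) / 2)
  expect_equal(tab$mean_sdi[tab$marker == "FASN"], 0.8)
  expect_equal(nrow(tab), 2) # no (GLS, 3D-TMS) or (FASN, Xeno) zero-filled rows
  expect_equal(nrow(sdi_model_contrast(tab, "Xeno", "3D-TMS")), 0)
})

test_that("reference marker counts load with valid per-subtype counts", {
  counts <- reference_marker_counts()
  expect_equal(length(unique(counts$marker)), 14)
  expect_setequal(unique(counts$subtype), c("LumA", "LumB", "HER2+", "TNBC"))
  expect_true(all(counts$n_heterogeneous >= 0 &
                    counts$n_heterogeneous <= counts$n_evaluated))
  expect_true(all(counts$n_evaluated >= 6 & counts$n_evaluated <= 10))
})
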