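test_that("reverse recoding reflects endpoints, keeps missing, is an involution", {
  md <- item_metadata(c("a", "b"), reverse_coded = c(TRUE, FALSE))
  x <- toy_matrix(c(1L, 4L, NA, 2L, 3L, NA), item_ids = c("a", "b"))
  r <- recode_reverse(x, md)
  expect_identical(r[, "a"], c(p1 = 4L, p2 = 1L, p3 = NA_integer_))
  expect_identical(r[, "b"], x[, "b"])      # untouched
  expect_identical(recode_reverse(r, md), x) # involution
  md_bad <- item_metadata(c("a", "b", "zz"),
                          reverse_coded = c(FALSE, FALSE, TRUE))
  expect_error(recode_reverse(x, md_bad), "zz")
})

test_that("recoding preserves the midpoint sum for observed responses", {
  md <- item_metadata("a", reverse_coded = TRUE)
  x <- toy_matrix(sample(1:4, 30, replace = TRUE), item_ids = "a")
  r <- recode_reverse(x, md)
  expect_true(all(x + r == 5L))
})

test_that("per-item statistics match hand computation", {
  x <- toy_matrix(c(1L, 2L, 3L, NA), item_ids = "a")
  s <- compute_item_stats(x)
  expect_equal(s$mean, 2.0)
  expect_equal(s$completion, 0.75)
  expect_equal(s$frac_low, 0.50)
  expect_equal(s$frac_high, 0.25)
  expect_identical(c(s$observed_min, s$observed_max), c(1L, 3L))
})

test_that("debriefing fractions use the enrolled cohort as denominator", {
  x <- toy_matrix(rep(2L, 48), item_ids = "a")
  d <- flag_debrief(list("p1", "a", "difficult"))
  s <- compute_item_stats(x, debrief = d)
  expect_equal(s$completion, 1.0)
  expect_equal(s$frac_difficult, 1 / 48)
  expect_equal(s$frac_upsetting, 0)
  # a duplicate flag from the same patient counts once
  d2 <- flag_debrief(list(c("p1", "p1"), c("a", "a"),
                          c("difficult", "difficult")))
  expect_equal(compute_item_stats(x, debrief = d2)$frac_difficult, 1 / 48)
})

test_that("an item with no responses is degenerate, not an error", {
  x <- toy_matrix(c(NA, NA, 1L, 2L), item_ids = c("a", "b"))
  s <- compute_item_stats(x)
  expect_true(is.na(s$mean[1]))
  expect_true(is.na(s$observed_min[1]))
  expect_equal(s$completion[1], 0)
})

test_that("frac_low + frac_high equals completion identically on any input", {
  for (seed in 1:5) {
    x <- random_cohort(n = 17, k = 8, miss = 0.25, seed = seed)
    s <- compute_item_stats(x)
    expect_identical(s$frac_low + s$frac_high, s$completion)
  }
})

test_that("completion time summary follows the midpoint-median rule", {
  expect_equal(completion_time_summary(c(5, 10, 20))[["median"]], 10)
  expect_equal(completion_time_summary(c(5, 7, 11, 13))[["median"]], 9)
  one <- completion_time_summary(10)
  expect_equal(one[["median"]], 10)
  expect_equal(one[["mean"]], 10)
  d <- debrief_records(times = data.frame(patient_id = c("p1", "p2"),
                                          completion_minutes = c(NA, 8)))
  expect_equal(completion_time_summary(d)[["n"]], 1)
  expect_error(completion_time_summary(numeric(0)), "no non-missing")
})

test_that("cohort summary rounds percentages half away from zero", {
  cl <- data.frame(disease = rep(c("AA", "PNH", "AA+PNH"), c(21, 13, 14)),
                   age = c(rep(40, 47), 80))
  cs <- cohort_summary(cl)
  expect_equal(cs$n, 48)
  tab <- cs$categorical
  expect_equal(tab$percent[tab$category == "AA"], 44)      # 43.75 up
  expect_equal(tab$percent[tab$category == "PNH"], 27)     # 27.08 down
  expect_equal(tab$percent[tab$category == "AA+PNH"], 29)  # 29.17 down
  expect_equal(cs$numeric$median, 40)
  # declared vocabulary: empty categories report 0, unknown values error
  cs2 <- cohort_summary(cl, categorical = "disease",
                        levels = list(disease = c("AA", "PNH", "AA+PNH",
                                                  "other")))
  expect_equal(cs2$categorical$percent[cs2$categorical$category == "other"],
               0)
  expect_error(cohort_summary(cl, categorical = "disease",
                              levels = list(disease = "AA")),
               "unknown category")
})
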