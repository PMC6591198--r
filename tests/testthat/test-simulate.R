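test_that("the same seed yields byte-identical cohorts and CSVs", {
  a <- simulate_cohort(default_cohort_config(seed = 33))
  b <- simulate_cohort(default_cohort_config(seed = 33))
  expect_identical(a$responses, b$responses)
  expect_identical(a$debrief, b$debrief)
  expect_identical(a$latent, b$latent)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  expect_identical(readLines(file.path(d1, "responses.csv")),
                   readLines(file.path(d2, "responses.csv")))
  c2 <- simulate_cohort(default_cohort_config(seed = 34))
  expect_false(identical(a$responses, c2$responses))
})

test_that("zero loadings give uncorrelated continuous scores", {
  md <- item_metadata(paste0("i", 1:4))
  cfg <- cohort_config(n_patients = 10000, metadata = md,
                       scales = as.list(stats::setNames(md$item_id,
                                                        md$item_id)),
                       loadings = stats::setNames(rep(0, 4), md$item_id),
                       seed = 2)
  co <- simulate_cohort(cfg)
  r <- stats::cor(co$latent)
  expect_true(all(abs(r[upper.tri(r)]) < 0.05))
})

test_that("per-item missingness concentrates at its configured rate", {
  md <- item_metadata(c("a", "b"))
  cfg <- cohort_config(n_patients = 10000, metadata = md,
                       scales = list(s = c("a", "b")), loadings = c(s = 0.5),
                       missingness = c(a = 0.32, b = 0), seed = 3)
  co <- simulate_cohort(cfg)
  s <- compute_item_stats(co$responses)
  expect_gt(s$completion[s$item_id == "a"], 0.31 * 0 + (1 - 0.33))
  expect_lt(s$completion[s$item_id == "a"], 1 - 0.31)
  expect_equal(s$completion[s$item_id == "b"], 1)
})

test_that("category fractions converge to the normal-CDF masses", {
  md <- item_metadata("a")
  mu <- 0.4
  cfg <- cohort_config(n_patients = 10000, metadata = md,
                       scales = list(s = "a"), loadings = c(s = 0.6),
                       latent_means = c(a = mu), seed = 4)
  co <- simulate_cohort(cfg)
  emp <- as.numeric(table(factor(co$responses[, "a"], levels = 1:4))) / 10000
  expect_true(all(abs(emp - category_masses(mu, c(-1, 0, 1))) < 0.02))
})

test_that("reverse items are emitted reversed so the pipeline must recode", {
  md <- item_metadata(c("a", "b"), reverse_coded = c(TRUE, FALSE))
  cfg <- cohort_config(n_patients = 3000, metadata = md,
                       scales = list(s = c("a", "b")),
                       loadings = c(s = 0.5),
                       latent_means = c(a = 1.5, b = 1.5), seed = 5)
  co <- simulate_cohort(cfg)
  # latent means are high on the problem scale: the raw emitted reverse item
  # must lean low, the plain item high; recoding realigns them
  expect_lt(mean(co$responses[, "a"]), 2)
  expect_gt(mean(co$responses[, "b"]), 3)
  rec <- recode_reverse(co$responses, md)
  expect_equal(mean(rec[, "a"]), mean(co$responses[, "b"]), tolerance = 0.15)
})

test_that("computed completion converges to one minus the missingness", {
  cfg <- default_cohort_config(seed = 6)
  cfg$n_patients <- 4000L
  co <- simulate_cohort(cfg)
  s <- compute_item_stats(recode_reverse(co$responses, cfg$metadata))
  expect_true(all(abs(s$completion - (1 - cfg$missingness)) < 0.03))
})

test_that("debriefing rates and completion times follow the configuration", {
  md <- item_metadata("a")
  cfg <- cohort_config(n_patients = 8000, metadata = md,
                       scales = list(s = "a"), loadings = c(s = 0),
                       p_difficult = c(a = 0.1),
                       issue_rates = c(sleep = 0.05), seed = 7)
  co <- simulate_cohort(cfg)
  s <- compute_item_stats(co$responses, debrief = co$debrief)
  expect_lt(abs(s$frac_difficult - 0.1), 0.02)
  expect_equal(s$frac_upsetting, 0)
  iss <- missing_issue_screen(co$debrief)
  expect_lt(abs(iss$n_patients[1] / 8000 - 0.05), 0.01)
  tm <- completion_time_summary(co$debrief)
  expect_gte(tm[["min"]], 5)
  expect_lte(tm[["max"]], 20)
  expect_lt(abs(tm[["median"]] - 10), 1.5)
})

test_that("invalid configurations are rejected", {
  md <- item_metadata(c("a", "b"))
  expect_error(cohort_config(metadata = md, scales = list(s = "a")),
               "exactly one generating scale")
  expect_error(cohort_config(metadata = md, scales = list(s = c("a", "b")),
                             loadings = c(s = 1)), "loadings")
  expect_error(cohort_config(metadata = md, scales = list(s = c("a", "b")),
                             loadings = c(s = 0.5),
                             cutpoints = c(0, 0, 1)),
               "strictly increasing")
  expect_error(cohort_config(metadata = md, scales = list(s = c("a", "b")),
                             loadings = c(s = 0.5),
                             missingness = c(a = 1, b = 0)),
               "missingness")
})

test_that("default configuration encodes the field-test conditions", {
  cfg <- default_cohort_config()
  expect_equal(cfg$n_patients, 48L)
  expect_equal(length(cfg$metadata$item_id), 69L)
  ref <- qlq_aapnh_phase3()$stats
  expect_equal(unname(cfg$missingness["s68"]), 1 - 0.68, tolerance = 1e-6)
  expect_equal(unname(cfg$p_priority["s22"]), 0.02)
  # inverted latent means reproduce the printed item means in expectation
  mu <- cfg$latent_means["s08"]
  expect_equal(expected_mean <- sum(1:4 * category_masses(mu, c(-1, 0, 1))),
               2.1, tolerance = 1e-6)
})
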