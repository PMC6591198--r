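test_that("criteria reproduce the published worked examples", {
  s <- item_statistics(
    item_id = c("s08", "s34"),
    mean = c(2.1, 2.6), observed_min = 1, observed_max = 4,
    frac_low = c(0.62, 0.38), frac_high = c(0.34, 0.47),
    completion = c(0.96, 0.85),
    frac_upsetting = c(0.00, 0.00), frac_difficult = c(0.07, 0.05),
    frac_priority = c(0.00, 0.00))
  f <- evaluate_criteria(s)
  expect_identical(unlist(f[1, paste0("c", 1:8)], use.names = FALSE),
                   c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_true(f$screen_keep[1])   # five of seven
  expect_identical(unlist(f[2, paste0("c", 1:8)], use.names = FALSE),
                   c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_false(f$screen_keep[2])  # four of seven, no priority
})

test_that("inequality strictness sits exactly on the stated boundaries", {
  s <- item_statistics("x", mean = 1.5, observed_min = 1, observed_max = 4,
                       frac_low = 0.50, frac_high = 0.50, completion = 1,
                       frac_upsetting = 0.05, frac_difficult = 0.05,
                       frac_priority = 0.02)
  f <- evaluate_criteria(s)
  expect_false(f$c1)  # mean > 1.5 strict
  expect_false(f$c2)  # frac_high > 0.50 strict
  expect_false(f$c5)  # upsetting < 0.05 strict
  expect_false(f$c6)  # difficult < 0.05 strict
  expect_true(f$c8)   # priority >= 0.02 non-strict
  s2 <- item_statistics("x", mean = 2, observed_min = 1, observed_max = 4,
                        frac_low = 0.05, frac_high = 0.95,
                        completion = 0.95)
  f2 <- evaluate_criteria(s2)
  expect_false(f2$c7)  # completion > 0.95 strict
  expect_false(f2$c3)  # ceiling: lower half not above 10%
})

test_that("a ceiling-only item fails the floor/ceiling criterion", {
  x <- toy_matrix(rep(4L, 10), item_ids = "a")
  f <- evaluate_criteria(compute_item_stats(x))
  expect_false(f$c3)
  expect_false(f$c4)  # range not covered either
})

test_that("a zero-completion item fails c1-c4 and is marked degenerate", {
  s <- compute_item_stats(toy_matrix(c(NA, NA, NA), item_ids = "a"))
  f <- evaluate_criteria(s)
  expect_true(f$degenerate)
  expect_identical(unlist(f[1, paste0("c", 1:4)], use.names = FALSE),
                   rep(FALSE, 4))
})

test_that("the keep rule needs five of c1-c7, or c8 alone", {
  mk <- function(on, c8 = FALSE) {
    f <- as.data.frame(as.list(stats::setNames(seq_len(7) %in% on,
                                               paste0("c", 1:7))))
    f$c8 <- c8
    f
  }
  expect_true(screen_decision(mk(1:5)))
  expect_false(screen_decision(mk(1:4)))
  expect_true(screen_decision(mk(integer(0), c8 = TRUE)))
  expect_true(screen_decision(mk(1:4, c8 = TRUE)))
  expect_equal(screen_decision(mk(1:4), criteria_thresholds(keep_count = 4)),
               TRUE)
})

test_that("the keep rule is monotone in every criterion", {
  set.seed(42)
  for (i in 1:60) {
    base <- as.data.frame(as.list(stats::setNames(
      as.logical(stats::rbinom(8, 1, 0.5)), paste0("c", 1:8))))
    v0 <- screen_decision(base)
    for (j in which(!unlist(base))) {
      up <- base
      up[[j]] <- TRUE
      expect_true(screen_decision(up) >= v0)
    }
  }
})

test_that("flag tabulation counts items and rejects duplicates", {
  ref <- qlq_aapnh_phase3()
  expect_equal(tabulate_flags(ref$flags)[["c7"]], 57)
  empty <- ref$flags[0, ]
  expect_identical(unname(tabulate_flags(empty)), rep(0L, 9))
  dup <- rbind(ref$flags, ref$flags[1, ])
  expect_error(tabulate_flags(dup), "duplicate")
})

test_that("missing-issue screening counts distinct patients", {
  d <- debrief_records(issues = data.frame(
    patient_id = c(paste0("p", 1:5), "p9", "p9"),
    issue_label = c(rep("travel insurance", 5), "diet", "diet")))
  scr <- missing_issue_screen(d)
  expect_identical(scr$n_patients[scr$issue_label == "travel insurance"], 5L)
  expect_true(scr$add[scr$issue_label == "travel insurance"])    # boundary
  expect_identical(scr$n_patients[scr$issue_label == "diet"], 1L)
  expect_false(scr$add[scr$issue_label == "diet"])
  none <- missing_issue_screen(debrief_records())
  expect_identical(nrow(none), 0L)
})

test_that("group decisions: roster size is the sum of resulting items", {
  dec <- group_decisions(c("a", "b", "c", "d"),
                         c("KEEP", "KEEP", "KEEP", "EXPAND"))
  expect_equal(apply_group_decisions(dec)$roster_size, 5)  # 3 + 2
  all_keep <- group_decisions(sprintf("i%02d", 1:69), "KEEP")
  expect_equal(apply_group_decisions(all_keep)$roster_size, 69)
})

test_that("group decisions validate action consistency and coverage", {
  expect_error(group_decisions("a", "DELETE", resulting_items = 1),
               "inconsistent")
  expect_error(group_decisions("a", "EXPAND", resulting_items = 1),
               "inconsistent")
  expect_error(group_decisions(c("a", "a"), "KEEP"), "more than one")
  expect_error(group_decisions("a", "MAYBE"), "unknown decision")
  ref <- qlq_aapnh_phase3()
  expect_error(apply_group_decisions(ref$decisions[-1, ], ref$flags),
               "no decision recorded")
  extra <- rbind(ref$decisions,
                 group_decisions("s99", "KEEP"))
  expect_error(apply_group_decisions(extra, ref$flags), "unknown item")
})

test_that("the concordance report lists only expert overrides", {
  ref <- qlq_aapnh_phase3()
  dec <- apply_group_decisions(ref$decisions, ref$flags)
  conc <- dec$concordance
  overrides <- conc$item_id[!conc$agree]
  # every disagreement is a screen-pass the experts dropped (redundancy
  # deletions); the two screen failures (s34, s50) were indeed deleted
  expect_true(all(conc$screen_keep[!conc$agree]))
  expect_false(any(c("s34", "s50") %in% overrides))
  expect_equal(sum(!conc$agree), 14)
})
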