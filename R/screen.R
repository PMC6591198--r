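#' Phase-III item screening
#'
#' The package's main entry point: runs the full item-analysis pipeline on a
#' cohort — recode reverse-worded items, compute per-item statistics,
#' evaluate the eight retention criteria and the keep rule, screen the
#' debriefing interviews for missing issues, estimate Cronbach's alpha for
#' the hypothesised scales, and (when expert decisions are supplied)
#' reconcile them with the screening verdicts. Identical inputs yield
#' identical output.
#'
#' Alternatively the statistics stage can be skipped by passing a ready-made
#' \code{stats} table (for example the published reference table of
#' [qlq_aapnh_phase3()]) instead of raw responses; the alpha stage is then
#' unavailable.
#'
#' @param responses integer response matrix (patients x items, \code{NA} =
#'   missing), on the raw scale as administered.
#' @param debrief optional [debrief_records()].
#' @param metadata an [item_metadata()] table; default infers a 1--4 range
#'   with no reverse coding from the matrix columns.
#' @param scales optional named list of item id vectors; when supplied, a
#'   Cronbach's alpha table is computed on the recoded responses.
#' @param thresholds a [criteria_thresholds()] object.
#' @param decisions optional [group_decisions()] table.
#' @param stats an \code{"item_statistics"} table, as an alternative to
#'   \code{responses}.
#' @return An object of class \code{"item_screen"} with components
#'   \code{stats}, \code{flags}, \code{alpha}, \code{issues},
#'   \code{decisions} (a \code{"decision_summary"} or \code{NULL}),
#'   \code{thresholds}, \code{n_patients}.
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(seed = 1))
#' scr <- item_screen(cohort$responses, debrief = cohort$debrief,
#'                    metadata = qlq_aapnh_metadata(),
#'                    scales = qlq_aapnh_scales())
#' summary(scr)
#' @export
item_screen <- function(responses = NULL, debrief = NULL, metadata = NULL,
                        scales = NULL, thresholds = criteria_thresholds(),
                        decisions = NULL, stats = NULL) {
  if (is.null(responses) && is.null(stats))
    stop("supply either a response matrix or an item-statistics table")
  alpha <- NULL
  n_patients <- NA_integer_
  if (!is.null(responses)) {
    if (is.null(metadata)) metadata <- item_metadata(colnames(responses))
    validate_responses(responses, metadata)
    recoded <- recode_reverse(responses, metadata)
    n_patients <- nrow(responses)
    if (is.null(stats))
      stats <- compute_item_stats(recoded, debrief = debrief,
                                  metadata = metadata)
    if (!is.null(scales))
      alpha <- scale_report(recoded, scales)
  }
  flags <- evaluate_criteria(stats, thresholds)
  issues <- if (is.null(debrief)) NULL else
    missing_issue_screen(debrief, thresholds)
  dec <- if (is.null(decisions)) NULL else
    apply_group_decisions(decisions, flags)
  out <- list(stats = stats, flags = flags, alpha = alpha, issues = issues,
              decisions = dec, thresholds = thresholds,
              n_patients = n_patients)
  class(out) <- "item_screen"
  out
}

#' @export
print.item_screen <- function(x, ...) {
  tot <- tabulate_flags(x$flags)
  cat("Phase-III item screen: ", nrow(x$flags), " items",
      if (!is.na(x$n_patients)) paste0(", ", x$n_patients, " patients"),
      "\n", sep = "")
  cat("  pass keep rule (>= ", x$thresholds$keep_count,
      " of c1-c7, or c8): ", tot[["overall"]], " of ", nrow(x$flags),
      "\n", sep = "")
  if (!is.null(x$decisions))
    cat("  expert decisions -> final roster of ",
        x$decisions$roster_size, " items\n", sep = "")
  invisible(x)
}

#' @export
summary.item_screen <- function(object, ...) {
  out <- list(totals = tabulate_flags(object$flags),
              n_items = nrow(object$flags),
              n_patients = object$n_patients,
              alpha = object$alpha,
              issues = object$issues,
              decisions = object$decisions)
  class(out) <- "summary.item_screen"
  out
}

#' @export
print.summary.item_screen <- function(x, ...) {
  cat("Items satisfying each retention criterion (of ", x$n_items,
      "):\n", sep = "")
  print(x$totals)
  if (!is.null(x$alpha)) {
    cat("\nInternal consistency of hypothesised scales:\n")
    print(x$alpha, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$issues)) {
    add <- x$issues[x$issues$add, , drop = FALSE]
    cat("\nMissing issues to add: ",
        if (nrow(add)) paste(add$issue_label, collapse = ", ") else "none",
        "\n", sep = "")
  }
  if (!is.null(x$decisions)) print(x$decisions)
  invisible(x)
}

#' @export
as.data.frame.item_screen <- function(x, ...) {
  s <- x$stats
  f <- x$flags
  stopifnot(identical(s$item_id, f$item_id))
  tab <- data.frame(
    item_id = s$item_id,
    mean = s$mean, c1 = as.integer(f$c1),
    frac_high = s$frac_high, c2 = as.integer(f$c2),
    frac_low = s$frac_low, c3 = as.integer(f$c3),
    range = ifelse(is.na(s$observed_min), "",
                   paste(s$observed_min, "to", s$observed_max)),
    c4 = as.integer(f$c4),
    frac_upsetting = s$frac_upsetting, c5 = as.integer(f$c5),
    frac_difficult = s$frac_difficult, c6 = as.integer(f$c6),
    completion = s$completion, c7 = as.integer(f$c7),
    frac_priority = s$frac_priority, c8 = as.integer(f$c8),
    overall = as.integer(f$screen_keep),
    stringsAsFactors = FALSE)
  tab
}

#' Render an item-characteristics report
#'
#' Produces the per-item report in the conventional column order (statistic
#' followed by its criterion flag, then the overall verdict and, when
#' available, the recorded decision), with fractions rounded to
#' \code{digits} decimals only at rendering, plus a totals row counting the
#' flags. CSV and markdown renderings carry identical numeric content.
#'
#' @param x an \code{"item_screen"} object.
#' @param format \code{"csv"} or \code{"markdown"}.
#' @param decisions optional [group_decisions()] table used to append a
#'   \code{decision} column and an item \code{status} (kept items plain,
#'   deleted/changed flagged).
#' @param digits decimals for fractions; default 2.
#' @return A character scalar holding the rendered report.
#' @examples
#' ref <- qlq_aapnh_phase3()
#' scr <- item_screen(stats = ref$stats)
#' cat(substr(render_table(scr, "markdown"), 1, 200))
#' @export
render_table <- function(x, format = c("csv", "markdown"),
                         decisions = NULL, digits = 2) {
  format <- match.arg(format)
  tab <- as.data.frame(x)
  fr <- c("mean", "frac_high", "frac_low", "frac_upsetting",
          "frac_difficult", "completion", "frac_priority")
  for (f in fr) tab[[f]] <- sprintf("%.*f", digits, tab[[f]])
  if (!is.null(decisions)) {
    if (!setequal(decisions$item_id, tab$item_id))
      stop("decision item set does not match the screened items")
    i <- match(tab$item_id, decisions$item_id)
    tab$decision <- decisions$action[i]
    tab$status <- ifelse(decisions$action[i] == "KEEP", "kept",
                         tolower(decisions$action[i]))
  }
  totals <- tabulate_flags(x$flags)
  total_row <- tab[1, ]
  total_row[1, ] <- ""
  total_row$item_id <- "Total"
  for (cc in paste0("c", 1:8)) total_row[[cc]] <- totals[[cc]]
  total_row$overall <- totals[["overall"]]
  tab <- rbind(tab, total_row)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
    close(con)
    paste0(paste(out, collapse = "\n"), "\n")
  } else {
    cells <- vapply(seq_len(nrow(tab)), function(i)
      paste0("| ", paste(unlist(tab[i, ]), collapse = " | "), " |"), "")
    header <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    rule <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    paste0(paste(c(header, rule, cells), collapse = "\n"), "\n")
  }
}

#' @export
plot.item_screen <- function(x, ...) {
  tot <- tabulate_flags(x$flags)
  graphics::barplot(tot, ylab = "items satisfying criterion",
                    ylim = c(0, nrow(x$flags)),
                    main = "Retention criteria", ...)
  graphics::abline(h = nrow(x$flags), lty = 2)
  invisible(x)
}
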