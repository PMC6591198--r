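#' Evaluate the eight item-retention criteria
#'
#' Applies the a-priori retention criteria to each item's statistics:
#' \tabular{ll}{
#'   c1 \tab mean > \code{mean_floor} (strict) \cr
#'   c2 \tab frac_high > \code{high_majority} (strict) \cr
#'   c3 \tab frac_low > \code{floor_ceiling} and frac_high >
#'     \code{floor_ceiling} (both strict) \cr
#'   c4 \tab observed range spans the declared response range \cr
#'   c5 \tab frac_upsetting < \code{upsetting_max} (strict) \cr
#'   c6 \tab frac_difficult < \code{difficult_max} (strict) \cr
#'   c7 \tab completion > \code{compliance_min} (strict) \cr
#'   c8 \tab frac_priority >= \code{priority_min} (non-strict) \cr
#' }
#' Degenerate items (completion 0, so mean and range undefined) fail c1--c4
#' and are marked in the \code{degenerate} column rather than raising, so
#' screening completes on arbitrary cohorts. The screening verdict
#' \code{screen_keep} applies [screen_decision()] row-wise.
#'
#' @param stats an [item_statistics()] data frame.
#' @param thresholds a [criteria_thresholds()] object.
#' @return A data frame of class \code{"criterion_flags"} with logical
#'   columns \code{c1}..\code{c8}, \code{degenerate} and \code{screen_keep}.
#' @examples
#' s <- item_statistics("s08", mean = 2.1, observed_min = 1, observed_max = 4,
#'                      frac_low = 0.62, frac_high = 0.34, completion = 0.96,
#'                      frac_difficult = 0.07)
#' evaluate_criteria(s)  # c1,c3,c4,c5,c7 hold -> kept
#' @export
evaluate_criteria <- function(stats, thresholds = criteria_thresholds()) {
  stopifnot(inherits(thresholds, "criteria_thresholds"))
  degen <- stats$completion <= 0 | is.na(stats$mean)
  flags <- data.frame(
    item_id = stats$item_id,
    c1 = !degen & stats$mean > thresholds$mean_floor,
    c2 = stats$frac_high > thresholds$high_majority,
    c3 = stats$frac_low > thresholds$floor_ceiling &
         stats$frac_high > thresholds$floor_ceiling,
    c4 = !degen & stats$observed_min == stats$response_min &
         stats$observed_max == stats$response_max,
    c5 = stats$frac_upsetting < thresholds$upsetting_max,
    c6 = stats$frac_difficult < thresholds$difficult_max,
    c7 = stats$completion > thresholds$compliance_min,
    c8 = stats$frac_priority >= thresholds$priority_min,
    degenerate = degen,
    stringsAsFactors = FALSE)
  flags[degen, c("c1", "c2", "c3", "c4")] <- FALSE
  flags$screen_keep <- screen_decision(flags, thresholds)
  class(flags) <- c("criterion_flags", "data.frame")
  flags
}

#' Screening keep rule
#'
#' An item passes the screen when at least \code{keep_count} (default 5) of
#' criteria 1--7 hold, or criterion 8 (patient priority) holds on its own.
#' The rule is monotone: turning any criterion on never flips a keep into a
#' drop.
#'
#' @param flags a \code{"criterion_flags"} data frame (or any data frame
#'   with logical columns \code{c1}..\code{c8}).
#' @param thresholds a [criteria_thresholds()] object (for
#'   \code{keep_count}).
#' @return Logical vector, one verdict per row.
#' @export
screen_decision <- function(flags, thresholds = criteria_thresholds()) {
  cn <- paste0("c", 1:7)
  stopifnot(all(c(cn, "c8") %in% names(flags)))
  rowSums(as.matrix(flags[cn])) >= thresholds$keep_count | flags$c8
}

#' Tally criterion flags over a questionnaire
#'
#' @param flags a \code{"criterion_flags"} data frame, one row per item.
#' @return Named integer vector: how many items satisfy each of
#'   \code{c1}..\code{c8}, plus \code{overall}, the number passing the keep
#'   rule.
#' @examples
#' tabulate_flags(qlq_aapnh_phase3()$flags)  # c7 = 57, overall = 67
#' @export
tabulate_flags <- function(flags) {
  if (anyDuplicated(flags$item_id))
    stop("duplicate item ids in flags table")
  cn <- paste0("c", 1:8)
  counts <- vapply(flags[cn], sum, 0L)
  c(counts, overall = sum(flags$screen_keep))
}

#' Screen debriefing interviews for missing issues
#'
#' An issue mentioned as lacking from the questionnaire by at least
#' \code{missing_issue_min_patients} distinct patients (default 5) is
#' flagged for addition. Repeat mentions by the same patient count once.
#' Issue labels are assumed normalised upstream.
#'
#' @param debrief a [debrief_records()] object.
#' @param thresholds a [criteria_thresholds()] object.
#' @return Data frame of \code{issue_label}, \code{n_patients}, \code{add},
#'   sorted by descending count; zero rows when no issues were mentioned.
#' @export
missing_issue_screen <- function(debrief,
                                 thresholds = criteria_thresholds()) {
  iss <- debrief$issues
  if (!nrow(iss))
    return(data.frame(issue_label = character(0), n_patients = integer(0),
                      add = logical(0), stringsAsFactors = FALSE))
  iss <- iss[!duplicated(iss[c("patient_id", "issue_label")]), ]
  cnt <- table(iss$issue_label)
  out <- data.frame(issue_label = names(cnt), n_patients = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out$add <- out$n_patients >= thresholds$missing_issue_min_patients
  out[order(-out$n_patients, out$issue_label), , drop = FALSE]
}

#' Apply recorded expert decisions and reconcile with the screen
#'
#' The screen never deletes an item by itself: the final roster comes from
#' the recorded expert-panel decisions, which may override the screening
#' verdict with stated arguments. This function tallies the decisions,
#' computes the final roster size (the sum of per-item resulting counts; an
#' EXPAND contributes two or more), and, when screening flags are supplied,
#' reports the items where the expert action disagrees with the screen.
#'
#' @param decisions a [group_decisions()] data frame.
#' @param flags optional \code{"criterion_flags"} data frame over the same
#'   item set; exactly one decision per flagged item is required.
#' @return A list of class \code{"decision_summary"}: \code{n_items},
#'   counts \code{n_keep}, \code{n_delete}, \code{n_change},
#'   \code{n_expand}, \code{roster_size}, and \code{concordance} (data frame
#'   of \code{item_id}, \code{screen_keep}, \code{expert_kept},
#'   \code{agree}; \code{NULL} when no flags are given).
#' @examples
#' ref <- qlq_aapnh_phase3()
#' apply_group_decisions(ref$decisions, ref$flags)  # roster of 54 items
#' @export
apply_group_decisions <- function(decisions, flags = NULL) {
  if (!inherits(decisions, "group_decisions"))
    decisions <- group_decisions(decisions$item_id, decisions$action,
                                 decisions$resulting_items,
                                 decisions$rationale)
  concordance <- NULL
  if (!is.null(flags)) {
    miss <- setdiff(flags$item_id, decisions$item_id)
    extra <- setdiff(decisions$item_id, flags$item_id)
    if (length(miss))
      stop("no decision recorded for item(s): ",
           paste(miss, collapse = ", "))
    if (length(extra))
      stop("decision for unknown item(s): ", paste(extra, collapse = ", "))
    i <- match(flags$item_id, decisions$item_id)
    concordance <- data.frame(
      item_id = flags$item_id,
      screen_keep = flags$screen_keep,
      expert_kept = decisions$resulting_items[i] > 0L,
      stringsAsFactors = FALSE)
    concordance$agree <- concordance$screen_keep == concordance$expert_kept
  }
  out <- list(n_items = nrow(decisions),
              n_keep = sum(decisions$action == "KEEP"),
              n_delete = sum(decisions$action == "DELETE"),
              n_change = sum(decisions$action == "CHANGE"),
              n_expand = sum(decisions$action == "EXPAND"),
              roster_size = sum(decisions$resulting_items),
              concordance = concordance)
  class(out) <- "decision_summary"
  out
}

#' @export
print.decision_summary <- function(x, ...) {
  cat("Expert decisions over ", x$n_items, " items: ",
      x$n_keep, " kept, ", x$n_delete, " deleted, ",
      x$n_change, " changed, ", x$n_expand, " expanded\n", sep = "")
  cat("Final roster:", x$roster_size, "items\n")
  if (!is.null(x$concordance)) {
    dis <- x$concordance[!x$concordance$agree, , drop = FALSE]
    if (nrow(dis))
      cat("Expert overrides of the screening verdict (", nrow(dis), "): ",
          paste(dis$item_id, collapse = ", "), "\n", sep = "")
    else
      cat("Expert decisions agree with the screening verdict for all items\n")
  }
  invisible(x)
}
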