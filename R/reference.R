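#' Published per-item results of the QLQ-AA/PNH phase-III field test
#'
#' Loads the packaged transcription of the published item-analysis table of
#' the QLQ-AA/PNH field test: for each of the 69 provisional items, the mean
#' response (after recoding, n = 48 enrolled patients), the fractions
#' scoring in the lower (1--2) and upper (3--4) halves, the observed range,
#' the debriefing fractions (upsetting, difficult to understand, named as
#' priority), the completion rate, the eight printed criterion flags with
#' the overall keep verdict, and the expert group's recorded decision.
#'
#' The printed flags are stored as data rather than recomputed: the
#' published fractions are rounded to two decimals, and one row (s69,
#' upsetting fraction printed as 0.05 with its acceptability flag set) sits
#' on the rounded boundary of the strict < 0.05 rule, so flags recomputed
#' from the rounded fractions cannot reproduce that row.
#'
#' @return A list with components:
#' \describe{
#'   \item{stats}{\code{"item_statistics"} data frame (69 rows) of the
#'     printed per-item quantities.}
#'   \item{flags}{\code{"criterion_flags"} data frame with the printed
#'     criterion flags \code{c1}..\code{c8} and verdict \code{screen_keep}.}
#'   \item{decisions}{data frame of recorded expert decisions:
#'     \code{item_id}, \code{action} (KEEP/DELETE/CHANGE/EXPAND),
#'     \code{resulting_items}, \code{rationale}.}
#'   \item{n_patients}{48, the enrolled cohort size.}
#' }
#' @examples
#' ref <- qlq_aapnh_phase3()
#' tabulate_flags(ref$flags)
#' @export
qlq_aapnh_phase3 <- function() {
  path <- system.file("extdata", "qlq_aapnh_phase3_items.csv",
                      package = "qlqscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = NULL)
  if (nrow(df) != 69L)
    stop("reference table integrity error: expected 69 items, found ",
         nrow(df))
  if (anyDuplicated(df$item_id))
    stop("reference table integrity error: duplicated item ids")
  stats <- item_statistics(item_id = df$item_id, mean = df$mean,
                           observed_min = df$obs_min,
                           observed_max = df$obs_max,
                           frac_low = df$frac_low, frac_high = df$frac_high,
                           completion = df$completion,
                           frac_upsetting = df$frac_upsetting,
                           frac_difficult = df$frac_difficult,
                           frac_priority = df$frac_priority)
  flags <- data.frame(item_id = df$item_id,
                      c1 = df$c1 == 1L, c2 = df$c2 == 1L, c3 = df$c3 == 1L,
                      c4 = df$c4 == 1L, c5 = df$c5 == 1L, c6 = df$c6 == 1L,
                      c7 = df$c7 == 1L, c8 = df$c8 == 1L,
                      degenerate = FALSE,
                      screen_keep = df$screen_keep == 1L,
                      stringsAsFactors = FALSE)
  class(flags) <- c("criterion_flags", "data.frame")
  decisions <- group_decisions(item_id = df$item_id, action = df$action,
                               resulting_items = df$resulting_items,
                               rationale = df$rationale)
  list(stats = stats, flags = flags, decisions = decisions,
       n_patients = 48L)
}

#' Record a set of expert group decisions
#'
#' Each provisional item receives exactly one recorded action: KEEP (kept
#' unchanged), DELETE (dropped), CHANGE (kept with altered wording or time
#' frame), or EXPAND (split into two or more items). The resulting item
#' count must be consistent with the action: 1 for KEEP/CHANGE, 0 for
#' DELETE, >= 2 for EXPAND.
#'
#' @param item_id character vector of item ids, one decision per item.
#' @param action character vector of actions.
#' @param resulting_items integer vector of items each decision contributes
#'   to the final questionnaire; defaults to the action's canonical count
#'   (EXPAND defaulting to 2).
#' @param rationale free-text reasons; empty for plain keeps.
#' @return A data frame of class \code{"group_decisions"}.
#' @export
group_decisions <- function(item_id, action, resulting_items = NULL,
                            rationale = "") {
  item_id <- as.character(item_id)
  action <- toupper(as.character(action))
  if (anyDuplicated(item_id))
    stop("more than one decision for item(s): ",
         paste(unique(item_id[duplicated(item_id)]), collapse = ", "))
  bad <- setdiff(action, c("KEEP", "DELETE", "CHANGE", "EXPAND"))
  if (length(bad))
    stop("unknown decision action(s): ", paste(unique(bad), collapse = ", "))
  if (is.null(resulting_items))
    resulting_items <- ifelse(action == "DELETE", 0L,
                              ifelse(action == "EXPAND", 2L, 1L))
  resulting_items <- as.integer(resulting_items)
  ok <- ifelse(action == "DELETE", resulting_items == 0L,
               ifelse(action == "EXPAND", resulting_items >= 2L,
                      resulting_items == 1L))
  if (!all(ok))
    stop("resulting_items inconsistent with action for item(s): ",
         paste(item_id[!ok], collapse = ", "))
  out <- data.frame(item_id = item_id, action = action,
                    resulting_items = resulting_items,
                    rationale = rep_len(as.character(rationale),
                                        length(item_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_decisions", "data.frame")
  out
}
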