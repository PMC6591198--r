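#' Debriefing interview records
#'
#' After completing the questionnaire each patient is debriefed: how long
#' completion took, which items they found upsetting or difficult to
#' understand, which they named as especially relevant ("priority"), and
#' whether any issue was missing from the questionnaire. Free-text missing
#' issues are assumed to have been normalised to canonical labels upstream
#' (a manual coding step), so identical labels mean the same issue.
#'
#' @param flags data frame with columns \code{patient_id}, \code{item_id},
#'   \code{flag}; \code{flag} is one of \code{"upsetting"},
#'   \code{"difficult"}, \code{"priority"}. May be \code{NULL} or empty.
#' @param times data frame with columns \code{patient_id},
#'   \code{completion_minutes} (positive or \code{NA}). May be \code{NULL}.
#' @param issues data frame with columns \code{patient_id},
#'   \code{issue_label}. May be \code{NULL}.
#' @param metadata optional [item_metadata()] table; when supplied, every
#'   flagged item id must exist in it.
#' @return An object of class \code{"debrief"}.
#' @export
debrief_records <- function(flags = NULL, times = NULL, issues = NULL,
                            metadata = NULL) {
  empty <- function(...) {
    cols <- list(...)
    structure(cols, names = names(cols), class = "data.frame",
              row.names = integer(0))
  }
  if (is.null(flags))
    flags <- empty(patient_id = character(0), item_id = character(0),
                   flag = character(0))
  if (is.null(times))
    times <- empty(patient_id = character(0),
                   completion_minutes = numeric(0))
  if (is.null(issues))
    issues <- empty(patient_id = character(0), issue_label = character(0))
  flags <- as.data.frame(flags, stringsAsFactors = FALSE)
  times <- as.data.frame(times, stringsAsFactors = FALSE)
  issues <- as.data.frame(issues, stringsAsFactors = FALSE)
  need <- function(df, what, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  need(flags, "flags", c("patient_id", "item_id", "flag"))
  need(times, "times", c("patient_id", "completion_minutes"))
  need(issues, "issues", c("patient_id", "issue_label"))
  bad <- setdiff(flags$flag, c("upsetting", "difficult", "priority"))
  if (length(bad))
    stop("unknown debriefing flag(s): ", paste(unique(bad), collapse = ", "))
  if (!is.null(metadata)) {
    unknown <- setdiff(flags$item_id, metadata$item_id)
    if (length(unknown))
      stop("debriefing flags reference unknown item(s): ",
           paste(unique(unknown), collapse = ", "))
  }
  tm <- times$completion_minutes
  if (any(!is.na(tm) & tm <= 0))
    stop("completion_minutes must be positive or missing")
  structure(list(flags = flags, times = times, issues = issues),
            class = "debrief")
}

#' @export
print.debrief <- function(x, ...) {
  cat("Debriefing records: ", nrow(x$flags), " item flags, ",
      sum(!is.na(x$times$completion_minutes)), " completion times, ",
      nrow(x$issues), " missing-issue mentions\n", sep = "")
  invisible(x)
}

#' Read debriefing records from CSV files
#'
#' @param flags_path long-format CSV \code{patient_id,item_id,flag}.
#' @param times_path optional CSV \code{patient_id,completion_minutes}.
#' @param issues_path optional CSV \code{patient_id,issue_label}.
#' @param metadata optional [item_metadata()] for id validation.
#' @return An object of class \code{"debrief"}.
#' @export
read_debrief <- function(flags_path = NULL, times_path = NULL,
                         issues_path = NULL, metadata = NULL) {
  rd <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) stop("no such file: ", p)
    utils::read.csv(p, check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE,
                    colClasses = "character")
  }
  times <- rd(times_path)
  if (!is.null(times))
    times$completion_minutes <- as.numeric(times$completion_minutes)
  debrief_records(flags = rd(flags_path), times = times,
                  issues = rd(issues_path), metadata = metadata)
}

#' Write debriefing records to CSV files
#'
#' @param debrief a [debrief_records()] object.
#' @param dir output directory; files \code{debrief_flags.csv},
#'   \code{debrief_times.csv} and \code{debrief_issues.csv} are written.
#' @return The directory, invisibly.
#' @export
write_debrief <- function(debrief, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(debrief$flags, file.path(dir, "debrief_flags.csv"),
                   row.names = FALSE, na = "", quote = FALSE)
  utils::write.csv(debrief$times, file.path(dir, "debrief_times.csv"),
                   row.names = FALSE, na = "", quote = FALSE)
  utils::write.csv(debrief$issues, file.path(dir, "debrief_issues.csv"),
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(dir)
}

#' Summarise questionnaire completion times
#'
#' @param debrief a [debrief_records()] object, or a numeric vector of
#'   completion times in minutes.
#' @return Named numeric vector with \code{median}, \code{mean}, \code{min},
#'   \code{max} and \code{n} over the non-missing times. The median of an
#'   even count is the midpoint of the two central values.
#' @examples
#' completion_time_summary(c(5, 7, 11, 13))  # median 9
#' @export
completion_time_summary <- function(debrief) {
  tm <- if (inherits(debrief, "debrief"))
    debrief$times$completion_minutes else as.numeric(debrief)
  tm <- tm[!is.na(tm)]
  if (!length(tm)) stop("no non-missing completion times")
  c(median = stats::median(tm), mean = mean(tm),
    min = min(tm), max = max(tm), n = length(tm))
}
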