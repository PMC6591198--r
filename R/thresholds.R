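#' Retention-criteria thresholds
#'
#' Bundle of the cut-offs used by the eight-criterion item retention screen
#' and the missing-issue rule. The defaults are the a-priori values of the
#' QLQ-AA/PNH phase-III field test: an item is kept when at least
#' \code{keep_count} of criteria 1--7 hold, or criterion 8 holds.
#'
#' The criteria are, for an item on a 1--4 Likert scale:
#' \enumerate{
#'   \item relevance: mean response > \code{mean_floor};
#'   \item relevance: more than \code{high_majority} of the cohort score 3 or 4;
#'   \item no floor or ceiling effect: more than \code{floor_ceiling} of the
#'     cohort in each half of the scale;
#'   \item range: observed responses span the full response range;
#'   \item acceptability: fewer than \code{upsetting_max} find the item upsetting;
#'   \item easiness: fewer than \code{difficult_max} find it difficult to understand;
#'   \item compliance: more than \code{compliance_min} complete the item;
#'   \item priority: at least \code{priority_min} name it as especially relevant.
#' }
#' All inequalities are strict except criterion 8, which is non-strict.
#'
#' @param mean_floor minimum item mean (criterion 1); default 1.5.
#' @param high_majority fraction of the cohort scoring in the upper half
#'   needed for criterion 2; default 0.50.
#' @param floor_ceiling minimum fraction in each half of the scale
#'   (criterion 3); default 0.10.
#' @param upsetting_max maximum fraction finding the item upsetting
#'   (criterion 5); default 0.05.
#' @param difficult_max maximum fraction finding the item difficult to
#'   understand (criterion 6); default 0.05.
#' @param compliance_min minimum completion rate (criterion 7); default 0.95.
#' @param priority_min minimum fraction naming the item especially relevant
#'   (criterion 8); default 0.02.
#' @param keep_count how many of criteria 1--7 must hold for the screen to
#'   keep an item when criterion 8 fails; default 5.
#' @param missing_issue_min_patients distinct patients that must mention the
#'   same missing issue before it is flagged for addition; default 5.
#' @return An object of class \code{"criteria_thresholds"}.
#' @seealso [evaluate_criteria()], [screen_decision()], [missing_issue_screen()]
#' @examples
#' criteria_thresholds()
#' criteria_thresholds(compliance_min = 0.90)
#' @export
criteria_thresholds <- function(mean_floor = 1.5,
                                high_majority = 0.50,
                                floor_ceiling = 0.10,
                                upsetting_max = 0.05,
                                difficult_max = 0.05,
                                compliance_min = 0.95,
                                priority_min = 0.02,
                                keep_count = 5L,
                                missing_issue_min_patients = 5L) {
  t <- list(mean_floor = as.numeric(mean_floor),
            high_majority = as.numeric(high_majority),
            floor_ceiling = as.numeric(floor_ceiling),
            upsetting_max = as.numeric(upsetting_max),
            difficult_max = as.numeric(difficult_max),
            compliance_min = as.numeric(compliance_min),
            priority_min = as.numeric(priority_min),
            keep_count = as.integer(keep_count),
            missing_issue_min_patients = as.integer(missing_issue_min_patients))
  frac <- c("high_majority", "floor_ceiling", "upsetting_max",
            "difficult_max", "compliance_min", "priority_min")
  for (f in frac) {
    v <- t[[f]]
    if (!is.finite(v) || v <= 0 || v >= 1)
      stop("threshold '", f, "' must lie in (0, 1), got ", v)
  }
  if (is.na(t$keep_count) || t$keep_count < 1L || t$keep_count > 7L)
    stop("keep_count must lie in 1..7")
  if (is.na(t$missing_issue_min_patients) || t$missing_issue_min_patients < 1L)
    stop("missing_issue_min_patients must be a positive integer")
  class(t) <- "criteria_thresholds"
  t
}

#' @export
print.criteria_thresholds <- function(x, ...) {
  cat("Item retention thresholds (keep if >=", x$keep_count,
      "of criteria 1-7, or criterion 8):\n")
  cat(sprintf("  c1 mean > %.2f | c2 upper-half > %.0f%% | c3 both halves > %.0f%%\n",
              x$mean_floor, 100 * x$high_majority, 100 * x$floor_ceiling))
  cat(sprintf("  c4 full range | c5 upsetting < %.0f%% | c6 difficult < %.0f%%\n",
              100 * x$upsetting_max, 100 * x$difficult_max))
  cat(sprintf("  c7 completion > %.0f%% | c8 priority >= %.0f%%\n",
              100 * x$compliance_min, 100 * x$priority_min))
  cat("  missing issue added when mentioned by >=",
      x$missing_issue_min_patients, "patients\n")
  invisible(x)
}

#' Read threshold overrides from a YAML file
#'
#' The file may set any subset of the [criteria_thresholds()] fields; fields
#' not mentioned keep their defaults.
#'
#' @param path path to a YAML file of named threshold values.
#' @return An object of class \code{"criteria_thresholds"}.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(criteria_thresholds))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown threshold field(s): ", paste(bad, collapse = ", "))
  do.call(criteria_thresholds, raw)
}
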