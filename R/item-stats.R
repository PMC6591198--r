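#' Recode reverse-worded items
#'
#' Items worded positively (a high raw response means fewer problems) are
#' reflected about the midpoint of their response range, x -> (min + max) - x
#' (5 - x on a 1--4 scale), so that after recoding higher values always
#' indicate more problems. Missing responses are preserved, other items are
#' untouched, and applying the operation twice restores the original matrix.
#'
#' @param x response matrix (patients x items, \code{NA} = missing).
#' @param metadata an [item_metadata()] table whose \code{reverse_coded}
#'   column marks the items to reflect.
#' @return The recoded matrix.
#' @export
recode_reverse <- function(x, metadata) {
  rev_ids <- metadata$item_id[metadata$reverse_coded]
  unknown <- setdiff(rev_ids, colnames(x))
  if (length(unknown))
    stop("reverse-coded item(s) absent from responses: ",
         paste(unknown, collapse = ", "))
  for (id in rev_ids) {
    i <- match(id, metadata$item_id)
    x[, id] <- (metadata$response_min[i] + metadata$response_max[i]) - x[, id]
  }
  x
}

#' Construct a per-item statistics table
#'
#' Low-level constructor used both by [compute_item_stats()] and to wrap
#' externally reported quantities (such as a published item table). All
#' fractions are of the enrolled cohort; a missing response counts in
#' neither the low nor the high category, so
#' \code{frac_low + frac_high = completion}.
#'
#' @param item_id item identifiers.
#' @param mean mean of the non-missing responses (\code{NA} if none).
#' @param observed_min,observed_max observed response range (\code{NA} if no
#'   responses).
#' @param frac_low,frac_high fractions of the cohort scoring in the lower /
#'   upper half of the scale.
#' @param completion fraction of the cohort with a non-missing response.
#' @param frac_upsetting,frac_difficult,frac_priority debriefing fractions.
#' @param response_min,response_max declared response range (default 1--4).
#' @return A data frame of class \code{"item_statistics"}.
#' @export
item_statistics <- function(item_id, mean, observed_min, observed_max,
                            frac_low, frac_high, completion,
                            frac_upsetting = 0, frac_difficult = 0,
                            frac_priority = 0,
                            response_min = 1L, response_max = 4L) {
  n <- length(item_id)
  out <- data.frame(item_id = as.character(item_id),
                    mean = as.numeric(mean),
                    observed_min = as.integer(observed_min),
                    observed_max = as.integer(observed_max),
                    frac_low = as.numeric(frac_low),
                    frac_high = as.numeric(frac_high),
                    completion = as.numeric(completion),
                    frac_upsetting = rep_len(as.numeric(frac_upsetting), n),
                    frac_difficult = rep_len(as.numeric(frac_difficult), n),
                    frac_priority = rep_len(as.numeric(frac_priority), n),
                    response_min = rep_len(as.integer(response_min), n),
                    response_max = rep_len(as.integer(response_max), n),
                    stringsAsFactors = FALSE)
  fr <- c("frac_low", "frac_high", "completion", "frac_upsetting",
          "frac_difficult", "frac_priority")
  for (f in fr)
    if (any(out[[f]] < 0 | out[[f]] > 1, na.rm = TRUE))
      stop("'", f, "' must lie in [0, 1]")
  class(out) <- c("item_statistics", "data.frame")
  out
}

#' Per-item descriptive statistics
#'
#' For every item: the mean and observed range over non-missing responses,
#' the fractions of the enrolled cohort scoring in the lower (e.g. 1--2) and
#' upper (e.g. 3--4) halves of the scale, the completion rate, and the
#' debriefing fractions (upsetting / difficult to understand / named as
#' priority). All fractions use the enrolled cohort size as denominator, so
#' missing responses count in neither half and
#' \code{frac_low + frac_high == completion} identically. Reverse-coded
#' items must already have been recoded (see [recode_reverse()]).
#'
#' An item with no responses at all gets \code{NA} mean and range and
#' completion 0.
#'
#' @param x recoded response matrix.
#' @param debrief optional [debrief_records()]; when absent all debriefing
#'   fractions are 0.
#' @param metadata optional [item_metadata()] table (default: 1--4 range for
#'   all columns of \code{x}).
#' @param n_enrolled denominator for all fractions; defaults to
#'   \code{nrow(x)}, the enrolled cohort.
#' @return A data frame of class \code{"item_statistics"}, one row per item.
#' @examples
#' x <- matrix(c(1L, 2L, 3L, NA), 4, 1,
#'             dimnames = list(paste0("p", 1:4), "a"))
#' compute_item_stats(x)  # mean 2, completion 0.75
#' @export
compute_item_stats <- function(x, debrief = NULL, metadata = NULL,
                               n_enrolled = nrow(x)) {
  if (is.null(metadata)) metadata <- item_metadata(colnames(x))
  validate_responses(x, metadata)
  if (n_enrolled < 1L) stop("n_enrolled must be at least 1")
  idx <- match(colnames(x), metadata$item_id)
  lo <- metadata$response_min[idx]
  hi <- metadata$response_max[idx]
  mid <- (lo + hi) / 2
  k <- ncol(x)
  obs <- colSums(!is.na(x))
  mean_v <- obs_min <- obs_max <- rep(NA_real_, k)
  frac_low <- frac_high <- numeric(k)
  for (j in seq_len(k)) {
    v <- x[!is.na(x[, j]), j]
    if (length(v)) {
      mean_v[j] <- mean(v)
      obs_min[j] <- min(v)
      obs_max[j] <- max(v)
      frac_low[j] <- sum(v <= mid[j]) / n_enrolled
      frac_high[j] <- sum(v > mid[j]) / n_enrolled
    }
  }
  fl <- if (is.null(debrief)) NULL else
    debrief$flags[!duplicated(debrief$flags[c("patient_id", "item_id",
                                              "flag")]), ]
  dfrac <- function(which) {
    if (is.null(fl)) return(numeric(k))
    sub <- fl[fl$flag == which, ]
    as.numeric(table(factor(sub$item_id, levels = colnames(x)))) / n_enrolled
  }
  # completion is the sum of the two category fractions by construction, so
  # the accounting identity frac_low + frac_high == completion is bit-exact
  item_statistics(item_id = colnames(x), mean = mean_v,
                  observed_min = obs_min, observed_max = obs_max,
                  frac_low = frac_low, frac_high = frac_high,
                  completion = frac_low + frac_high,
                  frac_upsetting = dfrac("upsetting"),
                  frac_difficult = dfrac("difficult"),
                  frac_priority = dfrac("priority"),
                  response_min = lo, response_max = hi)
}

# round half away from zero (21/48 -> 44%), unlike round()'s half-to-even
round_half_up <- function(x) trunc(x + 0.5 * sign(x))

#' Cohort characteristics summary
#'
#' Counts and integer percentages per category for categorical variables;
#' median, mean and range for numeric variables. Percentages round half away
#' from zero (21 of 48 -> 44%).
#'
#' @param clinical data frame with one row per patient.
#' @param categorical character vector naming the categorical columns; by
#'   default every character or factor column.
#' @param levels optional named list giving the declared vocabulary per
#'   categorical column; values outside it raise an error, and declared
#'   categories with zero patients are reported as 0%.
#' @return A list with components \code{n}, \code{categorical} (one data
#'   frame of \code{variable}, \code{category}, \code{n}, \code{percent} per
#'   row) and \code{numeric} (data frame of \code{variable}, \code{median},
#'   \code{mean}, \code{min}, \code{max}).
#' @examples
#' cl <- data.frame(disease = rep(c("AA", "PNH", "AA+PNH"), c(21, 13, 14)))
#' cohort_summary(cl)$categorical  # AA 21 44%
#' @export
cohort_summary <- function(clinical, categorical = NULL, levels = NULL) {
  n <- nrow(clinical)
  if (is.null(categorical))
    categorical <- names(clinical)[vapply(clinical, function(v)
      is.character(v) || is.factor(v), NA)]
  cat_rows <- list()
  for (v in categorical) {
    vals <- as.character(clinical[[v]])
    lev <- if (!is.null(levels) && !is.null(levels[[v]])) levels[[v]] else
      unique(vals[!is.na(vals)])
    bad <- setdiff(vals[!is.na(vals)], lev)
    if (length(bad))
      stop("unknown category in '", v, "': ",
           paste(unique(bad), collapse = ", "))
    cnt <- table(factor(vals, levels = lev))
    cat_rows[[v]] <- data.frame(variable = v, category = names(cnt),
                                n = as.integer(cnt),
                                percent = round_half_up(100 * as.integer(cnt) / n),
                                stringsAsFactors = FALSE)
  }
  num_cols <- setdiff(names(clinical)[vapply(clinical, is.numeric, NA)],
                      categorical)
  num_rows <- lapply(num_cols, function(v) {
    x <- clinical[[v]][!is.na(clinical[[v]])]
    data.frame(variable = v, median = stats::median(x), mean = mean(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  })
  list(n = n,
       categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
       numeric = if (length(num_rows)) do.call(rbind, num_rows) else NULL)
}
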