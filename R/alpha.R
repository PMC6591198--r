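#' Cronbach's alpha
#'
#' Internal-consistency coefficient of a k-item scale,
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right),}
#' where \eqn{s_i^2} are the item variances and \eqn{s_T^2} the variance of
#' the total score, both with the n-1 divisor, computed over listwise
#' complete patients (rows with any missing scale item are dropped).
#'
#' Alpha is undefined (returned as \code{NA} with a warning) when fewer
#' than three complete patients remain or the total-score variance is zero.
#'
#' @param x numeric matrix or data frame, patients in rows.
#' @param items optional character vector selecting the scale's columns
#'   (default: all columns).
#' @param missing how to handle missing responses; only \code{"listwise"}
#'   is implemented.
#' @return A single number \eqn{\le 1}, or \code{NA} when undefined.
#' @examples
#' set.seed(1)
#' f <- rnorm(200)
#' x <- sapply(1:4, function(i) 0.8 * f + 0.6 * rnorm(200))
#' cronbach_alpha(x)
#' @export
cronbach_alpha <- function(x, items = NULL, missing = c("listwise")) {
  missing <- match.arg(missing)
  x <- as.matrix(x)
  if (!is.null(items)) {
    unknown <- setdiff(items, colnames(x))
    if (length(unknown))
      stop("scale item(s) absent from responses: ",
           paste(unknown, collapse = ", "))
    x <- x[, items, drop = FALSE]
  }
  k <- ncol(x)
  if (k < 2L) stop("Cronbach's alpha needs at least 2 items, got ", k)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) {
    warning("fewer than 3 listwise-complete patients; alpha undefined")
    return(NA_real_)
  }
  total_var <- stats::var(rowSums(x))
  if (!is.finite(total_var) || total_var <= 0) {
    warning("zero total-score variance; alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}

#' Internal consistency of hypothesised scales
#'
#' One row per scale: its size, the number of patients remaining after
#' listwise deletion within the scale, and Cronbach's alpha. A scale whose
#' alpha is undefined (too few complete patients, zero variance) is
#' reported as \code{NA} rather than aborting the table.
#'
#' @param x response matrix (recoded; see [recode_reverse()]).
#' @param scales named list of character vectors of item ids, or a list of
#'   [scale_definition()] objects.
#' @return Data frame with columns \code{scale}, \code{k}, \code{n},
#'   \code{alpha}.
#' @export
scale_report <- function(x, scales) {
  if (length(scales) && inherits(scales[[1]], "scale_definition")) {
    nm <- vapply(scales, `[[`, "", "name")
    scales <- lapply(scales, `[[`, "item_ids")
    names(scales) <- nm
  }
  if (is.null(names(scales)) || any(!nzchar(names(scales))))
    stop("scales must be named")
  rows <- lapply(names(scales), function(nm) {
    ids <- scales[[nm]]
    unknown <- setdiff(ids, colnames(x))
    if (length(unknown))
      stop("scale '", nm, "' references unknown item(s): ",
           paste(unknown, collapse = ", "))
    sub <- x[, ids, drop = FALSE]
    n_complete <- sum(stats::complete.cases(sub))
    a <- tryCatch(suppressWarnings(cronbach_alpha(sub)),
                  error = function(e) NA_real_)
    data.frame(scale = nm, k = length(ids), n = n_complete, alpha = a,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Alpha of a scale with exchangeable items
#'
#' Spearman-Brown closed form: for k items with a common inter-item
#' correlation r, \eqn{\alpha = kr / (1 + (k-1)r)}. Under the simulator's
#' single-factor model with loading \eqn{\lambda}, the continuous scores
#' have \eqn{r = \lambda^2}, so this is the population alpha the simulator's
#' latent scores recover; the discretized (ordinal) alpha is attenuated
#' below it.
#'
#' @param k number of items.
#' @param r common inter-item correlation.
#' @return Population alpha.
#' @examples
#' spearman_brown_alpha(5, 0.64)  # 0.899
#' @export
spearman_brown_alpha <- function(k, r) k * r / (1 + (k - 1) * r)
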