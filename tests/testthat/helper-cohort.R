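# shared builders for small in-code fixtures

toy_matrix <- function(values, n_items = NULL, item_ids = NULL) {
  if (is.null(item_ids)) {
    if (is.null(n_items)) n_items <- 1L
    item_ids <- letters[seq_len(n_items)]
  }
  x <- matrix(as.integer(values), ncol = length(item_ids))
  dimnames(x) <- list(paste0("p", seq_len(nrow(x))), item_ids)
  x
}

random_cohort <- function(n = 20, k = 6, miss = 0.1, seed = 1) {
  set.seed(seed)
  x <- matrix(sample(1:4, n * k, replace = TRUE), n, k,
              dimnames = list(paste0("p", 1:n), paste0("i", 1:k)))
  x[matrix(runif(n * k) < miss, n, k)] <- NA_integer_
  x
}

flag_debrief <- function(..., times = NULL, issues = NULL, metadata = NULL) {
  triples <- list(...)
  flags <- if (length(triples))
    do.call(rbind, lapply(triples, function(tr)
      data.frame(patient_id = tr[[1]], item_id = tr[[2]], flag = tr[[3]],
                 stringsAsFactors = FALSE)))
  debrief_records(flags = flags, times = times, issues = issues,
                  metadata = metadata)
}

# independent covariance-matrix oracle for Cronbach's alpha:
# alpha = (k/(k-1)) * (1 - tr(S) / (1' S 1)) over listwise-complete rows
alpha_cov_oracle <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  S <- stats::cov(x)
  k <- ncol(S)
  (k / (k - 1)) * (1 - sum(diag(S)) / sum(S))
}
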