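#' Multi-threshold test accuracy dataset
#'
#' The central data container: per-study, per-disease-group counts of
#' patients whose test result exceeds each reported threshold. A study
#' contributes a disease-free group (`group = 1`) and a diseased group
#' (`group = 2`), each of size `N`, and for each of its thresholds
#' `C_1 < ... < C_T` the number of results strictly greater than the
#' threshold. Those counts are necessarily non-increasing in the threshold,
#' and validation enforces this.
#'
#' @param counts data frame with columns `study_id`, `group`, `N`,
#'   `threshold`, `count_above` (one row per study x group x threshold).
#'   `group` may be coded `0/1` (disease indicator), `1/2`,
#'   `"disease_free"/"diseased"` or `"control"/"case"`; it is normalised to
#'   the integers 1 (disease-free) and 2 (diseased).
#' @param covariates optional data frame with column `study_id` plus one
#'   numeric column per study-level covariate (one row per study).
#' @return an object of class `"dta_data"`: a list with elements `counts`
#'   (canonically sorted, normalised) and `covariates` (or `NULL`).
#' @seealso [read_dta()], [dta_from_accuracy()], [simulate_dta()]
#' @export
dta_data <- function(counts, covariates = NULL) {
  required <- c("study_id", "group", "N", "threshold", "count_above")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols))
    stop("count data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  counts <- as.data.frame(counts)[required]
  counts$study_id <- as.character(counts$study_id)
  counts$group <- normalize_group(counts$group)
  counts$N <- as.integer(counts$N)
  counts$threshold <- as.numeric(counts$threshold)
  counts$count_above <- as.integer(counts$count_above)
  counts <- counts[order(counts$study_id, counts$group, counts$threshold), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"study_id" %in% names(covariates))
      stop("covariate data must have a `study_id` column", call. = FALSE)
    covariates$study_id <- as.character(covariates$study_id)
    covariates <- covariates[order(covariates$study_id), , drop = FALSE]
    rownames(covariates) <- NULL
  }
  x <- structure(list(counts = counts, covariates = covariates),
                 class = "dta_data")
  validate_dta(x)
  x
}

# Map accepted group codings to j = 1 (disease-free) / 2 (diseased).
normalize_group <- function(g) {
  gc <- tolower(trimws(as.character(g)))
  map <- c("0" = 1L, "1" = 2L, "disease_free" = 1L, "diseased" = 2L,
           "control" = 1L, "case" = 2L)
  if (all(gc %in% c("1", "2")) && any(gc == "2")) {
    # already j-coded
    return(as.integer(gc))
  }
  if (!all(gc %in% names(map)))
    stop("unrecognised group labels: ",
         paste(unique(gc[!gc %in% names(map)]), collapse = ", "),
         "; accepted codings are 0/1, disease_free/diseased, control/case",
         call. = FALSE)
  unname(map[gc])
}

#' Validate a multi-threshold dataset
#'
#' Checks the structural invariants of the count data: positive group
#' sizes, counts within `[0, N]`, strictly increasing thresholds with no
#' duplicates within a study-group, counts non-increasing along the
#' threshold sequence, and both disease groups present for every study.
#' Errors name the offending study.
#'
#' @param x a `"dta_data"` object (or list with the same shape).
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_dta <- function(x) {
  d <- x$counts
  if (nrow(d) == 0L) stop("dataset has no rows", call. = FALSE)
  if (any(!is.finite(d$threshold)))
    stop("non-finite threshold values present", call. = FALSE)
  for (key in split(seq_len(nrow(d)), list(d$study_id, d$group), drop = TRUE)) {
    rows <- d[key, , drop = FALSE]
    sid <- rows$study_id[1]
    if (length(unique(rows$N)) != 1L || rows$N[1] < 1L)
      stop("study '", sid, "': group size N must be a single positive ",
           "integer per study-group", call. = FALSE)
    if (anyDuplicated(rows$threshold))
      stop("study '", sid, "': duplicated thresholds within a study-group",
           call. = FALSE)
    if (is.unsorted(rows$threshold, strictly = TRUE))
      stop("study '", sid, "': thresholds must be strictly increasing",
           call. = FALSE)
    if (any(rows$count_above < 0L) || any(rows$count_above > rows$N))
      stop("study '", sid, "': counts must lie in [0, N]", call. = FALSE)
    if (is.unsorted(rev(rows$count_above)))
      stop("study '", sid, "': counts above threshold must be ",
           "non-increasing with increasing threshold", call. = FALSE)
  }
  tab <- table(unique(d[c("study_id", "group")])$study_id)
  incomplete <- names(tab)[tab < 2L]
  if (length(incomplete))
    stop("study '", incomplete[1],
         "': both disease groups must be present", call. = FALSE)
  if (!is.null(x$covariates)) {
    cov <- x$covariates
    if (anyDuplicated(cov$study_id))
      stop("covariate data must have one row per study", call. = FALSE)
    extra <- setdiff(cov$study_id, d$study_id)
    if (length(extra))
      stop("covariate data contains unknown study '", extra[1], "'",
           call. = FALSE)
    vals <- cov[setdiff(names(cov), "study_id")]
    if (length(vals) && any(!vapply(vals, is.numeric, logical(1))))
      stop("covariate values must be numeric", call. = FALSE)
    if (length(vals) && any(!is.finite(as.matrix(vals))))
      stop("covariate values must be finite", call. = FALSE)
  }
  invisible(x)
}

#' Read a multi-threshold dataset from long-format CSV
#'
#' The canonical on-disk format is long: one row per study x group x
#' threshold, with header columns `study_id`, `group`, `N`, `threshold`,
#' `count_above`. Counts are of test results strictly greater than the
#' threshold. An optional covariate CSV has `study_id` plus one column per
#' study-level covariate.
#'
#' @param path path to the count CSV.
#' @param covariate_path optional path to the covariate CSV.
#' @return a validated [dta_data] object.
#' @export
read_dta <- function(path, covariate_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  covariates <- NULL
  if (!is.null(covariate_path)) {
    if (!file.exists(covariate_path))
      stop("file not found: ", covariate_path, call. = FALSE)
    covariates <- utils::read.csv(covariate_path, stringsAsFactors = FALSE)
  }
  dta_data(counts, covariates)
}

#' Write a multi-threshold dataset to long-format CSV
#'
#' Inverse of [read_dta()]: after canonical sorting the round trip
#' reproduces the records exactly.
#'
#' @param x a [dta_data] object.
#' @param path output path for the count CSV.
#' @param covariate_path optional output path for the covariate CSV.
#' @return `x`, invisibly.
#' @export
write_dta <- function(x, path, covariate_path = NULL) {
  stopifnot(inherits(x, "dta_data"))
  cts <- x$counts
  # 17 significant digits guarantee an exact double round trip
  cts$threshold <- sprintf("%.17g", cts$threshold)
  utils::write.csv(cts, path, row.names = FALSE, quote = FALSE)
  if (!is.null(covariate_path) && !is.null(x$covariates))
    utils::write.csv(x$covariates, covariate_path, row.names = FALSE,
                     quote = FALSE)
  invisible(x)
}

#' Build a single-study dataset from reported sensitivity and specificity
#'
#' Converts accuracy fractions back to the count scale:
#' `count_above` in the diseased group is `round(sens * N_diseased)` and in
#' the disease-free group `round((1 - spec) * N_disease_free)`. Monotonicity
#' of the reconstructed counts is re-checked after rounding; if rounding
#' breaks it, an error is raised for the caller to resolve (the package
#' never guesses which of two conflicting counts is correct).
#'
#' @param N_disease_free,N_diseased group sizes.
#' @param thresholds strictly increasing numeric thresholds.
#' @param sens,spec sensitivity and specificity at each threshold, in
#'   `[0, 1]`, same length as `thresholds`.
#' @param study_id label for the study.
#' @return a [dta_data] object with one study.
#' @export
dta_from_accuracy <- function(N_disease_free, N_diseased, thresholds,
                              sens, spec, study_id = "study1") {
  stopifnot(length(sens) == length(thresholds),
            length(spec) == length(thresholds))
  if (any(sens < 0 | sens > 1) || any(spec < 0 | spec > 1))
    stop("sens and spec must lie in [0, 1]", call. = FALSE)
  x2 <- as.integer(round(sens * N_diseased))
  x1 <- as.integer(round((1 - spec) * N_disease_free))
  counts <- data.frame(
    study_id = study_id,
    group = rep(1:2, each = length(thresholds)),
    N = rep(c(N_disease_free, N_diseased), each = length(thresholds)),
    threshold = rep(thresholds, 2),
    count_above = c(x1, x2))
  dta_data(counts)
}

#' Conditional binomial decomposition of a study-group's counts
#'
#' The multinomial distribution of a group's results over the `T + 1`
#' threshold-delimited categories factorises into a chain of conditional
#' binomials: the count above the first threshold out of `N` trials, then
#' each subsequent count out of the previous one. This returns the
#' `(trials, successes)` pairs of that chain; successes at step `t` equal
#' the trials at step `t + 1`.
#'
#' @param N group size.
#' @param counts_above non-increasing integer counts above each threshold.
#' @return data frame with columns `trials` and `successes`, one row per
#'   threshold.
#' @examples
#' conditional_counts(10, c(8, 5))  # trials 10, 8; successes 8, 5
#' @export
conditional_counts <- function(N, counts_above) {
  stopifnot(length(counts_above) >= 1L, N >= max(counts_above))
  if (is.unsorted(rev(counts_above)))
    stop("counts_above must be non-increasing", call. = FALSE)
  data.frame(trials = c(N, counts_above[-length(counts_above)]),
             successes = counts_above)
}

#' @export
print.dta_data <- function(x, ...) {
  d <- x$counts
  sg <- unique(d[c("study_id", "group")])
  cat("Multi-threshold test accuracy dataset\n")
  cat(sprintf("  %d studies, %d study-group series, %d count rows\n",
              length(unique(d$study_id)), nrow(sg), nrow(d)))
  cat(sprintf("  thresholds: %g to %g; group sizes: %d to %d\n",
              min(d$threshold), max(d$threshold), min(d$N), max(d$N)))
  if (!is.null(x$covariates))
    cat("  covariates:",
        paste(setdiff(names(x$covariates), "study_id"), collapse = ", "),
        "\n")
  invisible(x)
}

# Internal: flat observation table with factorisation bookkeeping.
# One row per (study, group, threshold) with trials, previous-row index and
# first-threshold flag, plus integer study index.
obs_table <- function(data) {
  d <- data$counts
  sid <- sort(unique(d$study_id))
  d$study <- match(d$study_id, sid)
  d <- d[order(d$study, d$group, d$threshold), , drop = FALSE]
  pieces <- split(seq_len(nrow(d)), list(d$study, d$group), drop = TRUE)
  trials <- integer(nrow(d)); first <- integer(nrow(d)); prev <- integer(nrow(d))
  for (idx in pieces) {
    x <- d$count_above[idx]
    trials[idx] <- c(d$N[idx[1]], x[-length(x)])
    first[idx] <- c(1L, rep(0L, length(idx) - 1L))
    prev[idx] <- c(idx[1], idx[-length(idx)])
  }
  d$trials <- trials; d$first <- first; d$prev <- prev
  attr(d, "study_ids") <- sid
  d
}
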