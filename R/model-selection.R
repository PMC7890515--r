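#' Split responses into train and test sets, stratified by participant
#'
#' Each participant contributes `train_fraction` of their responses to the
#' training set (rounded to the nearest response), so the pooled split also
#' lands within a fraction of a percent of the target for realistic cohort
#' sizes. The partition is exact and disjoint, and deterministic for a given
#' seed.
#'
#' @param responses Response table with a `participant_id` column.
#' @param train_fraction Fraction per participant for training (default 0.8).
#' @param seed Mandatory seed.
#' @param min_responses Participants below this count are an error (default
#'   5), listed by id.
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(responses, train_fraction = 0.8, seed,
                             min_responses = 5) {
  if (missing(seed) || is.null(seed)) stop("split_train_test requires a seed")
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- table(responses$participant_id)
  low <- names(counts)[counts < min_responses]
  if (length(low))
    stop("participant(s) with fewer than ", min_responses, " responses: ",
         paste(low, collapse = ", "))
  set.seed(seed)
  in_train <- logical(nrow(responses))
  for (p in names(counts)) {
    rows <- which(responses$participant_id == p)
    n_train <- round(length(rows) * train_fraction)
    n_train <- min(max(n_train, 1L), length(rows) - 1L)
    in_train[sample(rows, n_train)] <- TRUE
  }
  list(train = responses[in_train, , drop = FALSE],
       test = responses[!in_train, , drop = FALSE])
}

#' Bayesian R-squared of a fitted graded response model
#'
#' For each posterior draw, the variance of the predicted expected scores
#' across observations divided by itself plus the variance of the residuals
#' (observed minus predicted expected score). The prediction target is the
#' expected ordinal score (mean of the category values 0-3). Computed with
#' group-level effects included (`re = TRUE`) or zeroed out (`re = FALSE`,
#' the new-cluster convention).
#'
#' @param fit A [grm()] fit.
#' @param newdata Optional data rows; defaults to the training data.
#' @param re Include group-level deviations.
#' @return Numeric vector, one R-squared per posterior draw, each in
#'   `[0, 1]`. If the predictions carry no variance at all the ratio is
#'   undefined and `NaN` is returned for those draws.
#' @export
bayes_r2 <- function(fit, newdata = NULL, re = TRUE) {
  es <- predict(fit, newdata = newdata, type = "expected", re = re,
                summary = FALSE)
  y <- if (is.null(newdata)) fit$data$y else newdata$score
  var_fit <- apply(es, 1, stats::var)
  var_res <- apply(sweep(-es, 2, -y), 1, stats::var)
  tot <- var_fit + var_res
  out <- ifelse(tot > 0, var_fit / tot, NaN)
  if (anyNA(out)) warning("zero total variance in some draws; R2 undefined")
  out
}

#' Held-out mean absolute error of the posterior-mean expected score
#'
#' For each test response, the posterior mean of the expected score is the
#' point prediction; the MAE is the mean absolute difference to the observed
#' score, in score units (0-3). With `re = TRUE`, group deviations of
#' participants, photos and species seen in training are carried over and
#' unseen units get zero deviations; with `re = FALSE` all deviations are
#' zero (pure population-level prediction).
#'
#' @param fit A [grm()] fit.
#' @param test Held-out rows: a [grm_frame()] or a scored response table
#'   (then `taxonomy` is required). Must be non-empty and disjoint from the
#'   training rows.
#' @param taxonomy Needed when `test` is a raw scored table.
#' @param re Include group-level deviations for units seen in training.
#' @return Mean absolute error in score units.
#' @export
heldout_mae <- function(fit, test, taxonomy = NULL, re = TRUE) {
  if (!inherits(test, "grm_frame")) {
    if (is.null(taxonomy)) stop("supply taxonomy for a raw response table")
    test <- grm_frame(test, taxonomy)
  }
  if (nrow(test) == 0) stop("empty test set")
  train_keys <- paste(fit$data$frame$participant_id, fit$data$frame$photo_id)
  if (any(paste(test$participant_id, test$photo_id) %in% train_keys))
    stop("test set overlaps the training data")
  pred <- predict(fit, newdata = test, type = "expected", re = re,
                  summary = TRUE)
  mean(abs(test$score - pred$mean))
}
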