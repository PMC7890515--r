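#' Graded-response category probabilities
#'
#' The four-category graded response model on the cumulative-logit scale:
#' `P(Y <= k) = plogis(alpha * (tau[k+1] - eta))` for k = 0, 1, 2, and the
#' category probabilities are the adjacent differences. Higher linear
#' predictor `eta` shifts mass towards higher scores; the discrimination
#' `alpha` sharpens the transition.
#'
#' @param eta Linear predictor (vectorized).
#' @param alpha Positive discrimination (scalar or vector matching `eta`).
#' @param tau Strictly increasing threshold 3-vector.
#' @return An `n x 4` matrix of probabilities; columns are scores 0..3 and
#'   each row sums to 1.
#' @examples
#' # probability profile for an average participant on a typical photo
#' category_probs(eta = -1.97, alpha = exp(0.15), tau = c(-2.36, -1.17, -0.53))
#' @export
category_probs <- function(eta, alpha, tau) {
  if (length(tau) != 3 || any(diff(tau) <= 0))
    stop("tau must be 3 strictly increasing thresholds")
  if (any(alpha <= 0)) stop("alpha must be positive")
  n <- max(length(eta), length(alpha))
  eta <- rep_len(eta, n)
  alpha <- rep_len(alpha, n)
  q1 <- stats::plogis(alpha * (tau[1] - eta))
  q2 <- stats::plogis(alpha * (tau[2] - eta))
  q3 <- stats::plogis(alpha * (tau[3] - eta))
  out <- cbind(`0` = q1, `1` = q2 - q1, `2` = q3 - q2, `3` = 1 - q3)
  rownames(out) <- NULL
  out
}

#' Expected ordinal score under the graded response model
#'
#' `E[Y] = 3 - sum_k P(Y <= k)`, the mean of the category values 0..3.
#'
#' @inheritParams category_probs
#' @return Numeric vector of expected scores in `[0, 3]`.
#' @export
expected_score <- function(eta, alpha, tau) {
  3 - stats::plogis(alpha * (tau[1] - eta)) -
    stats::plogis(alpha * (tau[2] - eta)) -
    stats::plogis(alpha * (tau[3] - eta))
}

# log P(Y = y) for vectors, numerically stable at extreme eta/alpha
log_category_prob <- function(y, eta, alpha, tau) {
  c1 <- alpha * (tau[1] - eta)
  c2 <- alpha * (tau[2] - eta)
  c3 <- alpha * (tau[3] - eta)
  lsig <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(pmax(x, -700))))
  ldiff <- function(cu, cl) {
    d <- cu - cl
    lsig(cu) + lsig(-cl) + ifelse(d > 1e-10, log(-expm1(-d)), log(pmax(d, 1e-300)))
  }
  out <- numeric(length(eta))
  out[y == 0] <- lsig(c1[y == 0])
  out[y == 1] <- ldiff(c2[y == 1], c1[y == 1])
  out[y == 2] <- ldiff(c3[y == 2], c2[y == 2])
  out[y == 3] <- lsig(-c3[y == 3])
  out
}
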