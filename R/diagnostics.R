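# Rank-normalized split-chain Rhat and bulk/tail effective sample sizes
# (the modern forms of the potential scale reduction factor and ESS).

split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(m) {
  z <- stats::qnorm((rank(m, ties.method = "average") - 3 / 8) /
                      (length(m) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

rhat_basic <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Rhat on rank-normalized split chains, folded and unfolded
rhat <- function(m) {
  if (ncol(m) < 2) return(NA_real_)
  if (stats::sd(m) == 0) return(NA_real_)
  bulk <- rhat_basic(rank_normalize(split_chains(m)))
  folded <- rhat_basic(rank_normalize(split_chains(abs(m - stats::median(m)))))
  max(bulk, folded)
}

# ESS via per-chain autocovariances combined with Geyer's initial monotone
# positive sequence, on already-split chains.
ess_mean <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  if (n < 4 || stats::sd(m) == 0) return(NA_real_)
  acov <- vapply(seq_len(nc), function(ch) {
    stats::acf(m[, ch], lag.max = n - 1, plot = FALSE,
               type = "covariance", demean = TRUE)$acf[, 1, 1]
  }, numeric(n))
  acov <- matrix(acov, n, nc)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n +
    (if (nc > 1) stats::var(colMeans(m)) else 0)
  if (var_plus == 0) return(NA_real_)
  rho <- function(t) 1 - (mean_var - mean(acov[t + 1, ])) / var_plus
  pairs <- c(); t <- 0
  while (t + 1 < n - 1) {
    p <- rho(t) + rho(t + 1)
    if (p <= 0) break
    pairs <- c(pairs, p)
    t <- t + 2
  }
  if (!length(pairs)) return(nc * n)
  tau <- max(-1 + 2 * sum(cummin(pairs)), 1e-8)
  min(nc * n / tau, nc * n * log10(nc * n))
}

ess_bulk <- function(m) {
  if (stats::sd(m) == 0) return(NA_real_)
  ess_mean(rank_normalize(split_chains(m)))
}

ess_tail <- function(m) {
  if (stats::sd(m) == 0) return(NA_real_)
  q <- stats::quantile(m, c(0.05, 0.95))
  lo <- ess_mean(split_chains(matrix(as.numeric(m <= q[1]), nrow(m))))
  hi <- ess_mean(split_chains(matrix(as.numeric(m >= q[2]), nrow(m))))
  min(lo, hi)
}

#' Convergence diagnostics for posterior draws
#'
#' Rank-normalized split-chain Rhat (the maximum of the bulk and folded
#' variants) plus bulk and tail effective sample sizes per parameter. With a
#' single chain, Rhat is undefined and reported as `NA`.
#'
#' @param x A [grm()] fit, or an iterations x chains x parameters array, or
#'   an iterations x chains matrix for one parameter.
#' @param pars Optional parameter names to restrict to.
#' @return Data frame with columns `parameter`, `rhat`, `bulk_ess`,
#'   `tail_ess`.
#' @export
convergence_diagnostics <- function(x, pars = NULL) {
  if (inherits(x, "grm")) x <- x$draws
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1),
                               dimnames = list(NULL, NULL, "parameter"))
  stopifnot(length(dim(x)) == 3)
  if (dim(x)[1] < 4) stop("need at least 4 draws per chain")
  if (is.null(pars)) pars <- dimnames(x)[[3]]
  out <- data.frame(parameter = pars,
                    rhat = NA_real_, bulk_ess = NA_real_, tail_ess = NA_real_,
                    stringsAsFactors = FALSE)
  single <- dim(x)[2] < 2
  for (i in seq_along(pars)) {
    m <- x[, , pars[i], drop = FALSE]
    dim(m) <- dim(x)[1:2]
    out$rhat[i] <- if (single) NA_real_ else rhat(m)
    out$bulk_ess[i] <- ess_bulk(m)
    out$tail_ess[i] <- ess_tail(m)
  }
  rownames(out) <- NULL
  out
}
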