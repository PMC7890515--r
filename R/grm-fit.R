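#' Priors for the graded response model
#'
#' Weakly informative defaults: Normal(0, 2.5) on fixed effects and (ordered)
#' thresholds, Normal(0, 1) on the log-scale discrimination intercept,
#' half-Normal(0, 1) on group-level standard deviations, and an LKJ(2)
#' correlation prior on the photo and species difficulty-discrimination
#' correlations.
#'
#' @param beta_sd,tau_sd,delta0_sd,sd_scale,lkj_eta Prior scales/shape.
#' @return List of class `grm_prior`.
#' @export
grm_prior <- function(beta_sd = 2.5, tau_sd = 2.5, delta0_sd = 1,
                      sd_scale = 1, lkj_eta = 2) {
  stopifnot(beta_sd > 0, tau_sd > 0, delta0_sd > 0, sd_scale > 0, lkj_eta > 0)
  structure(list(beta_sd = beta_sd, tau_sd = tau_sd, delta0_sd = delta0_sd,
                 sd_scale = sd_scale, lkj_eta = lkj_eta),
            class = "grm_prior")
}

# parameter packing bookkeeping shared by the sampler and the transforms
grm_layout <- function(K, J, I, S, inc) {
  idx <- list(); pos <- 0
  take <- function(n) { out <- pos + seq_len(n); pos <<- pos + n; out }
  idx$beta <- take(K)
  idx$tau_raw <- take(3)
  if (inc$discrimination) idx$delta0 <- take(1)
  if (inc$participant) idx$theta_raw <- take(J)
  if (inc$photo) {
    idx$zb_photo <- take(I)
    if (inc$discrimination) idx$zd_photo <- take(I)
    idx$ls_pb <- take(1)
    if (inc$discrimination) { idx$ls_pd <- take(1); idx$rr_p <- take(1) }
  }
  if (inc$species) {
    idx$zb_species <- take(S)
    if (inc$discrimination) idx$zd_species <- take(S)
    idx$ls_sb <- take(1)
    if (inc$discrimination) { idx$ls_sd <- take(1); idx$rr_s <- take(1) }
  }
  idx$npar <- pos
  idx
}

# unconstrained chain draws -> named constrained draws
grm_constrain <- function(qm, layout, inc, sd_participant, xnames,
                          participant_levels, photo_levels, species_levels) {
  out <- list()
  beta <- qm[, layout$beta, drop = FALSE]
  colnames(beta) <- xnames
  out$beta <- beta
  t1 <- qm[, layout$tau_raw[1]]
  t2 <- t1 + exp(qm[, layout$tau_raw[2]])
  t3 <- t2 + exp(qm[, layout$tau_raw[3]])
  tau <- cbind(`tau[1]` = t1, `tau[2]` = t2, `tau[3]` = t3)
  out$tau <- tau
  if (inc$discrimination)
    out$discrimination <- cbind(discrimination = qm[, layout$delta0])
  if (inc$participant) {
    theta <- sd_participant * qm[, layout$theta_raw, drop = FALSE]
    colnames(theta) <- paste0("theta[", participant_levels, "]")
    out$theta <- theta
  }
  bivar <- function(zb, zd, ls_b, ls_d, rr, levels, tag) {
    sd_b <- exp(qm[, ls_b])
    b <- qm[, zb, drop = FALSE] * sd_b
    colnames(b) <- paste0("b_", tag, "[", levels, "]")
    res <- list(b = b, sds = cbind(sd_b))
    colnames(res$sds) <- paste0("sd_", tag, "_difficulty")
    if (!is.null(zd)) {
      sd_d <- exp(qm[, ls_d])
      rho <- tanh(qm[, rr])
      d <- (qm[, zb, drop = FALSE] * rho +
              qm[, zd, drop = FALSE] * sqrt(1 - rho^2)) * sd_d
      colnames(d) <- paste0("d_", tag, "[", levels, "]")
      res$d <- d
      res$sds <- cbind(res$sds, sd_d, rho)
      colnames(res$sds) <- paste0(c("sd_", "sd_", "cor_"), tag,
                                  c("_difficulty", "_discrimination", ""))
    }
    res
  }
  if (inc$photo) {
    ph <- bivar(layout$zb_photo, layout$zd_photo, layout$ls_pb, layout$ls_pd,
                layout$rr_p, photo_levels, "photo")
    out$photo <- ph
  }
  if (inc$species) {
    sps <- bivar(layout$zb_species, layout$zd_species, layout$ls_sb,
                 layout$ls_sd, layout$rr_s, species_levels, "species")
    out$species <- sps
  }
  mats <- c(list(out$beta, out$tau),
            if (!is.null(out$discrimination)) list(out$discrimination),
            if (!is.null(out$photo)) list(out$photo$sds),
            if (!is.null(out$species)) list(out$species$sds),
            if (!is.null(out$theta)) list(out$theta),
            if (!is.null(out$photo)) list(out$photo$b),
            if (!is.null(out$photo$d)) list(out$photo$d),
            if (!is.null(out$species)) list(out$species$b),
            if (!is.null(out$species$d)) list(out$species$d))
  do.call(cbind, mats)
}

#' Fit the hierarchical Bayesian graded response model
#'
#' Models each ordinal identification score (0-3) with cumulative-logit
#' curves: `P(Y <= k) = logistic(alpha * (tau_k - eta))`, where the linear
#' predictor `eta` sums participant ability, fixed effects (family, photo
#' region, optionally home region, its region interactions and photo
#' quality, plus the taxa-repeat learning covariate) and photo and species
#' difficulty deviations, and the discrimination `alpha = exp(delta0 + d_photo
#' + d_species)` varies by photo and species on a log link. Photo and species
#' (difficulty, discrimination) pairs are bivariate normal with estimated
#' standard deviations and correlation; the participant ability standard
#' deviation is fixed at 1 to set the latent scale. Posterior draws come from
#' a gradient-based no-U-turn sampler run over multiple chains.
#'
#' @param responses A [grm_frame()], or a scored response table (then
#'   `taxonomy` is required).
#' @param taxonomy A [taxonomy()], used to derive each photo's family.
#' @param model A [grm_model()] or one of [grm_model_names()].
#' @param prior A [grm_prior()].
#' @param chains,iter,warmup Number of chains and post-warmup/warmup
#'   iterations per chain.
#' @param seed Mandatory integer seed; chain seeds derive from it.
#' @param sd_participant Fixed participant-ability standard deviation
#'   (default 1).
#' @param include Named logical list switching model blocks:
#'   `participant`, `photo`, `species` group effects and `discrimination`
#'   (when `FALSE`, `alpha` is fixed at 1 and the model reduces to a
#'   proportional-odds ordinal regression with random intercepts).
#' @param adapt_delta,max_treedepth Sampler tuning.
#' @param quiet Suppress progress messages.
#' @return An object of class `grm`: posterior draws (iterations x chains x
#'   named parameters), the model frame and design, and sampler metadata.
#'   Divergent transitions after warmup are counted and reported by
#'   `print()`, never silently dropped.
#' @seealso [summary.grm()], [predict.grm()], [psis_loo()], [bayes_r2()]
#' @export
grm <- function(responses, taxonomy = NULL, model = "home_x_region",
                prior = grm_prior(), chains = 4, iter = 1000, warmup = 1000,
                seed, sd_participant = 1,
                include = list(participant = TRUE, photo = TRUE,
                               species = TRUE, discrimination = TRUE),
                adapt_delta = 0.8, max_treedepth = 10, quiet = TRUE) {
  if (missing(seed) || is.null(seed)) stop("grm() requires a seed")
  inc <- utils::modifyList(list(participant = TRUE, photo = TRUE,
                                species = TRUE, discrimination = TRUE),
                           include)
  frame <- if (inherits(responses, "grm_frame")) responses else {
    if (is.null(taxonomy))
      stop("supply a taxonomy, or a prepared grm_frame")
    grm_frame(responses, taxonomy)
  }
  if (is.character(model)) model <- grm_model(model)
  X <- build_design(frame, model)
  y <- frame$score
  participant_levels <- unique(frame$participant_id)
  photo_levels <- unique(frame$photo_id)
  species_levels <- unique(frame$true_species)
  pid <- match(frame$participant_id, participant_levels)
  ph <- match(frame$photo_id, photo_levels)
  sp <- match(frame$true_species, species_levels)
  J <- length(participant_levels); I <- length(photo_levels)
  S <- length(species_levels); K <- ncol(X)
  layout <- grm_layout(K, J, I, S, inc)

  lp_grad <- function(q) {
    grm_lp_grad(q, y, X, pid, ph, sp, J, I, S,
                inc$participant, inc$photo, inc$species, inc$discrimination,
                sd_participant, prior$beta_sd, prior$tau_sd, prior$delta0_sd,
                prior$sd_scale, prior$lkj_eta)
  }

  base_init <- numeric(layout$npar)
  base_init[layout$tau_raw] <- c(-1.5, log(0.8), log(0.8))
  if (inc$photo) base_init[layout$ls_pb] <- log(0.3)
  if (inc$species) base_init[layout$ls_sb] <- log(0.3)
  if (inc$photo && inc$discrimination) base_init[layout$ls_pd] <- log(0.2)
  if (inc$species && inc$discrimination) base_init[layout$ls_sd] <- log(0.2)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, chains)
  t0 <- Sys.time()
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    init <- base_init + stats::runif(layout$npar, -0.25, 0.25)
    if (!quiet) message("chain ", ch, "/", chains, " ...")
    runs[[ch]] <- nuts_chain(lp_grad, init, n_warmup = warmup, n_iter = iter,
                             seed = chain_seeds[ch],
                             max_treedepth = max_treedepth,
                             adapt_delta = adapt_delta)
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  con <- lapply(runs, function(r)
    grm_constrain(r$draws, layout, inc, sd_participant, colnames(X),
                  participant_levels, photo_levels, species_levels))
  par_names <- colnames(con[[1]])
  draws <- array(NA_real_, c(iter, chains, length(par_names) + 1),
                 dimnames = list(NULL, NULL, c(par_names, "lp__")))
  for (ch in seq_len(chains)) {
    draws[, ch, seq_along(par_names)] <- con[[ch]]
    draws[, ch, "lp__"] <- runs[[ch]]$lp
  }

  structure(list(
    draws = draws,
    fixed_names = colnames(X),
    model = model, prior = prior, include = inc,
    sd_participant = sd_participant,
    data = list(frame = frame, X = X, y = y, pid = pid, ph = ph, sp = sp,
                participant_levels = participant_levels,
                photo_levels = photo_levels,
                species_levels = species_levels),
    sampler = list(seed = seed, chain_seeds = chain_seeds, chains = chains,
                   iter = iter, warmup = warmup,
                   divergences = sum(vapply(runs, `[[`, 0L, "divergences")),
                   step_size = vapply(runs, `[[`, 0, "eps"),
                   elapsed = elapsed)
  ), class = "grm")
}

# flatten draws for a parameter across chains (iter*chains vector) or the
# full draw matrix (iter*chains x pars)
draw_matrix <- function(fit, pars = NULL) {
  d <- fit$draws
  if (is.null(pars)) pars <- dimnames(d)[[3]]
  out <- sapply(pars, function(p) as.vector(d[, , p]))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(pars),
                                       dimnames = list(NULL, pars))
  out
}

#' @export
print.grm <- function(x, ...) {
  cat("Hierarchical graded response model (cumulative logit)\n")
  cat("model:", x$model$name, "|", length(x$data$y), "responses |",
      length(x$data$participant_levels), "participants,",
      length(x$data$photo_levels), "photos,",
      length(x$data$species_levels), "species\n")
  cat("draws:", x$sampler$chains, "chains x", x$sampler$iter,
      "post-warmup iterations;",
      x$sampler$divergences, "divergent transitions\n")
  fe <- apply(draw_matrix(x, x$fixed_names), 2, stats::median)
  cat("fixed-effect posterior medians:\n")
  print(round(fe, 2))
  invisible(x)
}

#' Summarize a fitted graded response model
#'
#' Posterior medians, standard deviations, 95% credible intervals and
#' convergence diagnostics (rank-normalized split-chain Rhat, bulk and tail
#' effective sample sizes) for the population-level parameters, thresholds,
#' discrimination intercept and group-level standard deviations and
#' correlations.
#'
#' @param object A [grm()] fit.
#' @param prob Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A list of class `summary.grm` with data-frame components `fixed`
#'   and `group`.
#' @export
summary.grm <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  grp_names <- intersect(
    c("sd_photo_difficulty", "sd_photo_discrimination", "cor_photo",
      "sd_species_difficulty", "sd_species_discrimination", "cor_species"),
    dimnames(object$draws)[[3]])
  fixed_names <- c(paste0("tau[", 1:3, "]"),
                   if (object$include$discrimination) "discrimination",
                   object$fixed_names)
  tab <- function(pars) {
    m <- draw_matrix(object, pars)
    diag <- convergence_diagnostics(object, pars)
    data.frame(
      estimate = apply(m, 2, stats::median),
      est_error = apply(m, 2, stats::sd),
      l95 = apply(m, 2, stats::quantile, a),
      u95 = apply(m, 2, stats::quantile, 1 - a),
      rhat = diag$rhat, bulk_ess = diag$bulk_ess, tail_ess = diag$tail_ess,
      row.names = pars)
  }
  out <- list(fixed = tab(fixed_names),
              group = if (length(grp_names)) tab(grp_names) else NULL,
              model = object$model$name,
              n = length(object$data$y),
              divergences = object$sampler$divergences)
  class(out) <- "summary.grm"
  out
}

#' @export
print.summary.grm <- function(x, ...) {
  cat("Graded response model '", x$model, "', ", x$n, " responses\n", sep = "")
  cat("population-level effects and thresholds:\n")
  print(round(x$fixed, 2))
  if (!is.null(x$group)) {
    cat("group-level standard deviations and correlations:\n")
    print(round(x$group, 2))
  }
  if (x$divergences > 0)
    cat("warning:", x$divergences, "divergent transitions after warmup\n")
  invisible(x)
}

#' @export
coef.grm <- function(object, ...) {
  apply(draw_matrix(object, object$fixed_names), 2, stats::median)
}

# linear predictor and log-discrimination draws for arbitrary data rows.
# re = FALSE sets all group deviations to zero (new-cluster prediction).
grm_linpred <- function(fit, frame = NULL, re = TRUE, draw_idx = NULL) {
  data <- fit$data
  if (is.null(frame)) frame <- data$frame
  else {
    tmpl <- data$frame
    for (col in c("family", "region")) {
      vals <- as.character(frame[[col]])
      coerced <- factor(vals, levels(tmpl[[col]]))
      if (anyNA(coerced) && !all(is.na(vals[is.na(coerced)])))
        stop("level not in design for '", col, "': ",
             paste(unique(vals[is.na(coerced)]), collapse = ", "))
      frame[[col]] <- coerced
    }
    if (!"quality" %in% names(frame)) frame$quality <- factor("high", c("high", "low"))
  }
  X <- build_design(frame, fit$model)
  dm <- draw_matrix(fit)
  if (!is.null(draw_idx)) dm <- dm[draw_idx, , drop = FALSE]
  Sdraws <- nrow(dm)
  beta <- dm[, fit$fixed_names, drop = FALSE]
  eta <- beta %*% t(X)  # S x n
  la <- matrix(if (fit$include$discrimination) dm[, "discrimination"] else 0,
               Sdraws, nrow(X))
  add_group <- function(eta, la, ids, levels, tag) {
    idx <- match(ids, levels)
    seen <- !is.na(idx)
    if (!any(seen)) return(list(eta = eta, la = la))
    bcols <- paste0("b_", tag, "[", levels[idx[seen]], "]")
    eta[, seen] <- eta[, seen] + dm[, bcols, drop = FALSE]
    dname <- paste0("d_", tag, "[", levels[idx[seen]], "]")
    if (all(dname %in% colnames(dm)))
      la[, seen] <- la[, seen] + dm[, dname, drop = FALSE]
    list(eta = eta, la = la)
  }
  if (re) {
    if (fit$include$participant && "participant_id" %in% names(frame)) {
      idx <- match(frame$participant_id, data$participant_levels)
      seen <- !is.na(idx)
      if (any(seen)) {
        cols <- paste0("theta[", data$participant_levels[idx[seen]], "]")
        eta[, seen] <- eta[, seen] + dm[, cols, drop = FALSE]
      }
    }
    if (fit$include$photo && "photo_id" %in% names(frame)) {
      r <- add_group(eta, la, frame$photo_id, data$photo_levels, "photo")
      eta <- r$eta; la <- r$la
    }
    if (fit$include$species && "true_species" %in% names(frame)) {
      r <- add_group(eta, la, frame$true_species, data$species_levels, "species")
      eta <- r$eta; la <- r$la
    }
  }
  list(eta = eta, alpha = exp(la),
       tau = dm[, paste0("tau[", 1:3, "]"), drop = FALSE], n = nrow(X))
}

#' Predict from a fitted graded response model
#'
#' @param object A [grm()] fit.
#' @param newdata Data frame with `family`, `region`, `home`, `taxa_repeat`
#'   (and `quality` if the model uses it); for group-level prediction also
#'   `participant_id`, `photo_id`, `true_species` (unseen units get zero
#'   deviations). Defaults to the training data.
#' @param type `"expected"` for the posterior expected score (0-3 scale),
#'   `"probs"` for the four category probabilities.
#' @param re Include group-level deviations (`TRUE`) or predict for new
#'   clusters with deviations at zero (`FALSE`).
#' @param summary If `TRUE` return posterior medians and 95% intervals,
#'   otherwise per-draw values.
#' @param ... Unused.
#' @return For `type = "expected"`: a data frame (or draw matrix) of expected
#'   scores. For `"probs"`: an array draws x rows x 4, or its median/interval
#'   summary.
#' @export
predict.grm <- function(object, newdata = NULL,
                        type = c("expected", "probs"), re = TRUE,
                        summary = TRUE, ...) {
  type <- match.arg(type)
  lp <- grm_linpred(object, newdata, re = re)
  S <- nrow(lp$eta); n <- lp$n
  if (type == "expected") {
    es <- 3 - stats::plogis(lp$alpha * (lp$tau[, 1] - lp$eta)) -
      stats::plogis(lp$alpha * (lp$tau[, 2] - lp$eta)) -
      stats::plogis(lp$alpha * (lp$tau[, 3] - lp$eta))
    if (!summary) return(es)
    data.frame(estimate = apply(es, 2, stats::median),
               mean = colMeans(es),
               l95 = apply(es, 2, stats::quantile, 0.025),
               u95 = apply(es, 2, stats::quantile, 0.975))
  } else {
    q1 <- stats::plogis(lp$alpha * (lp$tau[, 1] - lp$eta))
    q2 <- stats::plogis(lp$alpha * (lp$tau[, 2] - lp$eta))
    q3 <- stats::plogis(lp$alpha * (lp$tau[, 3] - lp$eta))
    pr <- array(c(q1, q2 - q1, q3 - q2, 1 - q3), c(S, n, 4),
                dimnames = list(NULL, NULL, as.character(0:3)))
    if (!summary) return(pr)
    apply(pr, c(2, 3), stats::median)
  }
}

#' Posterior predictive ordinal scores
#'
#' @param object A [grm()] fit.
#' @param nsim Number of posterior predictive replicates.
#' @param seed Optional seed.
#' @param newdata,re As in [predict.grm()].
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated scores (0-3).
#' @export
simulate.grm <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                         re = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  total <- object$sampler$iter * object$sampler$chains
  draw_idx <- sample.int(total, nsim, replace = nsim > total)
  lp <- grm_linpred(object, newdata, re = re, draw_idx = draw_idx)
  n <- lp$n
  out <- matrix(NA_integer_, n, nsim)
  for (s in seq_len(nsim)) {
    pr <- category_probs(lp$eta[s, ], lp$alpha[s, ],
                         as.numeric(lp$tau[s, ]))
    u <- stats::runif(n)
    cum <- pr[, 1]; sc <- integer(n)
    for (k in 1:3) {
      sc[u >= cum] <- k
      if (k < 3) cum <- cum + pr[, k + 1]
    }
    out[, s] <- sc
  }
  as.data.frame(stats::setNames(as.data.frame(out),
                                paste0("sim_", seq_len(nsim))))
}

#' @export
residuals.grm <- function(object, re = TRUE, ...) {
  pred <- predict(object, type = "expected", re = re, summary = TRUE)
  object$data$y - pred$mean
}

#' Caterpillar plot of fixed effects
#'
#' @param x A [grm()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.grm <- function(x, ...) {
  m <- draw_matrix(x, x$fixed_names)
  med <- apply(m, 2, stats::median)
  lo <- apply(m, 2, stats::quantile, 0.025)
  hi <- apply(m, 2, stats::quantile, 0.975)
  ord <- order(med)
  graphics::plot(med[ord], seq_along(med), xlim = range(lo, hi),
                 yaxt = "n", xlab = "posterior median (95% CI)", ylab = "",
                 pch = 16, ...)
  graphics::segments(lo[ord], seq_along(med), hi[ord], seq_along(med))
  graphics::axis(2, at = seq_along(med), labels = names(med)[ord], las = 2,
                 cex.axis = 0.7)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Pointwise log-likelihood of one parameter set
#'
#' Evaluates, for each observation, the log of the graded-response category
#' probability selected by the observed score, with
#' `eta = theta_j + x'beta + b_photo + b_species` and
#' `alpha = exp(delta0 + d_photo + d_species)`.
#'
#' @param params Named list with `beta`, `tau`, and optionally `delta0`,
#'   `theta`, `b_photo`, `d_photo`, `b_species`, `d_species` (vectors indexed
#'   like the corresponding data columns; absent components count as zero).
#' @param data List with `y` (scores 0-3), `X` (design matrix), and integer
#'   index vectors `pid`, `ph`, `sp` where the group terms apply.
#' @return Numeric vector of per-observation log-likelihoods.
#' @export
grm_pointwise_loglik <- function(params, data) {
  comp <- unlist(params[intersect(names(params),
                                  c("beta", "tau", "delta0", "theta",
                                    "b_photo", "d_photo", "b_species",
                                    "d_species"))])
  if (any(!is.finite(comp))) stop("non-finite parameter value")
  eta <- as.vector(data$X %*% params$beta)
  if (!is.null(params$theta)) eta <- eta + params$theta[data$pid]
  if (!is.null(params$b_photo)) eta <- eta + params$b_photo[data$ph]
  if (!is.null(params$b_species)) eta <- eta + params$b_species[data$sp]
  la <- if (is.null(params$delta0)) 0 else params$delta0
  la <- rep_len(la, length(eta))
  if (!is.null(params$d_photo)) la <- la + params$d_photo[data$ph]
  if (!is.null(params$d_species)) la <- la + params$d_species[data$sp]
  log_category_prob(data$y, eta, exp(la), params$tau)
}

#' Pointwise log-likelihood matrix over posterior draws
#'
#' @param fit A [grm()] fit.
#' @param newdata Optional data rows (defaults to the training data).
#' @param re Include group deviations (the in-sample likelihood used for
#'   LOO) or zero them.
#' @param chunk Draws per block, to bound memory.
#' @return Matrix draws x observations of log-likelihood values.
#' @export
log_lik_matrix <- function(fit, newdata = NULL, re = TRUE, chunk = 500) {
  lp <- grm_linpred(fit, newdata, re = re)
  y <- if (is.null(newdata)) fit$data$y else newdata$score
  S <- nrow(lp$eta); n <- lp$n
  out <- matrix(NA_real_, S, n)
  for (lo in seq(1, S, by = chunk)) {
    hi <- min(lo + chunk - 1, S)
    for (s in lo:hi)
      out[s, ] <- log_category_prob(y, lp$eta[s, ], lp$alpha[s, ],
                                    as.numeric(lp$tau[s, ]))
  }
  out
}
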