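test_that("with alpha = 1 and no group effects the posterior matches a
           proportional-odds fit", {
  skip_if_not_installed("MASS")
  set.seed(51)
  n <- 2000
  x1 <- stats::rnorm(n); x2 <- stats::rbinom(n, 1, 0.5)
  pr <- category_probs(0.8 * x1 - 0.6 * x2, 1, c(-1, 0, 1))
  y <- apply(pr, 1, function(p) sample(0:3, 1, prob = p))
  X <- cbind(x1 = x1, x2 = x2)
  lpg <- function(q) grm_lp_grad(q, y, X, integer(n), integer(n), integer(n),
                                 0L, 0L, 0L, FALSE, FALSE, FALSE, FALSE,
                                 1, 2.5, 2.5, 1, 1, 2)
  ch <- nuts_chain(lpg, c(0, 0, -1.5, log(0.8), log(0.8)),
                   n_warmup = 300, n_iter = 400, seed = 52)
  q <- ch$draws
  post <- c(mean(q[, 1]), mean(q[, 2]),
            mean(q[, 3]), mean(q[, 3] + exp(q[, 4])),
            mean(q[, 3] + exp(q[, 4]) + exp(q[, 5])))
  mle <- MASS::polr(factor(y) ~ x1 + x2, method = "logistic")
  ref <- c(stats::coef(mle), mle$zeta)
  # at n = 2000 with weak priors, posterior means track the MLE closely
  expect_equal(unname(post), unname(ref), tolerance = 0.08)
})

test_that("the fit reports its structure and keeps the ability scale fixed", {
  fit <- shared_fit()
  expect_s3_class(fit, "grm")
  expect_equal(fit$sampler$chains, 2)
  expect_output(print(fit), "graded response model")
  # participant sd is fixed, not estimated: no such parameter is sampled
  expect_false("sd_participant" %in% dimnames(fit$draws)[[3]])
  expect_equal(fit$sd_participant, 1)
  # summary carries the Table-1-style blocks
  s <- summary(fit)
  expect_true(all(c("tau[1]", "discrimination", "home_region = T",
                    "taxa_repeat") %in% rownames(s$fixed)))
  expect_true(all(c("sd_photo_difficulty", "cor_species") %in%
                    rownames(s$group)))
  expect_true(all(s$group[c("sd_photo_difficulty", "sd_species_difficulty"),
                          "estimate"] > 0))
  expect_true(all(abs(s$group[c("cor_photo", "cor_species"), "estimate"]) <= 1))
  # thresholds ordered in every draw
  t1 <- as.vector(fit$draws[, , "tau[1]"])
  t2 <- as.vector(fit$draws[, , "tau[2]"])
  t3 <- as.vector(fit$draws[, , "tau[3]"])
  expect_true(all(t1 < t2 & t2 < t3))
  # chains mixed on the headline parameters
  expect_true(all(s$fixed$rhat < 1.2, na.rm = TRUE))
})

test_that("predictions respect the ordinal structure", {
  fit <- shared_fit()
  pr <- predict(fit, newdata = fit$data$frame[1:50, ], type = "probs",
                summary = FALSE)  # draws x rows x 4
  sums <- apply(pr, c(1, 2), sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-9)
  prs <- predict(fit, newdata = fit$data$frame[1:50, ], type = "probs")
  expect_true(all(prs >= 0 & prs <= 1))
  es <- predict(fit, type = "expected")
  expect_true(all(es$estimate >= 0 & es$estimate <= 3))
  expect_equal(length(residuals(fit)), length(fit$data$y))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_true(all(unlist(sims) %in% 0:3))
  # coef returns the fixed-effect medians
  expect_named(coef(fit), fit$fixed_names)
})

test_that("rank-normalized split Rhat separates mixed from unmixed chains", {
  set.seed(61)
  base <- stats::rnorm(1000)
  same <- array(rep(base, 4), c(1000, 4, 1),
                dimnames = list(NULL, NULL, "x"))
  d <- convergence_diagnostics(same)
  expect_lt(abs(d$rhat - 1), 0.01)
  shifted <- same
  shifted[, 2, 1] <- shifted[, 2, 1] + 5
  d2 <- convergence_diagnostics(shifted)
  expect_gt(d2$rhat, 1.1)
  # a single chain has no defined Rhat
  one <- array(base, c(1000, 1, 1), dimnames = list(NULL, NULL, "x"))
  expect_true(is.na(convergence_diagnostics(one)$rhat))
  expect_error(convergence_diagnostics(array(0, c(2, 2, 1))), "at least 4")
})

test_that("iid draws give effective sample sizes near the draw count", {
  set.seed(62)
  reps <- replicate(5, {
    m <- array(stats::rnorm(4000), c(1000, 4, 1),
               dimnames = list(NULL, NULL, "x"))
    unlist(convergence_diagnostics(m)[, c("bulk_ess", "tail_ess")])
  })
  expect_gt(min(reps), 0.6 * 4000)
  expect_lt(max(reps), 1.5 * 4000)
})
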