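test_that("category probabilities form a simplex and respect limits", {
  set.seed(21)
  for (i in 1:200) {
    eta <- stats::rnorm(1, 0, 3)
    alpha <- exp(stats::rnorm(1, 0, 1))
    tau <- sort(stats::rnorm(3, 0, 2))
    if (any(diff(tau) == 0)) next
    p <- category_probs(eta, alpha, tau)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  # extreme ability: species-level probability approaches 1
  expect_gt(category_probs(50, 1, c(-1, 0, 1))[, "3"], 1 - 1e-12)
  expect_gt(category_probs(-50, 1, c(-1, 0, 1))[, "0"], 1 - 1e-12)
  # huge discrimination with eta between the upper thresholds concentrates
  # mass on the bracketed category
  expect_gt(category_probs(0.5, 1e6, c(-1, 0, 1))[, "2"], 1 - 1e-9)
  expect_error(category_probs(0, 1, c(0, -1, 1)), "increasing")
  expect_error(category_probs(0, -1, c(-1, 0, 1)), "positive")
})

test_that("cumulative probabilities rise with eta and sharpen with alpha", {
  tau <- c(-2.36, -1.17, -0.53)
  etas <- seq(-4, 3, length.out = 40)
  p3 <- category_probs(etas, 1, tau)[, "3"]
  expect_true(all(diff(p3) > 0))
  # slope at eta = tau[3] scales with alpha
  h <- 1e-4
  slope <- function(a) (category_probs(tau[3] + h, a, tau)[, "3"] -
                          category_probs(tau[3] - h, a, tau)[, "3"]) / (2 * h)
  expect_gt(slope(2), 1.9 * slope(1))
})

test_that("plugging in published medians reproduces the first-photo prediction", {
  ref <- reference_grm_estimates()
  eta <- ref$beta[["Colubridae"]] + ref$beta[["NorthAmerica"]]
  p <- category_probs(eta, exp(ref$discrimination), ref$tau)
  expect_gt(p[, "3"], 0.15)
  expect_lt(p[, "3"], 0.19)
})

test_that("the design matrix reproduces the published parameterization", {
  sim <- shared_sim()
  fr <- grm_frame(shared_scored(), sim$taxonomy)
  # reference-cell rows are all zero in the full model
  full <- sim_config()  # 9 families, 6 regions
  fam9 <- names(full$families)
  frame9 <- data.frame(
    family = factor(fam9[1], fam9),
    region = factor("Africa", snake_regions()),
    home = FALSE, taxa_repeat = 0L,
    quality = factor("high", c("high", "low")))
  X <- build_design(frame9, "home_x_region")
  expect_equal(ncol(X), 20)
  expect_true(all(X[1, ] == 0))
  expect_identical(colnames(X), c(
    "Colubridae", "Cylindrophiidae", "Elapidae", "Lamprophiidae",
    "Leptotyphlopidae", "Pythonidae", "Typhlopidae", "Viperidae",
    "Asia", "Australasia", "Europe", "NorthAmerica", "SouthAmerica",
    "home_region = T", "taxa_repeat",
    "Asia: home_region = T", "Australasia: home_region = T",
    "Europe: home_region = T", "NorthAmerica: home_region = T",
    "SouthAmerica: home_region = T"))
  # column counts across the six candidates follow their term lists
  n_fam <- 8; n_reg <- 5
  want <- c(base = n_fam + n_reg + 1,
            quality = n_fam + n_reg + 1 + 1,
            home = n_fam + n_reg + 1 + 1,
            home_quality = n_fam + n_reg + 1 + 2,
            home_x_region = n_fam + n_reg + 1 + 1 + n_reg,
            home_x_region_quality = n_fam + n_reg + 1 + 2 + n_reg)
  got <- vapply(grm_model_names(), function(m)
    ncol(build_design(frame9, m)), 0)
  expect_equal(got, want)
  # unseen level is an explicit error naming the column
  bad <- fr[1, ]
  bad$family <- factor("Atlantidae", levels(fr$family))
  expect_error(build_design(bad, "base"), "family")
})

test_that("the model grid has six members and interaction implies main effect", {
  grid <- grm_model_grid()
  expect_length(grid, 6)
  expect_true(all(vapply(grid, function(m) !m$home_x_region || m$home, TRUE)))
})

test_that("pointwise log-likelihood matches a naive independent evaluator", {
  set.seed(31)
  n <- 5; K <- 3; J <- 2; I <- 3; S <- 2
  data <- list(y = sample(0:3, n, replace = TRUE),
               X = matrix(stats::rnorm(n * K), n, K),
               pid = sample(J, n, TRUE), ph = sample(I, n, TRUE),
               sp = sample(S, n, TRUE))
  params <- list(beta = stats::rnorm(K), tau = sort(stats::rnorm(3)),
                 delta0 = 0.2, theta = stats::rnorm(J),
                 b_photo = stats::rnorm(I), d_photo = stats::rnorm(I, 0, .2),
                 b_species = stats::rnorm(S), d_species = stats::rnorm(S, 0, .2))
  got <- grm_pointwise_loglik(params, data)
  naive <- vapply(seq_len(n), function(i) {
    eta <- sum(data$X[i, ] * params$beta) + params$theta[data$pid[i]] +
      params$b_photo[data$ph[i]] + params$b_species[data$sp[i]]
    a <- exp(params$delta0 + params$d_photo[data$ph[i]] +
               params$d_species[data$sp[i]])
    q <- stats::plogis(a * (params$tau - eta))
    p <- c(q[1], q[2] - q[1], q[3] - q[2], 1 - q[3])
    log(p[data$y[i] + 1])
  }, 0)
  expect_equal(got, naive, tolerance = 1e-10)
  expect_error(grm_pointwise_loglik(
    utils::modifyList(params, list(beta = c(NA, 1, 1))), data), "non-finite")
})

test_that("adding a constant to eta and all thresholds leaves the likelihood fixed", {
  set.seed(32)
  n <- 20
  data <- list(y = sample(0:3, n, TRUE), X = matrix(stats::rnorm(n), n, 1),
               pid = rep(1L, n), ph = rep(1L, n), sp = rep(1L, n))
  params <- list(beta = 0.7, tau = c(-1, 0, 1), delta0 = 0.1,
                 theta = 0.3, b_photo = 0, d_photo = 0,
                 b_species = 0, d_species = 0)
  base <- grm_pointwise_loglik(params, data)
  for (const in c(-2.5, 1.3)) {
    shifted <- params
    shifted$tau <- params$tau + const
    shifted$theta <- params$theta + const
    expect_equal(grm_pointwise_loglik(shifted, data), base,
                 tolerance = 1e-12)
  }
})

test_that("compiled log posterior gradient matches finite differences", {
  sim <- shared_sim()
  fr <- grm_frame(shared_scored()[1:300, ], sim$taxonomy)
  X <- build_design(fr, "home_x_region")
  pid <- match(fr$participant_id, unique(fr$participant_id))
  ph <- match(fr$photo_id, unique(fr$photo_id))
  sp <- match(fr$true_species, unique(fr$true_species))
  J <- max(pid); I <- max(ph); S <- max(sp); K <- ncol(X)
  npar <- K + 3 + 1 + J + (2 * I + 3) + (2 * S + 3)
  set.seed(41)
  q <- stats::rnorm(npar, 0, 0.3)
  f <- function(q) grm_lp_grad(q, fr$score, X, pid, ph, sp, J, I, S,
                               TRUE, TRUE, TRUE, TRUE, 1, 2.5, 2.5, 1, 1, 2)
  r <- f(q)
  idx <- sample(npar, 20)
  fd <- vapply(idx, function(i) {
    h <- 1e-5; qp <- q; qm <- q
    qp[i] <- qp[i] + h; qm[i] <- qm[i] - h
    (f(qp)$lp - f(qm)$lp) / (2 * h)
  }, 0)
  expect_equal(r$grad[idx], fd, tolerance = 1e-5)
})
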