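# No-U-turn sampler with dual-averaged step size and a diagonal metric
# (Hoffman & Gelman 2014; adaptation schedule in the style of Stan's
# windowed warmup, simplified to a single variance window). The target is
# supplied as a function of the unconstrained parameter vector returning
# list(lp, grad). Used by grm(); not exported as user API.

nuts_chain <- function(lp_grad, q0, n_warmup, n_iter, seed,
                       max_treedepth = 10, adapt_delta = 0.8) {
  set.seed(seed)
  npar <- length(q0)
  inv_metric <- rep(1, npar)  # estimated posterior variances
  q <- q0
  cur <- lp_grad(q)
  if (!is.finite(cur$lp)) stop("initial point has non-finite log posterior")

  leapfrog <- function(q, p, grad, eps) {
    p <- p + 0.5 * eps * grad
    q <- q + eps * inv_metric * p
    new <- lp_grad(q)
    p <- p + 0.5 * eps * new$grad
    list(q = q, p = p, lp = new$lp, grad = new$grad)
  }
  hamiltonian <- function(lp, p) lp - 0.5 * sum(p^2 * inv_metric)

  sample_momentum <- function() stats::rnorm(npar, 0, sqrt(1 / inv_metric))

  find_epsilon <- function(q, cur) {
    eps <- 0.1
    p <- sample_momentum()
    h0 <- hamiltonian(cur$lp, p)
    st <- leapfrog(q, p, cur$grad, eps)
    dh <- hamiltonian(st$lp, st$p) - h0
    if (!is.finite(dh)) dh <- -Inf
    dir <- if (dh > log(0.5)) 1 else -1
    for (it in 1:50) {
      eps <- eps * 2^dir
      st <- leapfrog(q, p, cur$grad, eps)
      dh <- hamiltonian(st$lp, st$p) - h0
      if (!is.finite(dh)) dh <- -Inf
      if ((dir == 1 && dh <= log(0.5)) || (dir == -1 && dh >= log(0.5))) break
    }
    eps
  }

  # dual averaging state
  da_init <- function(eps) list(mu = log(10 * eps), log_eps = log(eps),
                                log_eps_bar = 0, h_bar = 0, m = 0,
                                gamma = 0.05, t0 = 10, kappa = 0.75)
  da_update <- function(da, accept_stat) {
    da$m <- da$m + 1
    da$h_bar <- (1 - 1 / (da$m + da$t0)) * da$h_bar +
      (adapt_delta - accept_stat) / (da$m + da$t0)
    da$log_eps <- da$mu - sqrt(da$m) / da$gamma * da$h_bar
    w <- da$m^(-da$kappa)
    da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
    da
  }

  divergent <- FALSE
  n_accept <- 0; n_alpha <- 0

  build_tree <- function(q, p, grad, lp, log_u, dir, depth, eps, h0) {
    if (depth == 0) {
      st <- leapfrog(q, p, grad, dir * eps)
      h <- hamiltonian(st$lp, st$p)
      if (!is.finite(h)) h <- -Inf
      n_ok <- as.integer(log_u <= h)
      div <- (log_u - 1000) > h
      if (div) divergent <<- TRUE
      n_accept <<- n_accept + min(1, exp(h - h0))
      n_alpha <<- n_alpha + 1
      list(q_minus = st$q, p_minus = st$p, grad_minus = st$grad,
           q_plus = st$q, p_plus = st$p, grad_plus = st$grad,
           q_prop = st$q, lp_prop = st$lp, n = n_ok, stop = div)
    } else {
      t1 <- build_tree(q, p, grad, lp, log_u, dir, depth - 1, eps, h0)
      if (t1$stop) return(t1)
      if (dir == -1) {
        t2 <- build_tree(t1$q_minus, t1$p_minus, t1$grad_minus, lp, log_u,
                         dir, depth - 1, eps, h0)
        t1$q_minus <- t2$q_minus; t1$p_minus <- t2$p_minus
        t1$grad_minus <- t2$grad_minus
      } else {
        t2 <- build_tree(t1$q_plus, t1$p_plus, t1$grad_plus, lp, log_u,
                         dir, depth - 1, eps, h0)
        t1$q_plus <- t2$q_plus; t1$p_plus <- t2$p_plus
        t1$grad_plus <- t2$grad_plus
      }
      if (t2$n > 0 && stats::runif(1) < t2$n / max(t1$n + t2$n, 1)) {
        t1$q_prop <- t2$q_prop; t1$lp_prop <- t2$lp_prop
      }
      t1$n <- t1$n + t2$n
      dq <- t1$q_plus - t1$q_minus
      uturn <- sum(dq * (inv_metric * t1$p_minus)) < 0 ||
        sum(dq * (inv_metric * t1$p_plus)) < 0
      t1$stop <- t2$stop || uturn
      t1
    }
  }

  transition <- function(q, cur, eps) {
    p0 <- sample_momentum()
    h0 <- hamiltonian(cur$lp, p0)
    log_u <- h0 - stats::rexp(1)
    minus <- list(q = q, p = p0, grad = cur$grad)
    plus <- minus
    q_new <- q; lp_new <- cur$lp; accepted <- FALSE
    n <- 1L
    divergent <<- FALSE; n_accept <<- 0; n_alpha <<- 0
    for (depth in 0:(max_treedepth - 1)) {
      dir <- sample(c(-1, 1), 1)
      if (dir == -1) {
        t <- build_tree(minus$q, minus$p, minus$grad, cur$lp, log_u, dir,
                        depth, eps, h0)
        minus <- list(q = t$q_minus, p = t$p_minus, grad = t$grad_minus)
      } else {
        t <- build_tree(plus$q, plus$p, plus$grad, cur$lp, log_u, dir,
                        depth, eps, h0)
        plus <- list(q = t$q_plus, p = t$p_plus, grad = t$grad_plus)
      }
      if (!t$stop && t$n > 0 && stats::runif(1) < t$n / n) {
        q_new <- t$q_prop; lp_new <- t$lp_prop; accepted <- TRUE
      }
      n <- n + t$n
      if (t$stop) break
      dq <- plus$q - minus$q
      if (sum(dq * (inv_metric * minus$p)) < 0 ||
          sum(dq * (inv_metric * plus$p)) < 0) break
    }
    list(q = q_new, lp = lp_new, accept_stat = if (n_alpha > 0)
      n_accept / n_alpha else 0, divergent = divergent, depth = depth,
      accepted = accepted)
  }

  eps <- find_epsilon(q, cur)
  da <- da_init(eps)

  w_half <- floor(n_warmup / 2)
  win_lo <- max(1, floor(n_warmup / 4))
  window <- matrix(0, w_half - win_lo + 1, npar)
  n_div_sampling <- 0L
  draws <- matrix(NA_real_, n_iter, npar)
  lp_draws <- numeric(n_iter)
  depths <- integer(n_iter)

  for (it in seq_len(n_warmup + n_iter)) {
    warm <- it <= n_warmup
    step <- if (warm) exp(da$log_eps) else eps
    tr <- transition(q, cur, step)
    if (tr$accepted) {
      q <- tr$q
      cur <- lp_grad(q)  # refresh gradient at the accepted point
    }
    if (warm) {
      da <- da_update(da, tr$accept_stat)
      if (it >= win_lo && it <= w_half) window[it - win_lo + 1, ] <- q
      if (it == w_half && nrow(window) >= 10) {
        v <- apply(window, 2, stats::var)
        nw <- nrow(window)
        inv_metric <- (nw / (nw + 5)) * v + (5 / (nw + 5)) * 1e-3
        eps_now <- exp(da$log_eps)
        da <- da_init(eps_now)
      }
      if (it == n_warmup) eps <- exp(da$log_eps_bar)
    } else {
      i <- it - n_warmup
      draws[i, ] <- q
      lp_draws[i] <- cur$lp
      depths[i] <- tr$depth
      if (tr$divergent) n_div_sampling <- n_div_sampling + 1L
    }
  }
  list(draws = draws, lp = lp_draws, eps = eps, inv_metric = inv_metric,
       divergences = n_div_sampling, treedepth = depths)
}
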