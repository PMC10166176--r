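# Shared fixtures and independent oracles. Oracles are deliberately written
# as brute-force computations that do not reuse package internals.

# Brute-force product-limit estimator over sorted unique event times.
km_brute_force <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(times = ev_times, survival = surv)
}

# Discrete-event microsimulation of the three-state sequencing rules with
# exponential dwell times: leaves 1L during cycle u = ceiling(T1), dies
# immediately with probability `a`, otherwise enters 2L at cycle u and
# survives there for T2.
microsim_os <- function(n, lambda1, a, lambda2, horizon, seed) {
  set.seed(seed)
  t1 <- stats::rexp(n, lambda1)
  u <- ceiling(t1)
  attrit <- stats::runif(n) < a
  t2 <- stats::rexp(n, lambda2)
  vapply(0:horizon, function(t)
    mean(t1 > t | (!attrit & u <= t & t2 > t - u)), numeric(1))
}

# Exponential monthly survival grid S(t) = exp(-rate * t).
exp_grid <- function(rate, horizon = 180L) {
  g <- exp(-rate * (0:horizon))
  g[1] <- 1
  g
}

# Zero-mortality life table covering very old ages.
zero_lifetable <- function() generate_lifetable(50, 80, "constant", qx0 = 0)

# Small deterministic survival dataset used across tests.
toy_dataset <- function() {
  set.seed(42)
  t_ev <- stats::rweibull(120, shape = 1.3, scale = 30)
  cens <- stats::runif(120, 10, 60)
  survival_dataset(pmin(t_ev, cens), as.numeric(t_ev <= cens),
                   label = "toy")
}
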