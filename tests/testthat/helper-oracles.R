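# Independent brute-force oracles used to cross-check the model-fitting
# routes. These deliberately avoid the survival package.

# Cox partial log-likelihood for one covariate with distinct event times
# (Breslow form; equals Efron when there are no event-time ties), with
# optional case weights.
oracle_cox_loglik <- function(beta, time, event, x, w = rep(1, length(time))) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + w[i] * (beta * x[i] - log(sum(w[risk] * exp(beta * x[risk]))))
  }
  ll
}

oracle_cox_coef <- function(time, event, x, w = rep(1, length(time))) {
  stats::optimize(function(b) oracle_cox_loglik(b, time, event, x, w),
                  interval = c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# hand product-limit estimator evaluated at given times
oracle_km_surv <- function(time, event, at) {
  ts <- sort(unique(time[event == 1]))
  vapply(at, function(t0) {
    s <- 1
    for (tt in ts[ts <= t0]) {
      n <- sum(time >= tt)
      d <- sum(time == tt & event == 1)
      s <- s * (1 - d / n)
    }
    s
  }, numeric(1))
}

# two-group log-rank chi-square via observed-minus-expected arithmetic
oracle_logrank_chisq <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in ts) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# a random small survival dataset with distinct times
random_small_cox_data <- function(n, binary = TRUE) {
  x <- if (binary) sample(0:1, n, replace = TRUE) else round(rnorm(n), 2)
  if (length(unique(x)) == 1) x[1] <- x[1] + 1
  time <- sample(seq_len(50), n)
  event <- sample(c(0, 1), n, replace = TRUE, prob = c(0.3, 0.7))
  if (sum(event) == 0) event[1] <- 1
  data.frame(time = time, event = event, x = x)
}

# TRUE when the dataset identifies the coefficient: the partial likelihood
# must actually vary in beta (the covariate varies within some risk set)
# and its maximum must be interior
oracle_cox_identifiable <- function(d) {
  ll <- vapply(c(-1, 0, 1), function(b) oracle_cox_loglik(b, d$time, d$event, d$x),
               numeric(1))
  diff(range(ll)) > 1e-8 && abs(oracle_cox_coef(d$time, d$event, d$x)) < 5
}

GDMT_CLASSES_TEST <- c("RASI", "BETA_BLOCKER", "MRA", "SGLT2I")

# a snapshot with normal vitals and the given orders
normal_snapshot <- function(orders = NULL, ...) {
  patient_snapshot(orders = orders, sbp = 120, pulse = 75, k = 4.2,
                   egfr = 65, scr = 1.1, nyha = 2, ...)
}
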