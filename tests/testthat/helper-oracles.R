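# Independent oracles used across the suite. These are written from the
# model definitions directly (no calls into the package's fitting path) so
# they can serve as cross-checks for it.

# Censored AFT log-likelihood on the time scale: events contribute the log
# density of T, censored subjects the log survival. par is
# (intercept, [beta,] gamma, log_sigma).
oracle_aft_loglik <- function(par, time, event, x = NULL, a,
                              dist = c("weibull", "loglogistic")) {
  dist <- match.arg(dist)
  adjusted <- !is.null(x)
  mu <- if (adjusted) par[1] + par[2] * x + par[3] * a else par[1] + par[2] * a
  sigma <- exp(par[length(par)])
  w <- (log(time) - mu) / sigma
  if (dist == "weibull") {
    logf <- w - exp(w) - log(sigma) - log(time)
    logS <- -exp(w)
  } else {
    logf <- w - 2 * log1p(exp(w)) - log(sigma) - log(time)
    logS <- -log1p(exp(w))
  }
  sum(ifelse(event == 1, logf, logS))
}

# Brute-force maximizer of the same likelihood, started at the truth.
oracle_aft_mle <- function(time, event, x = NULL, a, start,
                           dist = c("weibull", "loglogistic")) {
  dist <- match.arg(dist)
  opt <- optim(start, function(p)
    -oracle_aft_loglik(p, time, event, x, a, dist),
    method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  opt$par
}

# Closed-form / 1-d profile MLE of the smallest-extreme-value location-scale
# model for an uncensored sample of log-times z: the scale solves
#   s = sum(z * e^{z/s}) / sum(e^{z/s}) - mean(z)
# and the location is mu = s * log(mean(e^{z/s})).
oracle_gumbel_mle <- function(z) {
  g <- function(s) {
    w <- exp((z - max(z)) / s)       # overflow-safe weights
    sum(z * w) / sum(w) - mean(z) - s
  }
  s <- uniroot(g, c(0.05 * stats::sd(z), 10 * stats::sd(z)), tol = 1e-12)$root
  mu <- s * (log(mean(exp((z - max(z)) / s))) ) + max(z)
  c(mu = mu, sigma = s)
}

# Normal-approximation power of the two-sided two-sample comparison with
# n/2 subjects per arm and outcome SD sd_y.
oracle_two_sample_power <- function(n_total, gamma, sd_y, alpha = 0.05) {
  za <- qnorm(1 - alpha / 2)
  d <- abs(gamma) * sqrt(n_total) / (2 * sd_y)
  pnorm(d - za) + pnorm(-d - za)
}

# binomial 95% interval half-width for a rejection-rate estimate
binom_halfwidth <- function(p, n_reps) 1.96 * sqrt(p * (1 - p) / n_reps)
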