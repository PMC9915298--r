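# Internal machinery that converts target epoch-metric values (MAD / ENMO,
# in mg) into waveform parameters for the signal synthesiser. Each movement
# segment is modelled as a magnitude deviation  d(t) = b + A sin(2*pi*f*t + phi)
# around 1 g, plus white sensor noise. Under that model, with eps ~ N(0, sigma)
# and phase-averaged theta, the expected epoch metrics have closed forms built
# from E|mu + eps| and E max(mu + eps, 0); we invert them numerically so the
# realised epoch values hit the requested distribution.

.theta_grid <- sin(2 * pi * (seq_len(64) - 0.5) / 64)

# E | mu + eps |,  eps ~ N(0, sigma)
.e_abs <- function(mu, sigma) {
  sigma <- max(sigma, 1e-9)
  mu * (1 - 2 * pnorm(-mu / sigma)) + 2 * sigma * dnorm(mu / sigma)
}

# E max(mu + eps, 0)
.e_relu <- function(mu, sigma) {
  sigma <- max(sigma, 1e-9)
  mu * pnorm(mu / sigma) + sigma * dnorm(mu / sigma)
}

# Expected MAD (mg) of an epoch with oscillation amplitude A (mg) and noise
# sigma (mg). The epoch mean magnitude absorbs b, so MAD depends on A only.
.expected_mad <- function(A, sigma) {
  vapply(A, function(a) mean(vapply(.theta_grid, function(s)
    .e_abs(a * s, sigma), 0)), 0)
}

# Expected ENMO (mg) of an epoch with amplitude A, magnitude bias b, noise
# sigma (all mg).
.expected_enmo <- function(A, b, sigma) {
  mean(vapply(.theta_grid, function(s) .e_relu(b + A * s, sigma), 0))
}

# Inverse of .expected_mad: returns a vectorised function target_mg -> A_mg.
# Targets at/below the noise floor map to A = 0.
.mad_inverter <- function(sigma, a_max = 4000) {
  a_grid <- c(0, exp(seq(log(0.05), log(a_max), length.out = 160)))
  m_grid <- .expected_mad(a_grid, sigma)
  function(target) approx(m_grid, a_grid, xout = target, rule = 2)$y
}

# Solve the magnitude bias b so that the expected ENMO equals `target`.
.solve_bias <- function(A, target, sigma) {
  lo <- -A - 6 * sigma - abs(target) - 1
  hi <- A + 6 * sigma + abs(target) + 1
  uniroot(function(b) .expected_enmo(A, b, sigma) - target,
          lower = lo, upper = hi, tol = 1e-6)$root
}

# Precompute, for one segment type, the map from log epoch-multiplier to the
# waveform pair (A, b). The MAD target scales as exp(lm); the ENMO target as
# exp(gamma * lm), where gamma is the ratio of the two metrics' log-spreads
# (rank-coupled lognormal marginals). `inv` is a .mad_inverter for the
# recording's noise level.
.type_solver <- function(mad_med, enmo_med, gamma, sigma, inv,
                         lm_range = 5) {
  if (mad_med <= 0 && enmo_med <= 0) {
    return(function(lm) list(A = numeric(length(lm)) ,
                             b = numeric(length(lm))))
  }
  lm_grid <- seq(-lm_range, lm_range, length.out = 41)
  A_grid <- inv(mad_med * exp(lm_grid))
  b_grid <- vapply(seq_along(lm_grid), function(i)
    .solve_bias(A_grid[i], enmo_med * exp(gamma * lm_grid[i]), sigma), 0)
  function(lm) {
    lm <- pmin(pmax(lm, -lm_range), lm_range)
    list(A = inv(mad_med * exp(lm)),
         b = approx(lm_grid, b_grid, xout = lm)$y)
  }
}
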