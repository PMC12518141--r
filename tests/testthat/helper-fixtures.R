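# Shared fixtures and independent oracles, built in code at test time.

# Coordinate grids in node units (0-based), matching the package convention.
grid_xy <- function(n) {
  list(X = matrix(0:(n - 1), n, n, byrow = TRUE),
       Y = matrix(0:(n - 1), n, n))
}

# Analytic single-defect angle field alpha = k * atan2(y - y0, x - x0),
# written independently of the synthetic_data module.
analytic_defect_alpha <- function(n, k, x0, y0, alpha0 = 0) {
  g <- grid_xy(n)
  fold_half(alpha0 + k * atan2(g$Y - y0, g$X - x0))
}

# Stationary Gaussian field with EXPONENTIAL correlation exp(-r/lambda),
# spectral synthesis; independent oracle for correlation_function.
exp_corr_field <- function(n, lambda, seed) {
  d <- c(0:(n %/% 2), -((n - 1) %/% 2):-1)
  R <- sqrt(outer(d^2, d^2, "+"))
  rho <- exp(-R / lambda)
  S <- Re(stats::fft(rho)); S[S < 0] <- 0
  set.seed(seed)
  w <- matrix(stats::rnorm(n * n), n, n)
  f <- Re(stats::fft(sqrt(S) * stats::fft(w), inverse = TRUE)) / n^2
  f / sqrt(mean(f^2))
}

# A small passive relaxation state for conservation checks.
quick_sim <- function(n = 48, steps = 100, ...) {
  p <- sim_params(nx = n, ny = n, dt = 0.5, seed = 7, ...)
  st <- sim_init(p)
  for (k in seq_len(steps)) st <- sim_step(st, p)
  list(state = st, params = p)
}

# Uniform-director Q5 state for operator unit checks.
uniform_q5 <- function(n, amplitude, theta) {
  n1 <- cos(theta); n2 <- sin(theta)
  z <- matrix(0, n, n)
  list(xx = z + amplitude * (n1^2 - 1 / 3), xy = z + amplitude * n1 * n2,
       xz = z, yy = z + amplitude * (n2^2 - 1 / 3), yz = z)
}
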