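# Independent oracles used across the suite. These deliberately solve the
# same problems by different routes (direct minimization, grid search,
# linear algebra) than the implementation under test.

ln_gamma <- function(x, T, params) log(activity_coefficients(x, T, params))

# Direct minimization of the reduced Gibbs energy of mixing over
# per-component split fractions beta_i (fraction of component i sent to
# phase II), with the analytic gradient (the chemical-potential
# difference). Independent of the flash's successive-substitution /
# Rachford-Rice route.
gibbs_min_oracle <- function(z, T, params, extra_starts = 1L) {
  clamp <- function(b) pmin(pmax(b, 1e-10), 1 - 1e-10)
  split_g <- function(b) {
    b <- clamp(b)
    nII <- b * z; nI <- (1 - b) * z
    xI <- nI / sum(nI); xII <- nII / sum(nII)
    sum(nI * (log(xI) + ln_gamma(xI, T, params))) +
      sum(nII * (log(xII) + ln_gamma(xII, T, params)))
  }
  split_grad <- function(b) {
    b <- clamp(b)
    nII <- b * z; nI <- (1 - b) * z
    xI <- nI / sum(nI); xII <- nII / sum(nII)
    muI <- log(xI) + ln_gamma(xI, T, params)
    muII <- log(xII) + ln_gamma(xII, T, params)
    z * (muII - muI)
  }
  n <- length(z)
  starts <- list(rep(0.5, n), c(0.95, rep(0.05, n - 1)),
                 c(0.05, rep(0.95, n - 1)))
  for (k in seq_len(extra_starts)) starts <- c(starts, list(stats::runif(n)))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, split_g, split_grad, method = "L-BFGS-B",
                      lower = 1e-9, upper = 1 - 1e-9,
                      control = list(maxit = 5000, factr = 1))
    if (is.null(best) || o$value < best$value) best <- o
  }
  b <- clamp(best$par)
  nII <- b * z; nI <- (1 - b) * z
  list(x_I = nI / sum(nI), x_II = nII / sum(nII), L_II = sum(nII),
       g = best$value)
}

# Brute-force 1-D grid search over binary two-phase splits of a feed z:
# for phase compositions (p, 1-p) and (q, 1-q) on a grid, the lever rule
# fixes the phase fractions; returns the minimum reduced Gibbs energy.
binary_split_grid_oracle <- function(z, T, params, n_grid = 400L) {
  stopifnot(length(z) == 2L)
  g_single <- function(x) {
    pos <- x > 0
    sum(x[pos] * (log(x[pos]) + ln_gamma(x, T, params)[pos]))
  }
  ps <- seq(1e-4, 1 - 1e-4, length.out = n_grid)
  best <- list(g = g_single(z), p = z[1], q = z[1])
  for (p in ps[ps < z[1]]) {
    for (q in ps[ps > z[1]]) {
      l2 <- (z[1] - p) / (q - p)      # lever rule, fraction of phase (q, .)
      if (l2 <= 0 || l2 >= 1) next
      g <- (1 - l2) * g_single(c(p, 1 - p)) + l2 * g_single(c(q, 1 - q))
      if (g < best$g) best <- list(g = g, p = p, q = q)
    }
  }
  best
}

# Feed placement by explicit linear algebra: solve the collinearity
# equations plus the unit-sum constraint as an overdetermined linear
# system in (z, t): z = x_II + t (x_I - x_II), z_1 fixed.
feed_linear_oracle <- function(tieline, z1) {
  xI <- tieline$x_aq; xII <- tieline$x_org
  n <- length(xI)
  # unknowns: z_2..z_n and t -> n unknowns; equations: collinearity for
  # components 2..n and sum(z) = 1
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:n) {
    A[i - 1, i - 1] <- 1
    A[i - 1, n] <- -(xI[i] - xII[i])
    b[i - 1] <- xII[i]
  }
  A[n, seq_len(n - 1)] <- 1
  A[n, n] <- 0
  b[n] <- 1 - z1
  sol <- solve(A, b)
  c(z1, sol[seq_len(n - 1)])
}

# Small parameterized systems reused by several files
binary_demix_params <- function(tau = 3, alpha = 0.2) {
  cs <- component_set(c("A", "B"))
  nrtl_params(cs, tau = matrix(c(0, tau, tau, 0), 2), alpha = alpha)
}

ideal_params <- function(n = 3L) {
  cs <- component_set(paste0("c", seq_len(n)))
  nrtl_params(cs, tau = matrix(0, n, n), alpha = 0.3)
}

random_interior_x <- function(n) {
  x <- stats::runif(n, 0.05, 1)
  x / sum(x)
}
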