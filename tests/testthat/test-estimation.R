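make_fixture_dataset <- function(noise = 0, n = 6, seed = 5,
                                 sys_seed = 1) {
  sys <- make_demixing_system("ternary_broth_like", seed = sys_seed)
  list(sys = sys,
       data = generate_tielines(sys, n = n, noise_sd = noise, seed = seed))
}

test_that("feed placement on a tie-line matches endpoints, midpoint and the linear-algebra oracle", {
  set.seed(21)
  fx <- make_fixture_dataset(noise = 0)
  tl <- fx$data$truth[[3]]
  # endpoint: z1 at the aqueous value recovers the aqueous composition
  eps <- 1e-9
  z_end <- feed_on_tieline(tl, tl$x_aq[1] - eps * sign(tl$x_aq[1] - tl$x_org[1]))
  expect_equal(z_end, tl$x_aq, tolerance = 1e-6)
  # midpoint of component 1 gives the segment midpoint
  z_mid <- feed_on_tieline(tl, (tl$x_aq[1] + tl$x_org[1]) / 2)
  expect_equal(z_mid, (tl$x_aq + tl$x_org) / 2, tolerance = 1e-12)
  expect_equal(sum(z_mid), 1, tolerance = 1e-12)
  # random interior placements agree with the explicit linear system
  for (k in 1:5) {
    t <- stats::runif(1, 0.05, 0.95)
    z1 <- (1 - t) * tl$x_org[1] + t * tl$x_aq[1]
    expect_equal(feed_on_tieline(tl, z1),
                 feed_linear_oracle(tl, z1), tolerance = 1e-10)
  }
  # out-of-interval placement is a domain error
  expect_error(feed_on_tieline(tl, max(tl$x_aq[1], tl$x_org[1]) + 0.01),
               "strictly between")
})

test_that("lever rule fraction reconstructs the feed and flags non-collinear points", {
  fx <- make_fixture_dataset(noise = 0)
  tl <- fx$data$truth[[2]]
  expect_equal(lever_fraction(tl, tl$x_aq), 0, tolerance = 1e-12)
  mid <- (tl$x_aq + tl$x_org) / 2
  expect_equal(lever_fraction(tl, mid), 0.5, tolerance = 1e-12)
  for (k in 1:5) {
    t <- stats::runif(1, 0.05, 0.95)
    z <- (1 - t) * tl$x_aq + t * tl$x_org
    L <- lever_fraction(tl, z)
    expect_equal(L, t, tolerance = 1e-10)
    expect_equal((1 - L) * tl$x_aq + L * tl$x_org, z, tolerance = 1e-10)
  }
  z_off <- mid + c(0.01, -0.02, 0.01)
  expect_error(lever_fraction(tl, z_off), "collinear")
})

test_that("K-value residual vanishes at the generating parameters and degrades predictably", {
  fx <- make_fixture_dataset(noise = 0)
  # ground-truth parameters reproduce the noiseless tie-lines
  for (tl in fx$data$truth) {
    kv <- kvalue_residual(fx$sys$params, tl)
    expect_false(kv$penalized)
    expect_lt(max(abs(kv$residual)), 1e-6)
  }
  # ideal parameters force K = 1: computed phases collapse to the feed and
  # the residual is the measured phase difference (up to sign/ordering)
  tl <- fx$data$truth[[3]]
  p0 <- nrtl_params(fx$sys$components, tau = matrix(0, 3, 3), alpha = 0.2)
  kv0 <- kvalue_residual(p0, tl)
  z <- feed_on_tieline(tl, (tl$x_aq[1] + tl$x_org[1]) / 2)
  expect_equal(kv0$residual, c(z - tl$x_aq, z - tl$x_org), tolerance = 1e-10)
  expect_null(kv0$computed)   # degenerate: computed phases coincide
})

test_that("noiseless fit initialized at the truth recovers a near-zero objective", {
  fx <- make_fixture_dataset(noise = 0)
  fit <- estimate_nrtl(fx$data, n_starts = 2, seed = 1,
                       init = nrtl_tau(fx$sys$params))
  expect_lt(fit$objective, 1e-8)
  expect_true(all(fit$gibbs_feasible))
})

test_that("objective is invariant to tie-line ordering and stored phase order", {
  fx <- make_fixture_dataset(noise = 0.002, seed = 9)
  data <- fx$data
  params <- fx$sys$params
  rms <- function(d) {
    r <- unlist(lapply(d$tielines, function(tl)
      kvalue_residual(params, tl)$residual))
    sqrt(mean(r^2))
  }
  base <- rms(data)
  shuffled <- data
  shuffled$tielines <- rev(data$tielines)
  expect_equal(rms(shuffled), base, tolerance = 1e-14)
  swapped <- data
  swapped$tielines <- lapply(data$tielines, function(tl)
    tie_line(x_org = tl$x_aq, x_aq = tl$x_org, T = tl$T))
  expect_equal(rms(swapped), base, tolerance = 1e-14)
})

test_that("fits of equal quality predict the same binodal (tie-line identifiability)", {
  fx <- make_fixture_dataset(noise = 0)
  fit_a <- estimate_nrtl(fx$data, n_starts = 2, seed = 1,
                         init = nrtl_tau(fx$sys$params))
  fit_b <- estimate_nrtl(fx$data, n_starts = 10, seed = 99)
  bc_a <- binodal_curve(fx$data$T, fit_a$params, n_lines = 6)
  if (abs(fit_a$objective - fit_b$objective) < 1e-6) {
    bc_b <- binodal_curve(fx$data$T, fit_b$params, n_lines = 6)
    expect_equal(length(bc_b), length(bc_a))
    expect_lt(binodal_rms(bc_a, bc_b), 1e-3)
  }
  # regardless of the multistart outcome, the truth-initialized fit must
  # reproduce the generating binodal
  expect_lt(binodal_rms(bc_a, fx$data$truth), 1e-3)
})
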