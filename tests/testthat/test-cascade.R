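broth_setup <- function(seed = 1) {
  sys <- make_demixing_system("ternary_broth_like", seed = seed)
  list(sys = sys,
       feed = stream(c(water = 97, solute = 3, ester = 0), "feed"),
       solvent = stream(c(water = 0, solute = 0, ester = 10), "solvent"))
}

test_that("a 1-stage cascade equals a single flash of the mixed inlet", {
  st <- broth_setup()
  res <- simulate_extractor(st$feed, st$solvent, 1, 298.15, st$sys$params,
                            tol = 1e-12)
  mixed <- st$feed$component_flows + st$solvent$component_flows
  tot <- sum(mixed)
  fr <- lle_flash(as.numeric(mixed / tot), 298.15, st$sys$params)
  expect_equal(as.numeric(res$extract$component_flows),
               tot * fr$L_II * fr$x_II, tolerance = 1e-8)
  expect_equal(as.numeric(res$raffinate$component_flows),
               tot * (1 - fr$L_II) * fr$x_I, tolerance = 1e-8)
})

test_that("the balance and sweep solvers agree", {
  st <- broth_setup()
  rb <- simulate_extractor(st$feed, st$solvent, 6, 298.15, st$sys$params,
                           tol = 1e-12)
  rs <- simulate_extractor(st$feed, st$solvent, 6, 298.15, st$sys$params,
                           tol = 1e-11, method = "sweep")
  expect_equal(as.numeric(rb$extract$component_flows),
               as.numeric(rs$extract$component_flows), tolerance = 1e-6)
})

test_that("converged cascades close the component material balance", {
  st <- broth_setup()
  for (ns in c(2, 8, 32)) {
    res <- simulate_extractor(st$feed, st$solvent, ns, 298.15,
                              st$sys$params, tol = 1e-12)
    expect_true(res$converged)
    inl <- st$feed$component_flows + st$solvent$component_flows
    outl <- res$extract$component_flows + res$raffinate$component_flows
    expect_lt(max(abs(inl - outl) / pmax(inl, 1e-12)), 1e-8)
    expect_lt(res$balance_residual, 1e-8)
  }
})

test_that("recovery is monotone in stage count and solvent flow", {
  st <- broth_setup()
  stages <- c(1, 2, 4, 8)
  solvents <- c(4, 7, 10, 14)
  rec <- matrix(NA_real_, length(stages), length(solvents))
  for (i in seq_along(stages)) for (j in seq_along(solvents)) {
    solv <- stream(c(water = 0, solute = 0, ester = solvents[j]), "solvent")
    res <- simulate_extractor(st$feed, solv, stages[i], 298.15,
                              st$sys$params, tol = 1e-11)
    rec[i, j] <- recovery(st$feed, res$extract, "solute")
  }
  for (j in seq_along(solvents)) expect_true(all(diff(rec[, j]) > -1e-9))
  for (i in seq_along(stages)) expect_true(all(diff(rec[i, ]) > -1e-9))
  expect_true(all(rec >= 0 & rec <= 1 + 1e-12))
})

test_that("cascade results are invariant to uniform inlet scaling", {
  st <- broth_setup()
  r1 <- simulate_extractor(st$feed, st$solvent, 4, 298.15, st$sys$params,
                           tol = 1e-12)
  feed10 <- stream(st$feed$component_flows * 10, "feed")
  solv10 <- stream(st$solvent$component_flows * 10, "solvent")
  r10 <- simulate_extractor(feed10, solv10, 4, 298.15, st$sys$params,
                            tol = 1e-12)
  expect_equal(as.numeric(r10$extract$component_flows),
               10 * as.numeric(r1$extract$component_flows),
               tolerance = 1e-10)
  expect_equal(recovery(feed10, r10$extract, "solute"),
               recovery(st$feed, r1$extract, "solute"), tolerance = 1e-10)
})

test_that("recovery handles identity, absence and zero-feed cases", {
  f <- stream(c(a = 2, b = 1), "f")
  expect_equal(as.numeric(recovery(f, f, "a")), 1)
  out <- stream(c(a = 0, b = 1), "out")
  expect_equal(as.numeric(recovery(f, out, "a")), 0)
  expect_equal(attr(recovery(f, f, "a"), "percent"), 100)
  expect_error(recovery(out, f, "a"), "positive flow")
})

test_that("distribution coefficient and selectivity follow their definitions", {
  tl <- tie_line(x_org = c(0.10, 0.30, 0.60), x_aq = c(0.85, 0.10, 0.05))
  ds <- distribution_and_selectivity(tl, 2, 1)
  expect_equal(ds$D, 0.30 / 0.10)
  expect_equal(ds$S, (0.30 / 0.10) / (0.10 / 0.85))
  # equal compositions in a hypothetical limit give D = S = 1
  tl2 <- tie_line(x_org = c(0.499, 0.301, 0.2), x_aq = c(0.499, 0.3, 0.201))
  ds2 <- distribution_and_selectivity(tl2, 1, 1)
  expect_equal(ds2$D, 1)
  expect_equal(ds2$S, 1)
  # D of the solute varies monotonically along the generated binodal
  sys <- make_demixing_system("ternary_broth_like", seed = 1)
  bc <- binodal_curve(298.15, sys$params, n_lines = 6)
  Ds <- vapply(bc, function(t) distribution_and_selectivity(t, 2, 1)$D,
               numeric(1))
  expect_true(all(diff(Ds) < 0) || all(diff(Ds) > 0))
})

test_that("the lever rule links mixing-point distances to flow ratios", {
  f <- stream(c(water = 541.4, acid = 3.2, ester = 0.7), "feed")
  s <- stream(c(water = 0, acid = 0, ester = 49.3), "solvent")
  lmb <- lever_material_balance(f, s)
  expect_equal(lmb$distance_ratio, lmb$flow_ratio, tolerance = 1e-10)
  expect_equal(as.numeric(sum(lmb$M)), 1, tolerance = 1e-12)
  # equal flows put M at the composition midpoint with ratio 1
  a <- stream(c(x = 1, y = 0), "a"); b <- stream(c(x = 0, y = 1), "b")
  lmb2 <- lever_material_balance(a, b)
  expect_equal(as.numeric(lmb2$M), c(0.5, 0.5))
  expect_equal(lmb2$distance_ratio, 1, tolerance = 1e-12)
  # identical compositions: degenerate distances, ratio from flows
  c1 <- stream(c(x = 2, y = 2), "c1"); c2 <- stream(c(x = 1, y = 1), "c2")
  lmb3 <- lever_material_balance(c1, c2)
  expect_true(is.na(lmb3$distance_ratio))
  expect_equal(lmb3$flow_ratio, 2)
})
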