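#' Bundle measured tie-lines into a dataset for regression
#'
#' @param components A [component_set()].
#' @param tielines List of [tie_line()] objects, all at the same
#'   temperature; at least two are needed for a fit.
#' @param noise_sd Stated measurement standard uncertainty in mole
#'   fraction (0.003 for typical HPLC-derived tie-line data).
#' @param truth Optional list of noiseless tie-lines (kept by the
#'   synthetic generator for recovery tests).
#' @param truth_params Optional [nrtl_params()] ground truth.
#' @return An object of class `tieline_dataset`.
#' @export
tieline_dataset <- function(components, tielines, noise_sd = 0.003,
                            truth = NULL, truth_params = NULL) {
  if (length(tielines) < 2L)
    stop("a tie-line dataset requires at least 2 tie-lines")
  Ts <- vapply(tielines, function(tl) tl$T, numeric(1))
  if (max(Ts) - min(Ts) > 1e-9)
    stop("all tie-lines in a dataset must share the same temperature")
  structure(list(components = components, tielines = tielines,
                 T = Ts[1], noise_sd = noise_sd,
                 truth = truth, truth_params = truth_params),
            class = "tieline_dataset")
}

#' @export
print.tieline_dataset <- function(x, ...) {
  cat("Tie-line dataset:", length(x$tielines), "tie-lines at", x$T, "K,",
      length(x$components$names), "components",
      sprintf("(noise sd %.4g)\n", x$noise_sd))
  invisible(x)
}

#' Place a feed on a tie-line by fixing one component
#'
#' The feed of a tie-line experiment lies on the straight segment joining
#' the two phase compositions. Fixing the feed mole fraction of component
#' 1 to `z1` determines the remaining components by collinearity:
#' `z = x_II + t (x_I - x_II)` with `t` chosen so that the first component
#' matches. The result automatically satisfies `sum(z) = 1`.
#'
#' @param tieline A [tie_line()].
#' @param z1 Feed mole fraction of component 1; must lie strictly between
#'   the two measured phase values of component 1.
#' @return Feed composition vector `z` on the segment.
#' @export
feed_on_tieline <- function(tieline, z1) {
  x_I <- tieline$x_aq; x_II <- tieline$x_org
  lo <- min(x_I[1], x_II[1]); hi <- max(x_I[1], x_II[1])
  if (!(z1 > lo && z1 < hi))
    stop(sprintf("z1 = %.6g must lie strictly between the measured values %.6g and %.6g",
                 z1, lo, hi))
  t <- (z1 - x_II[1]) / (x_I[1] - x_II[1])
  z <- x_II + t * (x_I - x_II)
  # affine combination of two unit-sum vectors: renormalize only to clean
  # up floating-point residue
  z / sum(z)
}

#' Lever-rule liquid-II fraction of a feed on a tie-line
#'
#' Computes \eqn{L^{II} = d(x^I, z) / d(x^I, x^{II})} from Euclidean
#' distances, the lever rule along the tie-line. The feed must be
#' collinear with the tie-line endpoints.
#'
#' @param tieline A [tie_line()].
#' @param z Feed composition on the tie-line segment.
#' @return The liquid-II (organic) mole fraction, in \[0, 1\].
#' @export
lever_fraction <- function(tieline, z) {
  x_I <- tieline$x_aq; x_II <- tieline$x_org
  dir <- x_II - x_I
  t <- sum((z - x_I) * dir) / sum(dir * dir)
  resid <- sqrt(sum((z - x_I - t * dir)^2))
  if (resid > 1e-8)
    stop(sprintf("feed is not collinear with the tie-line (residual %.3g)", resid))
  L <- sqrt(sum((z - x_I)^2)) / sqrt(sum(dir^2))
  if (t < 0) L <- -L   # outside the segment; caller's precondition violation
  if (L < -1e-10 || L > 1 + 1e-10)
    stop("feed lies outside the tie-line segment")
  min(max(L, 0), 1)
}

#' Non-iterative K-value residual of a tie-line
#'
#' The core of the tie-line-constrained estimation shortcut: instead of
#' flashing a feed iteratively, the feed `z` and liquid-II fraction
#' \eqn{L^{II}} are fixed by the measured tie-line geometry
#' ([feed_on_tieline()] and [lever_fraction()]), the K-values are
#' evaluated one-shot at the measured compositions
#' (\eqn{K_i = \gamma_i(x^I_{meas}) / \gamma_i(x^{II}_{meas})}), and the
#' phase equations then yield computed phase compositions directly:
#' \deqn{x_i^I = z_i / \{1 + (K_i - 1) L^{II}\},\quad x_i^{II} = K_i x_i^I.}
#' The residual is the difference between computed and measured
#' compositions over both phases.
#'
#' @param params An [nrtl_params()] object.
#' @param tieline A [tie_line()].
#' @param z1_rule Feed-placement rule for component 1: `"midpoint"`
#'   (default) or a numeric value strictly between the measured phase
#'   values.
#' @return A list with `computed` (a [tie_line()] of the computed phases,
#'   or `NULL` when degenerate), `residual` (length-2N vector, aqueous
#'   then organic), and `penalized` (logical; `TRUE` when a non-physical
#'   denominator forced the penalty value).
#' @export
kvalue_residual <- function(params, tieline, z1_rule = "midpoint") {
  x_I <- tieline$x_aq; x_II <- tieline$x_org
  n <- length(x_I)
  # re-resolve phase labels internally (liquid I = water-rich) so the
  # residual is invariant to the stored phase order
  water <- component_index(params, "water", 1L)
  solvent <- component_index(params, "octyl_acetate", n)
  if (!resolve_phase_labels(x_I, x_II, water, solvent)) {
    tmp <- x_I; x_I <- x_II; x_II <- tmp
    tieline <- tie_line(x_II, x_I, tieline$T)
  }
  z1 <- if (identical(z1_rule, "midpoint")) (x_I[1] + x_II[1]) / 2 else as.numeric(z1_rule)
  z <- feed_on_tieline(tieline, z1)
  L <- lever_fraction(tieline, z)

  lg_I <- ln_gamma_nrtl(x_I, tieline$T, params)
  lg_II <- ln_gamma_nrtl(x_II, tieline$T, params)
  K <- exp(lg_I - lg_II)

  denom <- 1 + (K - 1) * L
  if (any(denom <= 0)) {
    return(list(computed = NULL, residual = rep(10, 2 * n), penalized = TRUE))
  }
  xc_I <- z / denom
  xc_II <- K * xc_I
  xc_I <- xc_I / sum(xc_I)
  xc_II <- xc_II / sum(xc_II)
  computed <- if (sqrt(sum((xc_I - xc_II)^2)) > 1e-4)
    tie_line(xc_II, xc_I, tieline$T) else NULL
  list(computed = computed,
       residual = c(xc_I - x_I, xc_II - x_II),
       penalized = FALSE)
}

# internal: stack K-value residuals over a dataset for a parameter vector.
# `map` describes which entries of theta go where in the tau/alpha matrices.
dataset_residuals <- function(theta, map, data) {
  params <- map$build(theta)
  res <- lapply(data$tielines, function(tl)
    kvalue_residual(params, tl, map$z1_rule)$residual)
  do.call(c, res)
}

# internal: free-parameter mapping for the fit
make_param_map <- function(components, alpha = 0.2, fit_alpha = FALSE,
                           T_ref = 298.15, z1_rule = "midpoint") {
  n <- length(components$names)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  n_tau <- 2L * nrow(pairs)
  n_par <- n_tau + if (fit_alpha) nrow(pairs) else 0L
  build <- function(theta) {
    tau <- matrix(0, n, n)
    al <- matrix(alpha, n, n); diag(al) <- 0
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      tau[i, j] <- theta[2 * p - 1]
      tau[j, i] <- theta[2 * p]
      if (fit_alpha) { al[i, j] <- al[j, i] <- theta[n_tau + p] }
    }
    nrtl_params(components, tau = tau, alpha = al, T_ref = T_ref)
  }
  lower <- c(rep(-5, n_tau), if (fit_alpha) rep(0.2, nrow(pairs)))
  upper <- c(rep(12, n_tau), if (fit_alpha) rep(0.47, nrow(pairs)))
  list(build = build, n_par = n_par, n_tau = n_tau, pairs = pairs,
       lower = lower, upper = upper, z1_rule = z1_rule)
}

# internal: thermodynamic feasibility of fitted parameters on a dataset.
# For each measured tie-line's feed, the flash must yield a genuine
# two-phase split whose Gibbs energy of mixing is below the single-phase
# value.
gibbs_feasibility <- function(params, data, z1_rule = "midpoint") {
  vapply(data$tielines, function(tl) {
    z1 <- if (identical(z1_rule, "midpoint")) (tl$x_aq[1] + tl$x_org[1]) / 2
          else as.numeric(z1_rule)
    z <- feed_on_tieline(tl, z1)
    fr <- lle_flash(z, tl$T, params)
    if (!fr$two_phase || !fr$converged) return(FALSE)
    g_split <- flash_gibbs(fr, params)
    g_single <- gibbs_mixing_reduced(
      phase_split(list(list(x = z, l = 1)), tl$T), params)
    g_split <= g_single + 1e-12
  }, logical(1))
}

#' Estimate NRTL parameters from tie-line data
#'
#' Fits the NRTL binary interaction parameters to measured tie-lines by
#' minimizing the root-mean-square of the non-iterative
#' [kvalue_residual()] over all tie-lines and both phases. Because the
#' feed and liquid fraction are fixed by tie-line geometry and the
#' K-values are evaluated at the measured compositions, each objective
#' evaluation requires no flash iteration. The minimization runs
#' bounded local least-squares (Levenberg-Marquardt) from multiple
#' Latin-hypercube starting points in \eqn{\tau \in [-5, 12]}.
#'
#' An accepted fit must also be thermodynamically feasible: for every
#' measured feed, the full [lle_flash()] with the fitted parameters must
#' produce a genuine two-phase split whose Gibbs energy of mixing is below
#' the single-phase value. Candidates failing this check are refined with
#' a penalized objective; the best feasible candidate is returned.
#'
#' @param data A [tieline_dataset()].
#' @param alpha Fixed non-randomness value for all pairs (default 0.2,
#'   conventional for LLE regression) unless `fit_alpha = TRUE`.
#' @param fit_alpha Free the non-randomness parameters within
#'   \[0.2, 0.47\].
#' @param n_starts Number of multistart points (default 16).
#' @param init Optional starting tau matrix (e.g. a known nearby
#'   parameter set); used as an additional start.
#' @param z1_rule Feed-placement rule passed to [kvalue_residual()].
#' @param seed RNG seed for the Latin-hypercube starts (default 42).
#' @return An object of class `fit_result`: `params`, `objective` (RMS
#'   composition deviation), `per_tieline_residuals` (tie-lines x 2N
#'   matrix), `gibbs_feasible` (per-tie-line flags), `n_starts`, `seed`,
#'   `convergence` (per-start objective values).
#' @export
estimate_nrtl <- function(data, alpha = 0.2, fit_alpha = FALSE,
                          n_starts = 16L, init = NULL,
                          z1_rule = "midpoint", seed = 42L) {
  stopifnot(inherits(data, "tieline_dataset"))
  map <- make_param_map(data$components, alpha = alpha,
                        fit_alpha = fit_alpha, T_ref = data$T,
                        z1_rule = z1_rule)
  rms <- function(r) sqrt(mean(r^2))

  set.seed(seed)
  grid <- lhs::randomLHS(n_starts, map$n_par)
  starts <- lapply(seq_len(n_starts), function(k)
    map$lower + grid[k, ] * (map$upper - map$lower))
  if (!is.null(init)) {
    theta0 <- numeric(map$n_tau)
    for (p in seq_len(nrow(map$pairs))) {
      i <- map$pairs[p, 1]; j <- map$pairs[p, 2]
      theta0[2 * p - 1] <- init[i, j]; theta0[2 * p] <- init[j, i]
    }
    if (fit_alpha) theta0 <- c(theta0, rep(alpha, nrow(map$pairs)))
    starts <- c(list(pmin(pmax(theta0, map$lower), map$upper)), starts)
  }

  run_start <- function(theta) {
    fit <- try(minpack.lm::nls.lm(
      par = theta, lower = map$lower, upper = map$upper,
      fn = dataset_residuals, map = map, data = data,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    list(theta = fit$par, obj = rms(fit$fvec))
  }

  cands <- Filter(Negate(is.null), lapply(starts, run_start))
  if (!length(cands)) stop("all optimization starts failed")
  cands <- cands[order(vapply(cands, `[[`, numeric(1), "obj"))]

  best <- NULL
  for (cand in cands) {
    params <- map$build(cand$theta)
    feas <- gibbs_feasibility(params, data, z1_rule)
    if (all(feas)) { best <- c(cand, list(params = params, feas = feas)); break }
  }
  if (is.null(best)) {
    # penalized refinement of the least-bad candidates: add a constant
    # infeasibility penalty (10x the objective scale) per violating
    # tie-line and polish by Nelder-Mead
    pen_obj <- function(theta) {
      r <- rms(dataset_residuals(theta, map, data))
      params <- try(map$build(theta), silent = TRUE)
      if (inherits(params, "try-error")) return(1e6)
      feas <- gibbs_feasibility(params, data, z1_rule)
      r + 10 * r * sum(!feas) + 1e-3 * sum(!feas)
    }
    for (cand in cands[seq_len(min(3L, length(cands)))]) {
      opt <- stats::optim(cand$theta, pen_obj, method = "Nelder-Mead",
                          control = list(maxit = 2000))
      params <- map$build(opt$par)
      feas <- gibbs_feasibility(params, data, z1_rule)
      if (all(feas)) {
        best <- list(theta = opt$par,
                     obj = rms(dataset_residuals(opt$par, map, data)),
                     params = params, feas = feas)
        break
      }
    }
  }
  if (is.null(best))
    stop("no thermodynamically feasible parameter set found; ",
         "best infeasible objective = ",
         format(cands[[1]]$obj, digits = 6),
         " (consider more starts or freeing alpha)")

  res_mat <- t(vapply(data$tielines, function(tl)
    kvalue_residual(best$params, tl, z1_rule)$residual,
    numeric(2L * length(data$components$names))))
  structure(list(params = best$params, objective = best$obj,
                 per_tieline_residuals = res_mat,
                 gibbs_feasible = best$feas,
                 n_starts = length(starts), seed = seed,
                 convergence = vapply(cands, `[[`, numeric(1), "obj")),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("NRTL fit: RMS composition deviation %.4g over %d tie-lines\n",
              x$objective, nrow(x$per_tieline_residuals)))
  cat(sprintf("  multistart: %d starts (seed %d), all Gibbs-feasible: %s\n",
              x$n_starts, x$seed, all(x$gibbs_feasible)))
  invisible(x)
}

#' Predicted-vs-measured tie-line overlay
#'
#' Exports, for each measured tie-line in a dataset, the corresponding
#' model-computed tie-line (non-iterative K-value reconstruction with the
#' fitted parameters), in a long data frame ready for ternary-diagram
#' plotting.
#'
#' @param fit A [estimate_nrtl()] result.
#' @param data The [tieline_dataset()] that was fitted.
#' @return A data frame with columns `tieline`, `source`
#'   (measured/computed), `phase` (aqueous/organic) and one column per
#'   component mole fraction.
#' @export
tieline_overlay <- function(fit, data) {
  nms <- data$components$names
  rows <- list()
  for (k in seq_along(data$tielines)) {
    tl <- data$tielines[[k]]
    kv <- kvalue_residual(fit$params, tl, "midpoint")
    add <- function(source, phase, x) {
      r <- c(list(tieline = k, source = source, phase = phase),
             as.list(stats::setNames(x, nms)))
      rows[[length(rows) + 1L]] <<- as.data.frame(r)
    }
    add("measured", "aqueous", tl$x_aq)
    add("measured", "organic", tl$x_org)
    if (!is.null(kv$computed)) {
      add("computed", "aqueous", kv$computed$x_aq)
      add("computed", "organic", kv$computed$x_org)
    }
  }
  do.call(rbind, rows)
}
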