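#' Construct an NRTL parameter set
#'
#' Holds the binary interaction matrix `tau` and the non-randomness matrix
#' `alpha` of the Non-Random Two-Liquid activity-coefficient model for an
#' N-component mixture. `tau` may optionally be temperature dependent in
#' the common two-constant form `tau_ij(T) = a_ij + b_ij / T`; the plain
#' `tau` argument sets `a` with `b = 0`, i.e. a temperature-independent
#' matrix anchored at `T_ref`.
#'
#' @param components A [component_set()].
#' @param tau N x N numeric matrix of dimensionless interaction parameters
#'   (`tau[i, j]` is the parameter for the ordered pair i-j; diagonal must
#'   be zero). Ignored when `a` is supplied.
#' @param alpha N x N symmetric non-randomness matrix with zero diagonal and
#'   off-diagonal entries in \[0, 1\]. A scalar is recycled to all pairs.
#' @param T_ref Reference temperature in kelvin (default 298.15 K, the
#'   isothermal extraction temperature used throughout).
#' @param a,b Optional N x N matrices for the temperature-dependent form
#'   `tau(T) = a + b / T` (b in kelvin).
#' @return An object of class `nrtl_params`.
#' @examples
#' cs <- component_set(c("A", "B"))
#' p <- nrtl_params(cs, tau = matrix(c(0, 3, 3, 0), 2), alpha = 0.2)
#' activity_coefficients(c(0.5, 0.5), 298.15, p)
#' @export
nrtl_params <- function(components, tau = NULL, alpha = 0.3,
                        T_ref = 298.15, a = NULL, b = NULL) {
  n <- length(components$names)
  if (is.null(a)) {
    if (is.null(tau)) tau <- matrix(0, n, n)
    a <- as.matrix(tau)
    b <- matrix(0, n, n)
  } else {
    a <- as.matrix(a)
    if (is.null(b)) b <- matrix(0, n, n)
    b <- as.matrix(b)
  }
  if (!all(dim(a) == c(n, n)) || !all(dim(b) == c(n, n)))
    stop("tau (or a/b) must be ", n, "x", n, " to match the component set")
  if (length(alpha) == 1L) {
    alpha <- matrix(alpha, n, n); diag(alpha) <- 0
  }
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == c(n, n)))
    stop("alpha must be ", n, "x", n, " to match the component set")
  if (any(abs(diag(a)) > 0) || any(abs(diag(b)) > 0))
    stop("diagonal tau parameters must be zero")
  if (any(abs(alpha - t(alpha)) > 1e-12))
    stop("alpha must be symmetric")
  if (any(diag(alpha) != 0)) stop("diagonal alpha must be zero")
  if (any(alpha < 0 | alpha > 1)) stop("alpha entries must lie in [0, 1]")
  if (!is.numeric(T_ref) || T_ref <= 0) stop("T_ref must be a positive temperature in kelvin")
  dimnames(a) <- dimnames(b) <- dimnames(alpha) <-
    list(components$names, components$names)
  structure(list(components = components, a = a, b = b, alpha = alpha,
                 T_ref = T_ref),
            class = "nrtl_params")
}

#' @export
print.nrtl_params <- function(x, ...) {
  cat("NRTL parameter set for", length(x$components$names),
      "components at T_ref =", x$T_ref, "K\n")
  cat("tau at T_ref:\n"); print(round(nrtl_tau(x, x$T_ref), 4))
  cat("alpha:\n"); print(round(x$alpha, 4))
  invisible(x)
}

#' Interaction matrix at a given temperature
#'
#' @param params An [nrtl_params()] object.
#' @param T Temperature in kelvin.
#' @return The N x N `tau(T) = a + b / T` matrix.
#' @export
nrtl_tau <- function(params, T = params$T_ref) {
  params$a + params$b / T
}

#' NRTL activity coefficients
#'
#' Evaluates the multicomponent NRTL expression
#' \deqn{\ln\gamma_i = \frac{\sum_j \tau_{ji} G_{ji} x_j}{\sum_k G_{ki} x_k}
#'   + \sum_j \frac{x_j G_{ij}}{\sum_k G_{kj} x_k}
#'     \left(\tau_{ij} - \frac{\sum_m x_m \tau_{mj} G_{mj}}{\sum_k G_{kj} x_k}\right)}
#' with \eqn{G_{ij} = \exp(-\alpha_{ij}\tau_{ij})}. Vertex compositions are
#' valid inputs: the expression reduces to the pure-component limit
#' (\eqn{\gamma = 1}) for the dominant component and to the
#' infinite-dilution limit for the others.
#'
#' @param x Mole-fraction vector (sums to 1 within 1e-9).
#' @param T Temperature in kelvin.
#' @param params An [nrtl_params()] object whose dimension matches `x`.
#' @return Numeric vector of activity coefficients, all positive and finite.
#' @export
activity_coefficients <- function(x, T, params) {
  if (!inherits(params, "nrtl_params")) stop("params must be an nrtl_params object")
  if (!is.numeric(T) || T <= 0) stop("T must be a positive temperature in kelvin")
  n <- length(params$components$names)
  check_composition(x, n)
  exp(ln_gamma_nrtl(x, T, params))
}

# internal: ln gamma without composition checks (hot path)
ln_gamma_nrtl <- function(x, T, params) {
  tau <- params$a + params$b / T
  G <- exp(-params$alpha * tau)
  # S_j = sum_k G_kj x_k ; C_j = sum_m x_m tau_mj G_mj
  S <- as.numeric(crossprod(G, x))        # length n, S[j]
  C <- as.numeric(crossprod(tau * G, x))  # C[j]
  term1 <- C / S                           # evaluated at j = i
  # term2_i = sum_j x_j G_ij / S_j * (tau_ij - C_j / S_j)
  term2 <- as.numeric((G * (tau - rep(C / S, each = nrow(G)))) %*% (x / S))
  term1 + term2
}

#' Construct a phase split
#'
#' A phase split is a list of coexisting liquid phases, each with a
#' composition and an overall liquid (mole) fraction, at a temperature.
#' Used as the argument of [gibbs_mixing_reduced()].
#'
#' @param phases List of phases; each phase is a list with elements `x`
#'   (mole fractions summing to 1) and `l` (liquid fraction). Liquid
#'   fractions must sum to 1 across phases.
#' @param T Temperature in kelvin.
#' @return An object of class `phase_split`.
#' @export
phase_split <- function(phases, T) {
  if (!length(phases)) stop("phase split requires at least one phase")
  ls <- vapply(phases, function(p) p$l, numeric(1))
  if (any(ls < 0 | ls > 1)) stop("liquid fractions must lie in [0, 1]")
  if (abs(sum(ls) - 1) > 1e-12) stop("liquid fractions must sum to 1")
  for (p in phases) {
    if (any(p$x < 0 | p$x > 1)) stop("phase compositions must lie in [0, 1]")
    if (abs(sum(p$x) - 1) > 1e-12) stop("each phase composition must sum to 1")
  }
  structure(list(phases = phases, T = T), class = "phase_split")
}

#' Reduced Gibbs free energy of mixing
#'
#' Computes the dimensionless Gibbs free energy of mixing of a (possibly
#' multi-phase) liquid system,
#' \deqn{\Delta G_{mix}/RT = \sum_{k=1}^{N_p}\sum_{i=1}^{N_c}
#'   l_i^k\,(\ln x_i^k + \ln\gamma_i^k),}
#' where \eqn{l_i^k = l^k x_i^k} is the overall mole fraction held by
#' component i in phase k. At equilibrium this quantity is at a minimum
#' over all phase splits of the feed; the flash and the parameter
#' estimation use it as the thermodynamic feasibility criterion.
#'
#' Zero mole fractions follow the convention \eqn{x \ln x \to 0}.
#'
#' @param split A [phase_split()].
#' @param params An [nrtl_params()] object.
#' @return Dimensionless \eqn{\Delta G_{mix}/RT} (non-positive for a
#'   single ideal phase).
#' @export
gibbs_mixing_reduced <- function(split, params) {
  if (!inherits(split, "phase_split")) stop("split must be a phase_split object")
  total <- 0
  for (p in split$phases) {
    if (p$l == 0) next
    x <- p$x
    lg <- ln_gamma_nrtl(x, split$T, params)
    pos <- x > 0
    total <- total + p$l * sum(x[pos] * (log(x[pos]) + lg[pos]))
  }
  total
}

#' Tangent-plane phase-stability test
#'
#' Tests whether a liquid of composition `z` is stable as a single phase
#' by minimizing the tangent-plane distance
#' \deqn{TPD(w) = \sum_i w_i\,(\ln w_i + \ln\gamma_i(w)
#'   - \ln z_i - \ln\gamma_i(z))}
#' over trial compositions `w`, using Michelsen-style successive
#' substitution from vertex-biased starting points. A negative minimum
#' (below `-1e-8`) proves instability; the corresponding trial phase is a
#' suitable initialization for [lle_flash()].
#'
#' @param z Mole-fraction vector on the simplex.
#' @param T Temperature in kelvin.
#' @param params An [nrtl_params()] object.
#' @param n_starts Extra random interior starts in addition to the
#'   vertex-biased ones.
#' @return A list with elements `stable` (logical), `tpd_min` (smallest
#'   tangent-plane distance found), and `trial` (the minimizing trial
#'   composition, useful as a flash initialization when unstable).
#' @export
stability_test <- function(z, T, params, n_starts = 0L) {
  n <- length(params$components$names)
  check_composition(z, n)
  # pure components are trivially stable
  if (any(z >= 1 - 1e-12)) {
    return(list(stable = TRUE, tpd_min = 0, trial = z))
  }
  zi <- pmax(z, 1e-30)
  d <- log(zi) + ln_gamma_nrtl(z, T, params)  # feed chemical-potential offsets

  tpd <- function(w) {
    w <- pmax(w, 1e-30); w <- w / sum(w)
    sum(w * (log(w) + ln_gamma_nrtl(w, T, params) - d))
  }

  starts <- lapply(seq_len(n), function(i) {
    w <- rep(0.5 / (n - 1) * 0.2, n); w[i] <- 1 - sum(w[-i]); w / sum(w)
  })
  # vertex-biased: mostly component i with a trace of the feed
  starts <- c(starts, lapply(seq_len(n), function(i) {
    w <- 0.05 * z; w[i] <- w[i] + 0.95; w / sum(w)
  }))
  if (n_starts > 0L) {
    starts <- c(starts, lapply(seq_len(n_starts), function(k) {
      w <- stats::runif(n); w / sum(w)
    }))
  }

  best <- list(tpd = Inf, w = z)
  for (w in starts) {
    # successive substitution on W_i = exp(d_i - ln gamma_i(w))
    for (it in 1:200) {
      lg <- ln_gamma_nrtl(w, T, params)
      W <- exp(d - lg)
      w_new <- W / sum(W)
      if (max(abs(w_new - w)) < 1e-12) { w <- w_new; break }
      w <- w_new
    }
    v <- tpd(w)
    if (v < best$tpd) best <- list(tpd = v, w = w)
  }
  list(stable = best$tpd >= -1e-8, tpd_min = best$tpd, trial = best$w)
}
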