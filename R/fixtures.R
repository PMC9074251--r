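#' Synthetic demixing systems for testing and demonstration
#'
#' Builds a component set plus an NRTL parameter set with a known,
#' verified two-phase region. These synthetic systems stand in for
#' measured or simulated tie-line sources so that the whole
#' fit/flash/cascade pipeline can be exercised without external data.
#' They do not represent any specific real solvent system.
#'
#' Presets:
#' \describe{
#'   \item{`binary_symmetric`}{Two components with symmetric
#'     \eqn{\tau_{12} = \tau_{21} \approx 3}, \eqn{\alpha = 0.2}; the
#'     binodal is symmetric about the equimolar point.}
#'   \item{`ternary_type1`}{water/solute/solvent with exactly one
#'     immiscible binary edge (water-solvent); the solute is miscible
#'     with both.}
#'   \item{`ternary_broth_like`}{water/solute/ester mimicking a dilute
#'     fermentation-acid / high-boiling-ester extraction system: wide
#'     water-ester immiscibility and a solute that partitions to the
#'     ester phase (distribution coefficient D > 1).}
#'   \item{`quaternary_broth_like`}{the ternary broth-like system plus a
#'     minor second acid (water/acetic-like/solute/ester), for exercising
#'     extractor-scale stream calculations with a side product. A
#'     synthetic stand-in only; it does not reproduce any measured
#'     quaternary parameter set.}
#' }
#' The seed applies a small deterministic jitter (within 5 percent) to
#' the off-diagonal interaction parameters so different seeds give
#' distinct ground truths; the qualitative phase behaviour is preserved.
#'
#' @param kind Preset name.
#' @param seed Integer seed; identical seeds give identical systems.
#' @return An object of class `lle_system`: a list with `components`,
#'   `params`, `solute` (solute index, `NA` for binary), and `kind`.
#' @export
make_demixing_system <- function(kind = c("ternary_broth_like",
                                          "ternary_type1",
                                          "binary_symmetric",
                                          "quaternary_broth_like"),
                                 seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  jitter <- function(m) {
    j <- matrix(stats::runif(length(m), 0.975, 1.025), nrow(m))
    out <- m * j; diag(out) <- 0; out
  }
  if (kind == "binary_symmetric") {
    cs <- component_set(c("water", "solvent"), c(18.015, 172.26))
    t12 <- 3 * stats::runif(1, 0.975, 1.025)
    tau <- matrix(c(0, t12, t12, 0), 2)
    params <- nrtl_params(cs, tau = tau, alpha = 0.2)
    solute <- NA_integer_
  } else if (kind == "ternary_type1") {
    cs <- component_set(c("water", "solute", "solvent"),
                        c(18.015, 88.106, 172.26))
    tau <- jitter(matrix(c(0,   0.5, 3.2,
                           1.0, 0,   0.3,
                           3.2, 0.3, 0), 3, byrow = TRUE))
    params <- nrtl_params(cs, tau = tau, alpha = 0.2)
    solute <- 2L
  } else if (kind == "ternary_broth_like") {
    cs <- component_set(c("water", "solute", "ester"),
                        c(18.015, 88.106, 172.26))
    # solute with positive deviations from water (pushed out of the
    # aqueous phase) and near-ideal affinity for the ester
    tau <- jitter(matrix(c(0,    0.8, 4.0,
                           1.5,  0,  -0.3,
                           3.0, -0.2, 0), 3, byrow = TRUE))
    params <- nrtl_params(cs, tau = tau, alpha = 0.2)
    solute <- 2L
  } else {
    cs <- component_set(c("water", "acetic_acid", "butyric_acid",
                          "octyl_acetate"),
                        c(18.015, 60.052, 88.106, 172.26))
    # broth-like ternary extended with a weakly partitioning minor acid
    tau <- jitter(matrix(c(0,    0.3,  0.8, 4.0,
                           0.6,  0,    0,   0.8,
                           1.5,  0,    0,  -0.3,
                           3.0,  0.5, -0.2, 0), 4, byrow = TRUE))
    params <- nrtl_params(cs, tau = tau, alpha = 0.2)
    solute <- 3L
  }
  sys <- structure(list(components = cs, params = params,
                        solute = solute, kind = kind, seed = seed),
                   class = "lle_system")
  # the contract of a demixing preset: a two-phase region must exist
  mid <- rep(0, length(cs$names))
  edge <- if (kind == "binary_symmetric") c(1L, 2L) else c(1L, length(cs$names))
  mid[edge] <- 0.5
  if (stability_test(mid, params$T_ref, params)$stable)
    stop("internal error: preset '", kind, "' produced a miscible system")
  sys
}

#' @export
print.lle_system <- function(x, ...) {
  cat("Synthetic LLE system '", x$kind, "' (seed ", x$seed, "): ",
      paste(x$components$names, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic tie-line dataset with measurement noise
#'
#' Traces the noiseless binodal of a synthetic system ([binodal_curve()])
#' and perturbs every composition entry with truncated Gaussian noise
#' (clipped to \[0, 1\], then renormalized to the simplex), emulating
#' tie-line measurements with a stated standard uncertainty in mole
#' fraction. The noiseless truth and the generating parameters are kept
#' alongside for parameter-recovery tests.
#'
#' @param system An `lle_system` from [make_demixing_system()].
#' @param n Number of tie-lines (>= 2).
#' @param noise_sd Measurement noise standard deviation in mole fraction;
#'   0.003 is typical of careful HPLC phase analysis.
#' @param seed Integer RNG seed.
#' @param T Temperature in kelvin (default the parameter set reference).
#' @return A [tieline_dataset()] with `truth` (noiseless tie-lines) and
#'   `truth_params` attached.
#' @export
generate_tielines <- function(system, n = 6L, noise_sd = 0.003, seed = 1L,
                              T = system$params$T_ref) {
  stopifnot(inherits(system, "lle_system"), n >= 2L, noise_sd >= 0)
  truth <- binodal_curve(T, system$params, n_lines = n)
  if (length(truth) < n)
    stop("binodal tracing produced only ", length(truth), " of ", n,
         " requested tie-lines")
  set.seed(seed)
  perturb <- function(x) {
    y <- pmin(pmax(x + stats::rnorm(length(x), 0, noise_sd), 0), 1)
    y / sum(y)
  }
  noisy <- lapply(truth, function(tl)
    tie_line(perturb(tl$x_org), perturb(tl$x_aq), tl$T))
  tieline_dataset(system$components, noisy, noise_sd = noise_sd,
                  truth = truth, truth_params = system$params)
}

#' RMS deviation between two binodal tie-line sets
#'
#' Pairs tie-lines by order and computes the root-mean-square difference
#' over all composition entries of both phases. Used to compare a fitted
#' model's binodal against the generating truth.
#'
#' @param a,b Lists of [tie_line()] objects of equal length.
#' @return RMS composition deviation (mole fraction).
#' @export
binodal_rms <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  devs <- mapply(function(p, q) {
    c(p$x_org - q$x_org, p$x_aq - q$x_aq)
  }, a, b, SIMPLIFY = FALSE)
  sqrt(mean(unlist(devs)^2))
}
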