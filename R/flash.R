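#' Construct a tie-line
#'
#' A tie-line joins the compositions of two coexisting liquid phases at a
#' temperature: the organic (solvent-rich) phase and the aqueous
#' (water-rich) phase.
#'
#' @param x_org Organic-phase mole fractions (sum to 1 within 1e-6).
#' @param x_aq Aqueous-phase mole fractions (sum to 1 within 1e-6).
#' @param T Temperature in kelvin.
#' @return An object of class `tie_line`.
#' @export
tie_line <- function(x_org, x_aq, T = 298.15) {
  x_org <- as.numeric(x_org); x_aq <- as.numeric(x_aq)
  if (length(x_org) != length(x_aq))
    stop("tie-line phases must have the same number of components")
  for (x in list(x_org, x_aq)) {
    if (any(x < 0)) stop("tie-line compositions must be non-negative")
    if (abs(sum(x) - 1) > 1e-6)
      stop("tie-line compositions must sum to 1 within 1e-6")
  }
  if (sqrt(sum((x_org - x_aq)^2)) <= 1e-4)
    stop("tie-line phases must be distinct (Euclidean distance > 1e-4)")
  structure(list(x_org = x_org, x_aq = x_aq, T = T), class = "tie_line")
}

#' @export
print.tie_line <- function(x, ...) {
  cat("Tie-line at", x$T, "K\n")
  cat("  organic:", paste(sprintf("%.4f", x$x_org), collapse = " "), "\n")
  cat("  aqueous:", paste(sprintf("%.4f", x$x_aq), collapse = " "), "\n")
  invisible(x)
}

# internal: tie-line length in composition space
tieline_length <- function(tl) sqrt(sum((tl$x_org - tl$x_aq)^2))

# internal: solve the Rachford-Rice-type phase equation
# f(L) = sum_i z_i (K_i - 1) / (1 + (K_i - 1) L) = 0 for L in (0,1),
# bisection-safeguarded Newton, |f| tolerance 1e-12 equivalent via step size.
rachford_rice <- function(z, K, tol = 1e-12) {
  u <- K - 1
  f <- function(L) sum(z * u / (1 + u * L))
  f0 <- f(0); f1 <- f(1)
  if (f0 <= 0) return(0)   # all liquid I
  if (f1 >= 0) return(1)   # all liquid II
  lo <- 0; hi <- 1; L <- 0.5
  for (it in 1:200) {
    fl <- f(L)
    if (fl > 0) lo <- L else hi <- L
    dfl <- -sum(z * u^2 / (1 + u * L)^2)
    Ln <- L - fl / dfl
    if (!is.finite(Ln) || Ln <= lo || Ln >= hi) Ln <- (lo + hi) / 2
    if (abs(Ln - L) < tol) return(Ln)
    L <- Ln
  }
  L
}

# internal: resolve the aqueous/organic labels of a two-phase split.
# Liquid I = aqueous = water-rich; ties broken by (lower) solvent content.
# `water` / `solvent` are component indices (defaulting to 1 and N).
resolve_phase_labels <- function(xA, xB, water = 1L, solvent = NULL) {
  n <- length(xA)
  if (is.null(solvent)) solvent <- n
  if (abs(xA[water] - xB[water]) > 1e-12) {
    a_first <- xA[water] > xB[water]
  } else {
    a_first <- xA[solvent] < xB[solvent]
  }
  a_first
}

# internal: index of a named component, with positional fallback
component_index <- function(params, name, fallback) {
  idx <- match(name, params$components$names)
  if (is.na(idx)) fallback else idx
}

#' Isothermal two-liquid-phase flash
#'
#' Splits a feed of composition `z` into two equilibrium liquid phases by
#' solving the phase equations
#' \deqn{x_i^I = z_i / \{1 + (K_i - 1) L^{II}\},\quad
#'       x_i^{II} = K_i x_i^I,\quad K_i = \gamma_i^I / \gamma_i^{II},}
#' by successive substitution on the K-values with an inner one-dimensional
#' Rachford-Rice solve for the liquid-II fraction \eqn{L^{II}}. Oscillation
#' triggers damping (factor 0.5); a collapse onto the trivial solution
#' triggers a perturbed restart. A feed that passes the
#' [stability_test()] is returned unsplit with `converged = TRUE`.
#'
#' Phase labels follow the aqueous/organic convention: liquid I is the
#' water-rich phase (component named `"water"`, else component 1), liquid
#' II the solvent-rich phase.
#'
#' @param z Feed mole fractions on the simplex.
#' @param T Temperature in kelvin.
#' @param params An [nrtl_params()] object.
#' @param init Optional trial composition for the incipient phase; when
#'   absent the stability test supplies it.
#' @param max_iter Maximum outer iterations (default 500).
#' @param tol Iso-activity convergence tolerance on
#'   \eqn{\max_i |x_i^I\gamma_i^I - x_i^{II}\gamma_i^{II}|} (default 1e-10).
#' @return An object of class `flash_result` with elements `x_I`, `x_II`,
#'   `L_II`, `K`, `gamma_I`, `gamma_II`, `converged`, `iterations`,
#'   `iso_activity_residual`, `two_phase`, `T`, `z`.
#' @export
lle_flash <- function(z, T, params, init = NULL, max_iter = 500, tol = 1e-10) {
  n <- length(params$components$names)
  check_composition(z, n)
  water <- component_index(params, "water", 1L)
  solvent <- component_index(params, "octyl_acetate", n)

  single_phase <- function(converged = TRUE) {
    g <- exp(ln_gamma_nrtl(z, T, params))
    structure(list(x_I = z, x_II = z, L_II = 0, K = rep(1, n),
                   gamma_I = g, gamma_II = g, converged = converged,
                   iterations = 0L, iso_activity_residual = 0,
                   two_phase = FALSE, T = T, z = z),
              class = "flash_result")
  }

  if (is.null(init)) {
    st <- stability_test(z, T, params)
    if (st$stable) return(single_phase())
    init <- st$trial
  }

  zi <- pmax(z, 1e-30)
  K <- pmax(init, 1e-12) / zi
  K_prev_step <- NULL
  restarts <- 0L
  damp <- 1

  for (iter in seq_len(max_iter)) {
    L <- rachford_rice(z, K)
    L <- min(max(L, 1e-10), 1 - 1e-10)
    x_I <- zi / (1 + (K - 1) * L)
    x_II <- K * x_I
    x_I <- x_I / sum(x_I); x_II <- x_II / sum(x_II)

    if (sqrt(sum((x_I - x_II)^2)) < 1e-4) {
      # trivial solution: perturb and restart
      restarts <- restarts + 1L
      if (restarts > 5L) {
        return(single_phase(converged = FALSE))
      }
      pert <- stats::runif(n, 0.5, 2)
      K <- K * pert^restarts
      next
    }

    lg_I <- ln_gamma_nrtl(x_I, T, params)
    lg_II <- ln_gamma_nrtl(x_II, T, params)
    K_new <- exp(lg_I - lg_II)
    step <- log(K_new) - log(K)
    if (!is.null(K_prev_step) && sum(step * K_prev_step) < 0) damp <- 0.5
    K <- exp(log(K) + damp * step)
    K_prev_step <- step

    res <- max(abs(x_I * exp(lg_I) - x_II * exp(lg_II)))
    if (res < tol && max(abs(step)) < 1e-10) {
      # final consistent assembly at the converged K
      L <- rachford_rice(z, K)
      x_I <- zi / (1 + (K - 1) * L); x_II <- K * x_I
      x_I <- x_I / sum(x_I); x_II <- x_II / sum(x_II)
      lg_I <- ln_gamma_nrtl(x_I, T, params)
      lg_II <- ln_gamma_nrtl(x_II, T, params)
      res <- max(abs(x_I * exp(lg_I) - x_II * exp(lg_II)))
      a_first <- resolve_phase_labels(x_I, x_II, water, solvent)
      if (!a_first) {
        tmp <- x_I; x_I <- x_II; x_II <- tmp
        tmpg <- lg_I; lg_I <- lg_II; lg_II <- tmpg
        L <- 1 - L
      }
      K_out <- x_II / pmax(x_I, 1e-300)
      return(structure(list(
        x_I = x_I, x_II = x_II, L_II = L, K = K_out,
        gamma_I = exp(lg_I), gamma_II = exp(lg_II),
        converged = TRUE, iterations = iter, iso_activity_residual = res,
        two_phase = TRUE, T = T, z = z), class = "flash_result"))
    }
  }
  structure(list(x_I = x_I, x_II = x_II, L_II = L, K = K,
                 gamma_I = exp(lg_I), gamma_II = exp(lg_II),
                 converged = FALSE, iterations = max_iter,
                 iso_activity_residual = res, two_phase = TRUE,
                 T = T, z = z), class = "flash_result")
}

#' @export
print.flash_result <- function(x, ...) {
  if (!x$two_phase) {
    cat("Flash: single stable liquid phase\n")
  } else {
    cat(sprintf("Flash: two phases, L_II = %.6f (%s, %d iterations)\n",
                x$L_II, if (x$converged) "converged" else "NOT converged",
                x$iterations))
    cat("  x_I (aqueous):", paste(sprintf("%.5f", x$x_I), collapse = " "), "\n")
    cat("  x_II (organic):", paste(sprintf("%.5f", x$x_II), collapse = " "), "\n")
    cat(sprintf("  iso-activity residual: %.2e\n", x$iso_activity_residual))
  }
  invisible(x)
}

# internal: reduced Gibbs energy of a flash result, for feasibility checks
flash_gibbs <- function(fr, params) {
  if (!fr$two_phase) {
    split <- phase_split(list(list(x = fr$z, l = 1)), fr$T)
  } else {
    split <- phase_split(list(list(x = fr$x_I, l = 1 - fr$L_II),
                              list(x = fr$x_II, l = fr$L_II)), fr$T)
  }
  gibbs_mixing_reduced(split, params)
}

#' Trace the binodal curve as a sequence of tie-lines
#'
#' Marches feed compositions from the immiscible binary (water/solvent)
#' edge of the composition simplex toward the plait point, flashing each
#' feed, and returns the resulting tie-lines ordered by increasing solute
#' content. Marching stops when the tie-line length falls below 1e-3
#' (plait-point approach) or the feed becomes single-phase.
#'
#' @param T Temperature in kelvin.
#' @param params An [nrtl_params()] object (2 or 3 components).
#' @param n_lines Number of tie-lines requested.
#' @return List of [tie_line()] objects (empty, with a warning, for a
#'   fully miscible system).
#' @export
binodal_curve <- function(T, params, n_lines = 10L) {
  n <- length(params$components$names)
  if (n < 2L) stop("binodal tracing requires at least 2 components")
  # locate the immiscible binary edge; the water/solvent edge (first and
  # last components) is checked first, matching the usual layout
  pair_order <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pref <- pair_order[, 1] == 1L & pair_order[, 2] == n
  pair_order <- rbind(pair_order[pref, , drop = FALSE],
                      pair_order[!pref, , drop = FALSE])
  edge <- NULL
  for (r in seq_len(nrow(pair_order))) {
    i <- pair_order[r, 1]; j <- pair_order[r, 2]
    z <- rep(0, n); z[i] <- 0.5; z[j] <- 0.5
    if (!stability_test(z, T, params)$stable) { edge <- c(i, j); break }
  }
  if (is.null(edge)) {
    warning("system is fully miscible under these parameters; no binodal")
    return(list())
  }
  mid <- rep(0, n); mid[edge] <- 0.5

  if (n == 2L) {
    fr <- lle_flash(mid, T, params)
    return(list(tie_line(fr$x_II, fr$x_I, T)))
  }
  solute <- setdiff(seq_len(n), edge)[1]
  e_sol <- rep(0, n); e_sol[solute] <- 1

  flash_at <- function(s) lle_flash((1 - s) * mid + s * e_sol, T, params)

  # coarse march to bracket the plait point
  s_vals <- 0; frs <- list(flash_at(0))
  if (!frs[[1]]$two_phase) {
    warning("binary edge flash did not split; no binodal")
    return(list())
  }
  ds <- 0.02; s <- 0
  repeat {
    s_next <- s + ds
    if (s_next >= 1) break
    fr <- flash_at(s_next)
    if (!fr$two_phase || !fr$converged ||
        sqrt(sum((fr$x_I - fr$x_II)^2)) < 1e-3) break
    s <- s_next
    s_vals <- c(s_vals, s); frs <- c(frs, list(fr))
  }
  # refine the plait-point bound by bisection on the last step
  lo <- s; hi <- min(s + ds, 1)
  for (it in 1:20) {
    m <- (lo + hi) / 2
    fr <- lle_flash((1 - m) * mid + m * e_sol, T, params)
    if (fr$two_phase && fr$converged &&
        sqrt(sum((fr$x_I - fr$x_II)^2)) >= 1e-3) lo <- m else hi <- m
    if (hi - lo < 1e-4) break
  }
  s_end <- lo
  # evenly spaced feeds from the edge to just inside the plait point
  s_grid <- seq(0, s_end, length.out = n_lines)
  out <- vector("list", n_lines)
  for (k in seq_len(n_lines)) {
    fr <- flash_at(s_grid[k])
    if (!fr$two_phase || !fr$converged) next
    out[[k]] <- tie_line(fr$x_II, fr$x_I, T)
  }
  out <- Filter(Negate(is.null), out)
  # order by solute content of the organic phase
  ord <- order(vapply(out, function(tl) tl$x_org[solute], numeric(1)))
  out[ord]
}
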