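#' Define an ordered set of mixture components
#'
#' A component set fixes the ordering of components used by every
#' composition vector, parameter matrix and stream in the package, and
#' carries molar masses for mass/mole conversions.
#'
#' @param names Character vector of unique component identifiers, e.g.
#'   `c("water", "butyric_acid", "octyl_acetate")`.
#' @param molar_mass Numeric vector of molar masses in g/mol, one per
#'   component. Only used when converting between mass and mole bases;
#'   defaults to `NA` (conversion unavailable until supplied).
#' @return An object of class `component_set`.
#' @examples
#' component_set(c("water", "butyric_acid", "octyl_acetate"),
#'               molar_mass = c(18.015, 88.106, 172.26))
#' @export
component_set <- function(names, molar_mass = rep(NA_real_, length(names))) {
  if (length(names) == 0L) stop("component set must contain at least one component")
  names <- as.character(names)
  if (anyDuplicated(names)) stop("component names must be unique")
  if (any(!nzchar(names))) stop("component names must be nonempty")
  molar_mass <- as.numeric(molar_mass)
  if (length(molar_mass) != length(names))
    stop("molar_mass must have one entry per component")
  if (any(!is.na(molar_mass) & molar_mass <= 0))
    stop("molar masses must be positive")
  structure(list(names = names, molar_mass = stats::setNames(molar_mass, names)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat("Component set (", length(x$names), "):\n", sep = "")
  for (nm in x$names) {
    mm <- x$molar_mass[[nm]]
    cat("  ", nm, if (!is.na(mm)) sprintf(" (%.3f g/mol)", mm) else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.component_set <- function(x) length(x$names)

#' Convert between mass and mole fractions
#'
#' @param x Numeric fraction vector (sums to 1).
#' @param components A [component_set()] with molar masses.
#' @return Numeric vector of converted fractions summing to 1.
#' @name fraction-conversion
NULL

#' @rdname fraction-conversion
#' @export
mass_to_mole <- function(x, components) {
  mm <- components$molar_mass
  if (anyNA(mm)) stop("molar masses required for mass/mole conversion")
  n <- x / mm
  as.numeric(n / sum(n))
}

#' @rdname fraction-conversion
#' @export
mole_to_mass <- function(x, components) {
  mm <- components$molar_mass
  if (anyNA(mm)) stop("molar masses required for mass/mole conversion")
  w <- x * mm
  as.numeric(w / sum(w))
}

# internal: validate a mole-fraction vector against a component set
check_composition <- function(x, n_comp, tol = 1e-9, what = "composition") {
  if (length(x) != n_comp)
    stop(sprintf("%s has length %d but the system has %d components",
                 what, length(x), n_comp))
  if (any(x < 0)) stop(sprintf("%s has negative entries", what))
  if (abs(sum(x) - 1) > tol)
    stop(sprintf("%s does not sum to 1 (sum = %.12g)", what, sum(x)))
  invisible(TRUE)
}
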