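#' Analytic toy potential-energy surfaces
#'
#' Small analytic surfaces (energies in kcal/mol, coordinates in
#' arbitrary length units) used to exercise the accelerated-dynamics
#' engine where the exact Boltzmann distribution is known in closed
#' form.
#'
#' * `harmonic`: `0.5 * kappa * |x|^2`.
#' * `double_well_1d`: `a * (x^2 - b^2)^2`, minima at `x = +/-b` with
#'   energy 0 and an analytic barrier `a * b^4` at `x = 0`.
#' * `double_well_2d`: the 1D double well in `x` plus a transverse
#'   harmonic term `0.5 * kappa * y^2`; exposes the two-term
#'   decomposition needed for dual-boost runs.
#'
#' @param name One of `"harmonic"`, `"double_well_1d"`,
#'   `"double_well_2d"`.
#' @param kappa Harmonic force constant (kcal/mol per unit^2), > 0.
#' @param a,b Double-well parameters (`a` in kcal/mol per unit^4,
#'   `b` in length units), > 0.
#' @return An object of class `potential_surface` with elements
#'   `dimensionality`, `energy(x)`, `gradient(x)` (both take a numeric
#'   vector of length `dimensionality`), and for the 2D well a `terms`
#'   list with the two additive components.
#' @examples
#' pot <- toy_potential("double_well_1d", a = 7, b = 1)
#' pot$energy(0)   # barrier height a * b^4 = 7
#' @export
toy_potential <- function(name = c("harmonic", "double_well_1d",
                                   "double_well_2d"),
                          kappa = 1, a = 7, b = 1) {
  name <- match.arg(name)
  if (kappa <= 0 || a <= 0 || b <= 0)
    stop("potential parameters must be positive")
  surf <- switch(name,
    harmonic = list(
      dimensionality = 1L,
      energy = function(x) 0.5 * kappa * sum(x^2),
      gradient = function(x) kappa * x),
    double_well_1d = list(
      dimensionality = 1L,
      energy = function(x) a * (x[1]^2 - b^2)^2,
      gradient = function(x) 4 * a * x[1] * (x[1]^2 - b^2),
      barrier = a * b^4,
      minima = c(-b, b)),
    double_well_2d = {
      e1 <- function(x) a * (x[1]^2 - b^2)^2
      g1 <- function(x) c(4 * a * x[1] * (x[1]^2 - b^2), 0)
      e2 <- function(x) 0.5 * kappa * x[2]^2
      g2 <- function(x) c(0, kappa * x[2])
      list(
        dimensionality = 2L,
        energy = function(x) e1(x) + e2(x),
        gradient = function(x) g1(x) + g2(x),
        barrier = a * b^4,
        terms = list(
          structure(list(dimensionality = 2L, energy = e1,
                         gradient = g1), class = "potential_surface"),
          structure(list(dimensionality = 2L, energy = e2,
                         gradient = g2), class = "potential_surface")))
    })
  surf$name <- name
  structure(surf, class = "potential_surface")
}

#' Check a surface's gradient against finite differences
#'
#' @param potential A `potential_surface`.
#' @param x Point at which to compare.
#' @param h Finite-difference step.
#' @return Maximum relative discrepancy between analytic and central
#'   finite-difference gradient components.
#' @export
gradient_check <- function(potential, x, h = 1e-6) {
  g <- potential$gradient(x)
  fd <- vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (potential$energy(xp) - potential$energy(xm)) / (2 * h)
  }, 0)
  max(abs(g - fd) / pmax(abs(fd), 1e-8))
}
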