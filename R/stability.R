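# Local stability machinery.  At any equilibrium the characteristic
# polynomial of the 4x4 Jacobian factors as
#   (lambda + omega + mu)(lambda^3 + c1 lambda^2 + c2 lambda + c3)
# because the vaccinated class is driven but not coupled back through the
# infection terms.  c1..c3 are computed from closed forms; the Jacobian
# spectrum serves as the independent oracle in the test suite.

marginal_band <- 1e-8

verdict_from_re <- function(max_re, band = marginal_band) {
  if (abs(max_re) < band) "marginal"
  else if (max_re < 0) "stable"
  else "unstable"
}

assert_equilibrium <- function(state, params, tol = 1e-6) {
  res <- max(abs(seiv_rhs(state, params)))
  if (res > tol * params$A)
    stop(sprintf("state is not an equilibrium (max |rhs| = %.3g)", res),
         call. = FALSE)
  invisible(res)
}

#' Cubic characteristic coefficients at an endemic equilibrium
#'
#' Closed forms of the coefficients of the cubic factor of the
#' characteristic polynomial, in terms of the auxiliary rates
#' \eqn{E = \beta I^*(1+\alpha I^*)} (force of infection at equilibrium)
#' and \eqn{F = \beta S^*(1+2\alpha I^*)} (marginal transmission):
#' \deqn{c_1 = 3\mu+\tau+\sigma+\epsilon+E}
#' \deqn{c_2 = (\mu+E)(2\mu+\tau+\sigma+\epsilon) +
#'             (\tau+\mu+\epsilon)(\mu+\sigma) - \sigma F}
#' \deqn{c_3 = (\mu+E)(\tau+\mu+\epsilon)(\mu+\sigma) - \sigma\tau E -
#'             \mu\sigma F}
#' The roots of this cubic together with \eqn{-(\omega+\mu)} make up the
#' full Jacobian spectrum.  (In the \eqn{c_3} expression the
#' \eqn{\sigma\tau E} term enters with a minus sign; see the methods
#' vignette for the cofactor derivation.)
#'
#' @param at an endemic equilibrium state vector; verified by substitution
#'   into the vector field (error if not an equilibrium).
#' @param params a [seiv_params] object.
#' @param check verify `at` is an equilibrium (default `TRUE`).
#' @return List with `c1`, `c2`, `c3`, `E_aux`, `F_aux`.
#' @export
cubic_coefficients <- function(at, params, check = TRUE) {
  x <- as_state(at)
  if (check) assert_equilibrium(x, params)
  with(params, {
    E_aux <- beta * x[["I"]] * (1 + alpha * x[["I"]])
    F_aux <- beta * x[["S"]] * (1 + 2 * alpha * x[["I"]])
    c1 <- 3 * mu + tau + sigma + epsilon + E_aux
    c2 <- (mu + E_aux) * (2 * mu + tau + sigma + epsilon) +
      (tau + mu + epsilon) * (mu + sigma) - sigma * F_aux
    c3 <- (mu + E_aux) * (tau + mu + epsilon) * (mu + sigma) -
      sigma * tau * E_aux - mu * sigma * F_aux
    list(c1 = c1, c2 = c2, c3 = c3, E_aux = E_aux, F_aux = F_aux)
  })
}

#' Local stability of the disease-free equilibrium
#'
#' The disease-free equilibrium is locally asymptotically stable when
#' `R0 < 1` and unstable when `R0 > 1`; `R0 = 1` is the bifurcation point.
#' The threshold verdict is cross-checked against the sign of the largest
#' real part of the Jacobian spectrum at `P0` and an error is raised if
#' the two disagree outside the marginal band.
#'
#' @param params a [seiv_params] object.
#' @return An object of class `seiv_stability` with components `point`
#'   (`"P0"`), `verdict`, `R0`, `jacobian`, `eigenvalues`, `max_re`.
#' @examples
#' dfe_stability(example1_params())$verdict
#' @export
dfe_stability <- function(params) {
  ts <- seiv_thresholds(params)
  P0 <- disease_free_equilibrium(params)
  J <- seiv_jacobian(P0, params)
  ev <- eigen(J, only.values = TRUE)$values
  max_re <- max(Re(ev))
  verdict_eig <- verdict_from_re(max_re)
  verdict_r0 <- if (abs(ts$R0 - 1) < marginal_band) "marginal"
                else if (ts$R0 < 1) "stable" else "unstable"
  if (verdict_eig != verdict_r0 &&
      !("marginal" %in% c(verdict_eig, verdict_r0)))
    stop("R0 verdict and spectral verdict disagree at P0", call. = FALSE)
  structure(list(point = "P0", verdict = verdict_r0, R0 = ts$R0,
                 jacobian = J, eigenvalues = ev, max_re = max_re),
            class = "seiv_stability")
}

#' Local stability of an endemic equilibrium
#'
#' Evaluates the Routh-Hurwitz conditions `c1 > 0`, `c3 > 0`,
#' `c1*c2 - c3 > 0` for the cubic factor of the characteristic polynomial;
#' all three hold exactly when every eigenvalue other than
#' \eqn{-(\omega+\mu)} has negative real part.  The verdict is required to
#' agree with the sign of the largest real part of the full 4 x 4 Jacobian
#' spectrum (within a marginal band of `1e-8`).
#'
#' @param at a verified endemic equilibrium (see [endemic_equilibria]).
#' @param params a [seiv_params] object.
#' @return An object of class `seiv_stability` with `jacobian`,
#'   `eigenvalues`, `c1`, `c2`, `c3`, `E_aux`, `F_aux`, `hurwitz_ok`,
#'   `verdict` and `max_re`.
#' @examples
#' eq <- endemic_equilibria(example2_params(tau = 20))
#' endemic_stability(eq$endemic[[1]], example2_params(tau = 20))$verdict
#' @export
endemic_stability <- function(at, params) {
  x <- as_state(at)
  assert_equilibrium(x, params)
  cc <- cubic_coefficients(x, params, check = FALSE)
  J <- seiv_jacobian(x, params)
  ev <- eigen(J, only.values = TRUE)$values
  max_re <- max(Re(ev))
  hurwitz_ok <- cc$c1 > 0 && cc$c3 > 0 && cc$c1 * cc$c2 - cc$c3 > 0
  verdict <- verdict_from_re(max_re)
  if (verdict == "stable" && !hurwitz_ok ||
      verdict == "unstable" && hurwitz_ok)
    stop("Hurwitz verdict and spectral verdict disagree", call. = FALSE)
  structure(c(list(point = "P*", verdict = verdict, jacobian = J,
                   eigenvalues = ev, max_re = max_re,
                   hurwitz_ok = hurwitz_ok), cc),
            class = "seiv_stability")
}

#' @export
print.seiv_stability <- function(x, ...) {
  cat(sprintf("Local stability at %s: %s\n", x$point, x$verdict))
  cat("  eigenvalues:",
      paste(format(x$eigenvalues, digits = 6), collapse = ", "), "\n")
  if (!is.null(x$c1))
    cat(sprintf("  c1 = %.6g, c2 = %.6g, c3 = %.6g, c1*c2 - c3 = %.6g\n",
                x$c1, x$c2, x$c3, x$c1 * x$c2 - x$c3))
  invisible(x)
}
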