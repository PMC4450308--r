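#' Vector field of the SEIV model
#'
#' Time derivatives of the four compartments:
#' \deqn{\dot S = (1-p)A + \omega V + \tau I - \mu S - \beta S I (1+\alpha I)}
#' \deqn{\dot V = pA - \omega V - \mu V}
#' \deqn{\dot E = \beta S I (1+\alpha I) - (\mu+\sigma) E}
#' \deqn{\dot I = \sigma E - (\mu+\tau+\epsilon) I}
#'
#' The field is polynomial and is evaluated as written for any finite
#' state, including slightly negative components produced by integrator
#' roundoff; no clipping happens here.
#'
#' @param state numeric length-4 state `(S, V, E, I)` (named or positional).
#' @param params a [seiv_params] object.
#' @return Named numeric vector `(dS, dV, dE, dI)`.
#' @examples
#' seiv_rhs(seiv_state(0, 0, 0, 0), example1_params())
#' @export
seiv_rhs <- function(state, params) {
  x <- as_state(state)
  with(params, {
    inc <- beta * x[["S"]] * x[["I"]] * (1 + alpha * x[["I"]])
    c(dS = (1 - p) * A + omega * x[["V"]] + tau * x[["I"]] -
        mu * x[["S"]] - inc,
      dV = p * A - omega * x[["V"]] - mu * x[["V"]],
      dE = inc - (mu + sigma) * x[["E"]],
      dI = sigma * x[["E"]] - (mu + tau + epsilon) * x[["I"]])
  })
}

#' Derivative of the total population
#'
#' Closed form \eqn{A - \mu N - \epsilon I} with \eqn{N = S+V+E+I}; equal to
#' the sum of the [seiv_rhs] components up to floating-point reassociation.
#'
#' @inheritParams seiv_rhs
#' @return A single number, `dN/dt`.
#' @export
total_derivative <- function(state, params) {
  x <- as_state(state)
  params$A - params$mu * sum(x) - params$epsilon * x[["I"]]
}

#' Membership in the forward-invariant region
#'
#' The biologically feasible region is
#' \eqn{\Omega = \{S>0, V>0, E\ge 0, I\ge 0,\; S+V+E+I \le A/\mu\}};
#' trajectories started inside never leave it.  The population bound is
#' checked with a relative tolerance scaled by `A/mu`.
#'
#' @inheritParams seiv_rhs
#' @param tol nonnegative relative tolerance on the bound (default `1e-6`,
#'   the scale of integration error).
#' @return A list with `inside_omega` (logical), `total` (the population
#'   `S+V+E+I`), and `bound` (`A/mu`).
#' @export
in_invariant_region <- function(state, params, tol = 1e-6) {
  stopifnot(tol >= 0)
  x <- as_state(state)
  bound <- params$A / params$mu
  total <- sum(x)
  inside <- x[["S"]] > 0 && x[["V"]] > 0 && x[["E"]] >= 0 && x[["I"]] >= 0 &&
    total <= bound * (1 + tol)
  list(inside_omega = inside, total = total, bound = bound)
}

#' Jacobian matrix of the SEIV vector field
#'
#' Analytic Jacobian of [seiv_rhs] at an arbitrary state, in compartment
#' order `(S, V, E, I)`.  Because the vaccinated class is decoupled from
#' infection, its row contributes the factor \eqn{(\lambda+\omega+\mu)} to
#' the characteristic polynomial at any equilibrium.
#'
#' @inheritParams seiv_rhs
#' @return A 4 x 4 numeric matrix with dimnames `S, V, E, I`.
#' @examples
#' seiv_jacobian(disease_free_equilibrium(example1_params()), example1_params())
#' @export
seiv_jacobian <- function(state, params) {
  x <- as_state(state)
  S <- x[["S"]]; I <- x[["I"]]
  with(params, {
    dincS <- beta * I * (1 + alpha * I)       # d(incidence)/dS
    dincI <- beta * S * (1 + 2 * alpha * I)   # d(incidence)/dI
    J <- rbind(
      c(-mu - dincS, omega, 0,            tau - dincI),
      c(0,          -(omega + mu), 0,     0),
      c(dincS,       0,    -(mu + sigma), dincI),
      c(0,           0,     sigma,       -(mu + tau + epsilon)))
    dimnames(J) <- list(c("S", "V", "E", "I"), c("S", "V", "E", "I"))
    J
  })
}
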