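# Checkable sufficient conditions for global stability: a Lyapunov-type
# condition for the disease-free equilibrium and the geometric-approach
# (second additive compound / Lozinskii measure) inequalities for the
# endemic equilibrium.

#' Global-stability condition for the disease-free equilibrium
#'
#' Evaluates the Lyapunov quantity \eqn{R_0 (1 + \alpha A/\mu)}.  When it
#' is below 1, the disease-free equilibrium is globally asymptotically
#' stable in the invariant region provided either `R1_star > 1` (no
#' endemic state can exist below `R0 = 1`) or `R1_star < 1` together with
#' `R0 < R0_star` (below the saddle-node, so the backward branch is
#' absent).  Outside these branches the condition is inconclusive --
#' never a claim of instability.
#'
#' @param params a [seiv_params] object.
#' @return An object of class `seiv_global`: list with `lyapunov_value`,
#'   `dfe_globally_stable` (logical), `branch` (`"R1*>1"`, `"R1*<1, R0<R0*"`
#'   or `"inconclusive"`), and `thresholds`.
#' @examples
#' dfe_global_condition(example1_params())
#' @export
dfe_global_condition <- function(params) {
  ts <- seiv_thresholds(params)
  lyap <- ts$R0 * (1 + params$alpha * params$A / params$mu)
  branch <- "inconclusive"
  verdict <- FALSE
  if (lyap < 1 && isTRUE(ts$defined)) {
    if (ts$R1_star > 1) {
      branch <- "R1*>1"
      verdict <- TRUE
    } else if (ts$R1_star < 1 && ts$R0 < ts$R0_star) {
      branch <- "R1*<1, R0<R0*"
      verdict <- TRUE
    }
  }
  structure(list(lyapunov_value = lyap, dfe_globally_stable = verdict,
                 branch = branch, thresholds = ts),
            class = "seiv_global")
}

#' Geometric global-stability condition for the endemic equilibrium
#'
#' For `R0 > 1` the endemic equilibrium is globally asymptotically stable
#' when the time-averaged Lozinskii measure of the second additive
#' compound of the Jacobian is negative; a checkable sufficient condition
#' is `d > 0` with
#' \deqn{d = \min\Big\{\sigma - (\mu+\omega),\;
#'   \epsilon - \mu - \sigma - \beta c(1+\alpha c) +
#'   \beta\frac{A}{\mu}\Big(1 + 2\alpha\frac{A}{\mu}\Big)\Big\}}
#' when `omega > tau`, and with \eqn{\sigma} replaced by
#' \eqn{\omega + \sigma} in the second term when `omega < tau`.  Here `c`
#' is the uniform-persistence constant, a lower bound on `S` and `I` along
#' trajectories; no closed form for it is available, so it is an explicit
#' caller input and any positive verdict is conditional on it.  Local
#' stability (the Routh-Hurwitz conditions) is still required for the
#' global claim, and is reported alongside.
#'
#' @param params a [seiv_params] object with `R0 > 1`.
#' @param c uniform-persistence constant (individuals), strictly positive;
#'   default `1e-6 * A/mu`.
#' @return An object of class `seiv_global`: list with `d_value`, `branch`
#'   (`"omega>tau"` or `"omega<tau"`), `persistence_c`,
#'   `endemic_condition_met` (`d > 0`), `first_condition`
#'   (`mu + omega < sigma`), and `hurwitz_ok` for the endemic equilibrium
#'   (`NA` when there is none).
#' @export
endemic_global_condition <- function(params, c = 1e-6 * params$A / params$mu) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("the persistence constant c must be a single positive number",
         call. = FALSE)
  d <- with(params, {
    Nbar <- A / mu
    gain <- beta * Nbar * (1 + 2 * alpha * Nbar)
    loss <- beta * c * (1 + alpha * c)
    second <- if (omega > tau) epsilon - mu - sigma - loss + gain
              else epsilon - mu - omega - sigma - loss + gain
    min(sigma - (mu + omega), second)
  })
  eq <- endemic_equilibria(params)
  hurwitz <- if (length(eq$endemic)) {
    st <- eq$endemic[[length(eq$endemic)]]
    cc <- cubic_coefficients(st, params, check = FALSE)
    cc$c1 > 0 && cc$c3 > 0 && cc$c1 * cc$c2 - cc$c3 > 0
  } else NA
  structure(list(d_value = d,
                 branch = if (params$omega > params$tau) "omega>tau"
                          else "omega<tau",
                 persistence_c = c,
                 endemic_condition_met = d > 0,
                 first_condition = params$mu + params$omega < params$sigma,
                 hurwitz_ok = hurwitz),
            class = "seiv_global")
}

#' @export
print.seiv_global <- function(x, ...) {
  if (!is.null(x$lyapunov_value)) {
    cat(sprintf("Disease-free global condition: R0(1 + alpha*A/mu) = %.6g\n",
                x$lyapunov_value))
    cat("  globally stable:", x$dfe_globally_stable,
        "| branch:", x$branch, "\n")
  } else {
    cat(sprintf(
      "Endemic geometric condition (%s, c = %.6g): d = %.6g (met: %s)\n",
      x$branch, x$persistence_c, x$d_value, x$endemic_condition_met))
    cat("  local Routh-Hurwitz at P*:", x$hurwitz_ok, "\n")
  }
  invisible(x)
}
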