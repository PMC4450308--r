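#' Disease-free equilibrium
#'
#' The infection-free steady state
#' \eqn{P_0 = \left(\frac{A[\mu(1-p)+\omega]}{\mu(\mu+\omega)},
#' \frac{pA}{\mu+\omega}, 0, 0\right)}, which exists for every parameter
#' set.
#'
#' @param params a [seiv_params] object.
#' @return A named state vector `(S, V, E, I)`.
#' @examples
#' round(disease_free_equilibrium(example1_params()))
#' @export
disease_free_equilibrium <- function(params) {
  with(params, c(S = A * (mu * (1 - p) + omega) / (mu * (mu + omega)),
                 V = p * A / (mu + omega), E = 0, I = 0))
}

#' Endemic-equilibrium quadratic
#'
#' At an endemic steady state the infectious count `I*` satisfies
#' \eqn{k_1 I^{*2} + k_2 I^* + k_3 = 0} with
#' \deqn{k_1 = \alpha\beta[\sigma\tau(\mu+\omega) - M],\quad
#'       k_2 = M(\mu\alpha R_0 - \beta) + \sigma\beta\tau(\mu+\omega),\quad
#'       k_3 = \mu M (R_0 - 1).}
#' The signs encode the case structure: `k3 > 0` iff `R0 > 1`, `k2 > 0`
#' iff `R0 > R1_star`, and `k1 < 0` whenever
#' `M > sigma*tau*(mu+omega)`.  The discriminant satisfies the identity
#' \deqn{k_2^2 - 4k_1k_3 = (\mu M\alpha R_0 + \beta[M-\sigma\tau(\mu+\omega)])^2
#'       - 4\mu M\alpha\beta[M-\sigma\tau(\mu+\omega)],}
#' so it is nonnegative exactly when \eqn{R_0 \ge R_0^*}.
#'
#' @param params a [seiv_params] object.
#' @return An object of class `seiv_quadratic`: list with `k1`, `k2`, `k3`,
#'   `discriminant`, and the threshold set used (`thresholds`).
#' @export
endemic_quadratic <- function(params) {
  ts <- seiv_thresholds(params)
  out <- with(params, {
    k1 <- alpha * beta * (stau_of(params) - ts$M)
    k2 <- ts$M * (mu * alpha * ts$R0 - beta) +
      sigma * beta * tau * (mu + omega)
    k3 <- mu * ts$M * (ts$R0 - 1)
    list(k1 = k1, k2 = k2, k3 = k3,
         discriminant = k2 * k2 - 4 * k1 * k3)
  })
  out$thresholds <- ts
  class(out) <- "seiv_quadratic"
  out
}

stau_of <- function(params)
  with(params, sigma * tau * (mu + omega))

#' @export
print.seiv_quadratic <- function(x, ...) {
  cat(sprintf(
    "Endemic quadratic k1 I^2 + k2 I + k3 = 0\n  k1 = %.6g  k2 = %.6g  k3 = %.6g\n  discriminant = %.6g\n",
    x$k1, x$k2, x$k3, x$discriminant))
  invisible(x)
}

# Numerically stable positive roots of k1 x^2 + k2 x + k3 = 0.  Avoids the
# cancellation between -k2 and the square root when |k1 k3| << k2^2 by the
# q-formula; degenerates gracefully to the linear root when k1 ~ 0.
quadratic_roots <- function(k1, k2, k3) {
  if (k1 == 0) {
    if (k2 == 0) return(numeric(0))
    return(-k3 / k2)
  }
  disc <- k2 * k2 - 4 * k1 * k3
  if (disc < 0) return(numeric(0))
  q <- -(k2 + sign(k2 + (k2 == 0)) * sqrt(disc)) / 2
  r <- c(q / k1, if (q != 0) k3 / q else -k2 / k1 - q / k1)
  sort(unique(r))
}

#' Equilibrium case classification
#'
#' Decision table over the thresholds:
#' \itemize{
#'   \item `R1_star < 1` (backward-capable branch): no endemic equilibrium
#'     for `R0 < R0_star`; two endemic equilibria for
#'     `R0_star < R0 < 1`; one for `R0 > 1`.
#'   \item `R1_star > 1` (forward branch): none for `R0 < 1`, one for
#'     `R0 > 1`.
#' }
#' Exact ties (`R0 == R0_star`, `R0 == 1`, `R1_star == 1`) are labelled
#' `"boundary"`; comparisons are strict with no tolerance because they feed
#' the case labels.
#'
#' @param ts a `seiv_thresholds` object.
#' @return One of `"no-endemic"`, `"one-endemic"`, `"two-endemic"`,
#'   `"boundary"`.
#' @export
classify_equilibria <- function(ts) {
  stopifnot(inherits(ts, "seiv_thresholds"))
  if (!isTRUE(ts$defined))
    stop("thresholds undefined (alpha = 0, mu = 0, or M < sigma*tau*(mu+omega))",
         call. = FALSE)
  if (ts$R0 == 1 || ts$R0 == ts$R0_star || ts$R1_star == 1)
    return("boundary")
  if (ts$R1_star < 1) {
    if (ts$R0 < ts$R0_star) "no-endemic"
    else if (ts$R0 < 1) "two-endemic"
    else "one-endemic"
  } else {
    if (ts$R0 < 1) "no-endemic" else "one-endemic"
  }
}

#' All equilibria of the SEIV model
#'
#' Solves the endemic quadratic for positive roots `I*`, back-substitutes
#' \deqn{E^* = \frac{\mu+\tau+\epsilon}{\sigma} I^*,\quad
#'       S^* = \frac{(\mu+\sigma)(\mu+\tau+\epsilon)}
#'                  {\sigma\beta(1+\alpha I^*)},\quad
#'       V^* = \frac{pA}{\mu+\omega},}
#' and verifies every reported equilibrium by substitution into the full
#' vector field.  A residual above `tol * A` raises an error rather than
#' returning a silently wrong equilibrium.
#'
#' Roots below `1e-9 * A/mu` are treated as numerically zero (they
#' duplicate the disease-free equilibrium).  A near-double root
#' (`|discriminant| < 1e-12 * k2^2`) is reported once and labelled
#' `"boundary"`, the tangency case.
#'
#' @param params a [seiv_params] object.
#' @param tol relative residual tolerance (default `1e-8`), scaled by `A`.
#' @return An object of class `seiv_equilibria`: list with `P0`, `endemic`
#'   (list of state vectors with attribute `I_star`), `residuals`,
#'   `case_label` from [classify_equilibria] (or `NA` when thresholds are
#'   undefined), `theorem_branch` (`"R1*<1"` or `"R1*>1"`), and
#'   `quadratic`.
#' @examples
#' endemic_equilibria(example2_params(tau = 20))
#' @export
endemic_equilibria <- function(params, tol = 1e-8) {
  quad <- endemic_quadratic(params)
  ts <- quad$thresholds
  tol_pos <- 1e-9 * params$A / params$mu

  near_double <- quad$k1 != 0 &&
    abs(quad$discriminant) < 1e-12 * quad$k2^2 && quad$discriminant >= 0
  roots <- if (near_double) -quad$k2 / (2 * quad$k1)
           else quadratic_roots(quad$k1, quad$k2, quad$k3)
  roots <- roots[is.finite(roots) & roots > tol_pos]

  endemic <- lapply(roots, function(I_star) {
    st <- with(params, c(
      S = (mu + sigma) * (mu + tau + epsilon) /
        (sigma * beta * (1 + alpha * I_star)),
      V = p * A / (mu + omega),
      E = (mu + tau + epsilon) / sigma * I_star,
      I = I_star))
    attr(st, "I_star") <- I_star
    st
  })
  residuals <- vapply(endemic,
                      function(st) max(abs(seiv_rhs(st, params))), 0)
  if (length(residuals) && max(residuals) > tol * params$A)
    stop(sprintf(
      "endemic equilibrium failed the residual check (max |rhs| = %.3g > %.3g)",
      max(residuals), tol * params$A), call. = FALSE)

  label <- if (near_double) "boundary"
           else if (isTRUE(ts$defined)) classify_equilibria(ts)
           else NA_character_
  out <- list(P0 = disease_free_equilibrium(params),
              endemic = endemic,
              residuals = residuals,
              case_label = label,
              theorem_branch = if (!isTRUE(ts$defined)) NA_character_
                               else if (ts$R1_star < 1) "R1*<1" else "R1*>1",
              quadratic = quad)
  class(out) <- "seiv_equilibria"
  out
}

#' @export
print.seiv_equilibria <- function(x, ...) {
  cat("SEIV equilibria  [case:", x$case_label, "| branch:",
      x$theorem_branch, "]\n")
  cat(sprintf("  P0: S = %.6g, V = %.6g\n", x$P0[["S"]], x$P0[["V"]]))
  if (!length(x$endemic)) {
    cat("  no endemic equilibrium\n")
  } else {
    for (i in seq_along(x$endemic)) {
      st <- x$endemic[[i]]
      cat(sprintf(
        "  P*%d: S = %.6g, V = %.6g, E = %.6g, I = %.6g  (residual %.2g)\n",
        i, st[["S"]], st[["V"]], st[["E"]], st[["I"]], x$residuals[i]))
    }
  }
  invisible(x)
}
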