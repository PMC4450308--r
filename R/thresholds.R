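#' Reproduction thresholds of the SEIV model
#'
#' Computes the closed-form threshold quantities that organise the model's
#' dynamics:
#' \itemize{
#'   \item `M = (mu+omega)(mu+sigma)(mu+tau+epsilon)`, the product of the
#'     three linear exit rates;
#'   \item `stau = sigma*tau*(mu+omega)`, the competing return-flow product
#'     (most formulas below require `M > stau`);
#'   \item the basic reproduction number
#'     \deqn{R_0 = \frac{\sigma\beta A[\mu(1-p)+\omega]}
#'                      {\mu(\mu+\omega)(\mu+\sigma)(\mu+\tau+\epsilon)};}
#'   \item the saddle-node threshold
#'     \eqn{R_0^* = \left(2\sqrt{\alpha\mu M\,\beta[M-\sigma\tau(\mu+\omega)]}
#'       - \beta[M-\sigma\tau(\mu+\omega)]\right)/(\alpha\mu M)}, below which
#'     no endemic state exists;
#'   \item the auxiliary threshold
#'     \eqn{R_1^* = \beta[M-\sigma\tau(\mu+\omega)]/(\alpha\mu M)}, whose
#'     position relative to 1 decides forward versus backward bifurcation;
#'   \item `alpha0 = (M - stau) / (sigma*A*[mu(1-p)+omega])`, the critical
#'     incidence nonlinearity (at the bifurcation point, `alpha > alpha0`
#'     is equivalent to `R1_star < 1`);
#'   \item `beta_star`, the transmission coefficient at which `R0 = 1`.
#' }
#'
#' `R0_star` and `R1_star` divide by `alpha*mu*M` and are reported as `NA`
#' with `defined = FALSE` when `alpha = 0`; `R0_star` additionally requires
#' `M >= stau` so that its square root is real.
#'
#' @param params a [seiv_params] object.
#' @return An object of class `seiv_thresholds`: a list with components
#'   `M`, `stau`, `R0`, `R0_star`, `R1_star`, `alpha0`, `beta_star`,
#'   `defined` (logical, thresholds involving `1/alpha` are real and
#'   well defined) and `params`.
#' @examples
#' seiv_thresholds(example2_params(tau = 20))
#' @export
seiv_thresholds <- function(params) {
  ts <- with(params, {
    M <- (mu + omega) * (mu + sigma) * (mu + tau + epsilon)
    stau <- sigma * tau * (mu + omega)
    g <- mu * (1 - p) + omega              # effective unvaccinated inflow
    R0 <- sigma * beta * A * g / (mu * (mu + omega) * (mu + sigma) *
                                    (mu + tau + epsilon))
    amM <- alpha * mu * M
    v <- beta * (M - stau)
    defined <- amM > 0
    R1_star <- if (defined) v / amM else NA_real_
    R0_star <- if (defined && M >= stau)
      (2 * sqrt(amM * v) - v) / amM else NA_real_
    alpha0 <- (M - stau) / (sigma * A * g)
    beta_star <- mu * (mu + tau + epsilon) * (mu + sigma) * (mu + omega) /
      (sigma * A * g)
    list(M = M, stau = stau, R0 = R0, R0_star = R0_star, R1_star = R1_star,
         alpha0 = alpha0, beta_star = beta_star,
         defined = defined && M >= stau)
  })
  ts$params <- params
  class(ts) <- "seiv_thresholds"
  ts
}

#' @export
print.seiv_thresholds <- function(x, ...) {
  cat("SEIV threshold set\n")
  cat(sprintf("  M         = %.6g   (sigma*tau*(mu+omega) = %.6g)\n",
              x$M, x$stau))
  cat(sprintf("  R0        = %.6g\n", x$R0))
  cat(sprintf("  R0*       = %.6g\n", x$R0_star))
  cat(sprintf("  R1*       = %.6g\n", x$R1_star))
  cat(sprintf("  alpha0    = %.6g\n", x$alpha0))
  cat(sprintf("  beta*     = %.6g\n", x$beta_star))
  if (!x$defined)
    cat("  (R0*/R1* undefined: alpha = 0 or M < sigma*tau*(mu+omega))\n")
  invisible(x)
}

#' Basic reproduction number via the next-generation matrix
#'
#' Builds the 2 x 2 new-infection matrix `F` and transition matrix `V` of
#' the infected subsystem `(E, I)` linearised at the disease-free
#' equilibrium, and returns the spectral radius of `F V^-1`.  This is the
#' constructive definition of \eqn{R_0}; it must agree with the closed form
#' in [seiv_thresholds].
#'
#' `F` has the single nonzero entry
#' \eqn{\beta A[\mu(1-p)+\omega]/(\mu(\mu+\omega))} in row 1, column 2
#' (new infections enter E, generated by I); `V` is lower triangular with
#' the exit rates \eqn{\mu+\sigma} and \eqn{\mu+\tau+\epsilon} on its
#' diagonal and the progression \eqn{-\sigma} below it.
#'
#' @param params a [seiv_params] object.
#' @return An object of class `seiv_ngm`: list with matrices `F`, `V`,
#'   `V_inv`, and `rho`, the spectral radius of `F %*% V_inv`.
#' @examples
#' ngm <- next_generation(example1_params())
#' all.equal(ngm$rho, seiv_thresholds(example1_params())$R0)
#' @export
next_generation <- function(params) {
  out <- with(params, {
    S0 <- A * (mu * (1 - p) + omega) / (mu * (mu + omega))
    Fm <- matrix(c(0, beta * S0,
                   0, 0), 2, 2, byrow = TRUE)
    Vm <- matrix(c(mu + sigma, 0,
                   -sigma, mu + tau + epsilon), 2, 2, byrow = TRUE)
    V_inv <- solve(Vm)
    K <- Fm %*% V_inv
    # spectral radius two ways: eigenvalues, and the single nonzero path
    # product F[1,2] * V_inv[2,1] (K has one nonzero row)
    rho_eig <- max(Mod(eigen(K, only.values = TRUE)$values))
    rho_path <- Fm[1, 2] * V_inv[2, 1]
    if (rho_path > 0 &&
        abs(rho_eig - rho_path) > 1e-10 * max(rho_path, 1e-300))
      stop("internal inconsistency in next-generation spectral radius")
    list(F = Fm, V = Vm, V_inv = V_inv, rho = rho_eig)
  })
  class(out) <- "seiv_ngm"
  out
}

#' @export
print.seiv_ngm <- function(x, ...) {
  cat("Next-generation matrices (infected subsystem E, I)\n")
  cat("F:\n"); print(x$F)
  cat("V:\n"); print(x$V)
  cat(sprintf("rho(F V^-1) = %.8g\n", x$rho))
  invisible(x)
}

#' Order relations among the thresholds
#'
#' Evaluates the two structural relations that hold whenever
#' `M > sigma*tau*(mu+omega)`:
#' (i) `R0_star <= 1` (a consequence of the AM-GM inequality), and
#' (ii) `R1_star < 1` exactly when `R1_star < R0_star`.
#'
#' @param ts a `seiv_thresholds` object.
#' @return A list of logicals: `premise` (`M > stau` and thresholds
#'   defined), `r0_star_le_1`, and `equivalence_holds` (relation (ii)).
#'   When the premise fails the relation entries are `NA`.
#' @export
threshold_relations <- function(ts) {
  stopifnot(inherits(ts, "seiv_thresholds"))
  premise <- isTRUE(ts$defined) && ts$M > ts$stau
  if (!premise)
    return(list(premise = FALSE, r0_star_le_1 = NA, equivalence_holds = NA))
  list(premise = TRUE,
       r0_star_le_1 = ts$R0_star <= 1,
       equivalence_holds = (ts$R1_star < 1) == (ts$R1_star < ts$R0_star))
}
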