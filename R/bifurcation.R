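# Center-manifold analysis of the transcritical bifurcation at R0 = 1 and
# Hopf detection in the treatment rate tau.

#' Eigenstructure at the bifurcation point R0 = 1
#'
#' Replaces the transmission coefficient by its critical value
#' \eqn{\beta^*} (so that \eqn{R_0 = 1}) and assembles the linearisation
#' at the disease-free equilibrium, which then has a simple zero
#' eigenvalue.  The closed-form right and left null vectors are
#' \deqn{V = \left(\frac{(\mu+\sigma)[\sigma\tau(\mu+\omega)-M]}{\mu M},\,
#'   0,\, 1,\, \frac{\sigma}{\tau+\mu+\epsilon}\right)^T,\quad
#'   W = \left(0,\,0,\,\frac{\mu+\tau+\epsilon}{2\mu+\sigma+\tau+\epsilon},\,
#'   \frac{(\mu+\sigma)(\mu+\tau+\epsilon)}
#'        {\sigma(2\mu+\sigma+\tau+\epsilon)}\right),}
#' normalised so that `W . V = 1`.
#'
#' @param params a [seiv_params] object; its `beta` is ignored and replaced
#'   by `beta_star` internally.
#' @return List with `beta_star`, `jacobian` (at `P0` with
#'   `beta = beta_star`), `eigenvalues`, `right_vec`, `left_vec`, and
#'   `zero_index` (which eigenvalue is the structural zero).  Errors if the
#'   zero eigenvalue is not simple or if some other eigenvalue fails to
#'   have negative real part.
#' @export
center_manifold_setup <- function(params) {
  ts <- seiv_thresholds(params)
  pstar <- params
  pstar$beta <- ts$beta_star
  P0 <- disease_free_equilibrium(pstar)
  J <- seiv_jacobian(P0, pstar)
  ev <- eigen(J, only.values = TRUE)$values
  scale <- max(abs(ev))
  zero <- which(abs(ev) < 1e-8 * scale)
  if (length(zero) != 1L)
    stop("zero eigenvalue of J(P0, beta*) is not simple", call. = FALSE)
  if (any(Re(ev[-zero]) >= -1e-12 * scale))
    stop("nonzero eigenvalues of J(P0, beta*) must have negative real part",
         call. = FALSE)
  v <- with(params, c(
    (mu + sigma) * (sigma * tau * (mu + omega) - ts$M) / (mu * ts$M),
    0, 1, sigma / (tau + mu + epsilon)))
  w <- with(params, {
    D <- 2 * mu + sigma + tau + epsilon
    c(0, 0, (mu + tau + epsilon) / D,
      (mu + sigma) * (mu + tau + epsilon) / (sigma * D))
  })
  stopifnot(abs(sum(w * v) - 1) < 1e-10)
  list(beta_star = ts$beta_star, jacobian = J, eigenvalues = ev,
       right_vec = v, left_vec = w, zero_index = zero)
}

#' Center-manifold coefficients a and b at R0 = 1
#'
#' The direction and stability exchange of the transcritical bifurcation
#' at \eqn{R_0 = 1} are decided by the two scalars
#' \deqn{a = \sum_{k,i,j} w_k v_i v_j
#'   \frac{\partial^2 f_k}{\partial x_i \partial x_j}(P_0, \beta^*), \qquad
#'   b = \sum_{k,i} w_k v_i
#'   \frac{\partial^2 f_k}{\partial x_i \partial \beta}(P_0, \beta^*).}
#' `a` and `b` are each computed two independent ways -- the generic sums
#' over the nonzero second derivatives of the vector field, and the
#' reconstructed closed forms
#' \deqn{a = \frac{2(\mu+\sigma)\left[\sigma\tau(\mu+\omega) - M +
#'   \sigma\alpha A g\right]}{(2\mu+\sigma+\tau+\epsilon)\, A\, g}, \qquad
#'   b = \frac{2\sigma A g}{\mu (2\mu+\sigma+\tau+\epsilon)(\mu+\omega)},}
#' with \eqn{g = \mu(1-p)+\omega} -- and the two routes must agree to
#' relative `1e-8` (an error names the offending coefficient otherwise).
#' `b` is always positive, so the bifurcation is backward exactly when
#' `a > 0`, which happens exactly when `alpha > alpha0`, equivalently when
#' `R1_star < 1` at the bifurcation point.
#'
#' @param params a [seiv_params] object (`beta` replaced by `beta_star`).
#' @return An object of class `seiv_bifurcation`: list with `beta_star`,
#'   `right_vec`, `left_vec`, `a_coef`, `b_coef`, `alpha0`, `direction`
#'   (`"forward"`, `"backward"` or `"degenerate"`), and the closed-form
#'   values `a_closed`, `b_closed`.
#' @examples
#' bifurcation_coefficients(example2_params(tau = 20))$direction
#' @export
bifurcation_coefficients <- function(params) {
  setup <- center_manifold_setup(params)
  v <- setup$right_vec
  w <- setup$left_vec
  ts <- seiv_thresholds(params)
  out <- with(params, {
    g <- mu * (1 - p) + omega
    S0 <- A * g / (mu * (mu + omega))
    bstar <- ts$beta_star
    D <- 2 * mu + sigma + tau + epsilon
    # nonzero second derivatives at (P0, beta*):
    #   d2f1/dSdI = -beta*, d2f1/dI2 = -2 alpha beta* S0,
    #   d2f3/dSdI = +beta*, d2f3/dI2 = +2 alpha beta* S0,
    #   d2f1/dIdbeta = -S0,  d2f3/dIdbeta = +S0
    a_sum <- 2 * w[1] * v[1] * v[4] * (-bstar) +
      w[1] * v[4]^2 * (-2 * alpha * bstar * S0) +
      2 * w[3] * v[1] * v[4] * bstar +
      w[3] * v[4]^2 * (2 * alpha * bstar * S0)
    b_sum <- 2 * (w[1] * v[4] * (-S0) + w[3] * v[4] * S0)
    a_closed <- 2 * (mu + sigma) *
      (sigma * tau * (mu + omega) - ts$M + sigma * alpha * A * g) /
      (D * A * g)
    b_closed <- 2 * sigma * A * g / (mu * D * (mu + omega))
    a_scale <- 2 * (mu + sigma) *
      max(abs(sigma * tau * (mu + omega) - ts$M), sigma * alpha * A * g) /
      (D * A * g)
    list(a_sum = a_sum, b_sum = b_sum,
         a_closed = a_closed, b_closed = b_closed, a_scale = a_scale)
  })
  relerr <- function(x, y) abs(x - y) / max(abs(x), abs(y), 1e-300)
  # a may vanish by cancellation at alpha = alpha0, so its agreement is
  # judged against the magnitude of its constituent terms
  if (abs(out$a_sum - out$a_closed) > 1e-8 * out$a_scale)
    stop(sprintf("coefficient a: generic sum %.10g != closed form %.10g",
                 out$a_sum, out$a_closed), call. = FALSE)
  if (relerr(out$b_sum, out$b_closed) > 1e-8)
    stop(sprintf("coefficient b: generic sum %.10g != closed form %.10g",
                 out$b_sum, out$b_closed), call. = FALSE)
  a <- out$a_sum
  dir_tol <- 1e-10 * out$a_scale
  direction <- if (abs(a) <= dir_tol) "degenerate"
               else if (a > 0) "backward" else "forward"
  structure(list(beta_star = setup$beta_star,
                 right_vec = v, left_vec = w,
                 a_coef = a, b_coef = out$b_sum,
                 a_closed = out$a_closed, b_closed = out$b_closed,
                 alpha0 = ts$alpha0, direction = direction,
                 eigenvalues = setup$eigenvalues),
            class = "seiv_bifurcation")
}

#' @export
print.seiv_bifurcation <- function(x, ...) {
  cat("Transcritical bifurcation at R0 = 1\n")
  cat(sprintf("  beta* = %.8g\n  a = %.8g, b = %.8g, alpha0 = %.8g\n",
              x$beta_star, x$a_coef, x$b_coef, x$alpha0))
  cat("  direction:", x$direction, "\n")
  invisible(x)
}

#' Direction of the bifurcation at R0 = 1
#'
#' `"backward"` when the center-manifold coefficient `a > 0` (stable
#' endemic states coexist with the stable disease-free state below
#' `R0 = 1`), `"forward"` when `a < 0`.  Cross-checked against the
#' equivalent threshold rule: backward iff `R1_star < 1` evaluated at
#' `beta = beta_star`.
#'
#' @param params a [seiv_params] object.
#' @return `"forward"`, `"backward"` or `"degenerate"`.
#' @export
bifurcation_direction <- function(params) {
  bc <- bifurcation_coefficients(params)
  pstar <- params
  pstar$beta <- bc$beta_star
  ts <- seiv_thresholds(pstar)
  if (isTRUE(ts$defined) && bc$direction != "degenerate") {
    rule <- if (ts$R1_star < 1) "backward" else "forward"
    if (rule != bc$direction)
      stop("a-coefficient rule and R1* rule disagree on the direction",
           call. = FALSE)
  }
  bc$direction
}

#' Sign of the sensitivity of the backward-bifurcation coefficient to
#' vaccination coverage
#'
#' Central finite difference of the center-manifold coefficient `a` with
#' respect to the vaccinated fraction `p`, with the transmission
#' coefficient re-solved to `beta_star(p)` at each evaluation.  A negative
#' sign means vaccinating a larger share of recruits makes a backward
#' bifurcation less likely.
#'
#' @param params a [seiv_params] object.
#' @param h step size in `p` (default `1e-5`, clipped to keep `p` in
#'   \[0, 1\]).
#' @return List with `derivative` (the finite-difference estimate) and
#'   `sign` (-1, 0 or 1).
#' @export
sign_da_dp <- function(params, h = 1e-5) {
  h <- min(h, params$p, 1 - params$p, 0.4)
  if (h <= 0) h <- 1e-5
  a_at <- function(p) {
    q <- params
    q$p <- p
    bifurcation_coefficients(q)$a_coef
  }
  d <- (a_at(params$p + h) - a_at(params$p - h)) / (2 * h)
  list(derivative = d, sign = sign(d))
}

# h(tau) = c1 c2 - c3 at the (unique, R0 > 1) endemic equilibrium for the
# given tau; NA when no admissible equilibrium exists.
hopf_h <- function(params, tau) {
  q <- params
  q$tau <- tau
  ts <- seiv_thresholds(q)
  if (ts$R0 <= 1) return(NA_real_)
  eq <- endemic_equilibria(q)
  if (!length(eq$endemic)) return(NA_real_)
  st <- eq$endemic[[length(eq$endemic)]]
  cc <- cubic_coefficients(st, q, check = FALSE)
  cc$c1 * cc$c2 - cc$c3
}

#' Hopf bifurcation scan in the treatment rate
#'
#' Sweeps `tau` over a grid, computes the endemic equilibrium and the
#' Routh-Hurwitz margin `h(tau) = c1*c2 - c3` at each admissible point
#' (`R0(tau) > 1` with a positive equilibrium; others are recorded as
#' skipped), brackets every sign change and refines it by bisection to
#' relative `1e-10`.  At each root the cubic factor has the root structure
#' \eqn{\{+i\sqrt{c_2},\,-i\sqrt{c_2},\,-c_1\}}, so a candidate is `valid`
#' only if `c2 > 0`, the Jacobian carries a conjugate pair with real part
#' inside the marginal band, and the finite-difference transversality
#' estimate (the slope of the tracked pair's real part across the root)
#' is nonzero.
#'
#' @param params a [seiv_params] object (its own `tau` is ignored).
#' @param tau_min,tau_max scan range, `0 < tau_min < tau_max`.
#' @param n_grid number of grid points (at least 16, default 64).
#' @return An object of class `seiv_hopf`: list with `grid` (data frame of
#'   `tau`, `h`, `R0`, `admissible`), `candidates` (data frame of
#'   `tau_star`, `c2`, `im_pair` = sqrt(c2), `max_re_pair`,
#'   `transversality`, `valid`), and `n_skipped`.
#' @examples
#' hopf_scan(example2_params(), 1, 100, n_grid = 32)$candidates
#' @export
hopf_scan <- function(params, tau_min, tau_max, n_grid = 64L) {
  stopifnot(n_grid >= 16L, tau_min > 0, tau_max > tau_min)
  taus <- seq(tau_min, tau_max, length.out = n_grid)
  hs <- vapply(taus, function(t) hopf_h(params, t), 0)
  r0s <- vapply(taus, function(t) {
    q <- params; q$tau <- t; seiv_thresholds(q)$R0
  }, 0)
  grid <- data.frame(tau = taus, h = hs, R0 = r0s,
                     admissible = is.finite(hs))

  roots <- numeric(0)
  ok <- which(is.finite(hs))
  for (i in seq_len(n_grid - 1L)) {
    if (!(i %in% ok) || !((i + 1L) %in% ok)) next
    if (hs[i] == 0) { roots <- c(roots, taus[i]); next }
    if (hs[i] * hs[i + 1L] < 0) {
      lo <- taus[i]; hi <- taus[i + 1L]
      flo <- hs[i]
      while ((hi - lo) > 1e-10 * hi) {
        mid <- (lo + hi) / 2
        fm <- hopf_h(params, mid)
        if (!is.finite(fm)) break
        if (fm == 0) { lo <- hi <- mid; break }
        if (flo * fm < 0) hi <- mid else { lo <- mid; flo <- fm }
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }

  cand <- lapply(roots, function(ts) {
    q <- params
    q$tau <- ts
    eq <- endemic_equilibria(q)
    st <- eq$endemic[[length(eq$endemic)]]
    cc <- cubic_coefficients(st, q, check = FALSE)
    ev <- eigen(seiv_jacobian(st, q), only.values = TRUE)$values
    pair <- ev[abs(Im(ev)) > 1e-10]
    max_re_pair <- if (length(pair)) max(Re(pair)) else NA_real_
    dtau <- 1e-6 * ts
    re_at <- function(t) {
      q$tau <- t
      e <- endemic_equilibria(q)
      evv <- eigen(seiv_jacobian(e$endemic[[length(e$endemic)]], q),
                   only.values = TRUE)$values
      p <- evv[abs(Im(evv)) > 1e-10]
      if (length(p)) max(Re(p)) else NA_real_
    }
    trans <- (re_at(ts + dtau) - re_at(ts - dtau)) / (2 * dtau)
    data.frame(tau_star = ts, c2 = cc$c2,
               im_pair = if (cc$c2 > 0) sqrt(cc$c2) else NA_real_,
               max_re_pair = max_re_pair,
               transversality = trans,
               valid = cc$c2 > 0 && is.finite(max_re_pair) &&
                 abs(max_re_pair) < 1e-6 * cc$c1 &&
                 is.finite(trans) && trans != 0)
  })
  candidates <- if (length(cand)) do.call(rbind, cand)
                else data.frame(tau_star = numeric(0), c2 = numeric(0),
                                im_pair = numeric(0),
                                max_re_pair = numeric(0),
                                transversality = numeric(0),
                                valid = logical(0))
  structure(list(grid = grid, candidates = candidates,
                 n_skipped = sum(!grid$admissible)),
            class = "seiv_hopf")
}

#' @export
print.seiv_hopf <- function(x, ...) {
  cat(sprintf("Hopf scan over tau in [%g, %g] (%d grid points, %d skipped)\n",
              min(x$grid$tau), max(x$grid$tau), nrow(x$grid), x$n_skipped))
  if (!nrow(x$candidates)) cat("  no sign change of c1*c2 - c3\n")
  else print(x$candidates, row.names = FALSE)
  invisible(x)
}
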