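#' Integrate the SEIV system
#'
#' Stiff-capable adaptive integration (lsoda) of the model's vector field.
#' The example regimes mix rates spanning roughly `5e-6` to `40` per unit
#' time, so a stiff solver is the contract here.  Output is dense enough
#' for peak detection.  Compartments that dip to tiny negative values by
#' roundoff are clipped to zero only in the returned table, never inside
#' the vector field.
#'
#' @param params a [seiv_params] object.
#' @param init initial state (length-4, nonnegative).
#' @param t_end final time (> 0).
#' @param rtol,atol solver tolerances; defaults `1e-8` and
#'   `1e-10 * A/mu` (absolute tolerance scaled to the population bound).
#' @param n_out number of equally spaced output times (default 2001).
#' @return An object of class `seiv_trajectory`: list with `times`,
#'   `states` (matrix with columns S, V, E, I), `params`, `solver`
#'   (tolerances and `diagnostics`).
#' @examples
#' traj <- seiv_simulate(example1_params(), seiv_state(1e5, 1e5, 10, 10), 20)
#' tail(traj$states, 1)
#' @export
seiv_simulate <- function(params, init, t_end, rtol = 1e-8, atol = NULL,
                          n_out = 2001L) {
  stopifnot(t_end > 0, n_out >= 10L)
  x0 <- as_state(init)
  if (any(x0 < 0)) stop("initial state must be nonnegative", call. = FALSE)
  if (is.null(atol)) atol <- 1e-10 * params$A / params$mu
  times <- seq(0, t_end, length.out = n_out)
  deriv <- function(t, y, parms) list(unname(seiv_rhs(y, params)))
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  diag <- attributes(sol)$istate
  if (!is.null(diag) && diag[1] < 0)
    stop("integration failed (lsoda istate = ", diag[1], ")", call. = FALSE)
  if (nrow(sol) < n_out)
    stop("integration stopped early at t = ", max(sol[, 1]), call. = FALSE)
  states <- pmax(unclass(sol)[, c("S", "V", "E", "I"), drop = FALSE], 0)
  structure(list(times = sol[, 1], states = states, params = params,
                 solver = list(rtol = rtol, atol = atol,
                               method = "lsoda",
                               diagnostics = diag)),
            class = "seiv_trajectory")
}

#' @export
print.seiv_trajectory <- function(x, ...) {
  cat(sprintf("SEIV trajectory: %d samples on [0, %g]\n",
              length(x$times), max(x$times)))
  cat("final state:",
      paste(sprintf("%s = %.6g", colnames(x$states),
                    x$states[nrow(x$states), ]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.seiv_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states)
}

# local maxima of a series after 3-point median smoothing; the filter can
# flatten a sharp peak into a short plateau, so slope signs are carried
# through flats before looking for up-to-down transitions
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  med <- y
  med[2:(n - 1)] <- vapply(2:(n - 1), function(i)
    stats::median(y[(i - 1):(i + 1)]), 0)
  s <- sign(diff(med))
  for (i in seq_along(s))
    if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  which(s[-length(s)] > 0 & s[-1] < 0) + 1L
}

#' Long-run classification of a trajectory
#'
#' Inspects the tail window (`window_fraction` of the samples) and decides
#' between convergence to a point -- maximum variation of every compartment
#' below `tol * A/mu` -- and sustained oscillation: at least three strict
#' local maxima of the infectious series (after light 3-point median
#' smoothing against solver jitter) with peak-to-trough amplitude above
#' `tol * A/mu`.  The two outcomes are mutually exclusive; both can be
#' absent (slow transient).
#'
#' @param traj a `seiv_trajectory`.
#' @param window_fraction tail fraction to analyse (default 0.25).
#' @param tol relative tolerance, scaled by `A/mu` (default `1e-6`).
#' @return An object of class `seiv_asymptotics`: list with `converged`
#'   (logical), `converged_to` (mean tail state or `NULL`), `oscillating`,
#'   `amplitude` (peak-to-trough of I in the window), `period_estimate`
#'   (mean inter-peak spacing or `NA`), `n_peaks`.
#' @examples
#' traj <- seiv_simulate(example1_params(), seiv_state(1e5, 1e5, 10, 10), 20)
#' asymptotics(traj)$converged
#' @export
asymptotics <- function(traj, window_fraction = 0.25, tol = 1e-6) {
  stopifnot(inherits(traj, "seiv_trajectory"),
            window_fraction > 0, window_fraction <= 1)
  n <- length(traj$times)
  idx <- seq.int(max(1L, floor(n * (1 - window_fraction))), n)
  if (length(idx) < 10L)
    stop("analysis window too short (< 10 samples)", call. = FALSE)
  w <- traj$states[idx, , drop = FALSE]
  scale <- traj$params$A / traj$params$mu
  variation <- max(apply(w, 2, function(col) diff(range(col))))
  converged <- variation < tol * scale

  I <- w[, "I"]
  peaks <- find_peaks(I)
  amplitude <- diff(range(I))
  oscillating <- !converged && length(peaks) >= 3L &&
    amplitude > tol * scale
  period <- if (oscillating && length(peaks) >= 2L)
    mean(diff(traj$times[idx][peaks])) else NA_real_
  structure(list(converged = converged,
                 converged_to = if (converged) colMeans(w) else NULL,
                 oscillating = oscillating,
                 amplitude = amplitude,
                 period_estimate = period,
                 n_peaks = length(peaks)),
            class = "seiv_asymptotics")
}

#' @export
print.seiv_asymptotics <- function(x, ...) {
  if (x$converged) {
    cat("converged to:",
        paste(sprintf("%s = %.6g", names(x$converged_to), x$converged_to),
              collapse = ", "), "\n")
  } else if (x$oscillating) {
    cat(sprintf("oscillating: amplitude %.6g, period ~ %.4g (%d peaks)\n",
                x$amplitude, x$period_estimate, x$n_peaks))
  } else {
    cat("neither converged nor oscillating within the window\n")
  }
  invisible(x)
}

#' Random interior starting points
#'
#' Draws states log-uniformly inside the invariant region: each
#' compartment between `1e-6 * A/mu` and `A/mu`, rescaled when the total
#' exceeds the population bound.
#'
#' @param params a [seiv_params] object.
#' @param n number of draws.
#' @param seed integer seed.
#' @return A list of `n` state vectors.
#' @export
random_interior_states <- function(params, n, seed) {
  set.seed(as.integer(seed))
  bound <- params$A / params$mu
  lapply(seq_len(n), function(i) {
    x <- exp(stats::runif(4, log(1e-6 * bound), log(bound)))
    if (sum(x) > bound) x <- x * (0.99 * bound / sum(x))
    names(x) <- c("S", "V", "E", "I")
    x
  })
}
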