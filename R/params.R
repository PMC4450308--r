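#' Model parameters for the SEIV system
#'
#' Bundle and validate the nine constants of the SEIV model with waning
#' vaccination, nonlinear incidence \eqn{\beta S I (1 + \alpha I)}, treatment
#' return flow \eqn{\tau I} into the susceptible class, and disease-caused
#' death \eqn{\epsilon I}.
#'
#' @param A recruitment rate (individuals per unit time).
#' @param p fraction of recruits vaccinated at entry, in \[0, 1\].
#' @param omega vaccine waning rate (1/time).
#' @param mu natural death rate (1/time).
#' @param beta transmission coefficient (1/(individual * time)).
#' @param alpha incidence nonlinearity coefficient (1/individual).
#' @param sigma progression rate from exposed to infectious (1/time).
#' @param tau treatment/return rate from infectious back to susceptible
#'   (1/time).
#' @param epsilon disease-caused death rate of infectious individuals
#'   (1/time).
#'
#' @details All rates must be nonnegative and `A`, `mu`, `beta`, `sigma`
#'   strictly positive.  `omega`, `tau`, `epsilon` and `alpha` may be zero
#'   for degenerate-case studies; a warning is issued because several
#'   threshold quantities (which divide by `alpha` and `mu`) become
#'   undefined when `alpha = 0`.
#'
#' @return An object of class `seiv_params`: a named list with the nine
#'   components above.
#' @examples
#' prm <- seiv_params(A = 1e6, p = 0.9, omega = 5e-6, mu = 2, beta = 9e-5,
#'                    alpha = 5e-6, sigma = 0.006, tau = 40, epsilon = 0.08)
#' prm
#' @export
seiv_params <- function(A, p, omega, mu, beta, alpha, sigma, tau, epsilon) {
  vals <- c(A = A, p = p, omega = omega, mu = mu, beta = beta,
            alpha = alpha, sigma = sigma, tau = tau, epsilon = epsilon)
  if (!all(is.finite(vals)))
    stop("all parameters must be finite numbers", call. = FALSE)
  if (A <= 0 || mu <= 0 || beta <= 0 || sigma <= 0)
    stop("A, mu, beta and sigma must be strictly positive", call. = FALSE)
  if (p < 0 || p > 1)
    stop("p must lie in [0, 1]", call. = FALSE)
  if (omega < 0 || tau < 0 || epsilon < 0 || alpha < 0)
    stop("omega, tau, epsilon, alpha must be nonnegative", call. = FALSE)
  zero <- c(omega = omega, tau = tau, epsilon = epsilon, alpha = alpha) == 0
  if (any(zero))
    warning("degenerate parameter(s) equal to zero: ",
            paste(names(zero)[zero], collapse = ", "), call. = FALSE)
  structure(as.list(vals), class = "seiv_params")
}

#' @export
print.seiv_params <- function(x, ...) {
  cat("SEIV model parameters\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 8), format(v, digits = 8),
             collapse = "\n"), "\n")
  invisible(x)
}

#' A compartment state of the SEIV model
#'
#' @param S,V,E,I counts of susceptible, vaccinated, exposed and infectious
#'   individuals; all must be nonnegative and finite.
#' @return A named numeric vector `c(S, V, E, I)`.
#' @examples
#' seiv_state(1e5, 1e5, 10, 10)
#' @export
seiv_state <- function(S, V, E, I) {
  x <- c(S = S, V = V, E = E, I = I)
  if (!all(is.finite(x))) stop("state components must be finite", call. = FALSE)
  if (any(x < 0)) stop("state components must be nonnegative", call. = FALSE)
  x
}

# Coerce a length-4 vector to (S, V, E, I) order without the nonnegativity
# check; internal entry point used by the vector field, which stays defined
# for roundoff-negative states.
as_state <- function(x) {
  if (length(x) != 4L || !is.numeric(x))
    stop("state must be a numeric vector of length 4", call. = FALSE)
  if (!all(is.finite(x))) stop("state components must be finite", call. = FALSE)
  if (!is.null(names(x)) && all(c("S", "V", "E", "I") %in% names(x)))
    x <- x[c("S", "V", "E", "I")]
  names(x) <- c("S", "V", "E", "I")
  x
}

#' Parameter sets of the two worked numerical examples
#'
#' `example1_params()` is a vaccine-dominated regime (high coverage p = 0.9,
#' fast population turnover mu = 2) in which the infection cannot invade;
#' `example2_params()` is an endemic regime (p = 0.6, slow turnover
#' mu = 0.02, fast progression sigma = 45.6) studied at different treatment
#' rates `tau`.
#'
#' @param tau treatment rate for the endemic example (default 20).
#' @return A [seiv_params] object.
#' @examples
#' seiv_thresholds(example1_params())
#' @export
example1_params <- function() {
  seiv_params(A = 1e6, p = 0.9, omega = 0.000005, mu = 2, beta = 0.00009,
              alpha = 0.000005, sigma = 0.006, tau = 40, epsilon = 0.08)
}

#' @rdname example1_params
#' @export
example2_params <- function(tau = 20) {
  stopifnot(tau > 0)
  seiv_params(A = 1e6, p = 0.6, omega = 0.05, mu = 0.02, beta = 0.00005,
              alpha = 0.000005, sigma = 45.6, tau = tau, epsilon = 23)
}

#' Reproducible random parameter draws
#'
#' Draws one plausible parameter set, log-uniformly for the positive rates
#' and uniformly for the vaccinated fraction `p`.  The default ranges
#' bracket both worked examples.
#'
#' @param seed integer seed; the draw is a pure function of it.
#' @param ranges optional named list of `c(lo, hi)` ranges overriding the
#'   defaults for any of the nine parameters.
#' @return A [seiv_params] object.
#' @examples
#' identical(random_params(1), random_params(1))
#' @export
random_params <- function(seed, ranges = NULL) {
  defaults <- list(
    A     = c(1e4, 1e7),
    omega = c(1e-5, 1),
    mu    = c(0.01, 2),
    beta  = c(1e-7, 1e-3),
    alpha = c(1e-7, 1e-2),
    sigma = c(0.01, 50),
    tau   = c(0.1, 50),
    epsilon = c(0.01, 30),
    p     = c(0, 1)
  )
  if (!is.null(ranges)) defaults[names(ranges)] <- ranges
  rng <- local({
    set.seed(as.integer(seed))
    stats::runif(9)
  })
  logu <- function(u, r) exp(log(r[1]) + u * (log(r[2]) - log(r[1])))
  seiv_params(
    A     = logu(rng[1], defaults$A),
    p     = defaults$p[1] + rng[2] * (defaults$p[2] - defaults$p[1]),
    omega = logu(rng[3], defaults$omega),
    mu    = logu(rng[4], defaults$mu),
    beta  = logu(rng[5], defaults$beta),
    alpha = logu(rng[6], defaults$alpha),
    sigma = logu(rng[7], defaults$sigma),
    tau   = logu(rng[8], defaults$tau),
    epsilon = logu(rng[9], defaults$epsilon)
  )
}
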