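# Scenario configuration and batch driver: one JSON config in, a
# structured report (and optionally a run directory of CSV/JSON files)
# out.  Numbers round-trip through serialization at full precision.

#' Scenario configuration
#'
#' @param params a [seiv_params] object.
#' @param init initial state, a length-4 nonnegative vector, or the name
#'   of a preset (`"dfe"`, `"near_dfe"`); only used by the `simulate`
#'   analysis.
#' @param run character vector of analyses to run, a subset of
#'   `c("thresholds", "equilibria", "stability", "bifurcation",
#'   "hopf-scan", "global-stability", "simulate")`; empty for a
#'   metadata-only report.
#' @param options named list of per-analysis options (e.g.
#'   `simulate = list(t_end = 100)`, `hopf = list(tau_min = 1,
#'   tau_max = 100, n_grid = 32)`, `global = list(c = 0.01)`).
#' @param seed integer seed for randomized utilities.
#' @return An object of class `seiv_config`.
#' @export
scenario_config <- function(params, init = "near_dfe", run = character(0),
                            options = list(), seed = 1L) {
  stopifnot(inherits(params, "seiv_params"))
  known <- c("thresholds", "equilibria", "stability", "bifurcation",
             "hopf-scan", "global-stability", "simulate")
  if (!all(run %in% known))
    stop("unknown analysis: ", paste(setdiff(run, known), collapse = ", "),
         call. = FALSE)
  structure(list(params = params, init = init, run = run,
                 options = options, seed = as.integer(seed)),
            class = "seiv_config")
}

#' Read and write scenario configurations as JSON
#'
#' Serialization keeps 17 significant digits (IEEE double round-trip), so
#' `read_config(write_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param config a `seiv_config` object.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a `seiv_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "seiv_config"))
  x <- list(params = unclass(config$params),
            init = if (is.character(config$init)) config$init
                   else as.list(config$init),
            run = config$run, options = config$options, seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prm <- do.call(seiv_params, as.list(x$params))
  init <- if (is.character(x$init)) x$init else unlist(x$init)
  opts <- if (is.null(x$options) || length(x$options) == 0) list()
          else lapply(x$options, as.list)
  scenario_config(prm, init = init,
                  run = as.character(unlist(x$run)),
                  options = opts, seed = x$seed)
}

resolve_init <- function(config) {
  if (is.character(config$init)) {
    P0 <- disease_free_equilibrium(config$params)
    switch(config$init,
           dfe = P0,
           near_dfe = {
             eps <- 1e-4 * config$params$A / config$params$mu
             P0 + c(0, 0, eps, eps)
           },
           stop("unknown init preset: ", config$init, call. = FALSE))
  } else as_state(config$init)
}

#' Run all analyses requested by a scenario configuration
#'
#' Executes each requested analysis in a fixed order; a failure in one
#' analysis is captured as an error record in its own section and does not
#' abort the others.  With `out_dir` set, a machine-readable `summary.json`
#' (full precision, no timestamps, hence byte-reproducible), per-analysis
#' CSV tables and a plain-text log are written.
#'
#' @param config a `seiv_config`.
#' @param out_dir optional output directory (created if missing).
#' @return An object of class `seiv_run`: a named list of per-analysis
#'   results (`error` entries where an analysis failed), plus `config`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "seiv_config"))
  opt <- function(name, default) {
    o <- config$options[[name]]
    if (is.null(o)) default else utils::modifyList(default, o)
  }
  safely <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  res <- list()
  for (an in config$run) {
    res[[an]] <- safely(switch(an,
      "thresholds" = seiv_thresholds(config$params),
      "equilibria" = endemic_equilibria(config$params),
      "stability" = {
        eq <- endemic_equilibria(config$params)
        list(dfe = dfe_stability(config$params),
             endemic = lapply(eq$endemic, endemic_stability,
                              params = config$params))
      },
      "bifurcation" = bifurcation_coefficients(config$params),
      "hopf-scan" = {
        o <- opt("hopf", list(tau_min = 1, tau_max = 100, n_grid = 32L))
        hopf_scan(config$params, o$tau_min, o$tau_max, o$n_grid)
      },
      "global-stability" = {
        o <- opt("global",
                 list(c = 1e-6 * config$params$A / config$params$mu))
        list(dfe = dfe_global_condition(config$params),
             endemic = endemic_global_condition(config$params, c = o$c))
      },
      "simulate" = {
        o <- opt("simulate", list(t_end = 100, rtol = 1e-8,
                                  n_out = 2001L))
        traj <- seiv_simulate(config$params, resolve_init(config),
                              o$t_end, rtol = o$rtol,
                              n_out = as.integer(o$n_out))
        list(trajectory = traj, asymptotics = asymptotics(traj))
      }))
  }
  out <- structure(c(res, list(config = config)), class = "seiv_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

# machine-readable flat summary of a run (deterministic: no timestamps)
run_summary <- function(run) {
  s <- list(params = unclass(run$config$params), seed = run$config$seed)
  if (!is.null(run$thresholds) && is.null(run$thresholds$error)) {
    ts <- run$thresholds
    s$thresholds <- ts[c("M", "stau", "R0", "R0_star", "R1_star",
                         "alpha0", "beta_star")]
  }
  if (!is.null(run$equilibria) && is.null(run$equilibria$error)) {
    eq <- run$equilibria
    s$equilibria <- list(P0 = as.list(eq$P0), case = eq$case_label,
                         endemic = lapply(eq$endemic, as.list),
                         residuals = eq$residuals)
  }
  if (!is.null(run$stability) && is.null(run$stability$error))
    s$stability <- list(
      dfe = run$stability$dfe$verdict,
      endemic = vapply(run$stability$endemic, `[[`, "", "verdict"))
  if (!is.null(run$bifurcation) && is.null(run$bifurcation$error))
    s$bifurcation <- run$bifurcation[c("beta_star", "a_coef", "b_coef",
                                       "alpha0", "direction")]
  if (!is.null(run[["hopf-scan"]]) && is.null(run[["hopf-scan"]]$error))
    s$hopf <- list(candidates = run[["hopf-scan"]]$candidates)
  if (!is.null(run[["global-stability"]]) &&
      is.null(run[["global-stability"]]$error)) {
    g <- run[["global-stability"]]
    s$global <- list(lyapunov = g$dfe$lyapunov_value,
                     dfe_globally_stable = g$dfe$dfe_globally_stable,
                     d = g$endemic$d_value,
                     endemic_condition_met = g$endemic$endemic_condition_met)
  }
  if (!is.null(run$simulate) && is.null(run$simulate$error))
    s$simulate <- list(
      final = as.list(run$simulate$trajectory$states[
        nrow(run$simulate$trajectory$states), ]),
      converged = run$simulate$asymptotics$converged,
      oscillating = run$simulate$asymptotics$oscillating)
  errs <- names(run)[vapply(run, function(x)
    is.list(x) && !is.null(x$error), TRUE)]
  if (length(errs))
    s$errors <- lapply(run[errs], `[[`, "error")
  s
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(run_summary(run), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  log <- c(sprintf("params-hash %s",
                   substr(digest_params(run$config$params), 1, 12)))
  if (!is.null(run$simulate) && is.null(run$simulate$error)) {
    df <- as.data.frame(run$simulate$trajectory)
    utils::write.csv(format(df, digits = 17),
                     file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE, quote = FALSE)
    log <- c(log, "simulate: trajectory.csv written")
  }
  if (!is.null(run$equilibria) && is.null(run$equilibria$error)) {
    eq <- run$equilibria
    rows <- rbind(
      data.frame(kind = "P0", t(eq$P0), residual = 0,
                 label = eq$case_label),
      if (length(eq$endemic))
        do.call(rbind, lapply(seq_along(eq$endemic), function(i)
          data.frame(kind = paste0("P*", i), t(eq$endemic[[i]]),
                     residual = eq$residuals[i], label = eq$case_label))))
    utils::write.csv(format(rows, digits = 17),
                     file.path(out_dir, "equilibria.csv"),
                     row.names = FALSE, quote = FALSE)
    log <- c(log, "equilibria: equilibria.csv written")
  }
  for (an in run$config$run)
    log <- c(log, sprintf("%s: %s", an,
                          if (!is.null(run[[an]]$error))
                            paste("ERROR", run[[an]]$error) else "ok"))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

# order-stable content hash of a parameter set (no external digest dep)
digest_params <- function(params) {
  v <- unlist(params)[order(names(unlist(params)))]
  paste(sprintf("%a", v), collapse = "|")
}

#' @export
print.seiv_run <- function(x, ...) {
  cat("SEIV scenario run: analyses =",
      paste(x$config$run, collapse = ", "), "\n")
  for (an in x$config$run) {
    if (!is.null(x[[an]]$error))
      cat(" ", an, "-> ERROR:", x[[an]]$error, "\n")
    else cat(" ", an, "-> ok\n")
  }
  invisible(x)
}
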