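test_that("example parameter constructors return the printed values", {
  p1 <- example1_params()
  expect_equal(p1$p, 0.9)
  expect_equal(p1$tau, 40)
  expect_identical(round(seiv_thresholds(p1)$M, 4), 168.8254)
  p2 <- example2_params(tau = 20)
  expect_identical(round(seiv_thresholds(p2)$R1_star, 4), 267.6519)
  p2b <- example2_params(tau = 40)
  same <- setdiff(names(unclass(p2)), "tau")
  expect_identical(unclass(p2)[same], unclass(p2b)[same])
  expect_error(example2_params(tau = -1))
})

test_that("random draws are reproducible and valid", {
  expect_identical(random_params(42), random_params(42))
  expect_false(identical(random_params(42), random_params(43)))
  for (i in 1:200) {
    prm <- random_params(i)
    expect_s3_class(prm, "seiv_params")
    ts <- seiv_thresholds(prm)
    expect_true(is.finite(ts$R0))
    # thresholds defined whenever the square-root premise holds
    expect_identical(ts$defined, prm$alpha > 0 && ts$M >= ts$stau)
  }
})

test_that("configs round-trip through JSON at full precision", {
  for (i in 1:20) {
    cfg <- scenario_config(random_params(i + 1234),
                           init = c(S = 1 / 3, V = pi, E = 1e-17, I = 2),
                           run = c("thresholds", "equilibria"),
                           options = list(global = list(c = exp(1))),
                           seed = i)
    path <- tempfile(fileext = ".json")
    write_config(cfg, path)
    back <- read_config(path)
    expect_identical(unclass(back$params), unclass(cfg$params))
    expect_identical(back$init, cfg$init)
    expect_identical(back$run, cfg$run)
    expect_identical(back$options$global$c, exp(1))
    expect_identical(back$seed, cfg$seed)
    unlink(path)
  }
  expect_error(scenario_config(example1_params(), run = "nonsense"),
               "unknown analysis")
})

test_that("a full scenario run reproduces the example analyses", {
  cfg <- scenario_config(example1_params(),
                         init = c(1e5, 1e5, 10, 10),
                         run = c("thresholds", "equilibria", "stability",
                                 "global-stability", "simulate"),
                         options = list(simulate = list(t_end = 20)))
  run <- run_scenario(cfg)
  expect_identical(round(run$thresholds$M, 4), 168.8254)
  expect_length(run$equilibria$endemic, 0)
  expect_equal(run$stability$dfe$verdict, "stable")
  expect_true(run[["global-stability"]]$dfe$dfe_globally_stable)
  expect_true(run$simulate$asymptotics$converged)
})

test_that("empty run-spec yields a metadata-only report", {
  cfg <- scenario_config(example1_params(), run = character(0))
  run <- run_scenario(cfg)
  expect_identical(setdiff(names(run), "config"), character(0))
})

test_that("analysis failures are captured per section, not fatal", {
  cfg <- scenario_config(example1_params(), init = "bogus-preset",
                         run = c("thresholds", "simulate"))
  run <- run_scenario(cfg)
  expect_null(run$thresholds$error)
  expect_false(is.null(run$simulate$error))
  expect_match(run$simulate$error, "preset")
})

test_that("repeated runs write byte-identical machine-readable summaries", {
  cfg <- scenario_config(example2_params(20),
                         run = c("thresholds", "equilibria"))
  d1 <- file.path(tempdir(), "run_a")
  d2 <- file.path(tempdir(), "run_b")
  run_scenario(cfg, out_dir = d1)
  run_scenario(cfg, out_dir = d2)
  s1 <- readBin(file.path(d1, "summary.json"), "raw",
                file.size(file.path(d1, "summary.json")))
  s2 <- readBin(file.path(d2, "summary.json"), "raw",
                file.size(file.path(d2, "summary.json")))
  expect_identical(s1, s2)
  eqcsv <- utils::read.csv(file.path(d1, "equilibria.csv"))
  expect_equal(nrow(eqcsv), 2)  # P0 and one endemic state
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the discrepancy report recomputes every quantity it compares", {
  dr <- discrepancy_report()
  expect_setequal(dr$quantity,
                  c("I_star", "S_star", "E_star", "V_star", "R0_star",
                    "tau_star", "d"))
  # internal consistency of the recomputed values
  prm <- example2_params(20)
  st <- endemic_equilibria(prm)$endemic[[1]]
  expect_equal(dr$computed[dr$quantity == "I_star"], st[["I"]])
  expect_equal(dr$delta[dr$quantity == "d"], 0, tolerance = 1e-10)
  expect_equal(dr$delta[dr$quantity == "V_star"], 28.57143,
               tolerance = 1e-6)
  # the reported I* genuinely fails the steady-state equations ...
  reported <- c(S = 432250, V = 8571400, E = 187060, I = 198280)
  expect_gt(max(abs(seiv_rhs(reported, prm))), 1e3 * prm$A * 1e-8)
  # ... while the recomputed one satisfies them
  expect_lt(max(abs(seiv_rhs(st, prm))), 1e-8 * prm$A)
  # no Hopf candidate on the scanned range for the true branch
  expect_true(is.na(dr$computed[dr$quantity == "tau_star"]))
})
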