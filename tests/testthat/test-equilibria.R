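test_that("disease-free equilibrium matches its closed form in both examples", {
  P0 <- disease_free_equilibrium(example1_params())
  expect_equal(round(P0[["S"]]), 50001)
  expect_equal(signif(P0[["V"]], 5), 450000)
  expect_equal(P0[["E"]], 0)
  expect_equal(P0[["I"]], 0)
  P0b <- disease_free_equilibrium(example2_params(20))
  expect_equal(signif(P0b[["S"]], 5), 41429000)
  expect_equal(signif(P0b[["V"]], 5), 8571400)
  # no vaccination, vanishing waning: everyone susceptible
  prm <- suppressWarnings(
    seiv_params(A = 1e5, p = 0, omega = 1e-12, mu = 0.1, beta = 1e-5,
                alpha = 1e-5, sigma = 1, tau = 1, epsilon = 0.1))
  expect_equal(disease_free_equilibrium(prm)[["S"]], 1e6, tolerance = 1e-6)
  expect_lt(disease_free_equilibrium(prm)[["V"]], 1e-4)
})

test_that("quadratic coefficient signs encode the threshold order", {
  q2 <- endemic_quadratic(example2_params(20))
  expect_lt(q2$k1, 0)
  expect_lt(q2$k2, 0)  # R0 < R1* here
  expect_gt(q2$k3, 0)  # R0 > 1
  ts <- q2$thresholds
  expect_true(ts$R0 > 1 && ts$R0 < ts$R1_star)
  for (i in 1:300) {
    prm <- draw_defined(i + 40)
    qq <- endemic_quadratic(prm)
    ts <- qq$thresholds
    expect_lt(qq$k1, 0)
    expect_identical(qq$k3 > 0, ts$R0 > 1)
    expect_identical(qq$k2 > 0, ts$R0 > ts$R1_star)
    # discriminant identity rearranged in terms of R0
    v <- prm$beta * (ts$M - ts$stau)
    u <- prm$mu * ts$M * prm$alpha * ts$R0
    expect_lt(relerr(qq$discriminant,
                     (u + v)^2 - 4 * prm$mu * ts$M * prm$alpha * v), 1e-10)
    if (ts$R0 >= ts$R0_star) expect_gte(qq$discriminant, 0)
  }
})

test_that("k3 vanishes at the critical transmission coefficient", {
  prm <- example2_params(20)
  prm$beta <- seiv_thresholds(prm)$beta_star
  q2 <- endemic_quadratic(prm)
  expect_lt(abs(q2$k3), 1e-10 * prm$mu * q2$thresholds$M)
  # with alpha < alpha0 (forward case) there is no positive root
  expect_length(endemic_equilibria(prm)$endemic, 0)
})

test_that("the endemic example has one equilibrium, verified against
           independent multivariate root-finding", {
  skip_if_not_installed("pracma")
  prm <- example2_params(20)
  eq <- endemic_equilibria(prm)
  expect_equal(eq$case_label, "one-endemic")
  expect_equal(eq$theorem_branch, "R1*>1")
  expect_length(eq$endemic, 1)
  st <- eq$endemic[[1]]
  # frozen oracle values (np.roots + back-substitution)
  expect_equal(st[["I"]], 35329.0087, tolerance = 1e-8)
  expect_equal(st[["S"]], 731552.2835, tolerance = 1e-8)
  expect_equal(st[["E"]], 33330.13058, tolerance = 1e-8)
  expect_equal(st[["V"]], 8571428.571, tolerance = 1e-8)
  expect_lt(max(eq$residuals), 1e-8 * prm$A)

  # independent oracle: solve the full 4-d steady-state system from 20
  # random interior starts and keep the solutions with I > 0
  f <- function(x) seiv_rhs(x, prm)
  found <- list()
  for (s in random_interior_states(prm, 20, seed = 11)) {
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(f, unname(s), tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(sol)) next
    x <- sol$x
    if (max(abs(f(x))) < 1e-6 * prm$A && x[4] > 1)
      found <- c(found, list(x))
  }
  expect_gte(length(found), 1)
  for (x in found) {
    expect_lt(max(relerr(x, unname(st))), 1e-6)  # 6 significant figures
  }
})

test_that("the vaccine-dominated example has no endemic equilibrium", {
  eq <- endemic_equilibria(example1_params())
  expect_length(eq$endemic, 0)
  expect_equal(eq$case_label, "no-endemic")
  expect_equal(eq$theorem_branch, "R1*>1")
})

test_that("backward regime below R0 = 1 carries two endemic equilibria", {
  prm <- two_endemic_params(r0 = 0.98)
  ts <- seiv_thresholds(prm)
  expect_true(ts$R1_star < 1)
  expect_true(ts$R0_star < ts$R0 && ts$R0 < 1)
  eq <- endemic_equilibria(prm)
  expect_equal(eq$case_label, "two-endemic")
  expect_length(eq$endemic, 2)
  expect_lt(max(eq$residuals), 1e-8 * prm$A)
  # below the saddle-node both disappear
  prm2 <- two_endemic_params(r0 = 0.5)
  ts2 <- seiv_thresholds(prm2)
  expect_true(ts2$R0 < ts2$R0_star)
  expect_length(endemic_equilibria(prm2)$endemic, 0)
  expect_equal(classify_equilibria(ts2), "no-endemic")
})

test_that("case labels match the positive-root count on random draws", {
  n <- 0
  for (i in 1:600) {
    prm <- draw_defined(i + 4200)
    ts <- seiv_thresholds(prm)
    # exclude boundary bands
    if (abs(ts$R0 - 1) < 1e-6 || abs(ts$R0 - ts$R0_star) < 1e-6 ||
        abs(ts$R1_star - 1) < 1e-6) next
    eq <- endemic_equilibria(prm)
    expected <- switch(eq$case_label, "no-endemic" = 0L,
                       "one-endemic" = 1L, "two-endemic" = 2L)
    expect_identical(length(eq$endemic), expected)
    n <- n + 1
  }
  # include constructed backward cases so the two-endemic branch is hit
  for (r0 in seq(0.9, 0.99, by = 0.01)) {
    eq <- endemic_equilibria(two_endemic_params(r0 = r0))
    expect_identical(length(eq$endemic), 2L)
    expect_equal(eq$case_label, "two-endemic")
  }
  expect_gte(n, 500)
})

test_that("the vaccinated component is the same at every equilibrium", {
  prm <- two_endemic_params()
  eq <- endemic_equilibria(prm)
  v_star <- prm$p * prm$A / (prm$mu + prm$omega)
  expect_equal(eq$P0[["V"]], v_star)
  for (st in eq$endemic) expect_equal(st[["V"]], v_star)
})

test_that("classification errors when the thresholds are undefined", {
  prm <- suppressWarnings(
    seiv_params(A = 1e5, p = 0.5, omega = 0.1, mu = 0.1, beta = 1e-5,
                alpha = 0, sigma = 1, tau = 1, epsilon = 0.1))
  expect_error(classify_equilibria(seiv_thresholds(prm)), "undefined")
})
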