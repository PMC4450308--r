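test_that("the linearisation at beta* has the expected eigen-structure", {
  for (prm in list(example2_params(20), hopf_fixture_params(),
                   example1_params())) {
    setup <- center_manifold_setup(prm)
    ev <- setup$eigenvalues
    scale <- max(Mod(ev))
    # -mu and -(mu+omega) are always in the spectrum at P0
    expect_lt(min(Mod(ev - (-prm$mu))), 1e-8 * scale)
    expect_lt(min(Mod(ev - (-(prm$mu + prm$omega)))), 1e-8 * scale)
    # simple zero eigenvalue, all others strictly negative
    expect_equal(sum(Mod(ev) < 1e-8 * scale), 1)
    expect_lt(sort(Re(ev))[2], 0)
    # the trace of the infected block is the remaining eigenvalue
    trace_EI <- -(2 * prm$mu + prm$sigma + prm$tau + prm$epsilon)
    expect_lt(min(Mod(ev - trace_EI)), 1e-6 * scale)
    # closed-form structure of the null vectors
    expect_identical(setup$right_vec[2], 0)
    expect_identical(setup$left_vec[1:2], c(0, 0))
    expect_equal(sum(setup$left_vec * setup$right_vec), 1)
    # numeric nullspace is parallel to the closed-form right vector
    ns <- svd(setup$jacobian)$v[, 4]
    v <- setup$right_vec
    cosang <- abs(sum(ns * v)) / sqrt(sum(ns^2) * sum(v^2))
    expect_lt(acos(min(cosang, 1)), 1e-8)
  }
})

test_that("center-manifold coefficients: b > 0 and sign(a) = sign(alpha - alpha0)", {
  for (i in 1:500) {
    prm <- draw_defined(i + 31000)
    bc <- bifurcation_coefficients(prm)  # errors if sum != closed form
    expect_gt(bc$b_coef, 0)
    if (abs(prm$alpha - bc$alpha0) > 1e-10 * bc$alpha0)
      expect_identical(sign(bc$a_coef), sign(prm$alpha - bc$alpha0))
  }
})

test_that("a vanishes at the critical nonlinearity alpha0", {
  prm <- example2_params(20)
  prm$alpha <- seiv_thresholds(prm)$alpha0
  bc <- bifurcation_coefficients(prm)
  expect_lt(abs(bc$a_coef), 1e-10 * abs(bc$a_closed) + 1e-10 *
              2 * (prm$mu + prm$sigma))
  expect_equal(bc$direction, "degenerate")
})

test_that("bifurcation direction: a-rule, R1*-rule and alpha-rule agree", {
  # strong nonlinearity: backward; linear incidence limit: forward
  prm_back <- example2_params(20)
  prm_back$alpha <- 10 * seiv_thresholds(prm_back)$alpha0
  expect_equal(bifurcation_direction(prm_back), "backward")
  prm_fwd <- example2_params(20)
  prm_fwd$alpha <- 1e-12  # effectively bilinear incidence
  expect_equal(bifurcation_direction(prm_fwd), "forward")
  for (i in 1:500) {
    prm <- draw_defined(i + 47000)
    dir <- bifurcation_direction(prm)  # errors if the two rules disagree
    expect_true(dir %in% c("forward", "backward", "degenerate"))
  }
})

test_that("more vaccination makes backward bifurcation less likely", {
  prm <- example2_params(20)
  expect_lt(sign_da_dp(prm)$sign, 0)
  n <- 0
  for (i in 1:150) {
    prm <- draw_defined(i + 61000)
    if (prm$p < 1e-4 || prm$p > 1 - 1e-4) next
    expect_lt(sign_da_dp(prm)$derivative, 0)
    n <- n + 1
  }
  expect_gte(n, 100)
})

test_that("Hopf scan finds the fixture's critical treatment rate", {
  prm <- hopf_fixture_params()
  scan <- hopf_scan(prm, 0.5, 5, n_grid = 24)
  expect_equal(nrow(scan$candidates), 1)
  cand <- scan$candidates[1, ]
  # frozen oracle: brentq root of h and the spectral crossing coincide
  expect_equal(cand$tau_star, 1.68896846076, tolerance = 1e-8)
  expect_true(cand$valid)
  expect_gt(cand$c2, 0)
  expect_equal(cand$im_pair, 0.38675231, tolerance = 1e-6)
  expect_gt(cand$transversality, 0)
  # at the candidate the cubic roots are {+- i sqrt(c2), -c1}
  q <- prm
  q$tau <- cand$tau_star
  st <- endemic_equilibria(q)$endemic[[1]]
  cc <- cubic_coefficients(st, q)
  roots <- polyroot(c(cc$c3, cc$c2, cc$c1, 1))
  expect_lt(min(Mod(roots - complex(imaginary = sqrt(cc$c2)))),
            1e-6 * cc$c1)
  expect_lt(min(Mod(roots - (-cc$c1))), 1e-6 * cc$c1)
  # the second crossing (restabilisation) has opposite transversality
  scan2 <- hopf_scan(prm, 5, 6.2, n_grid = 16)
  expect_equal(nrow(scan2$candidates), 1)
  expect_equal(scan2$candidates$tau_star[1], 5.69135046277,
               tolerance = 1e-7)
  expect_lt(scan2$candidates$transversality[1], 0)
})

test_that("Hopf scan on the endemic example finds no candidate on [1, 100]", {
  scan <- hopf_scan(example2_params(), 1, 100, n_grid = 34)
  expect_equal(nrow(scan$candidates), 0)
  adm <- scan$grid[scan$grid$admissible, ]
  expect_gt(nrow(adm), 30)
  expect_true(all(adm$h < 0))  # Hurwitz margin negative everywhere
})

test_that("points without an admissible equilibrium are skipped, not fatal", {
  # R0 < 1 throughout this range for the vaccine-dominated example
  scan <- hopf_scan(example1_params(), 1, 10, n_grid = 16)
  expect_equal(scan$n_skipped, 16)
  expect_equal(nrow(scan$candidates), 0)
})
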