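test_that("make_matrix lays out flows, stays and structural zeros", {
  M <- make_matrix(bm_params())
  expect_equal(unname(M["X", ]), c(0.883, 0.070, 0.047, 0, 0))
  expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
  ## structural zeros exactly zero
  expect_identical(unname(M[cbind(c("X", "X", "C1", "C1", "A", "A",
                                    "C2", "C2", "R"),
                                  c("R", "C2", "R", "C2", "X", "C1",
                                    "X", "C1", "C1"))]),
                   rep(0, 9))
  ## no flows at all -> identity
  zero <- do.call(transition_params,
                  as.list(setNames(rep(0, 11), names(crimedyn:::PARAM_ARROWS))))
  expect_equal(unclass(make_matrix(zero)), diag(5),
               ignore_attr = TRUE)
})

test_that("excess outflows are rejected naming the source state", {
  expect_error(
    transition_params(alpha_x1 = 0.1, alpha_xa = 0.1, beta_1x = 0.1,
                      gamma_1a = 0.1, zeta_a2 = 0.1, beta_ar = 0.1,
                      gamma_2a = 0.1, beta_2r = 0.1,
                      alpha_r2 = 0.5, alpha_ra = 0.4, epsilon_rx = 0.3),
    "state\\(s\\): R")
  expect_error(transition_params(1.2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
               "outside \\[0, 1\\]")
})

test_that("step applies one annual update and conserves mass", {
  bm <- bm_params()
  s0 <- state_vector(1, 0, 0, 0, 0)
  expect_equal(as.numeric(step_state(s0, bm)),
               c(0.883, 0.070, 0.047, 0, 0), tolerance = 1e-12)
  ## identity parameters leave any state unchanged
  zero <- do.call(transition_params,
                  as.list(setNames(rep(0, 11), names(crimedyn:::PARAM_ARROWS))))
  s <- state_vector(0.2, 0.3, 0.1, 0.15, 0.25)
  expect_equal(as.numeric(step_state(s, zero)), as.numeric(s))
  ## mass conservation over random states and parameters
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    v <- state_vector(runif(5))
    expect_equal(sum(as.numeric(step_state(v, p))), 1, tolerance = 1e-12)
  }
})

test_that("simulate_chain reproduces the printed transient and equilibrium", {
  bm <- bm_params()
  tr <- simulate_chain(bm_initial(), bm, 6)
  expect_equal(nrow(tr), 7)
  expect_lt(abs(tr[7, "X"] - 0.679), 0.005)
  tr300 <- simulate_chain(bm_initial(), bm, 300)
  expect_lt(max(abs(tr300[301, ] - c(0.642, 0.060, 0.095, 0.152, 0.050))),
            0.005)
  wm300 <- simulate_chain(wm_initial(), wm_params(), 300)
  expect_lt(abs(wm300[301, "A"] - 0.060), 0.005)
  ## n_steps = 0 returns just the start
  tr0 <- simulate_chain(bm_initial(), bm, 0)
  expect_equal(nrow(tr0), 1)
  expect_equal(unname(tr0[1, ]), as.numeric(bm_initial()))
})

test_that("closed-form equilibrium matches the frozen null-space oracle", {
  eq <- equilibrium_closed_form(bm_params())
  expect_equal(as.numeric(eq$state_star), unname(BM_EQ), tolerance = 1e-6)
  expect_equal(eq$crime_rate, 1 - eq$x_star)
  eqw <- equilibrium_closed_form(wm_params())
  expect_equal(as.numeric(eqw$state_star), unname(WM_EQ), tolerance = 1e-6)
  ## no entry into crime: X* = 1 exactly
  p <- set_param(set_param(random_params(), "alpha_x1", 0), "alpha_xa", 0)
  expect_equal(equilibrium_closed_form(p)$x_star, 1, tolerance = 1e-12)
})

test_that("degenerate parameterizations raise an explicit error", {
  ## flow into crime but none of the return flows: D = 0
  p <- transition_params(0.1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_error(equilibrium_closed_form(p), "degenerate")
})

test_that("stationary solve agrees with closed form and flags reducibility", {
  eq <- equilibrium_solve(wm_params())
  expect_lt(abs(eq$state_star[["R"]] - 0.100), 0.005)
  set.seed(21)
  for (i in 1:200) {
    p <- random_params()
    expect_equal(equilibrium_closed_form(p)$x_star,
                 equilibrium_solve(p)$x_star, tolerance = 1e-10)
  }
  ## identity parameters: every state absorbing, non-unique
  zero <- do.call(transition_params,
                  as.list(setNames(rep(0, 11), names(crimedyn:::PARAM_ARROWS))))
  expect_warning(eq0 <- equilibrium_solve(zero), "not unique")
  expect_false(eq0$unique)
})

test_that("equilibrium is a fixed point, reached from any interior start", {
  bm <- bm_params()
  eq <- equilibrium_solve(bm)
  stepped <- step_state(eq$state_star, bm)
  expect_equal(as.numeric(stepped), as.numeric(eq$state_star),
               tolerance = 1e-9)
  ## long-run iteration matches the solve
  final <- simulate_chain(state_vector(rep(0.2, 5)), bm, 300)[301, ]
  expect_equal(unname(final), as.numeric(eq$state_star), tolerance = 1e-6)
  ## initial-condition independence
  set.seed(31)
  for (i in 1:5) {
    p <- random_params()
    a <- simulate_chain(state_vector(runif(5, 0.05, 1)), p, 500)[501, ]
    b <- simulate_chain(state_vector(runif(5, 0.05, 1)), p, 500)[501, ]
    expect_equal(unname(a), unname(b), tolerance = 1e-8)
  }
})

test_that("equilibrium_iterate follows the convergence protocol", {
  eq <- equilibrium_iterate(bm_params(), state0 = bm_initial())
  expect_lte(eq$n_steps_to_converge, 300)
  expect_equal(eq$x_star, BM_EQ[["X"]], tolerance = 1e-8)
})

test_that("state vectors normalize and validate on construction", {
  v <- state_vector(0.794, 0.097, 0.070, 0.016, 0.024)  # sums to 1.001
  expect_equal(sum(as.numeric(v)), 1, tolerance = 1e-12)
  expect_error(state_vector(-0.1, 0.5, 0.2, 0.2, 0.2), "nonnegative")
  expect_error(state_vector(c(0.5, 0.5)), "5")
})

test_that("matrix -> params round trip is exact", {
  bm <- bm_params()
  back <- params_from_matrix(make_matrix(bm), renormalize = FALSE)
  expect_equal(c(unclass(back)), c(unclass(bm)))
})
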