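test_that("panels are bit-identical under a seed and differ across seeds", {
  cfg <- synth_config(n_persons = 200, params = fs_params())
  a <- generate_panel(cfg, seed = 7)
  b <- generate_panel(cfg, seed = 7)
  c <- generate_panel(cfg, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$panel$offended, c$panel$offended))
  ## the caller's RNG stream is untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_panel(cfg, seed = 7)); after <- runif(3)
  expect_identical(before, after)
})

test_that("no onset and everyone starting in X yields an all-quiet panel", {
  quiet <- set_param(set_param(fs_params(), "alpha_x1", 0), "alpha_xa", 0)
  cfg <- synth_config(n_persons = 150, params = quiet,
                      initial = c(1, 0, 0, 0, 0))
  res <- generate_panel(cfg, seed = 3)
  expect_true(all(res$panel$offended == 0))
  expect_true(all(res$panel$arrested == 0))
  expect_true(all(res$truth$state == "X"))
})

test_that("subgroup mix and ages follow the configuration", {
  cfg <- synth_config(n_persons = 20000, params = fs_params())
  res <- generate_panel(cfg, seed = 17)
  p1 <- res$panel[res$panel$wave == 1, ]
  expect_equal(mean(p1$sex == "man"), 0.51, tolerance = 0.02)
  expect_equal(mean(p1$race == "Black"), 0.26, tolerance = 0.02)
  expect_equal(mean(p1$race == "White"), 0.519, tolerance = 0.02)
  expect_true(all(p1$age %in% 12:17))
  ## ages advance one year per wave
  p <- res$panel[res$panel$person_id == p1$person_id[1], ]
  expect_equal(diff(p$age), rep(1, 6))
})

test_that("observables encode the latent state semantics", {
  cfg <- synth_config(n_persons = 4000, params = bm_params())
  res <- generate_panel(cfg, seed = 19)
  s <- res$truth$state
  expect_equal(res$panel$arrested, as.integer(s == "A"))
  expect_true(all(res$panel$offended[s %in% c("C1", "C2")] == 1))
  expect_true(all(res$panel$offended[s %in% c("X", "R")] == 0))
  ## arrested persons co-report offending at the configured rate
  off_a <- res$panel$offended[s == "A"]
  se <- sqrt(0.7 * 0.3 / length(off_a))
  expect_lt(abs(mean(off_a) - 0.7), 3 * se)
})

test_that("history mode round-trips through state assignment exactly", {
  for (seed in c(2, 23)) {
    cfg <- synth_config(n_persons = 600, params = bm_params(),
                        mode = "history")
    res <- generate_panel(cfg, seed = seed)
    st <- assign_states(res$panel)
    expect_identical(st$state, res$truth$state)
    expect_identical(st$ever_arrested, res$truth$ever_arrested)
    expect_identical(st$inactive_streak, res$truth$inactive_streak)
  }
})

test_that("markov mode reproduces the generating chain", {
  cfg <- synth_config(n_persons = 20000, params = wm_params(),
                      mode = "markov")
  res <- generate_panel(cfg, seed = 29)
  em <- empirical_matrix(build_transitions(res$truth))
  M <- unclass(make_matrix(wm_params()))
  n_origin <- rowSums(em$counts)
  for (s in rownames(M)) for (d in colnames(M)) {
    se <- sqrt(M[s, d] * (1 - M[s, d]) / n_origin[s])
    expect_lt(abs(unclass(em$matrix)[s, d] - M[s, d]), 3 * se + 1e-12)
  }
})

test_that("a person-level random intercept tilts crime-ward flows", {
  cfg <- synth_config(n_persons = 15000, params = fs_params(),
                      sigma_u = 1.5)
  res <- generate_panel(cfg, seed = 31)
  em1 <- empirical_matrix(build_transitions(res$truth))
  cfg0 <- synth_config(n_persons = 15000, params = fs_params())
  em0 <- empirical_matrix(build_transitions(generate_panel(cfg0,
                                                           seed = 31)$truth))
  ## heterogeneity raises persistence: X-stayers' average tilt is below
  ## average, so the pooled X->C1 rate differs from the zero-sigma panel
  expect_false(isTRUE(all.equal(unclass(em1$matrix)["X", "C1"],
                                unclass(em0$matrix)["X", "C1"],
                                tolerance = 1e-3)))
  ## rows remain stochastic
  expect_equal(unname(rowSums(unclass(em1$matrix))), rep(1, 5),
               tolerance = 1e-9)
})

test_that("emergent rehabilitation rate matches its closed form", {
  expect_equal(emergent_rehab_rate(
    set_param(set_param(bm_params(), "R->C2", 0), "R->A", 0)), 1)
  p_all <- transition_params(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1,
                             0.6, 0.4, 0)
  expect_equal(emergent_rehab_rate(p_all), 0)
  expect_equal(emergent_rehab_rate(bm_params()), (1 - 0.126 - 0.118)^2)
})

test_that("emergent rehabilitation matches simulated completion frequency", {
  cfg <- synth_config(n_persons = 30000, params = bm_params(),
                      mode = "history")
  res <- generate_panel(cfg, seed = 37)
  tr <- res$truth
  tr <- tr[order(tr$person_id, tr$wave), ]
  ## cohort entering R (first inactive year) with 2 more observed waves
  enter <- which(tr$state == "R" & tr$inactive_streak == 1L &
                   tr$wave <= max(tr$wave) - 2)
  stopifnot(length(enter) > 500)
  completed <- tr$state[enter + 2] == "X"
  q2 <- emergent_rehab_rate(bm_params())
  se <- sqrt(q2 * (1 - q2) / length(enter))
  expect_lt(abs(mean(completed) - q2), 3 * se)
})

test_that("per-subgroup parameter lists are honored", {
  cfg <- synth_config(n_persons = 8000,
                      params = list("Black men" = bm_params(),
                                    "White men" = wm_params(),
                                    "Black women" = fs_params(),
                                    "White women" = fs_params(),
                                    "Hispanic men" = fs_params(),
                                    "Hispanic women" = fs_params()),
                      mode = "markov")
  res <- generate_panel(cfg, seed = 41)
  tr <- build_transitions(merge(res$truth, res$panel,
                                by = c("person_id", "wave")))
  em_b <- empirical_matrix(tr, sex = "man", race = "Black")
  em_w <- empirical_matrix(tr, sex = "man", race = "White")
  ## the Black-men C2->A rate is visibly higher (0.276 vs 0.201)
  expect_gt(unclass(em_b$matrix)["C2", "A"],
            unclass(em_w$matrix)["C2", "A"] - 0.02)
  ## missing subgroup key refuses
  cfg_bad <- synth_config(n_persons = 50,
                          params = list("Black men" = bm_params()))
  expect_error(generate_panel(cfg_bad, seed = 1), "subgroup")
})

test_that("configuration validation", {
  expect_error(synth_config(n_persons = 0), "n_persons")
  expect_error(synth_config(p_man = 1.2), "p_man")
  expect_error(synth_config(sigma_u = -1), "sigma_u")
  expect_error(synth_config(params = fs_params(),
                            initial = c(-1, 1, 0, 0, 0)), "nonnegative")
})
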