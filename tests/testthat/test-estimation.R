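## Simulate outcomes from the transition regression model itself:
## logit Pr(y=1) = X beta + u_i, u_i ~ N(0, sigma_u^2).
simulate_logit_data <- function(n_persons, n_pairs, beta, sigma_u) {
  id <- rep(seq_len(n_persons), each = n_pairs)
  age <- rep(sample(12:17, n_persons, TRUE), each = n_pairs) +
    rep(seq_len(n_pairs) - 1L, n_persons)
  sex <- rep(ifelse(runif(n_persons) < 0.51, "man", "woman"),
             each = n_pairs)
  race <- rep(sample(c("Black", "White", "Hispanic"), n_persons, TRUE,
                     c(0.26, 0.519, 0.212)), each = n_pairs)
  X <- crimedyn:::transition_model_matrix(age, sex, race)
  u <- rep(rnorm(n_persons, 0, sigma_u), each = n_pairs)
  y <- rbinom(n_persons * n_pairs, 1, plogis(drop(X %*% beta) + u))
  list(y = y, X = X, id = id)
}

test_that("the intercept-only model recovers logit(p) when sigma_u = 0", {
  set.seed(51)
  d <- simulate_logit_data(800, 4, c(qlogis(0.15), rep(0, 7)), 0)
  f <- ri_logit(d$y, d$X, d$id)
  expect_lt(abs(f$coefficients[["(Intercept)"]] - qlogis(0.15)),
            2 * f$se[1])
  ## sigma estimate collapses toward the boundary
  expect_lt(f$sigma_u, 0.25)
})

test_that("sigma_u constrained to 0 reduces to ordinary logistic regression", {
  set.seed(52)
  d <- simulate_logit_data(300, 4, c(-1.5, 0.05, 0, -0.3, 0.4, 0, 0, 0), 0.6)
  f0 <- ri_logit(d$y, d$X, d$id, random_intercept = FALSE)
  g <- glm.fit(d$X, d$y, family = binomial())
  expect_equal(unname(f0$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f0$sigma_u, 0)
})

test_that("single observation per person: sigma_u unidentified, glm returned", {
  set.seed(53)
  d <- simulate_logit_data(500, 1, c(-1, rep(0, 7)), 0)
  expect_warning(f <- ri_logit(d$y, d$X, d$id), "unidentified")
  expect_equal(f$sigma_u, 0)
  expect_true("sigma_u_unidentified" %in% f$flags)
})

test_that("fit matches the independent mixed-model oracle (lme4, AGQ 21)", {
  skip_if_not_installed("lme4")
  set.seed(54)
  d <- simulate_logit_data(400, 6, c(-2, 0.1, -0.02, -0.4, 0.5, 0.1,
                                     -0.2, 0), 0.8)
  ours <- ri_logit(d$y, d$X, d$id)
  df <- data.frame(y = d$y, d$X[, -1], id = d$id, check.names = FALSE)
  ref <- suppressWarnings(lme4::glmer(
    y ~ age_c + age_c2 + woman + black + hispanic +
      `woman:black` + `woman:hispanic` + (1 | id),
    data = df, family = binomial, nAGQ = 21))
  ## same optimum up to optimizer tolerance (differences far below the
  ## smallest standard error, ~0.1)
  expect_lt(max(abs(ours$coefficients - lme4::fixef(ref))), 0.02)
  expect_lt(abs(ours$sigma_u - sqrt(unname(unlist(lme4::VarCorr(ref))))),
            0.02)
  expect_lt(abs(ours$loglik - as.numeric(logLik(ref))), 0.05)
  expect_lt(max(abs(ours$se - coef(summary(ref))[, 2])), 0.02)
})

test_that("quadrature is stable: 21 and 41 nodes agree in log-likelihood", {
  set.seed(55)
  d <- simulate_logit_data(300, 6, c(-1.5, 0, 0, 0, 0.5, 0, 0, 0), 1.5)
  f21 <- ri_logit(d$y, d$X, d$id, nq = 21)
  f41 <- ri_logit(d$y, d$X, d$id, nq = 41,
                  start = c(f21$coefficients, f21$sigma_u))
  expect_equal(f21$loglik, f41$loglik, tolerance = 1e-6)
})

test_that("generating coefficients are recovered within 2 SE", {
  set.seed(56)
  beta <- c(-3.10, 0, 0, 0, 0.56, 0, 0, 0)
  d <- simulate_logit_data(3000, 6, beta, 0.5)
  f <- ri_logit(d$y, d$X, d$id)
  expect_lt(abs(f$coefficients[["(Intercept)"]] - beta[1]), 2 * f$se[1])
  expect_lt(abs(f$coefficients[["black"]] - beta[5]), 2 * f$se[5])
  expect_lt(abs(f$sigma_u - 0.5), 2 * f$se_sigma_u)
})

test_that("fit_transition_logit builds the risk set for one arrow", {
  cfg <- synth_config(n_persons = 1500, params = fs_params(),
                      mode = "markov")
  res <- generate_panel(cfg, seed = 57)
  tr <- build_transitions(merge(res$truth, res$panel,
                                by = c("person_id", "wave")))
  f <- fit_transition_logit(tr, "X->C1", random_intercept = FALSE)
  expect_equal(f$outcome, "X->C1")
  expect_equal(f$origin, "X")
  expect_equal(f$n_obs, sum(tr$from_state == "X"))
  ## pooled rate near the generating alpha_x1 (no covariate effects in
  ## the generator, so the average prediction matches the flat rate)
  p_hat <- mean(plogis(drop(
    crimedyn:::transition_model_matrix(tr$age[tr$from_state == "X"],
                                       tr$sex[tr$from_state == "X"],
                                       tr$race[tr$from_state == "X"]) %*%
      f$coefficients)))
  a1 <- unclass(fs_params())[["alpha_x1"]]
  se <- sqrt(a1 * (1 - a1) / f$n_obs)
  expect_lt(abs(p_hat - a1), 3 * se)
  expect_error(fit_transition_logit(tr, "X->R"), "admissible")
})

test_that("predicted probabilities behave as documented", {
  f0 <- structure(list(coefficients = setNames(rep(0, 8),
    colnames(crimedyn:::transition_model_matrix(16, "man", "White"))),
    sigma_u = 0), class = "ri_logit")
  expect_equal(predict_probability(f0, 25, "woman", "Black"), 0.5)
  f1 <- f0; f1$coefficients[1] <- -3.10
  expect_equal(predict_probability(f1, 16, "man", "White"),
               plogis(-3.10), tolerance = 1e-12)
  expect_equal(round(plogis(-3.10), 4), 0.0431)
  ## marginalization shrinks toward 0.5
  f2 <- f1; f2$sigma_u <- 1
  p_cond <- predict_probability(f2, 16, "man", "White",
                                integrate_random_effect = FALSE)
  p_marg <- predict_probability(f2, 16, "man", "White")
  expect_gt(p_marg, p_cond)
  expect_lt(p_marg, 0.5)
  ## monotone in the coefficient direction
  f3 <- f1; f3$coefficients["black"] <- 0.56
  expect_gt(predict_probability(f3, 16, "man", "Black"),
            predict_probability(f3, 16, "man", "White"))
})

test_that("subgroup table averages ages, derives stays, bounds intervals", {
  cols <- colnames(crimedyn:::transition_model_matrix(16, "man", "White"))
  mk_fit <- function(b0, b_black = 0, b_age = 0) {
    co <- setNames(rep(0, 8), cols)
    co[1] <- b0; co["black"] <- b_black; co["age_c"] <- b_age
    structure(list(coefficients = co, sigma_u = 0,
                   vcov = diag(1e-6, 9)), class = "ri_logit")
  }
  fits <- setNames(lapply(unname(crimedyn:::PARAM_ARROWS), function(a)
    mk_fit(-2.2)), unname(crimedyn:::PARAM_ARROWS))
  panel <- data.frame(age = rep(c(14, 15, 16, 17), 25),
                      sex = rep(c("man", "woman"), 50),
                      race = rep(c("White", "Black"), each = 50))
  tab <- subgroup_table(fits, panel, n_boot = 200, seed = 3)
  ## zero age effect: prediction equals the cell prediction for any age mix
  est <- tab$estimate[!tab$derived_stay]
  expect_equal(est, rep(plogis(-2.2), length(est)), tolerance = 1e-12)
  expect_true(all(tab$lower <= tab$estimate + 1e-9 &
                    tab$estimate <= tab$upper + 1e-9))
  ## derived stays: destination probabilities sum to 1 exactly per origin
  for (sg in unique(tab$subgroup)) for (s in c("X", "C1", "A", "R", "C2")) {
    rows <- tab$subgroup == sg & startsWith(tab$transition, paste0(s, "-"))
    expect_equal(sum(tab$estimate[rows]), 1, tolerance = 1e-12)
  }
  ## with an age effect, the age mix matters
  fits2 <- fits; fits2[["X->C1"]] <- mk_fit(-2.2, b_age = 0.3)
  tab2 <- subgroup_table(fits2, panel, ci = "delta", n_boot = 50, seed = 3)
  young <- panel[panel$age < 16, ]
  tab3 <- subgroup_table(fits2, young, ci = "delta", n_boot = 50, seed = 3)
  i2 <- tab2$transition == "X->C1" & tab2$subgroup == "White men"
  i3 <- tab3$transition == "X->C1" & tab3$subgroup == "White men"
  expect_gt(tab2$estimate[i2], tab3$estimate[i3])
  ## missing arrows refuse
  expect_error(subgroup_table(fits[-1], panel), "missing")
})
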