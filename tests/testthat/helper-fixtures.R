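## Shared fixtures: the two printed per-group parameter sets, random
## interior parameter draws, and tiny hand-built panels.

bm_params <- function() load_params(crimedyn_fixture("table5_black_men.json"))
wm_params <- function() load_params(crimedyn_fixture("table5_white_men.json"))
fs_params <- function() load_params(crimedyn_fixture("table2_full_sample.json"))

bm_initial <- function() load_state(crimedyn_fixture("table4_initial_black_men.json"))
wm_initial <- function() load_state(crimedyn_fixture("table4_initial_white_men.json"))

## Frozen equilibrium oracle values, computed once from the independent
## null-space solve of the 5-state matrix built from the printed inputs
## (solve(t(M) - I with a sum-to-one row); see test-core-model.R for the
## live dual-route check).
BM_EQ <- c(X = 0.64152909, C1 = 0.05987605, A = 0.09530632, R = 0.15237398,
           C2 = 0.05091455)
WM_EQ <- c(X = 0.73515369, C1 = 0.06474931, A = 0.05995730, R = 0.09939825,
           C2 = 0.04074145)

## One random interior parameter draw: outflow bundles scaled to sum < 1
## so every stay probability is strictly positive.
random_params <- function() {
  bundle <- function(k) {
    u <- runif(k, 0.05, 1)
    u * runif(1, 0.2, 0.9) / sum(u)
  }
  x <- bundle(2); c1 <- bundle(2); a <- bundle(2); c2 <- bundle(2)
  r <- bundle(3)
  transition_params(alpha_x1 = x[1], alpha_xa = x[2],
                    beta_1x = c1[1], gamma_1a = c1[2],
                    zeta_a2 = a[1], beta_ar = a[2],
                    gamma_2a = c2[1], beta_2r = c2[2],
                    alpha_r2 = r[1], alpha_ra = r[2], epsilon_rx = r[3])
}

## Hand-built panel: one row per wave from vectors of flags.
mini_panel <- function(offended, arrested, id = "p1", first_wave = 1L) {
  n <- length(offended)
  data.frame(person_id = id, wave = seq(first_wave, length.out = n),
             age = 14 + seq_len(n), sex = "man", race = "White",
             offended = offended, arrested = arrested,
             stringsAsFactors = FALSE)
}

expect_states <- function(panel, expected) {
  st <- assign_states(panel)
  expect_equal(st$state, expected)
  invisible(st)
}
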