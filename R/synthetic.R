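## Seeded synthetic longitudinal panel generator.  Emulates the structure
## the analysis assumes (7 annual waves, sex-by-race subgroup mix, baseline
## ages 12-17, per-subgroup transition rates), so that state assignment,
## estimation and the dynamics are testable with no external data.

#' Synthetic panel configuration
#'
#' Defaults emulate the panel the pipeline is designed for: about 6,459
#' persons over 7 annual waves; 51% men; race mix 26% Black, 51.9% White,
#' 21.2% Hispanic (independent of sex); baseline ages uniform on 12-17
#' (mean 14.5, close to the target cohort's 14.9); initial state
#' distribution from the packaged round-1 full-sample table; transition
#' rates from the packaged full-sample transition matrix.
#'
#' Two generating modes:
#' \describe{
#'   \item{`markov`}{the latent process is exactly the five-state chain of
#'     the supplied [transition_params]; used to test the model half
#'     (empirical rates converge to the generating matrix).}
#'   \item{`history`}{the R->X move is not drawn from `epsilon_rx` but
#'     happens deterministically when the inactive streak reaches 3 years
#'     (the rehabilitation rate becomes emergent), and an onset from
#'     rehabilitated X re-enters C2 rather than C1; with this bookkeeping
#'     [assign_states()] applied to the observables reproduces the latent
#'     states exactly, which tests the data-processing half.  Initial
#'     states are restricted to X, C1, A (the only states observable
#'     without unseen history) by renormalization.}
#' }
#'
#' @param n_persons number of persons.
#' @param n_waves number of annual waves.
#' @param p_man proportion men.
#' @param race_mix named proportions over Black/White/Hispanic, summing
#'   to 1.
#' @param age_range integer range of baseline ages (inclusive).
#' @param params a single [transition_params] used for everyone, or a
#'   named list keyed by subgroup label (`"Black men"`, `"White women"`,
#'   ...).  Default: packaged full-sample rates.
#' @param sigma_u SD of a person-level random intercept applied to the
#'   logits of the crime-ward destinations (C1, A, C2) with a shared
#'   loading, then renormalized (a fixed "propensity to offend").
#' @param age_effect length-2 coefficients of (age - 16) and (age - 16)^2
#'   on the same crime-ward logits.
#' @param p_offend_given_A probability an arrested person also reports
#'   offending that year.
#' @param initial initial state distribution (length 5, X C1 A R C2).
#' @param mode `"markov"` or `"history"`.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_persons = 6459L, n_waves = 7L, p_man = 0.51,
                         race_mix = c(Black = 0.26, White = 0.519,
                                      Hispanic = 0.212),
                         age_range = c(12L, 17L),
                         params = NULL,
                         sigma_u = 0, age_effect = c(0, 0),
                         p_offend_given_A = 0.7,
                         initial = c(X = 0.855, C1 = 0.079, A = 0.041,
                                     R = 0.013, C2 = 0.012),
                         mode = c("markov", "history")) {
  mode <- match.arg(mode)
  if (is.null(params))
    params <- load_params(crimedyn_fixture("table2_full_sample.json"))
  if (inherits(params, "transition_params")) params <- list(all = params)
  stopifnot(all(vapply(params, inherits, TRUE, "transition_params")))
  race_mix <- race_mix / sum(race_mix)
  stopifnot(n_persons >= 1, n_waves >= 1, p_man >= 0, p_man <= 1,
            sigma_u >= 0, p_offend_given_A >= 0, p_offend_given_A <= 1,
            length(age_effect) == 2)
  initial <- as.numeric(state_vector(initial))
  structure(list(n_persons = as.integer(n_persons),
                 n_waves = as.integer(n_waves), p_man = p_man,
                 race_mix = race_mix, age_range = age_range,
                 params = params, sigma_u = sigma_u,
                 age_effect = age_effect,
                 p_offend_given_A = p_offend_given_A,
                 initial = initial, mode = mode),
            class = "synth_config")
}

## person -> parameter set lookup
lookup_params <- function(config, sex, race) {
  if (length(config$params) == 1 && names(config$params)[1] == "all")
    return(rep(1L, length(sex)))
  key <- paste(race, ifelse(sex == "man", "men", "women"))
  idx <- match(key, names(config$params))
  if (anyNA(idx))
    stop("no transition parameters supplied for subgroup(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

## multinomial draw, one per row of a probability matrix
draw_dest <- function(P, r) {
  cum <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
  1L + rowSums(r > cum + 1e-15)
}

## tilt crime-ward destination columns (C1, A, C2) by exp(delta), then
## renormalize rows
tilt_crimeward <- function(P, delta) {
  if (all(delta == 0)) return(P)
  W <- P
  f <- exp(delta)
  W[, c(2, 3, 5)] <- W[, c(2, 3, 5)] * f
  W / rowSums(W)
}

#' Generate a synthetic person-wave panel
#'
#' Draws each person's subgroup and baseline age, an initial latent state,
#' and evolves the latent chain wave by wave according to the configured
#' mode (see [synth_config()]).  Observables per person-wave:
#' `arrested = (state == A)`; `offended = 1` for C1/C2,
#' `Bernoulli(p_offend_given_A)` for A, `0` for X/R.  Identical seeds give
#' bit-identical panels; the caller's RNG state is restored on exit.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return List with `panel` (person_id, wave, age, sex, race, offended,
#'   arrested) and `truth` (person_id, wave, state, ever_arrested,
#'   inactive_streak — the latent assignment).
#' @export
generate_panel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv) else
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)

  n <- config$n_persons
  waves <- config$n_waves
  sex <- ifelse(runif(n) < config$p_man, "man", "woman")
  race <- names(config$race_mix)[
    draw_dest(matrix(config$race_mix, n, 3, byrow = TRUE), runif(n))]
  age0 <- sample(seq(config$age_range[1], config$age_range[2]), n,
                 replace = TRUE)
  pidx <- lookup_params(config, sex, race)
  mats <- lapply(config$params, function(p) unclass(make_matrix(p)))
  u <- if (config$sigma_u > 0) rnorm(n, 0, config$sigma_u) else numeric(n)

  init <- config$initial
  history <- config$mode == "history"
  if (history) {
    ## only X, C1, A are observable without unseen history
    init <- c(init[1:3], 0, 0)
    init <- init / sum(init)
  }
  state <- draw_dest(matrix(init, n, 5, byrow = TRUE), runif(n))
  ever <- if (history) state == 3L else state %in% c(3L, 4L, 5L)
  streak <- ifelse(state %in% c(1L, 4L), 1L, 0L)

  S <- matrix(0L, n, waves)     # latent states (1..5)
  EV <- matrix(FALSE, n, waves)
  ST <- matrix(0L, n, waves)
  S[, 1] <- state; EV[, 1] <- ever; ST[, 1] <- streak

  for (w in seq_len(waves - 1)) {
    age_c <- age0 + (w - 1) - 16
    delta <- u + config$age_effect[1] * age_c +
      config$age_effect[2] * age_c^2
    new_state <- integer(n)
    r <- runif(n)
    for (g in seq_along(mats)) {
      in_g <- if (length(mats) == 1) rep(TRUE, n) else pidx == g
      if (!any(in_g)) next
      M <- mats[[g]]
      if (!history) {
        for (s in 1:5) {
          m <- in_g & state == s
          if (!any(m)) next
          P <- matrix(M[s, ], sum(m), 5, byrow = TRUE)
          P <- tilt_crimeward(P, delta[m])
          new_state[m] <- draw_dest(P, r[m])
        }
      } else {
        p <- config$params[[g]]
        pr <- unclass(p)
        for (s in 1:5) {
          m <- in_g & state == s
          if (!any(m)) next
          P <- matrix(0, sum(m), 5)
          if (s == 1L) {
            ## X: onset re-enters C1 if never arrested, C2 if rehabilitated
            ev_m <- ever[m]
            P[, 2] <- ifelse(ev_m, 0, pr[["alpha_x1"]])
            P[, 5] <- ifelse(ev_m, pr[["alpha_x1"]], 0)
            P[, 3] <- pr[["alpha_xa"]]
            P[, 1] <- 1 - P[, 2] - P[, 3] - P[, 5]
          } else if (s == 2L) {
            P[, 1] <- pr[["beta_1x"]]; P[, 3] <- pr[["gamma_1a"]]
            P[, 2] <- 1 - P[, 1] - P[, 3]
          } else if (s == 3L) {
            P[, 5] <- pr[["zeta_a2"]]; P[, 4] <- pr[["beta_ar"]]
            P[, 3] <- 1 - P[, 4] - P[, 5]
          } else if (s == 4L) {
            ## R: recidivate or stay inactive; rehabilitation is emergent
            P[, 5] <- pr[["alpha_r2"]]; P[, 3] <- pr[["alpha_ra"]]
            P[, 4] <- 1 - P[, 3] - P[, 5]
          } else {
            P[, 3] <- pr[["gamma_2a"]]; P[, 4] <- pr[["beta_2r"]]
            P[, 5] <- 1 - P[, 3] - P[, 4]
          }
          P <- tilt_crimeward(P, delta[m])
          new_state[m] <- draw_dest(P, r[m])
        }
      }
    }
    inactive_now <- new_state %in% c(1L, 4L)
    streak <- ifelse(inactive_now, streak + 1L, 0L)
    if (history) {
      ## an R occupant completing the third inactive year is rehabilitated;
      ## an inactive never-arrested person is plain X
      to_x <- new_state == 4L & streak >= 3L
      new_state[to_x] <- 1L
      new_state[new_state == 4L & !ever] <- 1L
    }
    ever <- ever | new_state == 3L
    state <- new_state
    S[, w + 1] <- state; EV[, w + 1] <- ever; ST[, w + 1] <- streak
  }

  person_id <- sprintf("P%05d", seq_len(n))
  long <- function(M) as.vector(t(M))
  st_chr <- STATE_NAMES[long(S)]
  offended <- integer(n * waves)
  offended[st_chr %in% c("C1", "C2")] <- 1L
  is_a <- st_chr == "A"
  offended[is_a] <- rbinom(sum(is_a), 1, config$p_offend_given_A)
  panel <- data.frame(
    person_id = rep(person_id, each = waves),
    wave = rep(seq_len(waves), n),
    age = rep(age0, each = waves) + rep(seq_len(waves) - 1L, n),
    sex = rep(sex, each = waves),
    race = rep(race, each = waves),
    offended = offended,
    arrested = as.integer(is_a),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    person_id = panel$person_id, wave = panel$wave, state = st_chr,
    ever_arrested = as.integer(long(EV)),
    inactive_streak = long(ST), stringsAsFactors = FALSE)
  list(panel = panel, truth = truth)
}

#' Emergent rehabilitation rate in history-consistent mode
#'
#' In history mode R->X is not drawn from `epsilon_rx`: a person entering R
#' (one inactive year behind them) is rehabilitated on completing the
#' 3-year inactive window, i.e. after surviving two further annual draws
#' without recidivating.  The implied completion probability is
#' `(1 - alpha_r2 - alpha_ra)^2`.
#'
#' @param params a [transition_params] object (or a [synth_config], whose
#'   first parameter set is used).
#' @return Probability that a person newly entering R reaches rehabilitated
#'   X before recidivating.
#' @export
emergent_rehab_rate <- function(params) {
  if (inherits(params, "synth_config")) params <- params$params[[1]]
  stopifnot(inherits(params, "transition_params"))
  q <- 1 - unclass(params)[["alpha_r2"]] - unclass(params)[["alpha_ra"]]
  q^2
}
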