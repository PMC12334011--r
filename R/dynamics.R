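#' Population state vector
#'
#' Fractions of the population in the five states (X, C1, A, R, C2) at one
#' time step.  Components are normalized to sum to 1 on construction
#' (printed tables are rounded and may sum to, e.g., 1.001).
#'
#' @param x,c1,a,r,c2 nonnegative fractions; alternatively pass a single
#'   numeric vector of length 5 as `x`.
#' @param t integer time index (years).
#' @return An object of class `state_vector`: a named numeric vector of
#'   length 5 summing to 1, with attribute `t`.
#' @examples
#' state_vector(0.794, 0.097, 0.070, 0.016, 0.024)
#' @export
state_vector <- function(x, c1 = NULL, a = NULL, r = NULL, c2 = NULL, t = 0L) {
  v <- if (length(x) == 5 && is.null(c1)) as.numeric(x) else c(x, c1, a, r, c2)
  if (length(v) != 5 || anyNA(v))
    stop("a state vector needs 5 non-missing components (X, C1, A, R, C2)",
         call. = FALSE)
  if (any(v < 0)) stop("state fractions must be nonnegative", call. = FALSE)
  s <- sum(v)
  if (s <= 0) stop("state vector has zero total mass", call. = FALSE)
  structure(setNames(v / s, STATE_NAMES), class = "state_vector",
            t = as.integer(t))
}

#' @export
print.state_vector <- function(x, ...) {
  cat("state distribution (t = ", attr(x, "t"), "): ", sep = "")
  cat(paste(sprintf("%s=%.4f", STATE_NAMES, as.numeric(x)), collapse = " "),
      "\n")
  invisible(x)
}

#' One-step update of the state distribution
#'
#' Applies the linear difference-equation system once: the new distribution
#' is the left product of the current one with the transition matrix.  Total
#' mass is conserved exactly (the population has constant size).
#'
#' @param state a [state_vector].
#' @param params a [transition_params] object.
#' @return The [state_vector] at the next time step.
#' @export
step_state <- function(state, params) {
  stopifnot(inherits(state, "state_vector"))
  M <- make_matrix(params)
  v <- as.numeric(state) %*% unclass(M)
  structure(setNames(drop(v), STATE_NAMES), class = "state_vector",
            t = attr(state, "t") + 1L)
}

#' Simulate the system forward
#'
#' Iterates the one-step update `n_steps` times from a starting
#' distribution.
#'
#' @param state0 a [state_vector] (or numeric length-5 vector).
#' @param params a [transition_params] object.
#' @param n_steps number of annual steps (>= 0).
#' @return A `(n_steps + 1) x 5` matrix of class `crime_trajectory`; row i
#'   is the distribution at time i - 1.
#' @examples
#' p <- transition_params(0.07, 0.047, 0.625, 0.125, 0.188, 0.543,
#'                        0.276, 0.453, 0.126, 0.118, 0.247)
#' traj <- simulate_chain(state_vector(0.794, 0.097, 0.070, 0.016, 0.024),
#'                        p, 300)
#' traj[nrow(traj), ]  # long-run distribution
#' @export
simulate_chain <- function(state0, params, n_steps) {
  if (!inherits(state0, "state_vector")) state0 <- state_vector(state0)
  stopifnot(n_steps >= 0)
  M <- unclass(make_matrix(params))
  out <- matrix(NA_real_, n_steps + 1, 5,
                dimnames = list(NULL, STATE_NAMES))
  v <- as.numeric(state0)
  out[1, ] <- v
  if (n_steps > 0) for (i in seq_len(n_steps)) {
    v <- drop(v %*% M)
    out[i + 1, ] <- v
  }
  structure(out, class = c("crime_trajectory", "matrix"),
            t0 = attr(state0, "t"))
}

#' @export
print.crime_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat("trajectory over", n - 1, "steps\n")
  show <- unique(pmin(c(1, 2, 7, 11, 51, n), n))
  df <- data.frame(t = show - 1, round(unclass(x)[show, , drop = FALSE], 4))
  print(df, row.names = FALSE)
  invisible(x)
}

eq_result <- function(v, d, method, n_steps = NA_integer_, unique = TRUE) {
  sv <- state_vector(v)
  structure(list(state_star = sv,
                 x_star = as.numeric(sv[["X"]]),
                 crime_rate = 1 - as.numeric(sv[["X"]]),
                 denominator_d = d,
                 method = method,
                 n_steps_to_converge = n_steps,
                 unique = unique),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("long-run equilibrium (", x$method, ")\n", sep = "")
  print(x$state_star)
  cat(sprintf("X* = %.4f   crime rate 1 - X* = %.4f\n", x$x_star,
              x$crime_rate))
  if (!x$unique) cat("NOTE: stationary distribution is not unique;",
                     "reported value is the limit from a strictly positive start\n")
  invisible(x)
}

## Closed-form denominator D of the equilibrium expression.  Two symbols in
## the published display are typographical variants and enter here as
## alpha_r2 and beta_2r (verified against the stationary solve; see the
## methods vignette).
equilibrium_denominator <- function(p) {
  with(as.list(unclass(p)), {
    alpha_x1 * (epsilon_rx * gamma_1a * gamma_2a +
                epsilon_rx * gamma_2a * beta_ar +
                gamma_1a * gamma_2a * beta_ar +
                gamma_1a * gamma_2a * alpha_ra +
                epsilon_rx * gamma_1a * zeta_a2 +
                gamma_1a * alpha_ra * zeta_a2 +
                alpha_r2 * gamma_1a * (gamma_2a + beta_ar + zeta_a2) +
                beta_2r * (epsilon_rx * (gamma_1a + beta_ar + zeta_a2) +
                           gamma_1a * (beta_ar + alpha_ra + zeta_a2))) +
    (beta_1x + gamma_1a) *
      (epsilon_rx * (gamma_2a * (beta_ar + alpha_xa) + alpha_xa * zeta_a2) +
       alpha_xa * (gamma_2a * (beta_ar + alpha_ra) + alpha_ra * zeta_a2 +
                   alpha_r2 * (gamma_2a + beta_ar + zeta_a2)) +
       beta_2r * (epsilon_rx * (beta_ar + alpha_xa + zeta_a2) +
                  alpha_xa * (beta_ar + alpha_ra + zeta_a2)))
  })
}

#' Closed-form long-run equilibrium
#'
#' Evaluates the analytic expression for the equilibrium fraction X* of the
#' criminally inactive/rehabilitated state,
#' `X* = epsilon_rx (beta_1x + gamma_1a) (gamma_2a beta_ar +
#' beta_2r (beta_ar + zeta_a2)) / D`, and recovers the remaining four
#' components from the per-state balance relations at the fixed point.
#'
#' @param params a [transition_params] object.
#' @return An `equilibrium_result`: list with `state_star` (the stationary
#'   [state_vector]), `x_star`, `crime_rate = 1 - x_star`, the diagnostic
#'   `denominator_d` and method metadata.
#' @seealso [equilibrium_solve()] for the independent stationary solve.
#' @export
equilibrium_closed_form <- function(params) {
  stopifnot(inherits(params, "transition_params"))
  p <- as.list(unclass(params))
  D <- equilibrium_denominator(params)
  if (abs(D) < 1e-300)
    stop("degenerate equilibrium: closed-form denominator D is zero ",
         "(no effective flow out of the crime states)", call. = FALSE)
  num <- with(p, epsilon_rx * (beta_1x + gamma_1a) *
                (gamma_2a * beta_ar + beta_2r * (beta_ar + zeta_a2)))
  x_star <- num / D
  ## Balance relations at the fixed point, solved for the other components:
  ##   C1* (beta_1x + gamma_1a) = alpha_x1 X*
  ##   C2* (gamma_2a + beta_2r) = zeta_a2 A* + alpha_r2 R*
  ##   R*  (alpha_r2 + alpha_ra + epsilon_rx) = beta_ar A* + beta_2r C2*
  ##   A*  (zeta_a2 + beta_ar) = gamma_1a C1* + alpha_xa X* + alpha_ra R* + gamma_2a C2*
  ## Solve the linear 4x4 system in (C1, A, R, C2) given X*.
  A4 <- with(p, rbind(
    c(beta_1x + gamma_1a, 0, 0, 0),
    c(-gamma_1a, zeta_a2 + beta_ar, -alpha_ra, -gamma_2a),
    c(0, -beta_ar, alpha_r2 + alpha_ra + epsilon_rx, -beta_2r),
    c(0, -zeta_a2, -alpha_r2, gamma_2a + beta_2r)))
  b4 <- with(p, c(alpha_x1 * x_star, alpha_xa * x_star, 0, 0))
  rest <- tryCatch(solve(A4, b4), error = function(e) NULL)
  if (is.null(rest)) {
    ## singular balance system (boundary parameters): fall back on the
    ## stationary solve for the remaining components
    return(eq_result(as.numeric(equilibrium_solve(params)$state_star),
                     D, "closed-form"))
  }
  v <- c(x_star, rest[1], rest[2], rest[3], rest[4])
  eq_result(v, D, "closed-form")
}

#' Stationary-distribution solve
#'
#' Independent route to the long-run equilibrium: solves the left null
#' space of `M - I` for the row-stochastic transition matrix `M` (the
#' stationary distribution of the chain).  Serves as the oracle for
#' [equilibrium_closed_form()].  When the chain is reducible (boundary
#' parameters, e.g. the identity matrix) the stationary distribution is not
#' unique; the result is flagged and the limit from a strictly positive
#' uniform start is returned.
#'
#' @param params a [transition_params] object.
#' @param tol convergence tolerance for the reducible-case iteration.
#' @return An `equilibrium_result` (see [equilibrium_closed_form()]), with
#'   `unique = FALSE` and a warning when the stationary distribution is not
#'   unique.
#' @export
equilibrium_solve <- function(params, tol = 1e-14) {
  M <- unclass(make_matrix(params))
  ## multiplicity of eigenvalue 1 of t(M) = number of recurrent classes
  ev <- eigen(t(M), only.values = TRUE)$values
  n_unit <- sum(abs(ev - 1) < 1e-9)
  D <- equilibrium_denominator(params)
  if (n_unit > 1) {
    warning("stationary distribution is not unique (reducible chain); ",
            "returning the limit reached from a strictly positive start",
            call. = FALSE)
    v <- rep(1 / 5, 5)
    for (i in seq_len(100000L)) {
      v_new <- drop(v %*% M)
      if (sum(abs(v_new - v)) < tol) break
      v <- v_new
    }
    return(eq_result(v_new, D, "power-iteration", n_steps = i,
                     unique = FALSE))
  }
  A <- t(M) - diag(5)
  A[5, ] <- 1
  v <- solve(A, c(0, 0, 0, 0, 1))
  eq_result(v, D, "null-space")
}

#' Iterative equilibrium with the standard convergence protocol
#'
#' Runs the forward simulation until the L1 change per step falls below
#' `tol` or `max_steps` steps have been taken, whichever comes first
#' (default protocol: 300 steps).
#'
#' @param state0 starting [state_vector]; defaults to the uniform
#'   distribution.
#' @param params a [transition_params] object.
#' @param max_steps maximum number of steps (default 300).
#' @param tol L1 per-step convergence tolerance (default 1e-12).
#' @return An `equilibrium_result` with `n_steps_to_converge` filled in.
#' @export
equilibrium_iterate <- function(params, state0 = NULL, max_steps = 300L,
                                tol = 1e-12) {
  M <- unclass(make_matrix(params))
  v <- if (is.null(state0)) rep(1 / 5, 5) else
    as.numeric(state_vector(state0))
  n <- 0L
  for (i in seq_len(max_steps)) {
    v_new <- drop(v %*% M)
    delta <- sum(abs(v_new - v))
    v <- v_new
    n <- i
    if (delta < tol) break
  }
  eq_result(v, equilibrium_denominator(params), "iteration", n_steps = n)
}

#' Equilibrium fraction in state X
#'
#' Convenience accessor used throughout the sensitivity and disparity
#' analyses.
#'
#' @param params a [transition_params] object.
#' @return The closed-form equilibrium X* (a scalar in `[0, 1]`).
#' @export
x_star <- function(params) {
  equilibrium_closed_form(params)$x_star
}
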