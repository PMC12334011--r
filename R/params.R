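#' Transition parameters of the five-state model
#'
#' Constructs the set of 11 free per-year transition probabilities that,
#' together with the derived stay probabilities, define the row-stochastic
#' 5x5 transition structure over the states X (criminally inactive /
#' rehabilitated), C1 (active, never arrested), A (arrested in the last
#' year), R (inactive with recent arrest history) and C2 (active with past
#' arrest).  Stay probabilities are never supplied: each source state's stay
#' is the complement of its outflows.
#'
#' @param alpha_x1 X->C1, onset of offending without arrest.
#' @param alpha_xa X->A, onset with same-year arrest.
#' @param beta_1x C1->X, desistance before any arrest.
#' @param gamma_1a C1->A, first-time arrest of the active never-arrested.
#' @param zeta_a2 A->C2, continued offending after arrest, no re-arrest.
#' @param beta_ar A->R, desistance in the year after arrest.
#' @param gamma_2a C2->A, re-arrest of the active previously arrested.
#' @param beta_2r C2->R, desistance of the active previously arrested.
#' @param alpha_r2 R->C2, recidivism without arrest.
#' @param alpha_ra R->A, recidivism with same-year arrest.
#' @param epsilon_rx R->X, rehabilitation (three inactive years completed).
#' @param label optional character label (e.g. the subgroup).
#'
#' @return An object of class `transition_params`: a named numeric vector of
#'   the 11 free rates with the label as an attribute.
#' @examples
#' p <- transition_params(alpha_x1 = 0.07, alpha_xa = 0.026, beta_1x = 0.582,
#'                        gamma_1a = 0.096, zeta_a2 = 0.221, beta_ar = 0.508,
#'                        gamma_2a = 0.2, beta_2r = 0.455, alpha_r2 = 0.127,
#'                        alpha_ra = 0.108, epsilon_rx = 0.288)
#' stay_probs(p)
#' @export
transition_params <- function(alpha_x1, alpha_xa, beta_1x, gamma_1a,
                              zeta_a2, beta_ar, gamma_2a, beta_2r,
                              alpha_r2, alpha_ra, epsilon_rx, label = NULL) {
  p <- c(alpha_x1 = alpha_x1, alpha_xa = alpha_xa, beta_1x = beta_1x,
         gamma_1a = gamma_1a, zeta_a2 = zeta_a2, beta_ar = beta_ar,
         gamma_2a = gamma_2a, beta_2r = beta_2r, alpha_r2 = alpha_r2,
         alpha_ra = alpha_ra, epsilon_rx = epsilon_rx)
  validate_params(p)
  structure(p, class = "transition_params", label = label)
}

validate_params <- function(p) {
  if (anyNA(p)) stop("transition parameters contain NA", call. = FALSE)
  bad <- names(p)[p < 0 | p > 1]
  if (length(bad))
    stop("transition parameter(s) outside [0, 1]: ",
         paste(bad, collapse = ", "), call. = FALSE)
  s <- stay_probs_raw(p)
  neg <- names(s)[s < -1e-12]
  if (length(neg))
    stop("outflows exceed 1 for source state(s): ",
         paste(neg, collapse = ", "),
         " (derived stay probability would be negative)", call. = FALSE)
  invisible(p)
}

stay_probs_raw <- function(p) {
  c(X  = 1 - p[["alpha_x1"]] - p[["alpha_xa"]],
    C1 = 1 - p[["beta_1x"]] - p[["gamma_1a"]],
    A  = 1 - p[["zeta_a2"]] - p[["beta_ar"]],
    C2 = 1 - p[["gamma_2a"]] - p[["beta_2r"]],
    R  = 1 - p[["alpha_r2"]] - p[["alpha_ra"]] - p[["epsilon_rx"]])
}

#' Derived stay probabilities
#'
#' The complement probability of remaining in each source state for one
#' year (sigma_xx, sigma_11, sigma_aa, sigma_22, sigma_rr).
#'
#' @param params a [transition_params] object.
#' @return Named numeric vector over the states X, C1, A, C2, R.
#' @export
stay_probs <- function(params) {
  stopifnot(inherits(params, "transition_params"))
  pmax(stay_probs_raw(params), 0)
}

#' @export
print.transition_params <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Five-state transition parameters",
      if (!is.null(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  df <- data.frame(arrow = unname(PARAM_ARROWS[names(unclass(x))]),
                   value = round(as.numeric(x), 4))
  print(df, row.names = FALSE)
  s <- stay_probs(x)
  cat("stay probabilities:",
      paste(sprintf("%s=%.4f", names(s), s), collapse = " "), "\n")
  invisible(x)
}

#' Build the row-stochastic 5x5 transition matrix
#'
#' Rows are source states, columns destination states, in the fixed order
#' (X, C1, A, R, C2).  Structural zeros (transitions impossible by the
#' state definitions, e.g. X cannot reach C2 in one step because C2 requires
#' a prior arrest) are exactly zero.
#'
#' @param params a [transition_params] object.
#' @return A 5x5 numeric matrix of class `transition_matrix`; each row sums
#'   to 1.
#' @export
make_matrix <- function(params) {
  stopifnot(inherits(params, "transition_params"))
  validate_params(unclass(params))
  p <- as.list(unclass(params))
  s <- stay_probs(params)
  M <- rbind(
    X  = c(s[["X"]],  p$alpha_x1, p$alpha_xa, 0,           0),
    C1 = c(p$beta_1x, s[["C1"]],  p$gamma_1a, 0,           0),
    A  = c(0,         0,          s[["A"]],   p$beta_ar,   p$zeta_a2),
    R  = c(p$epsilon_rx, 0,       p$alpha_ra, s[["R"]],    p$alpha_r2),
    C2 = c(0,         0,          p$gamma_2a, p$beta_2r,   s[["C2"]])
  )
  colnames(M) <- STATE_NAMES
  structure(M, class = c("transition_matrix", "matrix"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("5x5 transition matrix (rows: source, columns: destination)\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Convert a full transition matrix back to free parameters
#'
#' Inverse of [make_matrix()]: reads the 11 off-diagonal admissible cells.
#' Structural-zero cells must be (numerically) zero.
#'
#' @param M a 5x5 row-stochastic matrix with rows/columns in the order
#'   X, C1, A, R, C2.
#' @param label optional label passed to [transition_params()].
#' @param renormalize if `TRUE`, each row is divided by its sum first; a
#'   warning is emitted for any row whose raw sum deviates from 1 by more
#'   than `tol` (printed tables are rounded and may not sum to 1).
#' @param tol deviation that triggers the renormalization warning.
#' @return A [transition_params] object.
#' @export
params_from_matrix <- function(M, label = NULL, renormalize = TRUE,
                               tol = 0.02) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == 5, ncol(M) == 5)
  dimnames(M) <- list(STATE_NAMES, STATE_NAMES)
  rs <- rowSums(M)
  if (renormalize) {
    off <- abs(rs - 1) > tol
    if (any(off))
      warning("row sum(s) deviate from 1 by more than ", tol, " for state(s) ",
              paste(STATE_NAMES[off], collapse = ", "),
              " (raw sums: ", paste(round(rs[off], 3), collapse = ", "),
              "); rows renormalized", call. = FALSE)
    M <- M / rs
  }
  zero_cells <- rbind(c("X", "R"), c("X", "C2"), c("C1", "R"), c("C1", "C2"),
                      c("A", "X"), c("A", "C1"), c("C2", "X"), c("C2", "C1"),
                      c("R", "C1"))
  nz <- abs(M[zero_cells]) > 1e-9
  if (any(nz))
    stop("matrix has nonzero entries in structurally zero cells: ",
         paste(apply(zero_cells[nz, , drop = FALSE], 1, paste, collapse = "->"),
               collapse = ", "), call. = FALSE)
  transition_params(
    alpha_x1 = M["X", "C1"],  alpha_xa = M["X", "A"],
    beta_1x  = M["C1", "X"],  gamma_1a = M["C1", "A"],
    zeta_a2  = M["A", "C2"],  beta_ar  = M["A", "R"],
    gamma_2a = M["C2", "A"],  beta_2r  = M["C2", "R"],
    alpha_r2 = M["R", "C2"],  alpha_ra = M["R", "A"],
    epsilon_rx = M["R", "X"], label = label)
}

#' Replace one free parameter, absorbing the change in the stay probability
#'
#' The perturbation convention for all sensitivity and disparity analyses:
#' changing one free rate leaves the other 10 untouched and is absorbed
#' entirely by the same source state's stay probability.
#'
#' @param params a [transition_params] object.
#' @param name parameter identifier (canonical name like `"alpha_xa"` or
#'   arrow label like `"X->A"`).
#' @param value new value for that parameter.
#' @return A new [transition_params] object.
#' @export
set_param <- function(params, name, value) {
  nm <- resolve_param(name)
  p <- unclass(params)
  p[[nm]] <- value
  if (value < 0 || value > 1)
    stop("value for ", PARAM_ARROWS[[nm]], " outside [0, 1]", call. = FALSE)
  s <- stay_probs_raw(p)
  src <- PARAM_SOURCE[[nm]]
  if (s[[src]] < -1e-12)
    stop("setting ", PARAM_ARROWS[[nm]], " = ", value,
         " makes outflows from state ", src, " exceed 1", call. = FALSE)
  structure(p, class = "transition_params", label = attr(params, "label"))
}

## Largest admissible value for one parameter given the others (source
## state's stay probability absorbs the change down to zero).
param_upper <- function(params, name) {
  nm <- resolve_param(name)
  min(1, unclass(params)[[nm]] + stay_probs(params)[[PARAM_SOURCE[[nm]]]])
}

## TRUE when all free parameters are strictly interior and all stays > 0.
params_interior <- function(params, eps = 1e-10) {
  p <- unclass(params)
  all(p > eps) && all(p < 1 - eps) && all(stay_probs_raw(p) > eps)
}
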