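## Between-group disparity decomposition: how gaps in single transition
## rates translate into gaps in the long-run equilibrium, via one-at-a-time
## counterfactual substitutions.

#' Per-parameter gap table between two groups
#'
#' Absolute differences are `A - B` per parameter.  The relative-difference
#' convention is `(A - B) / B` by default (`relative = "a_vs_b"`, i.e.
#' group A's excess relative to group B); the reversed quotient
#' `(B - A) / A` is available as `relative = "b_vs_a"`.
#'
#' @param params_a,params_b [transition_params] for the two groups
#'   (conventionally A = Black men, B = White men).
#' @param relative which relative-difference quotient to report.
#' @return A data.frame of class `gap_table` with one row per parameter:
#'   `value_a`, `value_b`, `abs_diff`, `rel_diff` (NA when the reference
#'   value is 0), and logical flags `max_abs`, `max_rel` on the
#'   largest-magnitude entries.  Group equilibria and the equilibrium gap
#'   are attached as attributes.
#' @export
gap_table <- function(params_a, params_b,
                      relative = c("a_vs_b", "b_vs_a")) {
  relative <- match.arg(relative)
  pa <- unclass(params_a); pb <- unclass(params_b)
  nms <- names(PARAM_ARROWS)
  abs_diff <- as.numeric(pa[nms] - pb[nms])
  ref <- if (relative == "a_vs_b") as.numeric(pb[nms]) else as.numeric(pa[nms])
  num <- if (relative == "a_vs_b") abs_diff else -abs_diff
  rel_diff <- ifelse(ref > 0, num / ref, NA_real_)
  df <- data.frame(parameter = nms, arrow = unname(PARAM_ARROWS),
                   value_a = as.numeric(pa[nms]),
                   value_b = as.numeric(pb[nms]),
                   abs_diff = abs_diff, rel_diff = rel_diff,
                   row.names = NULL)
  df$max_abs <- abs(df$abs_diff) == max(abs(df$abs_diff))
  df$max_rel <- !is.na(df$rel_diff) &
    abs(df$rel_diff) == max(abs(df$rel_diff), na.rm = TRUE)
  xa <- x_star(params_a); xb <- x_star(params_b)
  structure(df, class = c("gap_table", "data.frame"),
            x_star_a = xa, x_star_b = xb, x_star_gap = xa - xb,
            relative_convention = relative)
}

## Equilibrium X* gap helper: gap = x_star(A) - x_star(B).
## The complementary crime-rate gap is identical in absolute value.
equilibrium_gap <- function(params_a, params_b) {
  x_star(params_a) - x_star(params_b)
}

#' Single-parameter equalization
#'
#' Counterfactual: set one group's named parameter to the other group's
#' value (stay probability absorbing the change) and recompute both
#' equilibria.  Both substitution directions are reported.
#'
#' @param params_a,params_b [transition_params] for the two groups.
#' @param name parameter identifier.
#' @return List with `baseline_gap` (x_star A - x_star B), `gap_a_to_b`
#'   (gap after A adopts B's value), `gap_b_to_a` (after B adopts A's),
#'   and the percent reduction in the absolute gap for each direction.
#' @export
equalize_one <- function(params_a, params_b, name) {
  nm <- resolve_param(name)
  g0 <- equilibrium_gap(params_a, params_b)
  a_sub <- set_param(params_a, nm, unclass(params_b)[[nm]])
  b_sub <- set_param(params_b, nm, unclass(params_a)[[nm]])
  g_ab <- equilibrium_gap(a_sub, params_b)
  g_ba <- equilibrium_gap(params_a, b_sub)
  pct <- function(g) if (abs(g0) > 0) 100 * (abs(g0) - abs(g)) / abs(g0)
                     else 0
  list(parameter = PARAM_ARROWS[[nm]], baseline_gap = g0,
       gap_a_to_b = g_ab, gap_b_to_a = g_ba,
       pct_reduction_a_to_b = pct(g_ab), pct_reduction_b_to_a = pct(g_ba))
}

#' Gap-reduction elasticity
#'
#' Moves group A's named parameter toward group B's value by
#' `fraction * (A - B)`, recomputes both equilibria, and returns the
#' percent reduction in the absolute equilibrium X* gap relative to
#' baseline.  `fraction = 1` reproduces [equalize_one()] (direction A to
#' B).
#'
#' @param params_a,params_b [transition_params] for the two groups.
#' @param name parameter identifier.
#' @param fraction fraction of the parameter gap to close, in `(0, 1]`.
#' @return Percent reduction in `|x_star(A) - x_star(B)|`.
#' @export
gap_reduction_elasticity <- function(params_a, params_b, name,
                                     fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  nm <- resolve_param(name)
  g0 <- equilibrium_gap(params_a, params_b)
  va <- unclass(params_a)[[nm]]; vb <- unclass(params_b)[[nm]]
  a_new <- set_param(params_a, nm, va - fraction * (va - vb))
  g1 <- equilibrium_gap(a_new, params_b)
  if (abs(g0) == 0) return(0)
  100 * (abs(g0) - abs(g1)) / abs(g0)
}

#' Full disparity report
#'
#' Combines the gap table, both-direction single-parameter equalizations
#' and the gap-reduction elasticity at a given fraction into one table.
#'
#' @param params_a,params_b [transition_params] for the two groups.
#' @param fraction fraction of the gap used for the elasticity column.
#' @param relative relative-difference convention, see [gap_table()].
#' @return A data.frame of class `disparity_report` with one row per
#'   parameter and attributes `x_star_a`, `x_star_b`, `x_star_gap`,
#'   `crime_rate_gap`.
#' @export
disparity_report <- function(params_a, params_b, fraction = 0.01,
                             relative = "a_vs_b") {
  gt <- gap_table(params_a, params_b, relative = relative)
  eq <- lapply(gt$parameter, function(n) equalize_one(params_a, params_b, n))
  gt$gap_after_a_to_b <- vapply(eq, `[[`, 0, "gap_a_to_b")
  gt$gap_after_b_to_a <- vapply(eq, `[[`, 0, "gap_b_to_a")
  gt$pct_reduction_equalize <- vapply(eq, `[[`, 0, "pct_reduction_a_to_b")
  gt$pct_reduction_fraction <- vapply(gt$parameter, function(n)
    gap_reduction_elasticity(params_a, params_b, n, fraction), 0)
  class(gt) <- c("disparity_report", class(gt))
  attr(gt, "fraction") <- fraction
  attr(gt, "crime_rate_gap") <- -attr(gt, "x_star_gap")
  gt
}

#' @export
print.disparity_report <- function(x, ...) {
  cat(sprintf("equilibrium X*: group A %.4f, group B %.4f, gap %+.4f\n",
              attr(x, "x_star_a"), attr(x, "x_star_b"),
              attr(x, "x_star_gap")))
  cat(sprintf("(crime-rate gap is the same magnitude, opposite sign: %+.4f)\n",
              attr(x, "crime_rate_gap")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
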