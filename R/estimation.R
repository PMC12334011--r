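## Random-intercept logistic regression for wave-to-wave transition
## outcomes, fit by maximizing the marginal likelihood with adaptive
## Gauss-Hermite quadrature over a scalar person-level intercept.
## Implemented directly (rather than via a mixed-model package) so that a
## single fit stays within seconds at panel scale; cross-checked against
## lme4::glmer in the test suite.

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for `int f(x) exp(-x^2) dx`, via the Golub-Welsch
#' eigenvalue construction.
#'
#' @param n number of nodes.
#' @return List with `nodes` and `weights` (both length `n`).
#' @export
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (sqrt(pi) * e$vectors[1, ]^2)[ord])
}

## Marginal log-likelihood and score of the random-intercept logit.
## X: model matrix; y: 0/1; id: integer person index 1..n (rows grouped or
## not); nq: quadrature nodes.  theta = c(beta, sigma).
## Returns an evaluator environment with fn(theta) and gr(theta) sharing
## one computation (warm-started inner Newton for the per-person modes).
ri_logit_objective <- function(X, y, id, nq = 21) {
  gh <- gauss_hermite(nq)
  z <- gh$nodes
  lw <- log(gh$weights)
  id <- match(id, unique(id))
  n <- max(id)
  sy <- rowsum(y, id)[, 1]
  u_warm <- numeric(n)
  last <- new.env(parent = emptyenv())
  last$theta <- NULL

  evaluate <- function(theta) {
    beta <- theta[-length(theta)]
    sigma <- theta[length(theta)]
    eta <- drop(X %*% beta)
    if (sigma < 1e-8) {
      p <- plogis(eta)
      ll <- sum(y * eta - log1p(exp(eta)))
      gr_beta <- drop(crossprod(X, y - p))
      ## score in sigma at the boundary is 0 to first order
      return(list(value = -ll, grad = -c(gr_beta, 0)))
    }
    ## per-person Newton for the mode of
    ##   h_i(u) = sum_j [y eta + u - log(1 + e^(eta+u))] - u^2 / (2 sigma^2)
    u <- u_warm
    for (it in 1:25) {
      p <- plogis(eta + u[id])
      g <- sy - rowsum(p, id)[, 1] - u / sigma^2
      H <- -rowsum(p * (1 - p), id)[, 1] - 1 / sigma^2
      step <- g / H
      u <- u - step
      if (max(abs(step)) < 1e-10) break
    }
    u_warm <<- u
    p <- plogis(eta + u[id])
    tau <- 1 / sqrt(rowsum(p * (1 - p), id)[, 1] + 1 / sigma^2)
    ## log-integrand at adaptive nodes u_ik = u_i + sqrt(2) tau_i z_k
    M <- matrix(0, n, nq)
    gb_acc <- numeric(length(y))   # posterior-mean residual per observation
    s_acc <- matrix(0, n, nq)      # u_ik^2 terms for the sigma score
    P <- matrix(0, length(y), nq)
    U <- matrix(0, n, nq)
    for (k in seq_len(nq)) {
      uk <- u + sqrt(2) * tau * z[k]
      U[, k] <- uk
      etak <- eta + uk[id]
      P[, k] <- plogis(etak)
      lik <- rowsum(y * etak - log1p(exp(etak)), id)[, 1]
      M[, k] <- lw[k] + z[k]^2 + lik +
        dnorm(uk, 0, sigma, log = TRUE) + 0.5 * log(2) + log(tau)
    }
    m <- apply(M, 1, max)
    lse <- m + log(rowSums(exp(M - m)))
    W <- exp(M - lse)              # posterior node weights, rows sum to 1
    ## score via the Fisher identity under the posterior:
    ##   d/dbeta  = X' (y - E_post p)
    ##   d/dsigma = E_post[u^2] / sigma^3 - 1 / sigma
    p_bar <- rowSums(P * W[id, , drop = FALSE])
    gr_beta <- drop(crossprod(X, y - p_bar))
    Eu2 <- rowSums(U^2 * W)
    gr_sigma <- sum(Eu2 / sigma^3 - 1 / sigma)
    list(value = -sum(lse), grad = -c(gr_beta, gr_sigma))
  }

  fn <- function(theta) {
    res <- evaluate(theta)
    last$theta <- theta; last$grad <- res$grad
    res$value
  }
  gr <- function(theta) {
    if (!is.null(last$theta) && isTRUE(all.equal(theta, last$theta)))
      return(last$grad)
    evaluate(theta)$grad
  }
  list(fn = fn, gr = gr)
}

#' Fit a random-intercept logistic regression
#'
#' Core engine: maximizes the marginal likelihood of a logit model with a
#' person-level Normal(0, sigma_u^2) random intercept, integrating by
#' adaptive Gauss-Hermite quadrature (default 21 nodes).  With
#' `random_intercept = FALSE`, or when no person has repeated
#' observations (sigma_u unidentified), the fit reduces to ordinary
#' logistic regression.
#'
#' @param y 0/1 outcome vector.
#' @param X model matrix (including the intercept column).
#' @param id person identifier, one per row of `X`.
#' @param random_intercept include the random intercept?
#' @param nq number of quadrature nodes.
#' @param start optional starting values `c(beta, sigma)`.
#' @return An object of class `ri_logit`: list with `coefficients`,
#'   `sigma_u`, `se` (coefficient standard errors), `se_sigma_u`, `vcov`
#'   (of `c(beta, sigma_u)`), `loglik`, `n_obs`, `n_persons`,
#'   `convergence` flag and `flags` (quasi-separation etc.).
#' @export
ri_logit <- function(y, X, id, random_intercept = TRUE, nq = 21,
                     start = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), length(id) == nrow(X),
            all(y %in% c(0, 1)))
  cluster_sizes <- table(id)
  flags <- character()
  if (random_intercept && max(cluster_sizes) < 2) {
    warning("no person has repeated observations: sigma_u is unidentified; ",
            "returning the sigma_u -> 0 logistic solution", call. = FALSE)
    random_intercept <- FALSE
    flags <- c(flags, "sigma_u_unidentified")
  }
  g0 <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta0 <- coef(g0)
  if (anyNA(beta0))
    stop("model matrix is rank-deficient; drop collinear covariates",
         call. = FALSE)

  if (!random_intercept) {
    eta <- drop(X %*% beta0)
    p <- plogis(eta)
    Vinv <- crossprod(X, X * (p * (1 - p)))
    V <- solve(Vinv)
    fit <- list(coefficients = setNames(beta0, colnames(X)),
                sigma_u = 0, se = sqrt(diag(V)), se_sigma_u = NA_real_,
                vcov = V, loglik = sum(y * eta - log1p(exp(eta))),
                n_obs = length(y), n_persons = length(cluster_sizes),
                nq = nq, convergence = 0L, flags = flags)
  } else {
    obj <- ri_logit_objective(X, y, id, nq = nq)
    th0 <- if (is.null(start)) c(beta0, 0.5) else start
    k <- length(th0)
    opt <- optim(th0, obj$fn, obj$gr, method = "L-BFGS-B",
                 lower = c(rep(-Inf, k - 1), 1e-4),
                 upper = c(rep(Inf, k - 1), 25),
                 control = list(maxit = 500, factr = 1e7))
    if (opt$convergence != 0)
      warning("random-intercept logit did not converge (code ",
              opt$convergence, "): ", opt$message, call. = FALSE)
    H <- num_jacobian(obj$gr, opt$par)
    H <- (H + t(H)) / 2
    V <- tryCatch(solve(H), error = function(e) {
      flags <<- c(flags, "singular_hessian")
      matrix(NA_real_, k, k)
    })
    se <- sqrt(pmax(diag(V), 0))
    fit <- list(coefficients = setNames(opt$par[-k], colnames(X)),
                sigma_u = unname(opt$par[k]), se = unname(se[-k]),
                se_sigma_u = unname(se[k]),
                vcov = V, loglik = -opt$value,
                n_obs = length(y), n_persons = length(cluster_sizes),
                nq = nq, convergence = opt$convergence, flags = flags)
  }
  if (any(abs(fit$coefficients) > 15) ||
      any(is.finite(fit$se) & fit$se > 100)) {
    fit$flags <- c(fit$flags, "quasi_separation")
    warning("possible quasi-separation: extreme coefficient(s) or ",
            "standard error(s); interpret with caution", call. = FALSE)
  }
  class(fit) <- "ri_logit"
  fit
}

## central-difference Jacobian of a gradient function (Hessian of the
## objective when g is its gradient)
num_jacobian <- function(g, x, h = 1e-5) {
  k <- length(x)
  J <- matrix(0, k, k)
  for (j in seq_len(k)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    J[, j] <- (g(xp) - g(xm)) / (2 * hj)
  }
  J
}

#' @export
print.ri_logit <- function(x, ...) {
  cat("random-intercept logistic regression (adaptive GH, ", x$nq,
      " nodes)\n", sep = "")
  print(data.frame(estimate = round(x$coefficients, 4),
                   se = round(x$se, 4)))
  cat(sprintf("sigma_u = %.4f (se %.4f)   loglik = %.2f   n_obs = %d   n_persons = %d\n",
              x$sigma_u, x$se_sigma_u, x$loglik, x$n_obs, x$n_persons))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

## Standard covariate coding: age centered at 16 (linear + quadratic),
## woman/Black/Hispanic dummies with White men as reference, sex-by-race
## interactions.
transition_model_matrix <- function(age, sex, race) {
  woman <- as.numeric(sex == "woman")
  black <- as.numeric(race == "Black")
  hispanic <- as.numeric(race == "Hispanic")
  a <- age - 16
  cbind("(Intercept)" = 1, "age_c" = a, "age_c2" = a^2, "woman" = woman,
        "black" = black, "hispanic" = hispanic,
        "woman:black" = woman * black, "woman:hispanic" = woman * hispanic)
}

#' Fit the transition regression for one arrow
#'
#' Restricts the transition records to the origin state's risk set, codes
#' the binary outcome "made this transition", and fits the
#' random-intercept logit with the standard covariate specification:
#' quadratic in (age - 16), woman, Black, Hispanic, and sex-by-race
#' interactions (White men as reference).
#'
#' @param transitions data.frame from [build_transitions()], carrying
#'   `age`, `sex`, `race`.
#' @param outcome arrow label, e.g. `"X->A"`.
#' @param random_intercept,nq passed to [ri_logit()].
#' @return An `ri_logit` fit with the outcome label and risk-set origin
#'   attached.
#' @export
fit_transition_logit <- function(transitions, outcome,
                                 random_intercept = TRUE, nq = 21) {
  if (!outcome %in% admissible_arrows())
    stop("'", outcome, "' is not an admissible arrow", call. = FALSE)
  need <- c("age", "sex", "race")
  miss <- setdiff(need, names(transitions))
  if (length(miss))
    stop("transitions lack covariate column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  origin <- sub("->.*", "", outcome)
  rs <- transitions[transitions$from_state == origin, , drop = FALSE]
  rs <- rs[complete.cases(rs[need]), , drop = FALSE]
  y <- as.numeric(rs$transition == outcome)
  if (sum(y) < 2 || length(unique(rs$person_id[y == 1])) < 2)
    stop("outcome ", outcome, " observed for fewer than 2 persons",
         call. = FALSE)
  X <- transition_model_matrix(rs$age, rs$sex, rs$race)
  fit <- ri_logit(y, X, rs$person_id, random_intercept = random_intercept,
                  nq = nq)
  fit$outcome <- outcome
  fit$origin <- origin
  fit
}

#' Predicted transition probability for a covariate profile
#'
#' With `integrate_random_effect = FALSE` returns the inverse logit of the
#' linear predictor at u = 0 (the median person).  With integration on,
#' returns the population-averaged probability
#' `int plogis(eta + u) dNormal(u; 0, sigma_u^2)` by Gauss-Hermite
#' quadrature, which shrinks predictions toward 0.5 relative to the
#' conditional version.
#'
#' @param fit an `ri_logit` from [fit_transition_logit()].
#' @param age age (or vector of ages) in years.
#' @param sex `"man"` or `"woman"`.
#' @param race `"Black"`, `"White"` or `"Hispanic"`.
#' @param integrate_random_effect marginalize over the random intercept?
#' @param nq quadrature nodes for the marginalization.
#' @return Probability (vector over `age`).
#' @export
predict_probability <- function(fit, age, sex, race,
                                integrate_random_effect = TRUE, nq = 21) {
  X <- transition_model_matrix(age, sex, race)
  eta <- drop(X %*% fit$coefficients)
  marginal_prob(eta, if (integrate_random_effect) fit$sigma_u else 0, nq)
}

marginal_prob <- function(eta, sigma, nq = 21) {
  if (sigma <= 0) return(plogis(eta))
  gh <- gauss_hermite(nq)
  w <- gh$weights / sqrt(pi)
  sapply(eta, function(e) sum(w * plogis(e + sqrt(2) * sigma * gh$nodes)))
}

#' Subgroup-averaged predicted probabilities for all transitions
#'
#' For each sex-by-race subgroup, averages the predicted probability of
#' each modeled arrow over the subgroup's observed age distribution, and
#' derives the five stay probabilities by complement within each origin
#' state.  Intervals come from a parametric bootstrap of the coefficient
#' sampling distribution (default) or the delta method.
#'
#' @param fits named list of `ri_logit` fits, names being the 11 non-stay
#'   arrows.
#' @param panel person-wave data.frame with `age`, `sex`, `race` (the
#'   empirical age mix per subgroup).
#' @param ci `"bootstrap"` (parametric, `n_boot` coefficient draws) or
#'   `"delta"`.
#' @param n_boot bootstrap draws.
#' @param level interval level.
#' @param integrate_random_effect marginalize predictions over the random
#'   intercept?
#' @param seed seed for the bootstrap draws.
#' @return data.frame with columns `subgroup`, `sex`, `race`, `transition`,
#'   `estimate`, `lower`, `upper`, `derived_stay`.
#' @export
subgroup_table <- function(fits, panel, ci = c("bootstrap", "delta"),
                           n_boot = 1000, level = 0.95,
                           integrate_random_effect = TRUE, seed = 1L) {
  ci <- match.arg(ci)
  stopifnot(all(names(fits) %in% PARAM_ARROWS))
  if (!all(PARAM_ARROWS %in% names(fits)))
    stop("fits must cover all 11 modeled arrows; missing: ",
         paste(setdiff(PARAM_ARROWS, names(fits)), collapse = ", "),
         call. = FALSE)
  cells <- unique(panel[c("sex", "race")])
  cells <- cells[order(cells$sex, cells$race), , drop = FALSE]
  alpha <- (1 - level) / 2
  out <- list()
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  for (ic in seq_len(nrow(cells))) {
    sx <- cells$sex[ic]; rc <- cells$race[ic]
    ages <- panel$age[panel$sex == sx & panel$race == rc]
    ages <- ages[!is.na(ages)]
    if (!length(ages)) {
      warning("empty subgroup cell ", sx, " x ", rc, " omitted",
              call. = FALSE)
      next
    }
    sub <- paste(rc, ifelse(sx == "man", "men", "women"))
    draws <- matrix(NA_real_, n_boot, length(PARAM_ARROWS),
                    dimnames = list(NULL, unname(PARAM_ARROWS)))
    est <- setNames(numeric(length(PARAM_ARROWS)), unname(PARAM_ARROWS))
    lo <- est; hi <- est
    for (arrow in unname(PARAM_ARROWS)) {
      fit <- fits[[arrow]]
      sig <- if (integrate_random_effect) fit$sigma_u else 0
      X <- transition_model_matrix(ages, sx, rc)
      eta <- drop(X %*% fit$coefficients)
      est[arrow] <- mean(marginal_prob(eta, sig))
      k <- length(fit$coefficients)
      Vb <- fit$vcov[seq_len(k), seq_len(k), drop = FALSE]
      if (ci == "bootstrap" && all(is.finite(Vb))) {
        L <- tryCatch(chol(Vb), error = function(e) NULL)
        if (!is.null(L)) {
          B <- matrix(rnorm(n_boot * k), n_boot, k) %*% L
          B <- sweep(B, 2, fit$coefficients, "+")
          pb <- apply(B, 1, function(b)
            mean(marginal_prob(drop(X %*% b), sig)))
          draws[, arrow] <- pb
          lo[arrow] <- quantile(pb, alpha)
          hi[arrow] <- quantile(pb, 1 - alpha)
        }
      }
      if (!is.finite(lo[arrow]) || ci == "delta") {
        ## delta method on the averaged probability
        grad <- crossprod(X, marginal_dprob(eta, sig)) / length(ages)
        se <- sqrt(drop(t(grad) %*% Vb %*% grad))
        lo[arrow] <- max(0, est[arrow] - qnorm(1 - alpha) * se)
        hi[arrow] <- min(1, est[arrow] + qnorm(1 - alpha) * se)
        draws[, arrow] <- rnorm(n_boot, est[arrow], se)
      }
    }
    res <- data.frame(subgroup = sub, sex = sx, race = rc,
                      transition = names(est), estimate = unname(est),
                      lower = unname(lo), upper = unname(hi),
                      derived_stay = FALSE, row.names = NULL)
    ## derived stays by complement within origin state
    for (s in STATE_NAMES) {
      arrows_s <- PARAM_ARROWS[PARAM_SOURCE == s]
      stay <- 1 - sum(est[unname(arrows_s)])
      sd_draws <- 1 - rowSums(draws[, unname(arrows_s), drop = FALSE])
      res <- rbind(res, data.frame(
        subgroup = sub, sex = sx, race = rc,
        transition = paste0(s, "->", s), estimate = stay,
        lower = quantile(sd_draws, alpha, names = FALSE),
        upper = quantile(sd_draws, 1 - alpha, names = FALSE),
        derived_stay = TRUE))
    }
    out[[length(out) + 1]] <- res
  }
  do.call(rbind, out)
}

## derivative of the marginalized probability wrt eta
marginal_dprob <- function(eta, sigma, nq = 21) {
  if (sigma <= 0) { p <- plogis(eta); return(p * (1 - p)) }
  gh <- gauss_hermite(nq)
  w <- gh$weights / sqrt(pi)
  sapply(eta, function(e) {
    p <- plogis(e + sqrt(2) * sigma * gh$nodes)
    sum(w * p * (1 - p))
  })
}

#' Convert a subgroup prediction table to transition parameters
#'
#' Extracts the 11 modeled arrow estimates for one subgroup as a
#' [transition_params] object (stays are re-derived as complements).
#'
#' @param table output of [subgroup_table()].
#' @param subgroup subgroup label, e.g. `"Black men"`.
#' @return A [transition_params] object.
#' @export
params_from_subgroup_table <- function(table, subgroup) {
  tb <- table[table$subgroup == subgroup & !table$derived_stay, ]
  if (nrow(tb) != 11)
    stop("subgroup '", subgroup, "' not found or incomplete", call. = FALSE)
  v <- setNames(tb$estimate, tb$transition)
  do.call(transition_params,
          c(as.list(setNames(v[unname(PARAM_ARROWS)],
                             names(PARAM_ARROWS))),
            list(label = subgroup)))
}
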