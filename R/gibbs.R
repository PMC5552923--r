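#' Conditional draw of the fixed effects
#'
#' Samples `beta | u_f, u_m, sigma2_e` from its full conditional
#' `N(P^{-1} h, P^{-1})` with `P = X'X / sigma2_e + B0^{-1}` and
#' `h = X'(y - Z_f u_f - Z_m u_m) / sigma2_e + B0^{-1} b0` — the standard
#' conjugate Gaussian regression update. Exposed mainly for testing the
#' sampler against closed forms; [run_chain()] performs the same algebra
#' in compiled code.
#'
#' @param state List with elements `u_f`, `u_m`, `sigma2_e` (current values).
#' @param design A [build_design()] result.
#' @param prior A [build_prior()] result.
#' @param n Number of independent draws.
#' @return An `n x p` matrix of draws (named columns).
#' @export
cond_beta <- function(state, design, prior, n = 1) {
  X <- design$X
  s2e <- state$sigma2_e
  B0_inv <- stable_inverse(prior$B0)
  P <- crossprod(X) / s2e + B0_inv
  resid <- design$y - design$Z_f %*% state$u_f - design$Z_m %*% state$u_m
  h <- crossprod(X, resid) / s2e + B0_inv %*% prior$b0
  draw_mvn_canonical_r(P, h, n, colnames(X))
}

#' Conditional draw of one parental random effect
#'
#' Samples `u_role | beta, u_other, variances` from
#' `N(P^{-1} h, P^{-1})` with `P = Z'Z / sigma2_e + A^{-1} / sigma2_role`
#' and `h = Z' r / sigma2_e`, where `r` is the partial residual with the
#' fixed effects and the other parental effect removed. Taxa never
#' observed in the role are still drawn, propagated through `A`.
#'
#' @param state List with `beta`, `u_f`, `u_m`, `sigma2_f`, `sigma2_m`,
#'   `sigma2_e`.
#' @param role `"maternal"` or `"paternal"`.
#' @param design A [build_design()] result.
#' @param A_inv [stable_inverse()] of the role's relatedness sub-matrix.
#' @param n Number of independent draws.
#' @return An `n x q` matrix of draws (taxa as columns).
#' @export
cond_u <- function(state, role = c("maternal", "paternal"), design, A_inv,
                   n = 1) {
  role <- match.arg(role)
  Z <- if (role == "maternal") design$Z_f else design$Z_m
  s2_role <- if (role == "maternal") state$sigma2_f else state$sigma2_m
  if (s2_role <= 1e-12) s2_role <- 1e-12
  other <- if (role == "maternal") design$Z_m %*% state$u_m
           else design$Z_f %*% state$u_f
  resid <- design$y - design$X %*% state$beta - other
  P <- crossprod(Z) / state$sigma2_e + A_inv / s2_role
  h <- crossprod(Z, resid) / state$sigma2_e
  draw_mvn_canonical_r(P, h, n, colnames(Z))
}

#' Conditional draw of a variance component
#'
#' The scaled inverse-gamma update: given the quadratic form
#' (`u' A^{-1} u` for a parental component, `e'e` for the residual) and its
#' count (`q` or `n`), draws from the inverse-gamma with shape
#' `(nu + count) / 2` and scale `(nu * V + quad_form) / 2`. With
#' `count = 0` this is a draw from the prior itself.
#'
#' @param quad_form Non-negative quadratic form.
#' @param count Number of contributing terms.
#' @param prior_V,prior_nu Prior scale and belief (both positive).
#' @param n Number of draws.
#' @return Numeric vector of `n` variance draws.
#' @export
cond_var <- function(quad_form, count, prior_V, prior_nu, n = 1) {
  if (prior_V <= 0 || prior_nu <= 0) stop("prior_V and prior_nu must be positive")
  if (quad_form < 0) stop("quad_form must be non-negative")
  shape <- (prior_nu + count) / 2
  scale <- (prior_nu * prior_V + quad_form) / 2
  pmax(1 / rgamma(n, shape = shape, rate = scale), 1e-12)
}

# N(P^{-1} h, P^{-1}) draws via Cholesky; R mirror of the C++ kernel step.
draw_mvn_canonical_r <- function(P, h, n, names = NULL) {
  R <- tryCatch(chol(P), error = function(e) {
    stop("precision matrix not positive definite", call. = FALSE)
  })
  mu <- backsolve(R, forwardsolve(t(R), h))
  d <- length(mu)
  z <- matrix(rnorm(n * d), nrow = d)
  out <- t(drop(mu) + backsolve(R, z))
  colnames(out) <- names
  out
}

#' Run one Gibbs chain
#'
#' Systematic-scan Gibbs: per sweep, a joint block draw of `beta`, then
#' `u_f`, `u_m`, then the three variance components. The sweep loop runs in
#' compiled code but consumes R's RNG stream, so a chain is bit-identical
#' for a given seed.
#'
#' @param design A [build_design()] result.
#' @param prior A [build_prior()] result.
#' @param n_iter,burnin,thin Chain length controls; `(n_iter - burnin) /
#'   thin` states are retained.
#' @param seed Integer seed (optional; caller's RNG state is restored).
#' @param start Optional list with `beta`, `u_f`, `u_m`, `sigma2_f`,
#'   `sigma2_m`, `sigma2_e` starting values.
#' @param fix_variances Optional list with `sigma2_f`, `sigma2_m`,
#'   `sigma2_e`: hold the variance components fixed at these values
#'   (used for validating the fixed-effect updates against GLS).
#' @param keep_u Also retain the per-taxon random-effect draws.
#' @return Matrix of retained draws, one column per parameter; if
#'   `keep_u`, the matrix `u_draws` is attached as an attribute.
#' @export
run_chain <- function(design, prior, n_iter = 20000, burnin = 5000,
                      thin = 10, seed = NULL, start = NULL,
                      fix_variances = NULL, keep_u = FALSE) {
  stopifnot(inherits(design, "design_matrices"), inherits(prior, "prior_spec"))
  if (n_iter <= burnin) stop("n_iter must exceed burnin")
  if (thin < 1) stop("thin must be >= 1")

  X <- design$X
  p <- ncol(X)
  qf <- ncol(design$Z_f); qm <- ncol(design$Z_m)
  Af_inv <- stable_inverse(design$A_f)
  Am_inv <- stable_inverse(design$A_m)
  B0_inv <- stable_inverse(prior$B0)
  B0_inv_b0 <- drop(B0_inv %*% prior$b0)

  v0 <- var(design$y) / 3
  st <- list(beta = rep(0, p), u_f = rep(0, qf), u_m = rep(0, qm),
             sigma2_f = v0, sigma2_m = v0, sigma2_e = v0)
  if (!is.null(start)) st <- modifyList(st, start)
  fix <- !is.null(fix_variances)
  if (fix) st <- modifyList(st, fix_variances)

  zf <- match(apply(design$Z_f > 0, 1, which.max), seq_len(qf)) - 1L
  zm <- match(apply(design$Z_m > 0, 1, which.max), seq_len(qm)) - 1L

  res <- with_seed(seed, gibbs_chain_cpp(
    design$y, X, as.integer(zf), as.integer(zm), Af_inv, Am_inv,
    B0_inv, B0_inv_b0,
    prior$variance$maternal$V, prior$variance$maternal$nu,
    prior$variance$paternal$V, prior$variance$paternal$nu,
    prior$variance$residual$V, prior$variance$residual$nu,
    as.integer(n_iter), as.integer(burnin), as.integer(thin),
    st$beta, st$u_f, st$u_m, st$sigma2_f, st$sigma2_m, st$sigma2_e,
    fix, keep_u))

  draws <- res$draws
  colnames(draws) <- c(colnames(X), "sigma2_maternal", "sigma2_paternal",
                       "sigma2_residual")
  if (keep_u) {
    u_draws <- res$u_draws
    colnames(u_draws) <- c(paste0("u_f.", design$taxa_f),
                           paste0("u_m.", design$taxa_m))
    attr(draws, "u_draws") <- u_draws
  }
  draws
}

#' Fit the phylogenetic mixed model by multi-chain Gibbs sampling
#'
#' Fits `y = X beta + Z_f u_f + Z_m u_m + e` with phylogenetically
#' structured parental random effects. By default two chains are run from
#' over-dispersed starting points (ordinary-least-squares estimate plus
#' and minus two standard errors) with distinct seeds, so that the
#' Gelman-Rubin diagnostic ([psrf()]) can detect non-convergence. A
#' warning is raised if any univariate potential scale reduction factor
#' exceeds 1.1 after fitting.
#'
#' @param dataset A [crossing_dataset()].
#' @param formula Model formula, e.g. `RI ~ gen_dist * sympatry`.
#' @param relate A [relatedness_matrix()] covering all taxa.
#' @param chains Number of chains (>= 2 recommended).
#' @param n_iter,burnin,thin Per-chain run-length controls.
#' @param seed Base seed; chain `c` uses `seed + c - 1`.
#' @param prior_mode `"independent"` or `"correlated"` fixed-effect prior.
#' @param beta_scale,nu Prior hyperparameters, see [build_prior()].
#' @param standardize Standardize continuous predictors, see
#'   [build_design()].
#' @param keep_u Retain per-taxon random-effect draws.
#' @return An `"ri_chains"` object: per-chain draw matrices plus settings,
#'   seeds and the design. Use [summary.ri_chains()], [psrf()],
#'   [contrast()].
#' @export
ri_fit <- function(dataset, formula, relate, chains = 2, n_iter = 20000,
                   burnin = 5000, thin = 10, seed = 1,
                   prior_mode = c("independent", "correlated"),
                   beta_scale = 1e8, nu = 1, standardize = FALSE,
                   keep_u = FALSE) {
  prior_mode <- match.arg(prior_mode)
  design <- build_design(dataset, formula, relate, standardize = standardize)
  prior <- build_prior(design, mode = prior_mode, beta_scale = beta_scale,
                       nu = nu)

  ols <- stats::lm.fit(design$X, design$y)
  beta_hat <- ols$coefficients
  sigma2_ols <- sum(ols$residuals^2) / max(1, length(design$y) - ncol(design$X))
  XtX_inv <- chol2inv(chol(crossprod(design$X)))
  beta_se <- sqrt(sigma2_ols * diag(XtX_inv))

  seeds <- as.integer(seed + seq_len(chains) - 1)
  chain_list <- vector("list", chains)
  for (c_ in seq_len(chains)) {
    sign_ <- if (c_ %% 2 == 1) 2 else -2
    start <- list(beta = beta_hat + sign_ * beta_se)
    chain_list[[c_]] <- tryCatch(
      run_chain(design, prior, n_iter = n_iter, burnin = burnin, thin = thin,
                seed = seeds[c_], start = start, keep_u = keep_u),
      error = function(e) stop("chain ", c_, " failed: ", conditionMessage(e),
                               call. = FALSE)
    )
  }

  out <- structure(
    list(chains = chain_list, param_names = colnames(chain_list[[1]]),
         n_iter = n_iter, burnin = burnin, thin = thin, seeds = seeds,
         prior = prior, design = design, formula = design$formula),
    class = "ri_chains"
  )
  conv <- psrf(out)
  if (any(is.finite(conv$psrf) & conv$psrf > 1.1)) {
    warning("potential scale reduction factor above 1.1 for: ",
            paste(names(conv$psrf)[conv$psrf > 1.1], collapse = ", "),
            " - chains may not have converged")
  }
  out
}

#' @export
print.ri_chains <- function(x, ...) {
  cat("Phylogenetic mixed-model fit (", length(x$chains), " chains x ",
      nrow(x$chains[[1]]), " retained draws)\n", sep = "")
  cat("  formula:", x$formula, "\n")
  cat("  iterations:", x$n_iter, "( burnin", x$burnin, ", thin", x$thin, ")\n")
  cat("  seeds:", paste(x$seeds, collapse = ", "), "\n")
  invisible(x)
}

# Pool retained draws across chains into one matrix.
pool_draws <- function(chains_obj) {
  do.call(rbind, chains_obj$chains)
}
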