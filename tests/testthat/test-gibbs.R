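test_that("cond_var draws match closed-form inverse-gamma moments", {
  set.seed(101)
  # shape = (2 + 20)/2 = 11, scale = (2*1 + 30)/2 = 16, mean = 16/10 = 1.6
  draws <- cond_var(quad_form = 30, count = 20, prior_V = 1, prior_nu = 2,
                    n = 1e5)
  expect_equal(mean(draws), 16 / 10, tolerance = 0.01)
  # variance = scale^2 / ((a-1)^2 (a-2)) = 256 / (100 * 9)
  expect_equal(var(draws), 256 / 900, tolerance = 0.03)

  # large count with quad_form = count * s^2 concentrates near s^2
  s2 <- 0.4
  big <- cond_var(quad_form = 1e4 * s2, count = 1e4, prior_V = 1,
                  prior_nu = 2, n = 2e4)
  expect_equal(mean(big), s2, tolerance = 0.01)

  # count = 0 is a draw from the prior: mean = nu*V/2 / ((nu/2) - 1)
  prior_draws <- cond_var(0, 0, prior_V = 2, prior_nu = 6, n = 1e5)
  expect_equal(mean(prior_draws), (6 * 2 / 2) / (3 - 1), tolerance = 0.02)

  expect_error(cond_var(1, 10, prior_V = 0, prior_nu = 1), "positive")
  expect_error(cond_var(-1, 10, prior_V = 1, prior_nu = 1), "non-negative")
})

test_that("cond_beta recovers the Bayesian regression closed form", {
  sim <- make_sim(n_taxa = 8, n_crosses = 40, tree_seed = 50, data_seed = 51)
  design <- build_design(sim$dataset, RI ~ gen_dist * sympatry, sim$relate)
  prior <- build_prior(design)
  state <- list(u_f = rep(0, ncol(design$Z_f)),
                u_m = rep(0, ncol(design$Z_m)), sigma2_e = 0.05)

  set.seed(102)
  draws <- cond_beta(state, design, prior, n = 1e4)
  ols <- stats::lm.fit(design$X, design$y)$coefficients
  mc_se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - ols) < 3 * mc_se + 1e-6))

  # infinitely tight prior at b0 = 0 collapses the draws onto b0
  tight <- prior
  tight$B0 <- diag(1e-12, ncol(design$X))
  set.seed(103)
  d2 <- cond_beta(state, design, tight, n = 100)
  expect_lt(max(abs(d2)), 1e-3)

  # no-information limit: huge residual variance returns the prior
  wide <- prior
  wide$B0 <- diag(1, ncol(design$X))
  state_noise <- state; state_noise$sigma2_e <- 1e12
  set.seed(104)
  d3 <- cond_beta(state_noise, design, wide, n = 2e4)
  expect_equal(unname(colMeans(d3)), rep(0, 4), tolerance = 0.05)
  expect_equal(unname(apply(d3, 2, var)), rep(1, 4), tolerance = 0.05)
})

test_that("cond_u shrinks role means by the scalar ridge factor when A = I", {
  sim <- make_sim(n_taxa = 8, n_crosses = 48, tree_seed = 60, data_seed = 61)
  design <- build_design(sim$dataset, RI ~ gen_dist * sympatry, sim$relate)
  q <- ncol(design$Z_f)
  A_inv <- diag(q)
  s2e <- 0.05; s2f <- 0.1
  state <- list(beta = rep(0, ncol(design$X)),
                u_f = rep(0, q), u_m = rep(0, ncol(design$Z_m)),
                sigma2_f = s2f, sigma2_m = 0.1, sigma2_e = s2e)

  set.seed(105)
  draws <- cond_u(state, "maternal", design, A_inv, n = 2e4)
  counts <- colSums(design$Z_f)
  role_sums <- drop(crossprod(design$Z_f, design$y))
  expected <- (role_sums / s2e) / (counts / s2e + 1 / s2f)
  mc_se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - expected) < 4 * mc_se + 1e-8))

  # prior collapse: sigma2_role -> 0 pulls u to 0
  state0 <- state; state0$sigma2_f <- 1e-12
  set.seed(106)
  d0 <- cond_u(state0, "maternal", design, A_inv, n = 50)
  expect_lt(max(abs(d0)), 1e-3)
})

test_that("chains are bit-identical for a given seed", {
  sim <- make_sim(n_taxa = 8, n_crosses = 30)
  design <- build_design(sim$dataset, RI ~ gen_dist * sympatry, sim$relate)
  prior <- build_prior(design)
  a <- run_chain(design, prior, n_iter = 500, burnin = 100, thin = 2, seed = 9)
  b <- run_chain(design, prior, n_iter = 500, burnin = 100, thin = 2, seed = 9)
  expect_identical(a, b)
  c_ <- run_chain(design, prior, n_iter = 500, burnin = 100, thin = 2, seed = 10)
  expect_false(identical(a, c_))
  # retained count contract
  expect_equal(nrow(a), (500 - 100) / 2)
})

test_that("fixed-variance chains reproduce closed-form GLS coefficients", {
  truth <- simulation_truth(sigma2_f = 0.04, sigma2_m = 0.04, sigma2_e = 0.09)
  sim <- make_sim(n_taxa = 15, n_crosses = 50, truth = truth,
                  tree_seed = 70, data_seed = 71)
  design <- build_design(sim$dataset, RI ~ gen_dist * sympatry, sim$relate)
  prior <- build_prior(design)  # beta_scale 1e8: effectively flat

  fixed <- list(sigma2_f = 0.04, sigma2_m = 0.04, sigma2_e = 0.09)
  draws <- run_chain(design, prior, n_iter = 6000, burnin = 1000, thin = 5,
                     seed = 77, fix_variances = fixed)
  beta_gls <- gls_oracle(design, 0.04, 0.04, 0.09)
  p <- ncol(design$X)
  for (j in seq_len(p)) {
    x <- draws[, j]
    ess <- coda::effectiveSize(x)
    mc_se <- sd(x) / sqrt(ess)
    expect_lt(abs(mean(x) - beta_gls[j]), 2 * mc_se + 1e-8)
  }
})

test_that("the noiseless limit recovers the generating coefficients exactly", {
  truth <- simulation_truth(sigma2_f = 0, sigma2_m = 0, sigma2_e = 0)
  sim <- make_sim(n_taxa = 10, n_crosses = 40, truth = truth,
                  tree_seed = 80, data_seed = 81)
  design <- build_design(sim$dataset, RI ~ gen_dist * sympatry, sim$relate)
  prior <- build_prior(design)
  fixed <- list(sigma2_f = 1e-10, sigma2_m = 1e-10, sigma2_e = 1e-10)
  draws <- run_chain(design, prior, n_iter = 300, burnin = 100, thin = 1,
                     seed = 13, fix_variances = fixed)
  est <- colMeans(draws[, 1:4])
  expect_equal(unname(est),
               c(truth$mu, truth$beta_gen_dist, truth$gamma_sym,
                 truth$beta_int),
               tolerance = 1e-3)
})

test_that("phylogenetic variance responds directionally to simulated signal", {
  strong <- simulation_truth(sigma2_f = 0.1, sigma2_m = 0.1, sigma2_e = 0.01)
  weak <- simulation_truth(sigma2_f = 0, sigma2_m = 0, sigma2_e = 0.01)
  sim_s <- make_sim(n_taxa = 15, n_crosses = 80, truth = strong,
                    tree_seed = 90, data_seed = 91)
  sim_w <- make_sim(n_taxa = 15, n_crosses = 80, truth = weak,
                    tree_seed = 90, data_seed = 92)
  fit_s <- ri_fit(sim_s$dataset, RI ~ gen_dist * sympatry, sim_s$relate,
                  n_iter = 4000, burnin = 1000, thin = 5, seed = 93)
  fit_w <- ri_fit(sim_w$dataset, RI ~ gen_dist * sympatry, sim_w$relate,
                  n_iter = 4000, burnin = 1000, thin = 5, seed = 94)
  tot <- function(f) {
    d <- do.call(rbind, f$chains)
    mean(d[, "sigma2_maternal"] + d[, "sigma2_paternal"])
  }
  expect_gt(tot(fit_s), 2 * tot(fit_w))
})

test_that("ri_fit runs the documented two-chain protocol", {
  sim <- make_sim(n_taxa = 10, n_crosses = 50)
  fit <- ri_fit(sim$dataset, RI ~ gen_dist * sympatry, sim$relate,
                n_iter = 2000, burnin = 500, thin = 5, seed = 3)
  expect_length(fit$chains, 2)
  expect_equal(fit$seeds, c(3L, 4L))
  expect_equal(nrow(fit$chains[[1]]), nrow(fit$chains[[2]]))
  expect_equal(fit$param_names,
               c("(Intercept)", "gen_dist", "sympatrysympatric",
                 "gen_dist:sympatrysympatric", "sigma2_maternal",
                 "sigma2_paternal", "sigma2_residual"))
})
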