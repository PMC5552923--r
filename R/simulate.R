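#' Simulate a pure-birth (Yule) phylogeny
#'
#' Generates an ultrametric pure-birth tree rescaled to unit depth with tip
#' labels `sp1..spN`. Deterministic for a given seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed (optional).
#' @return An ultrametric `"phylo"` tree of depth 1.
#' @export
simulate_yule <- function(n_tips, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  T_ <- max(tree_depths(tree))
  tree$edge.length <- tree$edge.length / T_
  tree$tip.label <- paste0("sp", seq_len(n_tips))
  tree
}

#' Generative truth for synthetic crossing data
#'
#' Holds every generative parameter of the crossing-data model: fixed
#' effects (intercept, genetic-distance slope, sympatry shift, their
#' interaction, optional geographic-distance and corolla-difference
#' slopes), the three variance components (maternal, paternal, residual),
#' the sympatry probability, and the latent Gaussian correlation among the
#' continuous predictors (genetic, geographic, floral) used by the copula.
#'
#' Default effect sizes are moderate on the RI scale: baseline isolation
#' 0.2, slope 0.5 per unit scaled genetic distance, +0.25 in sympatry with
#' a 0.4 interaction slope. Default standard deviations are 0.05 for each
#' parental effect and 0.1 residual (stored as variances).
#'
#' @param mu,beta_gen_dist,gamma_sym,beta_int,beta_geo_dist,beta_corolla
#'   Fixed-effect values.
#' @param sigma2_f,sigma2_m,sigma2_e Variance components (>= 0).
#' @param p_sympatry Probability that a pair is sympatric.
#' @param predictor_cor 3x3 correlation matrix (genetic, geographic,
#'   corolla); default identity.
#' @return A `"simulation_truth"` object.
#' @export
simulation_truth <- function(mu = 0.2, beta_gen_dist = 0.5, gamma_sym = 0.25,
                             beta_int = 0.4, beta_geo_dist = 0,
                             beta_corolla = 0,
                             sigma2_f = 0.05^2, sigma2_m = 0.05^2,
                             sigma2_e = 0.1^2, p_sympatry = 0.5,
                             predictor_cor = diag(3)) {
  if (any(c(sigma2_f, sigma2_m, sigma2_e) < 0)) stop("variances must be >= 0")
  if (p_sympatry < 0 || p_sympatry > 1) stop("p_sympatry must be in [0, 1]")
  stopifnot(is.matrix(predictor_cor), all(dim(predictor_cor) == 3))
  if (max(abs(diag(predictor_cor) - 1)) > 1e-8) {
    stop("predictor_cor must have unit diagonal")
  }
  if (min(eigen(predictor_cor, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-10) {
    stop("predictor_cor is not positive semi-definite")
  }
  structure(
    list(mu = mu, beta_gen_dist = beta_gen_dist, gamma_sym = gamma_sym,
         beta_int = beta_int, beta_geo_dist = beta_geo_dist,
         beta_corolla = beta_corolla,
         sigma2_f = sigma2_f, sigma2_m = sigma2_m, sigma2_e = sigma2_e,
         p_sympatry = p_sympatry, predictor_cor = predictor_cor),
    class = "simulation_truth"
  )
}

#' Simulate a crossing dataset with known truth
#'
#' Draws ordered species pairs with replacement (each species typically
#' appears in several crosses, in both parental roles), builds predictors,
#' and generates the response from the mixed model itself:
#' `y = X beta + Z_f u_f + Z_m u_m + e` with
#' `u_role ~ N(0, sigma2_role * A)` over all taxa and Gaussian residuals.
#' Responses are left untruncated by default — the fitted model is
#' Gaussian, and clipping to \[0, 1\] would bias recovery checks.
#'
#' The genetic-distance predictor is the patristic distance divided by
#' twice the tree depth, so it lies in \[0, 1\] (for a relatedness-matrix
#' input it is `1 - A` instead). Sympatry is Bernoulli, independent of
#' distance. When geographic/floral slopes are configured (or
#' `include_continuous = TRUE`), geographic distance (km, 0-1000) and
#' corolla difference (mm, 0-10) are generated from a Gaussian copula
#' correlated with genetic distance per `truth$predictor_cor`.
#'
#' @param tree_or_A An ultrametric `"phylo"` tree or a
#'   [relatedness_matrix()].
#' @param truth A [simulation_truth()].
#' @param n_crosses Number of crosses (at least number of parameters + 3).
#' @param seed Integer seed (optional).
#' @param include_continuous Force generation of the geographic and
#'   corolla predictors even when their slopes are 0.
#' @param clip Clamp responses to \[0, 1\] (realism experiments only).
#' @return A list with `dataset` (a [crossing_dataset()]), `truth`, and
#'   `relate` (the relatedness matrix used).
#' @export
simulate_crossing_data <- function(tree_or_A, truth = simulation_truth(),
                                   n_crosses, seed = NULL,
                                   include_continuous = FALSE, clip = FALSE) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (inherits(tree_or_A, "phylo")) {
    relate <- tree_to_relatedness(tree_or_A)
    T_ <- max(tree_depths(tree_or_A))
    GD <- cophenetic(tree_or_A)[relate$labels, relate$labels] / (2 * T_)
  } else if (inherits(tree_or_A, "relatedness_matrix")) {
    relate <- tree_or_A
    GD <- 1 - relate$A
    diag(GD) <- 0
  } else {
    stop("tree_or_A must be a 'phylo' tree or a relatedness_matrix")
  }
  taxa <- relate$labels
  q <- length(taxa)
  if (q < 4) stop("need at least 4 taxa")
  with_cont <- include_continuous || truth$beta_geo_dist != 0 ||
    truth$beta_corolla != 0
  n_par <- 4 + 2 * with_cont
  if (n_crosses < n_par + 3) {
    stop("n_crosses must be at least number of parameters + 3 (= ",
         n_par + 3, ")")
  }

  with_seed(seed, {
    maternal <- sample(taxa, n_crosses, replace = TRUE)
    paternal <- sample(taxa, n_crosses, replace = TRUE)
    same <- maternal == paternal
    while (any(same)) {
      paternal[same] <- sample(taxa, sum(same), replace = TRUE)
      same <- maternal == paternal
    }

    gen_dist <- GD[cbind(maternal, paternal)]
    sym01 <- stats::rbinom(n_crosses, 1, truth$p_sympatry)

    geo_dist <- corolla_diff <- NULL
    if (with_cont) {
      R <- truth$predictor_cor
      z1 <- qnorm((rank(gen_dist, ties.method = "average") - 0.5) / n_crosses)
      S21 <- R[2:3, 1, drop = FALSE]
      S22 <- R[2:3, 2:3] - S21 %*% t(S21)
      L <- t(chol(S22 + diag(1e-12, 2)))
      z23 <- S21 %*% t(z1) + L %*% matrix(rnorm(2 * n_crosses), nrow = 2)
      geo_dist <- 1000 * pnorm(z23[1, ])
      corolla_diff <- 10 * pnorm(z23[2, ])
    }

    draw_u <- function(sigma2) {
      if (sigma2 == 0) return(rep(0, q))
      drop(MASS::mvrnorm(1, rep(0, q), sigma2 * relate$A + diag(1e-12, q)))
    }
    u_f <- draw_u(truth$sigma2_f)
    u_m <- draw_u(truth$sigma2_m)
    names(u_f) <- names(u_m) <- taxa
    e <- rnorm(n_crosses, 0, sqrt(truth$sigma2_e))

    y <- truth$mu + truth$beta_gen_dist * gen_dist +
      truth$gamma_sym * sym01 + truth$beta_int * gen_dist * sym01 +
      u_f[maternal] + u_m[paternal] + e
    if (with_cont) {
      y <- y + truth$beta_geo_dist * geo_dist +
        truth$beta_corolla * corolla_diff
    }
    if (clip) y <- pmin(1, pmax(0, y))

    df <- data.frame(
      maternal = maternal, paternal = paternal, RI = unname(y),
      gen_dist = unname(gen_dist),
      sympatry = ifelse(sym01 == 1, "sympatric", "allopatric"),
      stringsAsFactors = FALSE)
    continuous <- "gen_dist"
    if (with_cont) {
      df$geo_dist <- geo_dist
      df$corolla_diff <- corolla_diff
      continuous <- c(continuous, "geo_dist", "corolla_diff")
    }
    schema <- cross_schema("maternal", "paternal", "RI",
                           continuous = continuous, categorical = "sympatry")
    # untruncated responses can stray past 1; the range warning is for
    # user-supplied tables, not the generator's own output
    ds <- withCallingHandlers(
      crossing_dataset(df, schema),
      warning = function(w) {
        if (grepl("outside", conditionMessage(w))) invokeRestart("muffleWarning")
      })
    list(dataset = ds, truth = truth, relate = relate)
  })
}
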