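#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `prob` of the draws:
#' samples are sorted and every window of `ceiling(prob * n)` consecutive
#' order statistics is scanned for minimum width; ties go to the leftmost
#' window.
#'
#' @param samples Numeric vector of posterior draws.
#' @param prob Coverage probability in (0, 1).
#' @return An `"hpd_interval"` list with `lower`, `upper`, `prob`.
#' @export
hpd <- function(samples, prob = 0.95) {
  if (prob <= 0 || prob >= 1) stop("prob must be in (0, 1)")
  n <- length(samples)
  if (n < ceiling(1 / (1 - prob))) {
    stop("need at least ", ceiling(1 / (1 - prob)), " samples for prob = ",
         prob)
  }
  xs <- sort(samples)
  w <- ceiling(prob * n)
  starts <- seq_len(n - w + 1)
  widths <- xs[starts + w - 1] - xs[starts]
  i <- which.min(widths)
  structure(list(lower = xs[i], upper = xs[i + w - 1], prob = prob),
            class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, ...) {
  cat(sprintf("%.0f%% HPD: (%.6g, %.6g)\n", 100 * x$prob, x$lower, x$upper))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factors
#'
#' For each parameter, with `m` chains of `n` retained draws,
#' `W` the mean within-chain variance and `B/n` the between-chain variance
#' of the chain means, the univariate factor is
#' `Rhat = sqrt( ((n-1)/n * W + (1 + 1/m) * B/n) / W )`. The multivariate
#' factor replaces `(B/n)/W` with the largest eigenvalue of
#' `W^{-1} B/n` over the joint draws. Values near 1 indicate convergence;
#' the conventional acceptance threshold is 1.1 per parameter.
#'
#' Parameters with zero within-chain variance are flagged degenerate:
#' constant and identical across chains reports 1 (trivially converged);
#' constant but differing across chains reports `Inf`.
#'
#' @param chains An `"ri_chains"` fit or a list of draw matrices with
#'   identical dimensions and column names.
#' @return A list with `psrf` (named vector), `mpsrf` (scalar), and
#'   `degenerate` (named logical).
#' @export
psrf <- function(chains) {
  mats <- if (inherits(chains, "ri_chains")) chains$chains else chains
  if (!is.list(mats) || length(mats) < 2) stop("need at least 2 chains")
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("chains must have equal dimensions")
  }
  n <- nrow(mats[[1]]); m <- length(mats)
  if (n < 10) stop("need at least 10 retained draws per chain")
  params <- colnames(mats[[1]])
  p <- ncol(mats[[1]])

  means <- vapply(mats, colMeans, numeric(p))           # p x m
  vars <- vapply(mats, function(M) apply(M, 2, var), numeric(p))
  if (p == 1) { means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1) }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, var)                      # var of chain means

  eps <- .Machine$double.eps
  degenerate <- W <= eps * pmax(abs(rowMeans(means)), 1)^2
  rhat <- sqrt(((n - 1) / n * W + (1 + 1 / m) * B_over_n) / W)
  rhat[degenerate & B_over_n <= eps] <- 1
  rhat[degenerate & B_over_n > eps] <- Inf
  names(rhat) <- names(degenerate) <- params

  ok <- !degenerate
  mpsrf <- NA_real_
  if (sum(ok) >= 1) {
    Wm <- matrix(0, sum(ok), sum(ok))
    for (M in mats) Wm <- Wm + stats::cov(M[, ok, drop = FALSE])
    Wm <- Wm / m
    Bm <- stats::cov(t(means[ok, , drop = FALSE]))      # B/n matrix
    lambda <- tryCatch({
      ev <- eigen(solve(Wm, Bm), only.values = TRUE)$values
      max(Re(ev))
    }, error = function(e) {
      ev <- eigen(MASS::ginv(Wm) %*% Bm, only.values = TRUE)$values
      max(Re(ev))
    })
    mpsrf <- sqrt((n - 1) / n + (1 + 1 / m) * lambda)
  }
  list(psrf = rhat, mpsrf = mpsrf, degenerate = degenerate)
}

#' Posterior of a linear combination of parameters
#'
#' Computes a derived quantity such as the total genetic-distance slope for
#' sympatric pairs (main slope plus interaction) per draw, pooled across
#' chains, then summarizes it like any other parameter: mean, mode, HPD,
#' and the HPD-excludes-zero significance call.
#'
#' @param chains An `"ri_chains"` fit.
#' @param weights Named numeric vector; names must be parameter columns.
#' @param prob HPD coverage.
#' @return A list with `sample` (the derived draws), `mean`, `mode`,
#'   `hpd`, and `excludes_zero`.
#' @export
contrast <- function(chains, weights, prob = 0.95) {
  stopifnot(inherits(chains, "ri_chains"))
  draws <- pool_draws(chains)
  unknown <- setdiff(names(weights), colnames(draws))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  sample <- drop(draws[, names(weights), drop = FALSE] %*% weights)
  interval <- hpd(sample, prob)
  list(sample = sample,
       mean = mean(sample),
       mode = posterior_mode(sample),
       hpd = interval,
       excludes_zero = interval$lower > 0 || interval$upper < 0)
}

# Gaussian-kernel density mode with Silverman's bandwidth.
posterior_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  d <- density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Summarize a fit
#'
#' Pooled posterior mean, kernel-density mode, 95% HPD, univariate PSRF and
#' the HPD-excludes-zero flag for every fixed effect and variance
#' component, plus any requested derived contrasts and the multivariate
#' PSRF. A warning is raised if pooling happens while any univariate PSRF
#' exceeds 1.1.
#'
#' @param object An `"ri_chains"` fit.
#' @param prob HPD coverage probability.
#' @param contrasts Named list of weight vectors passed to [contrast()].
#' @param ... Unused.
#' @return An `"ri_summary"`: a parameter table plus `multivariate_psrf`
#'   and run metadata.
#' @export
summary.ri_chains <- function(object, prob = 0.95, contrasts = list(), ...) {
  conv <- psrf(object)
  if (any(is.finite(conv$psrf) & conv$psrf > 1.1)) {
    warning("pooling chains with PSRF > 1.1; summaries may be unreliable")
  }
  draws <- pool_draws(object)
  rows <- lapply(colnames(draws), function(nm) {
    x <- draws[, nm]
    interval <- hpd(x, prob)
    data.frame(parameter = nm, mean = mean(x), mode = posterior_mode(x),
               hpd_lower = interval$lower, hpd_upper = interval$upper,
               psrf = unname(conv$psrf[nm]),
               excludes_zero = interval$lower > 0 || interval$upper < 0,
               stringsAsFactors = FALSE)
  })
  for (nm in names(contrasts)) {
    ct <- contrast(object, contrasts[[nm]], prob)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = nm, mean = ct$mean, mode = ct$mode,
      hpd_lower = ct$hpd$lower, hpd_upper = ct$hpd$upper,
      psrf = NA_real_, excludes_zero = ct$excludes_zero,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  structure(
    list(table = tab,
         multivariate_psrf = conv$mpsrf,
         metadata = list(
           formula = object$formula,
           n = length(object$design$y), p = ncol(object$design$X),
           chains = length(object$chains), n_iter = object$n_iter,
           burnin = object$burnin, thin = object$thin,
           seeds = object$seeds, prior_mode = object$prior$mode,
           beta_scale = object$prior$beta_scale,
           prior_V = object$prior$variance$residual$V,
           prior_nu = object$prior$variance$residual$nu,
           hpd_prob = prob)),
    class = "ri_summary"
  )
}

#' @export
print.ri_summary <- function(x, ...) {
  cat("Posterior summary (", x$metadata$chains, " chains, ",
      x$metadata$n_iter, " iterations)\n", sep = "")
  tab <- x$table
  tab$signif <- ifelse(tab$excludes_zero, "*", "")
  print(format(tab, digits = 4), row.names = FALSE)
  cat("Multivariate PSRF:", format(x$multivariate_psrf, digits = 4), "\n")
  invisible(x)
}

#' Export pooled draws for external trace plotting
#'
#' Writes one CSV row per retained draw with chain and iteration columns,
#' suitable for trace-plot inspection in any plotting tool.
#'
#' @param chains An `"ri_chains"` fit.
#' @param path Output CSV path.
#' @export
export_draws <- function(chains, path) {
  stopifnot(inherits(chains, "ri_chains"))
  dfs <- lapply(seq_along(chains$chains), function(i) {
    M <- chains$chains[[i]]
    data.frame(chain = i, iteration = seq_len(nrow(M)), M,
               check.names = FALSE)
  })
  write.table(do.call(rbind, dfs), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
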