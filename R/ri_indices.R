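#' Strength of one reproductive barrier
#'
#' The conventional index `RI = 1 - heterospecific / homospecific`, where
#' each argument is a success proportion for the relevant stage (e.g.,
#' fertilization or hatching rate). Heterospecific success exceeding
#' homospecific success gives a negative value (heterospecific advantage),
#' kept with a warning unless `clamp = TRUE`.
#'
#' @param heterospecific_success,homospecific_success Proportions in
#'   \[0, 1\]; `homospecific_success` must be positive.
#' @param clamp Clamp negative values to 0.
#' @return A single RI value, at most 1.
#' @export
barrier_strength <- function(heterospecific_success, homospecific_success,
                             clamp = FALSE) {
  stopifnot(is.numeric(heterospecific_success), is.numeric(homospecific_success))
  if (any(homospecific_success == 0)) {
    stop("undefined index: homospecific success is 0")
  }
  if (any(heterospecific_success < 0 | heterospecific_success > 1) ||
      any(homospecific_success < 0 | homospecific_success > 1)) {
    stop("success proportions must lie in [0, 1]")
  }
  ri <- 1 - heterospecific_success / homospecific_success
  if (any(ri < 0)) {
    if (clamp) ri[ri < 0] <- 0
    else warning("heterospecific success exceeds homospecific success; ",
                 "negative RI kept (use clamp = TRUE to floor at 0)")
  }
  ri
}

#' Composite reproductive-isolation index
#'
#' The unweighted arithmetic mean of the per-barrier strengths. With `k`
#' equally spaced score components the composite takes values on a grid of
#' step `1/k`, which is why the sequential index below is sometimes
#' preferred as a more continuous response.
#'
#' @param strengths Numeric vector of per-barrier RI values (negative
#'   values allowed: heterospecific advantage at one stage).
#' @return The mean strength.
#' @export
composite_index <- function(strengths) {
  if (length(strengths) == 0) stop("empty barrier series")
  if (anyNA(strengths) || any(!is.finite(strengths))) {
    stop("barrier strengths must be finite")
  }
  mean(strengths)
}

#' Sequential reproductive-isolation index
#'
#' Barriers act in biological order (e.g., fertilization, then hatching,
#' then metamorphosis): each barrier can only remove gene flow that
#' survived the earlier ones. The absolute contribution of barrier `n` is
#' `AC_n = RI_n * prod_{i<n}(1 - RI_i)` and the total isolation is
#' `1 - prod_k(1 - RI_k)`, which equals the sum of the contributions.
#' The multiplicative form requires every strength in \[0, 1\].
#'
#' @param strengths Numeric vector of per-barrier RI values in \[0, 1\],
#'   in biological order.
#' @return A list with `total` and `contributions` (named like
#'   `strengths` when it has names).
#' @export
sequential_index <- function(strengths) {
  if (length(strengths) == 0) stop("empty barrier series")
  if (anyNA(strengths) || any(strengths < 0) || any(strengths > 1)) {
    stop("sequential index requires strengths in [0, 1]")
  }
  surviving <- cumprod(1 - strengths)
  prior_survival <- c(1, surviving[-length(surviving)])
  contributions <- strengths * prior_survival
  names(contributions) <- names(strengths)
  list(total = 1 - surviving[length(surviving)], contributions = contributions)
}
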