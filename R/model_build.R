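#' Build design matrices from a crossing dataset and a model formula
#'
#' Realizes the mixed model `y = X beta + Z_f u_f + Z_m u_m + e`: the fixed
#' design `X` from a formula over the cross-level predictors, and two
#' incidence matrices mapping each cross to its maternal (`Z_f`) and
#' paternal (`Z_m`) species. Each `Z` is restricted to the taxa actually
#' observed in that parental role, which keeps the matrices dense and the
#' variance estimates precise; the corresponding relatedness sub-matrices
#' are extracted in matching order.
#'
#' The formula mini-language is R's own: `RI ~ gen_dist * sympatry` expands
#' to main effects plus interaction, `a:b` is the interaction alone.
#' Categorical terms (declared in the schema) are dummy-coded against a
#' reference level — by default the first level in sorted order, so a
#' sympatry factor with levels `allopatric`/`sympatric` is coded 0 for
#' allopatric. Override with `C(term, ref = "LEVEL")` inside the formula.
#'
#' @param dataset A [crossing_dataset()].
#' @param formula Model formula (or string), response on the left.
#' @param relate A [relatedness_matrix()] covering every taxon in the data.
#' @param standardize Center and scale continuous predictors. Default off:
#'   raw slopes (e.g., RI per km) are usually the quantity of interest.
#' @return A `"design_matrices"` object with elements `y`, `X`, `Z_f`,
#'   `Z_m`, `taxa_f`, `taxa_m`, `A_f`, `A_m`.
#' @export
build_design <- function(dataset, formula, relate, standardize = FALSE) {
  stopifnot(inherits(dataset, "crossing_dataset"),
            inherits(relate, "relatedness_matrix"))
  schema <- dataset$schema
  pf <- parse_model_formula(formula)
  if (!pf$response %in% schema$responses) {
    stop("response '", pf$response, "' is not a declared response column")
  }

  df <- dataset$data
  used_vars <- intersect(all.vars(pf$rhs), names(df))
  keep <- complete.cases(df[, c(pf$response, used_vars), drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " row(s) with missing predictor values")
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) stop("no complete rows left")

  orphans <- setdiff(unique(c(df[[schema$maternal]], df[[schema$paternal]])),
                     relate$labels)
  if (length(orphans)) {
    stop("taxa absent from relatedness matrix: ",
         paste(orphans, collapse = ", "))
  }

  for (col in intersect(used_vars, schema$categorical)) {
    lev <- sort(unique(as.character(df[[col]])))
    if (length(lev) < 2) {
      stop("categorical term '", col, "' is constant in the retained rows")
    }
    ref <- pf$refs[[col]] %||% lev[1]
    if (!ref %in% lev) {
      stop("reference level '", ref, "' not observed for term '", col, "'")
    }
    df[[col]] <- factor(df[[col]], levels = c(ref, setdiff(lev, ref)))
  }
  if (standardize) {
    for (col in intersect(used_vars, schema$continuous)) {
      df[[col]] <- as.numeric(scale(df[[col]]))
    }
  }

  X <- model.matrix(pf$rhs, data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(dropped_cols, collapse = ", "))
  }

  y <- df[[pf$response]]
  taxa_f <- sort(unique(df[[schema$maternal]]))
  taxa_m <- sort(unique(df[[schema$paternal]]))
  Z_f <- incidence_matrix(df[[schema$maternal]], taxa_f)
  Z_m <- incidence_matrix(df[[schema$paternal]], taxa_m)
  A_f <- relate$A[taxa_f, taxa_f, drop = FALSE]
  A_m <- relate$A[taxa_m, taxa_m, drop = FALSE]

  structure(
    list(y = y, X = X, Z_f = Z_f, Z_m = Z_m,
         taxa_f = taxa_f, taxa_m = taxa_m, A_f = A_f, A_m = A_m,
         response = pf$response, formula = pf$label, n_dropped = n_dropped),
    class = "design_matrices"
  )
}

#' @export
print.design_matrices <- function(x, ...) {
  cat("Design: n =", length(x$y), ", p =", ncol(x$X),
      ", maternal taxa =", ncol(x$Z_f), ", paternal taxa =", ncol(x$Z_m), "\n")
  cat("  formula:", x$formula, "\n")
  cat("  X columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

incidence_matrix <- function(labels, taxa) {
  Z <- matrix(0, nrow = length(labels), ncol = length(taxa),
              dimnames = list(NULL, taxa))
  Z[cbind(seq_along(labels), match(labels, taxa))] <- 1
  Z
}

# Accepts formula or string; extracts C(term, ref = "LEVEL") annotations.
parse_model_formula <- function(formula) {
  txt <- if (inherits(formula, "formula")) {
    paste(deparse(formula), collapse = " ")
  } else as.character(formula)
  refs <- list()
  pat <- "C\\(\\s*([A-Za-z._][A-Za-z0-9._]*)\\s*,\\s*ref\\s*=\\s*[\"']?([^\"')]+)[\"']?\\s*\\)"
  m <- gregexpr(pat, txt)
  hits <- regmatches(txt, m)[[1]]
  for (h in hits) {
    parts <- regmatches(h, regexec(pat, h))[[1]]
    refs[[parts[2]]] <- trimws(parts[3])
  }
  txt <- gsub(pat, "\\1", txt)
  f <- as.formula(txt)
  if (length(f) != 3) stop("formula must have a response on the left")
  list(response = all.vars(f[[2]]), rhs = f[-2], refs = refs, label = txt)
}

#' Build the prior specification for a fit
#'
#' Variance components (maternal, paternal, residual) each get a scaled
#' inverse-gamma prior whose scale `V` is one-third of the sample variance
#' of the response — the total response variance split evenly across the
#' three covariance components — with belief parameter `nu` (default 1).
#' The fixed effects get a zero-mean Gaussian prior `N(b0, B0)`:
#'
#' * `mode = "independent"`: `B0 = beta_scale * I`, effectively flat at the
#'   default scale, treating predictors as a priori independent.
#' * `mode = "correlated"`: off-diagonal entries of `B0` between continuous
#'   (non-dummy, non-intercept) columns are set to `beta_scale` times the
#'   empirical correlation of those design columns, acknowledging
#'   multicollinearity among predictors such as genetic and geographic
#'   distance. `B0` is projected to the nearest positive semi-definite
#'   matrix (eigenvalue clipping at 0, with a warning) if needed.
#'
#' @param design A [build_design()] result.
#' @param mode `"independent"` or `"correlated"`.
#' @param beta_scale Prior variance scale for the fixed effects
#'   (default `1e8`, effectively flat).
#' @param nu Belief (degrees-of-freedom) parameter for the variance priors.
#' @return A `"prior_spec"` object with `b0`, `B0`, and per-component
#'   `variance` entries (`V`, `nu`).
#' @export
build_prior <- function(design, mode = c("independent", "correlated"),
                        beta_scale = 1e8, nu = 1) {
  stopifnot(inherits(design, "design_matrices"))
  mode <- match.arg(mode)
  if (beta_scale <= 0) stop("beta_scale must be positive")
  if (nu <= 0) stop("nu must be positive")
  vy <- var(design$y)
  if (!is.finite(vy) || vy == 0) stop("degenerate response: var(y) = 0")
  V <- vy / 3

  p <- ncol(design$X)
  b0 <- setNames(rep(0, p), colnames(design$X))
  B0 <- diag(beta_scale, p)
  dimnames(B0) <- list(colnames(design$X), colnames(design$X))

  if (mode == "correlated") {
    cont <- which(vapply(seq_len(p), function(j) {
      nm <- colnames(design$X)[j]
      nm != "(Intercept)" && length(unique(design$X[, j])) > 2
    }, logical(1)))
    if (length(cont) >= 2) {
      R <- cor(design$X[, cont, drop = FALSE])
      B0[cont, cont] <- beta_scale * R
      diag(B0) <- beta_scale
      ev <- eigen(B0, symmetric = TRUE)
      if (min(ev$values) < 1e-8 * beta_scale) {
        warning("correlated beta prior is not positive definite; ",
                "negative eigenvalues clipped at 0")
        ev$values[ev$values < 0] <- 0
        B0 <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
        dimnames(B0) <- list(colnames(design$X), colnames(design$X))
      }
    }
  }

  structure(
    list(b0 = b0, B0 = B0,
         variance = list(
           maternal = list(V = V, nu = nu),
           paternal = list(V = V, nu = nu),
           residual = list(V = V, nu = nu)),
         mode = mode, beta_scale = beta_scale),
    class = "prior_spec"
  )
}
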