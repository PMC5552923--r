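#' Relatedness matrix for phylogenetically structured random effects
#'
#' Wraps the square symmetric matrix `A` that defines the covariance of the
#' per-species random effects (`u ~ N(0, sigma^2 * A)`), with unit diagonal.
#' `A` comes either from an ultrametric tree (shared root-to-MRCA depth,
#' scaled to \[0, 1\]) or from a pairwise genetic-distance matrix as `1 - D`.
#'
#' @param A Square symmetric numeric matrix with dimnames.
#' @param source Either `"tree"` or `"one_minus_distance"`.
#' @param generalized_inverse_used Logical flag, set by [stable_inverse()].
#' @return A `"relatedness_matrix"` object.
#' @export
relatedness_matrix <- function(A, source = c("tree", "one_minus_distance"),
                               generalized_inverse_used = FALSE) {
  source <- match.arg(source)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (is.null(rownames(A))) stop("A must carry taxon labels as dimnames")
  if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric")
  if (max(abs(diag(A) - 1)) > 1e-8) stop("A must have unit diagonal")
  structure(
    list(labels = rownames(A), A = A, source = source,
         generalized_inverse_used = generalized_inverse_used),
    class = "relatedness_matrix"
  )
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat("Relatedness matrix (", x$source, "): ", length(x$labels), " taxa\n",
      sep = "")
  invisible(x)
}

tree_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_len(ape::Ntip(tree))]
}

is_ultrametric_strict <- function(tree, rel_tol = 1e-6) {
  depths <- tree_depths(tree)
  T_ <- max(depths)
  if (T_ == 0) return(TRUE)
  (max(depths) - min(depths)) <= rel_tol * T_
}

#' Make a tree ultrametric by extending pendant edges
#'
#' Every tip's terminal branch is lengthened so that all root-to-tip depths
#' equal the maximum depth. Internal branches — the shared history that the
#' relatedness matrix encodes — are untouched, and topology is unchanged.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return An ultrametric `"phylo"` object.
#' @export
ultrametricize <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- ape::Ntip(tree)
  if (ntip == 1) return(tree)
  depths <- tree_depths(tree)
  T_ <- max(depths)
  pendant <- match(seq_len(ntip), tree$edge[, 2])
  tree$edge.length[pendant] <- tree$edge.length[pendant] + (T_ - depths)
  tree
}

#' Tree to relatedness matrix
#'
#' For tips i != j of an ultrametric tree of depth `T`, the relatedness is
#' the depth of their most recent common ancestor divided by `T` — the
#' proportion of evolutionary history the two taxa share. The diagonal is 1.
#' The result is a positive semi-definite correlation-scaled matrix, the
#' structured `A` in `u ~ N(0, sigma^2 * A)`.
#'
#' @param tree An ultrametric `"phylo"` object (see [ultrametricize()]).
#' @return A `"relatedness_matrix"` with `source = "tree"`.
#' @export
tree_to_relatedness <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depths <- tree_depths(tree)
  T_ <- max(depths)
  if (T_ <= 0) stop("tree has zero depth")
  if (!is_ultrametric_strict(tree)) {
    stop("tree is not ultrametric (depth spread ",
         format(max(depths) - min(depths)),
         "); run ultrametricize() first")
  }
  A <- ape::vcv.phylo(tree) / T_
  diag(A) <- 1
  relatedness_matrix(A, source = "tree")
}

#' Genetic-distance matrix to relatedness matrix
#'
#' Converts a pairwise genetic-distance matrix `D` (zero diagonal,
#' non-negative) into a relatedness matrix by `A = 1 - D` off-diagonal,
#' with unit diagonal, so that small distances mean high relatedness.
#' Distances above 1 yield negative relatedness entries, which are kept
#' with a warning unless `floor_negative = TRUE`. Positive
#' semi-definiteness is not guaranteed for such matrices; the sampler uses
#' [stable_inverse()] which falls back to a generalized inverse.
#'
#' @param D Labeled square symmetric distance matrix, `diag(D) = 0`.
#' @param floor_negative Clamp negative `1 - D` entries to 0.
#' @return A `"relatedness_matrix"` with `source = "one_minus_distance"`.
#' @export
distance_to_relatedness <- function(D, floor_negative = FALSE) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) stop("D must carry taxon labels as dimnames")
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  if (max(abs(diag(D))) > 1e-8) stop("diag(D) must be 0")
  if (any(D < 0)) stop("negative distances in D")
  A <- 1 - D
  diag(A) <- 1
  if (any(A < 0)) {
    if (floor_negative) {
      A[A < 0] <- 0
    } else {
      warning("distances above 1 produce negative relatedness entries; ",
              "kept (use floor_negative = TRUE to clamp)")
    }
  }
  relatedness_matrix(A, source = "one_minus_distance")
}

#' Inverse or Moore-Penrose pseudoinverse of a symmetric matrix
#'
#' Returns the ordinary inverse when the matrix is numerically full rank
#' (smallest eigenvalue magnitude above `max(dim) * eps * largest
#' singular value`); otherwise the Moore-Penrose pseudoinverse via
#' [MASS::ginv()], with the attribute `"generalized_inverse"` set to
#' `TRUE`. Either result satisfies `A %*% Ainv %*% A = A` to high
#' precision.
#'
#' @param A A symmetric matrix or a [relatedness_matrix()].
#' @return The (pseudo)inverse with dimnames preserved and the logical
#'   attribute `"generalized_inverse"`.
#' @export
stable_inverse <- function(A) {
  M <- if (inherits(A, "relatedness_matrix")) A$A else A
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (max(abs(M - t(M))) > 1e-8) stop("matrix is not symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(dim(M)) * .Machine$double.eps * max(abs(ev))
  if (min(ev) > tol) {
    inv <- solve(M)
    generalized <- FALSE
  } else {
    inv <- MASS::ginv(M)
    generalized <- TRUE
  }
  dimnames(inv) <- dimnames(M)
  attr(inv, "generalized_inverse") <- generalized
  inv
}

#' Graft a donor clade into a backbone tree
#'
#' Replaces the monophyletic backbone subtree spanned by `clade_tips` with
#' the topology of `donor`, rescaling every donor branch by
#' `(backbone clade depth) / (donor depth)` so the grafted clade occupies
#' exactly the time-depth of the clade it replaces. Both trees must be
#' ultrametric; the result is ultrametric with
#' `Ntip(backbone) - length(clade_tips) + Ntip(donor)` tips. This is how
#' a species-rich tree for one group is combined with a backbone tree that
#' covers more groups at lower resolution.
#'
#' @param backbone Ultrametric `"phylo"` tree.
#' @param donor Ultrametric `"phylo"` tree replacing the clade.
#' @param clade_tips Tip labels (>= 2) forming a monophyletic group in
#'   `backbone`.
#' @return The combined ultrametric `"phylo"` tree.
#' @export
graft_clade <- function(backbone, donor, clade_tips) {
  stopifnot(inherits(backbone, "phylo"), inherits(donor, "phylo"))
  if (length(clade_tips) < 2) stop("clade_tips must name at least 2 tips")
  missing_tips <- setdiff(clade_tips, backbone$tip.label)
  if (length(missing_tips)) {
    stop("tips absent from backbone: ", paste(missing_tips, collapse = ", "))
  }
  if (!is_ultrametric_strict(backbone) || !is_ultrametric_strict(donor)) {
    stop("both trees must be ultrametric; run ultrametricize() first")
  }
  if (!ape::is.monophyletic(backbone, clade_tips)) {
    others <- setdiff(backbone$tip.label, clade_tips)
    mrca <- ape::getMRCA(backbone, clade_tips)
    spanned <- ape::extract.clade(backbone, mrca)$tip.label
    stop("clade_tips are not monophyletic in backbone; the spanning clade ",
         "also contains: ", paste(intersect(spanned, others), collapse = ", "))
  }

  T_back <- max(tree_depths(backbone))
  mrca <- ape::getMRCA(backbone, clade_tips)
  node_depths <- ape::node.depth.edgelength(backbone)
  clade_depth <- T_back - node_depths[mrca]
  donor_depth <- max(tree_depths(donor))
  if (donor_depth <= 0) stop("donor tree has zero depth")

  donor <- donor
  donor$root.edge <- NULL
  donor$edge.length <- donor$edge.length * (clade_depth / donor_depth)

  placeholder <- clade_tips[1]
  reduced <- if (length(clade_tips) > 1) {
    ape::drop.tip(backbone, setdiff(clade_tips, placeholder))
  } else backbone
  tmp_label <- ".ricomp_graft_placeholder."
  reduced$tip.label[reduced$tip.label == placeholder] <- tmp_label

  where <- which(reduced$tip.label == tmp_label)
  bound <- ape::bind.tree(reduced, donor, where = where, position = clade_depth)
  out <- ape::drop.tip(bound, tmp_label)
  out
}
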