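# Small fixtures built in code; no files on disk beyond temp files.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_cross_df <- function() {
  data.frame(
    mother = c("A", "B"),
    father = c("B", "C"),
    RI = c(0.2, 0.8),
    gen_dist = c(0.1, 0.5),
    sympatry = c("allopatric", "sympatric"),
    stringsAsFactors = FALSE
  )
}

toy_schema <- function() {
  cross_schema("mother", "father", "RI",
               continuous = "gen_dist", categorical = "sympatry")
}

write_temp_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# A small simulated dataset + matching relatedness, for fit-level tests.
make_sim <- function(n_taxa = 15, n_crosses = 60, truth = simulation_truth(),
                     tree_seed = 11, data_seed = 12) {
  tree <- simulate_yule(n_taxa, seed = tree_seed)
  simulate_crossing_data(tree, truth, n_crosses = n_crosses, seed = data_seed)
}

# Independent brute-force HPD oracle: scan every window explicitly.
hpd_oracle <- function(x, prob) {
  xs <- sort(x)
  n <- length(xs)
  w <- ceiling(prob * n)
  best <- c(Inf, NA, NA)
  for (i in 1:(n - w + 1)) {
    width <- xs[i + w - 1] - xs[i]
    if (width < best[1]) best <- c(width, xs[i], xs[i + w - 1])
  }
  c(lower = best[2], upper = best[3])
}

# Closed-form GLS estimate for fixed variance components.
gls_oracle <- function(design, s2f, s2m, s2e) {
  V <- s2f * design$Z_f %*% design$A_f %*% t(design$Z_f) +
    s2m * design$Z_m %*% design$A_m %*% t(design$Z_m) +
    s2e * diag(length(design$y))
  Vi <- solve(V)
  XtVi <- t(design$X) %*% Vi
  drop(solve(XtVi %*% design$X, XtVi %*% design$y))
}

# MRCA-depth relatedness oracle by explicit path enumeration.
relatedness_oracle <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  depths <- ape::node.depth.edgelength(tree)
  T_ <- max(depths[seq_len(n)])
  A <- diag(1, n)
  dimnames(A) <- list(tips, tips)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    mrca <- ape::getMRCA(tree, c(tips[i], tips[j]))
    A[i, j] <- A[j, i] <- depths[mrca] / T_
  }
  A
}
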