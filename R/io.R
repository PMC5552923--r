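#' Read a rooted Newick tree
#'
#' Reads a single Newick string and validates it for use as a source of
#' phylogenetic covariance: tip labels must be unique and branch lengths
#' non-negative. Polytomies are preserved. Missing branch lengths are an
#' error unless `assume_unit_lengths = TRUE`, because the relatedness
#' matrix is meaningless without them.
#'
#' @param path Path to a file containing one Newick string.
#' @param assume_unit_lengths If `TRUE`, a tree without branch lengths is
#'   accepted and every edge is assigned length 1.
#' @return An [ape::read.tree()] `"phylo"` object with normalized tip labels.
#' @export
read_newick <- function(path, assume_unit_lengths = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tree <- parse_newick_string(txt, assume_unit_lengths = assume_unit_lengths)
  tree
}

# Shared parser/validator so tests can exercise strings directly.
parse_newick_string <- function(txt, assume_unit_lengths = FALSE) {
  check_balanced_parens(txt)
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found in input")
  tree$tip.label <- normalize_labels(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dups, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    if (!assume_unit_lengths) {
      stop("tree has no branch lengths; supply them or set assume_unit_lengths = TRUE")
    }
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("tree has missing or non-finite branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length in tree")
  }
  tree
}

# Report the character offset of the first unbalanced parenthesis.
check_balanced_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unbalanced ')' at character ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of string (length ",
         nchar(txt), ")")
  }
  invisible(TRUE)
}

#' Write a tree as Newick
#'
#' @param tree A `"phylo"` object.
#' @param path Output file path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Declare the layout of a crossing table
#'
#' A crossing table holds one row per interspecific cross: the maternal and
#' paternal taxon, one or more reproductive-isolation responses (roughly in
#' \[0, 1\]), and continuous/categorical predictors.
#'
#' @param maternal,paternal Column names holding the parental taxon labels.
#' @param responses Character vector of response column names.
#' @param continuous,categorical Character vectors of predictor column names.
#' @param delimiter Field delimiter; `NULL` auto-detects comma vs tab.
#' @return A `"cross_schema"` object.
#' @export
cross_schema <- function(maternal, paternal, responses,
                         continuous = character(), categorical = character(),
                         delimiter = NULL) {
  stopifnot(is.character(maternal), length(maternal) == 1,
            is.character(paternal), length(paternal) == 1,
            is.character(responses), length(responses) >= 1)
  if (identical(maternal, paternal)) {
    stop("maternal and paternal columns must differ")
  }
  if (!is.null(delimiter) && !delimiter %in% c(",", "\t")) {
    stop("delimiter must be ',' or '\\t' (or NULL for auto-detection)")
  }
  structure(
    list(maternal = maternal, paternal = paternal, responses = responses,
         continuous = continuous, categorical = categorical,
         delimiter = delimiter),
    class = "cross_schema"
  )
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab == 0 && n_com == 0) {
    stop("could not auto-detect delimiter (no comma or tab in header); ",
         "pass delimiter explicitly")
  }
  if (n_tab >= n_com) "\t" else ","
}

#' Read a crossing table
#'
#' Rows whose response is missing are dropped with a message reporting the
#' count. Response values outside \[-1, 1.5\] raise a warning (composite RI
#' indices can slightly exceed \[0, 1\] but values far outside suggest a
#' mis-declared column). Taxon labels are normalized to the Newick
#' convention (trimmed, internal spaces to underscores) so they can be
#' joined to tree tips by exact match.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [cross_schema()].
#' @return A `"crossing_dataset"`: the data plus schema and taxon universe.
#' @export
read_cross_table <- function(path, schema) {
  stopifnot(inherits(schema, "cross_schema"))
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- schema$delimiter %||% detect_delimiter(path)
  df <- read.table(path, header = TRUE, sep = delim, stringsAsFactors = FALSE,
                   check.names = FALSE)
  crossing_dataset(df, schema)
}

#' Construct a crossing dataset from a data frame
#'
#' @param df A data frame with one row per cross.
#' @param schema A [cross_schema()] describing `df`.
#' @return A `"crossing_dataset"` object.
#' @export
crossing_dataset <- function(df, schema) {
  stopifnot(is.data.frame(df), inherits(schema, "cross_schema"))
  declared <- c(schema$maternal, schema$paternal, schema$responses,
                schema$continuous, schema$categorical)
  missing_cols <- setdiff(declared, names(df))
  if (length(missing_cols)) {
    stop("declared columns absent from table: ", paste(missing_cols, collapse = ", "))
  }
  df[[schema$maternal]] <- normalize_labels(as.character(df[[schema$maternal]]))
  df[[schema$paternal]] <- normalize_labels(as.character(df[[schema$paternal]]))

  for (col in c(schema$responses, schema$continuous)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad)) {
        stop("non-numeric value in column '", col, "' at row ", bad[1])
      }
      df[[col]] <- parsed
    }
  }
  for (col in schema$responses) {
    v <- df[[col]]
    out <- which(!is.na(v) & (v < -1 | v > 1.5))
    if (length(out)) {
      warning("column '", col, "': ", length(out),
              " response value(s) outside [-1, 1.5]")
    }
  }

  n_file <- nrow(df)
  keep <- complete.cases(df[, schema$responses, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " row(s) with missing response")
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL

  structure(
    list(data = df, schema = schema,
         taxa = sort(unique(c(df[[schema$maternal]], df[[schema$paternal]]))),
         n_dropped = n_dropped, n_file_rows = n_file),
    class = "crossing_dataset"
  )
}

#' @export
print.crossing_dataset <- function(x, ...) {
  cat("Crossing dataset:", nrow(x$data), "crosses,", length(x$taxa), "taxa\n")
  cat("  responses:", paste(x$schema$responses, collapse = ", "), "\n")
  if (length(x$schema$continuous))
    cat("  continuous:", paste(x$schema$continuous, collapse = ", "), "\n")
  if (length(x$schema$categorical))
    cat("  categorical:", paste(x$schema$categorical, collapse = ", "), "\n")
  if (x$n_dropped > 0)
    cat("  (", x$n_dropped, "rows dropped for missing response )\n")
  invisible(x)
}

#' Read a labeled square matrix
#'
#' Reads e.g. a pairwise genetic-distance matrix: first row and first column
#' carry taxon labels, body is numeric. Row and column label sets must
#' agree; columns are reordered to match rows if necessary. Asymmetry up to
#' 1e-3 is symmetrized by averaging with a warning; beyond that it is an
#' error.
#'
#' @param path Path to a CSV/TSV file.
#' @param delimiter Field delimiter; `NULL` auto-detects comma vs tab.
#' @return A numeric matrix with identical row and column names.
#' @export
read_square_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- delimiter %||% detect_delimiter(path)
  df <- read.table(path, header = TRUE, sep = delim, row.names = 1,
                   check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) {
    stop("non-square matrix: ", nrow(M), " rows x ", ncol(M), " columns")
  }
  if (!is.numeric(M)) stop("matrix body is not numeric")
  rownames(M) <- normalize_labels(rownames(M))
  colnames(M) <- normalize_labels(colnames(M))
  if (!setequal(rownames(M), colnames(M))) {
    stop("row and column labels disagree")
  }
  M <- M[, rownames(M), drop = FALSE]
  asym <- max(abs(M - t(M)))
  if (asym > 1e-3) {
    stop("matrix asymmetric beyond tolerance 1e-3 (max |M - t(M)| = ",
         format(asym), ")")
  }
  if (asym > 0) {
    warning("matrix asymmetric by ", format(asym), "; symmetrized by averaging")
    M <- (M + t(M)) / 2
  }
  M
}

#' Write a fit summary as a machine-readable report
#'
#' One record per parameter (posterior mean, mode, 95% HPD bounds, PSRF,
#' excludes-zero flag) plus run metadata (chain seeds, iteration counts,
#' prior settings). The report round-trips through [read_fit_report()].
#'
#' @param summary An `"ri_summary"` from [summary.ri_chains()].
#' @param path Output JSON path.
#' @export
write_fit_report <- function(summary, path) {
  stopifnot(inherits(summary, "ri_summary"))
  if (nrow(summary$table) == 0) stop("no draws: empty summary")
  payload <- list(
    parameters = summary$table,
    multivariate_psrf = summary$multivariate_psrf,
    metadata = summary$metadata
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Read a fit report written by [write_fit_report()]
#'
#' @param path Path to the JSON report.
#' @return An `"ri_summary"` object.
#' @export
read_fit_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as.data.frame(payload$parameters)
  structure(
    list(table = tab,
         multivariate_psrf = payload$multivariate_psrf,
         metadata = payload$metadata),
    class = "ri_summary"
  )
}
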