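# Expression preprocessing: probe collapsing and per-gene z-standardization.
# An expression matrix is a plain numeric gene x sample matrix with unique
# rownames (genes) and colnames (samples) and a logical "standardized"
# attribute.

.check_expression <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have row (gene) and column (sample) names")
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  if (anyNA(x)) stop("expression matrix contains missing values")
  invisible(x)
}

#' Is an expression matrix standardized?
#'
#' @param x Numeric matrix.
#' @return `TRUE` if `x` carries a true `standardized` attribute.
#' @export
is_standardized <- function(x) isTRUE(attr(x, "standardized"))

.as_probe_map <- function(probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    if (ncol(probe_to_gene) < 2L)
      stop("probe map data frame needs two columns: probe, gene")
    map <- data.frame(probe = as.character(probe_to_gene[[1L]]),
                      gene = as.character(probe_to_gene[[2L]]),
                      stringsAsFactors = FALSE)
  } else if (is.character(probe_to_gene)) {
    if (is.null(names(probe_to_gene)))
      stop("a character probe map must be named by probe id")
    map <- data.frame(probe = names(probe_to_gene),
                      gene = unname(probe_to_gene),
                      stringsAsFactors = FALSE)
  } else {
    stop("probe_to_gene must be a data frame or a named character vector")
  }
  map <- map[!is.na(map$gene) & nzchar(map$gene) &
               !is.na(map$probe) & nzchar(map$probe), , drop = FALSE]
  unique(map)
}

#' Collapse probe sets to genes by the per-sample median
#'
#' Maps probe identifiers to gene symbols and summarises multiple probe sets
#' of the same gene by the median expression value in each sample. Probes
#' without a gene mapping are dropped; probes mapping to several genes
#' contribute to every mapped gene.
#'
#' @param values Numeric probe x sample matrix with probe rownames.
#' @param probe_to_gene Probe-to-gene mapping: a data frame with columns
#'   (probe, gene) — duplicate probe rows express many-to-many mappings — or
#'   a named character vector `probe -> gene`.
#' @return Gene x sample matrix (one row per mapped gene, rows in sorted
#'   gene order) with `standardized = FALSE`.
#' @examples
#' m <- rbind(P1 = c(1, 5, 9), P2 = c(2, 6, 10), P3 = c(3, 7, 11))
#' colnames(m) <- c("s1", "s2", "s3")
#' collapse_probesets(m, c(P1 = "geneX", P2 = "geneX", P3 = "geneX"))
#' @export
collapse_probesets <- function(values, probe_to_gene) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("probe matrix must have rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate probe identifiers")
  if (anyNA(values)) stop("expression matrix contains missing values")
  map <- .as_probe_map(probe_to_gene)
  if (nrow(map) == 0L) stop("empty probe-to-gene mapping")
  map <- map[map$probe %in% rownames(values), , drop = FALSE]
  if (nrow(map) == 0L) stop("no probe in the mapping matches the matrix")
  idx <- split(match(map$probe, rownames(values)), map$gene)
  out <- t(vapply(idx, function(i) {
    if (length(i) == 1L) values[i, ] else apply(values[i, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(values))))
  colnames(out) <- colnames(values)
  attr(out, "standardized") <- FALSE
  out
}

#' Z-standardize each gene across samples
#'
#' Transforms each gene row to `(x - mean) / sd` using the sample standard
#' deviation (divisor `n - 1`). Zero-variance genes cannot be correlated with
#' anything and are removed with a warning.
#'
#' @param expr Gene x sample numeric matrix, not yet standardized.
#' @return The standardized matrix (`standardized = TRUE`), possibly with
#'   fewer rows.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3), g2 = c(4, 0, 2))
#' colnames(m) <- c("s1", "s2", "s3")
#' standardize_expression(m)
#' @export
standardize_expression <- function(expr) {
  .check_expression(expr)
  if (is_standardized(expr)) stop("matrix is already standardized")
  if (ncol(expr) < 2L) stop("standardization requires at least 2 samples")
  ctr <- expr - rowMeans(expr)
  sd <- sqrt(rowSums(ctr^2) / (ncol(expr) - 1L))
  zero <- sd < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sprintf(
      "removed %d zero-variance gene(s): %s", sum(zero),
      paste(utils::head(rownames(expr)[zero], 5L), collapse = ", ")
    ))
  }
  out <- ctr[!zero, , drop = FALSE] / sd[!zero]
  attr(out, "standardized") <- TRUE
  out
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of probe or
#' gene identifiers.
#'
#' @param path File path.
#' @return Numeric matrix with `standardized = FALSE`.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs an id column plus samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  attr(m, "standardized") <- FALSE
  .check_expression(m)
  m
}

#' Write an expression matrix to TSV
#'
#' @param expr Gene x sample matrix.
#' @param path Output path.
#' @param id_column Name for the identifier column (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path, id_column = "gene") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping from TSV
#'
#' Two columns, probe id then gene symbol; duplicate probe rows express
#' many-to-many mappings.
#'
#' @param path File path.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @return Data frame with columns `probe`, `gene`.
#' @export
read_probe_map <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  .as_probe_map(df)
}

#' Read an ordered phenotype from TSV
#'
#' Two columns, sample id then category label. Empty or `"NA"` labels become
#' missing values.
#'
#' @param path File path.
#' @param levels Category labels in increasing order; default: sorted unique
#'   observed labels.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @return Named ordered factor (names are sample ids).
#' @export
read_phenotype_tsv <- function(path, levels = NULL, header = FALSE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("phenotype TSV needs two columns: sample, category")
  lab <- as.character(df[[2L]])
  if (is.null(levels)) levels <- sort(unique(lab[!is.na(lab)]))
  out <- factor(lab, levels = levels, ordered = TRUE)
  names(out) <- as.character(df[[1L]])
  if (anyDuplicated(names(out))) stop("duplicate sample identifiers")
  out
}
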