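# Pearson co-expression network: pairwise correlations, candidate
# thresholds, hard thresholding, topology diagnostics.

#' All pairwise Pearson correlations between genes
#'
#' @param expr Standardized gene x sample matrix with at least 3 samples.
#' @return Symmetric gene x gene correlation matrix (unit diagonal).
#' @export
pairwise_correlations <- function(expr) {
  .check_expression(expr)
  if (!is_standardized(expr))
    stop("expression matrix must be standardized first (standardize_expression)")
  if (ncol(expr) < 3L) stop("need at least 3 samples for correlations")
  ctr <- expr - rowMeans(expr)
  sd <- sqrt(rowSums(ctr^2))
  if (any(sd < .Machine$double.eps^0.5))
    stop("zero-variance gene present; remove it before correlating")
  corr <- tcrossprod(ctr / sd)
  corr[corr > 1] <- 1
  corr[corr < -1] <- -1
  diag(corr) <- 1
  corr
}

.upper_values <- function(corr) corr[upper.tri(corr)]

#' Correlation value at a top-quantile cut
#'
#' The threshold retaining (at least) a fraction `q` of all gene pairs: the
#' `ceiling(q * n_pairs)`-th largest pairwise correlation, computed on the
#' signed correlation distribution.
#'
#' @param corr Correlation matrix from [pairwise_correlations()] (or a
#'   numeric vector of pair correlations).
#' @param q Fraction of pairs to retain, e.g. `0.001` for the top 0.1%.
#' @return The correlation threshold.
#' @export
correlation_quantile <- function(corr, q) {
  vals <- if (is.matrix(corr)) .upper_values(corr) else as.numeric(corr)
  stopifnot(length(vals) > 0L, q > 0, q <= 1)
  k <- max(1L, ceiling(q * length(vals)))
  sort(vals, decreasing = TRUE)[k]
}

#' Candidate correlation thresholds for network construction
#'
#' Three conventional candidates: the smallest correlation whose two-sided
#' correlation-test p-value (t statistic with m - 2 degrees of freedom),
#' Bonferroni-corrected over all pairs, is at most 0.01; and the top 1% and
#' top 0.1% quantiles of the signed correlation distribution. The final
#' choice is the user's, normally guided by the functional-similarity curve.
#'
#' @param corr Correlation matrix (or vector of pair correlations).
#' @param n_samples Number of samples m the correlations were computed from.
#' @return Object of class `"threshold_candidates"`: list with
#'   `bonferroni_p01`, `top1pct`, `top01pct`, `n_pairs`, `n_samples`.
#' @export
threshold_candidates <- function(corr, n_samples) {
  vals <- if (is.matrix(corr)) .upper_values(corr) else as.numeric(corr)
  stopifnot(length(vals) > 0L)
  n_pairs <- length(vals)
  bonf <- if (n_samples <= 2L) {
    NA_real_
  } else {
    p_target <- 0.01 / n_pairs
    df <- n_samples - 2L
    t_crit <- stats::qt(1 - p_target / 2, df)
    t_crit / sqrt(df + t_crit^2)
  }
  structure(
    list(bonferroni_p01 = bonf,
         top1pct = correlation_quantile(vals, 0.01),
         top01pct = correlation_quantile(vals, 0.001),
         n_pairs = n_pairs, n_samples = n_samples),
    class = "threshold_candidates"
  )
}

#' @export
print.threshold_candidates <- function(x, ...) {
  cat("Candidate correlation thresholds\n")
  cat(sprintf("  Bonferroni p<=0.01 : %s\n",
              ifelse(is.na(x$bonferroni_p01), "undefined (m <= 2)",
                     format(x$bonferroni_p01, digits = 4))))
  cat(sprintf("  top 1%% of pairs    : %s\n", format(x$top1pct, digits = 4)))
  cat(sprintf("  top 0.1%% of pairs  : %s\n", format(x$top01pct, digits = 4)))
  cat(sprintf("  (%d pairs, %d samples)\n", x$n_pairs, x$n_samples))
  invisible(x)
}

#' Build a thresholded co-expression network
#'
#' Connects two genes when their correlation reaches the threshold
#' (`r >= threshold`, signed; set `absolute = TRUE` to threshold `|r|`).
#' Genes incident to no edge are excluded from the network.
#'
#' @param corr Correlation matrix from [pairwise_correlations()].
#' @param threshold Correlation threshold in (-1, 1].
#' @param absolute Threshold the absolute correlation? Default `FALSE`:
#'   large negative correlations do not track functional similarity, so the
#'   conventional network keeps positive co-expression only.
#' @return Undirected, unweighted igraph whose vertices are gene names; the
#'   threshold is recorded as the graph attribute `"threshold"`. An empty
#'   graph (with a warning) when no pair reaches the threshold.
#' @export
build_network <- function(corr, threshold, absolute = FALSE) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            !is.null(rownames(corr)))
  stopifnot(length(threshold) == 1L, threshold > -1, threshold <= 1)
  val <- if (absolute) abs(corr) else corr
  sel <- which(upper.tri(val) & val >= threshold, arr.ind = TRUE)
  if (nrow(sel) == 0L) {
    warning("threshold exceeds every pairwise correlation; empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(
      cbind(rownames(corr)[sel[, 1L]], rownames(corr)[sel[, 2L]]),
      directed = FALSE
    )
  }
  igraph::graph_attr(g, "threshold") <- threshold
  g
}

#' Mean local clustering coefficient
#'
#' Average over all vertices of the local clustering coefficient (closed
#' neighbor pairs / possible neighbor pairs); vertices of degree < 2
#' contribute 0.
#'
#' @param net Undirected igraph.
#' @return Number in \[0, 1\] (0 for an empty graph).
#' @export
clustering_coefficient <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) return(0)
  igraph::transitivity(net, type = "localaverage", isolates = "zero")
}

#' Degree distribution of a network
#'
#' @param net Undirected igraph.
#' @return Named integer vector: count of vertices per degree (names are the
#'   degrees, ascending).
#' @export
degree_counts <- function(net) {
  stopifnot(igraph::is_igraph(net), igraph::vcount(net) > 0L)
  tab <- table(igraph::degree(net))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Write a network as a TSV edge list
#'
#' @param net igraph with vertex names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a network from a TSV edge list
#'
#' @param path Path to a two-column TSV of vertex-name pairs.
#' @return Undirected simple igraph.
#' @export
read_edgelist_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs two columns")
  igraph::simplify(igraph::graph_from_edgelist(
    cbind(as.character(df[[1L]]), as.character(df[[2L]])), directed = FALSE))
}
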