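# End-to-end fit: correlations -> threshold -> network -> iterative clique
# enumeration, packaged as a classed result with the usual methods.

#' Fit co-expression modules to an expression matrix
#'
#' Runs the whole module-discovery pipeline: all pairwise Pearson
#' correlations, candidate thresholds, hard thresholding into an unweighted
#' network, and iterative clique enumeration ([ice()]) of relatively
#' independent maximal cliques. The threshold is either given explicitly
#' (normally after inspecting the functional-similarity curve) or taken as a
#' top-quantile of the signed correlation distribution (default: top 0.1% of
#' all pairs).
#'
#' @param expr Standardized gene x sample matrix
#'   (see [standardize_expression()]).
#' @param threshold Explicit correlation threshold; overrides `quantile`.
#' @param quantile Top fraction of pairs to keep when `threshold` is `NULL`
#'   (default 0.001).
#' @param c_min Minimum core clique size for a module (default 10).
#' @param absolute Threshold absolute correlations? Default `FALSE`.
#' @return Object of class `"ice_fit"`: list with `call`, `n_genes`,
#'   `n_samples`, `threshold`, `candidates` ([threshold_candidates()]),
#'   `network` (igraph) and `result` ([ice()] result).
#' @examples
#' sim <- simulate_expression(simulation_spec(
#'   n_background = 40, module_sizes = c(6, 6), rho = 0.9,
#'   n_per_category = c(10, 10), delta = 0, seed = 7))
#' fit <- ice_fit(sim$expression, quantile = 0.005, c_min = 5)
#' fit
#' @export
ice_fit <- function(expr, threshold = NULL, quantile = 0.001, c_min = 10L,
                    absolute = FALSE) {
  corr <- pairwise_correlations(expr)
  cand <- threshold_candidates(corr, n_samples = ncol(expr))
  thr <- if (is.null(threshold)) {
    correlation_quantile(corr, quantile)
  } else {
    threshold
  }
  net <- build_network(corr, thr, absolute = absolute)
  res <- ice(net, c_min = c_min)
  structure(
    list(call = match.call(), n_genes = nrow(expr), n_samples = ncol(expr),
         threshold = thr, candidates = cand, network = net, result = res),
    class = "ice_fit"
  )
}

#' @export
print.ice_fit <- function(x, ...) {
  cat("Co-expression modules by iterative clique enumeration\n")
  cat(sprintf("  input: %d genes x %d samples\n", x$n_genes, x$n_samples))
  cat(sprintf("  threshold: r >= %.4f; network: %d nodes, %d edges\n",
              x$threshold, igraph::vcount(x$network),
              igraph::ecount(x$network)))
  cat(sprintf("  modules: %d (c_min = %d)\n", length(x$result$modules),
              x$result$c_min))
  invisible(x)
}

#' @export
summary.ice_fit <- function(object, ...) {
  net <- object$network
  out <- list(
    n_genes = object$n_genes,
    n_samples = object$n_samples,
    threshold = object$threshold,
    candidates = object$candidates,
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    clustering_coefficient = clustering_coefficient(net),
    modules = summary(object$result)
  )
  class(out) <- "summary.ice_fit"
  out
}

#' @export
print.summary.ice_fit <- function(x, ...) {
  cat("Co-expression module fit\n")
  cat(sprintf("  %d genes x %d samples; threshold r >= %.4f\n",
              x$n_genes, x$n_samples, x$threshold))
  cat(sprintf("  network: %d nodes, %d edges, mean clustering coefficient %.3f\n",
              x$n_nodes, x$n_edges, x$clustering_coefficient))
  cat(sprintf("  modules: %d\n", nrow(x$modules)))
  if (nrow(x$modules)) print(x$modules, row.names = FALSE)
  invisible(x)
}

#' Plot a co-expression module fit
#'
#' Two base-graphics panels: the degree distribution of the thresholded
#' network on log-log axes (co-expression networks typically show a
#' power-law-like decay) and the module core/expanded sizes.
#'
#' @param x An `"ice_fit"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ice_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  dc <- degree_counts(x$network)
  graphics::plot(as.numeric(names(dc)), dc, log = "xy",
                 xlab = "degree", ylab = "number of nodes",
                 main = "Degree distribution", pch = 16, ...)
  mods <- summary(x$result)
  if (nrow(mods)) {
    graphics::barplot(rbind(mods$core_size,
                            mods$expanded_size - mods$core_size),
                      names.arg = seq_len(nrow(mods)),
                      xlab = "module", ylab = "genes",
                      legend.text = c("core", "expansion"),
                      main = "Module sizes")
  }
  invisible(x)
}
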