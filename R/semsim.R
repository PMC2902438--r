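# Resnik semantic similarity over a GO-style is_a DAG, and the
# correlation-binned functional-similarity curve used to pick a network
# threshold.

#' Build an ontology DAG
#'
#' Constructs the minimal ontology object used for information-content and
#' Resnik similarity computations: a set of terms with `is_a`-style parent
#' links forming a rooted DAG.
#'
#' @param parents Named list mapping each term id to a character vector of
#'   parent term ids (empty for the root). Parents outside the term universe
#'   are dropped.
#' @return Object of class `"ontology"`: list with `terms`, `parents`,
#'   `ancestors` (per-term character vector, term itself included) and
#'   `root`.
#' @examples
#' ont <- ontology(list(root = character(0), A = "root", B = "A"))
#' ont$ancestors$B
#' @export
ontology <- function(parents) {
  stopifnot(is.list(parents), !is.null(names(parents)))
  terms <- names(parents)
  if (anyDuplicated(terms)) stop("duplicate term ids")
  parents <- lapply(parents, function(p) {
    p <- as.character(p)
    p[p %in% terms]
  })
  names(parents) <- terms
  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop(sprintf("ontology must have exactly one root, found %d", length(roots)))
  # topological order root -> leaves; also detects cycles
  depth <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  depth[roots] <- 0L
  pending <- setdiff(terms, roots)
  while (length(pending)) {
    ready <- pending[vapply(parents[pending],
                            function(p) all(!is.na(depth[p])), logical(1))]
    if (!length(ready)) stop("ontology graph contains a cycle")
    depth[ready] <- vapply(parents[ready],
                           function(p) max(depth[p]) + 1L, integer(1))
    pending <- setdiff(pending, ready)
  }
  anc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms[order(depth)]) {
    anc[[t]] <- unique(c(t, unlist(anc[parents[[t]]], use.names = FALSE)))
  }
  structure(list(terms = terms, parents = parents, ancestors = anc,
                 root = roots),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d terms, root %s\n", length(x$terms), x$root))
  invisible(x)
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas, keeping one namespace and following `is_a` (and
#' optionally `part_of`) links; obsolete terms are dropped. This covers the
#' subset of OBO needed for information-content computations.
#'
#' @param path OBO file path.
#' @param namespace Namespace to keep (default `"biological_process"`). Terms
#'   without a namespace line are kept.
#' @param use_part_of Also treat `relationship: part_of` as a parent link?
#'   Default `FALSE`.
#' @return An [ontology()] object.
#' @export
read_obo <- function(path, namespace = "biological_process",
                     use_part_of = FALSE) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete) &&
        (is.null(cur$namespace) || cur$namespace == namespace)) {
      terms[[cur$id]] <- cur$parents
    }
    terms
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { # other stanza type
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "namespace:")) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    } else if (startsWith(ln, "is_a:")) {
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    } else if (use_part_of && grepl("^relationship:\\s*part_of\\s", ln)) {
      cur$parents <- c(cur$parents,
                       trimws(sub("^relationship:\\s*part_of\\s+", "", ln)))
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no terms found in OBO file")
  ontology(terms)
}

#' Read gene annotations
#'
#' Accepts GAF 2.x (gene symbol in column 3, term id in column 5; comment
#' lines starting with `!` ignored) or a two-column TSV `gene<TAB>term`.
#'
#' @param path File path.
#' @param format `"auto"` (default; GAF if the first data line has >= 5
#'   columns), `"gaf"`, or `"tsv"`.
#' @return Named list mapping gene symbol to a character vector of directly
#'   annotated term ids.
#' @export
read_annotations <- function(path, format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (!length(lines)) stop("no annotation lines found")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (length(parts[[1L]]) >= 5L) "gaf" else "tsv"
  }
  if (format == "gaf") {
    bad <- which(lengths(parts) < 5L)
    if (length(bad)) stop(sprintf("malformed GAF line %d", bad[1L]))
    gene <- vapply(parts, `[[`, character(1), 3L)
    term <- vapply(parts, `[[`, character(1), 5L)
  } else {
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) stop(sprintf("malformed annotation line %d", bad[1L]))
    gene <- vapply(parts, `[[`, character(1), 1L)
    term <- vapply(parts, `[[`, character(1), 2L)
  }
  lapply(split(term, gene), unique)
}

#' Information content of ontology terms from annotation counts
#'
#' Propagates direct annotations to all ancestors and computes, for each
#' term, `ic(t) = -ln(count(t) / count(root))`, where `count(t)` is the
#' number of distinct genes annotated to `t` or any of its descendants.
#' Terms annotating no gene (even indirectly) are excluded from the table.
#'
#' @param ont An [ontology()] object.
#' @param annotations Named list gene -> character vector of term ids.
#'   Annotations to unknown terms are skipped with a warning.
#' @return Named numeric vector of information contents (natural log);
#'   `ic[root] == 0`.
#' @export
compute_ic <- function(ont, annotations) {
  stopifnot(inherits(ont, "ontology"), is.list(annotations))
  if (!length(annotations)) stop("at least one annotated gene is required")
  genes <- names(annotations)
  pairs_gene <- character(0)
  pairs_term <- character(0)
  unknown <- character(0)
  for (g in genes) {
    ts <- unique(as.character(annotations[[g]]))
    miss <- ts[!(ts %in% ont$terms)]
    if (length(miss)) unknown <- c(unknown, miss)
    ts <- setdiff(ts, miss)
    if (!length(ts)) next
    anc <- unique(unlist(ont$ancestors[ts], use.names = FALSE))
    pairs_gene <- c(pairs_gene, rep(g, length(anc)))
    pairs_term <- c(pairs_term, anc)
  }
  if (length(unknown)) {
    warning(sprintf("skipped %d annotation(s) to terms absent from the ontology: %s",
                    length(unknown),
                    paste(utils::head(unique(unknown), 5L), collapse = ", ")))
  }
  if (!length(pairs_term)) stop("no usable annotations")
  counts <- vapply(split(pairs_gene, pairs_term),
                   function(g) length(unique(g)), integer(1))
  total <- counts[[ont$root]]
  ic <- -log(counts / total)
  ic[sort(names(ic), method = "radix")]
}

#' Resnik similarity between two ontology terms
#'
#' Information content of the most informative common ancestor of the two
#' terms (each term counts among its own ancestors). Terms whose only common
#' ancestor has no defined information content score 0.
#'
#' @param t1,t2 Term ids.
#' @param ont An [ontology()] object.
#' @param ic Information content table from [compute_ic()].
#' @return Nonnegative number.
#' @export
resnik_similarity <- function(t1, t2, ont, ic) {
  stopifnot(inherits(ont, "ontology"))
  if (!(t1 %in% ont$terms) || !(t2 %in% ont$terms))
    stop("both terms must be present in the ontology")
  common <- intersect(ont$ancestors[[t1]], ont$ancestors[[t2]])
  common <- common[common %in% names(ic)]
  if (!length(common)) return(0)
  max(ic[common])
}

#' Functional similarity between two genes
#'
#' Aggregates term-level Resnik similarities across the two genes'
#' annotation sets: either the maximum over all cross pairs (default) or the
#' best-match average (mean of each term's best match in the other gene,
#' averaged over both directions).
#'
#' @param g1,g2 Gene symbols.
#' @param annotations Named list gene -> term ids.
#' @param ont An [ontology()] object.
#' @param ic Information content table.
#' @param method `"max"` (default) or `"bma"`.
#' @return Nonnegative number, or `NA_real_` when either gene is unannotated
#'   (such pairs are excluded from the similarity curve, not scored 0).
#' @export
gene_similarity <- function(g1, g2, annotations, ont, ic,
                            method = c("max", "bma")) {
  method <- match.arg(method)
  t1 <- unique(as.character(annotations[[g1]]))
  t2 <- unique(as.character(annotations[[g2]]))
  t1 <- t1[t1 %in% ont$terms]
  t2 <- t2[t2 %in% ont$terms]
  if (!length(t1) || !length(t2)) return(NA_real_)
  sim <- outer(t1, t2, Vectorize(function(a, b) resnik_similarity(a, b, ont, ic)))
  if (method == "max") {
    max(sim)
  } else {
    (mean(apply(sim, 1L, max)) + mean(apply(sim, 2L, max))) / 2
  }
}

#' Bin gene-pair similarities by co-expression level
#'
#' Assigns each gene pair to a fixed-width correlation bin spanning
#' \[-1, 1\] and averages the functional similarity within each bin. Bins are
#' left-open, right-closed; the lowest bin is closed on both ends. Pairs with
#' missing similarity (unannotated genes) are excluded; empty bins report
#' `NA` means.
#'
#' @param correlations Numeric vector of pairwise correlations in \[-1, 1\].
#' @param similarities Numeric vector of the same length; `NA` = unscorable.
#' @param bin_width Bin width (default 0.1).
#' @return Data frame of class `"similarity_curve"` with columns `bin_low`,
#'   `bin_high`, `mid`, `n`, `mean_similarity`. `sum(n)` equals the number of
#'   scored pairs.
#' @export
similarity_curve <- function(correlations, similarities, bin_width = 0.1) {
  stopifnot(length(correlations) == length(similarities),
            bin_width > 0, bin_width <= 2)
  if (any(!is.na(correlations) & abs(correlations) > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]")
  keep <- !is.na(correlations) & !is.na(similarities)
  r <- pmin(pmax(correlations[keep], -1), 1)
  s <- similarities[keep]
  breaks <- seq(-1, 1, by = bin_width)
  if (abs(breaks[length(breaks)] - 1) > 1e-9) breaks <- c(breaks, 1)
  bin <- cut(r, breaks = breaks, include.lowest = TRUE, right = TRUE)
  n <- as.integer(table(bin))
  means <- rep(NA_real_, length(levels(bin)))
  got <- tapply(s, bin, mean)
  means[match(names(got), levels(bin))] <- as.numeric(got)
  out <- data.frame(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1L],
    mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
    n = n,
    mean_similarity = means
  )
  class(out) <- c("similarity_curve", "data.frame")
  out
}

#' Correlation-vs-functional-similarity curve for an expression matrix
#'
#' Convenience wrapper: computes all pairwise Pearson correlations, scores
#' every pair of annotated genes with [gene_similarity()], and bins the
#' result with [similarity_curve()]. A sharp rise of the curve marks
#' correlation levels that are biologically meaningful; candidate thresholds
#' from [threshold_candidates()] are usually judged against it.
#'
#' @param expr Standardized gene x sample matrix.
#' @param annotations Named list gene -> term ids.
#' @param ont An [ontology()] object.
#' @param ic Information content table; computed from `annotations` when
#'   `NULL`.
#' @param method Aggregation passed to [gene_similarity()].
#' @param max_pairs Randomly subsample at most this many annotated gene pairs
#'   (`Inf` to disable); sampling uses the current RNG state.
#' @param bin_width Passed to [similarity_curve()].
#' @return A `"similarity_curve"` data frame.
#' @export
functional_similarity_curve <- function(expr, annotations, ont, ic = NULL,
                                        method = c("max", "bma"),
                                        max_pairs = 50000L, bin_width = 0.1) {
  method <- match.arg(method)
  stopifnot(is_standardized(expr))
  if (is.null(ic)) ic <- compute_ic(ont, annotations)
  genes <- intersect(rownames(expr), names(annotations))
  genes <- genes[vapply(annotations[genes],
                        function(t) any(t %in% ont$terms), logical(1))]
  if (length(genes) < 2L) stop("need at least two annotated genes")
  pairs <- utils::combn(genes, 2L)
  if (ncol(pairs) > max_pairs) {
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  sub <- expr[genes, , drop = FALSE]
  attr(sub, "standardized") <- TRUE  # row subsetting drops attributes
  corr <- pairwise_correlations(sub)
  r <- corr[cbind(pairs[1L, ], pairs[2L, ])]
  s <- vapply(seq_len(ncol(pairs)), function(i) {
    gene_similarity(pairs[1L, i], pairs[2L, i], annotations, ont, ic,
                    method = method)
  }, numeric(1))
  similarity_curve(r, s, bin_width = bin_width)
}
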