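# Hypergeometric over-representation of modules against gene-set
# collections (GO, transcription-factor targets, positional sets).

#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (member gene symbols);
#'   duplicates within a set are removed, empty sets rejected.
#' @param descriptions Optional named character vector of set descriptions.
#' @param source Source tag, e.g. `"GO"`, `"TFBS"`, `"positional"`,
#'   `"custom"`.
#' @return Object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source = "custom") {
  stopifnot(is.list(sets))
  if (length(sets) && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stop("sets must be uniquely named")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty gene set")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
  }
  structure(list(sets = sets, descriptions = descriptions, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection [%s]: %d sets, median size %g\n",
              x$source, length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else 0))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' One set per line: set id, description, then member genes, tab-separated
#' (the MSigDB format). Duplicate members within a set are removed.
#'
#' @param path GMT file path.
#' @param source Source tag recorded on the collection.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source = "custom") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(gene_set_collection(stats::setNames(list(), character(0)),
                               source = source))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: need id, description and >= 1 gene",
                 bad[1L]))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate set id: %s", ids[duplicated(ids)][1L]))
  desc <- stats::setNames(vapply(parts, `[[`, character(1), 2L), ids)
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  gene_set_collection(sets, desc, source = source)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Merge binding-motif gene sets per transcription factor
#'
#' Motif-organized target sets (as distributed for TFBS collections) are
#' merged into one set per transcription factor by taking the union of the
#' member genes of all motifs mapping to that factor. Motif sets with no
#' known factor are dropped.
#'
#' @param collection Motif-keyed [gene_set_collection()].
#' @param motif_to_tf Mapping motif id -> transcription factor: a named
#'   character vector or a two-column data frame (motif, tf); a motif may map
#'   to several factors via duplicate rows.
#' @return A `gene_set_collection` keyed by transcription factor
#'   (source `"TFBS"`).
#' @export
merge_motif_sets <- function(collection, motif_to_tf) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.data.frame(motif_to_tf)) {
    map <- data.frame(motif = as.character(motif_to_tf[[1L]]),
                      tf = as.character(motif_to_tf[[2L]]),
                      stringsAsFactors = FALSE)
  } else if (is.character(motif_to_tf) && !is.null(names(motif_to_tf))) {
    map <- data.frame(motif = names(motif_to_tf), tf = unname(motif_to_tf),
                      stringsAsFactors = FALSE)
  } else {
    stop("motif_to_tf must be a named character vector or two-column data frame")
  }
  map <- unique(map[map$motif %in% names(collection$sets) &
                      !is.na(map$tf) & nzchar(map$tf), , drop = FALSE])
  if (!nrow(map))
    return(gene_set_collection(stats::setNames(list(), character(0)),
                               source = "TFBS"))
  sets <- lapply(split(map$motif, map$tf), function(motifs) {
    unique(unlist(collection$sets[motifs], use.names = FALSE))
  })
  gene_set_collection(sets, source = "TFBS")
}

.check_hyper_params <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("N, K, n, k must be nonnegative integers")
  if (K > N || n > N) stop("K and n cannot exceed N")
  if (k > min(n, K)) stop("k cannot exceed min(n, K)")
  invisible(NULL)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` when `n` genes are drawn without replacement from a reference
#' of `N` genes of which `K` belong to the category — the over-representation
#' p-value for an overlap of `k`.
#'
#' @param N Reference (platform) gene count.
#' @param K Category size within the reference.
#' @param n Module size within the reference.
#' @param k Observed overlap.
#' @return Probability in (0, 1].
#' @examples
#' hypergeom_tail(N = 10, K = 5, n = 4, k = 4)  # 5 / 210
#' @export
hypergeom_tail <- function(N, K, n, k) {
  .check_hyper_params(N, K, n, k)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Expected overlap under random draws
#'
#' Expected number of category members among `n` genes drawn from a
#' reference of `N` genes containing `K` category members: `n * K / N`.
#'
#' @inheritParams hypergeom_tail
#' @return Nonnegative number.
#' @examples
#' expected_overlap(N = 19803, K = 144, n = 13)  # about 0.09
#' @export
expected_overlap <- function(N, K, n) {
  if (N <= 0) stop("N must be positive")
  if (K < 0 || n < 0 || K > N || n > N) stop("require 0 <= K, n <= N")
  n * K / N
}

#' Over-representation of a module against a gene-set collection
#'
#' Hypergeometric upper-tail test of the module against every set it
#' overlaps, with Bonferroni adjustment. The reference is the full gene
#' universe of the platform (all genes after preprocessing); module genes
#' outside it are dropped with a warning and every set is intersected with
#' it.
#'
#' @param module Character vector of module gene symbols.
#' @param collection A [gene_set_collection()].
#' @param reference Character vector: the reference gene universe.
#' @param adjust_by Bonferroni family: `"tested"` (default; the sets with
#'   nonzero overlap actually tested for this module) or `"all"` (every
#'   nonempty set in the collection after intersection with the reference).
#' @param alpha Significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @return Data frame sorted by p: `set`, `description`, `N`, `K`, `n`, `k`,
#'   `expected`, `p`, `p_adj`, `significant`. Zero rows when the module
#'   overlaps no set.
#' @export
enrich_module <- function(module, collection, reference,
                          adjust_by = c("tested", "all"), alpha = 0.05) {
  adjust_by <- match.arg(adjust_by)
  stopifnot(inherits(collection, "gene_set_collection"))
  reference <- unique(as.character(reference))
  if (!length(reference)) stop("empty reference gene universe")
  module <- unique(as.character(module))
  outside <- setdiff(module, reference)
  if (length(outside)) {
    warning(sprintf("dropped %d module gene(s) outside the reference",
                    length(outside)))
    module <- intersect(module, reference)
  }
  if (!length(module)) stop("no module gene inside the reference")
  sets <- lapply(collection$sets, intersect, reference)
  sets <- sets[lengths(sets) > 0L]
  N <- length(reference)
  n <- length(module)
  k <- vapply(sets, function(s) length(intersect(module, s)), integer(1))
  tested <- which(k >= 1L)
  n_family <- if (adjust_by == "all") length(sets) else length(tested)
  rows <- lapply(tested, function(i) {
    K <- length(sets[[i]])
    data.frame(set = names(sets)[i],
               description = unname(collection$descriptions[names(sets)[i]]),
               N = N, K = K, n = n, k = k[i],
               expected = expected_overlap(N, K, n),
               p = hypergeom_tail(N, K, n, k[i]),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    out <- data.frame(set = character(0), description = character(0),
                      N = integer(0), K = integer(0), n = integer(0),
                      k = integer(0), expected = numeric(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * n_family)
  out$significant <- out$p_adj < alpha
  out[order(out$p, out$set), , drop = FALSE]
}
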