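#' Iterative clique enumeration of co-expression modules
#'
#' Decomposes a graph into relatively independent maximal cliques. At each
#' iteration the maximum clique of the current residual graph is found (the
#' module "core"), expanded to the largest maximal clique of the *original*
#' graph containing it (the module), and the module's vertices are removed
#' from the residual graph. Iteration stops when the residual maximum clique
#' has fewer than `c_min` vertices. Because each core lives in the residual
#' graph, every module contributes at least `c_min` vertices not seen in any
#' earlier module, while the expansion step still allows restrained overlap
#' between modules.
#'
#' A module is emitted only when its core has at least `c_min` vertices, so
#' `c_min` is a uniform contract on all output (including the first module).
#' All clique searches are exact and deterministically tie-broken
#' (see [maximum_clique()]), so the output is reproducible bit for bit and
#' invariant to the order in which vertices or edges were added to the graph.
#'
#' @param g Undirected [igraph][igraph::graph] object; vertex names are used
#'   as gene identifiers.
#' @param c_min Minimum core clique size for a module to be emitted
#'   (default 10, the conventional choice for genome-scale co-expression
#'   networks).
#' @return An object of class `"ice_result"`: a list with elements
#'   \describe{
#'     \item{modules}{list of modules, each a list with `core` and `expanded`
#'       character vectors of vertex names (label-sorted), `core` a subset of
#'       `expanded`;}
#'     \item{c_min}{the threshold used;}
#'     \item{residual_max_clique}{integer vector of residual maximum-clique
#'       sizes observed at each iteration (the last entry is the one that
#'       fell below `c_min`, unless the residual graph emptied first).}
#'   }
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' ice(g, c_min = 3)
#' @export
ice <- function(g, c_min = 10L) {
  c_min <- as.integer(c_min)
  stopifnot(length(c_min) == 1L, c_min >= 1L)
  cg <- .as_cgraph(g)
  active <- rep(TRUE, cg$n)
  modules <- list()
  residual_sizes <- integer(0)
  repeat {
    vs <- which(active)
    if (!length(vs)) break
    adj_res <- lapply(cg$adj, function(x) x[active[x]])
    raw <- .max_clique_idx(adj_res, vs)
    residual_sizes <- c(residual_sizes, length(raw))
    if (length(raw) < c_min) break
    core <- .lex_min_clique(adj_res, length(raw), vs)
    # expansion works in the original graph
    cand <- setdiff(Reduce(intersect, cg$adj[core]), core)
    exp_idx <- core
    if (length(cand)) {
      raw2 <- .max_clique_idx(cg$adj, cand)
      if (length(raw2)) {
        exp_idx <- c(core, .lex_min_clique(cg$adj, length(raw2), cand))
      }
    }
    exp_idx <- sort.int(exp_idx)
    modules[[length(modules) + 1L]] <- list(
      core = cg$labels[sort.int(core)],
      expanded = cg$labels[exp_idx]
    )
    active[exp_idx] <- FALSE
  }
  names(modules) <- if (length(modules)) {
    sprintf("module_%d", seq_along(modules))
  } else {
    character(0)
  }
  structure(
    list(modules = modules, c_min = c_min,
         residual_max_clique = residual_sizes),
    class = "ice_result"
  )
}

#' @export
print.ice_result <- function(x, ...) {
  cat(sprintf("Iterative clique enumeration: %d module(s), c_min = %d\n",
              length(x$modules), x$c_min))
  if (length(x$modules)) {
    cs <- vapply(x$modules, function(m) length(m$core), integer(1))
    es <- vapply(x$modules, function(m) length(m$expanded), integer(1))
    cat(sprintf("  core sizes:     %s\n", paste(cs, collapse = " ")))
    cat(sprintf("  expanded sizes: %s\n", paste(es, collapse = " ")))
  }
  invisible(x)
}

#' @export
summary.ice_result <- function(object, ...) {
  mods <- object$modules
  df <- data.frame(
    module = names(mods),
    core_size = vapply(mods, function(m) length(m$core), integer(1)),
    expanded_size = vapply(mods, function(m) length(m$expanded), integer(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    seen <- character(0)
    df$new_genes <- NA_integer_
    for (i in seq_len(nrow(df))) {
      df$new_genes[i] <- length(setdiff(mods[[i]]$expanded, seen))
      seen <- union(seen, mods[[i]]$expanded)
    }
  }
  df
}

#' Tabulate an ice_result as one row per module gene
#'
#' @param x An `"ice_result"`.
#' @param ... Unused.
#' @return A data frame with columns `module`, `gene`, `in_core`.
#' @export
as.data.frame.ice_result <- function(x, ...) {
  if (!length(x$modules)) {
    return(data.frame(module = character(0), gene = character(0),
                      in_core = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(names(x$modules), function(nm) {
    m <- x$modules[[nm]]
    data.frame(module = nm, gene = m$expanded,
               in_core = m$expanded %in% m$core,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Extract module gene sets from a module result
#'
#' @param x An `"ice_result"` or `"ice_fit"` object.
#' @param which `"expanded"` (default) or `"core"`.
#' @return Named list of character vectors of gene names.
#' @export
module_genes <- function(x, which = c("expanded", "core")) {
  which <- match.arg(which)
  if (inherits(x, "ice_fit")) x <- x$result
  stopifnot(inherits(x, "ice_result"))
  lapply(x$modules, `[[`, which)
}
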