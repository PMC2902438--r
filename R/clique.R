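# Exact clique search used by the iterative module enumeration.
#
# Internal graph representation: vertices are re-indexed 1..n in sorted label
# order (radix/C-locale sort), so "lexicographically smallest clique" becomes
# "smallest index vector". Adjacency is a list of sorted integer vectors.

.as_cgraph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) stop("graph must be undirected")
  g <- igraph::simplify(g)
  n <- igraph::vcount(g)
  labs <- if ("name" %in% igraph::vertex_attr_names(g)) {
    as.character(igraph::V(g)$name)
  } else {
    # unnamed graphs: keep numeric vertex order, label by id
    NULL
  }
  perm <- if (is.null(labs)) seq_len(n) else order(labs, method = "radix")
  rank <- integer(n)
  rank[perm] <- seq_len(n)
  adj <- rep(list(integer(0)), n)
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g, names = FALSE)
    a <- rank[el[, 1L]]
    b <- rank[el[, 2L]]
    adj <- split(c(b, a), factor(c(a, b), levels = seq_len(n)))
    adj <- lapply(adj, function(v) sort.int(unique(v)))
  }
  list(
    n = n,
    adj = adj,
    labels = if (is.null(labs)) as.character(seq_len(n)) else labs[perm]
  )
}

# Greedy sequential coloring of candidate set P (in the order given).
# Returns P reordered by color class together with the color number of each
# position; the color number is an upper bound on the clique size within the
# prefix ending at that position.
.color_sort <- function(adj, P) {
  np <- length(P)
  ord <- integer(np)
  bnd <- integer(np)
  pos <- 0L
  k <- 0L
  remaining <- P
  while (length(remaining)) {
    k <- k + 1L
    avail <- remaining
    cls <- integer(0)
    while (length(avail)) {
      v <- avail[1L]
      cls <- c(cls, v)
      avail <- avail[-1L]
      if (length(avail)) avail <- avail[!(avail %in% adj[[v]])]
    }
    idx <- pos + seq_along(cls)
    ord[idx] <- cls
    bnd[idx] <- k
    pos <- pos + length(cls)
    remaining <- remaining[!(remaining %in% cls)]
  }
  list(order = ord, bound = bnd)
}

# Branch-and-bound maximum clique (Tomita-style MCQ) over the subgraph induced
# on `cand`. If `target` is finite the search stops as soon as a clique of at
# least `target` vertices is found (decision mode). Returns one maximum clique
# as an integer vector (not necessarily the lexicographically smallest).
.max_clique_idx <- function(adj, cand = seq_along(adj), target = Inf) {
  best <- integer(0)
  if (!length(cand)) return(best)
  deg <- vapply(cand, function(v) sum(adj[[v]] %in% cand), integer(1))
  P0 <- cand[order(-deg, cand)]
  expand <- function(C, P) {
    cs <- .color_sort(adj, P)
    ord <- cs$order
    bnd <- cs$bound
    for (i in rev(seq_along(ord))) {
      if (length(best) >= target) return(invisible(NULL))
      if (length(C) + bnd[i] <= length(best)) return(invisible(NULL))
      v <- ord[i]
      P2 <- ord[seq_len(i - 1L)]
      if (length(P2)) P2 <- P2[P2 %in% adj[[v]]]
      C2 <- c(C, v)
      if (length(P2)) {
        expand(C2, P2)
      } else if (length(C2) > length(best)) {
        best <<- C2
      }
    }
    invisible(NULL)
  }
  expand(integer(0), P0)
  best
}

# Lexicographically smallest clique of size `omega` within `P0`
# (existence of such a clique is assumed). Greedy: pick the smallest vertex
# that can still be completed to a clique of the required size.
.lex_min_clique <- function(adj, omega, P0 = seq_along(adj)) {
  chosen <- integer(0)
  P <- sort.int(P0)
  while (length(chosen) < omega) {
    need <- omega - length(chosen)
    found <- FALSE
    for (v in P) {
      if (need == 1L) {
        chosen <- c(chosen, v)
        found <- TRUE
        break
      }
      cand <- adj[[v]]
      cand <- cand[cand > v]
      cand <- cand[cand %in% P]
      if (length(cand) >= need - 1L &&
          length(.max_clique_idx(adj, cand, target = need - 1L)) >= need - 1L) {
        chosen <- c(chosen, v)
        P <- cand
        found <- TRUE
        break
      }
    }
    if (!found) stop("internal error: clique completion failed") # nocov
  }
  chosen
}

.is_clique <- function(adj, idx) {
  if (length(idx) < 2L) return(TRUE)
  for (i in seq_len(length(idx) - 1L)) {
    rest <- idx[(i + 1L):length(idx)]
    if (!all(rest %in% adj[[idx[i]]])) return(FALSE)
  }
  TRUE
}

#' Exact maximum clique of a graph
#'
#' Finds a maximum clique by branch and bound with greedy-coloring upper
#' bounds, then refines the answer to the clique whose sorted vertex-label
#' sequence is lexicographically smallest among all maximum cliques, so the
#' result is deterministic for a given graph.
#'
#' @param g An undirected [igraph][igraph::graph] object. Vertex names are
#'   used as labels for the tie-break; unnamed graphs break ties by vertex id.
#' @return Character vector of vertex names forming a maximum clique, in
#'   label-sorted order. The empty graph yields `character(0)`.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' maximum_clique(g)
#' @seealso [expand_to_largest_maximal()], [ice()]
#' @export
maximum_clique <- function(g) {
  cg <- .as_cgraph(g)
  if (cg$n == 0L) return(character(0))
  raw <- .max_clique_idx(cg$adj)
  lex <- .lex_min_clique(cg$adj, length(raw))
  cg$labels[lex]
}

#' Expand a clique to the largest maximal clique containing it
#'
#' Given a clique `core` of `g`, returns the largest maximal clique of `g`
#' that contains it: the core plus a maximum clique of the subgraph induced
#' on the common neighbors of all core vertices. Ties are broken as in
#' [maximum_clique()].
#'
#' @param g An undirected igraph object with vertex names.
#' @param core Character vector of vertex names forming a clique in `g`.
#' @return Character vector of vertex names (label-sorted), a superset of
#'   `core`, maximal in `g`.
#' @export
expand_to_largest_maximal <- function(g, core) {
  cg <- .as_cgraph(g)
  idx <- match(as.character(core), cg$labels)
  if (anyNA(idx)) stop("core contains vertices absent from the graph")
  if (anyDuplicated(idx)) stop("core contains duplicate vertices")
  if (!.is_clique(cg$adj, idx)) stop("core is not a clique in the graph")
  if (!length(idx)) stop("core must contain at least one vertex")
  cand <- Reduce(intersect, cg$adj[idx])
  cand <- setdiff(cand, idx)
  if (length(cand)) {
    raw <- .max_clique_idx(cg$adj, cand)
    if (length(raw)) {
      add <- .lex_min_clique(cg$adj, length(raw), cand)
      idx <- c(idx, add)
    }
  }
  cg$labels[sort.int(idx)]
}
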