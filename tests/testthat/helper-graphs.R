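# Graph fixtures built in code.

named_graph <- function(...) {
  edges <- rbind(...)
  igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
}

# Disjoint union of complete graphs; labels c<i>n<j>.
clique_union <- function(sizes) {
  el <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    labs <- sprintf("c%dn%02d", i, seq_len(sizes[i]))
    t(utils::combn(labs, 2L))
  }))
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}

# Two complete graphs sharing `overlap` vertices: a K_n1 on a01.. and a K_n2
# whose first `overlap` vertices are the last `overlap` vertices of the K_n1.
overlapping_cliques <- function(n1, n2, overlap) {
  a <- sprintf("a%02d", seq_len(n1))
  shared <- a[(n1 - overlap + 1L):n1]
  b <- c(shared, sprintf("b%02d", seq_len(n2 - overlap)))
  el <- rbind(t(utils::combn(a, 2L)), t(utils::combn(b, 2L)))
  igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
}

# Toy ontology root -> A -> B with 10 annotated genes, 2 of them on B.
toy_dag <- function() {
  ont <- icemod::ontology(list(root = character(0), A = "root", B = "A"))
  ann <- c(
    stats::setNames(rep(list("B"), 2), sprintf("gB%d", 1:2)),
    stats::setNames(rep(list("root"), 8), sprintf("gR%d", 1:8))
  )
  list(ont = ont, ann = ann)
}
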