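test_that("information content follows annotation propagation on a toy DAG", {
  toy <- toy_dag()
  ic <- compute_ic(toy$ont, toy$ann)
  # 2 of 10 genes reach A only via B; count(A) includes descendants
  expect_equal(unname(ic["root"]), 0)
  expect_equal(unname(ic["A"]), -log(0.2), tolerance = 1e-12)
  expect_equal(unname(ic["B"]), -log(0.2), tolerance = 1e-12)

  # terms with no annotated gene (even via descendants) are excluded
  ont2 <- ontology(list(root = character(0), A = "root", B = "A",
                        lonely = "root"))
  ic2 <- compute_ic(ont2, toy$ann)
  expect_false("lonely" %in% names(ic2))

  # annotations to unknown terms are skipped with a warning
  ann3 <- c(toy$ann, list(gX = "not_a_term"))
  expect_warning(ic3 <- compute_ic(toy$ont, ann3), "absent")
  expect_equal(ic3, ic)
})

test_that("information content is monotone non-decreasing from parent to child", {
  set.seed(3)
  for (rep in 1:5) {
    # random rooted DAG on 15 terms: parents drawn among earlier terms
    terms <- sprintf("t%02d", 1:15)
    parents <- list(t01 = character(0))
    for (i in 2:15) {
      parents[[terms[i]]] <- sample(terms[seq_len(i - 1)],
                                    size = sample(1:min(2, i - 1), 1))
    }
    ont <- ontology(parents)
    ann <- lapply(1:20, function(g) sample(terms, sample(1:3, 1)))
    names(ann) <- sprintf("g%02d", 1:20)
    ic <- compute_ic(ont, ann)
    for (t in names(ic)) {
      for (p in ont$parents[[t]]) {
        if (p %in% names(ic)) expect_gte(ic[[t]], ic[[p]] - 1e-12)
      }
    }
  }
})

test_that("Resnik term similarity is the IC of the best common ancestor", {
  toy <- toy_dag()
  ic <- compute_ic(toy$ont, toy$ann)
  expect_equal(resnik_similarity("B", "B", toy$ont, ic), unname(ic["B"]))
  expect_equal(resnik_similarity("B", "A", toy$ont, ic), unname(ic["A"]))
  expect_equal(resnik_similarity("A", "B", toy$ont, ic),
               resnik_similarity("B", "A", toy$ont, ic))
  # siblings whose only common ancestor is the root score 0
  ont <- ontology(list(root = character(0), A = "root", B = "root"))
  ann <- list(g1 = "A", g2 = "B", g3 = "root")
  ic2 <- compute_ic(ont, ann)
  expect_equal(resnik_similarity("A", "B", ont, ic2), 0)
  expect_error(resnik_similarity("A", "nope", ont, ic2), "present")
})

test_that("gene-level similarity aggregates term pairs and stays symmetric", {
  toy <- toy_dag()
  ic <- compute_ic(toy$ont, toy$ann)
  ann <- list(g1 = "B", g2 = c("A", "B"), g3 = "B", unannot = character(0))
  # max over cross pairs {sim(B,A), sim(B,B)} = ic(B)
  expect_equal(gene_similarity("g1", "g2", ann, toy$ont, ic),
               unname(ic["B"]))
  expect_equal(gene_similarity("g1", "g3", ann, toy$ont, ic),
               unname(ic["B"]))
  expect_equal(gene_similarity("g2", "g1", ann, toy$ont, ic),
               gene_similarity("g1", "g2", ann, toy$ont, ic))
  expect_true(is.na(gene_similarity("g1", "unannot", ann, toy$ont, ic)))
  # adding an annotation cannot decrease max-aggregated similarity
  ann2 <- ann
  ann2$g1 <- c("B", "A")
  expect_gte(gene_similarity("g1", "g2", ann2, toy$ont, ic),
             gene_similarity("g1", "g2", ann, toy$ont, ic))
  # best-match average of identical single annotations equals ic(t)
  expect_equal(gene_similarity("g1", "g3", ann, toy$ont, ic, method = "bma"),
               unname(ic["B"]))
})

test_that("similarity curve bins pairs into 0.1 intervals, right-closed", {
  # all pairs in one bin
  bin_at <- function(curve, low) which.min(abs(curve$bin_low - low))
  curve <- similarity_curve(c(0.55, 0.57, 0.60), c(1, 2, 3))
  row <- curve[bin_at(curve, 0.5), ]
  expect_equal(row$n, 3L)
  expect_equal(row$mean_similarity, 2)
  expect_equal(sum(curve$n), 3L)
  # a correlation exactly on an edge goes to the bin it closes (right-closed)
  c2 <- similarity_curve(c(0.5), c(7))
  expect_equal(c2$n[bin_at(c2, 0.4)], 1L)
  expect_equal(c2$n[bin_at(c2, 0.5)], 0L)
  # -1 belongs to the lowest bin, which is closed on both ends
  c3 <- similarity_curve(c(-1), c(1))
  expect_equal(c3$n[1], 1L)
  # unscorable pairs are excluded, empty bins report NA
  c4 <- similarity_curve(c(0.1, 0.9), c(NA, 5))
  expect_equal(sum(c4$n), 1L)
  expect_true(is.na(c4$mean_similarity[which.min(abs(c4$bin_low - 0))]))
})

test_that("when similarity equals correlation the curve tracks bin midpoints", {
  set.seed(5)
  r <- runif(4000, -1, 1)
  curve <- similarity_curve(r, r)
  ok <- !is.na(curve$mean_similarity)
  expect_true(all(abs(curve$mean_similarity[ok] - curve$mid[ok]) <= 0.05 + 1e-9))
  expect_true(all(curve$mean_similarity[ok] > curve$bin_low[ok] - 1e-9))
  expect_true(all(curve$mean_similarity[ok] <= curve$bin_high[ok] + 1e-9))
})

test_that("OBO and annotation parsers handle namespaces, obsoletes and GAF", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0008150",
    "name: biological_process",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: child process",
    "namespace: biological_process",
    "is_a: GO:0008150 ! biological_process",
    "",
    "[Term]",
    "id: GO:0005575",
    "name: cellular_component",
    "namespace: cellular_component",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: gone",
    "namespace: biological_process",
    "is_obsolete: true",
    "is_a: GO:0008150",
    "",
    "[Typedef]",
    "id: part_of"
  ), obo)
  ont <- read_obo(obo)
  expect_setequal(ont$terms, c("GO:0008150", "GO:0000001"))
  expect_equal(ont$root, "GO:0008150")

  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.1",
    paste("DB", "X1", "TP53", "", "GO:0000001", "ref", "IEA", "", "P",
          sep = "\t"),
    paste("DB", "X2", "TP53", "", "GO:0008150", "ref", "IEA", "", "P",
          sep = "\t"),
    paste("DB", "X3", "BRCA1", "", "GO:0000001", "ref", "IEA", "", "P",
          sep = "\t")
  ), gaf)
  ann <- read_annotations(gaf)
  expect_setequal(names(ann), c("TP53", "BRCA1"))
  expect_setequal(ann$TP53, c("GO:0000001", "GO:0008150"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TP53\tGO:0000001", "BRCA1\tGO:0008150"), tsv)
  ann2 <- read_annotations(tsv)
  expect_equal(ann2$TP53, "GO:0000001")
})

test_that("cyclic or multi-root term graphs are rejected", {
  expect_error(ontology(list(a = "b", b = "a")), "root")
  expect_error(ontology(list(root = character(0), a = c("root", "b"),
                             b = "a")), "cycle")
  expect_error(ontology(list(r1 = character(0), r2 = character(0))),
               "exactly one root")
})

test_that("the expression-level similarity curve wrapper scores annotated pairs only", {
  toy <- toy_dag()
  ic <- compute_ic(toy$ont, toy$ann)
  set.seed(9)
  expr <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(c("g1", "g2", "g3", "g4", "g5"),
                                 sprintf("s%02d", 1:12)))
  expr <- standardize_expression(expr)
  ann <- list(g1 = "B", g2 = "A", g3 = "B", g4 = "root")
  curve <- functional_similarity_curve(expr, ann, toy$ont, ic)
  expect_equal(sum(curve$n), choose(4, 2))  # g5 unannotated: excluded
  expect_s3_class(curve, "similarity_curve")
})
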