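test_that("GMT reading deduplicates members and validates lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc one\tA\tB\tB",
               "S2\tdesc two\tB\tC"), f)
  col <- read_gmt(f, source = "GO")
  expect_length(col, 2L)
  expect_setequal(col$sets$S1, c("A", "B"))
  expect_setequal(col$sets$S2, c("B", "C"))  # shared genes kept in both sets
  expect_equal(unname(col$descriptions["S1"]), "desc one")
  expect_equal(col$source, "GO")

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_length(read_gmt(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA", "S2\tonly-description"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("GMT reader agrees with an independent reader on well-formed files", {
  skip_if_not_installed("fgsea")
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("alpha\td\tg1\tg2\tg3", "beta\td\tg2\tg4"), f)
  ours <- read_gmt(f)
  theirs <- fgsea::gmtPathways(f)
  expect_setequal(names(ours$sets), names(theirs))
  for (nm in names(theirs)) expect_setequal(ours$sets[[nm]], theirs[[nm]])
})

test_that("motif sets merge per transcription factor; unmapped motifs drop", {
  col <- gene_set_collection(list(M1 = c("A", "B"), M2 = c("B", "C"),
                                  M3 = c("D")))
  merged <- merge_motif_sets(col, c(M1 = "TFX", M2 = "TFX"))
  expect_length(merged, 1L)
  expect_setequal(merged$sets$TFX, c("A", "B", "C"))
  expect_equal(merged$source, "TFBS")
  # one-to-one mapping renames without changing contents
  ren <- merge_motif_sets(col, c(M1 = "F1", M2 = "F2", M3 = "F3"))
  expect_setequal(ren$sets$F1, c("A", "B"))
  expect_setequal(ren$sets$F3, "D")
  # data frame mapping allows one motif -> several factors
  multi <- merge_motif_sets(col, data.frame(motif = c("M1", "M1"),
                                            tf = c("F1", "F2")))
  expect_setequal(names(multi$sets), c("F1", "F2"))
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_tail(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 5, 4, 0), 1)
  set.seed(19)
  for (rep in 1:8) {
    N <- sample(6:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_tail(N, K, n, k), hyper_tail_enum(N, K, n, k),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_tail(10, 11, 4, 2), "exceed")
  expect_error(hypergeom_tail(10, 5, 4, 5), "exceed")
})

test_that("hypergeometric tail matches a log-gamma oracle, also for extreme tails", {
  set.seed(29)
  for (rep in 1:20) {
    N <- sample(50:5000, 1)
    K <- sample(1:(N %/% 2), 1)
    n <- sample(1:(N %/% 2), 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_tail(N, K, n, k), hyper_tail_lgamma(N, K, n, k),
                 tolerance = 1e-10)
  }
  # the full-overlap regional case: a single-term tail far below double eps
  p <- hypergeom_tail(19803, 144, 13, 13)
  expect_equal(p, exp(lchoose(144, 13) - lchoose(19803, 13)),
               tolerance = 1e-10)
  expect_equal(p, hyper_tail_lgamma(19803, 144, 13, 13), tolerance = 1e-10)
})

test_that("tail probabilities are monotone in k, symmetric in n and K, and the pmf sums to 1", {
  set.seed(31)
  for (rep in 1:25) {
    N <- sample(20:400, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    ks <- 0:min(n, K)
    tails <- vapply(ks, function(k) hypergeom_tail(N, K, n, k), numeric(1))
    expect_true(all(diff(tails) <= 1e-12))
    k <- sample(ks, 1)
    expect_equal(hypergeom_tail(N, K, n, k), hypergeom_tail(N, n, K, k),
                 tolerance = 1e-12)
    pmf_sum <- sum(dhyper(max(0, n + K - N):min(n, K), K, N - K, n))
    expect_equal(pmf_sum, 1, tolerance = 1e-12)
  }
})

test_that("expected overlap is n*K/N", {
  expect_equal(expected_overlap(19803, 144, 13), 13 * 144 / 19803)
  expect_equal(round(expected_overlap(19803, 144, 13), 2), 0.09)
  expect_equal(expected_overlap(100, 0, 10), 0)
  expect_equal(expected_overlap(50, 12, 50), 12)  # whole population drawn
  expect_error(expected_overlap(0, 0, 0), "positive")
})

test_that("module enrichment tests overlapping sets with Bonferroni control", {
  ref <- sprintf("g%03d", 1:100)
  col <- gene_set_collection(list(
    hit = sprintf("g%03d", 1:20),
    other = sprintf("g%03d", 51:60),
    outside = c("x1", "x2")
  ))
  module <- sprintf("g%03d", c(1:8, 95, 96))
  res <- enrich_module(module, col, ref)
  expect_equal(res$set[1], "hit")
  expect_equal(res$k[res$set == "hit"], 8L)
  expect_equal(res$N[1], 100L)
  # "outside" has no member in the reference, "other" has zero overlap
  expect_false(any(c("other", "outside") %in% res$set))
  # family = sets actually tested (here 1); "all" multiplies by both nonzero sets
  res_all <- enrich_module(module, col, ref, adjust_by = "all")
  expect_equal(res_all$p_adj, pmin(1, res_all$p * 2))
  expect_equal(res$p_adj, pmin(1, res$p))
  # the enrichment p matches the tail function on its own parameters
  expect_equal(res$p[1], hypergeom_tail(100, 20, 10, 8), tolerance = 1e-12)
  expect_lt(res$p[1], 1e-4)
  expect_true(res$significant[1])
})

test_that("enrichment edge cases: forced overlap, disjoint module, reference filtering", {
  # module equal to the set with the set as reference: overlap is forced, p = 1
  ref <- sprintf("g%d", 1:12)
  col <- gene_set_collection(list(all = ref))
  res <- enrich_module(ref, col, ref)
  expect_equal(res$p, 1)
  expect_equal(res$expected, 12)
  # module disjoint from all sets: empty result
  col2 <- gene_set_collection(list(s = c("a", "b")))
  res2 <- enrich_module(c("g1", "g2"), col2, ref)
  expect_equal(nrow(res2), 0L)
  # module genes outside the reference are dropped with a warning
  expect_warning(res3 <- enrich_module(c("g1", "zzz"), col, ref), "dropped")
  expect_equal(res3$n, 1L)
  expect_error(enrich_module("g1", col, character(0)), "empty reference")
  expect_error(suppressWarnings(enrich_module("zzz", col, ref)), "no module gene")
})

test_that("planted enrichment matches the enumeration oracle on a scaled-down instance", {
  set.seed(41)
  ref <- sprintf("g%02d", 1:50)
  special <- ref[1:20]
  col <- gene_set_collection(list(special = special))
  module <- c(sample(special, 7), sample(setdiff(ref, special), 3))
  res <- enrich_module(module, col, ref)
  expect_equal(res$p, hyper_tail_lgamma(50, 20, 10, 7), tolerance = 1e-10)
  # and full brute force on a tiny instance of the same design
  ref2 <- sprintf("h%02d", 1:15)
  col2 <- gene_set_collection(list(special = ref2[1:6]))
  module2 <- c(ref2[1:4], ref2[14:15])
  res2 <- enrich_module(module2, col2, ref2)
  expect_equal(res2$p, hyper_tail_enum(15, 6, 6, 4), tolerance = 1e-12)
})

test_that("GMT round-trips through write_gmt", {
  col <- gene_set_collection(list(A = c("x", "y"), B = "z"),
                             c(A = "first", B = "second"), source = "GO")
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(col, f)
  back <- read_gmt(f, source = "GO")
  expect_equal(back$sets, col$sets)
  expect_equal(back$descriptions, col$descriptions)
})
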