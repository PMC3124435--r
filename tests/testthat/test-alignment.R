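test_that("a single-vertex graph aligns a single residue", {
  g <- make_patch_graph("A:1", NULL)
  al <- align_query_to_graph(g, "Y", NNK_MODEL, aa = c("A:1" = "Y"))
  expect_equal(al$raw_score, NNK_MODEL$matrix["Y", "Y"])
  expect_equal(al$path$vertex, "A:1")
  expect_equal(al$path$query_pos, 1L)
})

test_that("a chain graph spelling the query is matched along the diagonal", {
  keys <- paste0("A:", 49:53)
  g <- make_patch_graph(keys, cbind(1:4, 2:5))
  aa <- setNames(c("Y", "G", "V", "K", "N"), keys)
  al <- align_query_to_graph(g, "YGVKN", NNK_MODEL, aa = aa)
  diag_sum <- sum(diag(NNK_MODEL$matrix[aa, aa]))
  expect_equal(al$raw_score, diag_sum)
  # the recovered path is the contiguous surface segment 49..53
  expect_equal(al$path$vertex, keys)
  expect_equal(al$path$query_pos, 1:5)
})

test_that("an edgeless graph still aligns single residues", {
  g <- make_patch_graph(c("A:1", "A:2"), NULL)
  aa <- c("A:1" = "A", "A:2" = "A")
  al <- align_query_to_graph(g, "AA", NNK_MODEL, aa = aa)
  o <- brute_force_best_path(g, "AA", NNK_MODEL, aa = aa)
  expect_equal(al$raw_score, o$raw_score)
  # adjacency is impossible, so at most one vertex is matched
  expect_lte(sum(!is.na(al$path$vertex)), 1L)
})

test_that("dynamic programming equals the exhaustive oracle", {
  set.seed(202)
  for (i in 1:60) {
    g <- random_test_graph(sample(2:8, 1), runif(1, 0.2, 0.6))
    aa <- random_aa(g)
    q <- random_peptide(sample(3:6, 1))
    al <- align_query_to_graph(g, q, NNK_MODEL, aa = aa)
    o <- brute_force_best_path(g, q, NNK_MODEL, aa = aa)
    expect_equal(al$raw_score, o$raw_score)
    expect_gte(al$raw_score, 0)
    # the path reproduces its own score under the model
    expect_equal(rescore_alignment(al, NNK_MODEL, aa), al$raw_score)
  }
})

test_that("branch-and-bound never changes scores, only the work done", {
  set.seed(203)
  for (i in 1:40) {
    g <- random_test_graph(sample(3:9, 1), runif(1, 0.25, 0.6))
    aa <- random_aa(g)
    q <- random_peptide(sample(3:6, 1))
    a_bb <- align_query_to_graph(g, q, NNK_MODEL, use_bb = TRUE, aa = aa)
    a_nb <- align_query_to_graph(g, q, NNK_MODEL, use_bb = FALSE, aa = aa)
    expect_equal(a_bb$raw_score, a_nb$raw_score)
    expect_lte(a_bb$states_expanded, a_nb$states_expanded)
  }
})

test_that("the best score is invariant under vertex relabelling", {
  set.seed(204)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    g <- random_test_graph(n, 0.5)
    aa <- random_aa(g)
    q <- random_peptide(4)
    s1 <- align_query_to_graph(g, q, NNK_MODEL, aa = aa)$raw_score
    perm <- sample(n)
    keys2 <- g$vertices[perm]
    inv <- order(perm)
    e2 <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
    g2 <- make_patch_graph(keys2, e2)
    s2 <- align_query_to_graph(g2, q, NNK_MODEL, aa = aa)$raw_score
    expect_equal(s1, s2)
  }
})

test_that("a uniform positive shift of the matrix never lowers the best score", {
  set.seed(205)
  shifted <- NNK_MODEL
  shifted$matrix <- shifted$matrix + 3
  for (i in 1:10) {
    g <- random_test_graph(6, 0.5)
    aa <- random_aa(g)
    q <- random_peptide(4)
    s0 <- align_query_to_graph(g, q, NNK_MODEL, aa = aa)$raw_score
    s1 <- align_query_to_graph(g, q, shifted, aa = aa)$raw_score
    expect_gte(s1, s0)
  }
})

test_that("the pruning bound is admissible", {
  expect_equal(bb_upper_bound(7.5, 0, NNK_MODEL), 7.5)
  expect_equal(bb_upper_bound(2, 3, NNK_MODEL), 2 + 3 * max(NNK_MODEL$matrix))
  set.seed(206)
  for (i in 1:10) {
    g <- random_test_graph(6, 0.5)
    aa <- random_aa(g)
    q <- random_peptide(4)
    best <- brute_force_best_path(g, q, NNK_MODEL, aa = aa)$raw_score
    # from the empty state (score 0, all query remaining) the bound must
    # dominate the best full completion
    expect_gte(bb_upper_bound(0, nchar(q), NNK_MODEL), best)
  }
})

test_that("the brute-force oracle refuses oversized graphs", {
  g <- random_test_graph(13, 0.3)
  expect_error(brute_force_best_path(g, "AAA", NNK_MODEL,
                                     aa = random_aa(g)),
               "12 vertices")
})

test_that("mimotope input validates and reads both text formats", {
  expect_error(mimotope_set("AXZ!"), "alphabet")
  ms <- mimotope_set(c("ygvkn", "ACDE"))
  expect_equal(ms$sequence, c("YGVKN", "ACDE"))
  plain <- tempfile(); writeLines(c("YGVKN", "", "ACDE"), plain)
  expect_equal(read_mimotopes(plain)$sequence, c("YGVKN", "ACDE"))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">pep1", "YGVKN", ">pep2", "ACDE"), fa)
  ms2 <- read_mimotopes(fa)
  expect_equal(ms2$sequence, c("YGVKN", "ACDE"))
  expect_equal(ms2$label, c("pep1", "pep2"))
})
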