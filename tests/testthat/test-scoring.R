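test_that("the method-of-moments Gumbel fit has its closed form", {
  # two-point sample with mean 10 and sd pi/sqrt(6) gives scale exactly 1
  a <- (pi / sqrt(6)) / sqrt(2)
  ev <- fit_evd(scores = c(10 - a, 10 + a))
  expect_equal(ev$scale, 1, tolerance = 1e-12)
  expect_equal(ev$location, 10 - 0.57721566490153286, tolerance = 1e-12)
})

test_that("the fit is equivariant under scaling of the score sample", {
  set.seed(31)
  x <- rnorm(500, 8, 2)
  e1 <- fit_evd(scores = x)
  e2 <- fit_evd(scores = 2 * x)
  expect_equal(e2$scale, 2 * e1$scale)
  expect_equal(e2$location, 2 * e1$location)
})

test_that("parameters of a known Gumbel are recovered", {
  set.seed(32)
  x <- 5 - 2 * log(-log(runif(1e5)))   # Gumbel(5, 2) by inversion
  ev <- fit_evd(scores = x)
  expect_equal(ev$location, 5, tolerance = 0.02)
  expect_equal(ev$scale, 2, tolerance = 0.02)
  evm <- fit_evd(scores = x, method = "mle")
  expect_equal(evm$location, 5, tolerance = 0.02)
  expect_equal(evm$scale, 2, tolerance = 0.02)
})

test_that("a degenerate zero-variance sample is flagged with a scale floor", {
  ev <- fit_evd(scores = rep(4, 300))
  expect_true(ev$degenerate)
  expect_gt(ev$scale, 0)
})

test_that("P-values follow the Gumbel survival function", {
  ev <- structure(list(location = 3, scale = 1.5, degenerate = FALSE),
                  class = "evd_model")
  expect_equal(p_value(3, ev), 1 - exp(-1))
  expect_lt(p_value(1e3, ev), 1e-200)
  expect_equal(p_value(-1e3, ev), 1 - 1e-16)   # clamped below 1
  x <- seq(-1, 15, by = 0.5)                   # away from the clamps
  p <- p_value(x, ev)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("random queries on the calibration graph give near-uniform P-values", {
  set.seed(33)
  g <- random_test_graph(10, 0.45)
  aa <- random_aa(g)
  g2 <- mimomap:::graph_with_sequence(g, aa)
  ev <- fit_evd(g2, query_length = 4, NNK_MODEL, n_samples = 1000, seed = 7)
  freqs <- nnk_frequencies()
  p <- vapply(1:400, function(i) {
    q <- paste(sample(names(freqs), 4, TRUE, prob = freqs), collapse = "")
    p_value(align_query_to_graph(g2, q, NNK_MODEL)$raw_score, ev)
  }, 0.0)
  # coarse uniformity: mean near 1/2 and no gross enrichment of small P
  expect_equal(mean(p), 0.5, tolerance = 0.1)
  expect_lt(mean(p < 0.05), 0.15)
  expect_gt(mean(p < 0.5), 0.3)
})

test_that("patch scores sum the -log10 P evidence and rank correctly", {
  ev <- structure(list(location = 0, scale = 1, degenerate = FALSE),
                  class = "evd_model")
  als <- list(
    structure(list(path = data.frame(), raw_score = -log(-log(1 - 0.1)),
                   query = "ACDE", graph_ref = "A:1"),
              class = "path_alignment"),
    structure(list(path = data.frame(), raw_score = -log(-log(1 - 0.01)),
                   query = "ACDE", graph_ref = "A:1"),
              class = "path_alignment"))
  ps <- score_patch(als, list("4" = ev))
  expect_equal(ps$aggregate, 3, tolerance = 1e-9)
  expect_equal(score_patch(list(), list())$aggregate, 0)
  ps_rev <- score_patch(rev(als), list("4" = ev))
  expect_equal(ps_rev$aggregate, ps$aggregate)
})

test_that("ranking is descending with deterministic tie-breaks", {
  mk_ps <- function(center, agg) structure(
    list(patch = center, per_mimotope = data.frame(), aggregate = agg),
    class = "patch_score")
  mk_patch <- function(center, n) structure(
    list(center = center, members = paste0("A:", seq_len(n)), radius = 15),
    class = "patch")
  scores <- list(mk_ps("A:1", 2), mk_ps("A:2", 5), mk_ps("A:3", 1))
  patches <- list(mk_patch("A:1", 5), mk_patch("A:2", 5), mk_patch("A:3", 5))
  r <- rank_patches(scores, patches)
  expect_equal(r$patch, c("A:2", "A:1", "A:3"))
  expect_equal(r$aggregate, c(5, 2, 1))
  # tie: smaller patch first, then lower centre number
  scores2 <- list(mk_ps("A:9", 4), mk_ps("A:2", 4), mk_ps("A:5", 4))
  patches2 <- list(mk_patch("A:9", 8), mk_patch("A:2", 3), mk_patch("A:5", 3))
  r2 <- rank_patches(scores2, patches2)
  expect_equal(r2$patch, c("A:2", "A:5", "A:9"))
  # duplication does not perturb relative order of the originals
  r3 <- rank_patches(c(scores, scores), c(patches, patches))
  expect_equal(r3$patch[1:2], c("A:2", "A:2"))
})

test_that("unrelated mimotopes are not called significant on a null antigen", {
  # peptides drawn from the library distribution the calibration assumes
  m <- make_toy_structure(toy_spec(18, "helix", seed = 41))
  freqs <- nnk_frequencies()
  set.seed(42)
  mims <- mimotope_set(vapply(1:8, function(i)
    paste(sample(names(freqs), 5, TRUE, prob = freqs), collapse = ""), ""))
  fit <- mimomap(m, mims, evd_samples = 300, seed = 99)
  p <- unlist(lapply(fit$patch_scores, function(s) s$per_mimotope$p_value))
  # nominal 5% level: no gross enrichment (binomial slack at n = length(p))
  expect_lt(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(p)) + 0.02)
  # and the selected top patch is not driven by spuriously tiny P-values
  top <- fit$patch_scores[[match(fit$ranking$patch[1],
                                 vapply(fit$patch_scores, `[[`, "", "patch"))]]
  expect_lte(sum(top$per_mimotope$p_value < 0.05), 4L)
})
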