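test_that("compactness factor is e over a*k", {
  expect_equal(compute_cf(29, 10, 4), 0.725)
  expect_equal(compute_cf(0, 7, 4), 0)
  expect_equal(compute_cf(10, 5, 4), 0.5)  # complete K5
  expect_error(compute_cf(1, 0, 4))
})

test_that("mutually close surface residues give identical patch memberships", {
  m <- bare_model(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0)),
                  radii = rep(1.7, 3), split_residues = 1:3)
  surf <- compute_surface(m)
  p <- generate_patches(m, surf, radius = 15)
  expect_length(p, 3L)
  expect_equal(unique(lapply(p, function(x) sort(x$members))),
               list(c("A:1", "A:2", "A:3")))
  expect_equal(vapply(p, `[[`, "", "center"), c("A:1", "A:2", "A:3"))
})

test_that("an isolated residue forms a singleton patch", {
  m <- bare_model(rbind(c(0, 0, 0), c(5, 0, 0), c(40, 0, 0)),
                  radii = rep(1.7, 3), split_residues = 1:3)
  p <- generate_patches(m, compute_surface(m), radius = 15)
  expect_equal(p[[3]]$members, "A:3")
})

test_that("oversized patches are precluded", {
  # 60 exposed residues in a 12 A ball: central patches hold all 60
  set.seed(9)
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < 60) {
    cand <- runif(3, -12, 12)
    if (sum(cand^2) > 144) next
    if (nrow(pts) == 0 || min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= 4.5)
      pts <- rbind(pts, cand)
  }
  m <- bare_model(pts, radii = rep(1.7, 60), split_residues = 1:60)
  surf <- compute_surface(m)
  p <- generate_patches(m, surf, radius = 15, max_size = 50L)
  expect_gt(attr(p, "n_discarded"), 0L)
  expect_true(all(vapply(p, function(x) length(x$members), 0L) <= 50L))
  # a permissive cap retains them
  p2 <- generate_patches(m, surf, radius = 15, max_size = 60L)
  expect_gt(length(p2), length(p))
})

test_that("fixed-threshold edges follow pairwise anchor distance", {
  m <- bare_model(rbind(c(0, 0, 0), c(5, 0, 0)), radii = c(1.7, 1.7),
                  split_residues = 1:2)
  anchors <- rbind("A:1" = c(0, 0, 0), "A:2" = c(5, 0, 0))
  patch <- structure(list(center = "A:1", members = c("A:1", "A:2"),
                          radius = 15), class = "patch")
  g <- build_graph_fdt(patch, anchors, threshold = 6.5)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$cf, 1 / 8)
  anchors2 <- rbind("A:1" = c(0, 0, 0), "A:2" = c(7, 0, 0))
  expect_equal(nrow(build_graph_fdt(patch, anchors2, 6.5)$edges), 0L)
})

test_that("edge sets grow monotonically with the threshold", {
  set.seed(11)
  anchors <- matrix(rnorm(20 * 3, sd = 6), ncol = 3,
                    dimnames = list(paste0("A:", 1:20), NULL))
  patch <- structure(list(center = "A:1", members = rownames(anchors),
                          radius = 15), class = "patch")
  prev <- 0L
  for (t in c(3, 5, 6.5, 8, 12)) {
    g <- build_graph_fdt(patch, anchors, t)
    expect_gte(nrow(g$edges), prev)
    if (prev > 0L) {
      smaller <- build_graph_fdt(patch, anchors, t_last)
      key <- function(e) paste(e[, 1], e[, 2])
      expect_true(all(key(smaller$edges) %in% key(g$edges)))
    }
    prev <- nrow(g$edges); t_last <- t
  }
})

test_that("the adaptive threshold stays put when CF already sits in the band", {
  # 10 vertices in a line 6 A apart: at 6.5 A there are 9 edges, CF 0.225;
  # instead craft a set whose CF at 6.5 is inside [0.67, 0.79]
  set.seed(21)
  repeat {
    anchors <- matrix(rnorm(12 * 3, sd = 3.2), ncol = 3,
                      dimnames = list(paste0("A:", 1:12), NULL))
    d <- as.matrix(dist(anchors))
    cf <- sum(d[upper.tri(d)] <= 6.5) / (4 * 12)
    if (cf >= 0.68 && cf <= 0.78) break
  }
  patch <- structure(list(center = "A:1", members = rownames(anchors),
                          radius = 15), class = "patch")
  g <- build_graph_adt(patch, anchors)
  expect_equal(g$threshold, 6.5)
  expect_true(g$band_reached)
})

test_that("a two-vertex patch cannot reach the band and hits the bound", {
  anchors <- rbind("A:1" = c(0, 0, 0), "A:2" = c(4, 0, 0))
  patch <- structure(list(center = "A:1", members = c("A:1", "A:2"),
                          radius = 15), class = "patch")
  g <- build_graph_adt(patch, anchors)   # CF ceiling is 1/8
  expect_false(g$band_reached)
  expect_equal(g$threshold, graph_params()$threshold_bounds[2])
})

test_that("the adaptive threshold matches an independent grid-scan oracle", {
  params <- graph_params()
  for (seed in 1:6) {
    m <- make_toy_structure(toy_spec(24, if (seed %% 2) "helix" else "coil",
                                     seed = seed))
    surf <- compute_surface(m)
    patches <- generate_patches(m, surf)
    anchors <- t(vapply(m$residues, side_chain_anchor, numeric(3)))
    rownames(anchors) <- residue_keys(m)
    for (p in patches[seq(1, length(patches), by = 4)]) {
      g <- build_graph_adt(p, anchors, params)
      o <- adt_grid_oracle(p, anchors, params)
      expect_equal(g$threshold, o$threshold, tolerance = 1e-9)
      expect_equal(isTRUE(g$band_reached), o$band)
      if (isTRUE(g$band_reached)) {
        expect_gte(g$cf, 0.67); expect_lte(g$cf, 0.79)
      }
      # CF is reproducible from the edge list
      expect_equal(g$cf, nrow(g$edges) / (4 * length(g$vertices)))
    }
  }
})

test_that("ADT and FDT graphs share the vertex set over the same patch", {
  m <- make_toy_structure(toy_spec(20, "helix", seed = 13))
  surf <- compute_surface(m)
  patches <- generate_patches(m, surf)
  anchors <- t(vapply(m$residues, side_chain_anchor, numeric(3)))
  rownames(anchors) <- residue_keys(m)
  for (p in patches[c(1, 8, 15)]) {
    expect_identical(build_graph_adt(p, anchors)$vertices,
                     build_graph_fdt(p, anchors)$vertices)
  }
})

test_that("average CF is the permutation-invariant arithmetic mean", {
  g1 <- make_patch_graph(paste0("A:", 1:4), cbind(1:3, 2:4))  # cf fixed
  g2 <- make_patch_graph(paste0("A:", 1:2), cbind(1, 2))
  expect_equal(average_cf(list(g1, g2)), mean(c(g1$cf, g2$cf)))
  expect_equal(average_cf(list(g2, g1)), average_cf(list(g1, g2)))
  expect_equal(average_cf(list(g1)), g1$cf)
})
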