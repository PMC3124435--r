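test_that("an isolated sphere recovers the closed-form expanded area", {
  m <- bare_model(c(0, 0, 0), radii = 1.70)
  a <- shrake_rupley_asa(m, probe_radius = 1.4, n_sphere_points = 960L)
  expect_equal(as.numeric(a), 4 * pi * 3.10^2, tolerance = 0.02)
})

test_that("distant atoms do not occlude each other", {
  m <- bare_model(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.70, 1.70),
                  split_residues = c(1L, 2L))
  a <- shrake_rupley_asa(m, 1.4, 960L)
  expect_equal(as.numeric(a), rep(4 * pi * 3.10^2, 2))
})

test_that("a fully enclosed atom has zero accessible area", {
  # surround a carbon with a shell of carbons at 2.5 A
  i <- seq_len(40) - 0.5
  phi <- acos(1 - 2 * i / 40); th <- pi * (1 + sqrt(5)) * i
  shell <- 2.5 * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  m <- bare_model(rbind(c(0, 0, 0), shell), radii = rep(1.70, 41),
                  split_residues = c(1L, rep(2L, 40)))
  a <- shrake_rupley_asa(m, 1.4, 960L)
  expect_equal(a[1], 0)
})

test_that("residue ASA is the order-independent sum of member atom areas", {
  m <- bare_model(rbind(c(0, 0, 0), c(10, 0, 0)), radii = c(1.7, 1.7))
  areas <- c(10.0, 5.5)
  attr(areas, "residue_index") <- c(1L, 1L)
  expect_equal(unname(residue_asa(areas, m)), 15.5)
  areas2 <- c(5.5, 10.0)
  attr(areas2, "residue_index") <- c(1L, 1L)
  expect_equal(residue_asa(areas2, m), residue_asa(areas, m))
})

test_that("surface flags follow RSA against the maximum-area table", {
  tab <- max_area_table()
  asa <- setNames(c(tab[["A"]], 0), c("A:1", "A:2"))
  aa <- setNames(c("A", "A"), c("A:1", "A:2"))
  s <- surface_flags(asa, aa, rsa_threshold = 0.05)
  expect_equal(s$rsa, c(1, 0))
  expect_equal(s$is_surface, c(TRUE, FALSE))
  expect_error(surface_flags(setNames(1, "A:1"), setNames("X", "A:1")),
               "no maximum area")
})

test_that("the exposed central alanine of an extended tripeptide has RSA near 1", {
  # extended ALA-ALA-ALA with full heavy-atom alanine residues
  ala <- function(x0) rbind(N = c(x0 - 1.2, 0.5, 0), CA = c(x0, 0, 0),
                            C = c(x0 + 1.3, -0.5, 0), O = c(x0 + 1.3, -1.7, 0.3),
                            CB = c(x0, 0.8, 1.3))
  coords <- rbind(ala(0), ala(3.8), ala(7.6))
  m <- bare_model(coords, radii = vdw_radius(rep(c("N", "C", "C", "O", "C"), 3)),
                  aa = c("A", "A", "A"), split_residues = rep(1:3, each = 5))
  for (ri in 1:3) m$residues[[ri]]$atoms$name <- c("N", "CA", "C", "O", "CB")
  s <- compute_surface(m)
  expect_gt(s$rsa[2], 0.70)
  expect_lt(s$rsa[2], 1.15)
})

test_that("areas converge with the sampling density", {
  m <- make_toy_structure(toy_spec(10, "helix", seed = 4))
  a1 <- residue_asa(shrake_rupley_asa(m, 1.4, 960L), m)
  a2 <- residue_asa(shrake_rupley_asa(m, 1.4, 3840L), m)
  expect_lt(max(abs(a1 - a2) / pmax(a2, 1)), 0.02)
})

test_that("ASA is invariant under rigid motion within sampling tolerance", {
  m <- make_toy_structure(toy_spec(10, "helix", seed = 4))
  a1 <- residue_asa(shrake_rupley_asa(m, 1.4, 960L), m)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- m
  for (i in seq_along(m2$residues)) {
    xyz <- as.matrix(m2$residues[[i]]$atoms[, c("x", "y", "z")])
    xyz <- xyz %*% t(R) + matrix(c(5, -3, 11), nrow(xyz), 3, byrow = TRUE)
    m2$residues[[i]]$atoms$x <- xyz[, 1]
    m2$residues[[i]]$atoms$y <- xyz[, 2]
    m2$residues[[i]]$atoms$z <- xyz[, 3]
  }
  a2 <- residue_asa(shrake_rupley_asa(m2, 1.4, 960L), m2)
  expect_lt(max(abs(a1 - a2) / pmax(a1, 1)), 0.03)
})

test_that("the surface set shrinks as the RSA threshold rises", {
  m <- make_toy_structure(toy_spec(15, "coil", seed = 6))
  areas <- shrake_rupley_asa(m, 1.4, 960L)
  rasa <- residue_asa(areas, m)
  aa <- antigen_sequence(m)
  prev <- Inf
  for (thr in c(0.01, 0.05, 0.2, 0.5)) {
    n <- sum(surface_flags(rasa, aa, rsa_threshold = thr)$is_surface)
    expect_lte(n, prev)
    prev <- n
  }
})
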