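#' Specification for a synthetic toy structure
#'
#' @param n_residues number of residues (>= 3).
#' @param geometry "helix" (ideal alpha-helix: high exposure, regular
#'   contacts) or "coil" (compact jittered random walk: denser, irregular
#'   contact regimes).
#' @param sequence one-letter sequence of length `n_residues`, or `NULL`
#'   to draw residues uniformly at random under `seed`.
#' @param seed RNG seed; the generated structure is deterministic in it.
#' @return a `toy_spec` list.
#' @export
toy_spec <- function(n_residues, geometry = c("helix", "coil"),
                     sequence = NULL, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 3L)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    stopifnot(nchar(sequence) == n_residues)
  }
  structure(list(n_residues = n_residues, geometry = geometry,
                 sequence = sequence, seed = seed),
            class = "toy_spec")
}

unit3 <- function(v) v / sqrt(sum(v^2))

# backbone + pseudo C-beta coordinates for a toy chain
toy_coordinates <- function(spec) {
  n <- spec$n_residues
  if (spec$geometry == "helix") {
    # ideal alpha-helix: 1.5 A rise and 100 degrees per residue,
    # C-alpha radius 2.3 A around the z axis
    ang <- (seq_len(n) - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), (seq_len(n) - 1) * 1.5)
  } else {
    # compact jittered-lattice globule at protein-interior density
    # (~4 A between neighbouring C-alpha sites), traversed in snake
    # order so consecutive residues stay adjacent; probes the
    # dense-contact regime (CF above the band at a 6.5 A threshold),
    # complementing the sparser helix
    set.seed(spec$seed)
    m <- ceiling(n^(1 / 3))
    sites <- matrix(0, 0, 3)
    for (z in seq_len(m)) {
      ys <- if (z %% 2) seq_len(m) else rev(seq_len(m))
      for (y in ys) {
        xs <- if ((y + z) %% 2) seq_len(m) else rev(seq_len(m))
        sites <- rbind(sites, cbind(xs, y, z))
      }
    }
    ca <- 4.0 * sites[seq_len(n), , drop = FALSE] +
      matrix(runif(3 * n, -0.4, 0.4), n, 3)
  }
  fwd <- rbind(ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE],
               ca[n, ] - ca[n - 1, ])
  bwd <- rbind(ca[2, ] - ca[1, ],
               ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    v1 <- unit3(fwd[i, ]); v0 <- unit3(bwd[i, ])
    if (spec$geometry == "helix") {
      side <- unit3(c(ca[i, 1], ca[i, 2], 0))      # radially outward
      cb_dir <- unit3(side - 0.6 * c(0, 0, 1))
    } else {
      perp <- pracma_cross(v1, c(0, 0, 1))
      if (sum(perp^2) < 1e-8) perp <- pracma_cross(v1, c(0, 1, 0))
      cb_dir <- unit3(perp)
    }
    ni <- ca[i, ] - 1.46 * v0
    ci <- ca[i, ] + 1.52 * v1
    oi <- ci + 1.23 * cb_dir
    cbi <- ca[i, ] + 1.53 * cb_dir
    out[[i]] <- rbind(N = ni, CA = ca[i, ], C = ci, O = oi, CB = cbi)
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a small protein-like structure
#'
#' Builds an ideal-geometry backbone (N, C-alpha, C, O) plus a
#' pseudo-C-beta per residue at a standard tetrahedral offset, on chain
#' "A" with residue numbers 1..n.  Deterministic given the spec's seed;
#' round-trips through [as_pdb_text()] / [load_antigen()].
#'
#' @param spec a [toy_spec()].
#' @return an `antigen_model` (source_id "synthetic-toy").
#' @export
#' @examples
#' m <- make_toy_structure(toy_spec(20, "helix", seed = 7))
#' m
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  seq <- spec$sequence
  if (is.null(seq)) {
    set.seed(spec$seed)
    seq <- paste(sample(AA_ALPHABET, spec$n_residues, replace = TRUE),
                 collapse = "")
  }
  letters1 <- strsplit(seq, "")[[1]]
  coords <- toy_coordinates(spec)
  residues <- lapply(seq_len(spec$n_residues), function(i) {
    xyz <- coords[[i]]
    elem <- c("N", "C", "C", "O", "C")
    list(key = paste0("A:", i), chain_id = "A", seq_number = i,
         insertion_code = "", aa = letters1[i],
         atoms = data.frame(name = rownames(xyz), element = elem,
                            x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
                            z = round(xyz[, 3], 3),
                            radius = vdw_radius(elem),
                            stringsAsFactors = FALSE),
         cb_coord = round(xyz["CB", ], 3))
  })
  structure(list(residues = residues, source_id = "synthetic-toy",
                 chain_id = "A"),
            class = "antigen_model")
}

#' Plant a surface path spelling an epitope sequence
#'
#' Relabels a connected run of surface residues (consecutive side-chain
#' anchors within `link_distance`) so that it spells `epitope_seq`; the
#' run is chosen deterministically from `seed` among all eligible runs.
#' Coordinates are untouched, so geometry and surface exposure are
#' preserved.
#'
#' @param model an `antigen_model` (typically a toy structure).
#' @param epitope_seq one-letter sequence to plant.
#' @param seed RNG seed selecting among eligible runs.
#' @param link_distance maximum anchor distance between consecutive
#'   planted residues (default 6.5 Angstrom, the graph-edge scale).
#' @param surf optional precomputed `accessibility_result`.
#' @return list with `model` (relabelled) and `planted_keys` (residue
#'   keys of the planted path, in epitope order).
#' @export
plant_epitope_path <- function(model, epitope_seq, seed = 1L,
                               link_distance = 6.5, surf = NULL) {
  letters1 <- strsplit(toupper(epitope_seq), "")[[1]]
  stopifnot(all(letters1 %in% AA_ALPHABET))
  L <- length(letters1)
  if (is.null(surf)) surf <- compute_surface(model)
  n_surf <- sum(surf$is_surface)
  if (L > n_surf)
    stop("epitope (", L, ") longer than the surface residue count (",
         n_surf, ")")
  anchors <- anchor_matrix(model)
  n <- length(model$residues)
  is_surf <- surf$is_surface
  ok_start <- logical(max(n - L + 1L, 0L))
  for (s in seq_along(ok_start)) {
    idx <- s:(s + L - 1L)
    if (!all(is_surf[idx])) next
    steps <- sqrt(rowSums((anchors[idx[-1], , drop = FALSE] -
                           anchors[idx[-L], , drop = FALSE])^2))
    ok_start[s] <- all(steps <= link_distance)
  }
  if (!any(ok_start))
    stop("no connected surface run of length ", L, " available")
  set.seed(seed)
  s <- sample(which(ok_start), 1L)
  idx <- s:(s + L - 1L)
  for (j in seq_len(L)) model$residues[[idx[j]]]$aa <- letters1[j]
  list(model = model, planted_keys = residue_keys(model)[idx])
}

#' Sample mimotopes around an epitope sequence
#'
#' Emulates affinity-selected phage-display peptides: `n` copies of the
#' epitope with independent per-position substitution probability
#' `mutation_rate`, substitutions drawn from NNK amino-acid frequencies
#' (so a position can redraw its original letter at the NNK rate).
#'
#' @param epitope_seq one-letter epitope sequence.
#' @param n number of peptides.
#' @param mutation_rate per-position substitution probability in \[0, 1\].
#' @param seed RNG seed.
#' @return a [mimotope_set()].
#' @export
sample_mimotopes <- function(epitope_seq, n, mutation_rate = 0.2,
                             seed = 1L) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, n >= 1L)
  letters1 <- strsplit(toupper(epitope_seq), "")[[1]]
  freqs <- nnk_frequencies()
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    mut <- runif(length(letters1)) < mutation_rate
    out <- letters1
    if (any(mut))
      out[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE, prob = freqs)
    paste(out, collapse = "")
  }, "")
  mimotope_set(seqs)
}
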