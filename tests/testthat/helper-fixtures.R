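# shared fixtures, all built in code

NNK_MODEL <- derive_nnk_matrix()
AA20 <- rownames(NNK_MODEL$matrix)

# one fixed-column PDB ATOM line; altloc sits in column 17
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          elem, alt = " ", icode = " ") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resn, chain, resno, icode, x, y, z, 1.0, 0.0, elem)
}

# hand-written GLY-ALA-SER fragment on chain A
tiny_pdb_file <- function(extra_lines = character(0)) {
  lines <- c(
    pdb_atom_line(1, "N",  "GLY", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.5, 0.0, 0.0, "C"),
    pdb_atom_line(3, "C",  "GLY", "A", 1, 2.2, 1.3, 0.0, "C"),
    pdb_atom_line(4, "N",  "ALA", "A", 2, 3.5, 1.3, 0.0, "N"),
    pdb_atom_line(5, "CA", "ALA", "A", 2, 4.3, 2.5, 0.0, "C"),
    pdb_atom_line(6, "CB", "ALA", "A", 2, 4.3, 3.5, 1.1, "C"),
    pdb_atom_line(7, "N",  "SER", "A", 3, 5.6, 2.5, 0.0, "N"),
    pdb_atom_line(8, "CA", "SER", "A", 3, 6.5, 3.6, 0.0, "C"),
    pdb_atom_line(9, "CB", "SER", "A", 3, 6.5, 4.6, 1.1, "C"),
    extra_lines,
    "TER", "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# a bare single-residue model with arbitrary atoms (coords n x 3, radii)
bare_model <- function(coords, radii, aa = "A", split_residues = NULL) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (is.null(split_residues)) split_residues <- rep(1L, n)
  res_ids <- sort(unique(split_residues))
  residues <- lapply(res_ids, function(ri) {
    sel <- which(split_residues == ri)
    list(key = paste0("A:", ri), chain_id = "A", seq_number = ri,
         insertion_code = "", aa = if (length(aa) > 1) aa[ri] else aa,
         atoms = data.frame(name = c("CB", paste0("X", seq_len(length(sel) - 1)))[
                              seq_along(sel)],
                            element = rep("C", length(sel)),
                            x = coords[sel, 1], y = coords[sel, 2],
                            z = coords[sel, 3],
                            radius = radii[sel], stringsAsFactors = FALSE),
         cb_coord = coords[sel[1], ])
  })
  structure(list(residues = residues, source_id = "bare", chain_id = "A"),
            class = "antigen_model")
}

# random connected-ish graph over n vertices with edge probability p
random_test_graph <- function(n, p, aa_seed = NULL) {
  keys <- paste0("A:", seq_len(n))
  full <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(full)) < p
  make_patch_graph(keys, full[keep, , drop = FALSE])
}

random_aa <- function(graph) {
  setNames(sample(AA20, length(graph$vertices), replace = TRUE),
           graph$vertices)
}

random_peptide <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# recompute an alignment's score from its emitted columns
rescore_alignment <- function(al, model, aa) {
  if (nrow(al$path) == 0L) return(0)
  qs <- strsplit(al$query, "")[[1]]
  sc <- 0
  for (r in seq_len(nrow(al$path))) {
    qp <- al$path$query_pos[r]; v <- al$path$vertex[r]
    sc <- sc + if (is.na(qp) || is.na(v)) model$gap_penalty
               else model$matrix[qs[qp], aa[[v]]]
  }
  sc
}

# independent grid-scan oracle for the adaptive distance threshold:
# walks the 0.01 A grid from the start in the direction the initial CF
# demands, applying the same stop rules as the implementation claims
adt_grid_oracle <- function(patch, anchors, params) {
  am <- anchors[patch$members, , drop = FALSE]
  k <- nrow(am)
  dm <- as.matrix(dist(am))
  cf_of <- function(t) sum(dm[upper.tri(dm)] <= t) / (params$a_constant * k)
  lo <- params$cf_target - params$cf_tol
  hi <- params$cf_target + params$cf_tol
  t <- params$start_threshold
  cf <- cf_of(t)
  if (cf >= lo && cf <= hi) return(list(threshold = t, band = TRUE))
  repeat {
    dir <- if (cf < lo) 1 else -1
    tn <- t + dir * params$step
    if (tn < params$threshold_bounds[1] || tn > params$threshold_bounds[2]) {
      t <- max(params$threshold_bounds[1],
               min(params$threshold_bounds[2], tn))
      cf <- cf_of(t)
      return(list(threshold = t, band = cf >= lo && cf <= hi))
    }
    cfn <- cf_of(tn)
    if (cfn >= lo && cfn <= hi) return(list(threshold = tn, band = TRUE))
    if ((cf < lo && cfn > hi) || (cf > hi && cfn < lo)) {
      pick <- if (abs(cf - params$cf_target) < abs(cfn - params$cf_target))
        t else tn
      return(list(threshold = pick, band = FALSE))
    }
    t <- tn; cf <- cfn
  }
}
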