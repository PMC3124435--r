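#' Maximum exposed residue areas (RSA denominators)
#'
#' Theoretical maximum solvent-accessible areas per amino acid in an
#' extended tripeptide context (Tien et al. 2013), in square Angstrom.
#' Relative solvent accessibility divides a residue's ASA by this value.
#'
#' @param table optional named numeric vector (one-letter codes) replacing
#'   or patching the default values.
#' @return named numeric vector over the 20 standard amino acids.
#' @export
max_area_table <- function(table = NULL) {
  def <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
           Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
           L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
           S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)
  if (!is.null(table)) {
    stopifnot(is.numeric(table), !is.null(names(table)))
    if (any(table <= 0)) stop("maximum areas must be positive")
    def[names(table)] <- table
  }
  def
}

# deterministic near-uniform points on the unit sphere (golden spiral);
# avoids a random seed so ASA is reproducible by construction
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolling-ball ASA: each atom's sphere is expanded by the probe radius
#' and sampled with a deterministic point lattice; the accessible area is
#' the fraction of points not buried inside any neighbouring expanded
#' sphere, times the expanded-sphere area \eqn{4\pi(r+p)^2}.
#'
#' @param model an `antigen_model`.
#' @param probe_radius probe sphere radius in Angstrom (water: 1.4).
#' @param n_sphere_points number of test points per atom (>= 60);
#'   the default 960 keeps areas within ~1 percent of convergence.
#' @return numeric vector of per-atom areas (square Angstrom) in model
#'   atom order, with attribute `residue_index` mapping atoms to residues.
#' @export
shrake_rupley_asa <- function(model, probe_radius = 1.4,
                              n_sphere_points = 960L) {
  stopifnot(probe_radius > 0, n_sphere_points >= 60L)
  atoms <- do.call(rbind, lapply(seq_along(model$residues), function(i) {
    a <- model$residues[[i]]$atoms
    cbind(a$x, a$y, a$z, a$radius, i)
  }))
  if (is.null(atoms) || nrow(atoms) == 0L) stop("empty antigen model")
  xyz <- atoms[, 1:3, drop = FALSE]
  rad <- atoms[, 4] + probe_radius
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_sphere_points)
  areas <- numeric(n)
  # neighbour lists once, via squared-distance cutoffs
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * rad[i]^2
      next
    }
    sp <- pts * rad[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (sp[free, 1] - xyz[j, 1])^2 + (sp[free, 2] - xyz[j, 2])^2 +
        (sp[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 > rad[j]^2
    }
    areas[i] <- 4 * pi * rad[i]^2 * sum(free) / n_sphere_points
  }
  attr(areas, "residue_index") <- as.integer(atoms[, 5])
  areas
}

#' Sum per-atom areas into per-residue ASA
#'
#' @param per_atom_areas output of [shrake_rupley_asa()].
#' @param model the same `antigen_model`.
#' @return named numeric vector of residue ASA in square Angstrom.
#' @export
residue_asa <- function(per_atom_areas, model) {
  idx <- attr(per_atom_areas, "residue_index")
  if (is.null(idx)) stop("per_atom_areas lacks its residue index")
  out <- vapply(seq_along(model$residues),
                function(i) sum(per_atom_areas[idx == i]), 0.0)
  setNames(out, residue_keys(model))
}

#' Relative accessibility and surface flags
#'
#' RSA is the residue ASA divided by that residue type's maximum exposed
#' area; residues with RSA above the threshold (default 0.05) are flagged
#' as surface residues.
#'
#' @param res_asa named per-residue ASA from [residue_asa()].
#' @param aa named one-letter residue types (same order/names).
#' @param max_table maximum-area table, see [max_area_table()].
#' @param rsa_threshold surface cut-off on RSA (dimensionless).
#' @return object of class `accessibility_result`: data frame with `key`,
#'   `aa`, `asa`, `rsa`, `is_surface`.
#' @export
surface_flags <- function(res_asa, aa, max_table = max_area_table(),
                          rsa_threshold = 0.05) {
  unknown <- setdiff(unique(aa), names(max_table))
  if (length(unknown))
    stop("no maximum area for residue type(s): ",
         paste(unknown, collapse = ", "))
  rsa <- unname(res_asa / max_table[aa])
  out <- data.frame(key = names(res_asa), aa = unname(aa),
                    asa = unname(res_asa), rsa = rsa,
                    is_surface = rsa > rsa_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "rsa_threshold") <- rsa_threshold
  class(out) <- c("accessibility_result", "data.frame")
  out
}

#' Compute per-residue accessibility for an antigen model
#'
#' Convenience wrapper: Shrake-Rupley per-atom areas, residue sums, RSA
#' and surface flags in one call.  ASA is computed on the antigen chain
#' alone, as prediction only ever sees the free antigen.
#'
#' @inheritParams shrake_rupley_asa
#' @inheritParams surface_flags
#' @param model an `antigen_model`.
#' @return an `accessibility_result` data frame (see [surface_flags()]).
#' @export
#' @examples
#' m <- make_toy_structure(toy_spec(12, seed = 1))
#' head(compute_surface(m))
compute_surface <- function(model, probe_radius = 1.4,
                            n_sphere_points = 960L,
                            max_table = max_area_table(),
                            rsa_threshold = 0.05) {
  areas <- shrake_rupley_asa(model, probe_radius, n_sphere_points)
  rasa <- residue_asa(areas, model)
  surface_flags(rasa, antigen_sequence(model), max_table, rsa_threshold)
}

#' Export accessibility as TSV
#' @param surf an `accessibility_result`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_surface_tsv <- function(surf, path) {
  write.table(as.data.frame(surf), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
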