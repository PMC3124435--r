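#' Tile the antigen surface into overlapping patches
#'
#' One candidate patch per surface residue: the centre plus every surface
#' residue whose side-chain anchor (C-beta) lies within `radius` of the
#' centre's anchor.  Patches exceeding `max_size` residues are discarded
#' (epitopes sit in loose, protruding regions; oversized patches mark
#' dense cores and would blow up the path search).
#'
#' @param model an `antigen_model`.
#' @param surf matching `accessibility_result` from [compute_surface()].
#' @param radius patch radius in Angstrom (default 15).
#' @param max_size maximum residues per retained patch (default 50).
#' @return list of `patch` objects (`center`, `members`, `radius`), with
#'   attribute `n_discarded` counting oversized patches.
#' @export
generate_patches <- function(model, surf, radius = 15, max_size = 50L) {
  stopifnot(inherits(model, "antigen_model"), radius > 0, max_size >= 1L)
  keys <- residue_keys(model)
  if (!identical(surf$key, keys))
    stop("surface result does not match the antigen model")
  surf_keys <- surf$key[surf$is_surface]
  if (length(surf_keys) == 0L)
    stop("no surface residues above the RSA threshold")
  anchors <- anchor_matrix(model)[surf_keys, , drop = FALSE]
  d <- as.matrix(stats::dist(anchors))
  patches <- list()
  n_disc <- 0L
  for (i in seq_along(surf_keys)) {
    members <- surf_keys[d[i, ] <= radius]
    if (length(members) > max_size) { n_disc <- n_disc + 1L; next }
    patches[[length(patches) + 1L]] <- structure(
      list(center = surf_keys[i], members = members, radius = radius),
      class = "patch")
  }
  if (n_disc > 0L)
    message(n_disc, " patch(es) larger than ", max_size, " residues discarded")
  attr(patches, "n_discarded") <- n_disc
  patches
}

#' Compactness factor of a graph
#'
#' CF = e / (a k): the observed number of edges over the expected number,
#' where the expected edge count grows linearly with the vertex count k
#' (a residue only contacts its spatial neighbours), with empirical
#' constant a = 4.
#'
#' @param e observed edge count.
#' @param k vertex count (>= 1).
#' @param a expected edges per vertex (default 4).
#' @return dimensionless compactness factor.
#' @export
#' @examples
#' compute_cf(29, 10)  # 0.725
compute_cf <- function(e, k, a = 4L) {
  stopifnot(k >= 1L, a >= 1L, e >= 0L)
  e / (a * k)
}

#' Graph-generation parameters
#'
#' Defaults reflect the method's standard operating point: a compactness
#' band of 0.73 +/- 0.06, a starting distance threshold of 6.5 Angstrom
#' adjusted in 0.01 Angstrom steps, and a = 4 expected edges per vertex.
#' `threshold_bounds` guards termination for patches whose CF ceiling lies
#' below the band (e.g. two-residue patches).
#'
#' @param cf_target centre of the compactness band.
#' @param cf_tol half-width of the band.
#' @param start_threshold initial distance threshold, Angstrom.
#' @param step threshold increment, Angstrom.
#' @param threshold_bounds length-2 numeric, allowed threshold range.
#' @param a_constant expected edges per vertex.
#' @param mode "adt" (adaptive) or "fdt" (fixed threshold).
#' @return a `graph_params` list.
#' @export
graph_params <- function(cf_target = 0.73, cf_tol = 0.06,
                         start_threshold = 6.5, step = 0.01,
                         threshold_bounds = c(3.0, 20.0),
                         a_constant = 4L, mode = c("adt", "fdt")) {
  mode <- match.arg(mode)
  stopifnot(cf_tol >= 0, step > 0, length(threshold_bounds) == 2L,
            threshold_bounds[1] < threshold_bounds[2], a_constant >= 1L)
  structure(list(cf_target = cf_target, cf_tol = cf_tol,
                 start_threshold = start_threshold, step = step,
                 threshold_bounds = threshold_bounds,
                 a_constant = a_constant, mode = mode),
            class = "graph_params")
}

# edges among patch members at a threshold; anchors: named n x 3 matrix
patch_edges <- function(anchors, threshold) {
  n <- nrow(anchors)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  d <- as.matrix(stats::dist(anchors))
  idx <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
  idx
}

new_patch_graph <- function(patch, anchors, threshold, a, band_reached = NA) {
  ed <- patch_edges(anchors, threshold)
  k <- nrow(anchors)
  structure(list(patch = patch,
                 vertices = rownames(anchors),
                 edges = ed,
                 threshold = threshold,
                 a_constant = a,
                 cf = compute_cf(nrow(ed), k, a),
                 band_reached = band_reached),
            class = "patch_graph")
}

#' Build a patch graph with a fixed distance threshold (FDT)
#'
#' Vertices are the patch members; an edge joins every pair of members
#' whose anchors lie within `threshold` Angstrom.
#'
#' @param patch a `patch`.
#' @param anchors full anchor matrix (rownames = residue keys), e.g.
#'   `anchor_matrix(model)` -- only patch members are used.
#' @param threshold distance threshold in Angstrom (default 6.5).
#' @param a expected edges per vertex for the CF.
#' @return a `patch_graph` (`vertices`, `edges` two-column index matrix,
#'   `threshold`, `cf`, `band_reached = NA`).
#' @export
build_graph_fdt <- function(patch, anchors, threshold = 6.5, a = 4L) {
  stopifnot(inherits(patch, "patch"), threshold > 0)
  new_patch_graph(patch, anchors[patch$members, , drop = FALSE],
                  threshold, a, band_reached = NA)
}

#' Build a patch graph with an adaptive distance threshold (ADT)
#'
#' Starts at `params$start_threshold`; while the compactness factor falls
#' below (above) the band, the threshold is increased (decreased) by
#' `params$step` and the graph rebuilt, until CF enters
#' \[cf_target - cf_tol, cf_target + cf_tol\] or a threshold bound is hit.
#' If one step jumps across the band, the side whose CF is closer to the
#' target is kept.  An unreachable band never raises an error: the
#' closest-CF graph is returned with `band_reached = FALSE`.
#'
#' @param patch a `patch`.
#' @param anchors full anchor matrix (rownames = residue keys).
#' @param params a [graph_params()] object.
#' @return a `patch_graph` with `band_reached` set.
#' @export
build_graph_adt <- function(patch, anchors, params = graph_params()) {
  stopifnot(inherits(patch, "patch"))
  am <- anchors[patch$members, , drop = FALSE]
  k <- nrow(am)
  a <- params$a_constant
  lo <- params$cf_target - params$cf_tol
  hi <- params$cf_target + params$cf_tol
  bounds <- params$threshold_bounds
  d <- if (k >= 2L) as.matrix(stats::dist(am)) else
    matrix(0, 1, 1)
  ut <- upper.tri(d)
  cf_at <- function(t) compute_cf(sum(d[ut] <= t), k, a)
  t <- params$start_threshold
  cf <- cf_at(t)
  band_reached <- cf >= lo && cf <= hi
  prev_t <- t; prev_cf <- cf
  while (!band_reached) {
    dir <- if (cf < lo) +1 else -1
    t_new <- t + dir * params$step
    if (t_new < bounds[1] || t_new > bounds[2]) {
      t <- max(bounds[1], min(bounds[2], t_new))
      cf <- cf_at(t)
      band_reached <- cf >= lo && cf <= hi
      break
    }
    prev_t <- t; prev_cf <- cf
    t <- t_new
    cf <- cf_at(t)
    if (cf >= lo && cf <= hi) { band_reached <- TRUE; break }
    # jumped across the band in one step: keep the closer side
    if ((prev_cf < lo && cf > hi) || (prev_cf > hi && cf < lo)) {
      if (abs(prev_cf - params$cf_target) < abs(cf - params$cf_target)) {
        t <- prev_t; cf <- prev_cf
      }
      band_reached <- FALSE
      break
    }
  }
  new_patch_graph(patch, am, t, a, band_reached = band_reached)
}

#' Build graphs for all patches
#'
#' @param patches list of `patch` objects from [generate_patches()].
#' @param model the `antigen_model`.
#' @param params a [graph_params()]; `params$mode` selects ADT or FDT
#'   (FDT uses `params$start_threshold` as its fixed threshold).
#' @return list of `patch_graph` objects.
#' @export
build_patch_graphs <- function(patches, model, params = graph_params()) {
  anchors <- anchor_matrix(model)
  lapply(patches, function(p) {
    if (params$mode == "fdt")
      build_graph_fdt(p, anchors, params$start_threshold, params$a_constant)
    else
      build_graph_adt(p, anchors, params)
  })
}

#' Construct a patch graph from an explicit edge list
#'
#' Mainly useful for testing and for importing graphs built elsewhere;
#' the pipeline itself builds graphs from patches with
#' [build_graph_fdt()] / [build_graph_adt()].
#'
#' @param vertices character vector of residue keys.
#' @param edges two-column matrix: vertex indices (integer) or residue
#'   keys (character); may have zero rows.
#' @param center the patch centre key (default first vertex).
#' @param a expected edges per vertex for the CF.
#' @param threshold nominal distance threshold to record.
#' @return a `patch_graph`.
#' @export
make_patch_graph <- function(vertices, edges, center = vertices[1],
                             a = 4L, threshold = NA_real_) {
  if (is.null(edges) || length(edges) == 0L)
    edges <- matrix(integer(0), ncol = 2)
  if (is.character(edges))
    edges <- matrix(match(edges, vertices), ncol = 2)
  edges <- matrix(as.integer(edges), ncol = 2)
  stopifnot(all(!is.na(edges)), all(edges >= 1), all(edges <= length(vertices)),
            all(edges[, 1] != edges[, 2]))
  structure(list(patch = structure(list(center = center,
                                        members = vertices,
                                        radius = NA_real_),
                                   class = "patch"),
                 vertices = vertices, edges = edges,
                 threshold = threshold, a_constant = a,
                 cf = compute_cf(nrow(edges), length(vertices), a),
                 band_reached = NA),
            class = "patch_graph")
}

#' Mean compactness factor over graphs
#'
#' @param graphs list of `patch_graph` objects.
#' @param band_reached_only drop graphs whose ADT never reached the CF
#'   band before averaging.
#' @return arithmetic mean CF.
#' @export
average_cf <- function(graphs, band_reached_only = FALSE) {
  stopifnot(length(graphs) > 0L)
  cfs <- vapply(graphs, `[[`, 0.0, "cf")
  if (band_reached_only) {
    keep <- vapply(graphs, function(g) isTRUE(g$band_reached), NA)
    if (any(keep)) cfs <- cfs[keep]
  }
  mean(cfs)
}

#' @export
print.patch_graph <- function(x, ...) {
  cat("Patch graph centred at", x$patch$center, "\n")
  cat("  ", length(x$vertices), "vertices,", nrow(x$edges),
      "edges, threshold", sprintf("%.2f", x$threshold), "A, CF",
      sprintf("%.3f", x$cf))
  if (!is.na(x$band_reached))
    cat(if (x$band_reached) " (band reached)" else " (band unreachable)")
  cat("\n")
  invisible(x)
}

#' Export a patch graph as an edge-list TSV
#' @param graph a `patch_graph`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_graph_tsv <- function(graph, path) {
  df <- data.frame(from = graph$vertices[graph$edges[, 1]],
                   to = graph$vertices[graph$edges[, 2]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
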