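#' Map mimotopes onto an antigen surface
#'
#' The full prediction pipeline: per-residue solvent accessibility,
#' surface patches, compactness-regulated patch graphs, best-path
#' alignment of every mimotope to every graph, extreme-value P-value
#' calibration, and patch ranking.  The top-ranked patch is the candidate
#' conformational B-cell epitope.
#'
#' @param antigen an `antigen_model` from [load_antigen()] or
#'   [make_toy_structure()], or a PDB path (then `chain` is required).
#' @param mimotopes a [mimotope_set()], a character vector of peptides,
#'   or a path readable by [read_mimotopes()].
#' @param chain chain identifier when `antigen` is a path.
#' @param mode "adt" (adaptive distance threshold regulated by the
#'   compactness factor; default) or "fdt" (fixed threshold).
#' @param patch_radius patch radius in Angstrom (default 15).
#' @param max_patch_size largest retained patch (default 50 residues).
#' @param rsa_threshold surface RSA cut-off (default 0.05).
#' @param probe_radius ASA probe radius in Angstrom (default 1.4).
#' @param n_sphere_points ASA sampling points per atom (default 960).
#' @param cf_target,cf_tol compactness band (default 0.73 +/- 0.06).
#' @param threshold starting (ADT) or fixed (FDT) distance threshold.
#' @param step ADT threshold increment (default 0.01 Angstrom).
#' @param subst a `substitution_model`; default NNK-adjusted BLOSUM62.
#' @param gap_penalty gap penalty when `subst` is not supplied.
#' @param evd_samples random peptides per EVD calibration (default 1000).
#' @param evd_scope "graph" calibrates every patch graph separately;
#'   "antigen" calibrates once per query length on a median-size graph
#'   and reuses it (cheaper, less exact).
#' @param seed master seed for all calibration randomness.
#' @param use_bb branch-and-bound pruning (identical scores, fewer
#'   states).
#' @param top_n candidates kept in the ranking report.
#' @param surf optional precomputed `accessibility_result`.
#' @return an object of class `mimomap_fit`; see [print.mimomap_fit()],
#'   [summary.mimomap_fit()], [predicted_epitope()], [plot.mimomap_fit()].
#' @export
#' @examples
#' planted <- plant_epitope_path(make_toy_structure(toy_spec(24, seed = 3)),
#'                               "YGVKN", seed = 3)
#' mims <- sample_mimotopes("YGVKN", 5, 0.2, seed = 3)
#' fit <- mimomap(planted$model, mims, evd_samples = 300)
#' fit
mimomap <- function(antigen, mimotopes, chain = NULL,
                    mode = c("adt", "fdt"),
                    patch_radius = 15, max_patch_size = 50L,
                    rsa_threshold = 0.05, probe_radius = 1.4,
                    n_sphere_points = 960L,
                    cf_target = 0.73, cf_tol = 0.06,
                    threshold = 6.5, step = 0.01,
                    subst = NULL, gap_penalty = -5,
                    evd_samples = 1000L,
                    evd_scope = c("graph", "antigen"),
                    seed = 42L, use_bb = TRUE, top_n = 5L,
                    surf = NULL) {
  mode <- match.arg(mode)
  evd_scope <- match.arg(evd_scope)
  if (is.character(antigen)) {
    if (is.null(chain)) stop("supply `chain` when `antigen` is a path")
    antigen <- load_antigen(antigen, chain)
  }
  stopifnot(inherits(antigen, "antigen_model"))
  if (is.character(mimotopes) && length(mimotopes) == 1L &&
      file.exists(mimotopes)) {
    mimotopes <- read_mimotopes(mimotopes)
  } else if (!inherits(mimotopes, "mimotope_set")) {
    mimotopes <- mimotope_set(mimotopes)
  }
  if (is.null(subst)) subst <- default_substitution_model(gap_penalty)

  if (is.null(surf))
    surf <- compute_surface(antigen, probe_radius, n_sphere_points,
                            rsa_threshold = rsa_threshold)
  patches <- generate_patches(antigen, surf, patch_radius, max_patch_size)
  params <- graph_params(cf_target, cf_tol, threshold, step, mode = mode)
  graphs <- build_patch_graphs(patches, antigen, params)
  aa <- antigen_sequence(antigen)
  graphs <- lapply(graphs, graph_with_sequence, aa_by_key = aa)

  lengths_needed <- sort(unique(nchar(mimotopes$sequence)))
  evd_ref <- NULL
  if (evd_scope == "antigen") {
    sizes <- vapply(graphs, function(g) length(g$vertices), 0L)
    evd_ref <- which.min(abs(sizes - stats::median(sizes)))[1]
  }
  alignments <- vector("list", length(graphs))
  scores <- vector("list", length(graphs))
  diagnostics <- data.frame()
  shared_evds <- NULL
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    t0 <- proc.time()[["elapsed"]]
    als <- lapply(seq_len(nrow(mimotopes)), function(mi)
      align_query_to_graph(g, mimotopes$sequence[mi], subst,
                           use_bb = use_bb))
    if (evd_scope == "graph" || gi == evd_ref) {
      evds <- lapply(lengths_needed, function(L)
        fit_evd(g, L, subst, evd_samples,
                seed = (seed + 131L * gi + L) %% .Machine$integer.max))
      names(evds) <- as.character(lengths_needed)
      if (evd_scope == "antigen") shared_evds <- evds
    } else {
      evds <- shared_evds
    }
    if (is.null(evds)) {          # antigen scope, reference not yet reached
      g2 <- graphs[[evd_ref]]
      shared_evds <- lapply(lengths_needed, function(L)
        fit_evd(g2, L, subst, evd_samples,
                seed = (seed + 131L * evd_ref + L) %% .Machine$integer.max))
      names(shared_evds) <- as.character(lengths_needed)
      evds <- shared_evds
    }
    ps <- score_patch(als, evds)
    alignments[[gi]] <- als
    scores[[gi]] <- ps
    diagnostics <- rbind(diagnostics, data.frame(
      patch = g$patch$center, vertices = length(g$vertices),
      edges = nrow(g$edges), cf = g$cf, threshold = g$threshold,
      band_reached = g$band_reached,
      states_expanded = sum(vapply(als, `[[`, 0.0, "states_expanded")),
      elapsed_s = proc.time()[["elapsed"]] - t0))
  }
  ranking <- rank_patches(scores, patches, top_n = length(scores))
  top_patch <- patches[[match(ranking$patch[1],
                              vapply(patches, `[[`, "", "center"))]]
  structure(list(antigen = antigen, mimotopes = mimotopes, surf = surf,
                 patches = patches, graphs = graphs,
                 alignments = alignments, patch_scores = scores,
                 ranking = ranking, top_n = top_n,
                 predicted = top_patch$members,
                 subst = subst, mode = mode, params = params,
                 evd_scope = evd_scope, evd_samples = evd_samples,
                 seed = seed, diagnostics = diagnostics),
            class = "mimomap_fit")
}

#' Predicted epitope residues
#'
#' @param fit a `mimomap_fit`.
#' @param rank which ranked patch to extract (default 1, the candidate
#'   epitope).
#' @return character vector of residue keys.
#' @export
predicted_epitope <- function(fit, rank = 1L) {
  stopifnot(inherits(fit, "mimomap_fit"), rank >= 1L,
            rank <= nrow(fit$ranking))
  ctr <- fit$ranking$patch[rank]
  fit$patches[[match(ctr, vapply(fit$patches, `[[`, "", "center"))]]$members
}

#' @export
print.mimomap_fit <- function(x, ...) {
  cat("Mimotope surface mapping (", x$mode, " graphs)\n", sep = "")
  cat("  antigen: ", x$antigen$source_id, " chain ", x$antigen$chain_id,
      ", ", length(x$antigen$residues), " residues (",
      sum(x$surf$is_surface), " surface)\n", sep = "")
  cat("  mimotopes:", nrow(x$mimotopes), " patches:", length(x$patches),
      " mean CF:", sprintf("%.3f", average_cf(x$graphs)), "\n")
  cat("  candidate epitope: patch", x$ranking$patch[1], "with",
      x$ranking$size[1], "residues, score",
      sprintf("%.2f", x$ranking$aggregate[1]), "\n")
  invisible(x)
}

#' Summarise a mimotope mapping
#'
#' @param object a `mimomap_fit`.
#' @param ... unused.
#' @return a `summary.mimomap_fit` holding the top-`top_n` ranking and
#'   per-mimotope alignments of the candidate patch.
#' @export
summary.mimomap_fit <- function(object, ...) {
  top_center <- object$ranking$patch[1]
  gi <- match(top_center,
              vapply(object$graphs, function(g) g$patch$center, ""))
  per <- object$patch_scores[[gi]]$per_mimotope
  per$label <- object$mimotopes$label
  per$path <- vapply(object$alignments[[gi]], function(al) {
    v <- ifelse(is.na(al$path$vertex), "-", al$path$vertex)
    paste(v, collapse = " ")
  }, "")
  structure(list(ranking = head(object$ranking, object$top_n),
                 top_patch = top_center,
                 predicted = object$predicted,
                 per_mimotope = per[, c("label", "sequence", "raw_score",
                                        "p_value", "path")],
                 mode = object$mode,
                 average_cf = average_cf(object$graphs)),
            class = "summary.mimomap_fit")
}

#' @export
print.summary.mimomap_fit <- function(x, ...) {
  cat("Ranked patches (", x$mode, "; mean CF ",
      sprintf("%.3f", x$average_cf), "):\n", sep = "")
  print(x$ranking, row.names = FALSE)
  cat("\nCandidate epitope (patch ", x$top_patch, "): ",
      paste(x$predicted, collapse = ", "), "\n\n", sep = "")
  cat("Mimotope alignments on the candidate patch:\n")
  df <- x$per_mimotope
  df$raw_score <- sprintf("%.1f", df$raw_score)
  df$p_value <- sprintf("%.3g", df$p_value)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot patch scores
#'
#' Barplot of aggregate patch scores in rank order, the candidate patch
#' highlighted.
#'
#' @param x a `mimomap_fit`.
#' @param max_patches how many ranked patches to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.mimomap_fit <- function(x, max_patches = 25L, ...) {
  r <- head(x$ranking, max_patches)
  cols <- c("firebrick", rep("grey70", nrow(r) - 1L))
  graphics::barplot(r$aggregate, names.arg = r$patch, las = 2,
                    col = cols, ylab = "patch score  (sum -log10 P)",
                    main = "Ranked surface patches", ...)
  invisible(x)
}

#' Evaluate a mapping against a known epitope
#'
#' @param fit a `mimomap_fit`.
#' @param truth residue keys of the known epitope (see
#'   [read_truth_set()]).
#' @param universe "surface" (default: surface residues of the chain) or
#'   "all" residues.
#' @param rank which ranked patch to evaluate (default 1).
#' @return list with `counts` ([confusion_counts()]) and `metrics`
#'   ([prediction_metrics()]).
#' @export
evaluate_prediction <- function(fit, truth, universe = c("surface", "all"),
                                rank = 1L) {
  universe <- match.arg(universe)
  uni <- if (universe == "surface") fit$surf$key[fit$surf$is_surface]
         else fit$surf$key
  truth <- intersect(truth, uni)
  pred <- intersect(predicted_epitope(fit, rank), uni)
  counts <- confusion_counts(pred, truth, uni)
  list(counts = counts, metrics = prediction_metrics(counts))
}

#' Compare adaptive and fixed distance thresholds
#'
#' Runs the pipeline under both graph modes on identical patches and
#' reports, per mode, the mean compactness factor and the top patch --
#' the design used to study the impact of CF regulation.
#'
#' @inheritParams mimomap
#' @param ... further arguments passed to [mimomap()].
#' @return data frame with one row per mode: `mode`, `n_patches`,
#'   `average_cf`, `band_reached_frac`, `top_patch`, `top_size`,
#'   `top_score`, plus attribute `fits` carrying both fits.
#' @export
compare_modes <- function(antigen, mimotopes, ...) {
  fits <- lapply(c("adt", "fdt"), function(m)
    mimomap(antigen, mimotopes, mode = m, ...))
  out <- do.call(rbind, lapply(fits, function(f) data.frame(
    mode = f$mode,
    n_patches = length(f$patches),
    average_cf = average_cf(f$graphs),
    band_reached_frac = mean(vapply(f$graphs, function(g)
      isTRUE(g$band_reached), NA)),
    top_patch = f$ranking$patch[1],
    top_size = f$ranking$size[1],
    top_score = f$ranking$aggregate[1],
    stringsAsFactors = FALSE)))
  attr(out, "fits") <- setNames(fits, c("adt", "fdt"))
  out
}

#' Jmol/PyMOL-style selection string for the candidate epitope
#' @param fit a `mimomap_fit`.
#' @param rank ranked patch to select.
#' @return single selection string, e.g. `"select 49:A, 50:A"`.
#' @export
viewer_selection <- function(fit, rank = 1L) {
  keys <- predicted_epitope(fit, rank)
  parts <- sub("^([^:]*):(.*)$", "\\2:\\1", keys)
  paste("select", paste(parts, collapse = ", "))
}

#' Write mapping results as JSON and TSV
#'
#' @param fit a `mimomap_fit`.
#' @param dir output directory (created if needed).
#' @param stem file name stem (default "mimomap").
#' @return invisibly, the JSON path.
#' @export
write_results <- function(fit, dir, stem = "mimomap") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(fit)
  payload <- list(
    schema = "mimomap/1",
    antigen = fit$antigen$source_id,
    chain = fit$antigen$chain_id,
    mode = fit$mode,
    seed = fit$seed,
    average_cf = average_cf(fit$graphs),
    candidate_epitope = list(patch = s$top_patch,
                             residues = fit$predicted,
                             selection = viewer_selection(fit)),
    ranking = fit$ranking,
    alignments = s$per_mimotope)
  json_path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  write.table(fit$ranking, file.path(dir, paste0(stem, "_patches.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(s$per_mimotope,
              file.path(dir, paste0(stem, "_alignments.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json_path)
}

#' Run the full pipeline from a configuration list
#'
#' Thin driver used by the command-line front end: loads the inputs,
#' runs [mimomap()], optionally evaluates against a truth set, and
#' writes JSON + TSV results and a run log into the output directory.
#'
#' @param config named list; recognised fields: `pdb`, `chain`,
#'   `mimotopes` (path), `truth` (path, optional), `mode`, `cf_target`,
#'   `cf_tol`, `threshold`, `step`, `patch_radius`, `max_patch_size`,
#'   `rsa_threshold`, `gap_penalty`, `matrix` (NCBI-format path,
#'   optional), `evd_samples`, `evd_scope`, `seed`, `out_dir`, `top_n`.
#' @return the `mimomap_fit`, invisibly; results are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  need <- c("pdb", "chain", "mimotopes", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config lacks required field(s): ", paste(missing, collapse = ", "))
  defaults <- list(mode = "adt", cf_target = 0.73, cf_tol = 0.06,
                   threshold = 6.5, step = 0.01, patch_radius = 15,
                   max_patch_size = 50L, rsa_threshold = 0.05,
                   gap_penalty = -5, evd_samples = 1000L,
                   evd_scope = "graph", seed = 42L, top_n = 5L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  subst <- if (!is.null(config$matrix))
    read_score_matrix(config$matrix, config$gap_penalty)
  else default_substitution_model(config$gap_penalty)
  antigen <- load_antigen(config$pdb, config$chain)
  fit <- mimomap(antigen, read_mimotopes(config$mimotopes),
                 mode = config$mode, patch_radius = config$patch_radius,
                 max_patch_size = config$max_patch_size,
                 rsa_threshold = config$rsa_threshold,
                 cf_target = config$cf_target, cf_tol = config$cf_tol,
                 threshold = config$threshold, step = config$step,
                 subst = subst, evd_samples = config$evd_samples,
                 evd_scope = config$evd_scope, seed = config$seed,
                 top_n = config$top_n)
  write_results(fit, config$out_dir)
  log_lines <- c(
    paste("antigen:", config$pdb, "chain", config$chain),
    paste("mode:", config$mode, " seed:", config$seed),
    paste("patches:", length(fit$patches),
          " mean CF:", sprintf("%.3f", average_cf(fit$graphs))),
    utils::capture.output(print(fit$diagnostics, row.names = FALSE)))
  if (!is.null(config$truth)) {
    ev <- evaluate_prediction(fit, read_truth_set(config$truth))
    log_lines <- c(log_lines, sprintf(
      "evaluation: TP=%d FP=%d TN=%d FN=%d Se=%.3f Pr=%.3f MCC=%.3f",
      ev$counts$tp, ev$counts$fp, ev$counts$tn, ev$counts$fn,
      ev$metrics$se, ev$metrics$pr, ev$metrics$mcc))
  }
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(fit)
}
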