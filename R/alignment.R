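#' Construct a mimotope set
#'
#' @param sequences character vector of one-letter peptide sequences.
#' @param labels optional labels (default "m1", "m2", ...).
#' @return a `mimotope_set`: data frame with `label` and `sequence`.
#' @export
mimotope_set <- function(sequences, labels = NULL) {
  sequences <- toupper(trimws(sequences))
  if (length(sequences) == 0L) stop("no mimotope sequences supplied")
  bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                sequences)
  if (any(bad))
    stop("mimotope(s) with letters outside the 20-letter alphabet: ",
         paste(sequences[bad], collapse = ", "))
  if (is.null(labels)) labels <- paste0("m", seq_along(sequences))
  structure(data.frame(label = labels, sequence = sequences,
                       stringsAsFactors = FALSE),
            class = c("mimotope_set", "data.frame"))
}

#' Read mimotopes from FASTA or plain text
#'
#' FASTA input (first non-blank line starts with ">") is read with
#' Biostrings; otherwise one peptide per line is assumed.
#'
#' @param path input file.
#' @return a [mimotope_set()].
#' @export
read_mimotopes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty mimotope file: ", path)
  if (startsWith(trimws(lines[1]), ">")) {
    seqs <- Biostrings::readAAStringSet(path)
    mimotope_set(as.character(seqs), labels = names(seqs))
  } else {
    mimotope_set(trimws(lines))
  }
}

# encode a peptide as 0-based indices into AA_ALPHABET
encode_peptide <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], AA_ALPHABET) - 1L
  if (anyNA(idx)) stop("non-standard letter in peptide ", seq)
  idx
}

# graph pieces needed by the C++ aligner
graph_for_dp <- function(graph) {
  n <- length(graph$vertices)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(graph$edges)) {
    for (r in seq_len(nrow(graph$edges))) {
      a <- graph$edges[r, 1]; b <- graph$edges[r, 2]
      adj[[a]] <- c(adj[[a]], b - 1L)
      adj[[b]] <- c(adj[[b]], a - 1L)
    }
  }
  list(adj = adj, vaa = graph$vertex_aa)
}

# attach vertex amino acids to a graph (needed before aligning)
graph_with_sequence <- function(graph, aa_by_key) {
  graph$vertex_aa <- match(unname(aa_by_key[graph$vertices]), AA_ALPHABET) - 1L
  if (anyNA(graph$vertex_aa))
    stop("graph vertices without a standard amino-acid letter")
  graph
}

#' Align one mimotope to the best simple path of a patch graph
#'
#' Dynamic programming over (end vertex, visited set) states finds the
#' maximum-score local alignment between the query peptide and any simple
#' path of the graph, with linear gap penalties for internal insertions
#' (unmatched path vertex) and deletions (unmatched query position) and
#' free end gaps.  Paths ending at the same vertex with the same visited
#' set are deduplicated, keeping the best score.  Branch-and-bound
#' pruning (`use_bb = TRUE`) discards states whose admissible upper bound
#' falls below the best complete alignment found so far; it changes state
#' counts, never the returned score.
#'
#' @param graph a `patch_graph` whose vertices carry amino acids: either
#'   pass `aa` (named letters, e.g. `antigen_sequence(model)`) or a graph
#'   already processed by the pipeline.
#' @param query a peptide string or one row of a [mimotope_set()].
#' @param model a `substitution_model` (default NNK-adjusted BLOSUM62).
#' @param use_bb enable branch-and-bound pruning.
#' @param allow_insertion,allow_deletion enable the two gap directions.
#' @param aa named one-letter residue types covering the graph vertices.
#' @return a `path_alignment`: list with `path` (data frame `query_pos`,
#'   `vertex` residue keys, `NA` marking gaps), `raw_score`, `query`,
#'   `graph_ref` (patch centre), and DP `states_expanded` /
#'   `states_created` diagnostics.
#' @export
align_query_to_graph <- function(graph, query,
                                 model = default_substitution_model(),
                                 use_bb = TRUE,
                                 allow_insertion = TRUE,
                                 allow_deletion = TRUE,
                                 aa = NULL) {
  if (is.data.frame(query)) query <- query$sequence[1]
  stopifnot(nchar(query) >= 1L, length(graph$vertices) >= 1L)
  if (!is.null(aa)) graph <- graph_with_sequence(graph, aa)
  if (is.null(graph$vertex_aa))
    stop("graph lacks vertex amino acids; pass `aa`")
  g <- graph_for_dp(graph)
  res <- dp_align_cpp(g$adj, g$vaa, encode_peptide(query), model$matrix,
                      model$gap_penalty, use_bb,
                      allow_insertion, allow_deletion, TRUE)
  path <- data.frame(
    query_pos = res$qpos,
    vertex = ifelse(is.na(res$vertex), NA_character_,
                    graph$vertices[res$vertex + 1L]),
    stringsAsFactors = FALSE)
  structure(list(path = path, raw_score = res$score, query = query,
                 graph_ref = graph$patch$center,
                 states_expanded = res$states_expanded,
                 states_created = res$states_created),
            class = "path_alignment")
}

#' @export
print.path_alignment <- function(x, ...) {
  cat("Path alignment: query", x$query, "on patch", x$graph_ref, "\n")
  cat("  raw score", sprintf("%.1f", x$raw_score), "\n")
  if (nrow(x$path)) {
    lab <- ifelse(is.na(x$path$vertex), "-", x$path$vertex)
    qs <- strsplit(x$query, "")[[1]]
    ql <- ifelse(is.na(x$path$query_pos), "-", qs[x$path$query_pos])
    cat("  ", paste(ql, collapse = " "), "\n")
    cat("  ", paste(lab, collapse = " "), "\n")
  }
  invisible(x)
}

# score one fixed vertex path against the query: standard free-end-gap
# pairwise DP on the path's residue string (independent of the graph DP)
score_path_sequence <- function(path_aa_idx, query_idx, smat, gap) {
  k <- length(query_idx); L <- length(path_aa_idx)
  # W[i+1, j+1]: best score of alignment of prefixes; free leading ends
  W <- matrix(0, k + 1L, L + 1L)
  best <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(L)) {
      m <- W[i, j] + smat[query_idx[i] + 1L, path_aa_idx[j] + 1L]
      d <- W[i, j + 1L] + gap     # consume query
      ins <- W[i + 1L, j] + gap   # consume path vertex
      W[i + 1L, j + 1L] <- max(m, d, ins, -Inf)
      best <- max(best, W[i + 1L, j + 1L])  # free trailing ends
    }
  }
  best
}

#' Exhaustive best-path search (test oracle)
#'
#' Enumerates every simple path of the graph and scores each against the
#' query with an independent pairwise free-end-gap alignment; returns the
#' maximum.  Exponential: guarded to graphs of at most 12 vertices.
#'
#' @inheritParams align_query_to_graph
#' @return list with `raw_score` and `path_vertices` (keys of the best
#'   path, in order; `NULL` when the empty alignment wins).
#' @export
brute_force_best_path <- function(graph, query,
                                  model = default_substitution_model(),
                                  aa = NULL) {
  if (is.data.frame(query)) query <- query$sequence[1]
  if (!is.null(aa)) graph <- graph_with_sequence(graph, aa)
  n <- length(graph$vertices)
  if (n > 12L) stop("brute force is limited to 12 vertices")
  g <- graph_for_dp(graph)
  q <- encode_peptide(query)
  smat <- model$matrix
  gap <- model$gap_penalty
  best <- list(score = 0, path = NULL)
  visit <- function(path, mask) {
    sc <- score_path_sequence(g$vaa[path], q, smat, gap)
    if (sc > best$score) best <<- list(score = sc, path = path)
    last <- path[length(path)]
    for (j in g$adj[[last]]) {
      jj <- j + 1L
      if (!bitwAnd(mask, bitwShiftL(1L, jj - 1L)))
        visit(c(path, jj), bitwOr(mask, bitwShiftL(1L, jj - 1L)))
    }
  }
  for (v in seq_len(n)) visit(v, bitwShiftL(1L, v - 1L))
  list(raw_score = best$score,
       path_vertices = if (is.null(best$path)) NULL
                       else graph$vertices[best$path])
}

#' Branch-and-bound upper bound of a state
#'
#' The admissible bound used by the pruned search: the state's score plus
#' the number of unconsumed query positions times the largest matrix
#' entry.  No completion of the state can exceed it.
#'
#' @param score the state's accumulated score.
#' @param remaining query positions not yet consumed (>= 0).
#' @param model a `substitution_model`.
#' @return the upper bound.
#' @export
bb_upper_bound <- function(score, remaining, model) {
  stopifnot(remaining >= 0)
  score + remaining * max(model$matrix)
}
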