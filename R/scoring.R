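EULER_GAMMA <- 0.57721566490153286

#' Fit a Gumbel model to alignment scores of random peptides
#'
#' Draws `n_samples` random peptides of the query's length from NNK
#' amino-acid frequencies, aligns each to the graph, and fits a Gumbel
#' (extreme value) distribution to the score sample.  The default fit is
#' the closed-form method of moments
#' (\eqn{\beta = s\sqrt{6}/\pi}, \eqn{\mu = \bar x - \gamma \beta});
#' maximum likelihood is available behind `method = "mle"`.
#'
#' @param graph a `patch_graph` carrying vertex amino acids (see
#'   [align_query_to_graph()]; pass `aa` otherwise).
#' @param query_length peptide length to calibrate for.
#' @param model a `substitution_model`.
#' @param n_samples number of random peptides (>= 200; default 1000).
#' @param seed RNG seed making the calibration deterministic.
#' @param method "moments" (default) or "mle".
#' @param aa optional named residue letters for the graph vertices.
#' @param scores optional pre-computed numeric score sample; when given,
#'   the graph is not consulted and the sample is fitted directly.
#' @return an `evd_model`: list with `query_length`, `location`, `scale`,
#'   `n_samples`, `seed`, `degenerate` flag.
#' @export
fit_evd <- function(graph = NULL, query_length = NULL,
                    model = default_substitution_model(),
                    n_samples = 1000L, seed = 42L,
                    method = c("moments", "mle"),
                    aa = NULL, scores = NULL) {
  method <- match.arg(method)
  if (is.null(scores)) {
    stopifnot(n_samples >= 200L, query_length >= 1L)
    if (!is.null(aa)) graph <- graph_with_sequence(graph, aa)
    if (is.null(graph$vertex_aa))
      stop("graph lacks vertex amino acids; pass `aa`")
    freqs <- nnk_frequencies()
    g <- graph_for_dp(graph)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    peptides <- replicate(n_samples,
                          sample.int(20L, query_length, replace = TRUE,
                                     prob = freqs) - 1L,
                          simplify = FALSE)
    scores <- dp_align_batch_cpp(g$adj, g$vaa, peptides, model$matrix,
                                 model$gap_penalty, TRUE, TRUE, TRUE)
  } else {
    n_samples <- length(scores)
    if (is.null(query_length)) query_length <- NA_integer_
  }
  m <- mean(scores)
  s <- sd(scores)
  degenerate <- !is.finite(s) || s < 1e-9
  if (degenerate) {
    scale <- 1e-9
    location <- m
  } else {
    scale <- s * sqrt(6) / pi
    location <- m - EULER_GAMMA * scale
    if (method == "mle") {
      nll <- function(par) {
        b <- exp(par[2])
        z <- (scores - par[1]) / b
        sum(log(b) + z + exp(-z))
      }
      fit <- optim(c(location, log(scale)), nll, method = "Nelder-Mead")
      location <- fit$par[1]
      scale <- exp(fit$par[2])
    }
  }
  structure(list(query_length = query_length, location = location,
                 scale = scale, n_samples = n_samples, seed = seed,
                 degenerate = degenerate, method = method),
            class = "evd_model")
}

# save/restore the global RNG state so calibration seeds do not perturb
# user-level simulations
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Gumbel P-value of an alignment score
#'
#' \eqn{P = 1 - \exp(-\exp(-(x-\mu)/\beta))}: the probability that a
#' random peptide of the same length reaches score `x` or better on the
#' calibrated graph.  Strictly decreasing in `x`, clamped away from 0 and
#' 1 so logarithms stay finite.
#'
#' @param raw_score alignment score(s).
#' @param evd an `evd_model`.
#' @return P-value(s) in (0, 1).
#' @export
p_value <- function(raw_score, evd) {
  stopifnot(inherits(evd, "evd_model"), evd$scale > 0)
  z <- (raw_score - evd$location) / evd$scale
  p <- -expm1(-exp(-z))
  pmin(pmax(p, 1e-300), 1 - 1e-16)
}

#' Aggregate alignments into a patch score
#'
#' The patch score sums the P-value evidence of all mimotope alignments
#' on that patch as \eqn{\sum_i -\log_{10} P_i}; higher is better.
#'
#' @param alignments list of `path_alignment` objects for one patch.
#' @param evds list of `evd_model`s keyed by query length (as character),
#'   covering every mimotope length present.
#' @return a `patch_score`: list with `patch`, `per_mimotope` data frame
#'   (`label`, `sequence`, `raw_score`, `p_value`) and `aggregate`.
#' @export
score_patch <- function(alignments, evds) {
  if (length(alignments) == 0L)
    return(structure(list(patch = NA_character_,
                          per_mimotope = data.frame(),
                          aggregate = 0),
                     class = "patch_score"))
  per <- do.call(rbind, lapply(alignments, function(al) {
    len <- as.character(nchar(al$query))
    if (is.null(evds[[len]]))
      stop("no EVD calibrated for query length ", len)
    p <- p_value(al$raw_score, evds[[len]])
    data.frame(sequence = al$query, raw_score = al$raw_score,
               p_value = p, stringsAsFactors = FALSE)
  }))
  structure(list(patch = alignments[[1]]$graph_ref,
                 per_mimotope = per,
                 aggregate = sum(-log10(per$p_value))),
            class = "patch_score")
}

#' Rank patch scores
#'
#' Descending by aggregate score; ties broken by smaller patch size, then
#' by centre residue number.  The top-ranked patch is the candidate
#' epitope.
#'
#' @param scores list of `patch_score` objects.
#' @param patches matching list of `patch` objects (for sizes).
#' @param top_n how many candidates to keep (default all).
#' @return data frame `rank`, `patch`, `size`, `aggregate`, ordered.
#' @export
rank_patches <- function(scores, patches, top_n = length(scores)) {
  stopifnot(length(scores) > 0L, length(scores) == length(patches))
  agg <- vapply(scores, `[[`, 0.0, "aggregate")
  size <- vapply(patches, function(p) length(p$members), 0L)
  resno <- as.integer(sub("^[^:]*:", "",
                          gsub("[A-Za-z]+$", "",
                               vapply(scores, `[[`, "", "patch"))))
  ord <- order(-agg, size, resno)
  out <- data.frame(rank = seq_along(ord),
                    patch = vapply(scores, `[[`, "", "patch")[ord],
                    size = size[ord],
                    aggregate = agg[ord],
                    stringsAsFactors = FALSE)
  head(out, top_n)
}
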