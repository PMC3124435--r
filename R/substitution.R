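# Published BLOSUM62 background (marginal) frequencies, normalised on use.
BLOSUM62_BACKGROUND <- c(A = 0.0742, R = 0.0520, N = 0.0446, D = 0.0536,
                         C = 0.0247, Q = 0.0342, E = 0.0543, G = 0.0741,
                         H = 0.0262, I = 0.0679, L = 0.0989, K = 0.0582,
                         M = 0.0250, F = 0.0474, P = 0.0387, S = 0.0573,
                         T = 0.0508, W = 0.0133, Y = 0.0341, V = 0.0729)

#' Codon counts of the NNK phage-display scheme
#'
#' Enumerates the 32 NNK codons (N = any base, K = G or T) and counts
#' codons per amino acid; the single stop codon (TAG) is reported under
#' `"*"`.  Counts sum to 32.
#'
#' @return named integer vector over the 20 amino acids plus `"*"`.
#' @export
#' @examples
#' nnk_codon_counts()[c("L", "M", "*")]  # 3, 1, 1
nnk_codon_counts <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), c("G", "T"), paste0))
  aa <- Biostrings::GENETIC_CODE[codons]
  counts <- table(factor(aa, levels = c(AA_ALPHABET, "*")))
  out <- setNames(as.integer(counts), names(counts))
  stopifnot(sum(out) == 32L)
  out
}

#' BLOSUM62 score matrix in canonical 20-letter order
#' @return 20 x 20 integer matrix (half-bit scores).
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  storage.mode(m) <- "double"
  m
}

# implied BLOSUM62 target frequencies q_ij = p_i p_j 2^(s_ij/2)
blosum62_target_freq <- function() {
  p <- BLOSUM62_BACKGROUND / sum(BLOSUM62_BACKGROUND)
  s <- blosum62_matrix()
  outer(p, p) * 2^(s / 2)
}

#' NNK-adjusted BLOSUM62 substitution model
#'
#' Phage-display peptide libraries built on NNK codons are biased: amino
#' acids are not drawn from natural background frequencies but from
#' codon-count frequencies f_i = codons_i / 32.  This function rebuilds
#' BLOSUM62-style half-bit log-odds with the query-side (mimotope)
#' background replaced by the NNK frequencies:
#' \deqn{s'_{ij} = \mathrm{round}\!\left(2\log_2 \frac{q_{ij}}{f_i\,p_j}\right)}
#' where the target frequencies \eqn{q_{ij}} are implied by the BLOSUM62
#' scores and background \eqn{p}.  Rows index the query (mimotope) amino
#' acid, columns the path (antigen) amino acid; the matrix is therefore
#' not symmetric.
#'
#' @param query_background named frequency vector for the query side; the
#'   default is the NNK codon frequencies.  Need not be normalised to the
#'   20 amino acids (the NNK default sums to 31/32 because TAG is a stop).
#' @param codon_counts NNK codon counts (used when `query_background` is
#'   `NULL`); must sum to 32 over amino acids plus stop.
#' @param gap_penalty linear gap penalty (negative) stored in the model.
#' @return a `substitution_model`: list with `matrix` (20 x 20, rows =
#'   query) and `gap_penalty`.
#' @export
derive_nnk_matrix <- function(query_background = NULL,
                              codon_counts = nnk_codon_counts(),
                              gap_penalty = -5) {
  if (is.null(query_background)) {
    if (!all(AA_ALPHABET %in% names(codon_counts)) ||
        sum(codon_counts) != 32L)
      stop("NNK codon counts must cover the 20 amino acids and sum to 32 ",
           "(including the stop codon)")
    query_background <- codon_counts[AA_ALPHABET] / 32
  }
  stopifnot(all(AA_ALPHABET %in% names(query_background)),
            all(query_background[AA_ALPHABET] > 0))
  f <- query_background[AA_ALPHABET]
  p <- BLOSUM62_BACKGROUND / sum(BLOSUM62_BACKGROUND)
  q <- blosum62_target_freq()
  s <- round(2 * log2(q / outer(f, p)))
  dimnames(s) <- list(AA_ALPHABET, AA_ALPHABET)
  substitution_model(s, gap_penalty, check_symmetry = FALSE)
}

#' Construct a substitution model
#'
#' @param matrix 20 x 20 numeric score matrix with one-letter dimnames
#'   covering the standard alphabet (rows = query amino acid).
#' @param gap_penalty linear gap penalty, must be negative.
#' @param check_symmetry assert symmetry (appropriate for unmodified
#'   matrices such as plain BLOSUM62; NNK-adjusted matrices are
#'   asymmetric by construction).
#' @return a `substitution_model` object.
#' @export
substitution_model <- function(matrix, gap_penalty = -5,
                               check_symmetry = FALSE) {
  stopifnot(is.matrix(matrix),
            all(AA_ALPHABET %in% rownames(matrix)),
            all(AA_ALPHABET %in% colnames(matrix)))
  m <- matrix[AA_ALPHABET, AA_ALPHABET]
  storage.mode(m) <- "double"
  if (check_symmetry && !isTRUE(all.equal(m, t(m))))
    stop("substitution matrix is not symmetric")
  if (!(gap_penalty < 0)) stop("gap_penalty must be negative")
  if (gap_penalty >= max(m)) stop("gap_penalty must be below the best score")
  structure(list(matrix = m, gap_penalty = gap_penalty),
            class = "substitution_model")
}

#' Default substitution model (NNK-adjusted BLOSUM62)
#'
#' Reads the NNK-adjusted BLOSUM62 shipped with the package (regenerated
#' by [derive_nnk_matrix()]); used by default throughout the aligner.
#'
#' @param gap_penalty linear gap penalty (negative, default -5).
#' @return a `substitution_model`.
#' @export
default_substitution_model <- function(gap_penalty = -5) {
  path <- system.file("extdata", "blosum62_nnk.mat", package = "mimomap")
  if (nzchar(path)) read_score_matrix(path, gap_penalty)
  else derive_nnk_matrix(gap_penalty = gap_penalty)
}

#' Read a score matrix in NCBI/EMBOSS plain-text format
#'
#' Lines starting with `#` are comments; the first non-comment line holds
#' the column letters, each following line a row letter and its scores.
#'
#' @param path matrix file.
#' @param gap_penalty gap penalty to attach to the model.
#' @return a `substitution_model`.
#' @export
read_score_matrix <- function(path, gap_penalty = -5) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  rn <- vapply(rows, `[[`, "", 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(m) <- list(rn, cols)
  keep_r <- intersect(rn, AA_ALPHABET)
  keep_c <- intersect(cols, AA_ALPHABET)
  substitution_model(m[keep_r, keep_c], gap_penalty)
}

#' Write a score matrix in NCBI plain-text format
#' @param model a `substitution_model`.
#' @param path output file.
#' @param comment optional header comment lines (without the leading #).
#' @return invisibly, `path`.
#' @export
write_score_matrix <- function(model, path, comment = NULL) {
  m <- model$matrix
  lines <- c(paste0("# ", comment),
             paste(" ", paste(sprintf("%3s", colnames(m)), collapse = " ")))
  for (i in seq_len(nrow(m)))
    lines <- c(lines, paste(rownames(m)[i],
                            paste(sprintf("%3d", as.integer(round(m[i, ]))),
                                  collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' NNK amino-acid sampling frequencies
#'
#' Normalised over the 20 amino acids (stop codons are never displayed),
#' used to draw random calibration peptides and mimotope mutations.
#'
#' @return named numeric vector summing to 1.
#' @export
nnk_frequencies <- function() {
  cc <- nnk_codon_counts()[AA_ALPHABET]
  cc / sum(cc)
}
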