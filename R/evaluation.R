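#' Confusion counts for a predicted epitope
#'
#' Partitions the residue universe by predicted and true epitope
#' membership.  `pe = tp + fp` is the number of predicted epitopic
#' residues.
#'
#' @param predicted residue keys predicted epitopic (subset of universe).
#' @param truth residue keys of the known epitope (subset of universe).
#' @param universe residue keys considered (typically the surface
#'   residues of the analysed chain).
#' @return a `confusion_counts` list: `tp`, `fp`, `tn`, `fn`, `pe`.
#' @export
confusion_counts <- function(predicted, truth, universe) {
  predicted <- unique(predicted); truth <- unique(truth)
  universe <- unique(universe)
  if (!all(predicted %in% universe)) stop("predicted set outside universe")
  if (!all(truth %in% universe)) stop("truth set outside universe")
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(universe) - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, pe = tp + fp),
            class = "confusion_counts")
}

#' Sensitivity, precision and Matthews correlation
#'
#' Se = TP/(TP+FN), Pr = TP/(TP+FP),
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any metric with a zero denominator is reported as 0 and flagged.
#'
#' @param counts a [confusion_counts()] object.
#' @return named list `se`, `pr`, `mcc`, plus `flags` naming any metric
#'   whose denominator was zero.
#' @export
prediction_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  flags <- character(0)
  se <- if (tp + fn > 0) tp / (tp + fn) else { flags <- c(flags, "se"); 0 }
  pr <- if (tp + fp > 0) tp / (tp + fp) else { flags <- c(flags, "pr"); 0 }
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den
         else { flags <- c(flags, "mcc"); 0 }
  list(se = se, pr = pr, mcc = mcc, flags = flags)
}

#' Read a known-epitope residue list
#'
#' One residue per line as "chain resnum\[icode\]" (whitespace separated);
#' blank lines and `#` comments ignored.
#'
#' @param path input file.
#' @return character vector of residue keys "chain:resnum\[icode\]".
#' @export
read_truth_set <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty truth file: ", path)
  parts <- strsplit(lines, "\\s+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed truth line(s): ",
                     paste(lines[bad], collapse = "; "))
  vapply(parts, function(p) paste0(p[1], ":", p[2]), "")
}
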