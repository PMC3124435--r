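#' @useDynLib mimomap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd optim setNames quantile
#' @importFrom utils head read.table write.table
NULL

# canonical one-letter alphabet used throughout (matrix row/col order)
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# nonstandard residues with an accepted standard parent; anything else is dropped
NONSTANDARD_MAP <- c(MSE = "M", SEC = "C", PYL = "K", SEP = "S", TPO = "T",
                     PTR = "Y", HYP = "P", CSO = "C", MLY = "K", M3L = "K",
                     KCX = "K", CME = "C", FME = "M")

#' Van der Waals radii by element
#'
#' Fixed radii (in Angstrom) used when expanding atom spheres for
#' solvent-accessible surface area: C 1.70, N 1.55, O 1.52, S 1.80, with
#' further common elements by symbol.  Unknown elements fall back to
#' 1.70 Angstrom.
#'
#' @param elements character vector of element symbols (e.g. "C", "N").
#' @param table optional named numeric vector overriding the built-in radii.
#' @return numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radius(c("C", "N", "O", "S"))
vdw_radius <- function(elements, table = NULL) {
  default <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               H = 1.20, P = 1.80, SE = 1.90, F = 1.47,
               CL = 1.75, BR = 1.85, I = 1.98)
  if (!is.null(table)) {
    stopifnot(is.numeric(table), !is.null(names(table)), all(table > 0))
    default[names(table)] <- table
  }
  r <- default[toupper(trimws(elements))]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Read an antigen chain from a PDB file
#'
#' Parses a PDB file, selects one chain of one model and returns a clean
#' antigen model: standard amino-acid residues with per-atom coordinates,
#' element radii and a side-chain anchor (C-beta, falling back to C-alpha
#' for glycine).  Heteroatoms, waters and all but the first-listed
#' alternate location are dropped; selenomethionine and a few other
#' modified residues are mapped to their standard parent.
#'
#' @param pdb_source path to a PDB file.
#' @param chain_id single chain identifier present in the file.
#' @param model_index which MODEL to use in multi-model (NMR) files;
#'   defaults to the first.
#' @param radii optional named vector of van der Waals radii by element.
#' @return an object of class `antigen_model`: a list with `residues`
#'   (list of residue records), `source_id`, and `chain_id`.  Each residue
#'   record holds `key` ("chain:resno\[icode\]"), `chain_id`, `seq_number`,
#'   `insertion_code`, `aa`, an atom data frame (`name`, `element`, `x`,
#'   `y`, `z`, `radius`) and `cb_coord`, the side-chain anchor.
#' @export
load_antigen <- function(pdb_source, chain_id, model_index = 1, radii = NULL) {
  if (!file.exists(pdb_source))
    stop("PDB file not found: ", pdb_source)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(pdb_source, multi = FALSE,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB input '", pdb_source, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", pdb_source)
  chains <- sort(unique(at$chain))
  if (!chain_id %in% chains)
    stop("chain '", chain_id, "' not present; available chains: ",
         paste(chains, collapse = ", "))
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (model_index != 1) {
    # bio3d with multi=FALSE already keeps the first model; other models
    # need the multi-model coordinate array
    pdb2 <- suppressWarnings(bio3d::read.pdb(pdb_source, multi = TRUE,
                                             rm.alt = FALSE, verbose = FALSE))
    nm <- nrow(pdb2$xyz)
    if (model_index > nm)
      stop("model_index ", model_index, " out of range (", nm, " models)")
    xyz <- matrix(pdb2$xyz[model_index, ], ncol = 3, byrow = TRUE)
    sel <- which(pdb2$atom$type == "ATOM" & pdb2$atom$chain == chain_id)
    at <- pdb2$atom[sel, , drop = FALSE]
    at$x <- xyz[sel, 1]; at$y <- xyz[sel, 2]; at$z <- xyz[sel, 3]
  }
  build_antigen_model(at, source_id = basename(pdb_source),
                      chain_id = chain_id, radii = radii)
}

# assemble residue records from a bio3d atom data.frame (one chain)
build_antigen_model <- function(at, source_id, chain_id, radii = NULL) {
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  rkey <- paste0(at$resno, "|", at$insert)
  residues <- list()
  dropped <- character(0)
  for (rk in unique(rkey)) {
    ra <- at[rkey == rk, , drop = FALSE]
    resid3 <- ra$resid[1]
    aa <- if (resid3 %in% AA_THREE) names(AA_THREE)[match(resid3, AA_THREE)]
          else unname(NONSTANDARD_MAP[resid3])
    if (is.na(aa) || is.null(aa)) next  # hetero-like / unmapped residue
    # altloc policy: first listed per atom name
    keep <- !duplicated(ra$elety)
    ra <- ra[keep, , drop = FALSE]
    elem <- ra$elesy
    bad <- is.na(elem) | elem == ""
    if (any(bad)) elem[bad] <- substr(gsub("[0-9]", "", ra$elety[bad]), 1, 1)
    cb <- which(ra$elety == "CB")
    ca <- which(ra$elety == "CA")
    if (length(cb) == 0L && length(ca) == 0L) {
      dropped <- c(dropped, paste0(chain_id, ":", sub("\\|", "", rk)))
      next
    }
    anchor_i <- if (length(cb)) cb[1] else ca[1]
    resno <- ra$resno[1]
    icode <- ra$insert[1]
    residues[[length(residues) + 1L]] <- list(
      key = paste0(chain_id, ":", resno, icode),
      chain_id = chain_id,
      seq_number = resno,
      insertion_code = icode,
      aa = aa,
      atoms = data.frame(name = ra$elety, element = elem,
                         x = ra$x, y = ra$y, z = ra$z,
                         radius = vdw_radius(elem, radii),
                         stringsAsFactors = FALSE),
      cb_coord = c(ra$x[anchor_i], ra$y[anchor_i], ra$z[anchor_i])
    )
  }
  if (length(dropped))
    warning("dropped ", length(dropped),
            " residue(s) lacking both CB and CA: ",
            paste(dropped, collapse = ", "))
  if (length(residues) == 0L)
    stop("chain ", chain_id, " contains no standard amino-acid residues")
  keys <- vapply(residues, `[[`, "", "key")
  if (anyDuplicated(keys))
    stop("duplicate residue keys in chain ", chain_id)
  structure(list(residues = residues, source_id = source_id,
                 chain_id = chain_id),
            class = "antigen_model")
}

#' Side-chain anchor coordinate of a residue
#'
#' The C-beta coordinate, or the C-alpha coordinate for glycine and any
#' other residue lacking C-beta.  Distances between these anchors define
#' patch membership and graph edges.
#'
#' @param residue one residue record from an [load_antigen()] model.
#' @return numeric length-3 coordinate in Angstrom.
#' @export
side_chain_anchor <- function(residue) {
  a <- residue$atoms
  i <- match("CB", a$name)
  if (is.na(i)) i <- match("CA", a$name)
  if (is.na(i)) stop("residue ", residue$key, " has neither CB nor CA")
  c(a$x[i], a$y[i], a$z[i])
}

# all anchors as an n x 3 matrix with residue keys as rownames
anchor_matrix <- function(model) {
  m <- t(vapply(model$residues, side_chain_anchor, numeric(3)))
  rownames(m) <- residue_keys(model)
  m
}

#' Residue keys of an antigen model
#' @param model an `antigen_model`.
#' @return character vector "chain:resno\[icode\]", in file order.
#' @export
residue_keys <- function(model) {
  vapply(model$residues, `[[`, "", "key")
}

#' One-letter sequence of an antigen model
#' @param model an `antigen_model`.
#' @return named character vector of one-letter codes.
#' @export
antigen_sequence <- function(model) {
  setNames(vapply(model$residues, `[[`, "", "aa"), residue_keys(model))
}

#' @export
print.antigen_model <- function(x, ...) {
  cat("Antigen model:", x$source_id, " chain", x$chain_id, "\n")
  cat("  ", length(x$residues), "residues,",
      sum(vapply(x$residues, function(r) nrow(r$atoms), 0L)), "atoms\n")
  invisible(x)
}

#' Write an antigen model back out as PDB text
#'
#' Emits standard fixed-column ATOM records for the retained residues,
#' suitable for round-tripping through [load_antigen()] or viewing.
#'
#' @param model an `antigen_model`.
#' @param path optional file to write; when `NULL` the text is returned.
#' @return invisibly, the character vector of PDB lines.
#' @export
as_pdb_text <- function(model, path = NULL) {
  lines <- character(0)
  serial <- 0L
  for (r in model$residues) {
    res3 <- AA_THREE[[r$aa]]
    for (j in seq_len(nrow(r$atoms))) {
      serial <- serial + 1L
      nm <- r$atoms$name[j]
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, res3, r$chain_id, r$seq_number,
        ifelse(r$insertion_code == "", " ", r$insertion_code),
        r$atoms$x[j], r$atoms$y[j], r$atoms$z[j], 1.0, 0.0,
        r$atoms$element[j]))
    }
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
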