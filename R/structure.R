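## Structure container -------------------------------------------------------
##
## A structure is a plain data.frame of atoms plus a class tag. Author
## residue numbering from the deposited file is kept verbatim (1-based, never
## renumbered) so that canonical E. coli 23S positions such as 2058 or 2552
## survive every round trip.

RNA_RESNAMES <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
                  "A3", "A5", "C3", "C5", "G3", "G5", "U3", "U5")
PROTEIN_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                      "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                      "THR", "TRP", "TYR", "VAL", "MSE")

polymer_class <- function(resid) {
  out <- rep("other", length(resid))
  out[toupper(resid) %in% RNA_RESNAMES] <- "rna"
  out[toupper(resid) %in% PROTEIN_RESNAMES] <- "protein"
  out
}

#' Build a structure object from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer author
#'   numbering), `resid` (residue name), `elety` (atom name), `elesy`
#'   (element symbol), `x`, `y`, `z` (angstrom) and optionally `het`
#'   (logical, HETATM record).
#' @param source label recording where the coordinates came from.
#' @return object of class `swm_structure`.
#' @export
swm_structure <- function(atoms, source = "in-memory") {
  needed <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$resno <- as.integer(atoms$resno)
  if (!nrow(atoms)) stop("structure model is empty")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table")
  }
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$polymer <- polymer_class(atoms$resid)
  ## one residue name per (chain, resno): author numbers unique within chains
  key <- paste(atoms$chain, atoms$resno)
  dup <- tapply(atoms$resid, key, function(r) length(unique(r)) > 1L)
  if (any(dup)) {
    stop("duplicated residue number within a chain: ",
         paste(names(dup)[dup], collapse = ", "))
  }
  structure(list(atoms = atoms, source = source), class = "swm_structure")
}

#' @export
print.swm_structure <- function(x, ...) {
  rid <- residue_table(x)
  cat(sprintf("swm_structure: %d atoms, %d residues, chains %s [%s]\n",
              nrow(x$atoms), nrow(rid),
              paste(sort(unique(rid$chain)), collapse = ","), x$source))
  print(table(rid$polymer))
  invisible(x)
}

#' Residue-level view of a structure
#'
#' @param s `swm_structure`.
#' @return data.frame with one row per residue: chain, resno, resid, polymer.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- !duplicated(paste(a$chain, a$resno))
  out <- a[key, c("chain", "resno", "resid", "polymer")]
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}

#' Load a structure from PDB or mmCIF
#'
#' Reads coordinates with \pkg{bio3d}, keeping heteroatoms and ions as
#' polymer class "other" and author residue numbering as deposited.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `swm_structure`.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop(sprintf("cannot parse %s as %s: %s",
                                     path, format, conditionMessage(e)), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || !nrow(a)) stop("empty model in ", path)
  atoms <- data.frame(chain = as.character(a$chain),
                      resno = as.integer(a$resno),
                      resid = as.character(a$resid),
                      elety = gsub("^[\"']|[\"']$", "", as.character(a$elety)),
                      elesy = as.character(a$elesy),
                      x = a$x, y = a$y, z = a$z,
                      het = a$type == "HETATM",
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  ## infer missing element symbols from the first letter of the atom name
  blank <- is.na(atoms$elesy) | atoms$elesy == ""
  atoms$elesy[blank] <- substr(gsub("[^A-Za-z].*", "", atoms$elety[blank]), 1L, 1L)
  swm_structure(atoms, source = basename(path))
}

#' Write a structure as fixed-width PDB v3.3
#'
#' @param s `swm_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  a <- s$atoms
  pdb <- list(atom = data.frame(type = ifelse(a$het, "HETATM", "ATOM"),
                                eleno = seq_len(nrow(a)),
                                elety = a$elety, alt = "", resid = a$resid,
                                chain = a$chain, resno = a$resno, insert = "",
                                x = a$x, y = a$y, z = a$z, o = 1, b = 0,
                                segid = "", elesy = a$elesy, charge = "",
                                stringsAsFactors = FALSE),
              xyz = bio3d::as.xyz(matrix(as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                                         nrow = 1)),
              calpha = rep(FALSE, nrow(a)))
  class(pdb) <- "pdb"
  bio3d::write.pdb(pdb, file = path)
  invisible(path)
}

## Residue selections --------------------------------------------------------

#' Create a residue selection
#'
#' @param chain chain identifiers (recycled against `resno`).
#' @param resno integer author residue numbers.
#' @param label free-text label.
#' @return data.frame of class `residue_selection` with columns chain, resno.
#' @export
residue_selection <- function(chain, resno, label = "") {
  sel <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                    stringsAsFactors = FALSE)
  if (!nrow(sel)) stop("empty residue selection")
  sel <- unique(sel[order(sel$chain, sel$resno), ])
  rownames(sel) <- NULL
  attr(sel, "label") <- label
  class(sel) <- c("residue_selection", "data.frame")
  sel
}

#' Parse a selection string like "A:2225-2228,B:2088-2091"
#'
#' @param text selection text; comma-separated `chain:start[-end]` blocks.
#' @param label label passed to [residue_selection()].
#' @export
parse_selection <- function(text, label = text) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1L]]
  ch <- character(0); rn <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^\\s*([^:]+):(-?[0-9]+)(?:-(-?[0-9]+))?\\s*$", p))[[1L]]
    if (!length(m)) stop("cannot parse selection block: '", p, "'")
    lo <- as.integer(m[3L])
    hi <- if (m[4L] == "") lo else as.integer(m[4L])
    rn <- c(rn, seq(lo, hi))
    ch <- c(ch, rep(m[2L], hi - lo + 1L))
  }
  residue_selection(ch, rn, label = label)
}

selection_key <- function(sel) paste(sel$chain, sel$resno)

resolve_selection <- function(s, sel) {
  rt <- residue_table(s)
  missing <- !(selection_key(sel) %in% paste(rt$chain, rt$resno))
  if (any(missing)) {
    stop("selection residues absent from structure: ",
         paste(sprintf("%s:%d", sel$chain[missing], sel$resno[missing]),
               collapse = ", "), call. = FALSE)
  }
  invisible(sel)
}

#' Subset a structure to a residue selection
#'
#' @param s `swm_structure`.
#' @param sel `residue_selection`.
#' @export
subset_structure <- function(s, sel) {
  resolve_selection(s, sel)
  keep <- paste(s$atoms$chain, s$atoms$resno) %in% selection_key(sel)
  swm_structure(s$atoms[keep, , drop = FALSE], source = s$source)
}
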