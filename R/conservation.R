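## Per-column conservation from a pre-aligned rRNA alignment, mapped to
## reference (E. coli) numbering.

GAP_CHARS <- c("-", ".")

#' Read a pre-aligned multi-FASTA alignment
#'
#' Letters are lowercased and DNA t is mapped to u; all records must have
#' equal gapped length and the reference record must be present.
#'
#' @param path multi-FASTA file.
#' @param ref_id record id of the reference sequence (first whitespace
#'   token of its header).
#' @return object of class `swm_alignment`: `ids`, `seqs` (character
#'   vectors of equal length), `ref_id`, `ncol`.
#' @export
read_alignment <- function(path, ref_id) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- tolower(as.character(set))
  seqs <- gsub("t", "u", seqs, fixed = TRUE)
  swm_alignment(ids, seqs, ref_id)
}

#' Build an alignment object from id and sequence vectors
#' @param ids,seqs parallel character vectors (gapped, lowercase RNA).
#' @param ref_id reference record id.
#' @export
swm_alignment <- function(ids, seqs, ref_id) {
  ids <- unname(as.character(ids)); seqs <- unname(as.character(seqs))
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    off <- ids[which(w != w[1L])[1L]]
    stop("ragged alignment: record '", off, "' has length ",
         w[w != w[1L]][1L], ", expected ", w[1L])
  }
  if (!ref_id %in% ids) stop("reference id '", ref_id, "' not in alignment")
  structure(list(ids = ids, seqs = seqs, ref_id = ref_id, ncol = w[1L]),
            class = "swm_alignment")
}

#' @export
print.swm_alignment <- function(x, ...) {
  cat(sprintf("swm_alignment: %d records x %d columns (reference %s)\n",
              length(x$ids), x$ncol, x$ref_id))
  invisible(x)
}

aln_matrix <- function(aln) {
  matrix(unlist(strsplit(aln$seqs, ""), use.names = FALSE),
         nrow = length(aln$seqs), byrow = TRUE)
}

#' Map alignment columns to reference positions
#'
#' Columns where the reference is non-gap map to successive reference
#' positions (1-based plus `offset`); reference-gap columns map to none.
#'
#' @param aln `swm_alignment`.
#' @param offset numbering offset: the first reference letter is reported
#'   as position `1 + offset`.
#' @return data.frame: column, position.
#' @export
map_columns <- function(aln, offset = 0L) {
  ref <- strsplit(aln$seqs[match(aln$ref_id, aln$ids)], "")[[1L]]
  nongap <- !(ref %in% GAP_CHARS)
  if (!any(nongap)) stop("reference sequence is all gaps")
  data.frame(column = which(nongap),
             position = cumsum(nongap)[nongap] + as.integer(offset))
}

#' Conservation of one alignment column
#'
#' Conservation is 100 times the frequency of the modal unambiguous base
#' among non-gap letters; IUPAC ambiguity letters are excluded from both
#' numerator and denominator. With `method = "reference"` the frequency of
#' the reference record's base is reported instead of the modal base.
#'
#' @param aln `swm_alignment`.
#' @param column column index.
#' @param method "modal" (default) or "reference".
#' @return percentage in \[0, 100\], or NA for an empty column.
#' @export
column_conservation <- function(aln, column, method = c("modal", "reference")) {
  method <- match.arg(method)
  stopifnot(column >= 1L, column <= aln$ncol)
  col <- substr(aln$seqs, column, column)
  keep <- col %in% RNA_BASES
  if (!any(keep)) return(NA_real_)
  counts <- table(factor(col[keep], levels = RNA_BASES))
  top <- if (method == "modal") max(counts) else {
    rb <- substr(aln$seqs[match(aln$ref_id, aln$ids)], column, column)
    if (!rb %in% RNA_BASES) return(NA_real_)
    counts[[rb]]
  }
  100 * top / sum(counts)
}

#' Per-reference-position conservation profile
#'
#' @inheritParams column_conservation
#' @param offset numbering offset passed to [map_columns()].
#' @return data.frame class `conservation_profile`: position, ref_base,
#'   conservation (percent), coverage (fraction of records non-gap).
#' @export
conservation_profile <- function(aln, offset = 0L,
                                 method = c("modal", "reference")) {
  method <- match.arg(method)
  cmap <- map_columns(aln, offset)
  ref <- strsplit(aln$seqs[match(aln$ref_id, aln$ids)], "")[[1L]]
  cons <- vapply(cmap$column, function(j) column_conservation(aln, j, method),
                 numeric(1L))
  cover <- vapply(cmap$column, function(j) {
    col <- substr(aln$seqs, j, j)
    mean(!(col %in% GAP_CHARS))
  }, numeric(1L))
  out <- data.frame(position = cmap$position, ref_base = ref[cmap$column],
                    conservation = cons, coverage = cover,
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Summarize conservation over a region
#'
#' Unweighted arithmetic mean of per-position conservation plus counts of
#' positions exceeding the supplied thresholds (strict >).
#'
#' @param profile `conservation_profile`.
#' @param positions reference positions of the region.
#' @param thresholds percentages for the "above" counts.
#' @return list: `mean`, `per_position` (profile subset), `n_above`
#'   (named by threshold).
#' @export
region_summary <- function(profile, positions, thresholds = c(91, 95)) {
  ix <- match(positions, profile$position)
  if (anyNA(ix)) {
    stop("positions absent from profile: ",
         paste(positions[is.na(ix)], collapse = ", "))
  }
  sub <- profile[ix, , drop = FALSE]
  rownames(sub) <- NULL
  n_above <- vapply(thresholds, function(t) sum(sub$conservation > t, na.rm = TRUE), 0L)
  list(mean = mean(sub$conservation, na.rm = TRUE), per_position = sub,
       n_above = stats::setNames(n_above, thresholds))
}
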