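## Anything-but-wildtype library model and combinatorial constructs.

ABWT_CODE <- c(a = "b", c = "d", g = "h", u = "v")
IUPAC_SET <- list(a = "a", c = "c", g = "g", u = "u",
                  b = c("c", "g", "u"),   # anything but adenosine
                  d = c("a", "g", "u"),   # anything but cytidine
                  h = c("a", "c", "u"),   # anything but guanosine
                  v = c("a", "c", "g"),   # anything but uridine
                  n = c("a", "c", "g", "u"))

#' Encode designed positions with anything-but-wildtype ambiguity codes
#'
#' At masked positions the wild-type base is replaced by the IUPAC code for
#' "any base except it": a->b, c->d, g->h, u->v. Other positions pass
#' through unchanged.
#'
#' @param seq lowercase RNA text.
#' @param mask integer positions (1-based) to encode; defaults to all.
#' @return character scalar with ambiguity codes at masked positions.
#' @export
encode_anything_but_wt <- function(seq, mask = seq_len(nchar(seq))) {
  bases <- split_bases(seq)
  check_rna(bases, "input sequence")
  stopifnot(all(mask >= 1L), all(mask <= length(bases)))
  bases[mask] <- ABWT_CODE[bases[mask]]
  paste(bases, collapse = "")
}

#' Expand one IUPAC code to its base set
#'
#' @param code single character in a,c,g,u,b,d,h,v,n.
#' @return character vector of bases.
#' @export
expand_ambiguity <- function(code) {
  if (length(code) != 1L || !code %in% names(IUPAC_SET)) {
    stop("unsupported ambiguity code: '", code, "'")
  }
  IUPAC_SET[[code]]
}

#' Define a design library over selected positions
#'
#' Each position carries its wild-type base and the replacement alphabet;
#' by default the alphabet is "anything but wild type" (three bases).
#'
#' @param region region name, e.g. "H75".
#' @param chain,resno position identifiers (recycled chain).
#' @param wt wild-type bases, lowercase RNA (string or vector).
#' @param allowed optional list of allowed base sets per position; default
#'   excludes the wild-type base at every position.
#' @param strand_lengths optional integer vector giving how the positions
#'   split into physical strands, for (strand1,strand2) display and
#'   position-wise pairing.
#' @return object of class `library_def`.
#' @export
library_definition <- function(region, chain, resno, wt, allowed = NULL,
                               strand_lengths = NULL) {
  wt <- split_bases(wt)
  check_rna(wt, "wild-type bases")
  n <- length(wt)
  pos <- data.frame(chain = rep_len(as.character(chain), n),
                    resno = as.integer(resno), wt = wt,
                    stringsAsFactors = FALSE)
  if (is.null(allowed)) {
    allowed <- lapply(wt, function(b) setdiff(RNA_BASES, b))
  }
  stopifnot(length(allowed) == n)
  for (i in seq_len(n)) {
    if (!length(allowed[[i]])) stop("empty allowed set at position ", i)
    check_rna(allowed[[i]], sprintf("allowed set %d", i))
  }
  if (!is.null(strand_lengths) && sum(strand_lengths) != n) {
    stop("strand lengths do not sum to the number of positions")
  }
  structure(list(region = region, positions = pos, allowed = allowed,
                 strand_lengths = strand_lengths),
            class = "library_def")
}

#' @export
print.library_def <- function(x, ...) {
  cat(sprintf("library_def %s: %d positions, space size %d\n",
              x$region, nrow(x$positions), library_size(x)))
  cat(" wt:", display_strands(paste(x$positions$wt, collapse = ""),
                              x$strand_lengths), "\n")
  invisible(x)
}

#' Size of a library's sequence space
#' @param lib `library_def`.
#' @export
library_size <- function(lib) prod(vapply(lib$allowed, length, 1L))

display_strands <- function(bases, strand_lengths = NULL) {
  if (is.null(strand_lengths)) return(bases)
  ends <- cumsum(strand_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  paste0("(", paste(substring(bases, starts, ends), collapse = ","), ")")
}

## index (0-based) -> bases under lexicographic order of the allowed sets
decode_variant <- function(lib, idx) {
  sizes <- vapply(lib$allowed, length, 1L)
  k <- length(sizes)
  out <- character(k)
  for (i in rev(seq_len(k))) {
    out[i] <- sort(lib$allowed[[i]])[idx %% sizes[i] + 1L]
    idx <- idx %/% sizes[i]
  }
  paste(out, collapse = "")
}

#' Enumerate or sample a library's sequence space
#'
#' Exhaustive in lexicographic order (a < c < g < u) when the space fits in
#' `cap`; otherwise a seeded uniform sample without replacement of size
#' `cap`.
#'
#' @param lib `library_def`.
#' @param cap maximum number of variants returned.
#' @param seed RNG seed used only when sampling.
#' @return data.frame class `variant_set`: id (`REGION.k`), bases.
#' @export
enumerate_library <- function(lib, cap = Inf, seed = NULL) {
  stopifnot(cap >= 1)
  total <- library_size(lib)
  idx <- if (total <= cap) seq_len(total) - 1L
         else with_seed(seed, sample.int(total, size = cap) - 1L)
  bases <- vapply(idx, function(i) decode_variant(lib, i), "")
  out <- data.frame(id = sprintf("%s.%d", lib$region, seq_along(bases)),
                    bases = bases, stringsAsFactors = FALSE)
  attr(out, "region") <- lib$region
  attr(out, "space_size") <- total
  class(out) <- c("variant_set", "data.frame")
  out
}

#' Build all combinatorial constructs over per-region variant menus
#'
#' Takes per-region option menus and forms the Cartesian product over
#' {WT} + variants for each region, including the all-WT construct. The
#' count is the product of (1 + number of variants) per region; ids are
#' assigned in product order (first region cycling fastest).
#'
#' @param regions named list; each element a character vector of variant
#'   ids, or a data.frame with columns `id` and optionally `n_mut`
#'   (mutations the variant carries, used to total mutated positions).
#' @param wt_label label used for the wild-type option.
#' @return data.frame class `construct_set`: id (`Ck`), one column per
#'   region, `n_mutated_regions`, and `n_mutations` when counts were given.
#' @export
build_combinations <- function(regions, wt_label = "WT") {
  stopifnot(is.list(regions), length(names(regions)) == length(regions))
  menus <- list(); mut <- list()
  for (rg in names(regions)) {
    el <- regions[[rg]]
    if (is.data.frame(el)) {
      ids <- el$id
      counts <- if (!is.null(el$n_mut)) el$n_mut else rep(NA_real_, length(ids))
    } else {
      ids <- as.character(el)
      counts <- rep(NA_real_, length(ids))
    }
    if (anyDuplicated(ids)) stop("duplicate variant ids in region ", rg)
    menus[[rg]] <- c(wt_label, ids)
    mut[[rg]] <- c(0, counts)
  }
  grid <- expand.grid(menus, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(id = sprintf("C%d", seq_len(nrow(grid))), grid,
                    stringsAsFactors = FALSE)
  out$n_mutated_regions <- rowSums(grid != wt_label)
  counts <- mapply(function(rg) mut[[rg]][match(grid[[rg]], menus[[rg]])],
                   names(regions))
  nm <- rowSums(matrix(as.numeric(counts), nrow = nrow(grid)))
  if (!all(is.na(nm))) out$n_mutations <- nm
  class(out) <- c("construct_set", "data.frame")
  out
}

#' Apply library substitutions to a reference sequence
#'
#' Substitutes variant bases into a numbered reference gene sequence,
#' guarding against numbering drift: the reference base at every library
#' position must equal the recorded wild-type base.
#'
#' @param reference lowercase RNA string.
#' @param positions residue numbers of the library positions.
#' @param wt expected wild-type bases at those positions.
#' @param bases replacement bases (same length).
#' @param offset numbering offset: residue number p maps to string index
#'   `p - offset`. Default 0 means position 1 is the first letter.
#' @return list with `sequence` (mutant string) and `n_mutated`.
#' @export
apply_to_reference <- function(reference, positions, wt, bases, offset = 0L) {
  ref <- split_bases(reference)
  wt <- split_bases(wt); bases <- split_bases(bases)
  stopifnot(length(positions) == length(wt), length(wt) == length(bases))
  idx <- as.integer(positions) - as.integer(offset)
  if (any(idx < 1L | idx > length(ref))) {
    stop("library position outside the reference numbering range")
  }
  mism <- which(ref[idx] != wt)
  if (length(mism)) {
    stop(sprintf("wild-type mismatch at position %d: reference '%s', library '%s'",
                 positions[mism[1L]], ref[idx[mism[1L]]], wt[mism[1L]]),
         call. = FALSE)
  }
  ref[idx] <- bases
  list(sequence = paste(ref, collapse = ""), n_mutated = sum(bases != wt))
}
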