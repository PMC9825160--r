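## Scaffold context: frozen structural neighborhood around designable residues.

#' Select the distance-sphere neighborhood around designed residues
#'
#' Expands a set of designable residues to every residue of the structure
#' (any chain, any polymer class, ions included) that has at least one heavy
#' atom within `radius` angstrom of any atom of any designed residue.
#' Distances are Euclidean and the boundary is inclusive (`<=`), so the set
#' at a given radius is reproducible. Primary-sequence neighbors of the
#' designed residues (the minimize-adjacent list) are computed with
#' [adjacent_min_res()].
#'
#' @param s `swm_structure`.
#' @param designed `residue_selection` of designable residues.
#' @param radius sphere radius in angstrom (default 25.0, several shells of
#'   indirect interactions).
#' @return object of class `scaffold_context` with elements `structure`,
#'   `designed`, `neighbors`, `min_res`, `radius`.
#' @export
select_sphere_neighborhood <- function(s, designed, radius = 25.0) {
  stopifnot(radius >= 0)
  resolve_selection(s, designed)
  a <- s$atoms
  dkey <- selection_key(designed)
  akey <- paste(a$chain, a$resno)
  is_designed_atom <- akey %in% dkey

  ## any atom of a designed residue vs heavy atoms of every other residue
  dmat <- as.matrix(a[is_designed_atom, c("x", "y", "z")])
  cand <- !is_designed_atom & toupper(a$elesy) != "H"
  cmat <- as.matrix(a[cand, c("x", "y", "z")])
  neigh_keys <- character(0)
  if (nrow(cmat) && nrow(dmat)) {
    d2 <- outer(rowSums(cmat^2), rowSums(dmat^2), "+") - 2 * (cmat %*% t(dmat))
    d2[d2 < 0] <- 0  # numerical guard
    within <- sqrt(apply(d2, 1L, min)) <= radius
    neigh_keys <- unique(akey[cand][within])
  }
  rt <- residue_table(s)
  rkey <- paste(rt$chain, rt$resno)
  keep <- rt[rkey %in% neigh_keys, , drop = FALSE]
  neighbors <- if (nrow(keep)) residue_selection(keep$chain, keep$resno, "neighbors")
               else NULL
  ctx <- list(structure = s, designed = designed, neighbors = neighbors,
              min_res = adjacent_min_res(s, designed), radius = radius)
  class(ctx) <- "scaffold_context"
  ctx
}

#' @export
print.scaffold_context <- function(x, ...) {
  cat(sprintf("scaffold_context: %d designed residues, %d neighbors within %.1f A, %d minimize-adjacent\n",
              nrow(x$designed), if (is.null(x$neighbors)) 0L else nrow(x$neighbors),
              x$radius, if (is.null(x$min_res)) 0L else nrow(x$min_res)))
  invisible(x)
}

#' Primary-sequence neighbors of designed residues
#'
#' Returns the residues at positions n-1 and n+1 (same chain) of every
#' designed residue n, excluding the designed residues themselves and
#' positions absent from the structure; deduplicated and sorted by
#' (chain, number). These are the residues subjected to energy minimization
#' alongside the designed region so a flexible design can adapt to the rigid
#' crystal context.
#'
#' @inheritParams select_sphere_neighborhood
#' @return `residue_selection` or NULL when nothing adjacent remains.
#' @export
adjacent_min_res <- function(s, designed) {
  resolve_selection(s, designed)
  rt <- residue_table(s)
  present <- paste(rt$chain, rt$resno)
  cand <- data.frame(chain = rep(designed$chain, 2L),
                     resno = c(designed$resno - 1L, designed$resno + 1L),
                     stringsAsFactors = FALSE)
  key <- paste(cand$chain, cand$resno)
  keep <- key %in% present & !(key %in% selection_key(designed))
  cand <- unique(cand[keep, , drop = FALSE])
  if (!nrow(cand)) return(NULL)
  residue_selection(cand$chain, cand$resno, label = "min_res")
}

#' Split a context into native and starting models
#'
#' The native model holds designed plus neighbor residues; the starting
#' model holds the neighbors only, omitting the designed residues, ready to
#' pose the design problem. Both preserve source coordinates and numbering.
#'
#' @param ctx `scaffold_context`.
#' @param dir optional directory; when given, writes `native.pdb` and
#'   `starting.pdb` there.
#' @return list with `swm_structure` elements `native` and `starting`.
#' @export
split_native_starting <- function(ctx, dir = NULL) {
  stopifnot(inherits(ctx, "scaffold_context"))
  if (is.null(ctx$neighbors)) stop("context has no neighbors; nothing to write")
  nat_sel <- residue_selection(c(ctx$designed$chain, ctx$neighbors$chain),
                               c(ctx$designed$resno, ctx$neighbors$resno),
                               label = "native")
  native <- subset_structure(ctx$structure, nat_sel)
  starting <- subset_structure(ctx$structure, ctx$neighbors)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_structure_pdb(native, file.path(dir, "native.pdb"))
    write_structure_pdb(starting, file.path(dir, "starting.pdb"))
  }
  list(native = native, starting = starting)
}

## FASTA with numbering ------------------------------------------------------

RNA_LETTER <- c(A = "a", C = "c", G = "g", U = "u",
                RA = "a", RC = "c", RG = "g", RU = "u")

#' Sequence records with numbering for a model
#'
#' One record per contiguous chain segment (gaps in author numbering split
#' segments). RNA letters are lowercase (the working convention for RNA
#' sequence text), protein letters uppercase one-letter codes; headers carry
#' the chain and residue-number range.
#'
#' @param model `swm_structure`.
#' @param skip_other drop non-polymer residues (ions, ligands) instead of
#'   erroring on them.
#' @return data.frame class `context_fasta`: chain, start, end, seq.
#' @export
context_to_fasta <- function(model, skip_other = TRUE) {
  rt <- residue_table(model)
  if (!nrow(rt)) stop("empty model")
  if (skip_other) rt <- rt[rt$polymer != "other", , drop = FALSE]
  if (!nrow(rt)) stop("model has no polymer residues")
  letter <- character(nrow(rt))
  for (i in seq_len(nrow(rt))) {
    rn <- toupper(rt$resid[i])
    if (rt$polymer[i] == "rna" && rn %in% names(RNA_LETTER)) {
      letter[i] <- RNA_LETTER[[rn]]
    } else if (rt$polymer[i] == "protein") {
      letter[i] <- toupper(bio3d::aa321(rn))
    } else {
      stop("unknown residue name: ", rt$resid[i])
    }
  }
  ## split on chain changes and numbering gaps
  brk <- c(TRUE, rt$chain[-1L] != rt$chain[-nrow(rt)] |
                 rt$resno[-1L] != rt$resno[-nrow(rt)] + 1L)
  seg <- cumsum(brk)
  out <- do.call(rbind, lapply(split(seq_len(nrow(rt)), seg), function(ix) {
    data.frame(chain = rt$chain[ix[1L]],
               start = rt$resno[ix[1L]], end = rt$resno[ix[length(ix)]],
               seq = paste(letter[ix], collapse = ""),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("context_fasta", "data.frame")
  out
}

#' Write numbered sequence records as FASTA
#'
#' @param fasta result of [context_to_fasta()].
#' @param path output file.
#' @export
write_context_fasta <- function(fasta, path) {
  lines <- unlist(lapply(seq_len(nrow(fasta)), function(i) {
    c(sprintf(">chain%s:%d-%d", fasta$chain[i], fasta$start[i], fasta$end[i]),
      fasta$seq[i])
  }))
  writeLines(lines, path)
  invisible(path)
}
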