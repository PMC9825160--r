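## Energy scoring: pairing maps, the documented base-pairing stand-in score,
## pluggable energy models, and ingestion of externally computed score tables.

WC_PAIRS <- c("au", "ua", "cg", "gc")
WOBBLE_PAIRS <- c("gu", "ug")

## Stand-in score term weights (arbitrary energy units, lower = more stable).
## Chosen so that Watson-Crick-rich, stacked variants score well; these are
## toolkit constants, configurable via `weights` in toy_energy().
TOY_WEIGHTS <- c(wc = -3.0, wobble = -1.5, other = +1.0, continuity = -0.5)

#' Build a pairing map over library positions
#'
#' Pairs are indices into the flat vector of library positions. With
#' `strand_lengths = c(L, L)` and no explicit pairs, the position-wise
#' convention is used: the i-th base of the first strand pairs with the
#' i-th base of the second strand.
#'
#' @param pairs two-column integer matrix of paired position indices, or
#'   NULL to derive position-wise pairs from `strand_lengths`.
#' @param strand_lengths integer vector of strand lengths (needed for the
#'   helix-continuity term and strand display).
#' @param n_positions total number of positions (inferred when possible).
#' @return object of class `pairing_map`.
#' @export
pairing_map <- function(pairs = NULL, strand_lengths = NULL, n_positions = NULL) {
  if (is.null(pairs)) {
    if (is.null(strand_lengths) || length(strand_lengths) != 2L ||
        strand_lengths[1L] != strand_lengths[2L]) {
      stop("position-wise pairing needs two equal strand lengths")
    }
    L <- strand_lengths[1L]
    pairs <- cbind(seq_len(L), L + seq_len(L))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  n_positions <- n_positions %||% (if (!is.null(strand_lengths)) sum(strand_lengths)
                                   else max(pairs))
  idx <- as.vector(pairs)
  if (nrow(pairs) && (anyDuplicated(idx) || any(idx < 1L) || any(idx > n_positions))) {
    stop("pairing map indices must be unique and within 1..n_positions")
  }
  structure(list(pairs = pairs, strand_lengths = strand_lengths,
                 n_positions = n_positions), class = "pairing_map")
}

strand_of_position <- function(pm) {
  if (is.null(pm$strand_lengths)) rep(1L, pm$n_positions)
  else rep(seq_along(pm$strand_lengths), pm$strand_lengths)
}

#' Base-pairing stand-in energy score
#'
#' A deterministic, documented stand-in for an all-atom conformational
#' score: the sum of a per-pair term (-3.0 for Watson-Crick au/ua/cg/gc,
#' -1.5 for wobble gu/ug, +1.0 otherwise), plus a helix-continuity term of
#' -0.5 for every intra-strand adjacent position pair whose members both
#' sit in Watson-Crick pairs. Unpaired positions contribute nothing. Lower
#' is more stable. This is not an all-atom physics score and makes no
#' attempt to reproduce one numerically.
#'
#' @param bases variant bases (string or character vector) over the library
#'   positions.
#' @param pairing `pairing_map`.
#' @param weights named numeric overriding the default term weights
#'   (`wc`, `wobble`, `other`, `continuity`).
#' @return numeric score in arbitrary energy units.
#' @export
toy_energy <- function(bases, pairing, weights = TOY_WEIGHTS) {
  b <- split_bases(bases)
  check_rna(b, "variant bases")
  stopifnot(inherits(pairing, "pairing_map"))
  if (length(b) < pairing$n_positions) stop("too few bases for the pairing map")
  if (!nrow(pairing$pairs)) return(0)
  duo <- paste0(b[pairing$pairs[, 1L]], b[pairing$pairs[, 2L]])
  term <- ifelse(duo %in% WC_PAIRS, weights[["wc"]],
          ifelse(duo %in% WOBBLE_PAIRS, weights[["wobble"]], weights[["other"]]))
  score <- sum(term)
  ## continuity: adjacent intra-strand positions both in WC pairs
  wc_pos <- as.vector(pairing$pairs[duo %in% WC_PAIRS, , drop = FALSE])
  strand <- strand_of_position(pairing)
  n <- pairing$n_positions
  if (n > 1L) {
    adj <- which(strand[-n] == strand[-1L])
    both_wc <- (adj %in% wc_pos) & ((adj + 1L) %in% wc_pos)
    score <- score + sum(both_wc) * weights[["continuity"]]
  }
  score
}

#' Construct an energy model
#'
#' Wraps a scoring function with an optional Gaussian evaluation-noise
#' channel emulating the variability of conformational search, and a
#' Metropolis acceptance temperature.
#'
#' @param score function(bases) -> numeric score, lower = more stable.
#' @param sigma evaluation noise standard deviation (energy units);
#'   0 makes every evaluation deterministic.
#' @param temperature Metropolis acceptance temperature (energy units).
#' @return object of class `energy_model`.
#' @export
energy_model <- function(score, sigma = 0, temperature = 1) {
  stopifnot(is.function(score), sigma >= 0, temperature > 0)
  structure(list(score = score, sigma = sigma, temperature = temperature),
            class = "energy_model")
}

#' Energy model built on the base-pairing stand-in score
#'
#' @param pairing `pairing_map` passed to [toy_energy()].
#' @inheritParams energy_model
#' @param weights term weights passed to [toy_energy()].
#' @export
toy_energy_model <- function(pairing, sigma = 0, temperature = 1,
                             weights = TOY_WEIGHTS) {
  energy_model(function(bases) toy_energy(bases, pairing, weights),
               sigma = sigma, temperature = temperature)
}

## noisy evaluation used by the samplers
evaluate_model <- function(model, bases) {
  s <- model$score(bases)
  if (model$sigma > 0) s <- s + stats::rnorm(1L, 0, model$sigma)
  s
}

#' Read an external score table
#'
#' Parses whitespace-delimited score files in the common "SCORE:" sentinel
#' dialect (header row required, naming a score column and a tag column) or
#' plain whitespace/tab-separated tables with the same header contract.
#' Duplicate tags are merged keeping the minimum (best) score.
#'
#' @param path file path.
#' @param score_col,tag_col column names; `tag_col = NULL` tries
#'   "description" then "tag" then the last column.
#' @return data.frame class `score_records`: tag, score, source.
#' @export
read_scorefile <- function(path, score_col = "score", tag_col = NULL) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- grepl("^\\s*SCORE:", lines)
  if (any(keep)) {
    lines <- sub("^\\s*SCORE:\\s*", "", lines[keep])
    lineno <- lineno[keep]
  } else {
    blank <- !nzchar(trimws(lines))
    lineno <- lineno[!blank]; lines <- lines[!blank]
  }
  empty <- data.frame(tag = character(0), score = numeric(0),
                      source = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("score_records", "data.frame")
  if (!length(lines)) {
    warning("no score rows in ", path)
    return(empty)
  }
  toks <- strsplit(trimws(lines), "\\s+")
  header <- tolower(toks[[1L]])
  si <- match(tolower(score_col), header)
  if (is.na(si)) stop("score column '", score_col, "' missing from header of ", path)
  ti <- if (!is.null(tag_col)) match(tolower(tag_col), header)
        else { m <- match(c("description", "tag"), header)
               if (all(is.na(m))) length(header) else m[!is.na(m)][1L] }
  if (is.na(ti)) stop("tag column missing from header of ", path)
  rows <- toks[-1L]; rowno <- lineno[-1L]
  if (!length(rows)) {
    warning("score file has a header but no rows: ", path)
    return(empty)
  }
  score <- suppressWarnings(as.numeric(vapply(rows, function(r) r[si], "")))
  bad <- which(!is.finite(score))
  if (length(bad)) {
    stop(sprintf("non-numeric score on line %d of %s", rowno[bad[1L]], path))
  }
  tag <- vapply(rows, function(r) r[ti], "")
  out <- data.frame(tag = tag, score = score, source = basename(path),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$tag)) {
    message("merging ", sum(duplicated(out$tag)),
            " duplicate tags, keeping minimum score")
    out <- out[order(out$tag, out$score), ]
    out <- out[!duplicated(out$tag), ]
  }
  out <- out[order(out$score, out$tag), ]
  rownames(out) <- NULL
  class(out) <- c("score_records", "data.frame")
  out
}
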