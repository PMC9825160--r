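## Ranking and the three selection protocols: span-the-range exploration,
## top-fraction selection, and randomized negative controls.

#' Build a ranked set from scored sequences
#'
#' @param x data.frame with a `score` column and a `bases` or `tag`
#'   identifier column (campaign tables, forward-fold tables and score
#'   records all qualify).
#' @param provenance free-text origin label.
#' @return data.frame class `ranked_set`, sorted by score ascending with
#'   lexicographic tie-break.
#' @export
ranked_set <- function(x, provenance = "external") {
  stopifnot(is.data.frame(x), "score" %in% names(x))
  idc <- intersect(c("bases", "tag", "id"), names(x))
  if (!length(idc)) stop("no identifier column (bases/tag/id) found")
  out <- data.frame(tag = x[[idc[1L]]], score = x$score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$score, out$tag), ]
  rownames(out) <- NULL
  attr(out, "provenance") <- provenance
  class(out) <- c("ranked_set", "data.frame")
  out
}

as_ranked <- function(x) if (inherits(x, "ranked_set")) x else ranked_set(x)

#' Select sequences spanning the score range
#'
#' Picks `n` sequences at evenly spaced score quantiles (0, 1/(n-1), ...,
#' 1) by the nearest-rank rule, always including both extremes; when a
#' quantile lands on an already-used rank the pick steps to the next unused
#' rank. Used to explore the whole score range before committing to a
#' score-based selection rule.
#'
#' @param ranked `ranked_set` (or coercible data.frame).
#' @param n number of picks (default 50).
#' @return subset of `ranked`, in rank order.
#' @export
select_spanning <- function(ranked, n = 50L) {
  ranked <- as_ranked(ranked)
  N <- nrow(ranked)
  if (N < n) stop(sprintf("only %d ranked sequences; choose n <= %d", N, N))
  if (n == 1L) return(ranked[1L, , drop = FALSE])
  p <- (seq_len(n) - 1L) / (n - 1L)
  want <- pmax(1L, as.integer(ceiling(p * N)))
  used <- logical(N); picks <- integer(n)
  for (i in seq_len(n)) {
    r <- want[i]
    while (r <= N && used[r]) r <- r + 1L
    if (r > N) { r <- want[i]; while (r >= 1L && used[r]) r <- r - 1L }
    used[r] <- TRUE; picks[i] <- r
  }
  out <- ranked[sort(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the best sequences within a top score fraction
#'
#' Eligible rows are the best `ceiling(fraction * N)` by score; of those,
#' the `n` best are returned (all eligible rows when fewer than `n`). The
#' default mirrors a "best 30 percent, build 14" screening protocol.
#'
#' @param ranked `ranked_set` (or coercible data.frame).
#' @param fraction top fraction of the ranked list considered eligible.
#' @param n maximum number of sequences returned.
#' @export
select_top_fraction <- function(ranked, fraction = 0.30, n = 14L) {
  stopifnot(fraction > 0, fraction <= 1)
  ranked <- as_ranked(ranked)
  eligible <- ceiling(fraction * nrow(ranked))
  out <- ranked[seq_len(min(n, eligible)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw randomized negative-control variants
#'
#' Emulates a library built with randomized primers: every library position
#' is drawn from the full four-base alphabet (the wild-type base is allowed,
#' unlike in the anything-but-wildtype designed library). Distinct variants
#' are drawn uniformly without replacement, seeded.
#'
#' @param lib `library_def` (only its positions are used).
#' @param n number of controls (default 14, matching the designed picks).
#' @param seed RNG seed.
#' @return data.frame class `variant_set`: id (`RND.k`), bases.
#' @export
sample_random_controls <- function(lib, n = 14L, seed = NULL) {
  stopifnot(n >= 1L)
  k <- nrow(lib$positions)
  space <- 4^k
  if (n > space) stop("n exceeds the randomized space size ", space)
  idx <- with_seed(seed, sample.int(space, size = n)) - 1
  bases <- vapply(idx, function(i) {
    out <- character(k)
    for (j in rev(seq_len(k))) { out[j] <- RNA_BASES[i %% 4 + 1]; i <- i %/% 4 }
    paste(out, collapse = "")
  }, "")
  out <- data.frame(id = sprintf("RND.%d", seq_len(n)), bases = bases,
                    stringsAsFactors = FALSE)
  attr(out, "region") <- lib$region
  attr(out, "space_size") <- space
  class(out) <- c("variant_set", "data.frame")
  out
}
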