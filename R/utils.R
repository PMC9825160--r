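#' @keywords internal
"_PACKAGE"

## Lexicographic base order used everywhere a deterministic order is needed.
RNA_BASES <- c("a", "c", "g", "u")

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state; seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed (for independent trajectories / models) that stays
## inside the 32-bit integer range whatever the parent seed.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + i * 1009) %% 2147483587)
}

split_bases <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1L]] else as.character(x)
}

check_rna <- function(bases, what = "sequence") {
  bad <- which(!bases %in% RNA_BASES)
  if (length(bad)) {
    stop(sprintf("invalid RNA base '%s' at position %d of %s",
                 bases[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(bases)
}
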