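## Seeded synthetic-data generators: ideal A-form helices, simulated
## activity screens with a stated score -> activity link, and simulated
## alignments with target per-column conservation. Everything here is
## synthetic and labelled as such; the helix stands in for crystallographic
## coordinates in tests, not for any deposited structure.

## Standard A-form literature geometry, declared as toolkit constants.
AFORM_RISE <- 2.81          # angstrom per base pair
AFORM_TWIST <- 32.7         # degrees per base pair
AFORM_P_RADIUS <- 9.213     # gives ~5.9 A consecutive P-P at the above
AFORM_C1_RADIUS <- 9.4      # with the half-angle below: ~10.4 A paired C1'-C1'
AFORM_C1_HALF_ANGLE <- 33.58  # degrees

RNA_COMPLEMENT <- c(a = "u", u = "a", c = "g", g = "c")

#' Generate an ideal A-form RNA double helix
#'
#' Coarse three-pseudo-atom residues (P, C1', base centroid CEN) on ideal
#' A-form geometry: 2.81 angstrom rise and 32.7 degree twist per base
#' pair. Sufficient for distance-sphere selection and pairing geometry;
#' no attempt at full atomic detail. Strands are antiparallel: residue i
#' of the first chain pairs with residue n-i+1 of the second.
#'
#' @param n_bp number of base pairs (1..20).
#' @param sequence first-strand sequence (string, length `n_bp`); the
#'   second strand defaults to its reverse complement. Alternatively a
#'   character vector of both strands.
#' @param chains two chain ids.
#' @param offsets author-numbering start for each chain.
#' @return `swm_structure` with `2 * n_bp` residues.
#' @export
make_ideal_helix <- function(n_bp, sequence = NULL, chains = c("A", "B"),
                             offsets = c(1L, 1L)) {
  stopifnot(n_bp >= 1L, n_bp <= 20L)
  if (is.null(sequence)) {
    sequence <- paste(rep_len(c("g", "a", "c", "u"), n_bp), collapse = "")
  }
  if (length(sequence) == 1L) {
    s1 <- split_bases(sequence)
    s2 <- rev(unname(RNA_COMPLEMENT[s1]))
  } else {
    s1 <- split_bases(sequence[1L]); s2 <- split_bases(sequence[2L])
  }
  if (length(s1) != n_bp || length(s2) != n_bp) {
    stop("sequence length does not match n_bp")
  }
  check_rna(s1, "strand 1"); check_rna(s2, "strand 2")
  deg <- pi / 180
  place <- function(theta, radius, z) c(radius * cos(theta * deg),
                                        radius * sin(theta * deg), z)
  rows <- list()
  add_residue <- function(chain, resno, base, theta, z, sign) {
    ## sign +1 for strand 1, -1 for strand 2 (mirrored about the pair axis)
    coords <- rbind(
      P = place(theta + sign * (AFORM_C1_HALF_ANGLE + 14), AFORM_P_RADIUS, z + sign * 1.0),
      `C1'` = place(theta + sign * AFORM_C1_HALF_ANGLE, AFORM_C1_RADIUS, z),
      CEN = place(theta + sign * 12, 2.5, z))
    data.frame(chain = chain, resno = resno, resid = toupper(base),
               elety = rownames(coords),
               elesy = c("P", "C", "C"),
               x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
               het = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_bp)) {
    theta <- (i - 1L) * AFORM_TWIST
    z <- (i - 1L) * AFORM_RISE
    rows[[length(rows) + 1L]] <-
      add_residue(chains[1L], offsets[1L] + i - 1L, s1[i], theta, z, +1)
    ## strand-2 partner of strand-1 residue i carries chain-2 number n-i+1
    rows[[length(rows) + 1L]] <-
      add_residue(chains[2L], offsets[2L] + n_bp - i, s2[n_bp - i + 1L],
                  theta, z, -1)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  swm_structure(atoms, source = sprintf("synthetic A-form helix (%d bp)", n_bp))
}

#' Simulate an activity screen from energy scores
#'
#' Generates a reproducible screen table under the stated link
#' `A_rel = max(0, alpha + beta * (score - score_ref) + eps)`,
#' `eps ~ Normal(0, sigma)`, with replicate fluorescence readouts around
#' `a_rel * wt_fluor` and a wild-type row fixed at relative activity 1.
#' The default link is negative (`beta < 0`): lower scores, i.e. more
#' stable conformations, yield more active constructs. When `sigma` is
#' NULL it is derived from the target score-activity correlation `rho`
#' via `sigma = |beta| * sd(score) * sqrt(1/rho^2 - 1)`.
#'
#' @param n number of constructs (ignored when `scores` given).
#' @param scores optional vector of energy scores; default uniform over
#'   `score_range`.
#' @param score_range range scores are drawn from.
#' @param alpha intercept of the link: relative activity at
#'   `score == score_ref`.
#' @param beta slope of the link (activity per energy unit).
#' @param sigma activity noise SD; NULL derives it from `rho`.
#' @param rho target Pearson correlation used when `sigma` is NULL.
#' @param score_ref score at which the link crosses `alpha` (use the
#'   wild-type score when simulating a designed library).
#' @param n_reps replicate measurements per construct.
#' @param wt_fluor wild-type fluorescence scale (arbitrary units).
#' @param rep_cv replicate noise as a fraction of `wt_fluor`.
#' @param ids construct ids; default `V1..Vn`.
#' @param seed RNG seed.
#' @return object of class `screen_sim`: `constructs` (construct, score,
#'   a_true), `measurements` (construct, replicate, value), `params`.
#' @export
simulate_screen <- function(n = 50L, scores = NULL, score_range = c(-10, 10),
                            alpha = 1, beta = -0.05, sigma = NULL, rho = -0.6,
                            score_ref = 0, n_reps = 3L, wt_fluor = 20000,
                            rep_cv = 0.05, ids = NULL, seed = NULL) {
  stopifnot(n_reps >= 1L)
  with_seed(seed, {
    if (is.null(scores)) {
      scores <- stats::runif(n, score_range[1L], score_range[2L])
      sd_s <- diff(score_range) / sqrt(12)
    } else {
      n <- length(scores)
      sd_s <- stats::sd(scores)
    }
    stopifnot(n >= 3L)
    if (is.null(sigma)) {
      stopifnot(!is.null(rho), abs(rho) > 0, abs(rho) <= 1)
      sigma <- abs(beta) * sd_s * sqrt(1 / rho^2 - 1)
    }
    ids <- ids %||% sprintf("V%d", seq_len(n))
    a_true <- pmax(0, alpha + beta * (scores - score_ref) +
                      stats::rnorm(n, 0, sigma))
    constructs <- data.frame(construct = c("WT", ids),
                             score = c(score_ref, scores),
                             a_true = c(1, a_true), stringsAsFactors = FALSE)
    meas <- do.call(rbind, lapply(seq_len(nrow(constructs)), function(i) {
      data.frame(construct = constructs$construct[i],
                 replicate = seq_len(n_reps),
                 value = stats::rnorm(n_reps,
                                      constructs$a_true[i] * wt_fluor,
                                      rep_cv * wt_fluor),
                 stringsAsFactors = FALSE)
    }))
    structure(list(constructs = constructs, measurements = meas,
                   params = list(alpha = alpha, beta = beta, sigma = sigma,
                                 rho = rho, score_ref = score_ref,
                                 n_reps = n_reps, wt_fluor = wt_fluor,
                                 rep_cv = rep_cv, seed = seed)),
              class = "screen_sim")
  })
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf("screen_sim: %d constructs x %d replicates (sigma = %.3f)\n",
              nrow(x$constructs), x$params$n_reps, x$params$sigma))
  invisible(x)
}

#' Simulate in vivo viability outcomes from in vitro activity
#'
#' Constructs above the activity threshold are alive with probability
#' `p_alive_above`, those below with `p_alive_below`; the gap between the
#' two emulates an imperfect but predictive in vitro screen (most, not
#' all, active constructs support life, and weak constructs occasionally
#' do).
#'
#' @param a_rel relative activities.
#' @param threshold activity threshold.
#' @param p_alive_above,p_alive_below conditional survival probabilities.
#' @param seed RNG seed.
#' @return character vector "alive"/"dead".
#' @export
simulate_viability <- function(a_rel, threshold = 1 / 3,
                               p_alive_above = 0.85, p_alive_below = 0.10,
                               seed = NULL) {
  with_seed(seed, {
    p <- ifelse(a_rel > threshold, p_alive_above, p_alive_below)
    ifelse(stats::runif(length(a_rel)) < p, "alive", "dead")
  })
}

#' Simulate an alignment with target per-column conservation
#'
#' Each column's modal base is planted at the target frequency among
#' non-gap letters (exact counts, so the planted conservation is recovered
#' up to rounding); the remaining mass is spread uniformly over the other
#' three bases. Targets at or below 25 percent are rejected (the modal
#' base of four letters cannot fall below the uniform frequency). The
#' reference record (first row) carries the ungapped modal bases.
#'
#' @param n_rows number of records including the reference.
#' @param targets per-column conservation targets, percentages in
#'   (25, 100].
#' @param gap_fraction probability that a non-reference cell is a gap.
#' @param modal optional modal bases per column; default seeded draw.
#' @param ref_id reference record id.
#' @param seed RNG seed.
#' @return `swm_alignment`.
#' @export
simulate_alignment <- function(n_rows = 1000L, targets, gap_fraction = 0,
                               modal = NULL, ref_id = "REF", seed = NULL) {
  stopifnot(n_rows >= 2L, gap_fraction >= 0, gap_fraction < 1)
  if (any(targets <= 25 | targets > 100)) {
    stop("conservation targets must lie in (25, 100]")
  }
  k <- length(targets)
  with_seed(seed, {
    if (is.null(modal)) modal <- sample(RNA_BASES, k, replace = TRUE)
    modal <- split_bases(modal)
    stopifnot(length(modal) == k)
    m <- matrix("", nrow = n_rows, ncol = k)
    m[1L, ] <- modal
    nr <- n_rows - 1L
    for (j in seq_len(k)) {
      others <- setdiff(RNA_BASES, modal[j])
      col <- rep("-", nr)
      filled <- if (gap_fraction > 0) stats::runif(nr) >= gap_fraction
                else rep(TRUE, nr)
      idx <- which(filled)
      ## exact-count planting: the reference row plus round(p * m) of the
      ## remaining non-gap cells carry the modal base
      n_modal <- max(0L, round(targets[j] / 100 * (length(idx) + 1L)) - 1L)
      take <- sample(idx, min(n_modal, length(idx)))
      col[take] <- modal[j]
      rest <- setdiff(idx, take)
      col[rest] <- sample(others, length(rest), replace = TRUE)
      m[-1L, j] <- col
    }
    ids <- c(ref_id, sprintf("SYN%04d", seq_len(nr)))
    swm_alignment(ids, apply(m, 1L, paste, collapse = ""), ref_id)
  })
}

#' Write an alignment as multi-FASTA
#'
#' @param aln `swm_alignment`.
#' @param path output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(stats::setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Demo anything-but-wildtype helix library
#'
#' An 8-position, two-strand library over the center of an rRNA-style
#' helix, with position-wise pairing between the strands (fourth position
#' of strand one pairing the fourth of strand two). Residue numbers follow
#' the 23S helix-75 center (2225-2228 / 2088-2091); the wild-type bases
#' are synthetic, chosen to form four Watson-Crick pairs like the real
#' helix. Used in examples, tests and the demo pipeline.
#'
#' @return list with `lib` (`library_def`), `pairing` (`pairing_map`) and
#'   `wt` (wild-type bases as a string).
#' @export
demo_helix_library <- function() {
  wt <- "gaaccuug"
  lib <- library_definition("H75", chain = rep(c("A", "B"), each = 4L),
                            resno = c(2225:2228, 2088:2091), wt = wt,
                            strand_lengths = c(4L, 4L))
  list(lib = lib, pairing = pairing_map(strand_lengths = c(4L, 4L)), wt = wt)
}
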