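## Identity-design Monte Carlo: single trajectories, multi-trajectory
## campaigns, and fixed-budget forward-folding re-scoring.

#' Run one design trajectory
#'
#' Metropolis walk over the library's sequence space: each cycle proposes
#' mutating one uniformly chosen position to a uniformly chosen allowed
#' base, evaluates the model score (plus one noise draw when the model has
#' an evaluation-noise channel), accepts downhill moves always and uphill
#' moves with probability exp(-delta/T). The lowest-scoring frame seen is
#' recorded. Bit-reproducible for a fixed seed.
#'
#' @param lib `library_def`.
#' @param model `energy_model`.
#' @param n_cycles Monte Carlo cycles (default 1000; structurally complex
#'   regions benefit from 2000).
#' @param seed RNG seed.
#' @param start starting bases; default a seeded uniform draw from the
#'   allowed sets.
#' @return object of class `trajectory_result`: `bases`, `score`, `seed`,
#'   `n_cycles`.
#' @export
design_trajectory <- function(lib, model, n_cycles = 1000L, seed = NULL,
                              start = NULL) {
  stopifnot(inherits(lib, "library_def"), inherits(model, "energy_model"),
            n_cycles >= 1L)
  k <- nrow(lib$positions)
  if (!k) stop("empty library")
  allowed <- lapply(lib$allowed, sort)
  with_seed(seed, {
    cur <- if (is.null(start)) {
      vapply(allowed, function(a) a[sample.int(length(a), 1L)], "")
    } else {
      s <- split_bases(start); stopifnot(length(s) == k); s
    }
    cur_score <- evaluate_model(model, cur)
    best <- cur; best_score <- cur_score
    for (cyc in seq_len(n_cycles)) {
      pos <- sample.int(k, 1L)
      prop <- cur
      prop[pos] <- allowed[[pos]][sample.int(length(allowed[[pos]]), 1L)]
      prop_score <- evaluate_model(model, prop)
      delta <- prop_score - cur_score
      if (delta <= 0 || stats::runif(1L) < exp(-delta / model$temperature)) {
        cur <- prop; cur_score <- prop_score
      }
      if (prop_score < best_score ||
          (prop_score == best_score &&
           paste(prop, collapse = "") < paste(best, collapse = ""))) {
        best <- prop; best_score <- prop_score
      }
    }
    structure(list(bases = paste(best, collapse = ""), score = best_score,
                   seed = seed, n_cycles = n_cycles),
              class = "trajectory_result")
  })
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("trajectory_result: best %s at %.3f (%d cycles)\n",
              x$bases, x$score, x$n_cycles))
  invisible(x)
}

#' Run a design campaign of independent trajectories
#'
#' Runs `n_trajectories` independent trajectories with per-trajectory seeds
#' derived from `seed`, then aggregates best frames: one row per distinct
#' best-frame sequence with its best score across trajectories and its
#' sampling frequency (how many trajectories ended on it). Rows are sorted
#' by score ascending, ties broken lexicographically.
#'
#' @inheritParams design_trajectory
#' @param n_trajectories number of independent trajectories (production
#'   campaigns use 10000 or more; desk studies far fewer).
#' @return data.frame class `campaign_table`: bases, score, freq; attribute
#'   `n_trajectories`.
#' @export
design_campaign <- function(lib, model, n_trajectories = 100L,
                            n_cycles = 1000L, seed = NULL) {
  stopifnot(n_trajectories >= 1L)
  res <- lapply(seq_len(n_trajectories), function(i) {
    design_trajectory(lib, model, n_cycles = n_cycles,
                      seed = derive_seed(seed, i))
  })
  bases <- vapply(res, `[[`, "", "bases")
  score <- vapply(res, `[[`, 0, "score")
  best <- tapply(score, bases, min)
  out <- data.frame(bases = names(best), score = as.numeric(best),
                    freq = as.integer(table(bases)[names(best)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$score, out$bases), ]
  rownames(out) <- NULL
  attr(out, "n_trajectories") <- n_trajectories
  class(out) <- c("campaign_table", "data.frame")
  out
}

#' Top sequences of a campaign
#'
#' @param campaign `campaign_table`.
#' @param n how many of the best-scoring sequences to keep (default 200,
#'   the usual hand-off size to forward folding).
#' @export
top_sequences <- function(campaign, n = 200L) {
  utils::head(campaign$bases, n)
}

#' Forward-fold re-scoring at a fixed sampling budget
#'
#' Re-scores fixed sequences under an identical budget so best scores are
#' comparable across sequences ("apples to apples"): for each sequence,
#' `n_models` independent models are generated, each the best of
#' `n_cycles` noisy evaluations of the fixed sequence (the sequence never
#' changes; only the model's noise channel is sampled), and the minimum
#' over models is reported. With a noiseless model the result equals the
#' deterministic score.
#'
#' @param variants character vector of base strings (or a `campaign_table`
#'   / `variant_set`, whose sequences are taken).
#' @param model `energy_model`.
#' @param n_cycles evaluations per model (default 500).
#' @param n_models models per sequence (default 400).
#' @param seed RNG seed; per-sequence streams are derived from it.
#' @param keep_models also return the per-model best scores (list column),
#'   useful for best-of-N diagnostics.
#' @return data.frame class `forward_fold`: bases, score (best over the
#'   whole budget), sorted ascending with lexicographic ties.
#' @export
forward_fold <- function(variants, model, n_cycles = 500L, n_models = 400L,
                         seed = NULL, keep_models = FALSE) {
  if (is.data.frame(variants)) variants <- variants$bases
  stopifnot(n_models >= 1L, n_cycles >= 1L)
  per_model <- vector("list", length(variants))
  score <- numeric(length(variants))
  for (i in seq_along(variants)) {
    true <- model$score(split_bases(variants[i]))
    if (model$sigma == 0) {
      pm <- rep(true, n_models)
    } else {
      pm <- with_seed(derive_seed(seed, i), {
        noise <- matrix(stats::rnorm(n_cycles * n_models, 0, model$sigma),
                        nrow = n_cycles)
        true + apply(noise, 2L, min)
      })
    }
    per_model[[i]] <- pm
    score[i] <- min(pm)
  }
  out <- data.frame(bases = variants, score = score, stringsAsFactors = FALSE)
  if (keep_models) out$models <- I(per_model)
  out <- out[order(out$score, out$bases), ]
  rownames(out) <- NULL
  class(out) <- c("forward_fold", "data.frame")
  out
}
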