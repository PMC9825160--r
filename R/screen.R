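## Screen analytics: wild-type-normalized activity, score-activity
## correlation, base-pair classification, multiplicative epistasis and
## in vitro -> in vivo viability concordance.

#' Normalize replicate screen readouts to the wild-type control
#'
#' Per construct, relative activity A_rel = mean(replicate maxima) divided
#' by the wild-type mean; the replicate standard deviation is carried
#' through on the same scale. Negative raw values are clipped to zero with
#' a warning. Normalization is scale invariant: multiplying every raw
#' value by a positive constant leaves every A_rel unchanged.
#'
#' @param raw data.frame with columns `construct` and `value` (one row per
#'   replicate measurement, e.g. max fluorescence).
#' @param wt_id construct id of the wild-type control.
#' @return data.frame class `activity_table`: construct, n_rep, mean_raw,
#'   a_rel, sd_rel.
#' @export
normalize_activity <- function(raw, wt_id = "WT") {
  stopifnot(all(c("construct", "value") %in% names(raw)))
  if (!wt_id %in% raw$construct) stop("wild-type id '", wt_id, "' not in table")
  if (any(raw$value < 0, na.rm = TRUE)) {
    warning("negative raw values clipped to 0")
    raw$value <- pmax(raw$value, 0)
  }
  mu <- tapply(raw$value, raw$construct, mean)
  sdv <- tapply(raw$value, raw$construct, stats::sd)
  nrep <- tapply(raw$value, raw$construct, length)
  wt_mean <- mu[[wt_id]]
  if (!is.finite(wt_mean) || wt_mean == 0) stop("wild-type mean is zero; cannot normalize")
  out <- data.frame(construct = names(mu), n_rep = as.integer(nrep),
                    mean_raw = as.numeric(mu),
                    a_rel = as.numeric(mu) / wt_mean,
                    sd_rel = as.numeric(sdv) / wt_mean,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$construct, unique(raw$construct))), ]
  rownames(out) <- NULL
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Correlate energy score with normalized activity
#'
#' Pearson correlation with a two-sided t-test p-value, an ordinary
#' least-squares fit of activity on score, and a pointwise 95 percent
#' confidence band for the fitted line.
#'
#' @param score,activity numeric vectors; alternatively pass a data.frame
#'   with `score` and `a_rel` columns as `score`.
#' @param conf band confidence level.
#' @return object of class `score_activity_cor`: `r`, `p`, `n`, `fit`
#'   (the lm), `band` (data.frame score, fit, lwr, upr).
#' @export
correlate_score_activity <- function(score, activity = NULL, conf = 0.95) {
  if (is.data.frame(score)) {
    activity <- score$a_rel %||% score$activity
    score <- score$score
  }
  stopifnot(length(score) == length(activity), length(score) >= 3L)
  if (stats::sd(score) == 0 || stats::sd(activity) == 0) {
    stop("constant input vector; correlation undefined")
  }
  ct <- stats::cor.test(score, activity, method = "pearson")
  fit <- stats::lm(activity ~ score)
  grid <- data.frame(score = seq(min(score), max(score), length.out = 100L))
  band <- cbind(grid, stats::predict(fit, grid, interval = "confidence",
                                     level = conf))
  names(band) <- c("score", "fit", "lwr", "upr")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(score),
                 fit = fit, band = band, conf = conf),
            class = "score_activity_cor")
}

#' @export
print.score_activity_cor <- function(x, ...) {
  cat(sprintf("score-activity correlation: r = %.2f, P = %.2g (n = %d)\n",
              x$r, x$p, x$n))
  cat(sprintf("OLS: activity = %.3f %+.3f * score\n",
              stats::coef(x$fit)[1L], stats::coef(x$fit)[2L]))
  invisible(x)
}

#' Plot a score-activity correlation
#'
#' Scatter of activity against score with the OLS line and its pointwise
#' confidence band.
#'
#' @param x `score_activity_cor`.
#' @param ... passed to [plot()].
#' @method plot score_activity_cor
#' @export
plot.score_activity_cor <- function(x, ...) {
  d <- stats::model.frame(x$fit)
  plot(d$score, d$activity, xlab = "energy score", ylab = "relative activity",
       pch = 19, ...)
  graphics::polygon(c(x$band$score, rev(x$band$score)),
                    c(x$band$lwr, rev(x$band$upr)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(x$band$score, x$band$fit, lwd = 2)
  graphics::points(d$score, d$activity, pch = 19)
  invisible(x)
}

#' Classify base pairs of a variant
#'
#' Position-wise pairing: Watson-Crick pairs are au/ua/cg/gc, wobble gu/ug,
#' everything else non-canonical.
#'
#' @param strand1,strand2 strand sequences; or give `strand1` as the flat
#'   base vector and supply `pairing`.
#' @param pairing optional `pairing_map`; default position-wise over the
#'   two strands.
#' @return list with `counts` (named WC/wobble/other) and `labels`
#'   (per-pair data.frame i, j, duo, class).
#' @export
classify_pairs <- function(strand1, strand2 = NULL, pairing = NULL) {
  if (!is.null(strand2)) {
    b1 <- split_bases(strand1); b2 <- split_bases(strand2)
    if (is.null(pairing)) {
      if (length(b1) != length(b2)) stop("strand lengths differ; supply a pairing map")
      pairing <- pairing_map(strand_lengths = c(length(b1), length(b2)))
    }
    bases <- c(b1, b2)
  } else {
    bases <- split_bases(strand1)
    if (is.null(pairing)) stop("supply either two strands or a pairing map")
  }
  check_rna(bases, "strands")
  if (max(pairing$pairs) > length(bases)) stop("pairing index out of range")
  duo <- paste0(bases[pairing$pairs[, 1L]], bases[pairing$pairs[, 2L]])
  cls <- ifelse(duo %in% WC_PAIRS, "WC",
         ifelse(duo %in% WOBBLE_PAIRS, "wobble", "other"))
  counts <- c(WC = sum(cls == "WC"), wobble = sum(cls == "wobble"),
              other = sum(cls == "other"))
  labels <- data.frame(i = pairing$pairs[, 1L], j = pairing$pairs[, 2L],
                       duo = duo, class = cls, stringsAsFactors = FALSE)
  list(counts = counts, labels = labels)
}

#' Epistasis deviations from the multiplicative expectation
#'
#' For each combination construct, the expected relative activity under
#' independence is the product of its constituent single-region relative
#' activities (wild-type components contribute a factor of 1); the
#' deviation D = observed - expected. Positive D flags synergistic rescue
#' (the combination outperforms what its parts predict), negative D
#' incompatibility. D is a toolkit-defined statistic for reading
#' combinatorial screens quantitatively.
#'
#' @param singles data.frame with `construct` (single-variant id) and
#'   `a_rel`.
#' @param combos data.frame with `construct` and observed `a_rel`.
#' @param composition named list: combo construct id -> character vector of
#'   constituent single ids; entries equal to `wt_label` are skipped.
#' @param wt_label label marking wild-type components.
#' @return data.frame class `epistasis_table`: construct, observed,
#'   expected, deviation; sorted by absolute deviation descending.
#' @export
epistasis_table <- function(singles, combos, composition, wt_label = "WT") {
  stopifnot(all(c("construct", "a_rel") %in% names(singles)),
            all(c("construct", "a_rel") %in% names(combos)))
  lut <- stats::setNames(singles$a_rel, singles$construct)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    id <- combos$construct[i]
    parts <- setdiff(composition[[id]] %||% character(0), wt_label)
    if (is.null(composition[[id]])) {
      warning("no composition for ", id, "; skipped"); next
    }
    if (!all(parts %in% names(lut))) {
      warning("missing single-variant record for ",
              paste(setdiff(parts, names(lut)), collapse = ", "),
              " (", id, " skipped)")
      next
    }
    expected <- prod(lut[parts])  # empty product = 1 (all-WT)
    rows[[length(rows) + 1L]] <- data.frame(
      construct = id, observed = combos$a_rel[i], expected = expected,
      deviation = combos$a_rel[i] - expected, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(construct = character(0), observed = numeric(0),
                         expected = numeric(0), deviation = numeric(0))
  out <- out[order(-abs(out$deviation), out$construct), ]
  rownames(out) <- NULL
  class(out) <- c("epistasis_table", "data.frame")
  out
}

#' In vitro to in vivo viability concordance
#'
#' Fraction of constructs above an in vitro activity threshold that
#' support life, with the full 2x2 contingency table. The default
#' threshold of 1/3 relative activity is the screening heuristic for
#' predicting in vivo success; untested constructs are excluded.
#'
#' @param records data.frame with `a_rel` and `viability`
#'   ("alive"/"dead"/"untested").
#' @param threshold relative-activity cutoff.
#' @return list: `fraction_alive_above`, `table` (2x2), `n_tested`.
#' @export
viability_concordance <- function(records, threshold = 1 / 3) {
  stopifnot(all(c("a_rel", "viability") %in% names(records)))
  rec <- records[records$viability %in% c("alive", "dead"), , drop = FALSE]
  if (!nrow(rec)) stop("no tested records")
  above <- factor(rec$a_rel > threshold, levels = c(TRUE, FALSE),
                  labels = c("above", "below"))
  alive <- factor(rec$viability, levels = c("alive", "dead"))
  tab <- table(activity = above, viability = alive)
  n_above <- sum(tab["above", ])
  frac <- if (n_above) tab["above", "alive"] / n_above else NA_real_
  list(fraction_alive_above = as.numeric(frac), table = tab,
       n_tested = nrow(rec), threshold = threshold)
}
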