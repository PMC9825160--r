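test_that("activity normalization is WT-relative and scale invariant", {
  raw <- data.frame(construct = rep(c("WT", "V1", "V2", "V3"), each = 2L),
                    value = c(5, 5, 4, 6, 0, 0, 5, 5))
  act <- normalize_activity(raw, wt_id = "WT")
  expect_equal(act$a_rel[act$construct == "WT"], 1)
  expect_equal(act$a_rel[act$construct == "V1"], 1)    # (4+6)/2 over (5+5)/2
  expect_equal(act$a_rel[act$construct == "V2"], 0)
  expect_equal(act$n_rep, rep(2L, 4L))
  ## scale invariance under any positive rescaling of the raw fluorescence
  for (k in c(0.01, 3, 1e4)) {
    raw_k <- raw; raw_k$value <- raw_k$value * k
    expect_equal(normalize_activity(raw_k, "WT")$a_rel, act$a_rel)
  }
  ## error and warning paths
  expect_error(normalize_activity(raw, "nope"), "not in table")
  zero <- data.frame(construct = c("WT", "V"), value = c(0, 1))
  expect_error(normalize_activity(zero, "WT"), "zero")
  neg <- data.frame(construct = c("WT", "V"), value = c(5, -1))
  expect_warning(act2 <- normalize_activity(neg, "WT"), "clipped")
  expect_equal(act2$a_rel[act2$construct == "V"], 0)
})

test_that("score-activity correlation returns r, p and a confidence band", {
  ## exact decreasing line: perfect anticorrelation
  s <- 1:10
  ct <- correlate_score_activity(s, 2 - 0.1 * s)
  expect_equal(ct$r, -1)
  expect_lt(ct$p, 1e-10)
  expect_true(all(c("score", "fit", "lwr", "upr") %in% names(ct$band)))
  expect_true(all(ct$band$lwr <= ct$band$fit & ct$band$fit <= ct$band$upr))
  expect_error(correlate_score_activity(s, rep(1, 10)), "constant")
  expect_error(correlate_score_activity(1:2, 2:1), "length")
  ## planted-link recovery on a simulated screen
  sim <- simulate_screen(n = 50L, seed = 42L)
  d <- sim$constructs[sim$constructs$construct != "WT", ]
  ct2 <- correlate_score_activity(d$score, d$a_true)
  expect_lt(abs(ct2$r - (-0.6)), 0.1)
  expect_lt(ct2$p, 0.01)
})

test_that("base pairs classify into Watson-Crick, wobble and other", {
  ## the 2-Watson-Crick helix variant
  cls <- classify_pairs("cggu", "gcgc")
  expect_equal(cls$counts, c(WC = 2L, wobble = 0L, other = 2L))
  expect_equal(cls$labels$class, c("WC", "WC", "other", "other"))
  expect_equal(classify_pairs("cccc", "gggg")$counts[["WC"]], 4L)
  expect_equal(classify_pairs("gggg", "uuuu")$counts[["wobble"]], 4L)
  ## counts always sum to the number of pairs in the map
  for (x in c("acgu", "uuuu", "gcau")) {
    expect_equal(sum(classify_pairs(x, "acgu")$counts), 4L)
  }
  pm <- pairing_map(matrix(c(1L, 9L), ncol = 2), n_positions = 9L)
  expect_error(classify_pairs("acgu", "acgu", pairing = pm), "out of range")
})

test_that("epistasis deviations follow the multiplicative expectation", {
  singles <- data.frame(construct = c("H91.2", "H73.2", "H75.1", "A", "B"),
                        a_rel = c(0.9, 0.0, 1.0, 1.1, 1.05))
  combos <- data.frame(construct = c("C43", "C31", "C58", "CWT"),
                       a_rel = c(0.0, 0.43, 0.0, 1.0))
  comp <- list(C43 = c("H91.2", "H73.2"),
               C31 = c("H91.2", "H73.2", "H75.1"),
               C58 = c("A", "B"),
               CWT = c("WT"))
  et <- epistasis_table(singles, combos, comp)
  ## inactive pair rescued by a third region: expected 0, D = +0.43
  expect_equal(et$expected[et$construct == "C31"], 0)
  expect_equal(et$deviation[et$construct == "C31"], 0.43)
  ## two above-WT singles that abolish activity together: D = -1.155
  expect_equal(et$expected[et$construct == "C58"], 1.155)
  expect_equal(et$deviation[et$construct == "C58"], -1.155)
  ## all-WT composition: expected 1, observed 1, D = 0
  expect_equal(et$deviation[et$construct == "CWT"], 0)
  ## sorted by |D| descending
  expect_equal(et$construct[1L], "C58")
  ## missing constituent: skipped with a warning
  combos2 <- rbind(combos, data.frame(construct = "CX", a_rel = 0.5))
  expect_warning(et2 <- epistasis_table(singles, combos2,
                                        c(comp, list(CX = "UNKNOWN"))),
                 "missing")
  expect_false("CX" %in% et2$construct)
})

test_that("viability concordance counts above-threshold survivors", {
  rec <- data.frame(a_rel = c(0.9, 0.5, 0.4, 0.1, 0.2),
                    viability = c("alive", "alive", "dead", "dead", "untested"))
  vc <- viability_concordance(rec, threshold = 1 / 3)
  expect_equal(vc$fraction_alive_above, 2 / 3)  # 3 above, 2 alive
  expect_equal(vc$n_tested, 4L)
  expect_equal(as.vector(vc$table), c(2L, 0L, 1L, 1L))
  ## all above-threshold alive
  rec2 <- data.frame(a_rel = c(0.5, 0.6), viability = c("alive", "alive"))
  expect_equal(viability_concordance(rec2)$fraction_alive_above, 1)
  expect_error(viability_concordance(
    data.frame(a_rel = 1, viability = "untested")), "no tested")
})
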