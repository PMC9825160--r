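test_that("stand-in energy reproduces hand-summed term tables", {
  pm44 <- pairing_map(strand_lengths = c(4L, 4L))
  ## no pairs: empty sum
  expect_equal(toy_energy("acgu", pairing_map(matrix(integer(0), ncol = 2),
                                              n_positions = 4L)), 0)
  ## single Watson-Crick pair
  expect_equal(toy_energy("cg", pairing_map(strand_lengths = c(1L, 1L))), -3)
  ## wobble pair
  expect_equal(toy_energy("gu", pairing_map(strand_lengths = c(1L, 1L))), -1.5)
  ## hand sum: pairs -3 -3 +1 +1, continuity -0.5 per strand = -5
  expect_equal(toy_energy("cggugcgc", pm44), -5)
  ## fully Watson-Crick demo wild type: 4 * -3 + 6 adjacencies * -0.5
  expect_equal(toy_energy("gacucuga", pm44), -15)
  expect_error(toy_energy("acgx", pm44), "invalid RNA base")
})

test_that("a trajectory finds the argmin of a single-position library", {
  lib1 <- library_definition("X", "A", c(1L, 2L), "gc",
                             allowed = list(c("a", "c", "u"), "g"),
                             strand_lengths = c(1L, 1L))
  pm <- pairing_map(strand_lengths = c(1L, 1L))
  model <- toy_energy_model(pm)  # sigma = 0
  ## brute force over the 3 effective variants: cg is the only WC pair
  for (seed in 1:5) {
    tr <- design_trajectory(lib1, model, n_cycles = 60L, seed = seed)
    expect_equal(tr$bases, "cg")
    expect_equal(tr$score, -3)
  }
})

test_that("trajectories and campaigns are seed-reproducible", {
  demo <- demo_helix_library()
  model <- toy_energy_model(demo$pairing, sigma = 1)
  t1 <- design_trajectory(demo$lib, model, n_cycles = 50L, seed = 99L)
  t2 <- design_trajectory(demo$lib, model, n_cycles = 50L, seed = 99L)
  expect_identical(t1, t2)
  c1 <- design_campaign(demo$lib, model, n_trajectories = 10L,
                        n_cycles = 30L, seed = 4L)
  c2 <- design_campaign(demo$lib, model, n_trajectories = 10L,
                        n_cycles = 30L, seed = 4L)
  expect_identical(c1, c2)
})

test_that("campaign frequencies are conserved and the noiseless optimum is exact", {
  ## 2-position library, 9 variants, noiseless: top row = global minimum
  lib2 <- library_definition("T2", "A", 1:2, "gc", strand_lengths = c(1L, 1L))
  pm2 <- pairing_map(strand_lengths = c(1L, 1L))
  model <- toy_energy_model(pm2)
  camp <- design_campaign(lib2, model, n_trajectories = 200L,
                          n_cycles = 40L, seed = 8L)
  expect_equal(sum(camp$freq), 200L)
  oracle <- brute_force_minimum(lib2, pm2)
  expect_equal(camp$bases[1L], oracle$bases)
  expect_equal(camp$score[1L], oracle$score)
  ## scores sorted ascending with lexicographic tie-break
  expect_true(all(diff(camp$score) >= 0))
})

test_that("forward folding is budget-fair and noise-consistent", {
  demo <- demo_helix_library()
  variants <- c("cggugcgc", "uggugcgc", "agcuagcu")
  ## noiseless limit: forward fold equals the deterministic score
  m0 <- toy_energy_model(demo$pairing, sigma = 0)
  ff0 <- forward_fold(variants, m0, n_cycles = 10L, n_models = 5L, seed = 1L)
  for (v in variants) {
    expect_equal(ff0$score[ff0$bases == v], toy_energy(v, demo$pairing))
  }
  ## best-of-N is non-increasing in N on the same seed stream
  m1 <- toy_energy_model(demo$pairing, sigma = 1)
  ff1 <- forward_fold(variants[1L], m1, n_cycles = 20L, n_models = 50L,
                      seed = 7L, keep_models = TRUE)
  prefix_min <- cummin(ff1$models[[1L]])
  expect_true(all(diff(prefix_min) <= 0))
  expect_equal(min(ff1$models[[1L]]), ff1$score)
  ## reproducibility
  ff2 <- forward_fold(variants, m1, n_cycles = 20L, n_models = 10L, seed = 3L)
  ff3 <- forward_fold(variants, m1, n_cycles = 20L, n_models = 10L, seed = 3L)
  expect_identical(ff2, ff3)
})

test_that("forward-fold ranking recovers a true score gap above 4 sigma", {
  demo <- demo_helix_library()
  sigma <- 0.5
  model <- toy_energy_model(demo$pairing, sigma = sigma)
  good <- "gacucuga"   # -15
  worse <- "gacucugg"  # -12.5: gap 2.5 > 4 * sigma
  expect_gt(toy_energy(worse, demo$pairing) - toy_energy(good, demo$pairing),
            4 * sigma)
  hits <- vapply(1:50, function(s) {
    ff <- forward_fold(c(worse, good), model, n_cycles = 20L, n_models = 20L,
                       seed = s)
    ff$bases[1L] == good
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("score files parse with sentinel dialect and min-merge of duplicates", {
  path <- withr::local_tempfile(fileext = ".sc")
  writeLines(c("SCORE:     score    rms    description",
               "SCORE:    -10.25   1.20   S_000001",
               "SCORE:    -12.75   0.80   S_000002",
               "SCORE:     -8.00   2.10   S_000003"), path)
  recs <- read_scorefile(path)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$tag[1L], "S_000002")  # sorted ascending by score
  expect_equal(recs$score[1L], -12.75)
  ## duplicate tags keep the minimum score
  writeLines(c("SCORE: score description",
               "SCORE: -10 M1", "SCORE: -12 M1", "SCORE: -5 M2"), path)
  expect_message(recs2 <- read_scorefile(path), "duplicate")
  expect_equal(nrow(recs2), 2L)
  expect_equal(recs2$score[recs2$tag == "M1"], -12)
  ## plain whitespace table without sentinel
  writeLines(c("score tag", "-1.5 a", "-2.5 b"), path)
  recs3 <- read_scorefile(path)
  expect_equal(recs3$tag, c("b", "a"))
  ## error and warning paths
  writeLines(c("SCORE: energy description", "SCORE: -1 x"), path)
  expect_error(read_scorefile(path), "score column")
  writeLines(c("SCORE: score description", "SCORE: oops x"), path)
  expect_error(read_scorefile(path), "line 2")
  writeLines(character(0), path)
  expect_warning(recs4 <- read_scorefile(path), "no score rows")
  expect_equal(nrow(recs4), 0L)
})
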