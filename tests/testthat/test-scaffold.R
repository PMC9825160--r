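test_that("sphere selection matches distances on a two-residue toy", {
  s <- two_residue_structure(gap = 10)
  designed <- residue_selection("A", 1L)
  expect_equal(neighbor_keys(select_sphere_neighborhood(s, designed, 15)), "A 2")
  expect_equal(neighbor_keys(select_sphere_neighborhood(s, designed, 5)),
               character(0))
  ## inclusive boundary: exactly at radius counts
  expect_equal(neighbor_keys(select_sphere_neighborhood(s, designed, 10)), "A 2")
  ## degenerate radius
  expect_equal(neighbor_keys(select_sphere_neighborhood(s, designed, 0)),
               character(0))
  expect_error(select_sphere_neighborhood(s, residue_selection("A", 99L), 10),
               "absent")
})

test_that("sphere selection agrees with the brute-force all-pairs oracle", {
  for (seed in c(11L, 12L, 13L, 14L)) {
    s <- random_toy_structure(n_res = 30L, seed = seed)
    rt <- residue_table(s)
    designed <- residue_selection(rt$chain[c(1L, 5L)], rt$resno[c(1L, 5L)])
    for (radius in c(4, 8, 15)) {
      ctx <- select_sphere_neighborhood(s, designed, radius)
      expect_equal(neighbor_keys(ctx), brute_neighbors(s, designed, radius),
                   info = sprintf("seed %d radius %g", seed, radius))
    }
  }
})

test_that("neighbor sets grow monotonically with radius", {
  s <- random_toy_structure(n_res = 50L, seed = 21L)
  rt <- residue_table(s)
  designed <- residue_selection(rt$chain[1L], rt$resno[1L])
  prev <- character(0)
  for (radius in c(5, 10, 20, 25)) {
    cur <- neighbor_keys(select_sphere_neighborhood(s, designed, radius))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("minimize-adjacent residues are the primary-sequence flanks", {
  h <- make_ideal_helix(12L, offsets = c(2221L, 2084L))
  designed <- parse_selection("A:2225-2228")
  mr <- adjacent_min_res(h, designed)
  expect_equal(paste(mr$chain, mr$resno), c("A 2224", "A 2229"))
  ## entire chain designed: nothing adjacent remains
  expect_null(adjacent_min_res(h, parse_selection("A:2221-2232")))
  ## two designed blocks separated by one residue: separator appears once
  two_blocks <- parse_selection("A:2222-2223,A:2225-2226")
  mr2 <- adjacent_min_res(h, two_blocks)
  expect_equal(sum(mr2$resno == 2224L), 1L)
  expect_setequal(mr2$resno, c(2221L, 2224L, 2227L))
})

test_that("native and starting models partition the context", {
  h <- make_ideal_helix(8L, offsets = c(2221L, 2084L))
  designed <- parse_selection("A:2225-2228,B:2088-2091")
  ctx <- select_sphere_neighborhood(h, designed, 25)
  models <- split_native_starting(ctx)
  n_designed <- nrow(designed)
  n_neigh <- nrow(ctx$neighbors)
  expect_equal(nrow(residue_table(models$native)), n_designed + n_neigh)
  expect_equal(nrow(residue_table(models$starting)), n_neigh)
  ## partition identity: starting + designed residue ids = native ids
  nat <- paste(residue_table(models$native)$chain,
               residue_table(models$native)$resno)
  sta <- paste(residue_table(models$starting)$chain,
               residue_table(models$starting)$resno)
  expect_setequal(c(sta, paste(designed$chain, designed$resno)), nat)
  ## serialized models reload with identical coordinates
  dir <- withr::local_tempdir()
  split_native_starting(ctx, dir = dir)
  nat2 <- load_structure(file.path(dir, "native.pdb"))
  a1 <- models$native$atoms
  a2 <- nat2$atoms
  expect_equal(round(sort(a2$x), 3), round(sort(a1$x), 3))
})

test_that("context FASTA uses lowercase RNA with numbered segments", {
  h <- make_ideal_helix(4L, sequence = "cggu", offsets = c(2225L, 2088L))
  fa <- context_to_fasta(h)
  arow <- fa[fa$chain == "A", ]
  expect_equal(arow$seq, "cggu")
  expect_equal(c(arow$start, arow$end), c(2225L, 2228L))
  ## numbering gap splits segments
  sub <- subset_structure(h, parse_selection("A:2225-2226,A:2228"))
  fa2 <- context_to_fasta(sub)
  expect_equal(nrow(fa2), 2L)
  expect_equal(fa2$seq, c("cg", "u"))
  expect_equal(fa2$start, c(2225L, 2228L))
  ## single residue
  fa3 <- context_to_fasta(subset_structure(h, residue_selection("A", 2225L)))
  expect_equal(fa3$seq, "c")
  ## segment letters map back to residue numbers (round trip)
  for (i in seq_len(nrow(fa2))) {
    expect_equal(nchar(fa2$seq[i]), fa2$end[i] - fa2$start[i] + 1L)
  }
  ## unknown residue names are rejected
  bad <- h
  bad$atoms$resid[bad$atoms$resno == 2225L & bad$atoms$chain == "A"] <- "XYZ"
  bad <- swm_structure(bad$atoms)
  expect_error(context_to_fasta(bad, skip_other = FALSE), "unknown residue")
  ## FASTA file output is well formed
  path <- withr::local_tempfile(fileext = ".fasta")
  write_context_fasta(fa, path)
  lines <- readLines(path)
  expect_equal(lines[1L], ">chainA:2225-2228")
  expect_equal(lines[2L], "cggu")
})
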