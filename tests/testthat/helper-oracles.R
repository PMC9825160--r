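## Independent oracles and small in-code fixtures shared across tests.

## Random toy structure: n_res residues on one or two chains, 1-3 atoms
## each (sometimes a hydrogen) at random coordinates in a 30 A box.
random_toy_structure <- function(n_res, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_res), function(i) {
    chain <- if (i <= ceiling(n_res / 2)) "A" else "B"
    resno <- if (chain == "A") i else i - ceiling(n_res / 2)
    n_atoms <- sample(1:3, 1L)
    elety <- c("C1'", "P", "H5'")[seq_len(n_atoms)]
    data.frame(chain = chain, resno = resno,
               resid = sample(c("A", "C", "G", "U", "MG"), 1L),
               elety = elety,
               elesy = c("C", "P", "H")[seq_len(n_atoms)],
               x = runif(n_atoms, 0, 30), y = runif(n_atoms, 0, 30),
               z = runif(n_atoms, 0, 30), het = FALSE,
               stringsAsFactors = FALSE)
  })
  swm_structure(do.call(rbind, rows), source = "toy")
}

## Brute-force all-pairs neighborhood oracle: a residue is a neighbor when
## any of its heavy atoms lies within `radius` of any atom of any designed
## residue (inclusive boundary).
brute_neighbors <- function(s, designed, radius) {
  a <- s$atoms
  dkey <- paste(designed$chain, designed$resno)
  akey <- paste(a$chain, a$resno)
  dat <- a[akey %in% dkey, , drop = FALSE]
  out <- character(0)
  for (key in setdiff(unique(akey), dkey)) {
    ra <- a[akey == key & toupper(a$elesy) != "H", , drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(dat))) {
        d <- sqrt((ra$x[i] - dat$x[j])^2 + (ra$y[i] - dat$y[j])^2 +
                  (ra$z[i] - dat$z[j])^2)
        if (d <= radius) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) out <- c(out, key)
  }
  sort(out)
}

neighbor_keys <- function(ctx) {
  if (is.null(ctx$neighbors)) character(0)
  else sort(paste(ctx$neighbors$chain, ctx$neighbors$resno))
}

## Exhaustive scoring of a library's whole sequence space.
brute_force_minimum <- function(lib, pairing) {
  v <- enumerate_library(lib)
  sc <- unname(vapply(v$bases, function(b) toy_energy(b, pairing), numeric(1L)))
  ord <- order(sc, v$bases)
  list(bases = v$bases[ord[1L]], score = sc[ord[1L]],
       all = data.frame(bases = v$bases, score = sc))
}

## Two-residue structure a known distance apart (closest heavy atoms).
two_residue_structure <- function(gap = 10) {
  atoms <- data.frame(chain = "A", resno = c(1L, 2L), resid = "G",
                      elety = "C1'", elesy = "C",
                      x = c(0, gap), y = 0, z = 0, het = FALSE,
                      stringsAsFactors = FALSE)
  swm_structure(atoms)
}
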