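## Shared fixture builders; all randomness is seeded by the caller.

## Exhaustive isotopologue enumeration oracle: expands every per-atom
## isotope assignment of a small formula (<= 6 atoms) and aggregates by
## nucleon offset. Independent of the convolution implementation.
enumerate_envelope <- function(formula, p_c13 = prosip:::NATURAL_C13) {
  iso <- prosip:::.ISOTOPES
  iso$C$abundance <- c(1 - p_c13, p_c13)
  atoms <- list()
  f <- unclass(formula)
  for (el in names(f)) {
    if (f[[el]] > 0) atoms <- c(atoms, rep(list(iso[[el]]), f[[el]]))
  }
  stopifnot(length(atoms) <= 6)
  grids <- lapply(atoms, function(a) seq_len(nrow(a)))
  combos <- expand.grid(grids)
  offs <- numeric(0); ab <- numeric(0); mm <- numeric(0)
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(combos))) {
    off <- 0L; pr <- 1; m <- 0
    for (j in seq_along(atoms)) {
      i <- combos[r, j]
      off <- off + atoms[[j]]$offset[i]
      pr <- pr * atoms[[j]]$abundance[i]
      m <- m + atoms[[j]]$mass[i]
    }
    key <- as.character(off)
    cur <- acc[[key]]
    if (is.null(cur)) cur <- c(0, 0)
    acc[[key]] <- cur + c(pr, pr * m)
  }
  offsets <- sort(as.integer(ls(acc)))
  ab <- vapply(offsets, function(o) acc[[as.character(o)]][1], numeric(1))
  mm <- vapply(offsets, function(o) acc[[as.character(o)]][2], numeric(1))
  list(offsets = offsets, abundance = ab, centroid_mass = mm / ab)
}

## A small deterministic peptide set with >= 20 carbons each.
fixture_peptides <- function() {
  c("ELVISLIVESK", "TESTPEPTIDER", "GNDAQWFYLK", "VVDLAPGHMSTK",
    "QWERTYPASSK", "LLGHDAFNESR", "MTPAVDEHIK", "GGFFYYWWHHK")
}

## Spectra for one peptide at one true enrichment (percent scale).
fixture_spectra <- function(peptides, atom_percent, n, noise_sd = 0.1,
                            seed = 1) {
  tab <- data.frame(
    peptide = rep_len(peptides, n),
    protein_id = "P1",
    atom_percent = atom_percent,
    stringsAsFactors = FALSE)
  generate_spectra(tab, noise_sd = noise_sd, dropout = 0, seed = seed)
}

## Two-genome community features with well-separated abundance profiles.
fixture_two_genome_features <- function(seed = 7) {
  com <- generate_community(n_genomes = 2, genome_length = 60000,
                            n_samples = 8, seed = seed)
  ## force disjoint abundance profiles
  ab <- com$abundance
  ab["genome_01", ] <- c(40, 40, 40, 40, 1, 1, 1, 1)
  ab["genome_02", ] <- c(1, 1, 1, 1, 40, 40, 40, 40)
  cov <- com$coverage
  set.seed(seed)
  for (r in seq_len(nrow(cov)))
    cov[r, ] <- stats::rpois(ncol(cov), ab[com$scaffolds$genome_id[r], ] * 2)
  feats <- scaffold_features(com$scaffolds, cov, min_length = 5000)
  truth <- com$scaffolds$genome_id[match(rownames(feats),
                                         com$scaffolds$scaffold_id)]
  list(features = feats, truth = truth, community = com, coverage = cov)
}
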