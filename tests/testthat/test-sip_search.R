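test_that("decoy database reverses sequences under a reserved prefix", {
  db <- make_decoy_db(c(P1 = "PEPTIDE", P2 = "ACDK"))
  expect_length(db, 4L)
  expect_equal(unname(db[["XXX_P1"]]), "EDITPEP")
  expect_equal(attr(db, "is_decoy"), c(FALSE, FALSE, TRUE, TRUE))
  ## palindrome: decoy equals target but stays flagged decoy
  db2 <- make_decoy_db(c(P3 = "ADA"))
  expect_equal(unname(db2[["XXX_P3"]]), "ADA")
  expect_true(attr(db2, "is_decoy")[2])
  expect_error(make_decoy_db(c(XXX_P = "AAA")), "prefix")
  expect_error(make_decoy_db(character()), "empty")
})

test_that("envelope scoring is a cosine on aligned intensities", {
  t <- c(0.2, 0.5, 0.3)
  expect_equal(score_envelope(10 * t, t), 1.0)
  expect_equal(score_envelope(c(0, 0, 0), t), 0.0)
  expect_equal(score_envelope(c(1, 0), c(0, 1)), 0.0)
  expect_equal(score_envelope(c(1, 0), c(0.5, 0.5)), 0.7071, tolerance = 1e-4)
  ## invariance under intensity scaling
  o <- c(3, 1, 0.5)
  expect_equal(score_envelope(o, t), score_envelope(1e6 * o, t))
  expect_error(score_envelope(c(1, 2), c(1, 2, 3)), "aligned")
})

test_that("atom percent estimation recovers the generating enrichment", {
  cfg <- search_config("sip")
  g <- fixture_spectra("ELVISLIVESK", 30, 1, noise_sd = 0, seed = 3)
  est <- estimate_atom_percent(g$spectra[[1]], "ELVISLIVESK", cfg)
  expect_true(est$matched)
  expect_equal(est$atom_percent, 30)
  gn <- fixture_spectra("ELVISLIVESK", 100 * prosip:::NATURAL_C13, 1,
                        noise_sd = 0, seed = 4)
  estn <- estimate_atom_percent(gn$spectra[[1]], "ELVISLIVESK", cfg)
  expect_equal(estn$atom_percent, 1.07)
  ## precursor far outside every offset window: no match
  sp <- g$spectra[[1]]
  far <- spectrum(sp$spectrum_id, sp$precursor_mz + 50, sp$precursor_charge,
                  sp$mz, sp$intensity)
  expect_false(estimate_atom_percent(far, "ELVISLIVESK", cfg)$matched)
})

test_that("noisy spectra still estimate within 2 atom percent", {
  g <- fixture_spectra(fixture_peptides(), 30, 24, noise_sd = 0.1, seed = 5)
  cfg <- search_config("sip")
  ests <- vapply(seq_along(g$spectra), function(i)
    estimate_atom_percent(g$spectra[[i]], g$manifest$peptide[i],
                          cfg)$atom_percent, numeric(1))
  expect_lt(abs(mean(ests) - 30), 2)
})

test_that("database search matches spectra to their generating peptides", {
  prots <- c(PA = "ELVISLIVESKGNDAQWFYLK",
             PB = "TESTPEPTIDERVVDLAPGHMSTK",
             PC = "QWERTYPASSKLLGHDAFNESR")
  db <- make_decoy_db(prots)
  cfg <- search_config("sip")
  index <- build_peptide_index(db, cfg)
  tab <- data.frame(peptide = rep(c("ELVISLIVESK", "TESTPEPTIDER",
                                    "QWERTYPASSK", "GNDAQWFYLK"), 5),
                    protein_id = "x", atom_percent = rep(c(20, 50, 1.07, 35),
                                                         5))
  gen <- generate_spectra(tab, noise_sd = 0.02, seed = 9)
  psms <- search_sample(gen$spectra, index, cfg)
  expect_equal(nrow(psms), nrow(gen$manifest))
  hit <- psms$peptide == gen$manifest$peptide[
    match(psms$spectrum_id, gen$manifest$spectrum_id)]
  expect_gte(mean(hit), 0.99)
  ## estimated atom% tracks truth
  truth <- gen$manifest$atom_percent[match(psms$spectrum_id,
                                           gen$manifest$spectrum_id)]
  expect_lt(max(abs(psms$atom_percent - truth)), 2)
  ## determinism: identical reruns give identical tables
  psms2 <- search_sample(gen$spectra, index, cfg)
  expect_identical(psms, psms2)
})

test_that("spectra matching nothing are absent and malformed ones skipped", {
  prots <- c(PA = "ELVISLIVESKGNDAQWFYLK")
  index <- build_peptide_index(make_decoy_db(prots), search_config("sip"))
  g <- fixture_spectra("ELVISLIVESK", 20, 1, noise_sd = 0, seed = 2)
  sp <- g$spectra[[1]]
  orphan <- spectrum("orphan", 333.3333, 2L, sp$mz, sp$intensity)
  empty <- spectrum("empty", sp$precursor_mz, 2L, numeric(), numeric())
  expect_message(
    psms <- search_sample(list(sp, orphan, empty), index,
                          search_config("sip")),
    "skipped 1")
  expect_equal(psms$spectrum_id, sp$spectrum_id)
})

test_that("the FDR filter retains the largest prefix under the level", {
  mk <- function(scores, decoy) data.frame(
    spectrum_id = paste0("s", seq_along(scores)),
    sample_id = "S", replicate_id = "R",
    peptide = paste0("PEP", seq_along(scores), "K"),
    mods = "", protein_ids = "P", is_decoy = decoy,
    atom_percent = 1.07, score = scores, parent_offset_da = 0L,
    precursor_charge = 2L, stringsAsFactors = FALSE)
  ## 10 targets, no decoys: everything passes
  all_t <- mk(seq(1, 0.1, length.out = 10), rep(FALSE, 10))
  expect_equal(nrow(fdr_filter(all_t, 0.01)), 10)
  ## T T T T D ...: exactly the first four at 1%
  tt <- mk(seq(1, 0.1, length.out = 10),
           c(FALSE, FALSE, FALSE, FALSE, TRUE, rep(FALSE, 5)))
  expect_equal(sort(fdr_filter(tt, 0.01)$peptide),
               sort(paste0("PEP", 1:4, "K")))
  ## all decoys outscore all targets: empty
  ad <- mk(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(fdr_filter(ad, 0.01)), 0)
  ## zero targets: empty
  expect_equal(nrow(fdr_filter(mk(0.5, TRUE), 0.01)), 0)
  expect_error(fdr_filter(tt, 1.5), "level")
})

test_that("FDR collapse keeps the best PSM per peptide", {
  df <- data.frame(
    spectrum_id = c("a", "b", "c"), sample_id = "S", replicate_id = "R",
    peptide = c("AAAK", "AAAK", "CCCK"), mods = "",
    protein_ids = "P", is_decoy = c(FALSE, FALSE, FALSE),
    atom_percent = 1.07, score = c(0.9, 0.4, 0.8),
    parent_offset_da = 0L, precursor_charge = 2L, stringsAsFactors = FALSE)
  out <- fdr_filter(df, 0.5)
  ## all PSM rows of retained peptides come back
  expect_equal(sort(out$spectrum_id), c("a", "b", "c"))
})
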