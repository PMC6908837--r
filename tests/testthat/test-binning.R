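test_that("feature matrix filters short scaffolds and stays finite", {
  fx <- fixture_two_genome_features()
  sc <- fx$community$scaffolds
  expect_true(all(rownames(fx$features) %in%
                    sc$scaffold_id[sc$length >= 5000]))
  expect_true(all(is.finite(fx$features)))
  ## zero coverage everywhere is finite via the pseudocount
  cov0 <- fx$coverage; cov0[] <- 0
  f0 <- scaffold_features(sc, cov0, min_length = 5000)
  expect_true(all(is.finite(f0)))
  ## scaffold without a coverage row errors
  expect_error(scaffold_features(sc, fx$coverage[-1, , drop = FALSE]),
               "coverage")
  ## within-genome feature distances sit below the cross-genome median
  d <- as.matrix(dist(fx$features))
  same <- outer(fx$truth, fx$truth, "==")
  diag(same) <- NA
  expect_lt(median(d[same & upper.tri(d)], na.rm = TRUE),
            median(d[!same & upper.tri(d)], na.rm = TRUE))
})

test_that("canonical tetranucleotide vector has 136 classes summing to 1", {
  v <- tetranucleotide_freq("ACGTACGTAAATTTCCCGGG")
  expect_length(v, 136)
  expect_equal(sum(v), 1)
  ## reverse complement maps to the same vector
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ACGTACGTAAATTTCCCGGG")))
  expect_equal(v, tetranucleotide_freq(rc))
})

test_that("Gaussian-mixture clustering separates distinct genomes", {
  fx <- fixture_two_genome_features()
  lab <- cluster_scaffolds(fx$features, k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(lab, fx$truth), 1.0)
  ## determinism under the same seed
  expect_identical(lab, cluster_scaffolds(fx$features, k = 2, seed = 1))
  ## identical rows collapse to one cluster
  same <- fx$features[rep(1, 8), , drop = FALSE]
  rownames(same) <- paste0("s", 1:8)
  expect_equal(unique(cluster_scaffolds(same, k = 2, seed = 1)), 1L)
  expect_error(cluster_scaffolds(fx$features[1:3, ], k = 10), "fewer")
  expect_error(cluster_scaffolds(fx$features, k = 1), "k must")
})

test_that("anchor refinement keeps tight neighborhoods, drops outliers", {
  ## constructed geometry: anchor + 10 tight neighbors + 5 outliers at
  ## 10x distance
  withr::with_seed(5, {
    base <- matrix(rnorm(16 * 4, sd = 0.05), 16, 4)
    base[12:16, ] <- base[12:16, ] + 10
    rownames(base) <- paste0("s", 1:16)
  })
  sets <- refine_bin(base, rownames(base), anchors = "s1")
  expect_length(sets, 1)
  expect_setequal(sets[[1]], paste0("s", 1:11))
  ## untargeted mode: cluster unchanged
  expect_equal(refine_bin(base, rownames(base)), list(rownames(base)))
  ## two anchors in one tight neighborhood merge into one candidate set
  sets2 <- refine_bin(base, rownames(base), anchors = c("s1", "s2"))
  expect_length(sets2, 1)
  expect_true(all(c("s1", "s2") %in% sets2[[1]]))
  ## anchor outside the cluster errors
  expect_error(refine_bin(base, paste0("s", 1:8), anchors = "s16"),
               "anchor")
})

test_that("every anchor lands in exactly one candidate MAG", {
  withr::with_seed(6, {
    f <- rbind(matrix(rnorm(40, sd = 0.1), 10, 4),
               matrix(rnorm(40, sd = 0.1) + 8, 10, 4))
    rownames(f) <- paste0("s", 1:20)
  })
  anchors <- c("s1", "s15")
  sets <- refine_bin(f, rownames(f), anchors = anchors)
  counts <- vapply(anchors, function(a)
    sum(vapply(sets, function(s) a %in% s, logical(1))), integer(1))
  expect_true(all(counts == 1L))
  ## candidate sets are disjoint
  expect_equal(anyDuplicated(unlist(sets)), 0L)
})

test_that("quality estimates match direct marker counting", {
  ms <- paste0("m", 1:100)
  q <- estimate_quality(ms, ms)
  expect_equal(q$completeness, 100)
  expect_equal(q$contamination, 0)
  q2 <- estimate_quality(ms[1:54], ms)
  expect_equal(q2$completeness, 54)
  q3 <- estimate_quality(c(paste0("m", 1:7), "m1"), paste0("m", 1:10))
  expect_equal(q3$completeness, 70)
  expect_equal(q3$contamination, 10)
  ## spec example variant: 8 markers present, one twice
  q4 <- estimate_quality(c(paste0("m", 1:8), "m8"), paste0("m", 1:10))
  expect_equal(q4$completeness, 80)
  expect_equal(q4$contamination, 10)
  expect_error(estimate_quality("m1", character()), "empty marker set")
  ## hits outside the marker set are ignored
  expect_equal(estimate_quality(c("m1", "zzz"), paste0("m", 1:10))$completeness,
               10)
})

test_that("MAG acceptance applies the mode-specific thresholds", {
  two_ids <- data.frame(protein_id = c("a", "b"),
                        sample_id = "S", atom_percent = c(20, 30))
  ## targeted co2 with completeness 54 / contamination 0.3 and two labeled
  ## identifications is accepted at medium quality
  m <- mag_record("M", completeness = 54, contamination = 0.3,
                  mode = "targeted_co2", labeled_idents = two_ids)
  v <- accept_mag(m)
  expect_true(v$accepted)
  expect_equal(v$quality_class, "medium")
  ## untargeted needs completeness > 70
  expect_false(accept_mag(mag_record("M", completeness = 65,
                                     contamination = 2,
                                     mode = "untargeted"))$accepted)
  expect_true(accept_mag(mag_record("M", completeness = 71,
                                    contamination = 9,
                                    mode = "untargeted"))$accepted)
  ## targeted contamination above 5 rejects regardless of support
  m6 <- mag_record("M", completeness = 80, contamination = 6,
                   mode = "targeted_co2", labeled_idents = two_ids)
  expect_false(accept_mag(m6)$accepted)
  expect_match(accept_mag(m6)$failed_rules, "contamination", all = FALSE)
  ## one identification is not enough in co2 mode
  m1 <- mag_record("M", completeness = 40, contamination = 1,
                   mode = "targeted_co2", labeled_idents = two_ids[1, ])
  expect_false(accept_mag(m1)$accepted)
  ## methanol: one protein in two replicates of a triplicate passes
  meth <- mag_record("M", completeness = 30, contamination = 2,
                     mode = "targeted_methanol",
                     labeled_idents = data.frame(
                       protein_id = "x", timepoint = "D3",
                       replicate_id = c("R1", "R3"),
                       atom_percent = c(93, 93)))
  expect_true(accept_mag(meth)$accepted)
  expect_error(accept_mag(m, mode = "bogus"), "unknown mode")
})

test_that("taxonomy voting follows the 75/50 and 2-of-3 phylum rules", {
  t1 <- assign_taxonomy(rep(c("Pseudomonas", "Other"), c(8, 2)))
  expect_equal(t1$taxon, "Pseudomonas")
  expect_equal(t1$confidence, "assigned")
  t2 <- assign_taxonomy(rep(c("Pseudomonas", "Other"), c(6, 4)))
  expect_equal(t2$confidence, "putative")
  t3 <- assign_taxonomy(rep(c("A", "B"), c(5, 5)))
  expect_equal(t3$confidence, "unclassified")
  expect_true(is.na(t3$taxon))
  ## cross-tool: 2-of-3 phylum agreement takes the LCA of the agreeing
  lca <- assign_taxonomy(tool_assignments = c(
    "Proteobacteria;Pseudomonadales;Pseudomonas",
    "Proteobacteria;Burkholderiales",
    "Actinobacteria;Streptomycetales"))
  expect_equal(lca$consensus_lineage, "Proteobacteria")
  expect_equal(lca$taxon, "Proteobacteria")
  ## deeper agreement keeps the longer common prefix
  lca2 <- assign_taxonomy(tool_assignments = c(
    "Proteobacteria;Rhizobiales;Bradyrhizobiaceae",
    "Proteobacteria;Rhizobiales;Methylobacteriaceae",
    "Firmicutes;Bacillales"))
  expect_equal(lca2$consensus_lineage,
               c("Proteobacteria", "Rhizobiales"))
  ## empty inputs: unclassified
  e <- assign_taxonomy()
  expect_equal(e$confidence, "unclassified")
})
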