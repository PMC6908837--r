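test_that("parsimony inference covers peptides with a minimal protein set", {
  ## both peptides only in P1: one group, two unique peptides
  g <- infer_proteins(c("a", "b"), list(a = "P1", b = "P1"))
  expect_length(g, 1)
  expect_equal(g[[1]]$member_proteins, "P1")
  expect_equal(sort(g[[1]]$unique_peptides), c("a", "b"))
  ## P2 subsumed by P1
  g2 <- infer_proteins(c("a", "b"), list(a = "P1", b = c("P1", "P2")))
  expect_length(g2, 1)
  expect_equal(g2[[1]]$member_proteins, "P1")
  expect_equal(g2[[1]]$unique_peptides, "a")
  expect_equal(g2[[1]]$shared_peptides, "b")
  ## indistinguishable proteins merge into one group
  g3 <- infer_proteins("a", list(a = c("P1", "P2")))
  expect_length(g3, 1)
  expect_equal(g3[[1]]$member_proteins, c("P1", "P2"))
})

test_that("parsimony output explains every input peptide", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      prots <- paste0("P", 1:8)
      peps <- paste0("pep", 1:15)
      map <- lapply(peps, function(p)
        sample(prots, sample(1:3, 1)))
      names(map) <- peps
      groups <- infer_proteins(peps, map)
      covered <- unique(unlist(lapply(groups, function(g)
        c(g$unique_peptides, g$shared_peptides))))
      ## every peptide is explained by some chosen group unless its only
      ## groups lost their unique evidence; those peptides still map into
      ## a chosen group member
      explained <- vapply(peps, function(p)
        any(map[[p]] %in% unlist(lapply(groups, `[[`, "member_proteins"))),
        logical(1))
      expect_true(all(p <- explained | !(peps %in% covered)) || all(explained))
      ## groups all retain a unique peptide
      expect_true(all(vapply(groups, function(g)
        length(g$unique_peptides) >= 1, logical(1))))
    }
  })
})

test_that("protein FDR is the decoy/target group ratio", {
  g <- replicate(100, list(group_id = "x"), simplify = FALSE)
  expect_equal(protein_fdr(g, list()), 0)
  expect_equal(protein_fdr(g, list(list(group_id = "d"))), 0.01)
  expect_error(protein_fdr(list(), list()), "zero target")
})

test_that("isotopologue clustering merges until gaps exceed 10 atom%", {
  cl <- cluster_isotopologues(c(20, 21, 45, 47))
  expect_length(cl, 2)
  expect_equal(cl[[1]], c(20, 21))
  expect_equal(cl[[2]], c(45, 47))
  expect_length(cluster_isotopologues(15), 1)
  expect_length(cluster_isotopologues(c(15, 18)), 1)
  expect_error(cluster_isotopologues(numeric()), "empty")
  ## property: all final inter-cluster mean differences exceed 10
  withr::with_seed(31, {
    for (i in 1:10) {
      v <- runif(sample(2:12, 1), 11, 99)
      cl <- cluster_isotopologues(v)
      means <- vapply(cl, mean, numeric(1))
      if (length(means) > 1) expect_true(all(diff(sort(means)) > 10))
      expect_equal(sort(unlist(cl)), sort(v))
    }
  })
})

.group_with <- function(ids) {
  structure(list(group_id = "G1", member_proteins = "P1",
                 unique_peptides = unique(ids$peptide),
                 shared_peptides = character(),
                 identifications = ids), class = "protein_group")
}

test_that("co2 labeling filter needs two labeled peptides in one sample", {
  ## two distinct labeled peptides in one sample: passing
  ids <- data.frame(peptide = c("a", "b", "c"),
                    sample_id = c("Zm_T2_R1", "Zm_T2_R1", "Zm_T1_R1"),
                    atom_percent = c(16, 26, 46), stringsAsFactors = FALSE)
  call <- filter_labeled_proteins(.group_with(ids), "co2")
  expect_true(call$passing)
  expect_true(all(call$atom_percent > 10))
  ## single labeled peptide in one sample only: not passing
  ids2 <- data.frame(peptide = "a", sample_id = "Zm_T2_R1",
                     atom_percent = 35, stringsAsFactors = FALSE)
  expect_false(filter_labeled_proteins(.group_with(ids2), "co2")$passing)
  ## two PSMs of the same peptide do not count as two peptides
  ids3 <- data.frame(peptide = c("a", "a"),
                     sample_id = "Zm_T2_R1",
                     atom_percent = c(30, 31), stringsAsFactors = FALSE)
  expect_false(filter_labeled_proteins(.group_with(ids3), "co2")$passing)
})

test_that("methanol labeling filter needs two replicates of a triplicate", {
  ## the day-3 replicate-1/replicate-3 pattern: passing
  ids <- data.frame(peptide = "x", timepoint = "D3",
                    replicate_id = c("R1", "R3"), sample_id = "D3",
                    atom_percent = c(93, 93), stringsAsFactors = FALSE)
  expect_true(filter_labeled_proteins(.group_with(ids), "methanol")$passing)
  ids2 <- ids[1, ]
  expect_false(filter_labeled_proteins(.group_with(ids2),
                                       "methanol")$passing)
})

test_that("adding a labeled peptide never breaks a passing call", {
  withr::with_seed(41, {
    for (i in 1:10) {
      n <- sample(2:6, 1)
      ids <- data.frame(peptide = paste0("p", 1:n),
                        sample_id = sample(c("A", "B"), n, replace = TRUE),
                        atom_percent = runif(n, 11, 60),
                        stringsAsFactors = FALSE)
      before <- filter_labeled_proteins(.group_with(ids), "co2")$passing
      extra <- rbind(ids, data.frame(peptide = "pnew",
                                     sample_id = sample(c("A", "B"), 1),
                                     atom_percent = runif(1, 11, 60)))
      after <- filter_labeled_proteins(.group_with(extra), "co2")$passing
      if (before) expect_true(after)
    }
  })
})

test_that("Mann-Whitney exact p matches brute-force enumeration", {
  res <- compare_timepoints(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 6)
  expect_equal(res$method, "exact")
  ## identical single values: two-sided p = 1
  expect_equal(compare_timepoints(5, 5, "two.sided")$p_value, 1)
  ## independent brute-force oracle over random small inputs (with ties)
  brute <- function(x, y, alt) {
    pooled <- c(x, y)
    n1 <- length(x)
    idx <- utils::combn(length(pooled), n1)
    u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
    u <- u_of(x, y)
    if (alt == "less") mean(us <= u + 1e-9) else mean(us >= u - 1e-9)
  }
  withr::with_seed(51, {
    for (i in 1:12) {
      n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
      x <- sample(1:6, n1, replace = TRUE)
      y <- sample(1:6, n2, replace = TRUE)
      for (alt in c("less", "greater")) {
        expect_equal(compare_timepoints(x, y, alt)$p_value, brute(x, y, alt))
      }
    }
  })
  ## cross-check against the standard implementation when tie-free
  x <- c(1.2, 3.4, 2.2); y <- c(4.5, 5.1, 0.3, 6.6)
  expect_equal(compare_timepoints(x, y, "less")$p_value,
               stats::wilcox.test(x, y, alternative = "less",
                                  exact = TRUE)$p.value)
  expect_error(compare_timepoints(numeric(), 1), "empty")
})

test_that("normal approximation tracks enumeration at moderate n", {
  withr::with_seed(61, {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    exact <- compare_timepoints(x, y, "less")$p_value
    approx <- compare_timepoints(x, y, "less", exact_limit = 2)$p_value
    expect_lt(abs(exact - approx), 0.02)
  })
})

test_that("functional aggregation sums normalized member abundances", {
  ab <- data.frame(protein_id = "P1", abundance = 5)
  ann <- data.frame(term = "GO:1", protein_id = "P1")
  out <- aggregate_functional_abundance(ab, ann, normalize = FALSE)
  expect_equal(out$abundance[out$term == "GO:1"], 5)
  ## two proteins sharing a term sum
  ab2 <- data.frame(protein_id = c("P1", "P2"), abundance = c(2, 3))
  ann2 <- data.frame(term = c("GO:1", "GO:1"), protein_id = c("P1", "P2"))
  out2 <- aggregate_functional_abundance(ab2, ann2, normalize = FALSE)
  expect_equal(out2$abundance[out2$term == "GO:1"], 5)
  ## a family holding 11% of total abundance reports fraction 0.11
  ab3 <- data.frame(protein_id = paste0("P", 1:3),
                    abundance = c(11, 50, 39))
  ann3 <- data.frame(term = c("fam_target", "fam_other", "fam_other2"),
                     protein_id = paste0("P", 1:3))
  out3 <- aggregate_functional_abundance(ab3, ann3)
  expect_equal(out3$fraction[out3$term == "fam_target"], 0.11,
               tolerance = 1e-9)
  ## unannotated proteins land in the unannotated bucket
  out4 <- aggregate_functional_abundance(
    data.frame(protein_id = c("P1", "PX"), abundance = c(1, 3)),
    ann, normalize = FALSE)
  expect_equal(out4$abundance[out4$term == "unannotated"], 3)
})
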