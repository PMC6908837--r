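## Parsimony protein inference, labeled-protein filtering, isotopologue
## clustering, timepoint statistics, and functional abundance aggregation.

#' Infer protein groups by the parsimony rule
#'
#' Greedy minimal set cover: repeatedly select the protein explaining the
#' most currently unexplained peptides (ties broken by accession order);
#' proteins with identical observed peptide sets are merged into one group.
#' Groups lacking a unique peptide (a peptide whose full protein set in the
#' map is contained in the group) are discarded.
#'
#' @param peptide_ids Character vector of identified peptide sequences, or a
#'   data.frame with a `peptide` column (extra columns, e.g. `atom_percent`,
#'   `sample_id`, are carried into each group's `identifications`).
#' @param peptide_proteins Named list mapping peptide sequence to the
#'   character vector of proteins containing it (the database-level map).
#' @return List of `protein_group` objects with fields `group_id`,
#'   `member_proteins`, `unique_peptides`, `shared_peptides`,
#'   `identifications`.
#' @export
infer_proteins <- function(peptide_ids, peptide_proteins) {
  df <- if (is.data.frame(peptide_ids)) peptide_ids else
    data.frame(peptide = peptide_ids, stringsAsFactors = FALSE)
  peptides <- sort(unique(df$peptide))
  peptides <- peptides[peptides %in% names(peptide_proteins)]
  if (!length(peptides)) return(list())
  ## protein -> observed peptide set
  prot_peps <- new.env(parent = emptyenv())
  for (pep in peptides)
    for (acc in peptide_proteins[[pep]])
      prot_peps[[acc]] <- c(prot_peps[[acc]], pep)
  prots <- sort(ls(prot_peps))
  sets <- lapply(prots, function(a) sort(unique(prot_peps[[a]])))
  names(sets) <- prots
  ## merge proteins with identical observed peptide sets
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  groups <- split(prots, keys)
  group_sets <- lapply(groups, function(g) sets[[g[1]]])
  ## greedy set cover over groups
  unexplained <- peptides
  chosen <- character()
  group_order <- names(groups)[order(vapply(groups, `[`, character(1), 1L))]
  while (length(unexplained)) {
    gain <- vapply(group_order, function(k)
      sum(group_sets[[k]] %in% unexplained), integer(1))
    if (all(gain == 0L)) break
    pick <- group_order[which.max(gain)]  # first max = lowest accession
    chosen <- c(chosen, pick)
    unexplained <- setdiff(unexplained, group_sets[[pick]])
    group_order <- setdiff(group_order, pick)
  }
  out <- list()
  for (k in chosen) {
    members <- sort(groups[[k]])
    peps <- group_sets[[k]]
    uniq <- peps[vapply(peps, function(pep)
      all(peptide_proteins[[pep]] %in% members), logical(1))]
    if (!length(uniq)) next
    out[[length(out) + 1L]] <- structure(list(
      group_id = members[1],
      member_proteins = members,
      unique_peptides = uniq,
      shared_peptides = setdiff(peps, uniq),
      identifications = df[df$peptide %in% peps, , drop = FALSE]
    ), class = "protein_group")
  }
  out
}

#' Protein-level FDR from decoy protein groups
#'
#' @param groups Target protein groups (from [infer_proteins] on target
#'   identifications).
#' @param decoy_groups Groups inferred identically from decoy
#'   identifications.
#' @return `length(decoy_groups) / length(groups)`.
#' @export
protein_fdr <- function(groups, decoy_groups) {
  if (!length(groups)) stop("zero target protein groups")
  length(decoy_groups) / length(groups)
}

#' Cluster labeled-peptide atom% values into protein isotopologues
#'
#' Agglomerative merging on cluster means: while the two clusters with the
#' closest means differ by <= 10 atom%, merge them; stops when all pairwise
#' mean differences exceed 10.
#'
#' @param atom_values Numeric atom% values, all > 10 (labeled peptides).
#' @param max_gap Merge threshold in atom% (default 10).
#' @return List of numeric vectors (the partition), ordered by cluster mean.
#' @export
cluster_isotopologues <- function(atom_values, max_gap = 10) {
  if (!length(atom_values)) stop("empty input")
  clusters <- as.list(sort(atom_values))
  repeat {
    if (length(clusters) == 1L) break
    means <- vapply(clusters, mean, numeric(1))
    d <- diff(means)  # sorted means: closest pair is adjacent
    i <- which.min(d)
    if (d[i] > max_gap) break
    clusters[[i]] <- c(clusters[[i]], clusters[[i + 1L]])
    clusters[[i + 1L]] <- NULL
    clusters <- clusters[order(vapply(clusters, mean, numeric(1)))]
  }
  clusters
}

#' Call a protein group labeled or unlabeled
#'
#' Labeling rules: an identification supports labeling when its atom% > 10.
#' In `"co2"` mode (the 13CO2 rhizosphere design) a group passes when at
#' least one sample of its plant-species block has >= 2 distinct labeled
#' peptide sequences. In `"methanol"` mode (SIP incubation triplicates) a
#' group passes when some triplicate (timepoint) has labeled
#' identifications in >= 2 distinct replicates.
#'
#' @param group `protein_group` whose `identifications` carry
#'   `atom_percent`, `sample_id`, `peptide`, and (co2) `species` or
#'   (methanol) `timepoint` + `replicate_id` columns.
#' @param mode `"co2"` or `"methanol"`.
#' @param min_atom_percent Labeling threshold, exclusive (default 10).
#' @return Object of class `labeled_protein_call`: `group_id`, `mode`,
#'   `passing`, `atom_percent` (supporting values), `clusters`
#'   (isotopologue partition of the supporting values), `support` (the
#'   supporting identification rows).
#' @export
filter_labeled_proteins <- function(group, mode = c("co2", "methanol"),
                                    min_atom_percent = 10) {
  mode <- match.arg(mode)
  ids <- group$identifications
  labeled <- ids[!is.na(ids$atom_percent) & ids$atom_percent > min_atom_percent, ,
                 drop = FALSE]
  passing <- FALSE
  if (nrow(labeled)) {
    if (mode == "co2") {
      per_sample <- tapply(labeled$peptide, labeled$sample_id,
                           function(x) length(unique(x)))
      passing <- any(per_sample >= 2L)
    } else {
      key <- if ("timepoint" %in% names(labeled)) labeled$timepoint
             else labeled$sample_id
      per_tp <- tapply(labeled$replicate_id, key,
                       function(x) length(unique(x)))
      passing <- any(per_tp >= 2L)
    }
  }
  clusters <- if (nrow(labeled))
    cluster_isotopologues(labeled$atom_percent) else list()
  structure(list(group_id = group$group_id,
                 mode = mode,
                 passing = passing,
                 atom_percent = labeled$atom_percent,
                 clusters = clusters,
                 support = labeled),
            class = "labeled_protein_call")
}

## All group-1/group-2 splits of the pooled values, U statistic per split.
## U counts pairs with x > y plus half-ties (U for the first sample).
.mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

#' Mann-Whitney U comparison of two timepoints
#'
#' Exact permutation null (full enumeration of group assignments) when
#' `n1 + n2 <= exact_limit`, normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param t1_values,t2_values Non-empty numeric vectors.
#' @param alternative `"less"` (first sample shifted left, i.e. the second
#'   timepoint larger — the default, matching enrichment growing over
#'   time), `"greater"`, or `"two.sided"`.
#' @param exact_limit Maximum `n1 + n2` for full enumeration (default 20).
#' @return List with `U` (statistic for the first sample), `p_value`,
#'   `method` (`"exact"` or `"normal"`), `alternative`.
#' @export
compare_timepoints <- function(t1_values, t2_values,
                               alternative = c("less", "greater", "two.sided"),
                               exact_limit = 20L) {
  alternative <- match.arg(alternative)
  if (!length(t1_values) || !length(t2_values)) stop("empty value list")
  x <- as.numeric(t1_values); y <- as.numeric(t2_values)
  n1 <- length(x); n2 <- length(y)
  u_obs <- .mw_u(x, y)
  if (n1 + n2 <= exact_limit) {
    pooled <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) .mw_u(pooled[i], pooled[-i]))
    p_le <- mean(us <= u_obs + 1e-9)
    p_ge <- mean(us >= u_obs - 1e-9)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    return(list(U = u_obs, p_value = p, method = "exact",
                alternative = alternative))
  }
  N <- n1 + n2
  ties <- table(c(x, y))
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  sigma <- sqrt(sigma2)
  p_le <- stats::pnorm((u_obs - mu + 0.5) / sigma)
  p_ge <- stats::pnorm((u_obs - mu - 0.5) / sigma, lower.tail = FALSE)
  p <- switch(alternative,
              less = p_le, greater = p_ge,
              two.sided = min(1, 2 * min(p_le, p_ge)))
  list(U = u_obs, p_value = p, method = "normal", alternative = alternative)
}

#' Aggregate protein abundances into functional terms
#'
#' Per-protein abundances (normalized peak-area sums) are summed over a
#' flat protein-to-term annotation map; proteins without annotation are
#' counted under `"unannotated"`.
#'
#' @param abundance data.frame with columns `protein_id`, `abundance`
#'   (optionally `sample_id`; aggregation is per sample when present).
#' @param annotation data.frame with columns `protein_id`, `term` (a
#'   protein may map to several terms).
#' @param normalize Scale abundances to sum to 1 per sample first
#'   (default TRUE, total-sum scaling).
#' @return data.frame with columns (`sample_id`,) `term`, `abundance`,
#'   `fraction` (share of the sample's total identified abundance).
#' @export
aggregate_functional_abundance <- function(abundance, annotation,
                                           normalize = TRUE) {
  ab <- abundance
  if (!"sample_id" %in% names(ab)) ab$sample_id <- "all"
  out <- list()
  for (s in unique(ab$sample_id)) {
    a <- ab[ab$sample_id == s, , drop = FALSE]
    total <- sum(a$abundance)
    if (normalize && total > 0) a$abundance <- a$abundance / total
    ## proteins with multiple terms: expand via merge
    m <- merge(a[, c("protein_id", "abundance")], annotation,
               by = "protein_id", all.x = TRUE)
    m$term[is.na(m$term)] <- "unannotated"
    agg <- stats::aggregate(abundance ~ term, data = m, FUN = sum)
    agg$fraction <- agg$abundance / sum(a$abundance)
    agg <- agg[order(agg$term), , drop = FALSE]
    agg <- cbind(sample_id = s, agg)
    out[[length(out) + 1L]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
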