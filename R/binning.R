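## Untargeted and labeled-anchor targeted binning of scaffolds, MAG quality
## estimation, acceptance rules, and taxonomy concordance voting.

## Canonical tetranucleotide index: 256 4-mers collapsed with their reverse
## complements into 136 equivalence classes.
.canonical_tetra_map <- local({
  bases <- c("A", "C", "G", "T")
  kmers <- apply(expand.grid(bases, bases, bases, bases)[, 4:1], 1, paste,
                 collapse = "")
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  canon <- vapply(kmers, function(k) min(k, rc(k)), character(1))
  factor(canon, levels = sort(unique(canon)))
})

#' Canonical tetranucleotide frequency vector of a sequence
#'
#' @param seq DNA sequence string.
#' @return Named numeric vector of 136 canonical 4-mer frequencies summing
#'   to 1 (zero vector for sequences shorter than 4).
#' @export
tetranucleotide_freq <- function(seq) {
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), 4)
  agg <- tapply(counts, .canonical_tetra_map, sum)
  agg <- agg[levels(.canonical_tetra_map)]
  agg[is.na(agg)] <- 0
  total <- sum(agg)
  if (total > 0) agg <- agg / total
  agg
}

#' Build the binning feature matrix
#'
#' Rows are scaffolds at least `min_length` bp; features are
#' `log(coverage + pseudocount)` per sample concatenated with the canonical
#' tetranucleotide composition vector, each column standardized
#' (zero-variance columns map to 0).
#'
#' @param scaffolds data.frame with columns `scaffold_id`, `length`,
#'   `sequence`.
#' @param coverage Numeric matrix (scaffold x sample) of mean depths, with
#'   rownames matching `scaffold_id`.
#' @param min_length Minimum scaffold length in bp (default 5000).
#' @param pseudocount Added to coverage before the log (default 0.01).
#' @return Numeric matrix with scaffold_id rownames and attribute
#'   `n_cov_features`.
#' @export
scaffold_features <- function(scaffolds, coverage, min_length = 5000,
                              pseudocount = 0.01) {
  keep <- scaffolds$length >= min_length
  sc <- scaffolds[keep, , drop = FALSE]
  if (!nrow(sc)) stop("no scaffolds pass the length threshold")
  missing <- setdiff(sc$scaffold_id, rownames(coverage))
  if (length(missing))
    stop("scaffold without coverage vector: ", missing[1])
  cov <- log(coverage[sc$scaffold_id, , drop = FALSE] + pseudocount)
  comp <- t(vapply(sc$sequence, tetranucleotide_freq,
                   numeric(nlevels(.canonical_tetra_map))))
  rownames(comp) <- sc$scaffold_id
  std <- function(m) {
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- Inf  # constant columns -> 0
    sweep(sweep(m, 2, mu), 2, sdv, "/")
  }
  feats <- cbind(std(cov), std(comp))
  rownames(feats) <- sc$scaffold_id
  attr(feats, "n_cov_features") <- ncol(cov)
  feats
}

#' Cluster scaffolds with a Gaussian mixture
#'
#' Features are projected onto principal components covering 90% of the
#' variance (capped at `n - 1` and 20 dimensions) and clustered with a
#' Gaussian mixture model at a fixed seed; degenerate inputs (all rows
#' identical) collapse to a single cluster.
#'
#' @param features [scaffold_features] matrix.
#' @param k Number of clusters (default 10).
#' @param seed Random seed (the procedure is deterministic given the seed).
#' @return Integer cluster labels named by scaffold_id.
#' @export
cluster_scaffolds <- function(features, k = 10L, seed = 1L) {
  n <- nrow(features)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("fewer scaffolds (", n, ") than clusters (", k, ")")
  if (all(apply(features, 2, function(col) length(unique(col)) == 1L))) {
    return(stats::setNames(rep(1L, n), rownames(features)))
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  vexp <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  d <- min(max(which(vexp >= 0.9)[1], 2L), n - 1L, 20L)
  x <- pc$x[, seq_len(d), drop = FALSE]
  labels <- withr::with_seed(seed, {
    fit <- tryCatch(
      mclust::Mclust(x, G = k, modelNames = c("EII", "VII", "EEI"),
                     verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$classification)) {
      as.integer(fit$classification)
    } else {
      as.integer(stats::kmeans(x, centers = k, nstart = 10)$cluster)
    }
  })
  stats::setNames(labels, rownames(features))
}

## Deterministic radius around an anchor centroid: the q-quantile of member
## distances, tightened to the first large multiplicative gap (ratio >
## gap_factor) in the sorted distances. Stands in for manual bin curation.
.anchor_radius <- function(d, quantile = 0.90, gap_factor = 3) {
  if (!length(d)) return(0)
  r <- stats::quantile(d, quantile, names = FALSE, type = 7)
  ds <- sort(d[d > 0])
  if (length(ds) >= 2L) {
    eps <- max(min(ds) * 1e-6, 1e-12)
    ratios <- ds[-1] / pmax(ds[-length(ds)], eps)
    gap <- which(ratios > gap_factor)
    if (length(gap)) r <- min(r, ds[gap[1]])
  }
  r
}

#' Refine a cluster into candidate MAG scaffold sets
#'
#' Targeted mode: anchors (scaffolds carrying genes for labeled unique
#' proteins) are merged into anchor groups by single-linkage at the median
#' pairwise member distance; each group claims the anchors plus the cluster
#' members within a deterministic radius of the anchor centroid (the
#' `radius_quantile` of member distances, tightened at the first
#' multiplicative distance gap). Members covered by several groups go to
#' the nearest centroid, so candidate sets are disjoint. Untargeted mode
#' returns the cluster unchanged.
#'
#' @param features [scaffold_features] matrix (full, or cluster subset).
#' @param members Scaffold ids of the cluster.
#' @param anchors Anchor scaffold ids (must lie in `members`); empty for
#'   untargeted mode.
#' @param radius_quantile Feature-distance quantile (default 0.90).
#' @param gap_factor Multiplicative gap that truncates the radius
#'   (default 3).
#' @return List of character vectors of scaffold ids (one per candidate
#'   MAG); a single-element list holding `members` in untargeted mode.
#' @export
refine_bin <- function(features, members, anchors = character(),
                       radius_quantile = 0.90, gap_factor = 3) {
  if (!length(anchors)) return(list(members))
  if (!all(anchors %in% members))
    stop("anchor not in the cluster: ",
         paste(setdiff(anchors, members), collapse = ", "))
  f <- features[members, , drop = FALSE]
  ## single-linkage anchor grouping at the median pairwise member distance
  if (length(anchors) > 1L) {
    dm <- as.matrix(stats::dist(f))
    link <- stats::median(dm[upper.tri(dm)])
    ad <- stats::as.dist(dm[anchors, anchors, drop = FALSE])
    grp <- stats::cutree(stats::hclust(ad, method = "single"), h = link)
  } else {
    grp <- stats::setNames(1L, anchors)
  }
  groups <- split(anchors, grp)
  centroids <- t(vapply(groups, function(a)
    colMeans(f[a, , drop = FALSE]), numeric(ncol(f))))
  non_anchor <- setdiff(members, anchors)
  ## distance of each member to each anchor-group centroid
  assign_tab <- lapply(seq_along(groups), function(gi) {
    d <- sqrt(colSums((t(f[non_anchor, , drop = FALSE]) - centroids[gi, ])^2))
    r <- .anchor_radius(d, radius_quantile, gap_factor)
    list(d = d, r = r)
  })
  sets <- lapply(groups, function(a) a)
  if (length(non_anchor)) {
    for (m in seq_along(non_anchor)) {
      cov_by <- which(vapply(assign_tab, function(t) {
        t$d[m] <= t$r
      }, logical(1)))
      if (!length(cov_by)) next
      dists <- vapply(cov_by, function(gi) assign_tab[[gi]]$d[m], numeric(1))
      gi <- cov_by[which.min(dists)]
      sets[[gi]] <- c(sets[[gi]], non_anchor[m])
    }
  }
  unname(lapply(sets, sort))
}

#' Estimate MAG completeness and contamination from single-copy markers
#'
#' Completeness is the percentage of the marker set present at least once;
#' contamination is the percentage of surplus marker copies
#' (`sum(max(0, count - 1)) / |marker set|`).
#'
#' @param marker_hits Character vector of marker ids observed on the MAG's
#'   scaffolds (with repetitions), or a data.frame with a `marker_id`
#'   column.
#' @param marker_set Character vector of expected single-copy marker ids.
#' @return List with `completeness` and `contamination` (percent).
#' @export
estimate_quality <- function(marker_hits, marker_set) {
  if (!length(marker_set)) stop("empty marker set")
  hits <- if (is.data.frame(marker_hits)) marker_hits$marker_id else marker_hits
  hits <- hits[hits %in% marker_set]
  counts <- table(hits)
  completeness <- 100 * length(counts) / length(marker_set)
  contamination <- 100 * sum(pmax(0, counts - 1)) / length(marker_set)
  list(completeness = completeness, contamination = contamination)
}

#' Construct a MAG record
#'
#' @param mag_id Identifier.
#' @param scaffolds Character vector of member scaffold ids.
#' @param completeness,contamination Quality estimates in percent.
#' @param mode `"untargeted"`, `"targeted_co2"`, or `"targeted_methanol"`.
#' @param labeled_idents data.frame of labeled-protein identifications
#'   supporting the MAG: columns `protein_id`, `atom_percent`, and
#'   (`co2`) `sample_id` / (`methanol`) `timepoint`, `replicate_id`.
#' @param taxonomy Optional result of [assign_taxonomy].
#' @return Object of class `mag_record`.
#' @export
mag_record <- function(mag_id, scaffolds = character(),
                       completeness = NA_real_, contamination = NA_real_,
                       mode = c("untargeted", "targeted_co2",
                                "targeted_methanol"),
                       labeled_idents = NULL, taxonomy = NULL) {
  mode <- match.arg(mode)
  if (!is.na(completeness) && (completeness < 0 || completeness > 100))
    stop("completeness must be in [0, 100]")
  if (!is.na(contamination) && contamination < 0)
    stop("contamination must be >= 0")
  structure(list(mag_id = mag_id, scaffolds = scaffolds,
                 completeness = completeness, contamination = contamination,
                 mode = mode, labeled_idents = labeled_idents,
                 taxonomy = taxonomy),
            class = "mag_record")
}

#' Apply the MAG acceptance rules
#'
#' Untargeted: completeness > 70% and contamination < 10%. Targeted
#' (both designs): contamination <= 5% on the reported (rounded) scale,
#' plus labeled support — co2 mode needs at least two labeled-protein
#' identifications; methanol mode needs one labeled protein identified in
#' at least two replicates of one incubation triplicate. The quality class
#' is `"medium"` at completeness >= 50% and contamination < 10%, else
#' `"low"`.
#'
#' @param mag [mag_record].
#' @param mode Optional override of `mag$mode`.
#' @return List with `accepted`, `failed_rules` (character), and
#'   `quality_class`.
#' @export
accept_mag <- function(mag, mode = NULL) {
  mode <- if (is.null(mode)) mag$mode else mode
  failed <- character()
  if (mode == "untargeted") {
    if (is.na(mag$completeness) || mag$completeness <= 70)
      failed <- c(failed, "completeness <= 70%")
    if (is.na(mag$contamination) || mag$contamination >= 10)
      failed <- c(failed, "contamination >= 10%")
  } else if (mode %in% c("targeted_co2", "targeted_methanol")) {
    if (is.na(mag$contamination) || mag$contamination > 5)
      failed <- c(failed, "contamination > 5%")
    ids <- mag$labeled_idents
    labeled <- if (is.null(ids)) ids else
      ids[!is.na(ids$atom_percent) & ids$atom_percent > 10, , drop = FALSE]
    if (mode == "targeted_co2") {
      n_ident <- if (is.null(labeled)) 0L else nrow(labeled)
      if (n_ident < 2L)
        failed <- c(failed, "fewer than 2 labeled-protein identifications")
    } else {
      ok <- FALSE
      if (!is.null(labeled) && nrow(labeled)) {
        key <- paste(labeled$protein_id, labeled$timepoint)
        reps <- tapply(labeled$replicate_id, key,
                       function(x) length(unique(x)))
        ok <- any(reps >= 2L)
      }
      if (!ok)
        failed <- c(failed,
                    "no labeled protein in >= 2 replicates of a triplicate")
    }
  } else stop("unknown mode: ", mode)
  quality_class <- if (!is.na(mag$completeness) && !is.na(mag$contamination) &&
                       mag$completeness >= 50 && mag$contamination < 10)
    "medium" else "low"
  list(accepted = length(failed) == 0L, failed_rules = failed,
       quality_class = quality_class)
}

## longest common prefix of rank-ordered lineage paths
.lineage_lca <- function(lineages) {
  paths <- lapply(lineages, function(s) strsplit(s, ";", fixed = TRUE)[[1]])
  depth <- min(lengths(paths))
  lca <- character()
  for (i in seq_len(depth)) {
    ranks <- vapply(paths, `[`, character(1), i)
    if (length(unique(ranks)) == 1L) lca <- c(lca, ranks[1]) else break
  }
  lca
}

#' Assign MAG taxonomy by marker-vote and cross-tool concordance
#'
#' Marker vote: the most common marker taxonomy label with concordance
#' fraction `f` is `"assigned"` at `f >= 0.75`, `"putative"` at
#' `0.5 < f < 0.75`, else `"unclassified"`. Cross-tool rule: when at least
#' two of the three tool lineages agree at the phylum level (the first
#' rank), the lowest common ancestor of the agreeing lineages is emitted.
#'
#' @param marker_taxonomies Character vector of per-marker taxonomy labels.
#' @param tool_assignments Character vector (up to 3) of rank-ordered
#'   lineage paths, `;`-separated (phylum first).
#' @return List with `taxon`, `confidence` (`"assigned"`, `"putative"`,
#'   `"unclassified"`), `marker_fraction`, `consensus_lineage` (character
#'   vector, possibly empty).
#' @export
assign_taxonomy <- function(marker_taxonomies = character(),
                            tool_assignments = character()) {
  taxon <- NA_character_; confidence <- "unclassified"; frac <- NA_real_
  if (length(marker_taxonomies)) {
    tab <- sort(table(marker_taxonomies), decreasing = TRUE)
    frac <- tab[1] / length(marker_taxonomies)
    if (frac >= 0.75) {
      taxon <- names(tab)[1]; confidence <- "assigned"
    } else if (frac > 0.5) {
      taxon <- names(tab)[1]; confidence <- "putative"
    }
  }
  consensus <- character()
  if (length(tool_assignments) >= 2L) {
    phyla <- vapply(tool_assignments, function(s)
      strsplit(s, ";", fixed = TRUE)[[1]][1], character(1))
    tab <- sort(table(phyla), decreasing = TRUE)
    if (tab[1] >= 2L) {
      agreeing <- tool_assignments[phyla == names(tab)[1]]
      consensus <- .lineage_lca(agreeing)
      if (length(consensus) && is.na(taxon)) {
        taxon <- consensus[length(consensus)]
      }
    }
  }
  list(taxon = taxon, confidence = confidence,
       marker_fraction = unname(frac), consensus_lineage = consensus)
}
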