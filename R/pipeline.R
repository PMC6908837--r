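## Pipeline orchestration: staged execution (simulate -> digest -> search ->
## infer -> bin -> report) over file artifacts in a working directory, a
## flat key=value config format, and the labeling summary.

#' Default pipeline configuration
#'
#' @param workdir Directory for all stage artifacts.
#' @param mode Experiment design: `"co2"` (plant-species/timepoint
#'   rhizosphere samples) or `"methanol"` (incubation triplicates).
#' @param seed Seed applied to every stochastic stage.
#' @param n_genomes,genome_length,n_samples Community parameters.
#' @param genes_per_genome Genes per genome in the synthetic proteome.
#' @param labeled_atom_percents True atom% of the labeled proteins (one
#'   protein per value, placed on distinct genomes).
#' @param n_unlabeled_sampled Unlabeled proteins that also yield spectra.
#' @param noise_sd,dropout,decoy_rate Spectrum noise model.
#' @param fdr_level Peptide-level FDR for filtering.
#' @param bin_k,bin_min_length,radius_quantile Binning parameters.
#' @return Config list.
#' @export
pipeline_config <- function(workdir = tempfile("prosip_"),
                            mode = c("co2", "methanol"),
                            seed = 1L,
                            n_genomes = 8L, genome_length = 40000L,
                            n_samples = 14L, genes_per_genome = 6L,
                            labeled_atom_percents = c(20, 50, 95),
                            n_unlabeled_sampled = 5L,
                            noise_sd = 0.05, dropout = 0, decoy_rate = 0,
                            fdr_level = 0.01,
                            bin_k = 10L, bin_min_length = 5000L,
                            radius_quantile = 0.90) {
  mode <- match.arg(mode)
  as.list(environment())
}

#' Read a flat key=value pipeline config file
#'
#' Lines of the form `key = value`; `#` starts a comment; comma-separated
#' values become numeric vectors where possible.
#'
#' @param path Config file path.
#' @return Config list merged over [pipeline_config] defaults.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  cfg <- pipeline_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!any(is.na(num))) num else val
  }
  cfg$mode <- match.arg(cfg$mode, c("co2", "methanol"))
  cfg
}

.artifact_paths <- function(config) {
  w <- config$workdir
  list(scaffolds = file.path(w, "scaffolds.fna"),
       coverage = file.path(w, "coverage.tsv"),
       proteins = file.path(w, "proteins.faa"),
       genes = file.path(w, "genes.gff3"),
       markers = file.path(w, "markers.tsv"),
       labels = file.path(w, "truth_labels.tsv"),
       genome_map = file.path(w, "truth_scaffold_genomes.tsv"),
       mgf = file.path(w, "spectra.mgf"),
       manifest = file.path(w, "spectra_manifest.tsv"),
       target_decoy = file.path(w, "target_decoy.faa"),
       index = file.path(w, "peptide_index.rds"),
       psms = file.path(w, "psms.tsv"),
       peptides = file.path(w, "peptides.tsv"),
       search_summary = file.path(w, "search_summary.tsv"),
       groups = file.path(w, "protein_groups.tsv"),
       labeled = file.path(w, "labeled_report.tsv"),
       mags = file.path(w, "mag_report.tsv"),
       mag_dir = file.path(w, "mags"),
       summary = file.path(w, "summary.tsv"))
}

.require_artifact <- function(path, producer) {
  missing <- path[!file.exists(path)]
  if (length(missing))
    stop("missing upstream artifact ", basename(missing[1]),
         ": run the '", producer, "' stage first", call. = FALSE)
}

## sample design labels for the two experiment modes
.design_samples <- function(mode) {
  if (mode == "co2") {
    g <- expand.grid(rep = c("R1", "R2"), tp = c("T1", "T2"),
                     sp = c("Zmays", "Taestivum", "Athaliana"),
                     stringsAsFactors = FALSE)
    data.frame(sample_id = paste(g$sp, g$tp, g$rep, sep = "_"),
               species = g$sp, timepoint = g$tp, replicate_id = g$rep,
               stringsAsFactors = FALSE)
  } else {
    g <- expand.grid(rep = c("R1", "R2", "R3"), tp = c("D3", "D8"),
                     stringsAsFactors = FALSE)
    data.frame(sample_id = paste(g$tp, g$rep, sep = "_"),
               species = NA_character_, timepoint = g$tp,
               replicate_id = g$rep, stringsAsFactors = FALSE)
  }
}

.parse_sample_meta <- function(sample_id, mode) {
  parts <- strsplit(sample_id, "_", fixed = TRUE)
  if (mode == "co2") {
    data.frame(species = vapply(parts, `[`, character(1), 1L),
               timepoint = vapply(parts, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(species = NA_character_,
               timepoint = vapply(parts, `[`, character(1), 1L),
               stringsAsFactors = FALSE)
  }
}

.stage_simulate <- function(config, paths) {
  community <- generate_community(
    n_genomes = config$n_genomes, genome_length = config$genome_length,
    n_samples = config$n_samples, seed = config$seed)
  proteome <- generate_proteome_and_labels(
    community, genes_per_genome = config$genes_per_genome,
    labeled_fraction = 0, seed = config$seed)
  ## deterministic labeled set: one protein per value, on distinct genomes
  lab_atoms <- config$labeled_atom_percents
  lab_genomes <- community$genomes$genome_id[seq_along(lab_atoms)]
  lab_ids <- vapply(lab_genomes, function(g)
    proteome$genes$protein_id[proteome$genes$genome_id == g][1], character(1))
  proteome$labels <- data.frame(protein_id = lab_ids,
                                genome_id = lab_genomes,
                                atom_percent = lab_atoms,
                                stringsAsFactors = FALSE)
  write_community(community, proteome, config$workdir)
  ## peptide table for spectra: labeled proteins contribute two distinct
  ## peptides in two samples (two replicates of one timepoint), unlabeled
  ## proteins one peptide at natural abundance
  design <- .design_samples(config$mode)
  first_peps <- function(pid, n) {
    peps <- digest(proteome$proteins[[pid]], max_missed = 0L)
    vapply(peps[seq_len(min(n, length(peps)))], `[[`, character(1),
           "sequence")
  }
  rows <- list()
  if (config$mode == "co2") {
    species <- unique(design$species)
    for (i in seq_along(lab_ids)) {
      sp <- species[(i - 1L) %% length(species) + 1L]
      for (pep in first_peps(lab_ids[i], 2L)) {
        for (s in design$sample_id[design$species == sp &
                                   (design$timepoint == "T2" |
                                    design$replicate_id == "R1")]) {
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = pep, protein_id = lab_ids[i],
            atom_percent = lab_atoms[i], sample_id = s,
            replicate_id = design$replicate_id[design$sample_id == s],
            stringsAsFactors = FALSE)
        }
      }
    }
  } else {
    for (i in seq_along(lab_ids)) {
      for (pep in first_peps(lab_ids[i], 2L)) {
        for (s in design$sample_id[design$timepoint == "D3" &
                                   design$replicate_id %in% c("R1", "R2")]) {
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = pep, protein_id = lab_ids[i],
            atom_percent = lab_atoms[i], sample_id = s,
            replicate_id = design$replicate_id[design$sample_id == s],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  unlabeled <- setdiff(names(proteome$proteins), lab_ids)
  unlabeled <- unlabeled[seq_len(min(config$n_unlabeled_sampled,
                                     length(unlabeled)))]
  for (i in seq_along(unlabeled)) {
    s <- design$sample_id[(i - 1L) %% nrow(design) + 1L]
    pep <- first_peps(unlabeled[i], 1L)
    if (!length(pep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = pep, protein_id = unlabeled[i],
      atom_percent = 100 * NATURAL_C13, sample_id = s,
      replicate_id = design$replicate_id[design$sample_id == s],
      stringsAsFactors = FALSE)
  }
  pep_tab <- do.call(rbind, rows)
  gen <- generate_spectra(pep_tab, noise_sd = config$noise_sd,
                          dropout = config$dropout,
                          decoy_rate = config$decoy_rate,
                          seed = config$seed)
  write_mgf(gen$spectra, paths$mgf)
  .write_tsv_atomic(gen$manifest, paths$manifest)
  message("simulate: ", nrow(community$scaffolds), " scaffolds, ",
          length(proteome$proteins), " proteins (", length(lab_ids),
          " labeled), ", length(gen$spectra), " spectra")
  invisible(paths)
}

.stage_digest <- function(config, paths) {
  .require_artifact(paths$proteins, "simulate")
  proteins <- read_protein_fasta(paths$proteins)
  db <- make_decoy_db(proteins)
  write_protein_fasta(db, paths$target_decoy)
  index <- build_peptide_index(db, search_config("sip"))
  saveRDS(index, paths$index)
  message("digest: ", length(db), " database entries, ",
          length(index$entries), " indexed peptides")
  invisible(paths)
}

.stage_search <- function(config, paths) {
  .require_artifact(c(paths$index, paths$mgf, paths$manifest), "digest")
  index <- readRDS(paths$index)
  manifest <- read_spectrum_manifest(paths$manifest)
  spectra <- read_mgf(paths$mgf, manifest)
  sc <- search_config("sip")
  psms <- search_sample(spectra, index, sc)
  .write_tsv_atomic(psms, paths$psms)
  ids <- fdr_filter(psms, level = config$fdr_level)
  thr <- attr(ids, "threshold")
  .write_tsv_atomic(ids, paths$peptides)
  .write_tsv_atomic(data.frame(
    key = c("n_spectra", "n_psms", "n_decoy_psms", "n_peptides_post_fdr",
            "score_threshold"),
    value = c(length(spectra), nrow(psms), sum(psms$is_decoy),
              length(unique(ids$peptide)),
              if (is.null(thr)) NA else round(thr, 6))),
    paths$search_summary)
  message("search: ", length(spectra), " spectra read, ", nrow(psms),
          " PSMs, ", length(unique(ids$peptide)), " peptides post-FDR")
  invisible(paths)
}

.stage_infer <- function(config, paths) {
  .require_artifact(c(paths$peptides, paths$psms, paths$index,
                      paths$search_summary), "search")
  index <- readRDS(paths$index)
  ids <- utils::read.delim(paths$peptides, stringsAsFactors = FALSE)
  summ <- utils::read.delim(paths$search_summary, stringsAsFactors = FALSE)
  thr <- as.numeric(summ$value[summ$key == "score_threshold"])
  ## database-level peptide -> protein maps (targets and decoys separately)
  tmap <- list(); dmap <- list()
  for (e in index$entries) {
    if (length(e$mods)) next
    if (e$is_decoy) dmap[[e$sequence]] <- e$protein_ids
    else tmap[[e$sequence]] <- setdiff(e$protein_ids,
                                       grep(paste0("^", DECOY_PREFIX),
                                            e$protein_ids, value = TRUE))
  }
  if (nrow(ids)) {
    ids <- cbind(ids, .parse_sample_meta(ids$sample_id, config$mode))
    ## one identification per (sample, peptide, charge)
    ids <- ids[!duplicated(ids[, c("sample_id", "peptide",
                                   "precursor_charge")]), , drop = FALSE]
  }
  groups <- infer_proteins(ids, tmap)
  ## decoy groups from decoy PSMs above the same score threshold
  psms <- utils::read.delim(paths$psms, stringsAsFactors = FALSE)
  dec <- psms[psms$is_decoy & !is.na(thr) & psms$score >= thr, , drop = FALSE]
  decoy_groups <- if (nrow(dec)) infer_proteins(dec, dmap) else list()
  pfdr <- if (length(groups)) protein_fdr(groups, decoy_groups) else NA
  grows <- lapply(groups, function(g) data.frame(
    group_id = g$group_id,
    member_proteins = paste(g$member_proteins, collapse = ";"),
    n_unique_peptides = length(g$unique_peptides),
    n_shared_peptides = length(g$shared_peptides),
    stringsAsFactors = FALSE))
  gdf <- if (length(grows)) do.call(rbind, grows) else
    data.frame(group_id = character(), member_proteins = character(),
               n_unique_peptides = integer(), n_shared_peptides = integer())
  .write_tsv_atomic(gdf, paths$groups)
  lab_mode <- if (config$mode == "co2") "co2" else "methanol"
  lrows <- list()
  for (g in groups) {
    call <- filter_labeled_proteins(g, mode = lab_mode)
    if (!nrow(call$support)) next
    s <- call$support
    lrows[[length(lrows) + 1L]] <- data.frame(
      protein_id = g$group_id,
      sample_id = s$sample_id,
      timepoint = s$timepoint,
      replicate_id = s$replicate_id,
      atom_percent = round(s$atom_percent),
      n_clusters = length(call$clusters),
      passing = call$passing,
      mag_id = "",
      stringsAsFactors = FALSE)
  }
  ldf <- if (length(lrows)) do.call(rbind, lrows) else
    data.frame(protein_id = character(), sample_id = character(),
               timepoint = character(), replicate_id = character(),
               atom_percent = numeric(), n_clusters = integer(),
               passing = logical(), mag_id = character())
  .write_tsv_atomic(ldf, paths$labeled)
  message("infer: ", length(groups), " protein groups (protein FDR ",
          formatC(pfdr, format = "f", digits = 4), "), ",
          sum(ldf$passing[!duplicated(ldf$protein_id)]),
          " labeled proteins")
  invisible(paths)
}

.stage_bin <- function(config, paths) {
  .require_artifact(c(paths$scaffolds, paths$coverage, paths$genes,
                      paths$markers), "simulate")
  .require_artifact(paths$labeled, "infer")
  dna <- Biostrings::readDNAStringSet(paths$scaffolds)
  scaffolds <- data.frame(scaffold_id = names(dna),
                          length = Biostrings::width(dna),
                          sequence = as.character(dna),
                          stringsAsFactors = FALSE)
  cov_df <- utils::read.delim(paths$coverage, check.names = FALSE,
                              stringsAsFactors = FALSE)
  coverage <- as.matrix(cov_df[, -1, drop = FALSE])
  rownames(coverage) <- cov_df$scaffold_id
  gff <- rtracklayer::import(paths$genes, format = "gff3")
  gene_scaffold <- stats::setNames(
    as.character(GenomicRanges::seqnames(gff)),
    S4Vectors::mcols(gff)$protein_id)
  markers <- utils::read.delim(paths$markers, stringsAsFactors = FALSE)
  marker_set <- sort(unique(markers$marker_id))
  labeled <- utils::read.delim(paths$labeled, stringsAsFactors = FALSE)
  features <- scaffold_features(scaffolds, coverage,
                                min_length = config$bin_min_length)
  k <- max(2L, min(config$bin_k, nrow(features) - 1L))
  clusters <- cluster_scaffolds(features, k = k, seed = config$seed)
  passing <- unique(labeled$protein_id[labeled$passing])
  anchor_scaffolds <- unique(stats::na.omit(gene_scaffold[passing]))
  dropped <- setdiff(anchor_scaffolds, rownames(features))
  if (length(dropped))
    message("bin: ", length(dropped),
            " anchor scaffold(s) below the length threshold, dropped")
  anchor_scaffolds <- intersect(anchor_scaffolds, rownames(features))
  mode <- if (config$mode == "co2") "targeted_co2" else "targeted_methanol"
  mags <- list()
  mag_i <- 0L
  for (cl in sort(unique(clusters))) {
    members <- names(clusters)[clusters == cl]
    anchors <- intersect(anchor_scaffolds, members)
    if (!length(anchors)) next
    sets <- refine_bin(features, members, anchors,
                       radius_quantile = config$radius_quantile)
    for (set in sets) {
      mag_i <- mag_i + 1L
      q <- estimate_quality(markers[markers$scaffold_id %in% set, ],
                            marker_set)
      set_prots <- names(gene_scaffold)[gene_scaffold %in% set]
      lid <- labeled[labeled$passing & labeled$protein_id %in% set_prots, ,
                     drop = FALSE]
      tax <- assign_taxonomy(
        markers$taxonomy[markers$scaffold_id %in% set])
      mags[[mag_i]] <- mag_record(
        sprintf("MAG%02d", mag_i), scaffolds = set,
        completeness = q$completeness, contamination = q$contamination,
        mode = mode, labeled_idents = lid, taxonomy = tax)
    }
  }
  mrows <- lapply(mags, function(m) {
    v <- accept_mag(m)
    data.frame(mag_id = m$mag_id,
               n_scaffolds = length(m$scaffolds),
               size_bp = sum(scaffolds$length[
                 scaffolds$scaffold_id %in% m$scaffolds]),
               completeness = round(m$completeness, 1),
               contamination = round(m$contamination, 1),
               n_labeled_idents = if (is.null(m$labeled_idents)) 0L else
                 nrow(m$labeled_idents),
               accepted = v$accepted,
               quality_class = v$quality_class,
               taxonomy = if (is.na(m$taxonomy$taxon)) "Unclassified" else
                 m$taxonomy$taxon,
               confidence = m$taxonomy$confidence,
               scaffolds = paste(m$scaffolds, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  mdf <- if (length(mrows)) do.call(rbind, mrows) else
    data.frame(mag_id = character(), n_scaffolds = integer(),
               size_bp = integer(), completeness = numeric(),
               contamination = numeric(), n_labeled_idents = integer(),
               accepted = logical(), quality_class = character(),
               taxonomy = character(), confidence = character(),
               scaffolds = character())
  .write_tsv_atomic(mdf, paths$mags)
  dir.create(paths$mag_dir, showWarnings = FALSE)
  for (m in mags) {
    Biostrings::writeXStringSet(dna[m$scaffolds],
                                file.path(paths$mag_dir,
                                          paste0(m$mag_id, ".fna")))
  }
  message("bin: ", length(mags), " candidate MAGs, ",
          sum(mdf$accepted), " accepted")
  invisible(paths)
}

.stage_report <- function(config, paths) {
  .require_artifact(paths$labeled, "infer")
  .require_artifact(paths$mags, "bin")
  labeled <- utils::read.delim(paths$labeled, stringsAsFactors = FALSE)
  mags <- utils::read.delim(paths$mags, stringsAsFactors = FALSE)
  summ <- summarize_labeling(labeled, mags, mode = config$mode)
  .write_tsv_atomic(data.frame(key = names(summ),
                               value = unlist(lapply(summ, function(v)
                                 if (is.numeric(v))
                                   formatC(v, format = "f", digits = 4)
                                 else as.character(v)))),
                    paths$summary)
  message("report: summary written (", length(summ), " fields)")
  invisible(paths)
}

#' Run one pipeline stage
#'
#' Stages write their outputs atomically under `config$workdir` and log the
#' counts needed to audit the FDR and acceptance decisions; a missing
#' upstream artifact raises an error naming the stage that produces it.
#'
#' @param stage One of `"simulate"`, `"digest"`, `"search"`, `"infer"`,
#'   `"bin"`, `"report"`, or `"all"`.
#' @param config [pipeline_config] list.
#' @return Invisibly, the artifact path list.
#' @export
run_stage <- function(stage = c("simulate", "digest", "search", "infer",
                                "bin", "report", "all"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  paths <- .artifact_paths(config)
  stages <- if (stage == "all")
    c("simulate", "digest", "search", "infer", "bin", "report") else stage
  for (s in stages) {
    switch(s,
           simulate = .stage_simulate(config, paths),
           digest = .stage_digest(config, paths),
           search = .stage_search(config, paths),
           infer = .stage_infer(config, paths),
           bin = .stage_bin(config, paths),
           report = .stage_report(config, paths))
  }
  invisible(paths)
}

#' Summarize a labeled-protein report
#'
#' Per-mode counts, atom% range, the timepoint enrichment comparison
#' (Mann-Whitney U, one-sided: later timepoint larger), and MAG acceptance
#' tallies. The summary is invariant to row order.
#'
#' @param labeled_report data.frame with columns `protein_id`,
#'   `timepoint`, `atom_percent`, `passing` (the labeled-report layout).
#' @param mag_report Optional data.frame with columns `accepted`,
#'   `quality_class`.
#' @param mode `"co2"` or `"methanol"`.
#' @return Named list of summary fields (empty report gives zero counts).
#' @export
summarize_labeling <- function(labeled_report, mag_report = NULL,
                               mode = c("co2", "methanol")) {
  mode <- match.arg(mode)
  out <- list(mode = mode)
  lr <- labeled_report[order(labeled_report$protein_id,
                             labeled_report$timepoint), , drop = FALSE]
  pass <- lr[lr$passing, , drop = FALSE]
  out$n_labeled_proteins <- length(unique(pass$protein_id))
  out$n_labeled_identifications <- nrow(pass)
  if (nrow(pass)) {
    out$atom_percent_min <- min(pass$atom_percent)
    out$atom_percent_mean <- mean(pass$atom_percent)
    out$atom_percent_max <- max(pass$atom_percent)
    tps <- sort(unique(pass$timepoint))
    if (length(tps) == 2L) {
      t1 <- pass$atom_percent[pass$timepoint == tps[1]]
      t2 <- pass$atom_percent[pass$timepoint == tps[2]]
      cmp <- compare_timepoints(t1, t2, alternative = "less")
      out$timepoint_U <- cmp$U
      out$timepoint_p <- cmp$p_value
    }
  }
  if (!is.null(mag_report) && nrow(mag_report)) {
    out$n_mags <- nrow(mag_report)
    out$n_mags_accepted <- sum(mag_report$accepted)
    out$n_mags_medium <- sum(mag_report$accepted &
                               mag_report$quality_class == "medium")
    out$n_mags_low <- sum(mag_report$accepted &
                            mag_report$quality_class == "low")
  } else {
    out$n_mags <- 0L; out$n_mags_accepted <- 0L
  }
  out
}
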