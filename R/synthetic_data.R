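## Ground-truth generators: multi-genome communities with distinct k-mer
## composition and per-sample abundance series, tryptic proteomes with a
## labeled subset, and centroided spectra whose envelopes follow the
## enrichment model plus noise. All generators are seed-deterministic.

## Markov-chain DNA sequence with a genome-specific dinucleotide bias.
.biased_sequence <- function(n, transition) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  state <- sample.int(4L, 1L)
  for (i in seq_len(n)) {
    out[i] <- bases[state]
    state <- sample.int(4L, 1L, prob = transition[state, ])
  }
  paste(out, collapse = "")
}

#' Generate a synthetic multi-genome community
#'
#' Genomes are random sequences with genome-specific dinucleotide bias
#' (Dirichlet-sampled transition matrices), fragmented into scaffolds with
#' lognormal lengths (minimum 1 kbp). Per-sample scaffold coverage is the
#' genome's lognormal abundance times a depth factor plus Poisson noise.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param genome_length Genome length in bp (single value or vector).
#' @param n_samples Number of samples in the abundance series (the study
#'   design emulated has 14).
#' @param abundance_meanlog,abundance_sdlog Lognormal abundance parameters.
#' @param depth_factor Mean depth multiplier applied to abundances.
#' @param scaffold_meanlog,scaffold_sdlog Lognormal scaffold-length
#'   parameters.
#' @param seed Random seed.
#' @return List with `genomes` (data.frame: genome_id, length, taxonomy),
#'   `scaffolds` (data.frame: scaffold_id, genome_id, length, sequence),
#'   `coverage` (matrix scaffold x sample), `abundance` (matrix genome x
#'   sample).
#' @export
generate_community <- function(n_genomes = 8L, genome_length = 40000L,
                               n_samples = 14L,
                               abundance_meanlog = 2, abundance_sdlog = 1,
                               depth_factor = 2,
                               scaffold_meanlog = log(8000),
                               scaffold_sdlog = 0.4,
                               seed = 1L) {
  if (n_genomes < 2L) stop("n_genomes must be >= 2")
  if (genome_length < 5000L) stop("genome_length too short")
  glen <- rep_len(genome_length, n_genomes)
  withr::with_seed(seed, {
    genome_ids <- sprintf("genome_%02d", seq_len(n_genomes))
    ## distinct composition: per-genome Dirichlet transition matrix
    sequences <- vapply(seq_len(n_genomes), function(g) {
      a <- matrix(stats::rgamma(16, shape = 1), 4, 4)
      trans <- a / rowSums(a)
      .biased_sequence(glen[g], trans)
    }, character(1))
    abundance <- matrix(stats::rlnorm(n_genomes * n_samples,
                                      abundance_meanlog, abundance_sdlog),
                        n_genomes, n_samples,
                        dimnames = list(genome_ids,
                                        sprintf("S%02d", seq_len(n_samples))))
    scaff_rows <- list()
    for (g in seq_len(n_genomes)) {
      pos <- 1L
      i <- 1L
      while (pos <= glen[g]) {
        len <- max(1000L, round(stats::rlnorm(1, scaffold_meanlog,
                                              scaffold_sdlog)))
        end <- min(pos + len - 1L, glen[g])
        if (glen[g] - end < 1000L) end <- glen[g]
        scaff_rows[[length(scaff_rows) + 1L]] <- data.frame(
          scaffold_id = sprintf("%s_scaf_%02d", genome_ids[g], i),
          genome_id = genome_ids[g],
          length = end - pos + 1L,
          sequence = substr(sequences[g], pos, end),
          stringsAsFactors = FALSE)
        pos <- end + 1L
        i <- i + 1L
      }
    }
    scaffolds <- do.call(rbind, scaff_rows)
    coverage <- matrix(0, nrow(scaffolds), n_samples,
                       dimnames = list(scaffolds$scaffold_id,
                                       colnames(abundance)))
    for (r in seq_len(nrow(scaffolds))) {
      lambda <- abundance[scaffolds$genome_id[r], ] * depth_factor
      coverage[r, ] <- stats::rpois(n_samples, lambda)
    }
    list(genomes = data.frame(genome_id = genome_ids, length = glen,
                              sequence = sequences,
                              stringsAsFactors = FALSE),
         scaffolds = scaffolds,
         coverage = coverage,
         abundance = abundance)
  })
}

## Random tryptic protein: concatenated blocks of 5-14 residues each ending
## in K or R (no proline after the cut), so digestion yields peptides of
## searchable length.
.tryptic_protein <- function(n_blocks) {
  aas <- setdiff(rownames(.RESIDUE_FORMULAS), c("K", "R", "P"))
  blocks <- vapply(seq_len(n_blocks), function(i) {
    len <- sample(5:14, 1L)
    body <- paste(sample(aas, len, replace = TRUE), collapse = "")
    paste0(body, sample(c("K", "R"), 1L))
  }, character(1))
  paste(blocks, collapse = "")
}

#' Generate a synthetic proteome with a 13C-labeled subset
#'
#' Places non-overlapping genes on the community's scaffolds, emits protein
#' sequences with tryptic sites, and assigns a chosen fraction of proteins
#' a true 13C atom% drawn uniformly from `atom_range`. Also places one copy
#' of each single-copy marker per genome on a random scaffold.
#'
#' @param community [generate_community] result.
#' @param genes_per_genome Number of genes per genome.
#' @param labeled_fraction Fraction of proteins that are labeled.
#' @param atom_range True atom% range for labeled proteins (percent scale;
#'   the 13CO2 design observed 15-46, the methanol design up to 98).
#' @param n_markers Size of the universal single-copy marker set.
#' @param seed Random seed.
#' @return List with `proteins` (named character vector), `genes`
#'   (data.frame: gene_id, protein_id, scaffold_id, genome_id, start, end,
#'   strand), `labels` (data.frame: protein_id, genome_id, atom_percent for
#'   the labeled subset), `markers` (data.frame: scaffold_id, marker_id,
#'   taxonomy), `marker_set` (character).
#' @export
generate_proteome_and_labels <- function(community, genes_per_genome = 10L,
                                         labeled_fraction = 0.3,
                                         atom_range = c(15, 46),
                                         n_markers = 20L, seed = 1L) {
  withr::with_seed(seed + 1L, {
    scaffolds <- community$scaffolds
    genes <- list(); proteins <- character(); labels <- list()
    for (g in community$genomes$genome_id) {
      sc <- scaffolds[scaffolds$genome_id == g, , drop = FALSE]
      ## distribute genes over scaffolds proportionally to length
      alloc <- sample(sc$scaffold_id, genes_per_genome, replace = TRUE,
                      prob = sc$length)
      offsets <- stats::setNames(rep(1L, nrow(sc)), sc$scaffold_id)
      for (i in seq_len(genes_per_genome)) {
        pid <- sprintf("%s_prot_%02d", g, i)
        prot <- .tryptic_protein(sample(3:6, 1L))
        sid <- alloc[i]
        glen_nt <- 3L * nchar(prot)
        start <- offsets[sid]
        end <- start + glen_nt - 1L
        slen <- sc$length[sc$scaffold_id == sid]
        if (end > slen) { start <- 1L; end <- min(glen_nt, slen) }
        offsets[sid] <- end + 1L
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = paste0(pid, "_gene"), protein_id = pid,
          scaffold_id = sid, genome_id = g,
          start = start, end = end, strand = "+",
          stringsAsFactors = FALSE)
        proteins[pid] <- prot
      }
    }
    genes <- do.call(rbind, genes)
    n_labeled <- round(labeled_fraction * length(proteins))
    if (n_labeled > 0L) {
      lab_ids <- sample(names(proteins), n_labeled)
      labels <- data.frame(
        protein_id = lab_ids,
        genome_id = genes$genome_id[match(lab_ids, genes$protein_id)],
        atom_percent = stats::runif(n_labeled, atom_range[1], atom_range[2]),
        stringsAsFactors = FALSE)
    } else {
      labels <- data.frame(protein_id = character(), genome_id = character(),
                           atom_percent = numeric(), stringsAsFactors = FALSE)
    }
    marker_set <- sprintf("SCG_%03d", seq_len(n_markers))
    markers <- list()
    for (g in community$genomes$genome_id) {
      sc <- scaffolds[scaffolds$genome_id == g, , drop = FALSE]
      placed <- sample(sc$scaffold_id, n_markers, replace = TRUE,
                       prob = sc$length)
      markers[[length(markers) + 1L]] <- data.frame(
        scaffold_id = placed, marker_id = marker_set,
        taxonomy = paste0("Phylum_", g), stringsAsFactors = FALSE)
    }
    list(proteins = proteins, genes = genes, labels = labels,
         markers = do.call(rbind, markers), marker_set = marker_set)
  })
}

#' Generate centroided spectra from peptides under the enrichment model
#'
#' For each selected peptide a precursor isotopologue envelope (at the
#' sampled charge, 2 or 3) and singly-charged b/y fragment envelopes are
#' computed at the peptide's true atom% and written as one centroided peak
#' list. Intensities are perturbed multiplicatively (lognormal, sd
#' `noise_sd`), peaks are dropped with probability `dropout`, and a
#' `decoy_rate` fraction of spectra is generated from shuffled peptide
#' sequences (unmatchable by construction, recorded in the manifest).
#'
#' @param peptides data.frame with columns `peptide`, `protein_id`,
#'   `atom_percent` (true 13C atom%, natural abundance = 1.07),
#'   `sample_id`, `replicate_id` (recycled if scalar).
#' @param noise_sd Multiplicative lognormal noise sd (0 = noiseless);
#'   the signal-to-noise ratio of a peak is approximately `1 / noise_sd`.
#' @param dropout Per-peak dropout probability.
#' @param decoy_rate Fraction of additional unmatchable spectra.
#' @param base_intensity Intensity scale of the most abundant peak.
#' @param seed Random seed.
#' @return List with `spectra` (list of [spectrum]) and `manifest`
#'   (data.frame: spectrum_id, sample_id, replicate_id, peptide,
#'   protein_id, atom_percent, charge, unmatchable).
#' @export
generate_spectra <- function(peptides, noise_sd = 0.05, dropout = 0,
                             decoy_rate = 0, base_intensity = 1e5,
                             seed = 1L) {
  stopifnot(is.data.frame(peptides), nrow(peptides) > 0)
  if (!"sample_id" %in% names(peptides)) peptides$sample_id <- "S01"
  if (!"replicate_id" %in% names(peptides)) peptides$replicate_id <- "R1"
  withr::with_seed(seed + 2L, {
    n_decoy <- round(decoy_rate * nrow(peptides))
    rows <- peptides
    rows$unmatchable <- FALSE
    if (n_decoy > 0L) {
      src <- rows[sample.int(nrow(peptides), n_decoy, replace = TRUE), ,
                  drop = FALSE]
      src$peptide <- vapply(src$peptide, function(s) {
        body <- strsplit(substr(s, 1L, nchar(s) - 1L), "")[[1]]
        repeat {
          shuf <- paste0(paste(sample(body), collapse = ""),
                         substr(s, nchar(s), nchar(s)))
          if (shuf != s) break
        }
        shuf
      }, character(1))
      src$protein_id <- "shuffled"
      src$unmatchable <- TRUE
      rows <- rbind(rows, src)
    }
    spectra <- vector("list", nrow(rows))
    manifest <- list()
    for (i in seq_len(nrow(rows))) {
      seqc <- rows$peptide[i]
      p <- rows$atom_percent[i] / 100
      z <- sample(2:3, 1L)
      f <- elemental_composition(seqc)
      env <- formula_envelope(f, enrichment_spec("C", p))
      prec_mz <- env$centroid_mass / z + PROTON_MASS
      prec_int <- env$abundance
      frag_mz <- numeric(); frag_int <- numeric()
      for (ff in .fragment_formulas(seqc)) {
        fe <- formula_envelope(ff, enrichment_spec("C", p))
        frag_mz <- c(frag_mz, fe$centroid_mass + PROTON_MASS)
        frag_int <- c(frag_int, fe$abundance)
      }
      mz <- c(prec_mz, frag_mz)
      intensity <- c(prec_int, frag_int) * base_intensity
      if (noise_sd > 0)
        intensity <- intensity * stats::rlnorm(length(intensity), 0, noise_sd)
      if (dropout > 0) {
        keep <- stats::runif(length(mz)) > dropout
        mz <- mz[keep]; intensity <- intensity[keep]
      }
      sid <- sprintf("synspec_%05d", i)
      ma <- which.max(prec_int)
      spectra[[i]] <- spectrum(sid, prec_mz[ma], z, mz, intensity,
                               sample_id = rows$sample_id[i],
                               replicate_id = rows$replicate_id[i])
      manifest[[i]] <- data.frame(
        spectrum_id = sid, sample_id = rows$sample_id[i],
        replicate_id = rows$replicate_id[i], peptide = seqc,
        protein_id = rows$protein_id[i],
        atom_percent = rows$atom_percent[i], charge = z,
        unmatchable = rows$unmatchable[i], stringsAsFactors = FALSE)
    }
    list(spectra = spectra, manifest = do.call(rbind, manifest))
  })
}

#' Write community artifacts to disk
#'
#' Emits the scaffold FASTA, coverage TSV, protein FASTA, gene GFF3
#' (attributes link gene to protein id), marker TSV and truth-label TSV
#' consumed by the downstream stages.
#'
#' @param community [generate_community] result.
#' @param proteome [generate_proteome_and_labels] result.
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_community <- function(community, proteome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    scaffolds = file.path(dir, "scaffolds.fna"),
    coverage = file.path(dir, "coverage.tsv"),
    proteins = file.path(dir, "proteins.faa"),
    genes = file.path(dir, "genes.gff3"),
    markers = file.path(dir, "markers.tsv"),
    labels = file.path(dir, "truth_labels.tsv"),
    genome_map = file.path(dir, "truth_scaffold_genomes.tsv"))
  dna <- Biostrings::DNAStringSet(
    stats::setNames(community$scaffolds$sequence,
                    community$scaffolds$scaffold_id))
  Biostrings::writeXStringSet(dna, paths$scaffolds)
  cov <- data.frame(scaffold_id = rownames(community$coverage),
                    community$coverage, check.names = FALSE)
  .write_tsv_atomic(cov, paths$coverage)
  write_protein_fasta(proteome$proteins, paths$proteins)
  g <- proteome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$scaffold_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- g$gene_id
  S4Vectors::mcols(gr)$protein_id <- g$protein_id
  rtracklayer::export(gr, paths$genes, format = "gff3")
  .write_tsv_atomic(proteome$markers, paths$markers)
  .write_tsv_atomic(proteome$labels, paths$labels)
  .write_tsv_atomic(community$scaffolds[, c("scaffold_id", "genome_id",
                                            "length")],
                    paths$genome_map)
  invisible(paths)
}
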