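## File formats: protein/nucleotide FASTA (via Biostrings), centroided MGF
## peak lists (line-oriented parser; no installed R package reads MGF), and
## the sidecar sample manifest.

#' Read a protein FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences; accession is the first
#'   whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write a protein FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Construct a centroided spectrum
#'
#' @param spectrum_id Unique identifier (MGF TITLE).
#' @param precursor_mz Precursor m/z in Th.
#' @param precursor_charge Integer charge in `[1, 6]`.
#' @param mz,intensity Parallel peak vectors; peaks are stored sorted by m/z.
#' @param sample_id,replicate_id Sample metadata labels.
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, precursor_charge,
                     mz, intensity, sample_id = NA_character_,
                     replicate_id = NA_character_) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must be parallel")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  if (precursor_charge < 1L || precursor_charge > 6L)
    stop("precursor charge must be in [1, 6]")
  ord <- order(mz)
  structure(list(spectrum_id = spectrum_id,
                 sample_id = sample_id,
                 replicate_id = replicate_id,
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 mz = mz[ord], intensity = intensity[ord]),
            class = "spectrum")
}

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS and CHARGE
#' headers. Sample and replicate labels are attached from an optional
#' manifest (see [read_spectrum_manifest]).
#'
#' @param path MGF path.
#' @param manifest Optional data.frame with columns `spectrum_id`,
#'   `sample_id`, `replicate_id`.
#' @return List of [spectrum] objects.
#' @export
read_mgf <- function(path, manifest = NULL) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  out <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    title <- vals[match("TITLE", keys)]
    pepmass <- as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1]][1])
    charge <- as.integer(sub("\\+$", "", vals[match("CHARGE", keys)]))
    peak_rows <- block[!is_kv & nzchar(block)]
    pk <- if (length(peak_rows)) {
      do.call(rbind, lapply(strsplit(peak_rows, "\\s+"), as.numeric))
    } else matrix(numeric(), ncol = 2)
    sample_id <- NA_character_; replicate_id <- NA_character_
    if (!is.null(manifest)) {
      j <- match(title, manifest$spectrum_id)
      if (!is.na(j)) {
        sample_id <- as.character(manifest$sample_id[j])
        replicate_id <- as.character(manifest$replicate_id[j])
      }
    }
    out[[i]] <- spectrum(title, pepmass, charge, pk[, 1], pk[, 2],
                         sample_id = sample_id, replicate_id = replicate_id)
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra List of [spectrum] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      paste0("PEPMASS=", formatC(sp$precursor_mz, format = "f", digits = 6)),
      paste0("CHARGE=", sp$precursor_charge, "+"),
      paste(formatC(sp$mz, format = "f", digits = 6),
            formatC(sp$intensity, format = "f", digits = 4)),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read a spectrum sample manifest
#'
#' @param path TSV with columns `spectrum_id`, `sample_id`, `replicate_id`
#'   (additional columns, e.g. generating-peptide truth, are passed through).
#' @return data.frame.
#' @export
read_spectrum_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

## Atomic TSV writer used by all pipeline stages: write to a temporary file
## in the target directory, then rename into place.
.write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
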