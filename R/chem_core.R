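## Peptide chemistry: in-silico tryptic digestion, elemental composition,
## and neutral mass arithmetic.

#' Construct an elemental formula
#'
#' @param C,H,N,O,S Non-negative integer atom counts.
#' @return Named integer vector of class `elemental_formula`.
#' @export
elemental_formula <- function(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L) {
  x <- c(C = as.integer(C), H = as.integer(H), N = as.integer(N),
         O = as.integer(O), S = as.integer(S))
  if (any(is.na(x)) || any(x < 0))
    stop("element counts must be non-negative integers")
  if (sum(x) == 0L)
    stop("formula must contain at least one atom")
  class(x) <- "elemental_formula"
  x
}

#' @export
print.elemental_formula <- function(x, ...) {
  nz <- x[x > 0]
  cat(paste0(names(nz), unclass(nz), collapse = " "), "\n")
  invisible(x)
}

#' Construct a peptide
#'
#' @param sequence Amino-acid string over the 20 canonical residues.
#' @param missed_cleavages Number of internal missed cleavage sites.
#' @param mods List of modifications, each `list(position =, id =)`;
#'   only `"M_ox"` (methionine oxidation, +O) is supported.
#' @param protein_ids Character vector of source protein accessions.
#' @return Object of class `peptide`.
#' @export
peptide <- function(sequence, missed_cleavages = 0L, mods = list(),
                    protein_ids = character()) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, rownames(.RESIDUE_FORMULAS))
  if (length(bad))
    stop("non-residue character(s) in sequence: ", paste(unique(bad), collapse = ", "))
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  for (m in mods) {
    if (is.null(.MODIFICATIONS[[m$id]]))
      stop("unknown modification id: ", m$id)
    if (m$position < 1L || m$position > nchar(sequence))
      stop("modification position out of bounds")
    if (res[m$position] != .MODIFICATIONS[[m$id]]$residue)
      stop("modification ", m$id, " not applicable at position ", m$position)
  }
  structure(list(sequence = sequence,
                 missed_cleavages = as.integer(missed_cleavages),
                 mods = mods,
                 protein_ids = protein_ids),
            class = "peptide")
}

## Positions i such that trypsin cuts between residue i and i+1:
## C-terminal to K/R, not when the next residue is P.
.tryptic_sites <- function(residues) {
  n <- length(residues)
  if (n < 2L) return(integer())
  i <- which(residues[-n] %in% c("K", "R") & residues[-1] != "P")
  i
}

#' Digest a protein sequence in silico
#'
#' Fully-specific tryptic digestion (cleavage C-terminal to K or R, never
#' before proline) generating all products with up to `max_missed` internal
#' missed cleavage sites.
#'
#' @param protein_sequence Residue string.
#' @param max_missed Maximum internal missed cleavages, 0..3.
#' @param enzyme Cleavage rule; only `"trypsin"` is implemented.
#' @param min_length,max_length Peptide length bounds (defaults 6 and 50).
#' @param protein_id Optional accession recorded on each peptide.
#' @return List of [peptide] objects in deterministic order (by start
#'   position, then by number of missed cleavages).
#' @export
digest <- function(protein_sequence, max_missed = 3L, enzyme = "trypsin",
                   min_length = 6L, max_length = 50L, protein_id = character()) {
  if (!identical(enzyme, "trypsin"))
    stop("unsupported enzyme: ", enzyme)
  if (max_missed < 0L || max_missed > 3L)
    stop("max_missed must be in [0, 3]")
  res <- strsplit(protein_sequence, "")[[1]]
  bad <- setdiff(res, rownames(.RESIDUE_FORMULAS))
  if (length(bad))
    stop("non-residue character(s) in sequence: ", paste(unique(bad), collapse = ", "))
  sites <- .tryptic_sites(res)
  ## fragment boundaries: [starts[i], ends[i]] are the 0-missed products
  starts <- c(1L, sites + 1L)
  ends <- c(sites, length(res))
  n_frag <- length(starts)
  out <- list()
  for (i in seq_len(n_frag)) {
    for (k in 0:max_missed) {
      j <- i + k
      if (j > n_frag) break
      s <- starts[i]; e <- ends[j]
      len <- e - s + 1L
      if (len < min_length || len > max_length) next
      out[[length(out) + 1L]] <- peptide(
        substr(protein_sequence, s, e),
        missed_cleavages = k,
        protein_ids = protein_id
      )
    }
  }
  out
}

#' Elemental composition of a peptide
#'
#' Sum of residue formulas plus one water; methionine oxidation adds one
#' oxygen per modification.
#'
#' @param pep A [peptide] or a plain sequence string.
#' @param mods Modifications when `pep` is a string (as in [peptide]).
#' @return [elemental_formula].
#' @export
elemental_composition <- function(pep, mods = list()) {
  if (is.character(pep)) pep <- peptide(pep, mods = mods)
  res <- strsplit(pep$sequence, "")[[1]]
  counts <- colSums(.RESIDUE_FORMULAS[res, , drop = FALSE]) + .WATER
  for (m in pep$mods) counts <- counts + .MODIFICATIONS[[m$id]]$delta
  f <- as.integer(counts)
  names(f) <- names(.WATER)
  class(f) <- "elemental_formula"
  f
}

#' Neutral mass of an elemental formula
#'
#' @param formula [elemental_formula].
#' @param mode `"monoisotopic"` (sum of lightest-isotope masses) or
#'   `"most_abundant"` (centroid mass of the maximal isotopologue envelope
#'   peak at the given carbon enrichment).
#' @param enrichment 13C atom fraction used when `mode = "most_abundant"`.
#' @return Mass in Da.
#' @export
neutral_mass <- function(formula, mode = c("monoisotopic", "most_abundant"),
                         enrichment = NATURAL_C13) {
  mode <- match.arg(mode)
  f <- unclass(formula)
  if (mode == "monoisotopic") {
    return(sum(vapply(names(f), function(el) {
      f[[el]] * .ISOTOPES[[el]]$mass[1]
    }, numeric(1))))
  }
  env <- formula_envelope(formula, enrichment_spec("C", enrichment))
  env$centroid_mass[most_abundant_offset(env) - env$offsets[1] + 1L]
}
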