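## Reference physical constants used throughout the package.
## Masses in unified atomic mass units (u); abundances are unitless fractions.
## Values follow the standard IUPAC/CODATA atomic mass and isotopic
## composition tables; they are versioned here so every envelope, precursor
## mass and score in the package derives from one audited table.

.ISOTOPES <- list(
  C = data.frame(offset = c(0L, 1L),
                 mass = c(12.0, 13.00335483507),
                 abundance = c(0.9893, 0.0107)),
  H = data.frame(offset = c(0L, 1L),
                 mass = c(1.00782503224, 2.01410177812),
                 abundance = c(0.999885, 0.000115)),
  N = data.frame(offset = c(0L, 1L),
                 mass = c(14.00307400446, 15.00010889894),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(offset = c(0L, 1L, 2L),
                 mass = c(15.99491461960, 16.99913175664, 17.99915961284),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(offset = c(0L, 1L, 2L, 4L),
                 mass = c(31.97207117443, 32.97145890985, 33.96786701, 35.96708071),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

.ELEMENTS <- names(.ISOTOPES)

PROTON_MASS <- 1.00727646688

## Spacing of adjacent carbon isotopologue peaks; integer "Da" parent-mass
## offsets are applied in multiples of this gap because they model
## deisotoping errors, whose natural spacing is the isotopologue gap.
C13_C12_GAP <- 13.00335483507 - 12.0

## Natural 13C atom fraction (overridable through EnrichmentSpec).
NATURAL_C13 <- 0.0107

## Monoisotopic residue compositions of the 20 canonical amino acids
## (residue = amino acid minus water). Columns: C, H, N, O, S.
.RESIDUE_FORMULAS <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  storage.mode(m) <- "integer"
  m
})

.WATER <- c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L)

## Supported variable modifications: elemental deltas added to the peptide
## composition. Only methionine oxidation is searched.
.MODIFICATIONS <- list(
  M_ox = list(residue = "M", delta = c(C = 0L, H = 0L, N = 0L, O = 1L, S = 0L))
)

#' Write the isotope reference table used by the package
#'
#' Dumps the versioned isotope masses and natural abundances to a
#' tab-separated file so the constants behind every envelope computation can
#' be audited.
#'
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_isotope_constants <- function(path) {
  tab <- do.call(rbind, lapply(names(.ISOTOPES), function(el) {
    cbind(element = el, .ISOTOPES[[el]])
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
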