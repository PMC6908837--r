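## Enrichment-parameterized isotopologue envelopes.
##
## Isotopologues are aggregated by nucleon-number offset from the all-light
## species (fine structure is not resolved: at 0.03/0.01 Da tolerances the
## sub-mDa splittings within an offset class are invisible). Each offset
## class carries a total abundance and an abundance-weighted centroid mass.

#' Enrichment specification
#'
#' @param element Element symbol; only carbon enrichment is supported (the
#'   labeling isotope is 13C), other elements keep natural abundances.
#' @param atom_fraction Heavy-isotope atom fraction in `[0, 1]`.
#' @return Object of class `enrichment_spec`.
#' @export
enrichment_spec <- function(element = "C", atom_fraction = NATURAL_C13) {
  if (!element %in% .ELEMENTS)
    stop("unsupported element: ", element)
  if (!identical(element, "C"))
    stop("enrichment is only supported for carbon")
  if (atom_fraction < 0 || atom_fraction > 1)
    stop("atom_fraction must be in [0, 1]")
  structure(list(element = element, atom_fraction = atom_fraction),
            class = "enrichment_spec")
}

#' Per-isotope distribution of one element under an enrichment hypothesis
#'
#' @param element Element symbol (C, H, N, O, S).
#' @param spec [enrichment_spec]; for carbon the two-isotope distribution is
#'   `(1 - p, p)`, all other elements return natural abundances.
#' @return data.frame with columns `offset`, `mass`, `abundance`.
#' @export
element_distribution <- function(element, spec = enrichment_spec()) {
  if (!element %in% .ELEMENTS)
    stop("unsupported element: ", element)
  d <- .ISOTOPES[[element]]
  if (identical(element, spec$element)) {
    p <- spec$atom_fraction
    d$abundance <- c(1 - p, p)
  }
  d
}

## Internal envelope representation during convolution: a list with
## `first` (lowest nucleon offset), `ab` (abundance per offset) and
## `mm` (abundance-weighted mass moment per offset, i.e. sum p*m).
.env_unit <- function(dist) {
  k <- max(dist$offset)
  ab <- numeric(k + 1L)
  mm <- numeric(k + 1L)
  ab[dist$offset + 1L] <- dist$abundance
  mm[dist$offset + 1L] <- dist$abundance * dist$mass
  list(first = 0L, ab = ab, mm = mm)
}

## Open convolution of two internal envelopes; the mass moment convolves by
## the product rule so centroids add correctly.
.env_conv <- function(a, b) {
  la <- length(a$ab); lb <- length(b$ab)
  n <- la + lb - 1L
  ab <- numeric(n); mm <- numeric(n)
  for (i in seq_len(la)) {
    if (a$ab[i] == 0 && a$mm[i] == 0) next
    idx <- i:(i + lb - 1L)
    ab[idx] <- ab[idx] + a$ab[i] * b$ab
    mm[idx] <- mm[idx] + a$mm[i] * b$ab + a$ab[i] * b$mm
  }
  .env_trim(list(first = a$first + b$first, ab = ab, mm = mm))
}

## Drop numerically negligible leading/trailing classes (total dropped mass
## < 1e-15 per side) so convolutions stay short without hurting the
## exhaustive-enumeration oracle at 1e-9.
.env_trim <- function(e, tol = 1e-15) {
  n <- length(e$ab)
  cs <- cumsum(e$ab)
  lead <- sum(cs < tol)
  cs2 <- cumsum(rev(e$ab))
  trail <- sum(cs2 < tol)
  if (lead + trail >= n) return(e)
  keep <- (lead + 1L):(n - trail)
  list(first = e$first + lead, ab = e$ab[keep], mm = e$mm[keep])
}

## n-fold self-convolution by binary exponentiation.
.env_power <- function(unit, n) {
  result <- NULL
  base <- unit
  while (n > 0L) {
    if (n %% 2L == 1L)
      result <- if (is.null(result)) base else .env_conv(result, base)
    n <- n %/% 2L
    if (n > 0L) base <- .env_conv(base, base)
  }
  result
}

#' Theoretical isotopologue envelope of a formula
#'
#' Convolves per-atom isotope distributions (carbon at the hypothesized
#' enrichment, other elements at natural abundance) into the distribution of
#' nucleon-offset classes, with an abundance-weighted centroid mass per
#' class.
#'
#' @param formula [elemental_formula].
#' @param spec [enrichment_spec].
#' @param truncate Cumulative-abundance cutoff in `(0.99, 1]`; the smallest
#'   set of most-abundant classes reaching the cutoff is kept (padded to a
#'   contiguous offset range) and abundances are renormalized.
#' @return Object of class `sip_envelope`: `offsets` (integer nucleon
#'   shifts), `abundance` (sums to 1), `centroid_mass` (Da, strictly
#'   increasing).
#' @export
formula_envelope <- function(formula, spec = enrichment_spec(),
                             truncate = 0.999) {
  if (truncate <= 0.99 || truncate > 1)
    stop("truncate must be in (0.99, 1]")
  f <- unclass(formula)
  env <- NULL
  for (el in names(f)) {
    if (f[[el]] == 0L) next
    unit <- .env_unit(element_distribution(el, spec))
    pw <- .env_power(unit, f[[el]])
    env <- if (is.null(env)) pw else .env_conv(env, pw)
  }
  if (is.null(env)) stop("empty formula")
  ab <- env$ab
  ## final truncation: keep most-abundant classes up to the cumulative
  ## cutoff, then the contiguous span covering them
  if (truncate < 1) {
    ord <- order(ab, decreasing = TRUE)
    need <- which(cumsum(ab[ord]) >= truncate)[1]
    if (is.na(need)) need <- length(ab)
    keep_idx <- sort(ord[seq_len(need)])
    span <- keep_idx[1]:keep_idx[length(keep_idx)]
  } else {
    span <- which(ab > 0)
    span <- span[1]:span[length(span)]
  }
  ab <- env$ab[span]
  mm <- env$mm[span]
  centroid <- ifelse(ab > 0, mm / ab, NA_real_)
  ## renormalize after truncation
  s <- sum(ab)
  structure(list(offsets = env$first + span - 1L,
                 abundance = ab / s,
                 centroid_mass = centroid),
            class = "sip_envelope")
}

#' Most abundant isotopologue offset of an envelope
#'
#' @param envelope [formula_envelope] result.
#' @return The nucleon offset (integer) of the maximal abundance class; ties
#'   break toward the lower offset.
#' @export
most_abundant_offset <- function(envelope) {
  envelope$offsets[which.max(envelope$abundance)]
}

#' @export
print.sip_envelope <- function(x, ...) {
  print(data.frame(offset = x$offsets, abundance = x$abundance,
                   centroid_mass = x$centroid_mass))
  invisible(x)
}

## ---- envelope cache -------------------------------------------------------

## Envelope computations recur heavily during grid searches (same fragment
## composition at the same enrichment across spectra); a process-level cache
## keyed by formula + enrichment + cutoff removes the redundancy.
.envelope_cache <- new.env(parent = emptyenv())

.cached_envelope <- function(formula, p, truncate = 0.999) {
  key <- paste(paste(unclass(formula), collapse = ","),
               format(p, digits = 10), truncate, sep = "|")
  hit <- .envelope_cache[[key]]
  if (!is.null(hit)) return(hit)
  env <- formula_envelope(formula, enrichment_spec("C", p), truncate = truncate)
  assign(key, env, envir = .envelope_cache)
  env
}

#' Clear the internal envelope cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_envelope_cache <- function() {
  n <- length(ls(.envelope_cache))
  rm(list = ls(.envelope_cache), envir = .envelope_cache)
  invisible(n)
}
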