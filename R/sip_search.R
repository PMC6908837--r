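## Enrichment-resolved peptide-spectrum matching, atom% estimation, and
## peptide-level target-decoy FDR.

DECOY_PREFIX <- "XXX_"

#' Search configuration
#'
#' Defaults implement the SIP search (parent offsets -4..4 Da, 0.03 Da
#' parent and 0.01 Da fragment tolerances, up to three missed cleavages,
#' full tryptic specificity, an enrichment grid in 1 atom% steps from
#' natural abundance to 99%). `mode = "regular"` pins the grid to natural
#' abundance and uses parent offsets -1..3.
#'
#' @param mode `"sip"` or `"regular"`.
#' @param parent_offsets_da Integer parent-mass offsets (units of the
#'   13C-12C gap), accommodating deisotoping errors.
#' @param parent_tol_da,fragment_tol_da Mass tolerances in Da.
#' @param enrichment_grid Ascending 13C atom fractions to hypothesize.
#' @param max_missed Missed cleavages allowed in the peptide index.
#' @param mods Variable modification ids (subset of `"M_ox"`).
#' @param min_length,max_length Peptide length bounds for digestion.
#' @param n_refine Number of top precursor-score enrichment hypotheses that
#'   receive full fragment-envelope scoring.
#' @return Object of class `search_config`.
#' @export
search_config <- function(mode = c("sip", "regular"),
                          parent_offsets_da = NULL,
                          parent_tol_da = 0.03,
                          fragment_tol_da = 0.01,
                          enrichment_grid = NULL,
                          max_missed = 3L,
                          mods = "M_ox",
                          min_length = 6L,
                          max_length = 50L,
                          n_refine = 3L) {
  mode <- match.arg(mode)
  if (is.null(parent_offsets_da))
    parent_offsets_da <- if (mode == "sip") -4:4 else -1:3
  if (is.null(enrichment_grid))
    enrichment_grid <- if (mode == "sip")
      c(NATURAL_C13, seq(0.02, 0.99, by = 0.01)) else NATURAL_C13
  if (parent_tol_da <= 0 || fragment_tol_da <= 0)
    stop("tolerances must be > 0")
  if (is.unsorted(enrichment_grid, strictly = TRUE))
    stop("enrichment_grid must be strictly ascending")
  structure(list(mode = mode,
                 parent_offsets_da = as.integer(parent_offsets_da),
                 parent_tol_da = parent_tol_da,
                 fragment_tol_da = fragment_tol_da,
                 enrichment_grid = enrichment_grid,
                 max_missed = as.integer(max_missed),
                 mods = mods,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 n_refine = as.integer(n_refine)),
            class = "search_config")
}

#' Build a concatenated target-decoy protein database
#'
#' Each target protein receives one full-sequence-reversed decoy whose
#' accession carries the reserved `XXX_` prefix.
#'
#' @param proteins Named character vector of target sequences.
#' @return Named character vector of length `2 * length(proteins)` with
#'   attribute `is_decoy` (logical, parallel).
#' @export
make_decoy_db <- function(proteins) {
  if (length(proteins) == 0L) stop("empty protein database")
  if (any(startsWith(names(proteins), DECOY_PREFIX)))
    stop("target accession collides with the reserved decoy prefix ", DECOY_PREFIX)
  rev_seq <- vapply(proteins, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1))
  decoys <- stats::setNames(rev_seq, paste0(DECOY_PREFIX, names(proteins)))
  db <- c(proteins, decoys)
  attr(db, "is_decoy") <- c(rep(FALSE, length(proteins)),
                            rep(TRUE, length(decoys)))
  db
}

#' Digest a protein database into a searchable peptide index
#'
#' Peptides identical in sequence are collapsed; each index entry records
#' the source proteins, decoy status (decoy iff no target protein contains
#' the peptide), elemental composition, monoisotopic mass and carbon count.
#' At most one methionine oxidation variant per peptide is generated when
#' `"M_ox"` is among the configured modifications.
#'
#' @param db Target or target+decoy database (named character vector; decoy
#'   accessions carry the `XXX_` prefix).
#' @param config [search_config].
#' @return Object of class `peptide_index`.
#' @export
build_peptide_index <- function(db, config = search_config()) {
  if (length(db) == 0L) stop("empty protein database")
  pep_map <- new.env(parent = emptyenv())
  for (acc in names(db)) {
    peps <- digest(db[[acc]], max_missed = config$max_missed,
                   min_length = config$min_length,
                   max_length = config$max_length)
    for (p in peps) {
      key <- p$sequence
      pep_map[[key]] <- c(pep_map[[key]], acc)
    }
  }
  seqs <- sort(ls(pep_map))
  entries <- list()
  for (s in seqs) {
    accs <- sort(unique(pep_map[[s]]))
    is_decoy <- all(startsWith(accs, DECOY_PREFIX))
    base <- elemental_composition(s)
    entries[[length(entries) + 1L]] <- list(
      sequence = s, mods = list(), protein_ids = accs, is_decoy = is_decoy,
      formula = base, mono_mass = neutral_mass(base),
      n_carbons = unname(base["C"]))
    if ("M_ox" %in% config$mods && grepl("M", s, fixed = TRUE)) {
      pos <- regexpr("M", s, fixed = TRUE)[[1]]
      mod <- list(list(position = pos, id = "M_ox"))
      f <- elemental_composition(s, mods = mod)
      entries[[length(entries) + 1L]] <- list(
        sequence = s, mods = mod, protein_ids = accs, is_decoy = is_decoy,
        formula = f, mono_mass = neutral_mass(f),
        n_carbons = unname(f["C"]))
    }
  }
  structure(list(entries = entries,
                 mono_mass = vapply(entries, `[[`, numeric(1), "mono_mass"),
                 is_decoy = vapply(entries, `[[`, logical(1), "is_decoy")),
            class = "peptide_index")
}

#' Cosine-normalized weighted dot product of observed and theoretical
#' envelope intensities
#'
#' @param observed Observed intensity per envelope offset (0 where no peak
#'   matched within tolerance).
#' @param theoretical Theoretical abundances (or a `sip_envelope`).
#' @return Score in `[0, 1]`; 0 when the observed vector is all-zero.
#' @export
score_envelope <- function(observed, theoretical) {
  t <- if (inherits(theoretical, "sip_envelope")) theoretical$abundance else theoretical
  if (length(observed) != length(t))
    stop("observed and theoretical must be aligned")
  no <- sqrt(sum(observed^2))
  nt <- sqrt(sum(t^2))
  if (no == 0 || nt == 0) return(0)
  max(0, min(1, sum(observed * t) / (no * nt)))
}

## Observed intensity aligned to envelope offsets: for each theoretical
## centroid m/z take the maximal peak intensity within tol, else 0.
.aligned_intensity <- function(sp, theo_mz, tol) {
  vapply(theo_mz, function(m) {
    lo <- findInterval(m - tol, sp$mz)
    hi <- findInterval(m + tol, sp$mz)
    if (hi > lo) max(sp$intensity[(lo + 1L):hi]) else 0
  }, numeric(1))
}

## b/y fragment compositions of a peptide (charge 1 ions only). Neutral
## b fragment = sum of residues; neutral y fragment = sum of residues + H2O.
## A single M_ox modification is attributed to its residue position.
.fragment_formulas <- function(sequence, mods = list()) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2L) return(list())
  counts <- .RESIDUE_FORMULAS[res, , drop = FALSE]
  counts <- matrix(as.numeric(counts), nrow = n,
                   dimnames = list(NULL, colnames(.RESIDUE_FORMULAS)))
  for (m in mods)
    counts[m$position, ] <- counts[m$position, ] + .MODIFICATIONS[[m$id]]$delta
  cum <- apply(counts, 2, cumsum)
  total <- cum[n, ]
  out <- vector("list", 2L * (n - 1L))
  for (i in seq_len(n - 1L)) {
    b <- cum[i, ]
    y <- total - cum[i, ] + .WATER
    fb <- as.integer(b); names(fb) <- colnames(counts); class(fb) <- "elemental_formula"
    fy <- as.integer(y); names(fy) <- colnames(counts); class(fy) <- "elemental_formula"
    out[[i]] <- fb
    out[[n - 1L + i]] <- fy
  }
  out
}

## Score one (entry, enrichment) hypothesis against a spectrum.
## Returns list(precursor_score, combined_score) or NULL if the precursor
## gate fails for every allowed parent offset.
.score_hypothesis <- function(sp, entry, p, config, fragments = TRUE) {
  env <- .cached_envelope(entry$formula, p)
  z <- sp$precursor_charge
  obs_neutral <- sp$precursor_mz * z - z * PROTON_MASS
  ma <- most_abundant_offset(env)
  ma_mass <- env$centroid_mass[match(ma, env$offsets)]
  deltas <- obs_neutral - (ma_mass + config$parent_offsets_da * C13_C12_GAP)
  hit <- which(abs(deltas) <= config$parent_tol_da)
  if (!length(hit)) return(NULL)
  offset_da <- config$parent_offsets_da[hit[which.min(abs(deltas[hit]))]]
  theo_mz <- env$centroid_mass / z + PROTON_MASS
  obs <- .aligned_intensity(sp, theo_mz, config$fragment_tol_da)
  prec <- score_envelope(obs, env$abundance)
  out <- list(precursor_score = prec, offset_da = offset_da,
              combined_score = NA_real_)
  if (!fragments) return(out)
  frags <- .fragment_formulas(entry$sequence, entry$mods)
  if (!length(frags)) {
    out$combined_score <- prec
    return(out)
  }
  fs <- vapply(frags, function(f) {
    fe <- .cached_envelope(f, p)
    fmz <- fe$centroid_mass + PROTON_MASS
    fobs <- .aligned_intensity(sp, fmz, config$fragment_tol_da)
    score_envelope(fobs, fe$abundance)
  }, numeric(1))
  out$combined_score <- 0.5 * prec + 0.5 * mean(fs)
  out
}

#' Estimate the 13C atom percent of a peptide from one spectrum
#'
#' Grid search over the configured enrichment hypotheses: each grid point
#' whose most-abundant theoretical precursor peak matches the observed
#' precursor mass (within tolerance, after one allowed integer parent
#' offset) is scored; the precursor-envelope score ranks all candidates and
#' the top `n_refine` receive full b/y fragment-envelope scoring. Ties in
#' the combined score break toward the lower enrichment.
#'
#' @param sp [spectrum].
#' @param pep [peptide], index entry, or sequence string.
#' @param config [search_config].
#' @return List with `atom_percent` (on the grid, percent scale), `score`,
#'   `parent_offset_da`, and `matched`; `matched = FALSE` when no grid point
#'   passes the precursor gate.
#' @export
estimate_atom_percent <- function(sp, pep, config = search_config()) {
  entry <- if (is.character(pep)) {
    f <- elemental_composition(pep)
    list(sequence = pep, mods = list(), formula = f,
         mono_mass = neutral_mass(f))
  } else if (inherits(pep, "peptide")) {
    f <- elemental_composition(pep)
    list(sequence = pep$sequence, mods = pep$mods, formula = f,
         mono_mass = neutral_mass(f))
  } else pep
  grid <- config$enrichment_grid
  prec <- vector("list", length(grid))
  for (i in seq_along(grid))
    prec[[i]] <- .score_hypothesis(sp, entry, grid[i], config, fragments = FALSE)
  ok <- which(!vapply(prec, is.null, logical(1)))
  if (!length(ok))
    return(list(matched = FALSE, atom_percent = NA_real_, score = NA_real_,
                parent_offset_da = NA_integer_))
  ps <- vapply(prec[ok], `[[`, numeric(1), "precursor_score")
  refine <- ok[order(-ps, grid[ok])][seq_len(min(config$n_refine, length(ok)))]
  best <- NULL
  for (i in refine) {
    h <- .score_hypothesis(sp, entry, grid[i], config, fragments = TRUE)
    if (is.null(best) || h$combined_score > best$score + 1e-12 ||
        (abs(h$combined_score - best$score) <= 1e-12 && grid[i] < best$p)) {
      best <- list(p = grid[i], score = h$combined_score,
                   offset = h$offset_da)
    }
  }
  list(matched = TRUE, atom_percent = 100 * best$p, score = best$score,
       parent_offset_da = best$offset)
}

#' Search a set of spectra against a peptide index
#'
#' For each spectrum the best-scoring (peptide, enrichment, parent offset)
#' candidate is retained (rank-1 only). Candidates are pre-filtered by a
#' monoisotopic-mass gate modulo the isotopologue gap, then scored with
#' [estimate_atom_percent]. Determinate tie-breaking: higher score, then
#' target before decoy, then lower enrichment, then peptide sequence.
#'
#' @param spectra List of [spectrum] objects.
#' @param index [build_peptide_index] result over the target+decoy database.
#' @param config [search_config].
#' @return data.frame of peptide-spectrum matches (one row per matched
#'   spectrum): spectrum_id, sample_id, replicate_id, peptide, mods,
#'   protein_ids (`;`-joined), is_decoy, atom_percent, score,
#'   parent_offset_da, precursor_charge.
#' @export
search_sample <- function(spectra, index, config = search_config()) {
  if (!length(index$entries)) stop("empty peptide index")
  grid <- config$enrichment_grid
  max_c <- max(vapply(index$entries, `[[`, numeric(1), "n_carbons"))
  rows <- list()
  n_skipped <- 0L
  for (sp in spectra) {
    if (!inherits(sp, "spectrum") || !length(sp$mz)) {
      n_skipped <- n_skipped + 1L
      next
    }
    z <- sp$precursor_charge
    obs_neutral <- sp$precursor_mz * z - z * PROTON_MASS
    ## coarse gate: some integer isotopologue shift k >= 0 plus an allowed
    ## parent offset must bring the monoisotopic mass within tolerance
    ## (slack 0.02 Da absorbs centroid-vs-k*gap deviation)
    shift <- obs_neutral - index$mono_mass
    kmin <- min(config$parent_offsets_da)
    kmax <- max(config$parent_offsets_da) +
      if (length(grid) > 1L) max_c else 2L
    k <- round(shift / C13_C12_GAP)
    resid <- abs(shift - k * C13_C12_GAP)
    cand <- which(resid <= config$parent_tol_da + 0.02 & k >= kmin & k <= kmax + 2)
    if (!length(cand)) next
    best <- NULL
    for (ci in cand) {
      entry <- index$entries[[ci]]
      est <- estimate_atom_percent(sp, entry, config)
      if (!est$matched) next
      cand_row <- list(entry = entry, est = est)
      if (is.null(best)) { best <- cand_row; next }
      a <- cand_row$est; b <- best$est
      better <-
        if (abs(a$score - b$score) > 1e-12) a$score > b$score
        else if (cand_row$entry$is_decoy != best$entry$is_decoy) !cand_row$entry$is_decoy
        else if (abs(a$atom_percent - b$atom_percent) > 1e-9) a$atom_percent < b$atom_percent
        else cand_row$entry$sequence < best$entry$sequence
      if (better) best <- cand_row
    }
    if (is.null(best)) next
    e <- best$entry; est <- best$est
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = sp$spectrum_id,
      sample_id = sp$sample_id,
      replicate_id = sp$replicate_id,
      peptide = e$sequence,
      mods = if (length(e$mods)) paste(vapply(e$mods, function(m)
        paste0(m$id, "@", m$position), character(1)), collapse = ",") else "",
      protein_ids = paste(e$protein_ids, collapse = ";"),
      is_decoy = e$is_decoy,
      atom_percent = est$atom_percent,
      score = est$score,
      parent_offset_da = est$parent_offset_da,
      precursor_charge = sp$precursor_charge,
      stringsAsFactors = FALSE)
  }
  psms <- if (length(rows)) do.call(rbind, rows) else data.frame(
    spectrum_id = character(), sample_id = character(),
    replicate_id = character(), peptide = character(), mods = character(),
    protein_ids = character(), is_decoy = logical(),
    atom_percent = numeric(), score = numeric(),
    parent_offset_da = integer(), precursor_charge = integer(),
    stringsAsFactors = FALSE)
  attr(psms, "n_skipped") <- n_skipped
  if (n_skipped > 0L)
    message("search_sample: skipped ", n_skipped, " malformed spectra")
  psms
}

#' Filter peptide-spectrum matches to a peptide-level FDR
#'
#' PSMs are collapsed to the best-scoring match per peptide sequence, sorted
#' by descending score (decoys rank before targets at exactly equal score,
#' the conservative order), and the largest score-threshold prefix with
#' `#decoy / #target <= level` is retained. Decoys are excluded from the
#' returned identifications.
#'
#' @param psms [search_sample] output.
#' @param level Nominal peptide FDR in `(0, 1)` (default 0.01).
#' @return data.frame of retained target peptide identifications (all PSM
#'   rows of retained peptides), with attribute `threshold` (score cutoff).
#' @export
fdr_filter <- function(psms, level = 0.01) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (!nrow(psms)) return(psms[0, ])
  if (!any(!psms$is_decoy)) return(psms[0, ])
  ## best PSM per peptide sequence
  ord <- order(psms$peptide, -psms$score)
  bp <- psms[ord, ][!duplicated(psms$peptide[ord]), ]
  ## conservative sort: score desc, decoys first within ties
  bp <- bp[order(-bp$score, !bp$is_decoy, bp$peptide), ]
  cum_d <- cumsum(bp$is_decoy)
  cum_t <- cumsum(!bp$is_decoy)
  ratio <- ifelse(cum_t == 0, Inf, cum_d / cum_t)
  pass <- which(ratio <= level)
  if (!length(pass)) return(psms[0, ])
  k <- max(pass)
  kept_peptides <- bp$peptide[seq_len(k)][!bp$is_decoy[seq_len(k)]]
  out <- psms[!psms$is_decoy & psms$peptide %in% kept_peptides, , drop = FALSE]
  attr(out, "threshold") <- bp$score[k]
  out
}
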