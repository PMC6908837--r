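## Bundled labeled-protein reports from two published soil SIP studies
## (a 13CO2 rhizosphere experiment and a 13C-methanol incubation
## experiment), in the package's report layout. They serve as worked
## examples for the targeted-binning acceptance rules.

#' Load the bundled 13CO2 rhizosphere labeled-protein report
#'
#' One row per labeled-protein identification (14 in total across 4 MAGs):
#' protein, plant host, timepoint, atom%, and the MAG-level completeness,
#' contamination and taxonomy.
#'
#' @return data.frame.
#' @export
load_co2_labeled_report <- function() {
  utils::read.delim(system.file("extdata", "co2_labeled_proteins.tsv",
                                package = "prosip"),
                    stringsAsFactors = FALSE)
}

#' Load the bundled 13C-methanol incubation labeled-protein report
#'
#' One row per labeled protein with its atom% per replicate of the day-3
#' and day-8 incubation triplicates (NA where not identified), and the
#' MAG-level quality values.
#'
#' @return data.frame.
#' @export
load_methanol_labeled_report <- function() {
  utils::read.delim(system.file("extdata", "methanol_labeled_proteins.tsv",
                                package = "prosip"),
                    stringsAsFactors = FALSE)
}

#' Build MAG records from the 13CO2 report
#'
#' @param report [load_co2_labeled_report] output (or compatible).
#' @return List of [mag_record] in `targeted_co2` mode, one per MAG, each
#'   carrying its labeled-protein identifications.
#' @export
mag_records_from_co2_report <- function(report = load_co2_labeled_report()) {
  lapply(split(report, report$mag_id), function(r) {
    mag_record(
      mag_id = r$mag_id[1],
      completeness = r$completeness[1],
      contamination = r$contamination[1],
      mode = "targeted_co2",
      labeled_idents = data.frame(
        protein_id = r$protein_id,
        sample_id = paste(r$plant_host, r$timepoint),
        atom_percent = r$atom_percent,
        stringsAsFactors = FALSE))
  })
}

#' Build MAG records from the 13C-methanol report
#'
#' The per-replicate atom% columns are pivoted to one identification per
#' non-missing cell (protein, timepoint, replicate, atom%).
#'
#' @param report [load_methanol_labeled_report] output (or compatible).
#' @return List of [mag_record] in `targeted_methanol` mode.
#' @export
mag_records_from_methanol_report <- function(
    report = load_methanol_labeled_report()) {
  rep_cols <- c(day3_rep1 = "D3.R1", day3_rep2 = "D3.R2", day3_rep3 = "D3.R3",
                day8_rep1 = "D8.R1", day8_rep2 = "D8.R2", day8_rep3 = "D8.R3")
  lapply(split(report, report$mag_id), function(r) {
    ids <- list()
    for (i in seq_len(nrow(r))) {
      for (col in names(rep_cols)) {
        v <- r[[col]][i]
        if (is.na(v)) next
        tp_rep <- strsplit(rep_cols[[col]], ".", fixed = TRUE)[[1]]
        ids[[length(ids) + 1L]] <- data.frame(
          protein_id = r$protein_id[i],
          timepoint = tp_rep[1], replicate_id = tp_rep[2],
          atom_percent = v, stringsAsFactors = FALSE)
      }
    }
    mag_record(
      mag_id = r$mag_id[1],
      completeness = r$completeness[1],
      contamination = r$contamination[1],
      mode = "targeted_methanol",
      labeled_idents = if (length(ids)) do.call(rbind, ids) else NULL)
  })
}
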