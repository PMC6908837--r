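# prosip

Genome-resolved proteomic stable isotope probing (SIP) in R.

In a proteomic SIP experiment a microbial community is fed an isotopically
heavy substrate (here ¹³CO₂ fixed by plants, or ¹³C-methanol added to
soil). Organisms that assimilate the substrate synthesize new proteins
whose carbon is partially ¹³C, so their tryptic peptides show mass-shifted
isotopologue envelopes in shotgun MS/MS data. `prosip` identifies those
labeled peptides, estimates their ¹³C enrichment, infers labeled proteins,
and reconstructs metagenome-assembled genomes (MAGs) for the labeled
organisms by binning the scaffolds that carry their genes. It is aimed at
microbial ecologists and proteomics methodologists who want a tested,
desk-scale implementation of the whole chain, including a synthetic-data
generator that provides ground truth for every stage.

## The model

For a peptide with elemental composition C_c H_h N_n O_o S_s and a
hypothesized ¹³C atom fraction *p*, the carbon isotope distribution is
Binomial(c, *p*) and the other elements keep natural abundances. The
theoretical isotopologue envelope is the convolution of the per-atom
distributions, aggregated by nucleon-number offset *k* from the all-light
species; each offset class carries an abundance *t_k* and an
abundance-weighted centroid mass. A peptide-spectrum match at enrichment
*p* is scored with a cosine-normalized weighted dot product

    S(p) = 1/2 · cos(t_prec, o_prec) + 1/2 · mean_f cos(t_f, o_f)

over the precursor envelope and the singly charged b/y fragment envelopes,
where *o* are observed intensities aligned to envelope offsets within the
fragment tolerance (0.01 Da). The enrichment estimate is the argmax of
S(p) over a grid (1 atom% steps from natural abundance 1.07% to 99% by
default), with precursor matching allowing integer parent-mass offsets
(−4..4 Da) at 0.03 Da tolerance. Identifications are filtered to a 1%
peptide-level FDR with a concatenated reversed-decoy database, proteins
are inferred by greedy parsimony with a one-unique-peptide rule, and a
protein is called ¹³C-labeled only above 10 atom% with replicated support
(two labeled peptides in one sample of the ¹³CO₂ design; one labeled
protein in two replicates of an incubation triplicate in the methanol
design). Scaffolds carrying labeled unique proteins seed targeted binning
over per-sample coverage series plus canonical tetranucleotide
composition; candidate MAGs are accepted at ≤5% contamination with the
labeling support above (untargeted MAGs at >70% completeness and <10%
contamination), with completeness/contamination computed from a
single-copy marker table.

## Worked example

Apply the targeted-binning acceptance rules to the bundled ¹³CO₂
rhizosphere labeled-protein report (14 identifications across 4 MAGs):

```r
library(prosip)
mags <- mag_records_from_co2_report()
for (m in mags) {
  v <- accept_mag(m)
  cat(sprintf("%s: accepted=%s quality=%s idents=%d\n",
      m$mag_id, v$accepted, v$quality_class, nrow(m$labeled_idents)))
}
#> MAG43: accepted=TRUE quality=low idents=3
#> MAG44: accepted=TRUE quality=low idents=2
#> MAG45: accepted=TRUE quality=medium idents=2
#> MAG46: accepted=TRUE quality=low idents=7
```

All four MAGs pass the targeted rule (≥2 labeled-protein identifications,
contamination ≤5%); MAG45 is medium quality (completeness ≥50%), the
other three are low quality. Estimating enrichment from a synthetic
spectrum generated at 30 atom% with 5% multiplicative noise recovers the
truth on the grid:

```r
g <- generate_spectra(data.frame(peptide = "ELVISLIVESK", protein_id = "P",
                                 atom_percent = 30), noise_sd = 0.05, seed = 4)
est <- estimate_atom_percent(g$spectra[[1]], "ELVISLIVESK", search_config("sip"))
sprintf("estimated atom%%: %.2f (score %.4f)", est$atom_percent, est$score)
#> "estimated atom%: 30.00 (score 0.9990)"
```

`compare_timepoints()` gives the exact Mann–Whitney comparison of atom%
between timepoints, and `run_stage("all", pipeline_config(...))` drives
the full simulate → digest → search → infer → bin → report pipeline on a
synthetic community (see the methods vignette). A thin command-line
wrapper is installed at `inst/scripts/prosip.R`.

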