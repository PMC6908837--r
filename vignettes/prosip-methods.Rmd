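---
title: "Methods: enrichment-resolved proteomic SIP and targeted binning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment-resolved proteomic SIP and targeted binning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosip)
```

## The problem

Proteomic stable isotope probing (SIP) identifies which members of a
microbial community assimilated an isotopically heavy substrate by finding
their newly synthesized, mass-shifted proteins in shotgun MS/MS data. The
read-out is the ¹³C atom% of labeled peptides, which proteomic SIP can
estimate accurately and down to low labeling levels because it rests on
precise mass measurements rather than density separation. `prosip`
implements that identification chain and couples it to targeted
metagenome binning, so that the organisms behind labeled proteins are
recovered as metagenome-assembled genomes (MAGs).

## Isotopologue envelope model

The unit of computation is the *isotopologue envelope* of an elemental
formula at a hypothesized ¹³C atom fraction $p$: carbon contributes a
two-point distribution $(1-p, p)$ per atom, H, N, O and S keep their
natural isotopic abundances, and the per-atom distributions are convolved
(by binary exponentiation per element, then across elements). Classes are
aggregated by nucleon-number offset $k$ from the all-light species; each
class carries a total abundance $t_k$ and an abundance-weighted centroid
mass. Fine structure within a class (for example ¹³C vs ¹⁵N
substitutions) is deliberately not resolved: at the 0.03 Da parent and
0.01 Da fragment tolerances used here, sub-mDa splittings are invisible,
and the centroid mass is the observable quantity.

Numerical choices:

* During convolution only leading/trailing classes with cumulative
  abundance below $10^{-15}$ are dropped, so for small formulas the
  envelope agrees with exhaustive enumeration over all isotope
  assignments to machine precision (the test suite checks $10^{-9}$).
* The user-facing `truncate` cutoff (default 0.999) is applied once at
  the end: the smallest set of most-abundant classes reaching the cutoff
  is kept and renormalized. `truncate = 1` disables truncation.
* The isotope masses and abundances are versioned constants
  (`write_isotope_constants()` dumps them for audit); the proton mass is
  1.00727646688 Da and integer parent offsets step by the ¹³C–¹²C gap,
  1.003355 Da, since they model deisotoping errors whose natural spacing
  is the isotopologue gap.

## Scoring and enrichment estimation

Published SIP search engines name a weighted dot-product score but not
its algebra, so the functional form here is the package's own choice,
stated explicitly: both the precursor envelope and every singly charged
b/y fragment envelope are scored as the cosine between theoretical
abundances and observed intensities aligned to envelope offsets (0 where
no peak lies within the fragment tolerance), and the combined score is
the unweighted mean of the precursor score and the average fragment
score. Cosine normalization makes scores invariant to intensity scaling
and confines them to $[0, 1]$.

Enrichment is estimated by grid search: the default SIP grid runs in 1
atom% steps from 2% to 99% plus the natural-abundance point (1.07%),
matching integer-valued reporting; the detection-limit simulation uses a
0.1% grid instead. A grid point is admissible when the most abundant
theoretical precursor peak matches the observed precursor mass within
0.03 Da after one allowed integer parent offset (−4..4 for SIP searches,
−1..3 for regular searches). For speed, all admissible points are ranked
by the precursor-envelope score alone and only the top 3 receive full
fragment scoring; ties in the final score break toward the *lower*
enrichment, the conservative direction for a labeling claim. Searching a
spectrum against a peptide index retains the rank-1 candidate only, with
deterministic tie-breaking (target before decoy, then lower enrichment,
then sequence order).

## Error control and protein inference

Identifications are controlled at a 1% peptide-level FDR against a
concatenated full-sequence-reversed decoy database: PSMs collapse to the
best match per peptide sequence, are sorted by descending score (decoys
first within exact ties, the conservative order), and the largest prefix
with #decoy/#target at or below the level is kept. Proteins are inferred
by greedy set cover (ties by accession order); proteins with identical
observed peptide sets merge into one group, and groups without a peptide
unique to their members are discarded. The protein-level FDR is the ratio
of decoy groups (inferred identically from decoy hits) to target groups.

A protein group is called ¹³C-labeled only on identifications above 10
atom%. The two experiment designs use different replication rules: in the
¹³CO₂ rhizosphere design a group must have at least two *distinct*
labeled peptide sequences in one sample (two PSMs of one peptide do not
count); in the ¹³C-methanol design a labeled protein must appear in at
least two replicates of one incubation triplicate. Labeled peptide atom%
values of a group are clustered into protein isotopologues by
agglomerative merging on cluster means until all pairwise mean
differences exceed 10 atom%. Timepoint comparisons use an exact
Mann–Whitney permutation test (full enumeration up to $n_1+n_2=20$, a
tie-corrected normal approximation with continuity correction beyond),
one-sided by default in the direction of enrichment growing over time.

## Binning

Scaffold features are `log(coverage + 0.01)` per sample concatenated with
canonical (reverse-complement-collapsed) tetranucleotide frequencies (136
dimensions), each column standardized. Scaffolds shorter than 5 kbp are
excluded, mirroring common binning practice. Clustering projects the
features onto principal components covering 90% of variance (capped at 20
and $n-1$) and fits a Gaussian mixture with fixed $k$ (default 10) under
a fixed seed; a spherical/diagonal model family keeps the fit stable at
small $n$, with a seeded k-means fallback for degenerate geometries. A
Gaussian mixture stands in for CONCOCT-style binning, and a deterministic
rule stands in for interactive bin curation: anchors (scaffolds carrying
genes of labeled unique proteins) merge by single linkage at the median
pairwise member distance, and each anchor group claims members within a
radius equal to the 0.90 quantile of member distances to the anchor
centroid, tightened at the first multiplicative gap (ratio > 3) in the
sorted distances. The gap rule is what lets a tight neighborhood exclude
far outliers that a plain quantile would admit; members covered by
several groups go to the nearest centroid so candidate MAGs are disjoint.

Completeness is the percentage of a user-supplied universal single-copy
marker set present at least once on a MAG's scaffolds; contamination is
the percentage of surplus copies. These simplified formulas replace
lineage-specific marker models and are exactly testable by direct
counting. Acceptance rules: untargeted MAGs need >70% completeness and
<10% contamination; targeted MAGs need contamination at or below 5% on
the reported (integer-rounded) scale plus labeled support — at least two
labeled-protein identifications in the ¹³CO₂ design, or one labeled
protein in two replicates of a triplicate in the methanol design. The
support rule counts *identifications*, not distinct proteins: the worked
CO₂ example includes an accepted MAG whose support is one protein
identified three times, which fixes that reading. MAGs at ≥50%
completeness and <10% contamination are classed medium quality, other
accepted MAGs low quality. Taxonomy combines a marker vote (assigned at
≥75% concordance, putative between 50% and 75%) with a 2-of-3 cross-tool
rule that emits the lowest common ancestor of lineages agreeing at the
phylum level (the first rank of a lineage path; labels are opaque
strings).

## Synthetic data: what it emulates and what it does not

The generator produces communities whose genomes differ in dinucleotide
composition (Markov chains with Dirichlet-sampled transition matrices)
and in lognormal per-sample abundance series over a 14-sample design;
scaffolds have lognormal lengths (minimum 1 kbp) and Poisson-noised
coverage. Proteomes are random tryptic proteins placed on scaffolds
without overlap and linked through GFF3; a labeled subset carries true
atom% values (the default pipeline scene labels three proteins at
20/50/95 atom%, spanning the moderate enrichments seen in ¹³CO₂
rhizosphere labeling and the near-complete labeling seen with
¹³C-methanol). Spectra are envelope-level centroided peak lists —
precursor plus b/y fragment envelopes at the true enrichment — with
multiplicative lognormal intensity noise (SNR ≈ 1/sd), optional peak
dropout, and an optional fraction of unmatchable spectra from shuffled
sequences. The generator does not simulate chromatography, charge states
above 3, co-isolation chimeras, profile-mode peaks, or read-level
sequencing; passing tests therefore demonstrate correctness of the
computations under the stated noise model, not robustness to every
artifact of real LC-MS/MS or real assemblies.

Problem sizes in the test suite are desk-scale by design: 50 spectra per
condition for atom% recovery and detection-limit checks, 20 seeded
entrapment searches for FDR control, five-seed binning scenes of 8
genomes × 40 kbp × 14 samples. These sizes give stable statistics while
keeping the full suite fast.

## Design choices on open points

* Peptide length bounds 6–50 residues: standard identifiability bounds
  for tryptic searches; bounds are configurable.
* Only methionine oxidation is supported as a variable modification (the
  modification routinely searched in soil metaproteomics), with one
  oxidized variant indexed per peptide.
* I and L are distinct residues throughout (they are isobaric, but
  collapsing them is an inference-time concern, left off by default).
* The ≥2-peptide labeling rule requires distinct peptide sequences, the
  stricter reading.
* Targeted contamination uses ≤5 on the reported integer scale: printed
  quality tables round to integers, and the worked methanol example
  contains an accepted MAG printed at exactly 5%.
* The envelope truncation applied during convolution is numerical only
  ($10^{-15}$), with the user-facing cumulative cutoff applied once at
  the end — keeping the oracle-equivalence property exact for small
  formulas.

## Known limitations

Semi-tryptic and open-modification searches, chimera deconvolution,
retention-time modeling, profile-likelihood abundance ratios, GO-graph
propagation (the functional aggregation uses a flat term map), and
¹⁵N/²H/¹⁸O labeling are out of scope; the enrichment architecture keeps
the element pluggable for future ¹⁵N reuse. MAGs without any marker hits
get completeness/contamination of zero rather than an alternative
estimate and should be treated as "no-marker" cases. The binning stand-in
reproduces acceptance thresholds and deterministic refinement, not the
judgment of interactive curation.
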