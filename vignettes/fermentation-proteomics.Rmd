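---
title: "Methods: temporal proteomics of brewing fermentation"
author: "fermprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal proteomics of brewing fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermprot)
```

# The analysis problem

Brewing yeast experiences a stereotyped sequence of environments across a
fermentation: oxygenated sugar-rich wort, anaerobic growth, nutrient
exhaustion, a cold crash, and (for repitched yeast) immediate inoculation
into the next batch. `fermprot` analyses label-free proteomics time courses
sampled across such cycles: two batches (a fresh pitch and a serially
repitched culture), around 17 time points, duplicate samples, and on the
order of 2,600 detected proteins. The package covers the full chain from
spectral-count quantification to pathway- and complex-level interpretation,
and ships a synthetic-data generator with known ground truth so that every
stage can be validated without any external dataset.

# Quantification

## Spectral counts to ppm abundances

Peptide-spectrum-match (PSM) counts scale with both protein abundance and
protein length: longer proteins yield more detectable peptides. The ppm
metric corrects for this. Proteins are digested in silico with trypsin
(cleavage after K or R, suppressed before P, zero missed cleavages) and
peptides are kept if 7–40 residues long, the range reliably identified by
the instrument. The *detectable length* \(L_i\) of protein \(i\) is the
summed length of its in-range peptides, and the correction factor is
\(1/L_i\). For peptide-level counts the per-sample protein weight is

\[ w_i = \sum_{p \in i} \mathrm{PSM}_p \cdot \ell_p \cdot \frac{1}{L_i}, \]

and ppm abundance is \(10^6 \, w_i / \sum_j w_j\), so every sample sums to
one million. For protein-level count matrices (the granularity at which
search-engine reports are typically consumed) the per-PSM peptide identity
is unknown; there the weight is the length-normalised spectral count
\(w_i = \mathrm{PSM}_i / L_i\). This is the unique protein-level reading
under which counts generated proportionally to abundance × detectable
length invert back to relative abundance, and it is what makes the
round-trip property hold: ppm computed on counts simulated at depth
\(\ge 10^5\) rank-correlates with the true abundances at Spearman
\(\rho \ge 0.99\). Zero missed cleavages are used because the correction
factor requires a unique, non-overlapping peptide tiling of the protein.
Proteins with no in-range peptide have no defined factor and are excluded
from ppm (with a warning) rather than given a zero factor.

## Filters and normalisation

Downstream analysis applies the filters of the standard workflow:
proteins need at least two unique peptides, and a value is only trusted at
a time point where both replicates detect the protein (discordant values
are masked as missing, never imputed, and never replaced by zero).
Replicates are then summed — a single observed replicate stands alone, so
summing maximises the number of retained proteins. Intensities are
log2-transformed (they are log-normally distributed) and median-centred
per sample; for trajectory analysis each protein is expressed as the log2
ratio to its own mean across time points (row-mean normalisation).

# Statistical analyses

## Differential expression

Pairwise comparisons between time points use a two-sided pooled-variance
Student t-test on log2 values (Welch is available as an option; the
workflow this follows used a plain t-test). P-values are adjusted per
comparison with Benjamini–Hochberg (a global-adjustment mode across all
pairs is provided as an option), and a protein is called differentially
expressed when \(q < 0.05\) and \(|\log_2 \mathrm{FC}| \ge 1\). With two
replicates per time point the pooled test has only two degrees of freedom;
no variance moderation is applied, so power at the study's own design is
intentionally limited — a real caveat of the original design that the
package reproduces rather than hides. Zero-pooled-variance rows get a
missing p-value (flagged) and are excluded from the adjustment, not set to
0 or 1.

## Trajectory clustering by node depth

Proteins changing at least two-fold from their mean (inclusive: a log2
ratio of exactly ±1 is kept, matching the "at least two-fold" reading) are
clustered with average linkage under correlation distance \(1 - r\) (the
default metric for expression rows in the heat-map tool this emulates;
Euclidean is an option). Clusters are extracted by *node depth*: starting
at the root (depth 0), the tree is descended a fixed number of levels, and
every node reached at the target depth — or leaf reached earlier — is one
cluster. Clusters larger than 500 proteins are re-cut at depth 5 relative
to the root. On a near-balanced trajectory tree the depth-3 cut yields
about eight clusters, which is exactly what the default study-scale
simulation produces. The cut is deterministic; `stats::hclust` breaks
merge ties by input order.

Cluster annotation uses a one-sided hypergeometric over-representation
test per term with BH adjustment across terms. The universe defaults to
the detected proteome (not the genome), the standard background choice for
over-representation analysis; it is configurable.

## Pathway perturbation scores

For each reaction of a pathway model, the differential reaction
perturbation score (DRPS) is the maximum over the reaction's measured
entities of the entity's abundance span — the largest absolute difference
between any two samples, equal to max − min. The pathway score is the
root-mean-square over reactions,

\[ \mathrm{DPPS} = \sqrt{\tfrac{1}{R} \sum_r \mathrm{DRPS}_r^2}, \]

with \(R\) the *total* number of reactions in the model (unmeasured
reactions score 0 but stay in the denominator; coverage is reported so
low-coverage pathways can be filtered). Scores are computed on
row-mean-normalised log2 abundances, the representation uploaded to the
original cellular-overview tool, and are invariant to any global shift.
All sample pairs enter the span by default since the study uploaded all
samples; entities in several pathways contribute independently to each.
The leave-out re-ranking masks chosen entities and recomputes every DPPS,
asking which pathways' scores are carried by a few driver enzymes — in the
brewing study, removing the three isobutyraldehyde-pathway enzymes (Bat1,
Bat2, Pdc5) collapsed several amino-acid and pyruvate pathways out of the
top ranks, and the packaged synthetic re-creation shows the same behaviour.

## Co-regulation

Protein–protein Pearson correlations are computed across all samples from
both batches on pairwise-complete observations with a minimum overlap of
three samples (the original analysis does not state its missing-data rule;
pairwise-complete with a small overlap floor is the conservative default).
Zero-variance profiles give missing correlations rather than zeros, so
undefined quantities never enter distribution summaries. Protein pairs
co-occurring in any catalogued complex are "interacting"; all other
defined pairs form the background (complex-portal variants are kept as
discrete complexes; binary interaction lists are two-member complexes).
The two distributions are contrasted with a one-sided Wilcoxon rank-sum
test — an addition of this implementation, since the original presents
only densities. Multi-localised proteins contribute to every compartment
they map to, so no information is lost in compartment-wise summaries.

# The synthetic-data generator

`simulateTimecourse()` draws intensities as
\(2^{(b_i + s_{c(i)}(t) + \delta_i \mathbf{1}[\text{batch}] + u_i(t) +
\varepsilon)}\): a per-protein baseline \(b_i \sim N(20, 2^2)\) in log2
units, a planted trajectory-class effect, a batch-specific offset, a
complex latent factor, and replicate noise — all additive in log2 space,
matching the log-normal behaviour of LFQ data. The defaults are the study
conditions: 2,600 proteins, 7 + 10 time points over two batches, two
replicates (34 samples).

* **Replicate noise** (`replicateNoiseSd = 0.7`). Chosen from the variance
  identity \(r \approx \sigma_b^2 / (\sigma_b^2 + \sigma_n^2)\): with a
  baseline spread of 2 log2 units, 0.7 puts the within-time-point replicate
  correlation at ≈ 0.89, the centre of the reported 0.84–0.94 band, and
  simulation confirms all 17 time points fall inside it.
* **Dropout** (`dropoutRate = 368/2600`). With probability `dropoutRate` a
  (protein, time point) loses exactly one replicate, chosen at random —
  giving the reported average of ~368 single-replicate detections per time
  point. Dropout marks values missing, never zero. Whether missingness
  depends on abundance is not reported; the default is
  abundance-independent (`"mcar"`), with an `"mnar"` mode that tilts the
  odds toward low-abundance proteins.
* **Trajectory archetypes.** Four shapes — early peak, monotone decline,
  late rise, late peak — each spanning `effect` log2 units over
  batch-relative time. They were chosen to mimic the biology (an early
  ribosome-biogenesis burst; declining division machinery; carbohydrate/
  lipid metabolism rising late; a late transient) *and* to form two
  positively correlated pairs with strong cross-pair anticorrelation, so
  the four classes sit in a near-balanced tree and a node-depth cut can
  recover them — a deliberate identifiability choice, since a chain-shaped
  class tree makes any fixed-depth cut mix classes.
* **Complexes.** Members of a planted complex share a latent time-course
  factor \(f_c(t) \sim N(0, 1.5^2)\) with loading \(\lambda\):
  \(u_i = \lambda f_c + \sqrt{1-\lambda^2} g_i\). Two members correlate at
  \(\approx \lambda^2\) before measurement noise, giving a clean dial for
  the co-regulation power analysis (defaults: 20 complexes of 5 at
  \(\lambda = 0.9\)).
* **Batch shift.** 50 proteins gain +1 log2 unit in the repitched batch,
  emulating the batch-specific pathway differences (e.g. ergosterol
  enzymes) seen between a fresh pitch and batch 15.
* One seed governs every draw; the generator restores the caller's RNG
  state, and identical configs are bit-identical. `simulateProteinFasta()`
  draws from an offset of the same seed so sequences are reproducible yet
  independent of the abundance draws.

What the generator does *not* emulate: intensity-dependent
(heteroscedastic) noise, correlated dropout of co-eluting peptides,
protein-group ambiguity, or contaminant dynamics. Passing tests therefore
demonstrate the correctness of the arithmetic and the statistical
operating characteristics under the stated model, not performance on raw
instrument output. One visible consequence: with homoscedastic noise
calibrated to the replicate-correlation band, per-protein noise is larger
than typical low-CV proteins in real data, so pairwise DEP counts at
n = 2 are small at the default settings — the DEP machinery's power is
instead validated at the n = 3, sd 0.3 design used in the operating-
characteristic simulations.

# Numerical choices and degenerate inputs

* ppm columns are conserved to a relative 10⁻⁶; samples with zero total
  weight give an all-missing column with a warning.
* Correlation entries need ≥ 3 overlapping observations; fewer, or a
  zero-variance vector, gives `NA` plus a warning.
* Pathway ranking breaks DPPS ties alphabetically by pathway id, so
  rankings are reproducible on degenerate (all-zero) inputs.
* The two-fold filter and the peptide length filter are inclusive at their
  boundaries (≥).
* BH adjustment excludes missing p-values from the test count.
* All tables are written as plain TSV with a JSON sidecar recording the
  processing state, and the run manifest records parameters, seed, row
  counts and per-file MD5 checksums; equal manifests imply byte-identical
  outputs.

# Problem sizes used in validation

The packaged checks run at sizes chosen to exercise the claims while
staying desk-scale: oracle equivalence on 100 random quantification
instances and 500 random pathway models; digestion on 10⁴ random
sequences; DEP operating characteristics over 1,000 simulated datasets of
1,000 proteins; trajectory recovery on 500 proteins; co-regulation power
on 1,000 proteins with 20 planted complexes and 100 null replicates; and
full-pipeline determinism on a 250-protein fixture.

# Known limitations

* No peptide-to-protein-group inference: protein groups are atomic ids.
* No variance moderation or time-series modelling; tests are pairwise, as
  in the workflow this implements.
* GO semantics (DAG propagation, term reduction) are out of scope; the
  enrichment is a generic over-representation test over user-supplied
  term sets.
* The DPPS reading of "maximum of differences between samples" is the
  parameter-free span (max − min) per entity; the algebraically equivalent
  max-over-sample-pairs form is asserted in the tests.
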