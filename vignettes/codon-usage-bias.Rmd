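---
title: "Quantifying codon usage bias in mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying codon usage bias in mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocub)
library(dplyr)
```

## The question the package answers

Synonymous codons are not used equally. In vertebrate mitochondrial
genomes, two forces compete to shape that bias: **mutation pressure**
(replication and transcription chemistry push base composition in a
particular direction, and synonymous sites simply follow) and **natural
selection** (translational efficiency and accuracy favour particular
codons regardless of the mutational background). `mitocub` implements the
standard battery of statistics used to attribute codon usage bias (CUB) to
one force or the other for a set of annotated mitogenomes, together with
the gene arithmetic needed to get from an annotation to clean codon data,
and a seeded simulator that generates every input the pipeline consumes.

All user-facing functions take data frames (or annotation objects) and
return tibbles, so analyses compose with the pipe; fitted objects carry
`tidy()`, `glance()`, `augment()` and `autoplot()` methods.

## From annotation to codons

Coordinates are 1-based and inclusive at both ends (GenBank convention),
so a feature spanning 11,970–13,805 is 1836 bp. The genome is circular,
but no feature in the supported layouts spans the origin; origin-spanning
locations (and GenBank `join()` locations) are rejected with an explicit
error rather than silently mishandled, because silently unwrapping
coordinates is the classic source of off-by-one codon frames.

Three ingest paths exist: `read_genbank()` for flat files,
`read_feature_table()` for the tabular summaries mitogenome papers print,
and `sim_mitogenome()` for synthetic data. Gene names are normalised to
the short mitochondrial convention (`nad6`, `cox1`, `cytb`, `rrnS`,
`trnL2`, ...) on ingest; Leu/Ser tRNAs are disambiguated by anticodon.
Unknown names pass through with a warning rather than erroring, because
annotation dialects vary more than any fixed map can cover.

`extract_cds()` returns the coding-sense sequence (reverse complement for
light-strand genes). Mitochondrial genes frequently end on an incomplete
stop codon — a terminal `T` or `TA` completed to `TAA` by
polyadenylation of the transcript — recognisable as a feature length not
divisible by 3. The trailing bases are flagged and trimmed by default so
codon-level statistics only ever see whole codons.

Intergenic spacers are computed between consecutive features as
`start(next) − end(prev) − 1`; negative values are gene overlaps (the
7-bp atp8/atp6 overlap is the canonical example). The spacer across the
circular origin is not emitted, matching the linearised presentation of
annotation tables. Where a published table's printed spacer column
disagrees with its printed coordinates, the coordinates win: they are the
primary data, and the spacer is arithmetic.

## The genetic code

All codon-level statistics are parameterised by an NCBI translation
table, default table 2 (vertebrate mitochondrial): stops are
TAA/TAG/AGA/AGG, ATA encodes Met and TGA Trp, leaving 60 sense codons in
which Leu and Ser are 6-fold, Met and Trp 2-fold families. Table 1
(standard) is also supported, mostly for cross-checking against classical
results stated for 61 sense codons. Codon tables come from
`Biostrings::getGeneticCode()`; the package derives families, degeneracy
classes and site tables from them rather than hard-coding.

## The statistics

**RSCU.** `rscu()` computes, per codon, the observed count divided by its
expectation under uniform usage within its synonymous family
(`count × family size / family total`); family sums equal the family size.
Codons with RSCU above 1.6 are called overrepresented and below 0.6
underrepresented — the conventional thresholds; both are arguments. A
codon in a family with zero usage has *no defined* RSCU and is reported
`NA`, never 0: a zero would silently flow into distance calculations.

**ENC.** `enc_observed()` is Wright's effective number of codons: per
synonymous family the homozygosity `F = (nΣp² − 1)/(n − 1)` is estimated
from families with at least two counted codons, averaged within each
degeneracy class, and combined as `N1 + N2/F2 + N3/F3 + N4/F4 + N6/F6`
with class sizes fixed by the code. ENC runs from 20 (one codon per amino
acid) to 61 (uniform usage, standard code; 60 under table 2). A class
with no estimable family borrows its estimate: the 3-fold class as
`(F2 + F4)/2` (the classical rule), any other by interpolating the
per-family effective-codon fraction of the estimable classes — a rule
chosen to be monotone and exact in the all-uniform and all-biased limits.
Sampling noise can push the estimator above the code maximum (a perfectly
uniform finite sample has `F = 0`); the result is clamped to the maximum
and the raw value kept in the `pre_clamp` attribute.

**Expected ENC and the ENC ratio.** The null curve
`ENC_exp = 2 + s + 29/(s² + (1 − s)²)` gives the ENC expected when bias
is driven by third-position composition (GC3s, the GC fraction at
synonymous third positions) alone. Note a denominator one sometimes sees
printed, `s² + (1 − s²)`, is algebraically constant (it collapses to
`31 + s`, a line, contradicting every plotted ENC curve) and is treated
here as a typographical corruption of Wright's `s² + (1 − s)²`; the
printed variant remains available via `enc_expected(..., formula =
"as_printed")` for auditability. The ENC ratio `(exp − obs)/exp`
classifies genes: within ±0.05 of zero (band edges inclusive) the gene
sits on the curve and composition alone explains its bias
("mutation"); outside the band, selection is implicated. A binomial test
(`binomial_test()`, exact tail by pmf summation) asks whether the
selection-called fraction exceeds the 50% chance level.

**GC3s exclusions.** GC3s follows the stated classical definition: third
positions of codons excluding Met, Trp and stops. Under table 2 Met and
Trp are two-codon families, so this definition is not strictly
"synonymous-only" there; a `code_aware` variant excluding only
single-codon families and stops is provided, with `paper`-style exclusion
as the default because it is what the field's tools compute.

**PR2.** `pr2()` plots third-position `A/(A+T)` against `G/(G+C)`;
(0.5, 0.5) is intra-strand parity. Quadrants are numbered 1–4
counter-clockwise from upper-right; points on an axis belong to no
quadrant. Counts are taken over all codons of each gene by default (the
field's common usage); a stricter fourfold-degenerate-only variant can be
had by filtering the codon table before counting, but is not a switch
here because the composition tables expose the raw third-position counts.

**Neutrality regression.** `neutrality_fit()` regresses GC12 (mean GC at
codon positions 1–2, percent) on GC3 and tests the Pearson correlation.
The decision rules operationalise "slope near 1" and "slope much less
than 1", which are verbal in the literature: significant correlation with
the 95% CI of the slope covering 1 → `mutation_dominant`; significant
correlation with the slope's upper CI bound below 0.5 →
`selection_dominant`; non-significant → `uncorrelated`; a significant
slope between those bands → `intermediate`. Both the `alpha` and the 0.5
bound are arguments. R² is reported as the squared Pearson r, which for
simple OLS equals `1 − SSE/SST`.

**Ka/Ks.** `ng86_pair()` implements Nei–Gojobori (1986) counting with
Jukes–Cantor correction — the default behaviour of the standard
population-genetics desktop tools. Site fractions per codon split each
position by the fraction of its three single-nucleotide changes that are
synonymous; changes to stop codons are excluded, so a codon contributes
`3 − (stop mutants)/3` sites. Differences between codons differing at
2–3 positions are averaged with equal weight over all minimal mutational
pathways, excluding pathways through stops (if every pathway crosses a
stop — rare — all pathways are averaged as a fallback rather than
dropping the codon pair). Alignment is assumed given: mitochondrial
orthologs in a family-level comparison are length-conserved, and
re-implementing a codon-aware aligner is out of scope; unequal lengths
are an error. Per-gene summaries default to the mean of defined pairwise
ratios (`ratio_of_means` available), and `kaks_group_contrast()` runs the
Mann–Whitney U test between gene groups (canonically cox1–3 versus
nad1–6 + nad4L).

**Mann–Whitney U.** Implemented in-package: the p-value is exact — full
enumeration of group assignments of the pooled values, which handles ties
without approximation — whenever the number of arrangements
`choose(na+nb, na)` is at most 20,000, and a tie-corrected normal
approximation with continuity correction otherwise. The enumeration-count
bound was chosen over a bound on `na·nb` because the arrangement count,
not the product, is what the computation actually scales with.

**RSCU clustering.** Species RSCU profiles (rows: species; columns: the
60 sense codons in a fixed canonical order — grouped by amino acid,
alphabetical within — so outputs are byte-stable) are compared by squared
Euclidean distance and clustered by group-average linkage (UPGMA).
`upgma()` is implemented in-package because reproducibility requires a
deterministic tie-break (lexicographically smallest cluster-label pair;
clusters are labelled by their smallest leaf), which `stats::hclust` does
not guarantee under permutation of the input; `hclust` serves as an
independent cross-check in the test suite. Undefined RSCU values are
imputed as 0 before distance computation (with a warning), matching
common heatmap practice; a `drop_codon` mode removes the affected columns
instead. Dendrograms export to Newick with leaf branches equal to half
the merge height, preserving the ultrametric.

## The synthetic-data generators

The simulator generates data at the scale and under the conditions of a
family-level mitogenome study (22 species, 13 protein-coding genes), and
its defaults *are* those study conditions — they are not tuning knobs.

`sim_mitogenome()` reuses the packaged annotation layout (13 PCGs, 22
tRNAs, 2 rRNAs, OL and control region, 16,607 bp, 12 coordinate
overlaps including the 7-bp atp8/atp6 overlap) and fills it with
simulated sequence: AT-rich background (A 32%, C 24.5%, T 24%, G 19.5%;
A > C > T > G as observed in fish mitogenomes), real coding sequence in
PCG spans (annotated start codon, stop-free internal codons, annotated
stop or incomplete `T`), light-strand genes stored reverse-complemented.
Start/stop codons are pinned first so that overlapping genes agree on
shared bases; internal codons are then sampled conditional on any bases
already fixed by an overlapping neighbour. What it does *not* emulate:
tRNA/rRNA secondary structure, strand-asymmetric mutation, and real
inter-species homology — each simulated genome is independent, so
cross-species analyses of simulated genomes measure the pipeline's
plumbing, not evolutionary signal.

`sim_neutrality_set()` generates per-gene codon sequences whose
GC12-versus-GC3 relationship is controlled. Each gene draws a GC3
propensity uniformly from 23.8–55.5% (the observed family-level span) and
hits it *exactly* (composition-exact sampling: the number of G/C third
positions is fixed, not binomially sampled), which keeps the regressor
noise-free so slope recovery is limited only by the configured GC12 noise
(default 0.3 percentage points, Gaussian). The mutation-driven regime
sets E[GC12] = GC3 (slope 1, intercept 0); the selection-driven regime
uses slope 0.0625 and intercept 44.16 — a near-horizontal regression of
the kind family-level fish studies report — and third-position identity
preferences of T over A (0.65) and G over C (0.70), which both place
genes in PR2 quadrant 4 and depress the observed ENC below the null curve
(the within-family concentration lowers family heterozygosity), so the
same cohort exercises the neutrality, PR2 and ENC-ratio analyses
coherently. With this noise level the cohort's Pearson r comes out near
0.88. Stop codons arising by chance are removed by swapping third
positions between codons, which preserves the positional composition
exactly. Sequences are 295 codons (the mean mitochondrial PCG length),
286 genes (13 × 22).

`sim_divergent_pair()` / `sim_kaks_genes()` evolve coding sequences by
single-nucleotide proposals accepted with probability 1 if synonymous and
ω if nonsynonymous (stops rejected; for ω > 1 the scheme inverts,
suppressing synonymous acceptance by 1/ω — the simple scheme is only
meaningful for ω ≤ 1, which is the purifying-selection regime of
interest). Recovery is unbiased within sampling error: at 500 codons and
0.2 substitutions per codon, the NG86 estimate recovers ω = 0.1/0.5/1.0
within ±0.1 on average. `sim_kaks_genes()` evolves each species
independently from a per-gene ancestor (a star phylogeny, so pairwise
divergence is the configured total), with per-gene ω targets spanning
0.029 (cox3) to 0.112 (nad2) — the published per-gene means for the six
genes such studies tabulate, mid-range values for the rest — and a
pairwise divergence of 0.3 substitutions per codon, which lands Ks in the
0.3–0.5 range typical of family-level mitochondrial comparisons.

All generators take an explicit integer seed, restore the caller's RNG
state, and are byte-reproducible.

## Numerical choices and degenerate inputs

* Ratios with zero denominators (GC skew of an AT-only sequence, RSCU of
  an unused family, PR2 with no third-position A/T) are `NA`, never 0 —
  downstream code must be able to distinguish "no signal" from
  "balanced".
* Percentages are reported on the 0–100 scale throughout (GC12, GC3,
  GC3s); `enc_expected()` takes a fraction, and the pipeline divides at
  the call site.
* The Jukes–Cantor correction is undefined at proportions ≥ 3/4;
  saturated comparisons yield `NA` with a warning rather than a clamped
  number.
* `neutrality_fit()` refuses fewer than 3 points or a degenerate
  (zero-variance) regressor.
* UPGMA ties are broken lexicographically; RSCU matrix columns are in a
  fixed canonical order; pipeline outputs are byte-identical across
  re-runs with equal inputs.

## Problem sizes

The test suite and the acceptance script run at the study's own scale
where that is cheap (286 neutrality points; 200 seeded replicates for the
regime-recovery and ω-recovery properties; 1000 random codon-count sets
for the ENC oracle equivalence) and at reduced scale where the quantity
being checked does not depend on size (pipeline integration runs use 2–4
simulated genomes; the Ka/Ks cohort uses 8 species × 400 codons, giving
28 pairwise comparisons per gene). These sizes were chosen so each
property is measured with comfortable margin over its tolerance.

## Limitations

* The attribution statistics are descriptive: an ENC ratio outside the
  band or a shallow neutrality slope indicates that composition alone
  does not explain the bias, not which selective agent is responsible.
* The simulator's mutation model is symmetric within its base classes;
  strand-asymmetric replication mutation, codon-position-specific rate
  variation and tRNA co-adaptation are not modelled, so passing the
  recovery tests demonstrates correctness of the estimators under the
  stated generative model, not realism of that model.
* Ka/Ks is counting-based (NG86); maximum-likelihood codon models and
  sliding-window analyses are out of scope, as is codon-aware alignment.
* Phylogenetic inference is out of scope; the RSCU dendrogram is a
  clustering of usage profiles, not a phylogeny, and no bootstrap support
  is computed for it.
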