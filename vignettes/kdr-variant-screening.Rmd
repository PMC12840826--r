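---
title: "Methods: codon-aware resistance-variant screening on a VGSC gene model"
author: "kdrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-aware resistance-variant screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrscreen)
```

## The problem

Target-site insecticide resistance in insects is dominated by point
mutations in the voltage-gated sodium channel (VGSC): kdr substitutions in
the pyrethroid-binding regions PyR1 and PyR2, and distinct substitutions in
domain IV S6 affecting sodium-channel-blocker insecticides (SCBIs) such as
indoxacarb.  Monitoring programmes that resequence field populations end up
with per-site variant observations on a single, very long, multi-exon gene
and need to answer four questions per site: does it change the protein,
where does it sit in the channel, is it a known resistance site under
canonical numbering, and how frequent is it in each population?

`kdrscreen` answers these with a small set of composable operations over an
explicit gene model.  This vignette records the modelling conventions, the
tunable parameters, and the design decisions made where the design was
genuinely open.

## Coordinate systems and the gene model

A `gene_model` couples the sense-strand genomic sequence with ordered,
non-overlapping 1-based inclusive exon intervals.  Three coordinate systems
coexist:

* **genomic** (1..gene length), the system of variant input;
* **CDS** (1..CDS length), the concatenation of exons in genomic order;
* **protein** (1..CDS/3), where position `ceil(cds/3)` is the codon index
  and the terminal stop codon *counts as a position* — a 6414-nt CDS has
  2138 positions.  All residue indices in the package assume this
  convention.

All user-facing coordinates are 1-based inclusive; BED input (0-based
half-open) is converted at the I/O boundary and nowhere else.  Only
plus-strand models are supported: the benchmark gene is handled on its
sense strand as supplied, and minus-strand support is a documented
non-goal.  `genomic_to_cds()` is bijective and order-preserving on exonic
positions (the test suite enumerates every position of the 36.8-kb
benchmark gene to check this); intronic positions carry their distance to
the nearest exon boundary instead of a codon.

## Classification procedure

For an exonic SNP the affected codon is cut from the assembled CDS, the
alternate base substituted at the codon offset, and both codons translated
with the standard nuclear genetic code (no alternative tables).  The
substitution assumes the two remaining codon positions carry the reference
base — the single-SNP assumption matching per-site variant reporting.
Classes are `synonymous`, `nonsynonymous`, `stop_gained`, `stop_lost`,
`intronic`, `flanking`.  Stop changes never enter the dN/dS counts.
Variants on the first or last two bases of an exon are classified by codon
effect but flagged (`near_exon_boundary`); splice-disruption calling is out
of scope.  Multi-allelic sites are represented as separate observations.

The test suite checks the classifier against an independently hand-coded
64-entry codon table over all 64 x 9 = 576 single-base substitutions.

## Topology and canonical numbering

A `topology_map` is an ordered set of labelled protein intervals using the
field's grammar (`D II-S5`, `D II-S45-L`, `D II-III-L`, `D IV < L`).  The
shipped configuration for the benchmark gene uses the domain partition
D I = 1–415, D II = 416–1029, D III = 1030–1560, D IV = 1561–2138
(cumulative 415/614/531/578 residues, each block containing the preceding
inter-domain linker plus S1–S6).  Segment-level boundaries inside the
blocks are not published for this gene; the shipped values respect the
block partition, the physical S1→S6 ordering and the region label of every
benchmark variant, and are otherwise arbitrary and user-editable.
Constructing the file is a constraint check, not a fit to hidden data.

Canonical (house-fly style) numbering is supplied as piecewise interval
offsets (`canonical = native + offset`), not computed by alignment — an
alignment-derived map is a possible extension.  The benchmark map encodes
the survey's cross-species equivalences verbatim: 922→918 and 1018→1014
(offset −4), 933 identity, and 1845→1851 (offset +6).  These offsets are
mutually inconsistent (the +6 has the opposite sign and the reference
species of each numbering is unstated); the package deliberately does not
reconcile them.

**Known-site matching.**  A catalog entry is `refAA + position + altAA`
plus a binding-site tag and compound class.  A *full* match requires
amino-acid equality and position equality under **either** the canonical or
the native numbering.  The native fallback is needed because resistance
catalogs mix numbering systems: sites first described in a given species
(the SCBI site V1845I, the PyR2 site T933I) are cited by that species' own
residue numbers, so canonical-only equality would reject a textbook match
whenever the canonical map carries a nonzero offset there.  The matched
numbering system is recorded in the output, and position-only matches
(different substitution at a known residue) are always reported separately.
The shipped catalog has the four confirmed sites (M918T, L1014F, T933I,
V1845I) plus literature-reported substitutions at the same residues
(M918L/V, L1014S/H/C/W, T929C, T933C/V) flagged `literature-only`.

## Frequency, presence, dN/dS, trend

**Frequency.**  `e = 100·g/(f+g)` percent per variant and population,
where `f`/`g` count observations without/with the change.  The package
treats them as generic observation counts; whether they are read counts or
individual counts in a pooled design does not change any statistic.
Display rounding is 2 dp *half away from zero* (base R's `round()` rounds
half to even and renders `100/800 %` as 0.12 rather than 0.13); statistics
are computed on full precision and rounded only for display.

**Presence.**  A variant is present in a population iff counts were
reported for that cell (an absent cell means "not detected").  A reported
cell with `g = 0` would be counted present-but-unchanged and flagged; the
benchmark contains no such cell, so the choice is inert there.

**dN/dS.**  The ratio of nonsynonymous to synonymous SNP *counts*.  This is
deliberately not an NG86/GY94 codon-model estimator (those are non-goals):
it ignores the unequal numbers of nonsynonymous and synonymous sites per
codon, and population-level SNP counts are not divergence data, so the
output carries a standing caveat.  Regime labels: below 1
purifying-consistent, above 1 positive-consistent, within ±0.1 of 1
neutral-consistent (the band is interpretive and configurable).

**Latitude trend.**  The monitored gradient ("frequency rises southward")
is formalised as the Spearman rank correlation between population latitude
and per-variant frequency, with pairwise deletion of unreported
populations, mid-ranks for ties, an `insufficient-data` flag below 3
points and a `degenerate` flag for constant input.  Spearman was chosen
over Pearson because the claim is ordinal (monotone increase), the
frequencies are bounded percentages, and five populations give no basis
for a linear model.  No significance is attached; it is a descriptive,
artifact-defined statistic.

## The packaged benchmark fixture

`vgsc_fixture()` assembles a full test bed from plain-text files under
`inst/extdata/`: 37 variants (31 sSNP + 6 nsSNP) with per-population
`(f, g)` counts and recorded display percentages for five Hainan
populations of *L. trifolii* (MY, TS, DA, TY, JY, north to south), the
topology/canonical/catalog YAML, and population coordinates.

Two data notes, recorded in the file headers and surfaced in
`fx$errata`:

* one cell (Y866Y, TY) has a recorded display value (22.23) inconsistent
  with its own counts (20/90 → 22.22); the counts are authoritative and
  the package reports the recomputed value;
* the SCBI-site codon change is stored as the single-base substitution
  GTT > ATT (V→I); the two-base variant ATA sometimes printed for this
  site encodes the same isoleucine and cannot arise from one nucleotide
  change.

The gene model is synthetic because the survey's exon coordinates are not
public: 13 exons (seeded from the exon lengths of the 13 sequenced gene
fragments, last adjusted) summing to 6414 nt, 12 introns summing to
30,360 nt, 36,774 nt total, each variant's reference codon planted at its
reported codon index, start ATG, terminal TAA, no internal stops,
GT...AG intron ends.  Everything downstream — variant genomic positions,
classes, labels, frequencies, matches — is recomputed from this model at
run time, so the fixture exercises the same code paths as user data.

## The synthetic-data generator

`simulate_gene()` and `simulate_observations()` produce gene models and
allele-count datasets with known ground truth.  Defaults are fixed at the
benchmark's study conditions and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| populations | the five Hainan sites | the monitored panel |
| `n_variants` | 37 | benchmark variant count |
| `fraction_nonsynonymous` | 6/37 | benchmark class mix |
| `cds_length` / `genomic_length` | 6414 / 36,774 | benchmark gene dimensions |
| `n_exons` | 13 | benchmark exon count |
| `depth_range` | 36–156 | the observed range of per-cell totals `f+g` |
| `missing_rate` | 0.30 | 57 of 185 benchmark cells are unreported |
| `trend_slope` | 3 logit/°lat | scale of the observed kdr gradient (≈58%→91% over 0.65°) |
| `baseline_range` | (−3, 1.5) | spans rare to majority variants at the northern end |

True frequencies follow `logit(p) = baseline + slope·(lat_max − lat)` — a
logistic curve in latitude, an artifact choice since the monitored trend is
stated verbally, not as a model.  Observed counts are
`g ~ Binomial(depth, p)`, `f = depth − g`, cells dropped independently with
probability `missing_rate` (each variant keeps ≥1 cell).  Classes are
planted by rejection: a Bernoulli(`fraction_nonsynonymous`) draw picks the
target class, realised by uniform choice among the codon's single-base
substitutions of that class; codons with no synonymous neighbour (ATG,
TGG) are skipped when a synonymous site was requested, and stop-creating
substitutions are never planted, so planted fractions match in
expectation.  Each simulation consumes one locally scoped RNG stream
derived from the mandatory seed; global RNG state is untouched.

**What the generator does and does not emulate.**  It reproduces the
sampling noise structure (binomial counts at realistic depths), the
missing-cell pattern (independent thinning), and the latitude gradient.
It does **not** emulate read-level error, mapping bias, linkage between
sites, population structure beyond the latitude trend, or non-independent
missingness (in real surveys absence is biological, not random).  Passing
recovery tests on simulated data therefore demonstrates correctness of the
estimators under the stated sampling model, not robustness to those
real-data artefacts.

## Numerical and testing choices

* Rounding: half away from zero at fixed decimals via
  `trunc(|x|·10^d + 0.5)`; exact decimal ties in the data (e.g. 0.125%)
  are representable, so no epsilon guard is applied.
* Interval coverage tests use the Wilson score interval
  (`prop.test(correct = FALSE)`): at depth 100 its coverage oscillates
  tightly around the nominal 95%, whereas Clopper–Pearson is conservative
  (≈97–98%) and would not sit inside a symmetric band around 0.95.
* Degenerate inputs fail loudly with classed conditions
  (`kdr_frame_error`, `kdr_coordinate_error`, `kdr_ref_mismatch`,
  `kdr_undefined_frequency`, `kdr_undefined_ratio`, ...): no silent
  `NaN`/`Inf` propagation; an empty variant file yields a header-only
  output with a warning and success status.
* Ties in extreme-frequency reporting resolve to the first row/column in
  matrix order (variant input order, north-to-south population order).
* Problem sizes in the test suite: full enumeration on the 36.8-kb
  benchmark gene; 576-case classifier oracle; simulation recovery at 50
  variants × 5 populations, depth 100, 20 seeds; Wilson coverage over
  1000 cells across 5 seeds.  These sizes give stable assertions at
  sub-minute runtimes.

## Known limitations

Single gene, plus strand, SNPs only; no phasing, so co-occurring
substitutions (e.g. a putative double mutant sharing identical frequencies
in two populations) cannot be resolved into haplotypes here; dN/dS is a
count ratio; canonical numbering is configuration, not alignment; the
latitude trend is descriptive with five points and should not be read as a
significance test.
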