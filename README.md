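# kdrscreen

Gene-centric screening of insecticide-resistance variants in the insect
voltage-gated sodium channel (VGSC).

## What this is for

Pyrethroids and sodium-channel-blocker insecticides (SCBIs, e.g.
indoxacarb) act on the VGSC, and point mutations in the channel —
*knockdown resistance* (kdr) — are the main target-site mechanism by which
pest populations escape them.  Resistance monitoring therefore reduces to a
concrete computational task: given one gene model (the VGSC genomic
sequence plus its exon structure) and a set of SNPs observed in field
populations, decide for every SNP whether it changes the protein, where it
sits in the channel's domain/segment/linker topology, whether it is a known
resistance site once residue numbering is transferred to the canonical
(house-fly style) coordinates, and how its frequency varies across
populations.

`kdrscreen` implements that pipeline for a single plus-strand gene, with
the leafminer *Liriomyza trifolii* VGSC as its packaged benchmark.  It is
aimed at molecular entomologists and resistance-monitoring programmes that
have per-site variant counts (e.g. from pooled whole-genome resequencing)
and want a reproducible, testable path from raw counts to a resistance
report.

## The statistics at its core

* **Codon-aware classification.**  Exonic SNPs are classified by
  reconstructing the affected codon from the assembled CDS, substituting
  the alternate base at the codon offset, and translating both codons with
  the standard genetic code: synonymous (sSNP), nonsynonymous (nsSNP),
  `stop_gained`/`stop_lost`, or intronic.
* **Change frequency.**  For each variant and population with `f`
  observations lacking the change and `g` carrying it,
  `e = 100 · g / (f + g)` percent.  Display values are rounded to 2 dp,
  half away from zero; statistics always use full precision.
* **Count-based dN/dS.**  `dN/dS = n_ns / n_s`, a raw count ratio (not a
  codon-model estimator).  A value below 1 is reported as
  *purifying-consistent*, with an explicit caveat about interpreting
  population-level SNP counts as a selection signature.
* **Presence summaries.**  A variant is *present* in a population iff
  counts were reported there; the package counts variants shared by all
  populations and private to one.
* **Latitude trend.**  Per variant, the Spearman rank correlation between
  population latitude and frequency (negative = frequency rises
  southward), an artifact-defined descriptive statistic.
* **Known-site matching.**  Native residue numbers are converted through a
  piecewise-offset canonical map and matched against a catalog of known
  kdr/SCBI sites; a full match needs both amino acids and the position to
  agree (under canonical or species-native numbering), position-only
  matches are reported separately.

## Worked example

The packaged benchmark (`vgsc_fixture()`) carries 37 VGSC variants
surveyed in five Hainan populations (MY, TS, DA, TY, JY, ordered north to
south) on a synthetic gene model that realises the reported gene
dimensions.

```r
library(kdrscreen)
fx  <- vgsc_fixture()
gene_lengths(fx$model)
#> $genomic       36774
#> $cds            6414
#> $intron        30360
#> $protein_positions 2138
#> $n_exons          13

eff <- annotate_variants(fx$model, fx$variants)
eff <- add_region_labels(eff, fx$topology)
eff <- add_canonical_positions(eff, fx$canonical)

m <- match_known_sites(eff, fx$canonical, fx$catalog)
m[m$match_type == "full", c("label", "matched_label", "binding_site", "numbering")]
#>   label  matched_label binding_site numbering
#> 1 M922T  M918T         PyR1         canonical
#> 2 T933I  T933I         PyR2         canonical
#> 3 L1018F L1014F        PyR1         canonical
#> 4 V1845I V1845I        D IVS6       native

summarize_variants(eff, fx$counts, populations = fx$populations)
#> <vgsc_summary> 37 variants x 5 populations
#>   nonsynonymous: 6, synonymous: 31, other: 0
#>   dN/dS count ratio: 6/31 = 0.19 [purifying-consistent]
#>   nonsynonymous: 3 in all populations, 2 in exactly one
#>   synonymous: 14 in all populations, 7 in exactly one
#>   max frequency: 100.00% (L1018F: MY)
```

Reading the output: the gene's 6414-nt CDS encodes 2138 protein positions
(terminal stop included); of the 37 variants, 6 change the protein and 31
do not (dN/dS = 0.19, consistent with a channel under strong sequence
constraint); the classic kdr substitution L1014F (native L1018F) is fixed
(100%) in every population; the four confirmed resistance sites are
recovered through the canonical map; and the southernmost populations
carry the highest resistance-allele frequencies (e.g. M922T has Spearman
rho = −1 against latitude).

File-level drivers (`run_annotate()`, `run_summarize()`) and a thin CLI
(`inst/cli/kdrscreen.R`, subcommands `annotate` / `summarize` /
`simulate` / `fixture`) wrap the same functions for FASTA + BED + TSV/VCF
inputs.

## Scope and limits

Plus-strand, single-gene models only; SNPs only (no indels/MNVs, no
phasing or haplotype analysis); dN/dS is a count ratio, not an NG86/GY94
estimator; canonical numbering is supplied as a config map, not computed
by alignment.  See the methods vignette (`vignettes/kdr-variant-screening.Rmd`)
for the modelling choices and their rationale.
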