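---
title: "Codon usage bias analysis with mitocub: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with mitocub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocub)
```

## The problem

Synonymous codons are not used equally. In a set of coding sequences (CDSs)
— here, the shared protein-coding genes of plant mitochondrial genomes —
this codon usage bias (CUB) carries information about the forces acting on
the genome: directional mutation pressure shifts the base composition of all
codon positions together, while translational selection acts on the
synonymous (mostly third) positions only. `mitocub` implements the standard
battery of statistics and diagnostics used to quantify CUB and attribute it
to mutation or selection, plus the bookkeeping around it: CDS screening,
pooled tables, optimal-codon calling, and clustering of genomes by usage
profile.

## Screening

`screen_cds()` keeps features that look like complete, translatable CDSs:

* length strictly greater than 300 bp (the stop codon counts toward the
  length; the threshold is exclusive by a literal reading of the usual
  "length > 300 bp" rule),
* length divisible by 3, ATG start, TGA/TAA/TAG stop,
* no ambiguity codes and no in-frame internal stop — the customary
  screening rules are silent on both, but codon counting requires
  unambiguous, translatable triplets, so such features are excluded and
  logged,
* one copy per gene: the longest, with gene names matched
  case-insensitively and trailing copy suffixes stripped (`nad5-1` ==
  `nad5`), reflecting inconsistent organelle annotation practice.

Every input feature and its outcome is retained in `screen_log()`, so
filtering is auditable. `shared_cds()` intersects gene names across species.

## Statistics

All statistics are computed on sense codons (stop codons excluded; an
`include_stop` flag exists for the positional GC of complete reading
frames). The genetic code defaults to the standard table — correct for land
plant mitochondria — and any NCBI table can be selected.

**RSCU.** For codon $c$ in a family of $n$ synonyms,
$\mathrm{RSCU}_c = x_c / (\sum_{i} x_i / n)$. Values sum to $n$ within each
observed family; unobserved families are absent rather than zero-filled,
so pooled and per-gene tables are comparable.

**Positional composition.** GC1/GC2/GC3 are percentages over counted
codons; GCall is their mean; GC12 the mean of the first two. GC3s and
A3s/T3s/C3s/G3s are restricted to synonymously variable codons (families
with at least two members; Met, Trp and stops excluded). Because the
convention for "GC3" differs between tools, both GC3 (all counted codons)
and GC3s are always computed and reported side by side.

**ENC.** Wright's effective number of codons estimates per-family codon
homozygosity $\hat F = (n\sum \hat p_i^2 - 1)/(n-1)$, averages it within
degeneracy classes, and combines
$N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$, clipped to
$[20, 61]$. Numerical choices: families with fewer than two counted codons
are dropped from their class; a missing three-fold class is imputed as the
mean of the two- and four-fold classes (Wright's own rule); any other
missing class is dropped with the remaining class terms rescaled by family
count; a class at exactly zero homozygosity (maximal diversity, possible in
tiny samples) makes the estimator unbounded and is clipped to 61. These
branches only matter for very small fixtures — real CDSs above 300 bp
populate all classes.

**CAI, CBI, Fop.** All three need a reference. CAI is the geometric mean of
relative adaptiveness weights over synonymously variable codons; CBI is the
Bennetzen–Hall normalized excess of optimal codons over the uniform-usage
expectation (computed over families that contain an optimal codon); Fop is
the plain optimal fraction of synonymous codons. The reference the classic
CodonW outputs were built on is tool-internal and not redistributed here;
`mitocub` instead derives a *self* reference from the data by default:
genes are ranked by ENC, the lowest-ENC decile (strongest bias, putatively
highest expression) is pooled, weights are each codon's pooled count over
its family maximum, and the optimal set holds each family's most-used
codon(s). Any external reference can be supplied via `reference_set()`, and
the profile table records which was used. Consequently CAI/CBI/Fop values
are comparable within an analysis but not across tools with different
references — an unavoidable property of these indices. Observed codons with
zero reference weight are floored at $10^{-4}$ with a warning rather than
collapsing CAI to zero.

## Diagnostics

**Neutrality regression** (`neutrality_fit()`): OLS of GC12 on GC3 across
genes, returned as a model object with `coef`/`predict`/`plot` methods. A
slope near 1 means all positions drift together (mutation pressure); near 0
means the third position varies while selection holds the first two. The
p-value is the two-sided t-test on the slope; the printed interpretation
uses 0.5 as the documented midpoint. No multiple-testing correction is
applied anywhere in the package, matching standard practice for these
single-shot diagnostics; the correlation matrix marks raw p-values at 0.05
and 0.01.

**ENC plot** (`enc_plot_data()`): observed ENC against the expectation
under composition-only bias,
$\mathrm{ENC} = 2 + s + 29/(s^2 + (1-s)^2)$ with $s$ the third-position GC
fraction. Genes below the curve use fewer codons than their composition
explains, implicating selection. The x-axis defaults to GC3s (the classic
choice) with GC3 available by flag, since usage in the literature is
ambiguous; both columns are in every output table.

**PR2 plot** (`pr2_points()`): x = G3/(G3+C3) against y = A3/(A3+T3).
Under strand-symmetric mutation with no selection both ratios are 0.5. The
default restricts third positions to the four-fold degenerate families,
where the third base is free of amino-acid constraint (Sueoka's
formulation); `scope = "all"` gives the literal all-synonymous reading.
Points on an axis or with a zero denominator get an `NA` quadrant and a
warning rather than an arbitrary assignment.

**Optimal codons** (`build_pools()`, `call_optimal()`): genes ranked by
ENC; the lowest decile forms the high-expression pool, the highest the
low-expression pool (low ENC = strong bias = putative high expression, the
standard orientation). Pool size is `ceiling(fraction * n)`, minimum 1,
with ENC ties broken by gene name for determinism — 10% of 21 genes gives
3-gene pools. Codon counts are summed within a pool before RSCU is computed
(pooling, not per-gene averaging). A codon is optimal when RSCU-H > 1 and
$\Delta$RSCU = RSCU-H − RSCU-L ≥ 0.08; the criterion is applied to the
high-pool RSCU, single-codon families are never callable, and the report
carries all intermediate values so calls can be audited. Published tables
built with these rules sometimes bold fewer codons than the stated criteria
admit; `mitocub` therefore reports its own calls alongside any
externally-reported flags (see `medicago_pool_rscu()`) instead of silently
reconciling them.

**RSCU clustering** (`rscu_cluster()`): dissimilarity $1 - r$ (Pearson)
between RSCU vectors over the 59 synonymously variable codons, agglomerated
with average linkage — the common default for correlation distances, and
configurable. Identical profiles sit at distance 0, perfectly anticorrelated
ones at 2. Output includes the `hclust` object and a Newick serialization.

## The synthetic generator

`generate_cds_set()` produces CDS sets with known ground truth so the whole
pipeline can be validated without downloads. All genes start ATG, end TAA,
contain no internal stop, and are deterministic given `seed`.

* **Mutation regime**: each gene draws a composition parameter $\theta$
  uniformly from `gc3_range` (default 0.28–0.58, the span observed in plant
  mitochondrial CDS sets) and samples the G+C probability of *all three*
  codon positions from $\theta$. GC12 therefore tracks GC3 and the
  neutrality slope is close to 1, attenuated slightly (to roughly 0.94 at
  the default sizes) by within-gene sampling noise relative to the spread
  of $\theta$.
* **Selection regime**: amino acids are drawn with frequencies common to
  all genes (uniform by default) and each codon is the family's preferred
  codon with probability `selection_strength` (default 0.5), else uniform
  among synonyms. The preferred set defaults to one U-ending (else
  A-ending) codon per family, mirroring the A/U-ending optimal codons of
  plant organelles. Third-position composition is thereby decoupled from
  the first two positions: the neutrality slope is close to 0 and ENC falls
  below the composition-only curve.

Defaults are 21 genes of 101–500 codons (roughly the size and length range
of a shared mitochondrial CDS set); validation runs use 200 genes of
300–900 codons.

Two honest caveats. First, a small negative residual slope (about −0.07 at
the validation sizes) remains in the selection regime: a codon draw couples
the two axes because non-synonymous codons (AUG, UGG) have fixed, G-ending
third positions, so genes that happen to draw more of them shift GC3
without a matching GC12 shift. Second, per-gene amino-acid variability
(`aa_concentration` finite) re-couples GC3 to GC12 through amino-acid
identity and pushes the slope further negative — with it enabled the regime
no longer models clean decoupling, which is why identical frequencies are
the default. More generally the generator emulates the *statistical*
structure the diagnostics assume (composition gradients, preferred-codon
selection) and none of the biology that real organelle data add: no codon
autocorrelation along genes, no gene-function composition differences, no
RNA editing, no annotation errors beyond what the screening tests inject.
Passing recovery tests therefore shows the estimators work under the
model's assumptions, not that real genomes satisfy those assumptions.

`worked_fixture()` complements the generator with three tiny genes whose
counts, RSCU and positional GC were computed by hand and frozen, serving as
an independent oracle for the arithmetic.

## Pipeline and outputs

`run_pipeline()` chains the stages over one or more genomes (GenBank flat
files, CDS FASTA, or in-memory sets) and writes, per species: screened
FASTA, screening manifest, a per-gene index table (CAI/CBI/Fop/ENC plus
composition), pooled RSCU, neutrality/ENC-plot/PR2 tables, a starred
correlation matrix, and the optimal-codon report; across species: the
shared-CDS manifest, shared optimal codons, and the RSCU dendrogram as
Newick, plus a JSON run report. Numeric formatting follows the field's
table conventions: 4 decimals for RSCU and $\Delta$RSCU, 3 for indices, 2
for percentages; the printed $\Delta$RSCU column equals the printed RSCU-H
minus RSCU-L exactly, so emitted tables are internally consistent at their
own precision. Reruns on identical inputs produce byte-identical tables. A
thin command-line wrapper (`inst/scripts/mitocub-cli.R`) exposes the
pipeline's flag surface for shell use.

## Known limitations

* CAI/CBI/Fop depend on the reference set; absolute values from other
  tools are not reproducible without their exact reference.
* The GenBank reader is a minimal flat-file parser (CDS features,
  join/complement locations, gene/locus_tag qualifiers); records using
  exotic location operators or external references (`accession:a..b`) are
  not supported — extract CDSs to FASTA in that case.
* "Expression" pools are ENC proxies, not measured expression.
* The ENC-plot and PR2 interpretations are qualitative diagnostics; the
  package deliberately reports deviations and quadrant tallies rather than
  significance claims for them.

## A worked miniature

```{r example}
fx <- worked_fixture()
counts <- count_codons(fx$cds$nucleotides[1])
rscu(counts)
enc_expected(c(0, 0.5, 1))
```

```{r pipeline-example}
sets <- list(
  A = generate_cds_set(n_genes = 10, regime = "mixed", seed = 1,
                       species = "A"),
  B = generate_cds_set(n_genes = 10, regime = "mixed", seed = 2,
                       species = "B"))
report <- suppressWarnings(run_pipeline(sets, outdir = tempfile()))
report
```
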