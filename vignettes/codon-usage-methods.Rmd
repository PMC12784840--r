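---
title: "Codon usage bias diagnostics for mitochondrial genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias diagnostics for mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocub)
```

`mitocub` implements the standard battery of codon-usage-bias diagnostics
for animal mitochondrial genomes — RSCU profiles, Wright's effective
number of codons against its mutation-only expectation, the GC12-on-GC3
neutrality regression, and parity-rule-2 coordinates — on top of a
GenBank-aware gene extractor for the invertebrate mitochondrial genetic
code. This vignette explains the models, the conventions and numerical
choices behind each statistic, and what the synthetic-mitogenome
generator does and does not emulate.

## The genetic code and what counts as "synonymous"

All computations use NCBI translation table 5 (invertebrate
mitochondrial): AGA and AGG encode serine, ATA encodes methionine, TGA
encodes tryptophan, and only TAA/TAG terminate. That leaves 62 sense
codons in 20 families whose degeneracy layout differs from the standard
code: ten twofold families (isoleucine among them), six fourfold
families (arginine, reduced to CGN, among them), leucine as the single
sixfold family, and serine as a single eightfold family (TCN plus AGN).

Methionine and tryptophan each have two codons under this code, but the
package follows the entrenched convention of treating them as
single-codon amino acids: their codons are excluded from every
synonymous-site statistic (RSCU, GC3s, third-position tallies, ENC
homozygosities), while still counting toward whole-codon quantities such
as GC1/GC2/GC3 and codon totals. With stops gone and the Met/Trp codons
set aside, 58 codons enter synonymous analyses, and the RSCU matrix has
58 columns.

## Gene extraction

`extract_pcgs()` trusts the CDS annotation: each feature is cut out
(joined across segments for a single origin-wrapping feature on the
circular molecule), reverse-complemented to sense orientation on the
minus strand, and shifted by the `codon_start` qualifier. Mitochondrial
CDS frequently end in an incomplete stop — a bare `T` or `TA` completed
to TAA by polyadenylation — and the extractor recognizes both, trimming
them and recording the variant, alongside complete TAA/TAG stops. Stop
codons (complete or reconstructed) never enter codon statistics. Start
codons, including the atypical ATT/ATA/TTG initiators common in
invertebrate mitochondria, are kept as ordinary codons and translated by
the table rather than being forced to methionine: they are part of the
coding sequence the genome actually uses.

Three conditions abort extraction rather than guess: a post-trim length
that is not a codon multiple (frame error), an internal stop
(annotation inconsistency, reported with its codon index), and a CDS
label that the synonym table cannot map to one of the 13 canonical
protein-coding genes. Genes containing ambiguity codes are dropped with
a warning — deterministic output is worth more here than a salvaged
gene.

## RSCU

For codon $c$ in a family of $n$ synonymous codons with family total
$N$,

$$\mathrm{RSCU}(c) = \frac{\text{count}(c)}{N/n},$$

i.e. observed over expected-under-uniform-usage. Values sum to $n$
within every observed family; 1 means no bias. Codons are classed as
strongly preferred (RSCU > 1.6), rarely used (RSCU < 0.6) or neutral
(boundaries inclusive), the thresholds conventional in codon-usage
studies. A family absent from a tally yields *undefined* RSCU
(`NA`), which is deliberately distinct from 0 — an unused codon in a
family that is present. Species-level profiles pool all protein-coding
genes of a species before computing RSCU, which is the unit on which
cross-species extremes and heatmaps are reported; per-gene profiles are
available for finer work.

## ENC and the mutation-only curve

Wright's effective number of codons summarizes how far usage departs
from uniformity. Per amino acid $a$ with $n_a \ge 2$ observed codons and
usage fractions $p_i$, the homozygosity is
$\hat F_a = (n_a \sum p_i^2 - 1)/(n_a - 1)$; amino acids pool into
degeneracy classes, $\hat F_k$ is the class mean, and

$$\mathrm{ENC} = 2 + \frac{10}{\hat F_2} + \frac{6}{\hat F_4}
  + \frac{1}{\hat F_6} + \frac{1}{\hat F_8},$$

where the leading 2 accounts for Met and Trp and the class sizes follow
the table-5 layout above. Conventions, all deterministic and surfaced in
the `enc_result`:

* $\hat F_a$ needs $n_a \ge 2$ (the formula divides by $n_a - 1$);
  amino acids below that are omitted from their class mean.
* Non-positive $\hat F_a$ (possible in small families, e.g. two codons
  used once each) cannot enter a harmonic term and are likewise
  omitted.
* A class left with no usable homozygosity is imputed as the plain mean
  of the available class values — the simple cross-class mean, applied
  uniformly, rather than family-size-specific heuristics.
* Raw ENC can exceed the sense-codon count when usage is
  over-dispersed; values are clipped at 61, the ceiling fixed by the
  ENC-ratio convention, with `clip = FALSE` available for diagnostics.

The mutation-only expectation at a given synonymous GC content is
$\mathrm{ENC}_{\exp} = 2 + s + 29/\left[s^2 + (1-s)^2\right]$ with
$s = \mathrm{GC3s}$, and the normalized deviation is the ENC ratio
$(\mathrm{ENC}_{obs} - \mathrm{ENC}_{\exp})/(61 - \mathrm{ENC}_{\exp})$.
A small analytic point worth recording: because of the linear $+s$ term
the printed curve is *not* exactly symmetric about $s = 0.5$ — the
symmetric, maximized-at-0.5 part is the curve minus that term, and
$f(0.5+x) - f(0.5-x) = 2x$. The property tests assert exactly that.

## Neutrality regression

Per species, GC12 (mean of positions 1 and 2, dominated by amino-acid
constraint) is regressed on GC3 across its genes by ordinary least
squares. Under pure mutation pressure both respond together and the
slope approaches 1; protein-level selection decouples them and drags
the slope toward 0. The fit reports slope, intercept, $R^2$, the
two-sided $t$-test p-value for the slope, the 95% confidence interval
on $n-2$ degrees of freedom, and Pearson's $r$; the verdict compares
the CI with unity (containing 1: neutral-compatible; entirely below:
selection-constrained; entirely above: positive/relaxed). P-values are
reported raw, per species, without multiple-testing correction — the
convention in this literature, where per-species regressions are read
individually. Fewer than 3 genes, or zero GC3 variance, is a hard
error, not a silent degenerate fit.

## PR2 coordinates

Within-strand parity rule 2 predicts A = T and G = C at selection-free
sites. Each gene is placed at
$\left(G_3/(G_3+C_3),\; A_3/(A_3+T_3)\right)$ from third-position
bases; (0.5, 0.5) is parity. By default only fourfold-degenerate
families (Val, Pro, Thr, Ala, Gly, Arg) contribute, where the third
base carries no amino-acid information — this is also why short genes
can sit at extreme coordinates, since a fourfold tally of a short gene
may hold only a handful of sites. `sites = "synonymous"` switches to
all synonymous third positions for sensitivity analysis. Zero
denominators give flagged `NA` coordinates which species means must
exclude. Both coordinates are emitted and axis assignment is left to
the plotting layer.

## Summary statistics and clustering

`summarize_values()` reports mean, sample SD ($n-1$ — the convention
behind "mean ± SD" reporting), coefficient of variation, range, median,
and the population-moment shape measures $g_1 = m_3/m_2^{3/2}$ and
excess $g_2 = m_4/m_2^2 - 3$. The moment form (not the small-sample
adjusted $G_1/G_2$) is the simplest documented choice and the one most
statistical software defaults trace back to; at the sample sizes in
play (tens of genes) the difference is far inside reporting precision.

Heatmap ordering uses agglomerative hierarchical clustering with
Euclidean distance and complete linkage on the RSCU matrix. Rows are
species by default; a transpose switch clusters codons instead, since
either orientation is a legitimate reading of published codon-usage
heatmaps. Missing cells (absent families) are imputed as 0 for the
distance computation only — never in any statistic — with a warning.
Rows are sorted by label before clustering so ties break
deterministically; complete linkage is monotone, so merge heights are
non-decreasing. The leaf order is exported as Newick text rather than
an image: the package emits plot-ready tables, not figures.

## The synthetic-mitogenome generator

`synthesize_genome()` writes GenBank flat files the ingest module
parses back byte-exactly, which makes every stage testable offline and,
more importantly, testable against *analytic* ground truth
(`ground_truth_stats()`).

The emission model draws codons i.i.d.: an amino acid from a
composition vector, then a codon within its family. The default codon
model is a single GC3 bias parameter $\theta$: G/C-ending codons get
weight $\theta$, A/T-ending ones $1-\theta$. Because every table-5
family splits evenly between G/C- and A/T-ending codons, the implied
GC3s equals $\theta$ exactly, and positions 1–2 are independent of
$\theta$ given the amino acid — which is what makes the closed-form
expectations clean. Explicit per-family weights override $\theta$ when
asymmetric usage is wanted.

Defaults are fixed at the compositional regime of mygalomorph
mitogenomes and are not tuning knobs: 13 protein-coding genes with
arthropod-like lengths (~3,700 codons per genome) on both strands,
ATT/ATA/TTG among the starts, complete and incomplete (T, TA)
terminators, an AT-rich amino-acid palette (elevated Leu/Ile/Phe/Ser),
$\theta = 0.265$ matching the mean synonymous GC content observed
across mygalomorph mitochondrial genes, and a seven-species cohort
whose $\theta$ values (0.18–0.44) span the observed per-species GC3s
range. Placeholder tRNA (22) and rRNA (2) features plus a control
region complete the 37-gene metazoan complement so parsers see
realistic feature tables; their sequences are random AT-rich filler
with no secondary-structure content.

`neutrality_scenario()` builds gene-level data for the two regimes the
neutrality plot is meant to separate. In the mutation scenario each
gene's $\theta$ varies and the amino-acid palette is interpolated
toward a GC-rich one at a rate chosen analytically so expected GC12
rises one-for-one with GC3 — the slope is near 1 by construction (just
below it, since both axes are estimated from finite genes and
errors-in-variables attenuate). In the selection scenario the palette
is fixed, GC12 is flat in expectation, and the slope is near 0.

What the generator does *not* emulate: codon autocorrelation along
genes, amino-acid composition differences among genes of one genome,
strand-asymmetric mutation pressure (so synthetic PR2 clouds center on
(0.5, 0.5) rather than the G-over-C, T-over-A displacement real
mitogenomes show), tRNA/rRNA sequence realism, and the deep
codon-usage asymmetries that push real RSCU values toward 3.5. Passing
recovery tests therefore demonstrates the estimators' correctness and
calibration under a known model — not that real mygalomorph genomes
satisfy that model.

## Problem sizes and tolerances in the test suite

Property tests fix their seeds and use sizes at which the asserted
bounds are sharp rather than lucky: uniform-usage RSCU recovery on a
pooled species profile of thirteen 10,000-codon genes (per-codon
sampling SD ≤ 0.02 for every family); RSCU convergence to the analytic
ground truth at 250,000 codons, where even the rarest fourfold family
(Arg at ~2% amino-acid frequency) has per-codon SD below 0.03 against
the 0.1 bound; ENC equivalence to a brute-force evaluation of the
homozygosity definitions on 200 random tallies at tolerance $10^{-9}$;
and slope-CI coverage over 1,000 replicates per true slope, judged
against binomial sampling bounds. Exact identities (family sums,
formula anchor points such as $\mathrm{ENC}_{\exp}(0.5) = 60.5$,
byte-level round trips) are asserted exactly.

## Limitations

* Extraction trusts the GenBank annotation; mis-annotated CDS
  boundaries propagate into every downstream statistic. Re-annotation
  is out of scope.
* The ENC degeneracy layout follows table 5. Published ENC values
  computed with standard-code layouts (Ile threefold, Arg sixfold,
  no eightfold Ser) can differ by up to roughly one unit for the same
  counts; comparisons across software should check the layout.
* Chi-square tests of categorical codon-class comparisons and
  multivariate analyses (correspondence analysis and relatives) are
  not implemented; the package stops at the four diagnostics above
  plus descriptive statistics and clustering.
* Statistics are only as defined as their denominators: genes made
  entirely of Met/Trp codons, empty fourfold tallies, or expected ENC
  of exactly 61 all yield flagged `NA`, never silent zeros.
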