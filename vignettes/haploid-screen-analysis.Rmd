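---
title: "Haploid gene-trap screen analysis: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploid gene-trap screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapscreen)
```

# The experiment this package models

In a haploid gene-trap screen, near-haploid cells (such as KBM-7) are
mutagenized with a retroviral gene-trap cassette. An integration in the
sense orientation within a gene body truncates the transcript and, because
the cells are haploid, inactivates the gene. The mutagenized pool is
exposed to a stimulus, and cells are sorted by a fluorescent reporter of
the pathway of interest into a *low* tail (reporter off) and a *high* tail
(reporter on) — typically the bottom and top 4% of the intensity
distribution. Insertion sites are then sequenced separately from the two
sorted populations.

The analytic idea: if a gene is required for the reporter response (a
*positive regulator*), cells carrying a disrupting insertion in it cannot
turn the reporter on, so that gene's insertions pile up in the low-sorted
population. Conversely, insertions in *negative regulators* enrich in the
high population.

# The screen statistic

For every gene $g$ the pipeline forms a 2×2 contingency table of unique
sense insertion counts,

| | in gene $g$ | all other genes |
|---|---|---|
| high population | $a$ | $b$ |
| low population | $c$ | $d$ |

and computes:

* a **two-sided Fisher's exact test** P value under the
  minimum-likelihood rule — the sum of hypergeometric point probabilities
  (margins fixed) over all tables whose point probability is at most that
  of the observed table, with a $10^{-7}$ relative tolerance for
  probability ties. This is the rule used by mainstream statistical
  software, so recomputed P values are directly comparable with published
  ones. Point probabilities are evaluated with log-gamma arithmetic
  (`dhyper(log = TRUE)`), which is exact in the exponent and stable at
  screen scale, where margins reach $10^6$.
* **Benjamini–Hochberg** adjusted P values ($P_{adj}$), computed across
  *all* tested genes as a single family (the screen-wide correction).
  The adjustment is delegated to `stats::p.adjust(method = "BH")`; the
  test suite verifies it against a literal transcription of the step-up
  rule.
* the **mutation ratio** $\dfrac{a/(a+b)}{c/(c+d)}$ and the **combined
  count** $a + c$. Plotting ratio (log scale) against combined count gives
  the "fishtail" plot; genes with $P_{adj} < 0.05$ and ratio $< 1$ are
  called positive regulators, ratio $> 1$ negative regulators. Direction
  labels come from the ratio, not from one-sided tests.

Genes with $a = c = 0$ carry no insertions and are untestable; they are
dropped before testing. No minimum-insertion prefilter is applied by
default (`minCombined = 0`), since the published analysis states none.

## Counting conventions

* **Uniqueness.** A unique insertion is one (chromosome, position,
  strand) triple. Position plus strand is the natural identity of a
  single-bp integration site after alignment.
* **Sense-only assignment.** An insertion disrupts a gene only when it
  falls inside the annotated gene span (introns included — gene-trap
  vectors trap in introns) *and* matches the gene's strand.
* **Coordinates.** Files are BED 0-based half-open; in R everything is a
  1-based closed `GRanges`. A site at file position 1000 is outside a
  gene spanning file coordinates [0, 1000).
* **Population totals.** $a + b$ (and $c + d$) count the unique sense
  gene-mapped insertions of a population. Intergenic and antisense
  insertions appear in neither the numerator nor the total.
* **Overlapping genes.** With overlapping annotations, a sense site in
  $k$ genes is counted once per gene but contributes once to the total.
  The simulator's genomes are non-overlapping, so the case arises only
  with user-supplied annotations.

# The screen simulator

`simulateScreen()` implements a deliberately transparent generative
model so that every downstream stage can be tested against known ground
truth:

1. a toy genome of `nGenes` non-overlapping genes with random strands,
   laid head-to-tail with intergenic gaps of $L\,f/(1-f)$ bp (so a
   fraction $f$ of the genome is intergenic);
2. one gene-trap integration per cell, uniform in position and strand —
   an idealization of near-haploid single-integration mutagenesis that
   keeps truth unambiguous for parameter recovery;
3. a log-normal reporter: log-intensity $\mathcal N(\mu, \sigma)$, the
   typical shape of flow-cytometry intensities. If the cell's insertion
   disrupts a planted hit gene (sense orientation, within the body), the
   log-intensity shifts by $-\Delta$ (positive regulator) or $+\Delta$
   (negative regulator) with probability `penetrance`;
4. quantile sorting: cells ranked by intensity (ties broken by cell
   index, for determinism), bottom and top `sortFraction` tails kept;
5. sequencing recovery: each sorted cell's insertion is retained with
   probability `recoveryRate`.

All draws come from one seeded stream; the caller's RNG state is left
untouched, and identical configurations give bit-identical screens.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| `nGenes` | 500 | large enough for a meaningful multiple-testing family, small enough to simulate in seconds |
| `geneLength` | 10 kb | order of magnitude of a compact human gene |
| `intergenicFraction` | 0.5 | roughly half of a mammalian genome is not gene body |
| `nCells` | 1e5 | a desk-scale screen; real screens use ~1e7 sorted cells |
| `sortFraction` | 0.04 | the bottom/top 4% gates used in reporter screens |
| `reporterLogMean`, `reporterLogSd` | 0, 1 | location is irrelevant (only ranks matter); unit log-sd sets the effect scale |
| `effectLogShift` | 3 | a 3σ shift: a strong knockout phenotype that nearly silences the reporter |
| `penetrance` | 0.9 | gene-trap disruption is mostly but not perfectly penetrant |
| `recoveryRate` | 0.8 | library preparation and alignment lose a minority of sorted insertions |

## What the simulator does not emulate

Retroviral integration-site bias, multi-insertion clones, PCR
duplicates, diploid escapers, FACS measurement error beyond the
log-normal reporter, and promoter/5′ trapping. Passing tests on
simulated screens therefore demonstrate the *statistical machinery* —
counting, exact tests, FDR control, direction calls — not robustness to
those real-data artefacts.

# Calibration and the discreteness of exact tests

Under the global null (zero penetrance) the per-gene Fisher P values
should be uniform — but only in the limit of deep per-gene counts. The
test suite verifies uniformity (Kolmogorov–Smirnov) on screens with
roughly 200 combined insertions per gene, comparable to the ~100
mutations per gene of a real genome-wide screen. At shallow depth the
same statistic is *conservative*, not miscalibrated: with ~3 combined
insertions per gene, some 40% of null genes sit at exactly $P = 1$
(the observed table is the mode of its hypergeometric distribution), and
a two-sided KS test against the uniform rejects decisively even though
the false-positive rate at $P_{adj} < 0.05$ is zero. The suite computes
both facts deliberately: sub-uniformity at low counts is a property of
every exact test, and the screen-wide error rate — the quantity that
matters for hit calling — stays controlled at any depth.

Problem sizes used by the test suite and the reproduction script: null
calibration uses 20 replicate screens of 500 genes × 1e5 cells; hit
recovery uses 10 replicates with 5 planted positive regulators
(penetrance 0.9, 3σ effect); the exact-test oracle enumerates all
245,025 tables with both row sums ≤ 30.

# Co-expression partner selection

The co-expression module reproduces a simple atlas screen: load a
gene-by-tissue expression matrix, drop rows with sample variance
(n−1 denominator, the default of `stats::var()`) below 1 — in squared
units of the atlas — correlate every remaining gene to a query gene
(Pearson, via `stats::cor()`), and keep partners with $r \ge 0.7$,
sorted by descending correlation with lexicographic tie-breaks. No log
transform is applied to the atlas values. Duplicate gene identifiers are
collapsed by the row mean before analysis (a `collapse = "max"` option
exists); the published partner count for any given atlas can depend on
this choice, which the original analysis does not document. Downstream
gene-ontology enrichment belongs to external services and is out of
scope; the module exports the ranked partner list those tools consume.

# Assay statistics

**Relative response ratio.** Split-luciferase complementation readings
are normalized between the negative control (empty vector) and the
positive complementation control:
$\mathrm{RRR}(\%) = \dfrac{\text{value} - \text{neg}}{\text{pos} - \text{neg}} \times 100$.
The statistic is invariant under a common gain and offset, so it is
comparable across plates.

**4PL dose-response.** `fit4PL()` fits
$y = \mathrm{bottom} + \dfrac{\mathrm{top} - \mathrm{bottom}}{1 + (\mathrm{EC}_{50}/x)^{\mathrm{hill}}}$
by Levenberg–Marquardt least squares, parameterized internally on
$\log \mathrm{EC}_{50}$ over log-dose for conditioning.
Initialization: plateaus from the response extremes, the hill sign from
the Spearman rank correlation of dose and response, and
$\mathrm{EC}_{50}$ from the dose nearest the half-range crossing — a
recipe that is robust for the 7–8-point titrations these assays use.
The parameterization is aliased — $(\mathrm{bottom}, \mathrm{top},
\mathrm{hill})$ and $(\mathrm{top}, \mathrm{bottom}, -\mathrm{hill})$
describe the same curve — and the data-driven initialization resolves
the alias so the hill sign encodes the curve direction. By construction
the fitted response at $x = \mathrm{EC}_{50}$ is
$(\mathrm{top}+\mathrm{bottom})/2$. The bottom plateau is free by
default because NF-κB reporter assays have a nonzero baseline;
`constrainBottomZero = TRUE` pins it. Each curve is fitted
independently; no parameters are shared across genotypes or conditions.
Published EC50 values for the stimuli behind this kind of assay
(sub-nanomolar for potent agonists, shifting by orders of magnitude in
loss-of-function backgrounds) are context for interpretation, not test
fixtures — the underlying titration data are not published, so the test
suite validates the fitter on synthetic curves: noiseless recovery to
$10^{-6}$ relative accuracy, and median EC50 error under 10% across
100 replicate triplicate titrations with 5% response noise.

# Degenerate inputs and numerical edges

* Fisher tables with a zero row sum are rejected (`degenerate table`);
  callers filter untestable genes first.
* BH rejects P values outside $(0, 1]$.
* `mutationRatio()` returns `Inf` when $c = 0 < a$ (kept in result
  tables, serialized as `inf`) and `NaN` when $a = c = 0$.
* Tied reporter intensities sort by cell index; tied correlations order
  lexicographically; tied point probabilities in the two-sided rule are
  included via the $10^{-7}$ relative tolerance.
* `fit4PL()` refuses flat responses (`flat-curve`) and fewer than 4
  distinct doses, and flags an EC50 outside the observed dose range as
  extrapolated rather than failing.

# Known limitations

* The pipeline starts at insertion coordinates: raw-read alignment and
  insertion calling belong to dedicated aligner pipelines.
* One insertion per cell is an idealization; real libraries contain
  multi-insertion clones whose phenotype attribution is ambiguous.
* The mutation ratio is a descriptive statistic: no confidence interval
  is attached to it, matching its use as a plot coordinate.
* At shallow sequencing depth the exact test is conservative (see
  above); interpret a lack of hits in tiny simulated screens
  accordingly.
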