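---
title: "Methods: the mPAI statistic and its calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mPAI statistic and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpaiR)
```

## The measurement model

A reciprocal (label-swap) SILAC experiment compares two biological states —
here, cancer cells with and without knockdown of a gain-of-function mutant
p53 — by mixing heavy- and light-labeled cells, fractionating them into
cytosol and chromatin, and quantifying each protein as a normalized
heavy/light (H/L) intensity ratio. The design is run twice with the labels
swapped: in run *exp1* the control (mutant-p53-expressing) cells carry the
heavy label, in run *exp2* the light label. The association index for a
protein is

$$\mathrm{mPAI} = \log_2\!\left[(H/L)_{\mathrm{exp1}}\right] -
                  \log_2\!\left[(H/L)_{\mathrm{exp2}}\right].$$

If the protein's abundance is unaffected by the knockdown, both ratios sit
near one and the index is near zero. If its abundance tracks the perturbed
state at fold change $f$, the two log-ratios move in opposite directions
under the label swap, so the index has expectation $2\log_2 f$ while any
label-specific bias common to both runs cancels. The index is antisymmetric
in the two runs and invariant under a common rescaling of both ratios; these
two algebraic identities are asserted as tests.

Because the sign of the index depends entirely on which label carried the
control cells, orientation is mandatory per-file metadata
(`control-heavy` / `control-light`) and is never inferred from the data.
`pair_experiments()` refuses two runs with the same orientation, and accepts
the tables in either argument order.

## From ratios to a per-gene profile

`mpai_profile()` chains the per-fraction steps:

1. **Ingestion filters** (`read_protein_quant()`): rows with a missing or
   non-positive ratio are dropped (their log-ratio is undefined), as are rows
   whose ratio rests on fewer than two peptides — the conventional minimum
   (one unique plus one razor peptide) for a reliable SILAC ratio — and
   decoy/contaminant rows where the table dialect flags them. Every dropped
   row is counted under exactly one reason, and the load report satisfies
   `rows_in = rows_retained + sum(excluded)`.
2. **Pairing**: only proteins quantified in *both* reciprocal runs receive an
   index. Proteins seen in a single run are excluded and counted; no
   imputation is attempted, because no imputation scheme is defensible for a
   statistic defined as a difference of two observed log-ratios.
3. **Gene collapsing**: when several entries map to one gene symbol, their
   indices are averaged arithmetically *on the log2 (mPAI) scale*, not on the
   ratio scale, and the multiplicity is recorded.
4. **Null fit**: the population of collapsed indices is summarized by its
   sample mean and sample standard deviation (n−1 denominator; at thousands
   of genes the denominator choice is negligible, n−1 is simply the
   convention). In a null-dominated study this fit describes the unaffected
   majority and anchors the z-scores.
5. **Classification**: strictly above +1 is `positive`, strictly below −1 is
   `negative`, boundaries inclusive are `neutral`. The fixed ±1 cut
   corresponds to roughly one null standard deviation at the default noise
   scale; `threshold_mode = "fit"` instead derives the cuts as
   $\mu \pm k\sigma$ from the fitted null.

Ratios are assumed already normalized by the upstream search engine, so no
re-normalization is applied by default; `median_center = TRUE` opts into
median-centering of each run's log-ratios for tables that arrive
unnormalized.

## The two-fraction comparison

`join_fractions()` inner-joins the cytosol (x) and chromatin (y) gene
profiles: only genes with both coordinates get a point in the scatter, and
genes seen in one fraction remain in that fraction's own profile (their
count is reported). Each joined gene is assigned a quadrant: `center` when
both coordinates lie inside the ±1 box, otherwise by the sign pair —
`double_positive` (+,+), `chromatin_pos_cytosol_neg` (−,+),
`double_negative` (−,−), `cytosol_pos_chromatin_neg` (+,−). Quadrant
membership outside the center uses sign while the `significant` flag uses
the ±1 box; both are reported because a named protein can sit outside the
box on one axis while its other coordinate is small. A coordinate of exactly
zero on a non-center point counts as positive — a documented tie-break for a
measure-zero case, not a scientific claim.

## Preranked enrichment

`run_enrichment()` tests whether a gene set concentrates at either extreme
of the mPAI-ranked list, using the weighted Kolmogorov–Smirnov running sum:
walking down the list (descending index, ties broken lexicographically by
symbol so the ranking is deterministic), set members add
$|s_i|^p / N_R$ (with $N_R$ the sum of $|s|^p$ over members) and
non-members subtract $1/(N - N_H)$. The enrichment score (ES) is the
extremum of largest magnitude, in $[-1, 1]$; the leading edge collects the
members at or before a positive extremum (or at or after a negative one).

Numerical choices worth stating:

* **Tie rule.** When the positive and negative extremum tie in magnitude —
  which happens systematically when both extrema fall outside the hit runs,
  making each an exact multiple of the miss decrement — the ES resolves to
  the positive extremum. The comparison uses a 1e-9 tolerance so the choice
  cannot flip on floating-point accumulation order; 1e-9 is far below any
  meaningful ES difference and far above double-precision noise.
* **Degenerate sets.** A set covering the whole list has ES = 1 by
  convention; a set whose members all carry a zero score (possible with
  $p>0$) falls back to equal hit increments.
* **Weight.** $p = 1$, the classic weighted statistic, is the default; $p$
  is configurable including 0 (the unweighted KS form).

The null is built by **gene-label permutation**: random same-size gene sets
drawn from the ranked universe. With a single preranked statistic per gene
there is no sample structure to permute, so this is the only available
scheme; it shares the known property that correlated real sets are compared
against an uncorrelated null. Since the null distribution depends only on
the set size, permutations are shared across sets of equal overlap size, and
the ES of a permuted set is evaluated at its hit breakpoints only — an
O(size) computation proven equal (to 1e-12, exhaustively at small list
sizes) to the full running-sum scan.

The nominal p-value is one-sided against the same-sign half of the null
with the add-one correction, $p = (1 + \#\{|ES_0| \ge |ES|\}) / (1 + n)$, so
finite permutations never report zero. The normalized score is
$NES = ES / \mathrm{mean}(|ES_0|)$ over same-sign null scores. Sets are
filtered to overlap sizes 5–500 before testing (the conventional range;
configurable), and results are reported split by direction with a flag at
the nominal $\alpha = 0.01$. No FDR across sets is computed: the reporting
rule of the analysis this package implements is a nominal 1% cut, and
claiming multiplicity control it does not have would be worse than stating
its absence.

## What the simulator emulates — and what it does not

`generate_study()` draws, for each protein with true fold $f$ in a fraction,
$(H/L)_{\mathrm{exp1}} = f\,2^{\varepsilon_1}$ and
$(H/L)_{\mathrm{exp2}} = f^{-1}2^{\varepsilon_2}$ with independent
$\varepsilon \sim N(0, \sigma_r^2)$ — multiplicative log-normal ratio noise
around the reciprocal design. Null proteins use $f = 1$ exactly, so truth
tables carry exact zeros. Dropout removes each protein from each run
independently (missing completely at random).

Defaults, chosen once as a realistic null-dominated fractionation study:

| parameter | default | rationale |
|---|---|---|
| `noise_sd` ($\sigma_r$) | 0.65 | gives a null mPAI sd of $\sqrt2 \times 0.65 \approx 0.92$, the scale seen in real cytosol/chromatin index populations |
| `dropout_rate` | 0.2 | per-run; yields ≈64% of proteins paired within a fraction and ≈41% present in the cytosol×chromatin intersection, matching the proportions typical of two-fraction SILAC overlap |
| `frac_affected` | 0.05 | a perturbation touching a few percent of the proteome |
| `effect_classes` | fold 4 in each direction | clear effects (expected index ±4) populating all four quadrants, including relocalization patterns |
| `n_gene_sets`, `set_size_range` | 50, 10–50 | a small Reactome-like collection |
| signal set | 6 double-positive genes | the size of a coherent replicative helicase complex |

The simulator deliberately does **not** model intensity-dependent
missingness, heavy-tailed ratio noise, peptide-level variance structure,
isotope incorporation efficiency, or correlated noise between fractions.
Consequently, passing tests demonstrate that the pipeline recovers what the
generative model puts in — calibration of the null fit, $2\log_2 f$ effect
recovery, quadrant and enrichment recovery — not that real LC-MS/MS data
satisfy the model. The normal noise model is a stated simplification; real
ratio distributions are heavier-tailed, which would widen the fitted sigma
and make the fixed ±1 cut more conservative.

Reproducibility: a study is generated from a single seeded RNG stream with a
fixed draw order (fraction, then run, vectorized over proteins), so an
identical seed yields a bit-identical study; the gene-set generator uses a
seed offset of 1000 from the study stream so the two outputs are
independently reproducible. Every pipeline TSV records the seed in a `#`
comment header, and each stage writes a JSON manifest with file checksums.

## Problem sizes used by the test suite

The suite exercises calibration at 5000 simulated proteins (null fit,
flagged fraction, effect recovery at folds 2 and 4, quadrant recovery),
p-value uniformity on 200 random sets at 1000 permutations over a
1200-protein null study, exhaustive ES-oracle comparison over all subsets of
ranked lists up to 12 genes, and end-to-end signal-set recovery on a
2000-protein study with 50 decoy sets at 1000 permutations. These sizes give
Monte-Carlo error comfortably inside the asserted bounds while keeping the
whole suite in the tens of seconds. The enrichment-recovery runs use
`dropout_rate = 0` so the injected 6-gene complex is fully observed — the
point of those runs is recovery of a known signal, not robustness to
missingness, which is exercised separately.

## Known limitations

* Protein groups are represented by their first accession; razor-peptide
  reassignment across groups is upstream business the package trusts.
* The ±1 classification cut is a calibrated convention, not a
  multiplicity-controlled test; genes near the boundary should be read via
  their z-scores.
* Gene-label permutation ignores inter-gene correlation within real
  complexes, so nominal p-values for tightly co-regulated sets are
  anti-conservative in the same way as any preranked analysis.
* The scatter export is a static payload; interactive serving is out of
  scope.
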