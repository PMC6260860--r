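---
title: "riboTE methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboTE methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboTE)
```

riboTE analyses paired RNA-Seq and ribosome-profiling count data from a
two-condition bacterial experiment. This vignette is the package's own
account of the statistics it implements: the models and their assumptions,
the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations.

## Count model and normalization

Counts are modeled as negative binomial with mean

$$\mu_{gs} = s_s\, q_g\, 2^{\,x_\text{cond}\beta_g + x_\text{assay}\gamma_g +
x_\text{cond} x_\text{assay}\delta_g}, \qquad
\operatorname{Var} = \mu + \alpha_g \mu^2,$$

where $x_\text{cond} = 1$ for autotrophic samples and $x_\text{assay} = 1$
for RPF libraries. $\beta_g$ is the mRNA condition log2 fold change,
$\gamma_g$ an assay-level offset (library chemistry differs between
RNA-Seq and Ribo-Seq), and $\delta_g$ the translation-efficiency (TE) log2
fold change — the quantity of interest when transcription and translation
decouple.

*Size factors* use the median-of-ratios method: the reference is the
per-gene geometric mean over samples (genes with any zero excluded), and a
sample's factor is the median ratio to that reference. We rescale factors
to geometric mean 1; fold changes are invariant to this representation
choice. The estimator assumes most genes are not differentially expressed
— it absorbs a global shift, so a matrix in which *every* gene changes in
the same direction will fold part of the effect into the factors. Counts
must be raw integers; normalized input is rejected because the method is
meaningless after rescaling.

*Dispersions* are method-of-moments within each (condition, assay)
replicate group on normalized counts, pooled with weights $n-1$, then
shrunk halfway (log scale, `shrink_weight = 0.5`) toward a parametric
trend $\alpha(\mu) = a_0 + a_1/\mu$ fit across genes, floored at
$10^{-4}$. This is a deliberate simplification of DESeq2's empirical-Bayes
machinery: it keeps the estimator reproducible and fully documented at the
cost of less efficient gene-wise shrinkage. Genes whose moment estimate is
nonpositive (under-dispersed, e.g. constant genes) go straight to the
floor — shrinking them toward the trend would manufacture dispersion that
the data do not show. Two replicates per cell is the supported minimum
(the design of the emulated experiment); with $n = 2$ the moment estimate
is noisy and the trend carries much of the information, which is why
null-calibration checks are run with the known generative dispersion.

*Wald tests* fit one mean per group (cell-means parameterization, log
link, size factors as offsets, dispersion fixed) by Newton iteration on
$\eta = \log\mu$; the score is $\sum_i (y_i - \mu s_i)/(1 + \alpha\mu
s_i)$ and the expected information $\sum_i \mu s_i/(1+\alpha\mu s_i)$.
The DE contrast is $\eta_\text{auto} - \eta_\text{het}$ within one assay;
the TE test is the interaction contrast $(\eta_{RPF,a} - \eta_{mRNA,a}) -
(\eta_{RPF,h} - \eta_{mRNA,h})$ with variance summed over the four
independent cells and a *shared* per-gene dispersion across assays.
Two-sided normal p-values are BH-adjusted (our own step-up implementation,
cross-checked against `p.adjust`). DEG and TE-class calls use the
two-fold / adjusted-p < 0.05 convention; no independent filtering and no
LFC shrinkage are applied, keeping the test minimal and auditable.

Degenerate inputs: genes with all-zero counts get $p = 1$, log2FC $= 0$
and a flag. A single group with zero total count has its fitted mean
floored at $0.5/\sum_i s_i$ — the 0.5 pseudo-count on the normalized
scale — for both the point estimate and the Wald standard error; a Wald
statistic at $\hat\mu = 0$ is otherwise undefined. The pseudo-count is not
scale-free, which is why exact invariance properties are stated for genes
with positive cell means.

## Translation efficiency and buffering

The TE point estimate is the replicate-averaged normalized RPF level
divided by the replicate-averaged normalized mRNA level, per condition;
`te_log2fc` is then exactly RPF log2FC − mRNA log2FC on the same means.
Genes with mean normalized mRNA below `mrna_floor` (default 1 normalized
count) in either condition are excluded and flagged rather than reported
with exploding ratios. Significance comes from the interaction Wald test
above; BH is applied across tested (non-excluded, non-zero) genes.

Translational buffering is summarized as the Spearman correlation between
mRNA log2FC and TE log2FC. Two cautions are built into how we test this:
measurement noise in the mRNA estimate enters the TE estimate with
opposite sign, so even independent true effects produce a slightly
negative raw correlation; and a gene with a strong condition effect in
*both* assays has $\delta = 0$ and must not be called a TE change. Both
appear as dedicated checks in the test suite.

The reporter helper implements the assay-side definition: relative TE =
protein fold change / mRNA fold change, rounded half-up to two decimals,
matching how β-galactosidase reporter measurements are reported.

## Stoichiometry

The synthesis-rate proxy for a gene is its mean normalized RPF level; for
a complex, the mean over member genes. Operon 1:1 subunit pairs are
assessed by the Pearson correlation of $\log_{10}$ RPF of first vs second
subunit across operons, per condition; complexes are compared by rate
ratios with an `equimolar` flag at `ratio_tol = 1.5`. No codon-level or
elongation-time correction is applied — the proxy is the footprint density
itself, which is the standard first-order reading of Ribo-Seq.

## 5'UTR folding

UTRs are extracted strand-aware from TSS to CDS start (reverse-complemented
on the minus strand) and transcribed to the RNA alphabet. Folding is a
self-contained Zuker-style dynamic program over the standard V/WM/W
recursions with:

- stacking energies for the six pair types (AU, UA, GC, CG, GU, UG) from a
  packaged TSV (kcal/mol, values adapted from published nearest-neighbor
  stacking estimates; the table is pluggable via `fold_params()`);
- hairpin loops $a + b\,u$ with $a = 4.0$, $b = 0.2$ kcal/mol and minimum
  loop 3 nt;
- bulge/interior loops $a + b\,(u_1+u_2)$ with $a = 2.5$, $b = 0.3$,
  unpaired span capped at 30 nt;
- multiloops $a + b\,k + c\,u$ with $a = 3.4$, $b = 0.4$, $c = 0.1$
  ($k$ branches including the closing pair, $u$ unpaired);
- no pseudoknots, no dangling ends, no temperature dependence.

The empty structure scores 0, so $\Delta G \le 0$ with equality exactly
when no pair forms. Traceback is deterministic: on ties the unpaired
option is preferred (this is what makes $\Delta G = 0 \iff$ no pairs
hold), and among pairings the one with the smaller opening index. The DP
optimum is verified against exhaustive enumeration of all valid structures
for sequences up to 12 nt, scored by an independent loop-decomposition
evaluator — so the model and the optimizer are checked against each other,
not against themselves.

Because the energy parameters are a simplified model, *absolute* ΔG values
differ from any particular published folder; only contrasts between gene
classes are meaningful. UTRs shorter than 8 nt are folded but flagged as
trivially unstructured.

Class comparisons use a two-sided Wilcoxon rank-sum test: exact (classical
Mann–Whitney count recurrence) when both groups have ≤ 25 observations and
no ties, otherwise a normal approximation with tie and continuity
corrections. With ties in a small sample the tie-corrected approximation
is used — full permutation enumeration at $n = 25$ per group is
combinatorially out of reach, and the exact path is validated against full
enumeration at $n = (5, 5)$.

## Metagene coverage profiles

Per gene, coverage is read 5′→3′ over 20 / 50 / 20 bins for
5′UTR / CDS / 3′UTR; bin value = mean per-base coverage in the bin, and
all bins are divided by the gene's mean per-base CDS coverage, making
profiles invariant to library depth. Genes with zero CDS coverage are
excluded. Regions shorter than their bin count are linearly resampled onto
the bin grid. Across genes we report per-bin medians; between conditions
the per-gene statistic is its mean normalized coverage in a region,
compared by rank-sum (default) or, for identical gene sets, optionally a
paired signed-rank test. The rank-sum default matches the convention of
reporting "Wilcoxon rank-sum" for such comparisons; the paired variant is
offered because the gene sets usually are identical. The per-gene
CDS-mean normalization is our choice of scale; any per-gene normalization
constant cancels from within-gene contrasts but changes between-gene
weighting.

## Enrichment and kappa grouping

Term enrichment is the upper-tail hypergeometric test with parameters
$(k, K, n, N)$, BH-corrected, with terms annotated to fewer than
`k_min = 3` universe genes dropped. The universe is the set of annotated
genes in the supplied table, not the genome: unannotated genes carry no
information about term membership and would only dilute $N$.

Enriched terms are grouped by Cohen's κ between their binary
DEG-membership vectors (the universe here is the DEG set itself;
unannotated DEGs count as non-members). Edges where κ ≥ 0.4 define a
graph. Groups are the connected components after removing articulation
terms; each articulation term is then assigned to every adjacent subgroup,
its first assignment primary and the rest secondary. This reproduces the
"term shared by two groups" behavior of seed-based grouping tools while
keeping the partition order-independent; for graphs without articulation
points it reduces to plain connected components. When both membership
vectors are constant (expected agreement 1), κ is defined as 1 for
identical vectors and 0 otherwise.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are the
conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_replicates` | 2 | biological duplicates per condition/assay |
| `base_mean_log_range` | (3, 10) | log2 range of base means $q_g$ |
| `dispersion` | (0.01, 0.5) | per-gene NB dispersion range (a modeling choice; the real per-gene dispersions are unknown) |
| `frac_de` | 0.30 | fraction with a condition effect (≈ the reported DEG fraction) |
| `lfc_condition_sd` | 2 | SD of $\beta_g$, giving fold changes into the hundreds at the tails |
| `frac_te`, `lfc_te_sd` | 0.15, 1.5 | TE-effect fraction and scale |
| `buffering_rho` | −0.5 | latent correlation of $(\beta, \delta)$ |
| `n_operons` | min(30, n/4) | adjacent 1:1 subunit pairs sharing all expression parameters |
| `utr5_length_range` | 20–150 nt | drawn per gene; 3'UTR fixed at 30 nt |
| `hairpin_stem_range` | 4–10 bp | TE-down genes get a planted stem from the upper half |
| `utr5_cov_base` / `utr5_cov_tedown` | 0.2 / 0.6 | 5'UTR/CDS footprint rate ratio, elevated for TE-down genes under autotrophy |

Every gene draws a latent bivariate-normal $(\beta, \delta)$ with
correlation `buffering_rho`; independent DE/TE indicator masks then select
which genes carry each effect, so the TE truth is unambiguous
($\delta_g$ applies to the RPF×autotrophic cell only). For the buffering
*recovery* experiment the canonical run sets `frac_de = frac_te = 1`, so
the planted correlation is the population value being estimated rather
than a masked sub-population property; this was fixed as part of the
experiment design. Each generator operation draws from its own RNG stream
derived from the seed plus an operation tag, so stages are individually
reproducible and reordering stages cannot change results.

RPF counting rule: the generator's counts represent whole-gene footprint
totals; it does not restrict counts to CDS-mapping fragments (coverage
tracks model the UTR/CDS split instead).

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: read-level artifacts (adapter content, MNase
sequence bias, rRNA contamination), multi-mapping, P-site offsets and
frame structure, operons longer than two genes, condition-dependent
dispersion, and UTR sequences with natural compositional bias. Results on
real libraries inherit all of these.

## Problem sizes and numerical choices

The shipped tests and analysis scripts run at desk scale, chosen so the
statistical assertions have adequate power while the whole suite stays
interactive: 1000–3000 genes for calibration checks (type-I error within
±0.015 of 0.05 needs a few thousand null genes), 20 replicate simulations
for bias bounds, 600 genes for the narrative analysis, and folding
enumeration up to 12 nt (the brute-force structure count grows too fast
beyond that). Newton iterations converge to $|{\Delta\eta}| < 10^{-12}$;
traceback equality checks use an epsilon of $10^{-6}$ kcal/mol, far below
the 0.1 granularity of the energy table.

## Limitations

- The dispersion estimator is a documented simplification; with two
  replicates, p-values computed from *estimated* dispersions are
  anti-conservative, which is the known price of plug-in Wald tests at
  tiny $n$. Calibration guarantees are stated at known dispersion.
- The folding model omits dangling ends, coaxial stacking and
  temperature; ΔG values are comparative, not thermodynamic predictions.
- The TE significance test assumes a shared dispersion across assays for
  a gene; assay-specific overdispersion would be absorbed into wider
  nulls.
- Kappa grouping depends on the annotation snapshot; group counts are not
  comparable across annotation versions.
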