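# riboTE

Integrated RNA-Seq + Ribo-Seq analysis of translational regulation in
bacteria grown under two conditions — built for the acetogen use case
(heterotrophic growth on glucose vs autotrophic growth on H₂/CO₂), where
transcriptional induction of CO₂-fixation genes is not always matched by
ribosome occupancy and translation efficiency becomes the interesting
signal.

The package is aimed at microbial systems biologists who have per-gene
count tables from paired mRNA and ribosome-protected-fragment (RPF)
libraries, plus an annotation with transcription start sites, and want the
full downstream chain in one tested place: normalization, differential
expression, translation efficiency with significance, operon subunit
stoichiometry, 5′UTR folding, metagene footprint profiles, and functional
enrichment. A synthetic-data generator with known ground truth makes every
stage verifiable without sequencing data.

## Models

**Counts.** For gene *g* in library *s*,

&nbsp;&nbsp;*K<sub>gs</sub>* ~ NB(μ<sub>gs</sub>, α<sub>g</sub>),&nbsp;
μ<sub>gs</sub> = *s<sub>s</sub>* · *q<sub>g</sub>* ·
2^(x<sub>cond</sub>β<sub>g</sub> + x<sub>assay</sub>γ<sub>g</sub> +
x<sub>cond</sub>x<sub>assay</sub>δ<sub>g</sub>)

with variance μ + αμ². Size factors *s<sub>s</sub>* come from the
median-of-ratios method; dispersions α<sub>g</sub> from a method-of-moments
estimate shrunk halfway (log scale) toward a parametric mean–dispersion
trend. β<sub>g</sub> is the mRNA condition log₂ fold change (Wald test per
assay; DEG = |log₂FC| ≥ 1 and BH-adjusted p < 0.05) and δ<sub>g</sub> is
the **translation-efficiency** log₂ fold change, tested as the
condition × assay interaction of a cell-means NB GLM.

**TE point estimate.** TE = mean normalized RPF / mean normalized mRNA per
condition; translational buffering is the Spearman correlation between
mRNA log₂FC and TE log₂FC.

**5′UTR folding.** A Zuker-style dynamic program under a simplified
nearest-neighbor model (packaged 6×6 stacking table; linear hairpin,
bulge/interior and multiloop penalties; min hairpin 3 nt; no pseudoknots)
returns the minimum free energy ΔG ≤ 0 and a dot-bracket structure.

**Enrichment.** Upper-tail hypergeometric p per functional term with BH
correction, then ClueGO-style grouping of enriched terms by Cohen's κ ≥
0.4 on their DEG-membership vectors.

## Worked example

The in-package reporter helper reproduces the promoter-5′UTR *lacZ*
worked example (mRNA fold change by qPCR, protein fold change by
β-galactosidase assay, autotrophic over heterotrophic):

```r
library(riboTE)
reporter_relative_te(data.frame(
  construct_id = c("ELIM_c1647", "ELIM_c1650", "ELIM_c1491"),
  mrna_fc     = c(1.01, 20.91, 2.75),
  protein_fc  = c(0.62,  0.99, 3.90)))
#>   construct_id mrna_fc protein_fc relative_te
#> 1   ELIM_c1647    1.01       0.62        0.61
#> 2   ELIM_c1650   20.91       0.99        0.05
#> 3   ELIM_c1491    2.75       3.90        1.42
```

A relative TE well below 1 (0.61, 0.05) marks constructs whose 5′UTR
represses translation under autotrophy despite transcriptional induction;
1.42 marks enhanced translation.

The full synthetic study lives in `analysis/` (run in order):

```sh
Rscript analysis/01_simulate.R            # 600-gene ground-truth dataset
Rscript analysis/02_differential_expression.R
Rscript analysis/03_translation_efficiency.R
# ... 04 stoichiometry, 05 UTR folding, 06 metagene, 07 enrichment, 08 reporter
```

which prints, for example:

```
mRNA DEGs: 78 of 600 genes (45 up, 33 down), lfc range [-5.5, 6.6]
translational buffering: Spearman rho = -0.45 (p = 0, n = 600)
heterotrophic Pearson r (log10 RPF, subunit1 vs subunit2) = 0.94 over 30 pairs
median dG: TE-up -8.2 kcal/mol (n=11), TE-down -24.1 kcal/mol (n=8)
TE-down genes (n=17): median 5'UTR occupancy het 0.19 vs auto 0.62, p = 8.57e-10
```

i.e. the pipeline recovers the planted structure: buffering close to the
generative ρ = −0.5, near-unit subunit correlations, more stable 5′UTRs
and elevated autotrophic 5′UTR footprint occupancy on TE-down genes.
Tables land in `results/` with a provenance header (version + config
hash).

## Layout

- `R/` — package code (I/O, simulation, DESeq2-style core, TE,
  stoichiometry, folding, metagene, enrichment, pipeline orchestration);
  `src/` holds the folding DP (Rcpp).
- `analysis/` — numbered narrative drivers over the package.
- `vignettes/riboTE-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, limitations.
- `tests/testthat/` — unit, property and acceptance-grade tests.
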