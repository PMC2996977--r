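---
title: "Calling tissue-dependent differentially methylated regions from methyl-sensitive restriction tiling arrays"
author: "dreamtdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tissue-dependent differentially methylated regions from methyl-sensitive restriction tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamtdmr)
```

## The measurement model

D-REAM-type assays digest genomic DNA with the methyl-sensitive restriction
enzyme HpyCH4IV, whose ACGT recognition site is blocked by CpG methylation.
Fragments flanking *unmethylated* sites are selectively amplified by
ligation-mediated PCR and hybridized to a tiling array, so probes over an
amplified fragment read a higher log intensity. Comparing two tissues probe
by probe around a site therefore reads out the *differential* methylation
of that site: if the site is hypomethylated in tissue $a$ relative to
tissue $b$, probes near it are brighter in $a$.

A tiling probe's raw intensity is dominated by its sequence affinity and
copy number, not by the biology. `fit_affinity_model()` fits, per sample,

$$\log_2 I_p \;=\; \mu + \sum_{k=1}^{25}\sum_{b \in \{C,G,T\}}
  \beta_{k b}\, \mathbb{1}[s_{p k} = b] + \gamma \log_2 c_p + \varepsilon_p$$

(position-specific nucleotide effects with A as reference, plus a
log-linear copy-number term), averages the coefficients across samples,
and standardizes each probe value to
$t = (\log_2 I - \widehat{\text{baseline}})/\hat\sigma$ with
$\hat\sigma = 1.4826 \cdot \mathrm{MAD}$ of the pooled residuals.

The windowed differential score at a site (`site_score()`) pools the
$t$-values of all probes within $\pm w$ bp of the site, across the
replicates of each tissue, and forms

$$S_{ab} = \sqrt{n_a + n_b}\,\left(\mathrm{TM}_\alpha(t_a) -
  \mathrm{TM}_\alpha(t_b)\right)$$

where $\mathrm{TM}_\alpha$ is the symmetric $\alpha$-trimmed mean and
$n_x$ counts contributing probe-replicate values. Positive $S_{ab}$ means
tissue $a$ is relatively hypomethylated at the site. The score is exactly
antisymmetric, $S_{ab} = -S_{ba}$, which guarantees that per-tissue hypo
classifications are disjoint.

This is a deliberately simplified re-expression of the model-based tiling
array (MAT) family of statistics: the original software bins probes by
predicted affinity and standardizes within bins, and its internals are not
exposed by typical downstream analyses. A single global robust scale is
used here instead — simpler, testable, and sufficient for differential
(two-tissue) use, where shared probe effects cancel.

## Threshold calibration from COBRA

Array scores have no intrinsic scale, so calls are anchored to an
independent wet-lab assay. COBRA (combined bisulfite restriction analysis)
bisulfite-converts the DNA, PCR-amplifies, and re-digests; only molecules
whose CpG was methylated retain the restriction site, so the methylation
level is the cut fraction
$\mathrm{level} = \mathrm{cut}/(\mathrm{cut} + \mathrm{uncut})$
(`methylation_level()`).

Calibration (`calibrate_thresholds()`) proceeds per *directed* tissue
comparison (six directions over three tissues):

1. candidate sites are those with directed score strictly greater than the
   prefilter (default 2);
2. a candidate is *confirmed* when its COBRA level in the putatively
   hypomethylated tissue is at least `delta` (default 0.2) below the level
   in the comparison tissue;
3. the calibrated threshold is the *lowest* score among confirmed
   candidates, and sites scoring at or above it are called hypomethylated
   in that comparison (`call_hypo_sites()`; the boundary is `>=` because
   the threshold site itself was confirmed).

No quantitative confirmation margin is printed anywhere upstream of this
package; `delta = 0.2` is this package's choice, is configurable, and with
`delta = 0` the inequality is strict so equal levels never confirm.
Calibration with zero confirmed candidates is an explicit error directing
the user to supply a threshold, never a silent default.

A site is a *tissue-X-hypo* T-DMR when it is called hypomethylated in X
against **every** other tissue (`classify_tissue_hypo()`).

## Gene assignment and summaries

Sites are assigned to genes through the −7 kb / +3 kb TSS flanking window,
measured in transcription direction: offset $= s - \mathrm{tss}$ on the +
strand and $\mathrm{tss} - s$ on the −, assigned iff
$-7000 \le \mathrm{offset} < 3000$ (half-open downstream bound), with
offset ≥ 0 classed downstream. Coordinates are 0-based half-open
throughout, BED on disk. A site inside two genes' windows counts for both
genes, matching per-gene flag reporting. `summarize_genes()` produces the
per-gene and per-tissue flags and the headline percentage of nuclear mt
genes with T-DMRs (rounded to integer percent); `positional_density()`
profiles tissue-hypo sites in 1 kb bins of the window.

Downstream analyses are exact-test machinery: one-sided hypergeometric
tails for category, TF-target, downstream-fraction and composition
comparisons (`fisher_exact()` and friends), and two-sample Wilcoxon
rank-sum tests of expression log2 ratios of the upstream-/downstream-hypo
gene classes against all nuclear mt genes (`position_class_report()`).
Sidedness follows the claimed direction of each comparison and is
switchable; raw p-values are reported without multiple-testing adjustment,
as is conventional for these small targeted families of tests. Motif
scanning is out of scope: TF target sets are consumed either as gene lists
or as binding-site intervals overlapped with the extended gene region
(10 kb upstream of the TSS to 1 kb beyond the 3' end,
`flag_target_genes()`).

## The synthetic stated world

Real D-REAM arrays cannot be bundled, so every stage is exercised on a
generator (`simulate_dream()`) whose defaults describe the emulated study
design and whose ground truth is recorded:

| parameter | default | meaning |
|---|---|---|
| `tissues`, `replicates_per_tissue` | liver/brain/heart, 2 | study shape |
| `n_genes`, `chrom_length` | 500, 8 Mb | one synthetic chromosome |
| `site_density` | 1 per kb | ACGT site frequency (order of 1/256 bp in real genomes; thinned for speed) |
| `probe_spacing` | 35 bp | promoter-array-like tiling of 25-mers |
| `fragment_signal` | 2 log2 units | amplified-fragment gain at a fully unmethylated site |
| `max_fragment_bp` | 1000 | amplified span cap per side (size selection is not printed anywhere; 1 kb keeps signal local) |
| `noise_sd` | 0.3 | replicate log-intensity noise |
| `affinity_sd` | 0.2 | per-position sequence-effect spread; gives probe baseline sd ≈ 0.85 and replicate correlation ≳ 0.93, the QC regime of real arrays |
| `hypo_level`/`hyper_level` | 0.1 / 0.9 | planted contrast 0.8 |
| `frac_tissue_hypo_genes` | 0.12 | planted genes per tissue (disjoint), the order of the real tissue-hypo catalogs |
| `expression_effect` | 2 log2 units | added in-tissue for genes with a planted *downstream* hypo site |
| `tf_planted_fold` | 1.6 | target-set enrichment planted into the hypo gene set |

Two stated-world choices deserve emphasis:

* **Nearest-site signal attribution.** A probe takes amplified-fragment
  signal from its nearest site when within the fragment cap. Consequently
  a planted site closer than about twice the scoring window to a
  neighbouring site would leak differential signal into the neighbour's
  window and lose part of its own. Planting is therefore restricted to
  sites isolated by `planted_isolation_bp` (650 bp) from their
  neighbours, which makes the clean invariant — noise-free planted sites
  score strictly positive, all other sites score exactly zero — hold
  exactly. Genes whose window offers no free isolated site are skipped
  with a warning and excluded from the recorded truth.
* **Private gene slots.** Each gene and its whole 10 kb TSS window live in
  a private slot of the chromosome, so planted signal is unambiguous at
  gene level. Overlapping windows and multi-gene site assignment are real
  phenomena; the calling code supports them and they are exercised by
  dedicated unit fixtures, but the recovery benchmark deliberately avoids
  them so that sensitivity and false-discovery proportion are well
  defined against the planted truth.

What a green synthetic run does *not* establish: robustness to array
spatial artifacts, cross-hybridization, bisulfite conversion failure,
multi-isoform TSS ambiguity, or genome-scale site clustering — none of
which the generator emulates.

## Numerical and boundary choices

* Scoring window ±300 bp, trim 0.10, minimum 4 probes per window,
  repeat-suppression copy cutoff 10 — conventional values for this array
  family; all configurable.
* Windows with too few probes are flagged unusable (`NA` score), never a
  silent zero.
* The candidate prefilter is strict (> 2); the call boundary is `>=` the
  calibrated threshold.
* An exact fit (all residuals zero) floors the residual scale at 1e-8 so
  standardization returns t = 0 rather than NaN.
* Rank-deficient affinity designs degenerate to the identifiable part
  (unidentifiable coefficients zeroed) with a warning.
* Fold enrichment is computed as a single ratio of integer products, so
  `fold × background fraction = set fraction` holds exactly.
* Rank-sum tests enumerate exactly for pooled n ≤ 20 without ties, else
  use the normal approximation with tie correction; all-tied input yields
  p = 1 with a warning.
* Whether the original pairwise comparisons used a one-sided or two-sample
  score mode is not recoverable from published MATscores; the two-sample
  form is used, matching "pairwise tissue comparisons". Similarly,
  "genes with T-DMRs" counts a gene when any assigned site passes in any
  direction, and the expression reference class "All" includes the U/D
  genes; both are the inclusive readings.

## Limitations

The package analyzes pre-extracted probe intensity tables, not raw .CEL
files; expression matrices are consumed after upstream summarization;
conserved-region motif scanning and ortholog mapping are out of scope.
The bundled acceptance machinery reproduces in-package arithmetic and
recovery properties of the stated world — it cannot, and does not try to,
reproduce catalog-scale results that require the real arrays and genome.
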