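---
title: "Methods: divergence and selection profiling of single-copy ortholog pairs"
author: "pogdiv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence and selection profiling of single-copy ortholog pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pogdiv)
```

## The problem

When two closely related taxa have been geographically isolated — the
classic case being congeneric species split between the forests of
eastern Asia and eastern North America — the genes still present as a
single expressed copy in both taxa (putatively single-copy orthologous
genes, POGs) offer a genome-wide window on how much, and under what
selective regime, the two genomes have diverged since isolation.
`pogdiv` implements the complete desk-side pipeline for this question:

1. pair transcripts across the two taxa (reciprocal best hit),
2. extract coding sequence and build codon-aware pairwise alignments,
3. estimate synonymous (Ks) and nonsynonymous (Ka) substitutions per
   site and their ratio for every gene pair,
4. summarize each taxon pair by its Ks peak-frequency value and the
   relative abundance of genes in six Ka/Ks selection categories,
5. test candidate positive-selection genes (Ka/Ks > 2) for spatially
   clustered substitutions, and
6. correlate divergence time, peak Ks, and category abundances across a
   panel of taxon pairs.

A codon-model simulator generates gene pairs, gene cohorts, and
multi-pair panels with known parameters so that every stage is testable
without any sequence download.

## Substitution-rate estimation

The unit of analysis is an in-frame codon alignment with gaps only in
whole-codon units. Gap columns and codon columns containing ambiguous
bases are removed pairwise before counting — the treatment is not stated
in most study descriptions; dropping them pairwise is conservative and
deterministic.

**NG86 counting.** Every codon position contributes (number of
synonymous single-nucleotide changes at the position)/3 synonymous
sites, so S + N = 3 per codon exactly. Mutations that would create a
stop codon are counted as nonsynonymous rather than excised from the
denominator; this keeps the S/N partition exact and matches the common
convention of counting-method implementations. Codon pairs differing at
k positions are resolved by averaging the synonymous/nonsynonymous step
counts over all k! orderings of single steps, with orderings that pass
through a stop codon discarded. Proportions of differences are corrected
for multiple hits with the Jukes–Cantor formula
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$, and standard errors come
from the delta method on the corrected proportion,
$\mathrm{Var}(d) = \frac{9\,p(1-p)}{(3-4p)^2 S}$. The published studies
this mirrors report SEs without naming a formula; the delta-method
variance is the standard large-sample choice.

**kappa.** The transition/transversion rate ratio is estimated from
fourfold-degenerate and nondegenerate codon positions (classified
identically in both sequences), applying the K80 correction within each
class and pooling the transition and transversion distances weighted by
class size: $\kappa = 2 d_{ts}/d_{tv}$. With no usable information the
estimator falls back to a configurable default (2) with a warning; with
no observed transversions it is capped at 99.

**YN00-style counting.** Site counts are reweighted so that each
alternative at a codon position carries weight
$\kappa^{\mathrm{ts}} \times f_p(\text{target base})$, with $f_p$ the
F3x4 position-specific base frequencies estimated from the pair (F1x4
and uniform are available). At $\kappa = 1$ with uniform frequencies the
counts reduce exactly to NG86, which is tested. For codons differing at
several positions, each step additionally carries a factor of the
current $\omega$ when nonsynonymous, and paths are weighted by the
product of their step rates; $\omega$ and the difference counts are
iterated until the change in $\omega$ is below 1e-6 (at most 100
iterations — values unstated in the source studies, matching common
practice). Multiple-hit correction uses the same Jukes–Cantor form as
NG86; simulation recovery (below) shows the residual bias of this
simplification is a few percent at study-scale divergences, well inside
the 15% recovery band the test suite enforces. Both estimators are
always available so either output can be compared externally; the PAML
sequential pair writer allows cross-checking against `yn00` where that
tool is installed.

**Sentinels.** Genes with Ks = 0 and Ka > 0 carry the conventional
ratio sentinel 99; Ka = Ks = 0 gives an undefined (NA) ratio. Both are
removed by `filter_estimates()` before any profiling, mirroring the
standard "remove Ks = 0 and Ka/Ks = 99" rule.

## Selection profile

Ks values are binned into half-open `[lo, hi)` bins of width 0.01. The
*peak Ks* is the midpoint of the modal bin; ties are broken toward the
lower bin with a warning. The *modified peak Ks* merges the modal bin
with an immediately adjacent bin when their frequencies differ by less
than 10% of their combined frequency, returning the shared boundary
(21% vs 19% adjacent bins yield the boundary, since 2% < 10% of 40%);
when both neighbors qualify the closer-frequency one is used — the
source description is silent on multi-way ties.

Ka/Ks ratios are classified into six categories. The published interval
notation is ambiguous at the boundaries, so the package fixes
lower-closed/upper-open purifying bins, a closed near-neutral bin, and
half-open positive bins — a gapless, overlap-free partition that is
exercised by a property test:

| category | Ka/Ks |
|---|---|
| strong purifying | < 0.1 |
| moderate purifying | [0.1, 0.5) |
| relaxed purifying | [0.5, 0.9) |
| near neutral | [0.9, 1.1] |
| weak/moderate positive | (1.1, 2] |
| strong positive | > 2 |

The overall purifying share (Ka/Ks < 0.9) is reported alongside the six
bins.

## Variation-cluster test

For genes with Ka/Ks > 2, the package asks whether their substitutions
are too closely spaced to be explained by chance. The original tool for
this step is not fully specified in the literature that cites it, so
`pogdiv` uses a standard aggregation statistic with the same intent: the
minimal window length containing $\lceil k/2 \rceil + 1$ consecutive
substitution positions (a scan statistic), with a permutation null that
redraws the k positions uniformly without replacement from the
gap-stripped sequence and the add-one p-value
$(1 + \#\{\text{perm} \le \text{obs}\})/(1 + n_{\mathrm{perm}})$
(default 999 permutations). The statistic is deliberately pluggable.
Positions are taken from the gap-stripped global codon alignment rather
than a separate local alignment; for the indel-light regime the package
targets, the difference coordinates are identical. Both nucleotide and
codon coordinates are supported, since tools differ on how multiple
differences within one codon are counted.

Calibration is part of the acceptance suite: under the uniform null the
rejection rate at $\alpha = 0.05$ sits inside the binomial 95% interval
over 1000 genes, and power on genes whose substitutions are confined to
a 5%-of-length window is strictly higher.

## Cross-pair associations

`pearson_r()` wraps the standard Pearson correlation with a two-sided
t-distribution p-value (n − 2 df); the studies this reproduces report r
from a spreadsheet correlation function and a p-value without naming the
test, and the t-form is the standard companion. The pair-level panel
correlates divergence time with (plain and modified) peak Ks and each
category abundance; abundances supplied as counts are normalized to
proportions. The gene-level screen correlates each widely shared gene's
Ka/Ks with divergence time across pairs, with pairwise deletion of
missing pairs (the "shared by ≥ 90% of pairs" design implies tolerated
missingness), dropping ratios of 0 and 99, and summarizes genes passing
|r| > 0.5 by sign.

## The simulator and what it does (not) emulate

Gene pairs evolve under a continuous-time Markov codon model with rates
proportional to
$\kappa^{\mathrm{ts}} \cdot \omega^{\mathrm{nonsyn}} \cdot \pi_{\text{target}}$
and stop codons unreachable. Branch length t is the expected number of
substitutions per codon summed over both branches under the neutral
(ω = 1) normalization, so estimator-recovery targets are well defined.
Ancestral codons are drawn from the equilibrium frequencies; each branch
is simulated exactly (per-codon jump chains), and realized
synonymous/nonsynonymous event counts are logged as ground truth.

Cohort defaults are the package's one-time choices of realistic study
conditions:

* gene length 500 codons (within the average-length range reported for
  assembled POG sets, scaled to codons), optionally drawn uniformly
  from 150–1500;
* category mixture (0.26, 0.51, 0.13, 0.025, 0.06, 0.015) for strong
  purifying, moderate purifying, relaxed purifying, near neutral, weak
  positive, strong positive — inside the ranges reported for allopatric
  transcriptome pairs and ordered as observed there (moderate > strong
  purifying > relaxed > weak positive > near neutral > strong
  positive); per-category ω is drawn uniformly from ranges kept away
  from the category boundaries so estimation noise does not
  systematically relabel genes;
* cohort divergence t = 0.1 expected neutral substitutions per codon,
  placing the bulk of the Ks distribution near 0.03–0.05 — the
  upper-middle of the peak-Ks range observed across real taxon pairs —
  while keeping per-gene ω estimates informative at 500 codons;
* 80% of strong-positive genes concentrate their nonsynonymous rate in
  a contiguous window of 5% of the gene (local ω scaled to preserve the
  gene-wide mean), providing positives for the cluster test.

One property of this design is worth stating plainly: because a
clustered gene's nonsynonymous changes are confined to 5% of its
length, its observable nonsynonymous differences saturate within the
window, capping its *estimated* Ka/Ks well below its true ω once
synonymous divergence is appreciable. At the default cohort divergence
the estimated Ka/Ks > 2 candidate set is therefore dominated by
unclustered genes — a synthetic analogue of the real-data caveat that
small-Ks ratio estimates are unreliable. The demonstration that most
Ka/Ks > 2 genes also test positive for clustering consequently uses a
dedicated shallow cohort (t = 0.05, all positive-selection genes
clustered), where candidacy and clustering coexist.

Panels place 20 taxon pairs evenly across 1.69–10.67 mya (the
divergence-time window of the motivating system) with t = 0.013 × time,
calibrated so peak Ks spans roughly < 0.01 to 0.06 as observed across
real taxon pairs. The category mixture drifts linearly with time —
moderate purifying 0.42 → 0.60, strong purifying 0.32 → 0.17, positive
categories mildly shrinking — so that the canonical association signs
(+ time~peak-Ks, + peak-Ks~moderate, − peak-Ks~strong-purifying,
− peak-Ks~positive) are recoverable by construction; a `mixture_drift =
FALSE` switch provides the null panel.

The simulator emulates substitution processes only: no indels by
default (whole-codon indels are available for alignment tests), no
assembly artifacts, no expression-level variation, no paralogy, no
among-site rate heterogeneity beyond the clustered-window mode, and no
real codon-usage bias unless frequencies are supplied. Passing tests on
simulated cohorts therefore demonstrates correctness of the estimators
and statistics under the model's assumptions, not robustness to
assembly noise or misorthology in real transcriptomes.

## Numerical and design choices

* Stop-codon fraction in the pre-pairing quality filter is evaluated in
  frame 0 of the given orientation (the frame is unstated in pipeline
  descriptions; frame 0 matches a naive contig scan).
* CDS extraction takes the longest ATG-anchored ORF over six frames
  (start-to-stop, or to the frame end when no stop follows), falling
  back to the longest stop-free codon run when no ATG exists anywhere; a
  pass-through mode (`cds = "as_is"`) accepts pre-extracted CDS. This
  replaces HMM-based CDS prediction with a deterministic,
  dependency-free rule adequate for simulated and curated inputs.
* Ortholog pairing uses reciprocal best hits under a deterministic
  local-alignment score (blastn-like match/mismatch 2/−3, affine gaps),
  with lexicographic tie-breaks; graph-clustering orthology inference is
  out of scope because two-taxon single-copy groups are exactly the RBH
  pairs. `pairing = "by_id"` shortcuts pairing for inputs with matching
  ids (simulated cohorts), since all-against-all scoring is quadratic in
  cohort size.
* Protein-level alignment uses BLOSUM62 with affine penalties (open 10,
  extend 0.5), the bundled aligner's canonical deterministic traceback,
  threaded back onto codons.
* Saturation (corrected proportion ≥ 3/4) raises an error rather than
  returning a clipped value; such genes are dropped with a logged
  reason in cohort runs.
* All randomness flows from explicit integer seeds; per-stage streams
  are derived from the root seed, and the caller's RNG state is always
  restored.
* Internally coordinates are 0-based half-open; FASTA/TSV output is
  1-based display only where applicable.

Problem sizes used by the automated checks — 100 replicates of
2000-codon pairs for estimator recovery, 1000 genes for cluster-test
calibration, a 10,000-gene cohort for rank-order recovery, and a
20-pair × 400-gene panel for association signs — are the package's
choices of smallest sizes at which the binomial/sampling error bands in
those checks are meaningful.

## Known limitations

* The YN00-style estimator simplifies the original method's
  class-specific multiple-hit correction to the Jukes–Cantor form; at
  high divergence (Ks ≳ 1) this underestimates Ks more than the
  original. The motivating data live at Ks < 0.2.
* The cluster statistic is a stand-in with the same intent as the
  original (unspecified) tool, not a reconstruction of it.
* Divergence times are inputs; the package does not estimate
  phylogenies or node ages, and the association panel deliberately
  reports raw p-values without multiple-testing correction, as the
  analyses it reproduces do.
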