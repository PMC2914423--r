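---
title: "Integer copy-number calling with contamination and ploidy adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integer copy-number calling with contamination and ploidy adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnarray)
```

## The problem

Array comparative genomic hybridization measures, probe by probe, how much
DNA a sample carries at each genomic position.  Most segmentation tools
stop at "gained / lost" calls.  `cnarray` instead estimates the *integer*
copy number (CN) per cancer-cell genome, which requires untangling three
confounded quantities:

* the (nonlinear) response of probe intensity to the amount of target DNA;
* the average copy number of the genome, because per-sample normalization
  forces the genome-wide mean signal to 2 whether or not the genome is
  diploid (the genome-size factor $\beta$);
* contamination of tumor tissue with benign, diploid cells (the fraction
  $\alpha$), which pulls every signal toward the diploid level.

Distinguishing a homozygous ($c=0$) from a heterozygous ($c=1$) deletion,
or CN 4 from CN 3, is exactly where these corrections matter: at
$\alpha = 0.48$ a homozygous deletion produces the same signal as an
uncontaminated single-copy region (about 1.14), and a CN 4 amplification
produces about 2.73, which sits on the CN 3 level.  `expected_signal()`
reproduces this arithmetic and `test-acceptance.R` asserts it.

## From probe quartets to one signal per SNP

For 500K-class SNP arrays each SNP is interrogated by 6 or 10 probe
quartets (perfect-match and mismatch 25-mers for both alleles).  The
combination pipeline, fitted on a reference panel of diploid samples
(`fit_reference_panel()`), works per SNP:

1. **Background and amplicon-size normalization** (`size_normalize()`).
   $\Delta I = I_{PM} - I_{MM}$, divided by the mean $\Delta I$ of all
   probes on PCR amplicons of the same size within the subarray.  Amplicon
   size is the dominant sample-specific covariate; GC content is not
   modeled.  Size groups with fewer than 20 observations are pooled with
   the nearest size; a group with non-positive mean carries no signal and
   its probes are dropped.
2. **Allele combination** (`estimate_allele_params()`).
   $S_q = k_A I_{qA} + k_B I_{qB}$, with $(k_A, k_B)$ the closed-form
   minimizer of $\sum_G N_G (k_A x_G + k_B y_G - 2)^2$ over the genotype
   classes $G \in \{AA, AB, BB\}$ of the panel ($x_G, y_G$ are class
   medians; lower-median convention for determinism).  The ratio
   $k_A/k_B$ captures uneven allele amplification (panel-typical median of
   $\max(k_A/k_B, k_B/k_A)$ is about 1.4, which the simulator reproduces).
   SNPs homozygous across the whole panel are unidentifiable and excluded.
   X-chromosome SNPs outside the pseudoautosomal regions use female panel
   samples only.
3. **Quartet weighting** (`fit_quartet_weights()`).  Inverse-variance
   weights $w_q \propto 1/\sigma_q^2$ with combined variance
   $\sigma_i^2 = (\sum_q \sigma_q^{-2})^{-1}$; roughly a twofold variance
   reduction versus equal weights at the default noise heterogeneity.
4. **QC and amplicon deduplication** (`qc_filter()`).  SNPs whose panel
   variance $\overline{(S_i - 2)^2}$ exceeds 0.25 are excluded.  SNPs
   sharing a PCR amplicon are averaged and reported once, on the
   lowest-position SNP (the choice is arbitrary but deterministic; the
   probe table needs an `amplicon_id` column for this, otherwise merging
   is skipped).

For 244K-style oligonucleotide arrays the vendor-normalized per-probe
signal is consumed directly (`read_signal_table()`; two-channel input is
converted as $2 \cdot \mathrm{test}/\mathrm{reference}$) and this whole
stage is bypassed.

## The intensity response and the sample model

The expected signal at copy number $c$ in a clean diploid-normalized
sample, $S_0(c)$, is tabulated for $c \le 5$
(0.36, 1.14, 2, 2.72, 3.41, 4.1 — measured on samples of known karyotype,
from a homozygous PTEN deletion up to 49,XXXXX) and continues as
$S_0(c) = 0.314\,c + 3.41$ for $c \ge 8$, calibrated against qPCR
(`qpcr_copy_number()` implements
$CN = 2^{\,1 - C_{Tgc} + C_{Trc} + C_{Tgr} - C_{Trr}}$).  No measurement
exists at $c = 6, 7$; the default fills the gap by linear interpolation
between $S_0(5)$ and the line's value at $c = 8$ (knots 4.707, 5.315),
which keeps the response strictly increasing and continuous to within 0.7
signal units.  The calibration is a config object
(`signal_calibration()`, JSON-serializable), not a constant, so re-fitted
response curves can be swapped in.

A sample is then described by `sample_model()`:
$$S(c) = \beta\,\bigl(2\alpha + (1 - \alpha)\,S_0(c)\bigr),$$
with $\alpha \in [0,1)$ the benign-DNA fraction and
$\beta \in [0.5, 2]$ the genome-size factor.  `normal` mode fixes
$(\alpha, \beta) = (0, 1)$; `cell_line` mode fixes $\alpha = 0$ (a cell
line has no benign admixture); `tumor` fits both; `agilent` fits both but
cannot use genotype-based anchoring.  Since $S_0(2) = 2$, the diploid
level is invariant to $\alpha$ — contamination compresses the scale
around 2 rather than shifting it.

## Estimating $\alpha$ and $\beta$ from histogram peaks

`smooth_signal()` computes $\log T_i = \frac1N \sum_j \log S_j$ over a
centered window of $N = 101$ probes (natural logs; windows truncate at
chromosome ends and never span chromosomes).  The histogram of $T$ with
bin 0.1 (`find_signal_peaks()`) shows one local maximum per copy-number
state present in the sample.  Peak finding merges equal-height plateaus
and keeps sub-threshold peaks flagged rather than dropped (default floor
0.02% of probes — genuinely small CN classes produce very small peaks).

Peak positions are refined by parabolic interpolation through the peak
bin and its two neighbors.  This is a deliberate departure from using raw
bin centers: at high contamination adjacent CN levels are only about
$2\beta(1-\alpha)\cdot 0.35$ apart (about 0.2 at $\alpha = 0.7$), so the
half-bin quantization of a bin-center position is of the same order as
the structure being fitted and demonstrably pushes the fit into wrong
assignments.

`anchor_peaks()` pins peaks to copy numbers before fitting, in order:
(1) a lone maximum is CN 2; (2) first-peak genotyping call rate below 60%
means CN 0 (no DNA, no genotype); (3) first-peak heterozygosity below 3%
means CN 1; (4) if the first peak is CN 0 and the second has
heterozygosity below 3%, the second is CN 1; (5) a maximum at least twice
as high as the runner-up is CN 2.  Conflicts keep the earlier rule's
anchor.  Rules 2–4 consume a per-sample genotype annotation table (the
package never calls genotypes) and are disabled in `agilent` mode or when
annotations are absent; they are also unreliable for heavily contaminated
samples, where benign DNA restores call rates and heterozygosity — the
simulator models exactly that reversion.

`fit_alpha_beta()` then minimizes
$$E_1(\alpha, \beta) = \sum_k H(T_k)\,\bigl(\log T_k - \log S(c_k)\bigr)^2$$
by direct enumeration ($\alpha$ in steps of 0.01 over $[0, 0.99]$,
$\beta$ in steps of 0.005 over $[0.5, 2]$; ties to smaller $\alpha$, then
smaller $\beta$), assigning each unanchored peak the $c_k \le 70$ nearest
in log-signal (ties to the smaller copy number).  The grid steps resolve
the few-percent accuracy the histogram supports; both are configurable.

## Segmentation and iterative refinement

Copy numbers along a chromosome form a hidden Markov chain with states
$0..70$, Gaussian emissions of $\log S_i$ around $\log S(c_i)$ with
variance $\sigma^2$, and a uniform probability $\gamma$ that adjacent
probes differ in state.  `decode_cn_path()` returns the joint
maximum-a-posteriori path by dynamic programming — the single most likely
CN solution, which is what a segment table reports — with cost
$$\sum_i \frac{(\log S_i - \log S(c_i))^2}{2\sigma^2}
  + \lambda \cdot \#\{\text{changes}\}, \qquad \lambda = -\ln\gamma = 54 .$$
The transition cost is uniform over target states (all changes are
treated identically), ties prefer staying in state and, at the final
backtrace, the smaller copy number.  The cap at CN 70 keeps the state
space tractable; chromosomes decode independently.

`refine_cn()` alternates decoding with grid minimization of
$$E_2(\alpha, \beta) = \frac1N \sum_i \bigl(\log S_i - \log S(c_i)\bigr)^2$$
over the same grid with the path fixed, updating $\sigma^2 = E_2$ each
round, until $|\Delta\alpha| < 0.03$ and $|\Delta\beta|/\beta < 0.001$
(at most 20 iterations; a revisited $(\alpha, \beta)$ pair aborts with the
best-$E_2$ iterate and `converged = FALSE`).  $\sigma^2$ is initialized
from the residuals of the raw log signal around the smoothed track's
nearest CN levels, floored at $10^{-4}$.  Peaks are not re-anchored
between rounds.

Because the $E_1$ surface is computed from binned peak positions, two
different peak-to-CN assignments can score within noise of each other in
heavily contaminated samples.  `run_call_pipeline()` therefore refines
from the best few distinct-assignment grid optima (default
`n_restarts = 3`) and keeps the solution with the smallest final $E_2$ —
the full per-probe likelihood arbitrates where the quantized histogram
cannot.  In simulated admixture series this choice is what keeps calls
concordant with the pure sample at $\alpha \ge 0.6$.

A `--no-contamination-adjust` switch (`contamination_adjust = FALSE`)
forces $\alpha = 0$ to demonstrate the failure mode it prevents:
homozygous deletions called heterozygous, CN 4 called CN 3.

## What the simulator emulates — and what it does not

`simulate_reference_panel()` generates quartet-level panels with
Hardy-Weinberg genotypes (allele frequencies uniform on 0.1–0.9, optional
Mendelian trios), per-(sample, subarray, size) amplicon effects,
log-normal allelic gain ratios (sd 0.499, making the median amplification
imbalance about 1.4), and per-quartet noise sds drawn from 0.12–0.72.
Those defaults were calibrated once so that a fitted panel reproduces the
platform-typical medians: combined SNP variance near 0.0376 and a roughly
twofold benefit of inverse-variance weighting.  `simulate_sample()` draws
$S_i = S(c_i)\,e^{\epsilon}$, $\epsilon \sim N(0, 0.097^2)$; the log-sd
0.097 again reproduces the linear-scale diploid variance
$\overline{(S_i-2)^2} \approx 0.0376$.  Genotype annotations follow the
anchoring rules' assumptions (call rate ~35% where $c = 0$,
heterozygosity ~1% where $c = 1$) and revert toward diploid values in
proportion to the benign-DNA fraction at the locus.
`mix_samples()` mixes on the linear signal scale, since DNA quantity is
additive.  Note that mixing a cancer genome whose $\beta_c \ne 1$ at mass
fraction $\alpha$ yields a sample whose model-consistent parameters are
$\beta' = \alpha + (1-\alpha)\beta_c$ and $\alpha' = \alpha/\beta'$; the
pipeline recovers $(\alpha', \beta')$, so a small systematic gap against
the mixing fraction is expected when $\beta_c$ is far from 1.

Not emulated: intra-tumor heterogeneity (all cancer cells share one CN
profile), spatial noise correlation between nearby probes (negligible on
these platforms, strong on very dense custom arrays), copy-neutral LOH,
translocations, GC effects, and real cross-hybridization structure.
Passing tests therefore show correctness of the estimators under the
stated noise model, not robustness to artifacts these factors cause on
real arrays.

## Problem sizes and experiments

The test-suite and `scripts/acceptance.R` operating points, chosen to
exercise every code path at minutes scale:

* default simulated genome: 4 autosomes x 5,000 probes (plus a half-size
  X where sex matters);
* false-call experiment (`experiment_false_alteration_rate()`): 20
  genomes, 10 implanted events each of 7–50 probes at CN 1 or 3, normal
  mode, scored for alterations of at least 7 probes.  At the default
  break penalty the detection threshold is about 7 probes for
  single-copy losses but about 22 probes for single-copy gains (the
  CN 3 level 2.72 is only 0.31 natural-log units above 2), so short
  implanted gains dominate the reported rate;
* admixture experiment (`experiment_contamination_robustness()`): one
  aneuploid genome (segments of 200–800 probes, CN 0–6, about 60%
  diploid, $\beta_c$ drawn from 0.9–1.2) mixed at
  $\alpha = 0.1, \dots, 0.7$, scored by probe concordance against the
  pure sample's calls and by $|\hat\alpha - \alpha|$;
* oracle checks: closed-form allele parameters against a zoomed
  200x200 grid search on 100 random designs; the DP decoder against
  exhaustive path enumeration on 100 random instances of up to 12 probes
  and 6 states.

## Known limitations

Subclonal (non-integer) states are not modeled and bias $\hat\alpha$ when
present.  Above roughly 80% contamination the compressed histogram no
longer identifies $(\alpha, \beta)$.  Small CN classes can fall below the
peak-height floor in very noisy samples.  The break penalty trades
sensitivity for specificity genome-wide; there is no per-size or
per-state tuning.
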