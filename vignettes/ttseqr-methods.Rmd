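---
title: "Models and methods behind ttseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ttseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ttseqr` implements a complete desk-scale analysis chain for transient
transcriptome sequencing (TT-seq) style experiments: a brief
4-thiouridine pulse labels nascent RNA, the labeled fraction is purified
and sequenced alongside a total RNA-seq sample, and the two
measurements, calibrated by spike-ins, resolve RNA synthesis from RNA
degradation.  The package covers strand-specific binned coverage,
antisense-bias correction, HMM genome segmentation into transcription
units (TUs), spike-in calibrated first-order kinetics, differential
synthesis testing, enhancer–promoter pairing inside insulated
neighborhoods, and PWM motif enrichment — plus a synthetic-data
generator with complete ground truth, so every stage can be validated
without any external sequencing data.

# The observation model

All count-level inference rests on one linear observation model.  For
feature $i$ with length $L_i$ and sample $j$:

$$E[k_{ij}] = L_i\,(\sigma_j\,\alpha_{ij} + \epsilon_j\,\beta_{ij})$$

where $\alpha_{ij}$ and $\beta_{ij}$ are the labeled and unlabeled RNA
amounts, $\sigma_j$ the sequencing depth (counts per bp per unit
amount) and $\epsilon_j$ the cross-contamination rate (unlabeled
molecules surviving the purification).  Labeled spike-ins have
$(\alpha, \beta) = (1, 0)$ and unlabeled ones $(0, 1)$, so per-sample
medians of $k_{ij}/L_i$ over the two spike-in classes estimate
$\sigma_j$ and $\epsilon_j$ (`calibrate()`).  The median, not the mean,
is used for robustness; with 8 + 8 spike-ins at counts in the
thousands the relative calibration error is a few percent.

For a total RNA-seq sample labeled and unlabeled RNA are sequenced
identically, so $\sigma_j \approx \epsilon_j$; the convention
$\epsilon_j \equiv 1$ is honored as a *consistent renormalization*: the
factor is kept as a per-sample `scale` and that sample's counts are
divided by it during fitting.  This keeps amounts in absolute spike-in
units, which is what makes the zero-noise round trip exact — an earlier
draft that rescaled only the calibration (not the counts) silently
mixed units across the TT/RNA pair and was caught by exactly that
invariant.

With one TT-seq and one RNA-seq observation the Poisson maximum
likelihood estimate of $(\alpha_i, \beta_i)$ is the solution of the
2×2 linear system (`fit_amounts()`); negative solutions are clamped to
zero and flagged rather than re-fit under constraints, because the
two-observation case makes the clamp transparent and testable.  With
replicates, `fit_amounts_ml()` maximizes the Poisson likelihood under
non-negativity.  Rates follow from first-order kinetics with labeling
duration $t$ (5 min by default):

$$\lambda_i = -\tfrac{1}{t}\,\log\frac{\beta_i}{\alpha_i+\beta_i},
\qquad \mu_i = (\alpha_i+\beta_i)\,\lambda_i,
\qquad t_{1/2} = \ln 2 / \lambda_i.$$

Boundary cases are flagged, not errored, so that vectorized use over
thousands of features survives degenerate rows: $\beta = 0$ reports
$\lambda = \infty$ with $\mu = \alpha/t$; $\alpha = 0$ reports
$\lambda = \mu = 0$; $\alpha = \beta = 0$ reports NA with an
`undefined` flag.  One analytic identity is worth remembering when
sanity-checking output: $\alpha = \beta$ forces $t_{1/2} = t$.

Amounts are fitted per time point (the time series is not pooled):
synthesis is time-varying by design in this system, so pooling would
average over the quantity of interest.

# Antisense correction

Strand-specific library protocols leak a small fraction $c$ of each
strand's real coverage onto the opposite strand.  The model is
symmetric mixing, $obs_s = real_s + c\,real_a$ (and vice versa), whose
inversion is $real_s = (obs_s - c\,obs_a)/(1-c^2)$.  $c$ is estimated
per sample as the median, over positions in strand-specific annotated
regions whose sense coverage exceeds 100, of the pseudo-counted
antisense-to-sense ratio.  The pseudo-count (default 1, applied per
position) biases the estimate upward by roughly
$(bg + 1)/\text{coverage}$, which is negligible at the genome-scale
coverage threshold but visible in very small simulated worlds; the
pipeline test therefore lowers `min_sense` rather than the tolerance.
For coverage profiles the antisense input is first averaged in a
symmetric 51-nt window; for feature counts the corrected values are
rounded to the nearest integer.

# Segmentation into transcription units

Coverage is computed from fragment midpoints in consecutive 200-bp bins
per strand, corrected for antisense bias, incremented by a pseudo-count
of 1, and segmented by a two-state ("transcribed"/"untranscribed")
hidden Markov model with Poisson–log-normal emissions: count $k$ in
state $s$ has likelihood $\int \mathrm{Pois}(k; e^y)\,N(y; m_s,
s_s^2)\,dy$, one independent term per sample track.  The integral is
evaluated by 30-node *adaptive* Gauss–Hermite quadrature, re-centered
per count value at the mode of the integrand; plain (uncentered)
quadrature was measurably inaccurate in the distribution tails (~8%
relative error at $k \approx 50$, caught by the numeric-integration
oracle test).  The M-step maximizes the expected complete-data
log-likelihood numerically on a table of unique count values, so the EM
log-likelihood trace is non-decreasing (asserted to $10^{-6}$).
Initialization splits bins at the 90th percentile of per-bin totals;
states are re-ordered after fitting so state 2 is the transcribed one.
Decoding is posterior (threshold 0.5) rather than Viterbi: posterior
runs give smoother segment calls at bin resolution and the choice is
exposed as a threshold argument.

Called segments receive a mean RPK (reads per kilobase) across tracks,
and a minimal-RPK filter is chosen by maximizing the nucleotide Jaccard
index against the reference annotation over a candidate grid (ties go
to the smallest candidate, i.e. the least filtering).  Boundaries are
refined within ±2 bins by a least-squares two-plateau fit: the
breakpoint minimizing the residual sum of squares becomes the new
boundary, with ties kept at the original position.

Classification applies, in order: the 20%-of-length plus exon-overlap
rule (mRNA/lincRNA, else ncRNA); combining TUs linked to the same gene;
merging ncRNAs ≤ 200 bp (one bin) apart; removing TUs that consume ≥
75% of two or more protein-coding genes (ambiguous); demoting mRNAs
shorter than 5 kb with < 10% protein-coding overlap; and flagging
ncRNAs starting ≤ 1 kb downstream of a protein-coding gene on the same
strand as likely readthrough (excluded from enhancer analyses, not
deleted).  The merge step runs after threshold filtering, in listed
order; the ordering is configurable at the function level since the
source procedure does not fully pin it down.  An ncRNA is promoted to
eRNA when its body or 1-kb (strand-aware) upstream window overlaps an
enhancer-state interval.

# Differential synthesis

Size factors are median-of-ratios restricted to protein-coding units.
Note that the invariance property worth testing is about factor
*ratios*: the absolute scale is pinned by the per-feature geometric
means, so multiplying one sample by $\gamma$ multiplies its factor
relative to the others by $\gamma$, not its absolute factor.

The per-time-point test against 0 min is a deliberate, documented
stand-in for DESeq2: a negative-binomial Wald test with method-of-
moments dispersion pooled across conditions and moderated toward the
trimmed across-feature mean (prior weight 20), size-factor offsets, and
BH adjustment within each contrast.  There is no dispersion shrinkage
curve and no fold-change shrinkage, so headline counts from a genome-
scale DESeq2 analysis are not reproduction targets.  The stand-in is
validated by calibration instead: on a null NB simulation (dispersion
0.05, mean 200, 2 replicates) the empirical type-I error at p < 0.05
must fall in [0.03, 0.07], and planted 4-fold changes must be detected
with power ≥ 0.9 at the FC ≥ 2, adjusted p ≤ 0.05 rule.  Cutoffs are
inclusive (≥, ≤) by default and switchable to strict, since both
conventions appear in common usage.

# Enhancer–promoter pairing

All eRNA × mRNA combinations whose TSSs fall in the same insulated
neighborhood are paired, minus pairs whose eRNA TSS lies within ±1 kb
of the mRNA TSS.  Distances are signed in the mRNA's orientation;
pairs closer than 10 kb are "proximal".  Temporal correlation is
Pearson's r over size-factor-normalized, replicate-averaged TT counts
across the four time points (normalized counts were chosen over raw
counts; with only four points, depth artifacts dominate raw-count
correlations).  The permutation null re-pairs enhancers and promoters
uniformly at random ignoring neighborhoods, with the same number of
pairs, and the p-value uses the add-one estimator
$(\#\{null \ge obs\}+1)/(n_{perm}+1)$; the summary statistic is the
mean pair correlation (median available as an option — the source
analysis compares distributions without naming a scalar).  A
closest-enhancer baseline pairs each promoter with its nearest eRNA TSS
(ties to the smaller coordinate) and contrasts same- versus
different-neighborhood pairs by rank-sum test.

# Motif analysis

PWMs are built from count matrices with a +0.01 pseudo-weight and
log2-odds scores against a uniform background; an occurrence is a
window scoring ≥ 80% of the PWM's maximal score, on either strand by
default (strandedness is not specified by the source procedure, so it
is an argument).  The 80% rule is applied on this package's score
scale, which is documented precisely because score scales differ
between implementations.  `N` scores as the position minimum.
Set-level enrichment counts sequences with ≥ 1 hit in a positive and a
negative set, computes the odds ratio with the Haldane–Anscombe +0.5
correction when a cell is zero, a two-sided Fisher exact p, and BH
correction across PWMs.  The scanner is verified against brute-force
window enumeration (all 4-mers exhaustively, plus random sequences with
Ns), and the Fisher p against a direct hypergeometric computation.

# The synthetic world

`simulate_world()` plants non-overlapping transcripts of four classes
on a toy genome (default 2 × 5 Mb, ~270 transcripts, inter-feature gap
≥ 1.5 kb so that merging and readthrough rules cannot fire across
unrelated units).  Defaults describe the stated experimental design —
4 time points (0/5/10/15 min) × 2 replicates, 5-min labeling — and a
kinetic world chosen to look like an immediate-response system:
log-normal half-lives with medians of 60 min (mRNA), 40 (lincRNA), 15
(ncRNA) and 6 (eRNA), so planted eRNAs are stochastically
shorter-lived than mRNAs; log-normal steady-state amounts (median 5);
30% of unpaired transcripts responsive with log2 amplitudes of 1–3 on
an immediate ramp (0, 0.5, 0.8, 1 of the amplitude at the four time
points).  Co-regulated enhancer–promoter pairs share a latent
per-time-point trajectory mixed so that the log fold changes of the two
members correlate at ρ = 0.8, attenuated with TSS distance
($e^{-d/100\text{kb}}$) to emulate distance-decaying co-regulation; 70%
of pairs are up-regulated.  Depths are σ ≈ 0.25 (TT) with ±20%
per-sample jitter, cross-contamination ε ≈ 0.005, RNA depth ≈ 0.05,
antisense bleed c = 0.05, background 0.1 counts per bin, and 8 + 8
spike-ins of 1–4 kb.  Where the source states no value (spike-in
counts, background, jitter), values were chosen once at what a
sequencing lab would consider realistic for a desk-scale study and are
configurable; they were not revisited after seeing test outcomes.

Synthesis is piecewise-constant per 5-min interval: the labeled amount
at harvest time $T$ uses the rate in force during $[T-t, T]$, and total
amounts evolve by the exact exponential recursion between time points
starting from steady state at 0 min.  Counts are Poisson around
$L_i(\sigma_j\alpha_{ij} + \epsilon_j\beta_{ij})$ and spread
multinomially over the feature's bins by overlap width (no read-level
simulation — the pipeline only consumes midpoint-binned coverage).
Antisense bleed mixes the two realized strand tracks deterministically
with the stated 2×2 model.  The returned count matrix holds the
feature-attributed, bleed-free and background-free counts — i.e. what a
perfect antisense correction would recover — while the tracks carry
background and bleed; this split is what makes the conservation and
round-trip invariants exactly testable.

What a green test does *not* establish: the generator has uniform
coverage within features (no mappability, GC or 3'-bias structure),
single-isoform single-exon reference genes by default, no overlapping
same-strand transcription, and independent Poisson noise (no library-
level correlation beyond depth).  Recovery rates on this world are
therefore upper bounds on real-data behavior.

# Numerical choices and degenerate inputs

* HMM: 30 quadrature nodes; emission sd floored at $10^{-3}$; EM stops
  at |Δll| < tol or `max_iter`; an all-equal input returns a flagged
  degenerate fit with a warning instead of cycling.
* Threshold optimization with empty TU or reference sets defines
  Jaccard as 0 with a warning.
* Boundary refinement clips windows at chromosome ends (warning) and
  keeps the original boundary on ties or flat windows.
* Constant temporal profiles give undefined correlations: flagged NA,
  excluded from summary statistics.
* The permutation test seeds its own RNG stream explicitly; all
  generator entry points take explicit seeds and never touch global
  state beyond `set.seed` at entry.

# Known limitations

The NB Wald stand-in is anti-conservative for very low counts (the
pseudo-count of 0.5 stabilizes the log fold change at the cost of bias
toward zero).  The kinetics module fits one (α, β) per time point and
does not deconvolve rate changes within a labeling interval.  The HMM
assumes emission independence across tracks given the state.  The
closest-pairing baseline searches the same chromosome only.  Insulated
neighborhoods are consumed as intervals; loop calling is out of scope.
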