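---
title: "Methods: a testable screen for copy-number-altered lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a testable screen for copy-number-altered lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Tumor genomes accumulate somatic copy-number alterations (SCNAs):
segments gained or lost relative to the germline, observed as segmented
log2 copy-ratio profiles from array or sequencing data. Alterations
that recur across independent tumors at high amplitude are candidates
for positive selection, and when a recurrent focal alteration contains
only lncRNAs, those lncRNAs become candidate noncoding drivers. This
package implements that screen end to end, with a synthetic data
generator that plants known truth so every stage has a testable
contract.

### Recurrence statistic

The genome is discretized into fixed-size marker bins (default
**10 kb**; segment boundaries are projected onto bins by width-weighted
averaging). For one direction (amplification or deletion) and marker
$m$,

$$G(m) = f(m)\,\bar a(m),$$

where $f(m)$ is the fraction of tumors whose marker value exceeds the
alteration threshold in that direction, and $\bar a(m)$ is the mean
absolute log2 ratio over exactly those altered tumors ($\bar a = 0$
when $f = 0$). The alteration threshold defaults to $|\log_2| > 0.1$ —
deliberately permissive, mirroring continuous segmented input; it also
defines the per-sample "amplified" call used by the downstream group
contrasts, so a cohort's percent-amplified exceeds the true carrier
fraction whenever background noise crosses 0.1.

### Null model and significance

The null preserves each tumor's segment structure but destroys
cross-sample alignment: per permutation, every tumor's marker vector is
circularly shifted within each chromosome by an independent uniform
offset, the track is rescored, and all marker G-scores across all
permutations are pooled (default **1,000 permutations**; the rescoring
loop is compiled). The empirical p-value is
$p(m) = (1 + \#\{G_{null} \ge G(m)\})/(1 + \#G_{null})$, and
Benjamini–Hochberg step-up over all markers of the direction gives
q-values, thresholded at $q < 0.25$.

Two consequences of this construction are worth knowing. First, the
null is exactly calibrated marginally — a signal-free cohort is one
more draw of the same alignment process. Second, marker p-values are
strongly positively dependent (a background segment spans ~200 markers
at the defaults), and BH step-up under such block dependence rejects a
whole block once each of its $k$ markers reaches $p \le 0.25\,k/M$.
Signal-free cohorts therefore still produce an occasional marginal
region near $q \approx 0.25$; at the default scale we observe zero
called peaks in roughly 85–95% of signal-free cohorts depending on the
seed set, with the marker-level $q<0.25$ fraction near 0.01. Raising
the permutation count from the minimum 100 to the default 1,000
measurably reduces spurious calls caused by a noisily estimated null
tail, which is why the default is 1,000 despite the cost.

### Peaks, nesting and peel-off

A *region* is a maximal run of contiguous significant markers. Its
*focal peak* is the widest run of markers tied at the region's maximal
G (ties resolved toward the widest run — conservative localization);
the *enlarged peak* grows the focal run while
$G \ge (1-\varepsilon)\,G_{peak}$ (default $\varepsilon = 0.05$). After
a peak is recorded, its supporting tumors — those altered at any focal
marker — are removed across the whole region (samples, not segments,
are the peel-off unit; a sample with two events in one region is
over-peeled, a documented simplification) and the region is rescored.
Residual markers are re-tested against the existing null through a
G-space cut: the smallest G whose empirical p passes the original BH
cut (the largest p among originally significant markers). This keeps
later-peak significance consistent with the original step-up without
re-running BH on a changed family; later peaks' q-values are read off
the original p-to-q step function. Iteration is capped (default 5 per
region) and each pass removes at least one supporting sample, so it
terminates.

### Classification and cross-cohort recurrence

A gene is *inside* a peak when its body overlaps the focal interval by
at least 1 bp — overlap, not containment, so a peak sitting on one end
of a long lncRNA still claims it. Categories follow strict precedence:
`contains_driver`, `coding`, `lncRNA_only`, `other_noncoding_only`,
`gene_desert` (empty). Across cohorts, same-direction focal peaks merge
into unique regions when reciprocal overlap is at least 0.25 on both
sides, transitively (single linkage); both the threshold and the level
(focal by default) are parameters since no canonical merge rule exists.

### Promoter TF enrichment

Promoters are $[\mathrm{TSS}-1\,\mathrm{kb}, \mathrm{TSS}+1\,\mathrm{kb})$,
strand-aware, clipped at chromosome bounds. A promoter is bound by a
factor when any site overlaps the window by ≥ 1 bp (binary, not
site-count weighted). For each factor, the upper-tail hypergeometric
probability $P(X \ge k)$ is computed from log-binomial coefficients
(numerically stable for genome-scale counts); tests assert agreement
with exhaustive draw enumeration to $10^{-12}$ on all parameter grids
up to $N = 12$. The enrichment universe is all annotated genes of the
tested set's biotype (all lncRNAs when testing altered lncRNAs): this
controls for biotype-specific promoter properties. BH q-values across
factors are reported as an addition to the raw $-\log_{10} p$.

### Expression and methylation concordance

An alteration is *putative functional* when at least one contained
lncRNA shows a tumor-vs-normal expression change agreeing with the
alteration direction with Welch-test $p < \alpha$ (default 0.05,
per-gene, uncorrected: this is a directional agreement screen, not a
discovery procedure; BH is available via the verdict table). Tests run
on $\log_2(x+1)$ of the linear FPKM-like values, a variance-stabilizing
choice. Note the analytic null survival rate is $\alpha/2$, not
$\alpha$: significance and direction agreement must coincide.
Methylation contrasts reuse the same Welch machinery on β-values with a
hypomethylated-in-tumor flag; constant-in-both-groups CpGs are reported
with `NA` p and a note rather than aborting the run.

### Immune-signature scores

Per sample, genes are ranked by expression (midranks on ties) and
walked in descending order; the running sum gains
$r_i^{\alpha}/\sum_{hits} r^{\alpha}$ at signature genes and loses
$1/\#misses$ elsewhere; the score is the mean of the running-sum values
(a weighted Kolmogorov–Smirnov area, exponent $\alpha = 0.25$). The
statistic is a fully specified, oracle-testable stand-in for
kernel-based single-sample enrichment scores: it preserves ordering
behavior but is not numerically interchangeable with them. Two
properties matter in practice: scores are invariant under any monotone
transform of a sample's expression (rank-based), and for $\alpha > 0$
random signatures have a small positive mean offset (~0.03 at 50
genes), because rank-weighting front-loads hit mass — exactly zero-mean
only at $\alpha = 0$. Group contrasts use the Wilcoxon rank-sum test:
exact by enumeration of all assignments over pooled midranks whenever
the pooled size is ≤ 20 (enumeration handles ties exactly, which the
textbook exact distribution does not), normal approximation with tie
and continuity corrections above that.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the
study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| genome | 2 × 10 Mb, 100 genes | 60 coding (5 drivers), 30 lncRNA, 10 pseudogene, non-overlapping |
| `noise_sd` | 0.1 | sd of background segment log2 means — typical residual noise of array segment means |
| `segment_mean_len` | 2 Mb | exponential background segment length: a mostly quiet genome |
| `carrier_frequency` | 0.5 | default planted recurrence; recovery tests also use 0.10, the regime of a frequently amplified lncRNA |
| `amplitude` (± sd) | 1.5 (0.2) | carrier log2-shift magnitude: a high-level amplification |
| `dosage_slope` | 1 | full coupling of log-expression to log2 copy ratio |
| `base_log_expr`, `expr_sd` | 3, 0.5 | log2 FPKM-like baseline and biological noise |
| β parameters | 0.7 − 0.2, sd 0.05 | normal promoter methylation, tumor hypomethylation shift |
| TF `background_rate` | 10 / Mb | Poisson background sites (200 bp) per factor |

Cohorts are piecewise-constant per-sample profiles: background segments
with Normal(0, `noise_sd`) means, plus each planted alteration carried
independently with its frequency, adding ±Normal(amplitude, sd) over
the interval. Carrier sets are returned as ground truth and match the
modified segments exactly. Deletions are negative log2 shifts — no
integer copy states, matching what segmented pipelines actually
consume. Genes never overlap, making lncRNA-only classification
unambiguous in tests.

What the generator does **not** emulate — probe-level noise, GC waves,
allele-specific states, whole-genome doubling, purity/ploidy mixtures,
arm-level events, correlated co-amplification of neighboring genes —
bounds what passing tests show: the pipeline's logic and calibration
are verified, not its robustness to every artifact of real array data.

## Numerical and design choices

- Coordinates are uniformly 0-based half-open internally; SEG and
  GTF-lite convert (1-based inclusive) at the disk boundary, BED does
  not. Chromosome names are taken verbatim; mismatches error rather
  than silently intersecting to nothing.
- All randomness flows from explicit integer seeds; every simulator
  and the permutation null are byte-reproducible. The pipeline splits
  one root seed into fixed per-stage offsets.
- The focal-peak tie rule (widest tied run) and the ≥ 1 bp containment
  rule are the two places where localization semantics were genuinely
  open; both are documented in output and configurable where the
  ambiguity matters (containment level: focal/enlarged/region).
- `welch_t` wraps the standard Welch–Satterthwaite test and adds
  explicit degenerate handling (identical constant groups give
  $t = 0, p = 1$; constant groups at different means error, callers
  that iterate surface the error per-item and continue).
- Problem sizes in tests: recovery and null calibration run 50 seeds ×
  200 tumors at 10 kb bins with 1,000 permutations; concordance
  calibration/power run 100 seeds at 50 tumors / 30 normals; oracle
  grids are exhaustive up to their stated bounds. These scales keep the
  full suite under ten minutes on one CPU while leaving the binomial
  noise on measured rates well inside the asserted bands.

## Known limitations

- BH at $q<0.25$ over block-dependent markers occasionally admits a
  marginal noise region (see above); cluster-level error control is
  out of scope.
- Peel-off can over-peel samples with multiple independent events in
  one region.
- The enrichment universe choice (all lncRNAs) is one defensible
  option among several (all genes, expressed lncRNAs); it is a
  parameter, not a conclusion.
- The immune score is a stand-in statistic: orderings and contrasts
  are meaningful, absolute values are not comparable across methods.
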