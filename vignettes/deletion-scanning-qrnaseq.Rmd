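---
title: "Deletion-scanning qRNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deletion-scanning qRNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circef)
```

## The experiment this package models

Many circular RNAs in lower eukaryotes arise not from direct backsplicing
between inverted repeats but through an *exon-containing lariat*: exon
skipping leaves the circle-forming exon inside a lariat, and a second round
of splicing within that lariat excises the exon as a covalently closed
circle. A central quantitative question is what determines how efficiently a
given exon circularizes.

The experimental design `circef` supports answers this with deletion
scanning. A plasmid pool carrying all deletions of a circle-forming exon
that an outward-facing combinatorial inverse-PCR scheme can produce is
expressed in cells; circle-derived RNA (RNase R enriched) and plasmid DNA
are amplified with the same primer pair and sequenced. Each deletion creates
a unique junction sequence within the exon, so junction-spanning reads
identify the isoform in both libraries, and the RNA:DNA count ratio, once
put on a per-gene-copy basis, measures each isoform's circularization
efficiency (CE). A typical study exon is the 181 nt second exon of the
fission-yeast *mrps16* gene, whose circle is the most abundant in that
organism; coordinates throughout use the `(x, y)` notation, the first and
last deleted nucleotide with 1 the first nucleotide of the exon.

## The CE estimator

For isoform $i$ let $n_c$ be its RNA-library junction reads, $n_{wt}$ the
RNA reads matching the wild-type circle (endogenous, single-copy
background), $n_v$ its DNA-library junction reads and $n_{vtot}$ the total
DNA reads after removing wild-type matches. With $s$ the plasmid:genome
copy-number ratio (19 in wild-type fission yeast, measured by qPCR),

$$\mathrm{CE} = \frac{n_c / (n_{wt}\, s)}{n_v / n_{vtot}}
  = f(A)\,g(B), \qquad
  A = \frac{n_v}{n_{vtot}},\; B = \frac{n_c}{n_c + n_{wt}},\;
  f(A) = \frac1A,\; g(B) = \frac{B}{(1-B)\,s}.$$

CE = 1 means the isoform circularizes at the wild-type per-copy rate. The
numerator is the isoform's circle output per plasmid copy (relative to the
wild-type circle from the single genomic copy); the denominator normalizes
by how well the isoform is represented in the plasmid pool. `compute_ce()`
evaluates both routes (they agree to floating tolerance by construction);
`ce_table()` assembles the counts from a pair of `assign_reads()` results.

### Variance and confidence intervals

Counts are modelled as independent Poisson variables, so conditional on the
total, $n_c \mid (n_c + n_{wt})$ is binomial with success probability $B$.
With $\operatorname{var}(A) = A(1-A)/n_{vtot}$ and
$\operatorname{var}(B) = B(1-B)/(n_c+n_{wt})$, the delta method
($\operatorname{var} h(x) \approx \operatorname{var}(x)\,h'(x)^2$) gives

$$\operatorname{var}\ln \mathrm{CE}
 = \frac{\operatorname{var}(A)}{A^2}
 + \frac{\operatorname{var}(B)}{\big(B(1-B)\big)^2},$$

the two libraries contributing independently; $s$ is treated as a known
constant and adds no variance. The 95% interval is
$\exp(\ln\mathrm{CE} \pm 2\,\mathrm{sd})$ — the constant is 2, not 1.96 —
which is multiplicatively symmetric about the point estimate. The test
suite verifies by simulation that at moderate counts the delta-method sd
matches the empirical sd of $\ln\mathrm{CE}$ within 10% and that interval
coverage sits in the nominal 93–97% band.

Numerical edge cases: a zero $n_c$ or $n_{wt}$ puts $B$ on the boundary
where the variance is undefined. The point estimate always uses raw counts;
for the interval, `estimate_ce()` by default applies a Haldane-style $+0.5$
to both RNA counts and flags the row (`zero_corrected`); with the
correction off the interval is reported as NA. An isoform absent from the
plasmid library ($n_v = 0$) has undefined CE and is flagged. Isoforms with
fewer than 200 plasmid reads are removed by `filter_low_coverage()` (the
boundary value 200 is kept). No overdispersion term is modelled — a
documented limitation: real libraries amplified at different PCR cycle
numbers may be noisier than Poisson, which is why concordance across
libraries, not a pooled estimate, is the recommended check.

## Junction enumeration and the truncation model

An outward-facing primer pair (reverse primer retaining the exon through
position $r$, forward primer retaining from position $f$) deletes
$(r+1, f-1)$. Because primers are used without purification, incomplete
(5′-truncated) synthesis products also occur; a truncation of $t$ nt on a
boundary primer moves that boundary $t$ nt outward, enlarging the deletion.
`enumerate_deletions()` enumerates all combinations of truncations
$0..T$ on both primers (default $T = 3$, "differing by only a few
nucleotides"; enumerating both primers simultaneously is a superset of any
narrower reading), collapses duplicate $(x, y)$ pairs — the junction, not
the provenance, identifies the molecule — and keeps only deletions strictly
inside the exon, since the scheme never touches a splice site. The tests
pin this against an independent exhaustive loop over primer-pair and
truncation tuples.

## Read assignment

Junction references carry `flank_len` retained nucleotides on each side of
the junction (clipped at exon ends), so any read up to `flank_len` long
that spans the junction fits entirely inside its reference. Matching is
therefore ungapped: every placement of the read inside a reference is
scored by Hamming distance (`N` never matches) and the minimum must not
exceed the mismatch budget (default 3). The scan is implemented in a small
C++ kernel; the test suite checks it against a plain-R exhaustive oracle.

Assignment is hierarchical, mirroring the two-index alignment the design
implies: reads are first matched against the unmutated exon, and only reads
failing the wild-type budget are tested against the junction index. Reads
of 40 nt or shorter are removed first (the filter is strict:
"greater than 40"). A read tying between two junction references at the
minimal distance is discarded as ambiguous by default — near-identical
truncation variants make such ties legitimate, and discarding avoids double
counting; `ambiguous = "best"` instead keeps the first reference in
$(x, y)$ order, deterministically. Quality scores are ignored; adapter
trimming is upstream of this package.

One consequence of the hierarchy is worth stating: a junction read whose
overhang past the junction is at most the mismatch budget *always* lies
within that budget of the wild-type sequence, so the wild-type pass
necessarily absorbs it. Only reads with more than `max_mismatches`
informative nucleotides on both sides of the junction can ever be assigned
to an isoform; the read simulator only emits such reads (below).

## Length trend, outliers, profiles and cohorts

`length_trend()` reports Spearman's rank correlation between remaining
exon length and CE — the headline statistic, deliberately assumption-light
because the data do not identify a functional form — together with a
weighted log-linear fit of $\ln\mathrm{CE}$ on length (weights
$1/\mathrm{sd}^2$). For outlier calling, the default reference curve is a
robust (Tukey-biweight) weighted loess of $\ln\mathrm{CE}$ on length (span
0.85, degree 2, falling back to the log-linear fit below 10 records). The
straight line was considered and rejected as the default flagging curve:
when the true length response saturates, a line converts its curvature into
spurious "outliers" at the ends of the length range, while the robust
smooth tracks the response without being attracted by the outliers it is
meant to find.

A record is flagged `high` when its entire 95% CI lies above the fitted
curve at its length (`ci_low > fitted`), `low` symmetrically — the same
judgement one makes visually from error bars against a trend line. Note the
calibration consequence: a well-calibrated 2-sd interval excludes a correct
curve for ~4.6% of ordinary records, so over ~60 isoforms two or three
marginal flags are expected even when nothing is biologically unusual.
CI-exclusion flagging is a screening rule, not a familywise-error-controlled
test; genuinely interesting isoforms (e.g. structure-relieving deletions at
several-fold the trend value) stand far outside this band.

`positional_profile()` gives the per-nucleotide view (how many deletions
cover each position, and their mean CE), and `plot_deletion_spans()` the
deletion-bar plot. For exon-size cohort comparisons, `notch_stats()`
computes the notched-boxplot interval $\pm 1.57\,\mathrm{IQR}/\sqrt{n}$
(IQR by the linear-interpolation quantile convention, R type 7 — stated
because notch values depend on it) and `ranksum_test()` wraps the Wilcoxon
rank sum test, exact for tie-free samples with $nm \le 10^4$ and otherwise
the tie-corrected normal approximation.

## qPCR quantification and the kinetic identity

`relative_abundance()` implements delta-Ct quantification under assumed
perfect primer efficiency: $\mathrm{ratio} = 2^{\overline{Ct}_{ref} -
\overline{Ct}_{target}}$, with SDs propagated from replicate Ct SDs in
quadrature on the log2 scale. A 3-cycle gap is one-eighth; a 4.907-cycle
gap is one-thirtieth. Ct values above 40 cycles are treated as non-detected
and propagate an NA. `enrichment_log2()` gives RNase R
enrichment/depletion as $\overline{Ct}_{mock} - \overline{Ct}_{treated}$.

The kinetic model is the minimal first-order realization of the lariat
pathway: lariat synthesis at $k_1$ from a constant pre-mRNA source, lariat
loss by decay $d_L$ plus the second splicing step $k_2$, circle decay
$d_C$. Closed forms: $L = k_1\,src/(d_L + k_2)$, $C = k_2 L / d_C$, so
$C/L = k_2/d_C$. If a mutation leaves decay rates untouched — an explicit
model assumption, and cryptic splicing is not modelled — the
mutant:wild-type circle-to-lariat ratio equals $k_{2,mut}/k_{2,wt}$
exactly. `predicted_log2_ratio()` and `infer_k2_fold_change()` express the
two sides of this identity; a mutation sparing the second step predicts 0,
one abolishing it is reported below detection rather than $-\infty$. The
tests confirm the closed forms against numerical ODE integration and the
round-trip identity to floating tolerance. The source level is an arbitrary
positive constant: only ratios are ever reported.

## The synthetic-data generator

`simulate_qrnaseq()` emulates the full experiment with known truth so every
stage is testable without external data.

* **Exon and scheme.** A uniform-random 181 nt exon; 8 forward and 8
  reverse primers drawn from mirrored windows (~22–47% and ~53–78% of the
  exon), giving 64 isoforms with remaining lengths of roughly 80–170 nt,
  every junction reference at least as wide as a read.
* **Pool composition.** Isoform proportions are symmetric
  Dirichlet(`library_alpha`); the default `alpha = 5` encodes the moderate
  skew expected of a pool of ~1500 colonies. The true skew of a real pool is
  unknown, so the parameter is exposed rather than fixed.
* **True CE.** Logistic in remaining length by default
  (`ce_max = 1`, `l50 = 190` nt, `k = 0.045`/nt): the wild-type-length exon
  sits just below the half-maximal shoulder and CE falls roughly
  exponentially with deleted length, spanning ~0.007–0.3 across the
  scheme's range — chosen once as a plausible strong length dependence.
  `flat` and `step` models are available. Planted outliers multiply the
  model value by `outlier_fold` (default 4) for `n_outliers` random
  isoforms.
* **Counts.** Poisson throughout, matching the estimator's variance model;
  PCR branching noise is deliberately out of scope because the design
  controls cycle numbers experimentally. DNA: $n_v \sim
  \mathrm{Pois}(d\,(1-w_{dna})\,p_i)$ plus a 1% residual wild-type template
  fraction. RNA: by default the wild-type background is set by per-copy
  consistency — one genomic copy at CE 1 sequenced at the same per-copy
  depth as the $s$ plasmid copies, i.e. $E[n_{wt}] = \mathrm{depth}/(1 +
  s\sum_i p_i \mathrm{CE}_i)$ and $E[n_{c,i}] \propto s\,p_i\,
  \mathrm{CE}_i$ — which makes the CE estimator consistent for the model CE
  with calibration factor exactly 1 (asserted in the tests). Setting
  `wt_background_fraction` explicitly overrides this; the truth table then
  records the implied calibration factor.
* **Reads.** 75 nt (truncated to the reference width when a junction
  reference is shorter), uniform over *informative* junction-spanning
  windows: at least `max_mismatches + 1` nt overhang on each side, and
  reads falling within the wild-type mismatch budget are redrawn (see the
  assignment section for why such reads cannot be assigned). Substitution
  errors are iid at `error_rate` (default 0.002, Illumina-like). Every read
  carries its true origin in the label table, making the generator its own
  assignment oracle: with `error_rate = 0` the assignment table must equal
  the label tally exactly, and the tests assert this.
* **Determinism.** Everything derives from the config seed; identical
  configs produce byte-identical outputs.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: PCR amplification noise and cycle-number
bias, rolling-circle concatemer reads, lariat branch-point
misincorporation, adapter sequence, quality-score structure, and any
sequence- or structure-dependence of circularization beyond the imposed
length model.

## Problem sizes and runtimes

The test suite runs the full pipeline once at the study's base conditions —
64 isoforms, 2×10^5 reads per library — which takes about two minutes on a
single core; Monte Carlo checks use 300–2000 replicates at the count level,
where draws are vectorised and cheap. `scripts/acceptance.R` recomputes the
worked-example CE, the 2000-replicate interval coverage and the kinetic
null prediction in a few seconds.

## Known limitations

* Poisson-only count noise (no overdispersion across PCR libraries).
* Ungapped matching: reads with indel sequencing errors are lost to the
  unassigned pool rather than rescued.
* The CI-exclusion outlier rule has the nominal ~5% per-record false-flag
  rate discussed above.
* The kinetic identity is only as good as its unchanged-decay assumption;
  debranching-deficient (`dbr1_null`) lariat decay must be supplied by the
  user, and cryptic splice isoforms are outside the model.
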