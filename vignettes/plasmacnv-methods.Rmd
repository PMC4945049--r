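---
title: "Methods: simulating and calling fetal CNVs from low-coverage plasma sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calling fetal CNVs from low-coverage plasma sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmacnv)
library(dplyr)
```

# The problem

In noninvasive prenatal testing (NIPT), cell-free DNA in maternal plasma is a
mixture of maternal and placental (fetal) fragments. At typical screening
depth — a few million uniquely aligned short reads per sample — a fetal copy
number variant (CNV) shows up only as a subtle shift in binned read depth: a
heterozygous fetal deletion shifts the local copy ratio by `-f/2`, where `f`
is the fetal fraction (commonly around 10%, so the signal is a 5% dip riding
on Poisson counting noise). Detecting megabase-scale events under these
conditions requires careful bias correction, a segmentation procedure with
genome-wide error control, and a calling threshold that knows how small a
real fetal signal can be.

`plasmacnv` implements that full analysis as a tested pipeline: a synthetic
data generator with the statistical structure of plasma sequencing, GC bias
correction, chromosome-Y fetal-fraction estimation, a segmentation-based
caller, and a concordance evaluator that scores calls against
karyotype/microarray confirmations the way clinical screening studies do.

# The mixture model behind the simulator

The generator tiles a genome (hg19 chromosome lengths ship with the package)
into fixed bins, default 100 kb, and draws all reads of a sample in a single
multinomial, so per-sample totals are exact. The sampling weight of bin $i$ is

$$ w_i \propto m_i \, g(\mathrm{gc}_i)\, r_i, $$

with mappability $m_i$ (default 1), a smooth GC efficiency curve $g$, and the
mixture copy ratio

$$ r_i = (1-f)\,\frac{c_{m,i}}{2} + f\,\frac{c_{f,i}}{2}, $$

where $c_{m,i}$ and $c_{f,i}$ are maternal and fetal copy numbers (2 on
autosomes unless a CNV spec says otherwise; chrX fetal copy is 1 for a male
fetus). Chromosome Y gets $r_i = \beta + f\,c_{f,Y}/2$ for a male fetus and
$r_i = \beta$ otherwise, with $\beta = 0.002$ a read mis-mapping background
that makes fetal sex calling a real decision rather than a zero test.

Why these defaults:

* **7,000,000 reads per sample** — the depth of multiplexed plasma screening
  runs; at 100 kb bins this is ~226 reads per bin, so the per-bin copy-ratio
  noise is $1/\sqrt{226} \approx 0.067$.
* **100 kb bins** — small enough to resolve the 1 Mb smallest events worth
  reporting (10 bins), large enough that per-bin counts are comfortably in
  the Gaussian-approximation regime.
* **GC bias** — a quadratic efficiency curve peaking at GC 0.42 with range
  roughly 0.7–1.2, the classic short-read library shape; the per-bin GC field
  itself is a smooth seeded random field (anchors every ~50 bins, spline
  interpolated, clamped to [0.30, 0.62]) so GC-correlated artefacts are
  spatially structured as in real genomes.
* **Fetal fraction** — cohort samples draw $f$ from a normal with mean 0.097
  and SD 0.03 truncated to [0.03, 0.25], matching the range observed in
  male pregnancies at this gestational window.
* **Overdispersion** — optional gamma multipliers on the weights (default
  off); the multinomial model is the simplest one consistent with
  "unique read" accounting.

What the generator deliberately does **not** emulate: read-level error
profiles, alignment and duplicate marking, mappability holes and blacklist
regions, batch effects across flow cells, and mosaicism beyond a single
mixture fraction. Passing tests on these simulations therefore demonstrate
the *statistical* operating characteristics of the method at the stated
depth and fetal fraction — not robustness to the artefact spectrum of any
particular laboratory's real data.

# GC correction

Each sample is corrected against itself: a loess fit (degree 1, i.e. local
linear regression with tricube weights, span 0.3) of count on GC over
autosomal bins with GC in [0.25, 0.75] and non-zero mappability. For speed
the fit uses at most 5,000 evenly spaced bins of the mask — at ~226 reads
per bin this changes the fitted curve by well under the Poisson noise floor.
Copy ratios are $\rho_i = \text{count}_i / \hat c(\mathrm{gc}_i)$, rescaled
so the **autosomal median is exactly 1**; sex chromosomes are corrected with
the autosomal curve but excluded from the median so their dosage signal
survives. Per-bin standard errors use the Poisson approximation
$\sigma_i = \sqrt{\max(\text{count}_i, 1)}/\hat c(\mathrm{gc}_i)/s$. Edge
cases: evaluation is clamped to the fitted GC range; a sample with
essentially constant GC falls back to a constant median curve with a
warning; a fitted curve that is non-positive anywhere over the data is an
error, not a silent division.

Whether the original pipeline corrected per sample or against a pooled
reference panel is not public; per-sample correction is the simpler choice
and is what is implemented here.

# Fetal fraction from chromosome Y

For a male fetus, the relative chrY coverage

$$ \mathrm{cr}_Y = \frac{\text{chrY reads}/\text{total reads}}
                        {\text{chrY binned length}/\text{genome binned length}} $$

interpolates between a female background (mis-mapping only) and an adult
male (one Y per diploid genome, so about 0.5). Two reference regressions of
$\mathrm{cr}_Y$ on chrY GC are fitted by ordinary least squares — one on an
adult-male panel, one on female-fetus pregnancies — and the estimate is the
sample's position between them:

$$ \varepsilon = \frac{\mathrm{cr}_Y - f_{Y,\mathrm{female}}(\mathrm{GC}_Y)}
                      {f_{Y,\mathrm{male}}(\mathrm{GC}_Y) - f_{Y,\mathrm{female}}(\mathrm{GC}_Y)}, $$

so $\varepsilon = 0$ exactly on the female curve and $\varepsilon = 1$
exactly on the male curve. The published formula mixes fitted and raw terms
in its notation; the reading implemented here — raw observed coverage in the
numerator against the fitted female reference — is the only one that yields
those two identities. The original estimator was defined on k-mer–based
relative coverage; this implementation uses read-count relative coverage,
which is equivalent at the precision the formula needs. Panels need at least
20 samples; the regressions are degree 1 by default (an intercept-only fit
is substituted when a panel's GC spread is negligible, which happens
whenever all panel samples share one genome model); the male curve must sit
strictly above the female curve over the observed GC range.

Sex calling: a fetus is called male when $\mathrm{cr}_Y$ exceeds the female
curve by more than $k = 3$ female-panel residual SDs, female when below,
indeterminate on an exact tie. $\varepsilon$ is reported only for male
calls, clamped to [0, 1] (the unclamped value is kept for diagnostics);
estimation for female fetuses (SNP-, size- or X-based methods) is out of
scope.

# Segmentation

The caller segments each chromosome's copy-ratio profile by recursive
binary segmentation with an **interval-vs-complement** statistic: for every
candidate sub-interval $[a, b]$ (at least `min_seg_bins` = 10 bins, leaving
a complement of at least 10 bins and no stub flank),

$$ t(a,b) = \frac{\bar x_{[a,b]} - \bar x_{\text{rest}}}
                 {\hat\sigma_{\text{seg}}\sqrt{1/n_{\text{in}} + 1/n_{\text{out}}}}, $$

with $\hat\sigma_{\text{seg}}$ the pooled SD of the whole segment being
scanned. The maximising interval (leftmost on ties; suffix windows are
canonicalised to their prefix complement so every partition has one
representative) is accepted as a split when $|t| \ge z_{\text{split}}$,
producing up to three children, each segmented in turn. The procedure is
deterministic and exhaustive — a property the test suite exploits by
checking the chosen split against an independent brute-force scan.

Two design points deserve explanation:

* **Why an interval statistic rather than a plain prefix/suffix split.** A
  fetal CNV sits in the middle of a chromosome at a shift of only $f/2$.
  Against a prefix/suffix mean comparison the event's contrast is diluted by
  the long normal flank on its own side: a 25 Mb deletion at $f = 0.10$ in
  the middle of chr4 yields a maximal two-sample $|t| \approx 2.6$ — far
  below any usable genome-wide threshold — whereas compared against its
  complement the same event scores $|t| \approx 12$. The interval form is
  the segmentation scheme of circular binary segmentation, here with a fixed
  analytic threshold instead of permutation p-values so results are exact
  and reproducible.
* **Why the pooled segment SD.** Standardising each window by its own sample
  variance gives the statistic heavy $t_{n-2}$ tails for 10-bin windows, and
  with millions of candidate windows per chromosome the genome-wide null is
  then uncontrollable. Pooling the SD of the scanned segment keeps the null
  Gaussian-like for every window length.

**Threshold calibration.** The default $z_{\text{split}} = 5.4$ is the
~99th percentile of the genome-wide null maximum of this statistic
(24 hg19-sized chromosomes at 100 kb bins, iid Gaussian ratios, 100 null
genomes), holding the per-sample false-split rate near 1–2% — consistent
with the ~1.6% per-sample false-positive rate reported for screening at
this depth. The weakest signal the method claims (10 Mb at $f = 0.10$,
$|t| \approx 7$) retains a comfortable margin above it. Boundary precision
follows the signal-to-noise ratio: near-exact at full-dose (maternal)
shifts, a wander of up to ~10 bins at the $f/2$ fetal shift, where the
max-$t$ surface is flat near the optimum.

# The dynamic calling threshold

A segment becomes a call when its mean deviates from its dosage baseline by
at least

$$ \theta = \max\!\left(z_c\,\frac{\sigma_{\text{seg}}}{\sqrt{n}},\;
                        \kappa\,\frac{f_{\text{eff}}}{2}\right), $$

with $z_c = 3.5$ and $\kappa = 0.5$. The first term scales with depth and
segment length — the "dynamic" part; the second is a biological floor: half
the expected single-copy fetal signal at the working fetal fraction.
$f_{\text{eff}}$ is the chrY estimate when available and a fallback
$f_0 = 0.07$ (near the low end of observed male-pregnancy fractions)
otherwise, e.g. for female fetuses. The exact form of the original
pipeline's threshold is unpublished; this expression is a reconstruction
constrained by its reported operating points (about 7M reads, 1–129 Mb
events, high sensitivity above 10 Mb) and is documented as such.

Calls smaller than 1 Mb are suppressed; adjacent same-direction calls
separated by fewer than `min_seg_bins` bins are merged. Autosomes are
tested against baseline 1; sex chromosomes against the called sex's expected
dosage (chrX $1 - f/2$ for a male fetus; chrY $\beta + f/2$ male, $\beta$
female), so a whole-chromosome sex mismatch is flagged while normal dosage
is not. Whole-autosome events (trisomies) emerge as ordinary
chromosome-spanning calls; no dedicated aneuploidy statistic is provided.

# Concordance evaluation

Clinical confirmations arrive as ISCN-style karyotype strings
(`46,XX,del(5)(p15.33p15.2)`) or microarray findings
(`arr 13q21.2(60,399–61,730)×3`). The parser resolves band names through a
UCSC-format cytoband table, with hierarchical prefixes expanding to band
unions (`p14` → p14.1–p14.3) and array coordinates taken verbatim in kb.
Derivative chromosomes, mosaics and arm shorthand are deliberately not
guessed: they raise an error pointing at the manifest's explicit-coordinate
override columns. The shipped cytoband table is **synthetic**: chr5's short
arm follows the standard hg19 ideogram (its band unions reproduce the sizes
that published Cri-du-chat case tables imply), other chromosomes are
plausible tilings for demonstration and testing; users evaluating real
calls should supply a real assembly file.

Each confirmed event is classified against the sample's calls
(same chromosome, same direction; one call confirms at most one event,
matched greedily by overlap with ties to the larger event):

* **consistent** — the call is contained in the event, or the kb overlap
  reaches 50% of *either* interval's length. The either-interval rule is the
  unique simple reading of the published footnotes that reproduces every
  printed overlap label;
* **partly consistent** — a candidate exists but overlaps less than 50% of
  both intervals (including zero overlap on the correct chromosome);
* **inconsistent** — no candidate call (a missed event).

Performance is stratified by event size at 10 Mb. Sensitivity is per event:
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$ with TP = consistent + partly
consistent. Specificity uses the hybrid accounting of screening
evaluations: $\mathrm{TN}/(\mathrm{TN}+\mathrm{FP})$, where TN is the
number of confirmed-euploid samples with *no* call at all and FP is the
stratified count of calls in euploid samples. (The per-sample alternative
$(N_{\text{euploid}} - \mathrm{FP})/N_{\text{euploid}}$ differs in the
second decimal for the size-stratified rows and does not reproduce the
published rates; the TN-based form reproduces all of them.) PPV is
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$. Confidence intervals are
Clopper–Pearson exact binomial — Wilson intervals do not match published
screening CIs, Clopper–Pearson does to within rounding. Empty strata report
`NA`, never 0.

# Numerical and interface choices

* Coordinates are 0-based half-open bp internally; the reporting convention
  at the IO boundary is closed kb intervals, matching clinical tables.
* All randomness is seed-threaded: a cohort, a pipeline run, and the
  acceptance script are byte-reproducible given `--seed`; model construction
  restores the caller's RNG state.
* Segmentation tie-breaks are leftmost-first; suffix/prefix window
  duplicates are canonicalised, so segmentation output is a deterministic
  function of its input.
* The pipeline (`run_pipeline()`) processes samples blind to the truth
  manifest — calling-stage functions contain no code path that reads truth
  data (enforced by a static test) — and evaluates only afterwards.

# Problem sizes used in the shipped checks

Unit tests run on a five-chromosome toy genome (190 Mb, 1,900 bins, 5×10^5
reads — the same ~226 reads/bin as full scale). The operating-point checks
run at full scale: 50 replicates for the >10 Mb detection rate at
$f = 0.10$, 60 euploid samples for the false-positive rate, 50 replicates
per fetal-fraction level for estimator bias/spread, 200 random signals for
the segmentation oracle, and a 12-replicate 3×3 size-by-fraction grid for
power monotonicity. These sizes give Monte Carlo resolution comfortably
inside the margins being asserted while keeping a full run in minutes.

# Known limitations

* The dynamic threshold and split statistic are reconstructions of an
  unpublished method, constrained by its reported operating points; absolute
  sensitivity/specificity on real cohorts cannot be validated from
  simulation alone.
* Per-sample GC correction cannot remove artefacts shared across samples
  (batch effects); no reference-panel normalisation is implemented.
* Fetal fraction requires a male fetus; female-fetus samples fall back to
  $f_0$ in the caller and their fraction is never estimated.
* Sub-megabase events are out of scope by design (the 1 Mb reporting floor
  equals 10 bins at the default resolution).
* The synthetic cytoband table is for demonstration; real ISCN parsing
  accuracy depends on a real assembly's band coordinates.
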