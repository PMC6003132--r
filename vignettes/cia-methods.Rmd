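---
title: "Scoring chromosomal imbalance from shallow WGS: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chromosomal imbalance from shallow WGS: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciascore)
```

## The model

Tumour genomes are chromosomally unstable: gains and losses accumulate from
the earliest stages of urothelial cancer, and exfoliated tumour cells carry
them into urine. At very low sequencing depth individual breakpoints cannot
be called, but the *aggregate* deviation of read depth from the diploid
expectation can — and that aggregate is what this package scores.

The read-depth model is the standard one for shallow-WGS CNV analysis. For
bin $i$ of a fixed 1-Mb tiling, the expected unique-read count is

$$E[n_i] \propto w_i \cdot \frac{c_i}{2} \cdot g(\mathrm{GC}_i) \cdot r_i,$$

where $w_i$ is the bin width, $c_i$ the (mixture) copy number,
$g(\cdot)$ a smooth library-preparation GC response, and $r_i$ a
locus-specific factor (mappability, amplification bias) that is stable
across libraries. Normalization inverts the two nuisance terms:

* **GC:** a loess fit of count against GC fraction over usable bins
  estimates $g$; corrected depth is `count / g(gc)`, rescaled to the median
  raw count so the profile keeps its scale.
* **Reference:** $r_i$ is estimated from a panel of presumed-diploid
  samples — each panel profile is scaled to its own median and the per-bin
  median across the panel is the reference. Dividing by it cancels
  whatever is reproducible across libraries, which is exactly the part
  that is not copy number.

The relative copy number is then
$x_i = 2\,(d_i / \tilde d) / r_i$ (with $\tilde d$ the sample median
depth), recentred so the *autosomal usable median is exactly 2*. For a
sample whose tumour fraction is $t$ and whose tumour cells carry $c$
copies over a region, $E[x_i] = t\,c + (1 - t)\,2$ there — the mixture
linearity that the parameter-recovery tests check.

Per-bin deviation is summarized as

$$Z_i = \sqrt{\left|\log_2 (x_i / 2)\right|},$$

zero exactly at diploid, 1 at a clonal single-copy gain ($x = 4$... note
that on this scale a clonal gain to three copies gives
$Z = \sqrt{\log_2 1.5} \approx 0.77$) or a clonal single-copy loss
($x = 1$). The square root deliberately compresses large deviations so a
handful of extreme bins cannot dominate the genome-wide summary.

The **CIA score** sums $Z$ over a percentile *rank window*: usable bins are
sorted ascending by $Z$ and the score is the sum over 1-based ranks
$\lceil 0.95N \rceil$ through $\lfloor 0.99N \rfloor$ (about 4% of the
genome, ~116 bins of ~2,900). The window is the key robustness device: it
looks at the most deviant bins (a genuinely unstable genome lifts the whole
upper tail) while discarding the top 1%, where isolated artefact bins live.
A sample is called positive when its score is *strictly above* the cutoff.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `bin_size` | 1,000,000 | bases | depth/resolution trade-off at ~5M reads: ~1,700 reads per bin |
| `min_mapq` | 30 | phred | proxy for "uniquely mapped"; BWA multi-mappers sit far below |
| `m`, `p` | 95, 99 | percentile | rank window; see above |
| `cutoff` | 24 | score | decision threshold for full-genome profiles, from ROC analysis on the original training cohort |
| `span` | 0.3 | loess span | smooth enough to track the unimodal GC response without chasing noise |
| `min_reference`, `max_cv` | 0.1, 0.5 | — | mask bins whose reference is near zero or unstable across the panel |
| `include_sex_chroms` | FALSE | — | mixed-sex cohorts would read X dosage as imbalance |

Two conventions are worth making explicit because the score depends on
them. First, the rank direction: the window is taken on the *ascending*
sort, so "ranks 95–99%" are high-deviation bins with the extreme tail
excluded — the only reading under which trimming the top 1% serves its
robustness purpose. Second, ranks are 1-based with ties broken by genomic
order, and the window is $\lceil m N /100\rceil .. \lfloor p N/100 \rfloor$
inclusive; on the analytic ramp fixture of 100 bins with $Z_i = i/100$ this
gives ranks 95–99 and a score of exactly 4.85, frozen in the tests.

Note the score is an *absolute sum*, so its scale grows with the number of
usable bins: the default cutoff of 24 belongs to full-genome (~2,900-bin)
profiles. On the 300-bin toy genome used in the test suite, diploid samples
score ~2 and scores should be compared within that genome (or via ROC), not
against 24.

## What the simulator emulates — and what it does not

`simulate_profile()` draws counts from the model above: expected count
$\propto$ width × mixture copy number × Gaussian-shaped GC response
(peaking at GC 0.45, a mild library-prep bias), scaled to `total_reads`
(default 5,000,000, typical shallow-WGS depth), with negative-binomial
noise at variance inflation `dispersion` (default 1.3× Poisson — single-cell
and low-input libraries are visibly overdispersed, but their true
dispersion is library-chemistry dependent and was set here once as a
plausible engineering default). Events are tumour-fraction-diluted, so
cases are mixtures of tumour and normal cells, as urine pellets are.

`simulate_cohort()` runs the whole pipeline — panel, reference, GC
correction, scoring — on an hg19-scale genome (2,897 autosomal bins built
from the packaged chromosome-sizes table, GC drawn from a Beta
distribution matched to the human 1-Mb GC landscape) with cases carrying a
300-bin single-copy gain at tumour fraction Uniform(0.4, 0.9).
`simulate_alignments()` emits per-bin reads as SAM so the counting stage is
exercised at read level; counting its output reproduces the profile
exactly.

What the simulator does *not* reproduce: amplification jackpotting and
waviness of real whole-genome-amplified libraries (noise is exchangeable
across bins given GC), mappability structure (the truth behind $r_i$ is
flat), segmental artefacts, and subclonal heterogeneity (one clone per
case). Passing tests therefore demonstrate that the *pipeline recovers the
model it assumes* — correctness of the machinery, not clinical performance
on real urine. In particular the published training-cohort AUC and
validation-set sensitivities depend on per-patient scores that are not
public, and no simulation here claims to reproduce them; the cohort-level
checks assert separation (AUC ≥ 0.9 under a strong case model, AUC ≈ 0.5
under a null), which is the part a correct implementation controls.

## Numerical choices and degenerate inputs

* **GC fit fallback.** Below 100 usable bins the loess is replaced by
  median-within-GC-decile bins; with so few points a local regression is
  unstable. Above that, loess is used even for small genomes — a decile
  step function leaves visible within-decile trend (residual
  |correlation| ~0.2 on a 300-bin genome with a linear bias), which the
  loess removes to below 0.1.
* **Zero counts.** A bin with zero reads corrects to zero depth (not an
  error); an all-zero profile is an error. Bins at zero across the whole
  panel are masked in the reference rather than imputed, and masked bins
  are absent from all percentile computations downstream.
* **Recentring.** Whether the original method recentred $x_i$ per sample
  is not documented; recentring the autosomal usable median to exactly 2
  is adopted here because it makes profiles comparable across depths and
  makes the diploid null exact by construction. The trade-off: an
  aberration covering most of the genome would be partially absorbed —
  acceptable for ~10%-genome events, and the reason genome-scale fixtures
  are used for event-recovery tests.
* **ROC conventions.** Calls are strictly-greater at every threshold;
  thresholds are the distinct scores plus one below the minimum; AUC is
  the trapezoid over (FPR, TPR), which equals Mann–Whitney pair counting
  (ties count ½) — asserted against exhaustive enumeration in the tests.
  The cutoff maximizes Youden's J, ties broken toward the larger cutoff
  (higher specificity), the usual preference for a rule-out test. How the
  original study picked its cutoff of 24 from the ROC is not stated; Youden
  is this package's choice and a fixed cutoff can be supplied instead.
* **Exact tests.** McNemar is the exact binomial version
  ($p = \min(1, 2 P(X \le \min(b,c)))$, $X \sim \mathrm{Bin}(b+c, ½)$) —
  the chi-square approximation is avoided since discordant counts in paired
  assay comparisons are often small. Fisher's exact test enumerates
  margin-fixed tables up to total 500 and switches to seeded Monte Carlo
  above. Kappa's p-value uses the Fleiss large-sample null variance
  computed from the marginals.
* **Percentile degeneracy.** Fewer than 100 usable bins is an error for
  scoring (the 4%-wide window would hold fewer than 4 bins); `m >= p` is
  an error.

## Problem sizes in the test suite

Unit and property tests run on the 300-bin toy genome with 5M-read
profiles; genome-scale assertions (mixture recovery, 200-bin gain, cohort
separation) use the 2,897-bin hg19-scale map with panels of 8–10 normals
and cohorts of 12–15 per arm — sizes chosen so the full suite stays fast
while keeping per-bin depth at the ~1,700-read level the method targets.
Monotonicity-in-tumour-fraction uses 10 seeds per grid point.

## Known limitations

* No segmentation: the score works on per-bin values directly, so it
  quantifies *how much* of the genome deviates, not *where*; breakpoints
  and integer copy-number calls are out of scope.
* The score scale depends on $N$ (absolute sum over a ~4% window), so
  cutoffs do not transfer across bin sizes or genomes.
* Sex chromosomes are carried through normalization but excluded from
  scoring by default; an X-only aberration is invisible unless
  `include_sex_chroms = TRUE` on a same-sex panel.
* A flat pseudo-reference (`flat_reference()`) lets the pipeline run
  without a panel, but locus-specific bias then leaks into $x_i$ and
  inflates scores; it warns accordingly.
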