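---
title: "Models and methods behind reporterpos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reporterpos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reporterpos` quantifies how the genomic position of an ectopically
integrated beta-galactosidase (*lacS*) reporter cassette shapes its
expression in *Sulfolobus acidocaldarius*, a crenarchaeon whose circular
chromosome folds into a transcriptionally active A compartment and a
coalescin-enriched, quieter B compartment. The pipeline has four analysis
stages — enzyme-kinetic slope estimation, relative transcription by
delta-delta-CT, genome-context annotation, and cross-level correlation —
plus a seeded generator that emulates every input, so each stage can be
validated by recovering known ground truths.

## The kinetic model and the window-scan slope estimator

ONPG conversion curves (OD410 read every 5 min for 4 h at 42 °C, 49 points)
are summarised by their initial conversion slope, a proxy for LacS amount.
The model is a Monod-type saturation curve with a smoothed lag:

$$ OD_{410}(t) = \frac{sl \cdot dt \cdot m}{sl \cdot dt + m},
\qquad dt = \frac{(t - t_{off}) + \sqrt{(t - t_{off})^2 + d^2}}{2} $$

with `sl` the initial rate (OD410 min^-1), `m` the plateau, `t_off` the lag
offset (min) and `d` the transition width (min). The smoothed ramp `dt` was
chosen because its `d -> 0` limit is the hinge `max(0, t - t_off)` and its
large-`t` slope is exactly 1, so `sl` is the asymptotic initial rate — the
interpretation the parameter name demands. At `t = t_off` the ramp equals
`d/2`.

Because assay artefacts (substrate depletion, evaporation, drift) tend to
accumulate late in the run, the slope is not taken from one fit. The model
is fitted to every truncated window `t_0..t_k` for `k = 5..N-1`
(`fit_window()`), the residual standard error `sqrt(SSE/(n - p))` is traced
along `k`, and local minima of that trace are candidate stopping points
(non-strict comparisons, so plateaus qualify; endpoints compare against
their single neighbour). Among converged, adequate, local-minimum fits the
one with the smallest standard error of `sl` wins (`scan_and_select()`);
ties go to the larger window. A fit is *adequate* when it converged, `sl`
and `m` are positive, the relative SE of `sl` is at most 0.5, and `t_off`
lies within `[t_0 - 30 min, t_k]` — all four thresholds are exposed in
`kinetics_control()`.

When a curve's free scan selects nothing, `estimate_slope()` retries with
`d` frozen at the mean fitted `d` of sibling replicates (technical
replicates of the same biological replicate preferred), dropping one degree
of freedom; a curve with no usable siblings is reported as `failed` rather
than raising. Per strain, replicate slopes are combined by geometric mean
with geometric standard error, and the reported error escalates on the log
scale to the largest of the geometric SE, the mean relative per-fit SE, and
the within-biological-replicate spread of log slopes across technical
replicates (`aggregate_activity()`), so a bad fit or discordant technical
replicates can never be hidden by agreeable biology.

### Numerical choices

Fits use bounded Levenberg-Marquardt (`minpack.lm::nls.lm`; `sl, m > 0`,
`d >= 0`, at most 2000 objective evaluations, objective tolerance 1e-10).
Two deterministic starts are tried — a data-driven guess (steepest
three-point OLS slope; plateau at 1.5x the window maximum; offset where the
signal first clears the baseline by three baseline standard deviations;
`d` at the sampling interval) and the same start with the plateau scaled up
100x into the quasi-linear regime — and the lower-SSE solution is kept,
because curves that stay far below saturation leave `m` nearly free and the
likelihood surface correspondingly multimodal. Parameter standard errors
come from the curvature `J^T J` at the optimum restricted to the
identifiable subspace: columns with negligible curvature (a `d` pinned at
its zero bound, an `m` drifted far beyond the data range) are dropped
before inversion, and a parameter the data do not constrain reports `NA`.
Flat or all-zero curves get a floored slope initialisation (1e-8) and are
flagged inadequate instead of erroring.

### What the estimator can and cannot do

At the package's reference synthetic conditions (`m = 1`, noise sd 0.002,
slopes around 1.4-2.4 x 10^-4) a 4-h curve reaches less than 6 % of its
plateau, so `m` is barely identifiable and the local information bound on
the slope is roughly 9-16 % relative. Recovery of a single curve's slope is
therefore unbiased in the median but noisy (interquartile range about
+-4-8 %), with occasional large excursions that are genuine global
least-squares optima of the noise realisation, not optimizer failures.
Below that — curve maxima within about an order of magnitude of the noise —
the minimal-SE selection rule acquires a positive median bias (about +8 %
at `sl = 1e-4`), because windows whose noise exaggerates the slope also
look better determined. Replication, not post-processing, is the remedy the
pipeline assumes: the geometric mean over technical replicates shrinks
these errors by `1/sqrt(n)`.

## Relative transcription by delta-delta-CT

Quantification cycles from qRT-PCR (reference gene *tbp*, `saci_1336`) are
averaged over technical replicates, normalised per biological replicate as
`dCT = CT(target) - CT(reference)`, and expressed relative to the baseline
strain — the one with the lowest expression, i.e. largest mean dCT, with
lexicographic tie-breaking (`select_baseline()`). Per biological replicate,
`fold = E^-(dCT - dCT*)` with the baseline's mean dCT as `dCT*` (replicates
are not paired across strains) and amplification efficiency `E = 2` by
default (a configuration hook, not an estimate). The per-strain fold change
is the geometric mean of the per-replicate ratios, consistent with the
significance test: a two-tailed one-sample t test of the log2 ratios
against 0 with `n - 1` degrees of freedom. Zero-variance samples return no
p-value (flagged) rather than `p = 0`, and single-replicate conditions
return no p-value at all. No multiple-testing correction is applied — the
analysis reports per-strain tests, which is a known limitation.
Condition regulation (`condition_fold_change()`) compares a strain against
itself across growth conditions, each condition normalised by its own
reference-gene CT; `regulation_concordance()` classifies reporter-versus-
neighbour regulation with a 0.58 log2 (about 1.5-fold) threshold.

## Genome-context annotation

Coordinates are 1-based inclusive internally (GFF3 convention); BED input
is shifted at the reader boundary. Distances use the circular metric
`min(|a-b|, L-|a-b|)` on the 2,225,959-bp chromosome, so no distance
exceeds half the genome. Compartment labels come from the covering
interval; a site in an annotation gap takes the label of the nearest
interval boundary, mirroring gene-by-gene compartment lift-over between
strains. Replication-origin coordinates are an input table, not constants:
back-deriving them from published per-site distances gives positions that
disagree by ~0.1-2 kb between rows, so the packaged fixture treats
published distances as a soft check (+-2.5 kb) only.

Insulation is decided from the immediate flanking genes. A site inside a
gene is never insulated (the overlapped gene donates). Divergent flanks
whose promoters face the site insulate it. A flank transcribing toward the
site donates read-through unless a same-strand terminator lies between its
3' end and the site; co-operonic flanks always read through (genes sharing
an `operon_id` are one transcription unit). Converging 3' ends with no
terminator in between are genuinely unresolvable from annotation alone —
the classifier refuses to guess, reporting the nearer upstream gene as
donor with an `ambiguous` flag. The donor search deliberately stops at the
nearest flanking gene: read-through reasoning from more distant units would
require transcript evidence the pipeline does not consume.

## Correlation report

`fit_linear()` is ordinary least squares with `R^2 = 1 - SSE/SST` and a
two-tailed t test on the slope (`n - 2` df). `correlation_report()` joins
the three stage outputs on strain id (complete cases only) and regresses
activity on expression, expression on origin distance, and activity on
origin distance, on raw scales by default — matching how such scatter
analyses are usually displayed — with a log option off by default since the
choice is not dictated by the data.

## The synthetic generator

`study_mimic_config()` pins every generator truth that the study reports:
reference-condition fold changes 55 (slaA), 6.2 (vapC), 5.2 (ccc1),
1.88 (clsN), 1.86 (acad) and 1 for the arlJ baseline; per-strain true
slopes chosen so the compartment means equal 2.412e-4 (A) and 1.419e-4 (B)
with clsN, slaA and vapC the most active; per-strain pop-in fractions
averaging 0.56 % (A) and 0.22 % (B) with ccc1/slaA highest and acad/arlJ
lowest; site positions, nearest-gene loci, expression levels (CPM) and
essentiality ranks from the published site table; and the six site
topologies (divergent promoters for clsN and acad, downstream ORF for slaA,
sdhC, l2p and arlB, operonic for ccc1, pre-terminator for vapC, converging
3' ends for arlJ). Values the study does not print per strain are fixed
plausible choices: fold changes 3.0 (sdhC), 2.6 (l2p), 3.4 (arlB);
condition-regulation factors follow the reported qualitative directions
(down for slaA/vapC, up for sdhC/arlB, starvation-specific up for acad).
The fixture covers the nine successfully constructed strains; the two
integrations that failed in the study are not simulated.

CT noise is Gaussian on the cycle scale: technical sd 0.15, biological sd
0.2 by default, with the biological effect shared between target and
reference genes of the same sample — that models loading covariance, which
delta-CT cancels, making delta-delta-CT unbiased by construction. The
target base CT (26 cycles at the baseline unit) keeps all CTs
detector-plausible (> 8 cycles up to 60-fold). Kinetic curves add Gaussian
noise (sd 0.002 OD) to the model curve at `m = 1`, `t_off = 10`, `d = 5`
on the 0-240-min grid; screening counts are binomial draws at the
configured pop-in fractions out of 20,000 CFUs per strain. One global seed
expands into fixed per-stream subseeds (`stream_seed()`), so generating one
table never perturbs another, and equal seeds give byte-identical outputs.

What the generator does *not* emulate: pipetting or plate-position
artefacts, non-Gaussian CT outliers, amplification-efficiency differences
between primer pairs, substrate depletion or evaporation drift in late
kinetic time points, and any sequence-level structure. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimators under the stated noise model, not robustness to every artefact
of real plates.

## Problem sizes and runtime choices

The reference analyses use the study-scale design throughout: 9 strains,
3 biological x 3 technical qPCR replicates per condition, 49-point curves
with 3 technical replicates per strain on the kinetic plate, and 44-window
scans per curve. Property suites use 50-200 seeded repetitions (500 for the
null-uniformity check of the regression p-values), sizes at which every
Monte Carlo bound tested has comfortable margin while the whole suite runs
in minutes on a laptop.

## Command-line use

`inst/scripts/reporterpos` exposes the stages as verbs (`simulate`,
`kinetics`, `ddct`, `context`, `correlate`, `run-all`) for shell use; each
is a thin wrapper over the exported functions, and `run_all()` writes every
stage table as TSV plus a YAML run report with seed, row counts and
collected warnings.
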