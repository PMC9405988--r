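---
title: "Methods: PLV networks, permutation significance, band selection and tvDFC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLV networks, permutation significance, band selection and tvDFC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the analysis it
implements: the model and its assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, the
numerical conventions, and the design choices that were genuinely open.

## 1. The analysis in one paragraph

Subjects watching emotional videos click at the moment of a felt
emotion, label the click with one of 24 emotion words, and rate it on
valence/arousal/dominance (1–9) and liking/familiarity/relevance (1–5).
Around each click a 7-s EEG epoch (6 s pre, 1 s post; 250 Hz) is
band-limited into six bands, Hilbert-transformed, and cut into nine
overlapping 1-s windows. Per window and channel pair, the phase-locking
value (PLV) measures synchrony; connections that differ from baseline
epochs are identified with a max-statistic permutation test; emotion
labels are pooled into eight groups on the valence–arousal plane;
inter-group distances between significant-connection vectors select the
most discriminative frequency band; per-event temporal variability of
the connectivity profile (tvDFC) on that band is regressed on the
rating scales with mixed models; and eigenvector-centrality hubs are
screened against random graphs.

## 2. Epoching and segmentation conventions

* Event window: `[click − 6 s, click + 1 s)`, half-open in samples,
  exactly `7 × sfreq` samples. Events whose 7-s windows overlap within
  a subject are **all** removed (both members of a pair), mirroring the
  exclusion of overlapping clicks in the study design the pipeline
  follows. Windows that merely touch (`[14, 21)` and `[21, 28)`) do not
  overlap under the half-open convention.
* Baseline: 7-s windows drawn uniformly at random, pairwise
  non-overlapping, wholly inside `[10, 70]` s of the eyes-open baseline
  recording. Placement uses the uniform-spacings construction
  (sorted uniforms scaled by the slack), so the tight packing of
  `floor(60/7) = 8` windows always succeeds and a fixed seed reproduces
  identical starts. The per-subject default count matches the subject's
  retained event count, capped at 8 by the packing bound; whether
  baseline windows may overlap is not specified anywhere, and
  non-overlap is enforced as the conservative choice.
* Segmentation: 250-sample windows, 175-sample step, 0-based half-open
  `[k·175, k·175 + 250)` for `k = 0..8` — nine segments per epoch, the
  last covering `[1400, 1650)`. The printed segment bounds imply a
  75-sample (30%) overlap; a nominal "33%" figure circulating for this
  segmentation is inconsistent with those bounds, and the bounds win.
  The window count obeys `1 + floor((L − w)/s)` and is property-tested
  against brute-force enumeration.

## 3. Filtering and phase estimation

Band edges are delta 1–4, theta 4–8, alpha 8–12, lower beta 12–20,
upper beta 20–30, gamma 30–40 Hz. Filtering is a 4th-order Butterworth
band-pass applied forward and backward (`filtfilt`), giving zero phase
distortion — essential because everything downstream lives on Hilbert
phases. No DSP package ships with the target environment, so the
bilinear-transform design and the odd-reflection-padded
forward–backward runner are implemented in `R/filters.R` and tested
against frozen reference coefficients and frequency responses.
Two numerical consequences are documented rather than hidden:

* an order-4 zero-phase band-pass attenuates a 50 Hz tone through the
  1–40 Hz filter to ≈ 15% RMS, not to < 5% (that would need ≈ order 8);
  the tests assert the true response;
* the six band filters overlap at their crossovers, so the sum of the
  band epochs reconstructs the 1–40 Hz signal only up to filter-bank
  leakage; the documented tolerance is 35% relative RMS on white noise.

Instantaneous phase is the argument of the FFT analytic signal computed
on the **full 7-s epoch**, never per 250-sample segment: segment-level
phases are sliced afterwards, so Hilbert edge distortion is confined to
the epoch ends rather than appearing at every window boundary. Whether
phases should be estimated per epoch or per segment was an open choice;
per-epoch estimation was selected for exactly this reason.

## 4. PLV and the per-event design choice

`PLV = |mean(exp(i·Δφ))|` over a window's 250 samples. It is 1 for any
constant phase relation, 0 for antipodal alternation, invariant to a
common phase offset, and `E[PLV²] = 1/N` for independent uniform
phases (the Rayleigh null, used as a calibration test). PLV is averaged
over *time within a segment for a single event*, not across trials:
the event-level regression and tvDFC need one network per event and
segment. Channel pairs are indexed lexicographically (`i < j` in
recording channel order) and that ordering is persisted in every output.

## 5. Significance against baseline: max-statistic permutation test

For one (band, segment, emotion group): event PLVs versus baseline-epoch
PLVs, per pair, with the pooled-variance two-sample t statistic. Using
t rather than the raw mean difference normalizes per-pair variability,
which the single-threshold method implicitly assumes when it compares
every pair against one distribution of maxima. Permutations exchange
condition labels **within subject** (each subject keeps its event and
baseline counts); this is the closest exchangeable scheme to a "related
samples" design in which subjects contribute unequal numbers of epochs
to both conditions, and it inherently respects between-subject
variability. Per permutation the maximum |t| over pairs is recorded;
the critical value is the `(c+1)`th largest of the `N` maxima with
`c = floor(alpha · N)`, and per-pair adjusted p-values use the add-one
convention `p = (1 + #{max ≥ |t|}) / (N + 1)`, so the smallest
attainable p is `1/(N+1)`. The test is two-sided (|t|): both hyper- and
hypo-synchrony count. Defaults: `alpha = 0.01`, `n_perm = 1000`,
seeded. Stepwise (Bonferroni–Holm-style) adjustment is sometimes quoted
alongside single-threshold testing, but the two do not compose into one
procedure; a single mechanism — the max-statistic adjusted p compared
to 0.01 — is implemented, since the single-threshold test is itself the
multiple-comparison correction.

## 6. Emotion grouping

Labels are pooled into `k = 8` groups by (1) proximity of per-label
mean positions on the valence–arousal plane and (2) approximate
instance balance. No algorithm is prescribed by those two criteria, so
the package uses the most auditable deterministic pair: complete-linkage
agglomerative clustering on Euclidean V–A distances, followed by a
greedy rebalancing pass that repeatedly moves the best-fitting label
from the most oversized group (> (1 + tol)·total/k, default tol = 25%)
to the nearest undersized group, stopping when balanced, when no move
improves the worst ratio, or when a group would be emptied. Groups are
numbered by descending mean valence (arousal as tie-break), giving a
stable "pleasant first" ordering. With all labels at one V–A point the
geometry is degenerate and the balancing pass alone determines the
partition — tested explicitly.

## 7. Band selection: connectivity distances and Gcst

Per (band, segment, group), significant pairs become a weighted
multi-hot vector (group-mean PLV where significant, 0 elsewhere).
Euclidean distances between all `C(8,2) = 28` group pairs, averaged
over the nine segments, give 28 pooled distances per band; their grand
mean over all bands is the global threshold **Gcst**. Each band's 28
distances are tested against Gcst with a one-sample t-test (df = 27),
one-sided (greater), Bonferroni-corrected by the number of bands;
Cohen's d = (mean − Gcst)/sd. Bands whose connectivity vectors are all
zero (nothing significant anywhere — common at desk scale) have
zero-variance distances; the operation errors per contract and the
pipeline records such bands as `t = 0, p = 1`, not selected. The two
top bands are additionally compared with a paired t-test on the 28
matched distances (Cohen's d = mean difference / sd of differences).
tvDFC and the regressions run only on the selected band unless
`band_override` forces one.

## 8. tvDFC and the mixed models

tvDFC is computed **per event**: the event's own per-segment PLV values,
masked by its group's per-segment significance mask, give nine vectors;
tv is the mean of the eight consecutive-segment Euclidean distances.
(Whether variability should be per event or per group was open; the
regression pairs tv with event-level ratings and subject random
effects, which forces the event level.)

The regression is `scale ~ tv + (1 | subject)` fitted by REML (lme4),
with both predictor and outcome z-scored first — slopes near 0.5 on a
1–9 rating scale are only interpretable as standardized coefficients,
so standardization is assumed and documented. Inference is Wald:
`t = β/se`, p from the normal reference, `CI = β ± 1.96·se`.
Satterthwaite degrees of freedom are not available in the target
environment; the normal reference is accurate at the hundreds of
events the design produces. Singular fits (subject variance estimated
at zero) are valid boundary solutions and collapse exactly to OLS,
which is tested; they are not flagged as failures. The follow-up
logistic mixed model binarizes tv at the within-dataset median ("high
temporal variability" has no prescribed cut) and tests the
arousal × dominance interaction with `glmer`; separation and
convergence warnings flag the fit rather than silently falling back.

## 9. Hubs

The hub adjacency pools the selected band across segments and groups:
for each pair, the mean weight of its significant appearances (union
scope; configurable). Eigenvector centrality is the principal
eigenvector of the symmetric adjacency, computed by dense symmetric
eigendecomposition on the largest connected component, zero elsewhere,
normalized to unit Euclidean norm (Perron non-negativity enforced).
The null is 10,000 Erdős–Rényi graphs at the observed density; a
channel is a hub when its centrality exceeds the 95th percentile of the
**pooled** null centralities — the simplest defensible reading of
"less than a 5% chance of being randomly selected". A rank-matched or
max-centrality null would be stricter alternatives; the pooled null is
slightly conservative in calibration tests because ties at zero inflate
the null mass. Weighted adjacency is used (binarization would discard
the PLV weights); the null graphs are binary at matched density, which
is the standard practice this choice mirrors. Density 0 or 1 makes the
null degenerate and errors.

## 10. The synthetic world: what it does and does not establish

`make_recording()` builds each channel as a sum over the six bands of a
constant-amplitude carrier at the band center with a diffusing phase
(Gaussian increments, 0.12 rad/sample — a coherence time of roughly
half a second, which keeps 1-s-window PLVs of independent channels well
away from both 0 and 1, as in real EEG), plus 1/f-shaped Gaussian
background noise (`signal_noise_sd`, default 6 µV against band
amplitudes `10/sqrt(f_c)` µV). A coupled pair in a band rewrites the
second channel's phase inside applicable event windows as the first
channel's phase plus a constant lag plus i.i.d. von Mises jitter with
concentration `4κ/(1−κ)` (∞ at κ = 1, uniform at κ = 0): κ = 1 yields
a constant lag and near-unit measured PLV; κ = 0 is indistinguishable
from no coupling; measured PLV is monotone in κ (tested over 50-seed
ensembles). Each event carries a hidden variability index
`v ~ U(0, 1)` that scales the jitter concentration block-wise across
the epoch (nine blocks, factor `1 − 0.95·v·U(0,1)` per block), so
high-v events have connectivity that reshapes from segment to segment;
the arousal rating is the label prototype plus `tv_slope · v` plus
Gaussian noise, clipped to scale.

What this emulates: band-limited oscillatory structure, realistic
segment-PLV null variability, event-locked coupling contrasts, group-
discriminative network structure, and a ground-truth link from
connectivity variability to arousal. What it does not: volume
conduction and reference effects, artifacts (blinks, EMG), amplitude
dynamics and cross-frequency structure, discrete rating scales
(ratings are continuous before clipping), and head geometry. A green
test therefore establishes that the *statistical machinery* behaves as
specified under a known generative model — not that the biology would
cooperate.

Two consequences worth stating plainly. First, pipeline-level recovery
of `tv_slope` from *measured* tvDFC is attenuated by estimation noise
and confounded by between-group differences (arousal prototypes differ
by group, and so do group masks), exactly as an observational analysis
would be; the regression-recovery acceptance test therefore runs at the
models-module level on records whose standardized slope is exact by
construction (variance budget β² + 0.09 + σ² = 1), while the generator's
own rating link is verified by regressing arousal on the injected index.
Second, at desk scale most bands have no significant connections at
all, which is why the degenerate band handling of section 7 exists.

## 11. Defaults that matter

| parameter | default | unit | why |
|---|---|---|---|
| `alpha_edges` | 0.01 | level | FWER level of the connection test |
| `n_perm` | 1000 | count | permutation resolution (min p ≈ 0.001) |
| `alpha_hubs` | 0.05 | level | hub exceedance probability |
| `n_random_graphs` | 10000 | count | ER null size |
| filter order | 4 | — | standard EEG Butterworth order; zero-phase |
| window/step | 250 / 175 | samples | the printed segmentation layout |
| `balance_tolerance` | 0.25 | fraction | "approximately equal" group sizes |
| `baseline span` | 10–70 | s | eyes-open baseline interior |
| `sfreq` | 250 | Hz | acquisition rate; must exceed 80 Hz |
| `signal_noise_sd` | 6 | µV | 1/f background vs 2–10 µV band carriers |
| `phase diffusion` | 0.12 | rad/sample | ~0.5 s coherence time |

## 12. Known limitations

Filter-bank leakage (section 3) makes the band sum an approximation of the
wideband signal; the permutation test needs every subject in both
conditions and at least two epochs per condition; groups with fewer
than two events are skipped (and logged) rather than tested; the hub
null compares weighted observed centralities against binary null
graphs, which is conventional but not scale-free; and the CLI is a
thin wrapper — the package API is the primary interface.
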