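---
title: "Methods: multi-region LFP rhythmicity analysis for social discrimination tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region LFP rhythmicity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`sblfp` implements an analysis pipeline for multichannel local field
potentials (LFP) recorded while a subject discriminates between two stimuli in
one of three social contexts: social preference (SP: social vs. object),
emotional-state preference (EsP: isolated vs. grouped) and sex preference
(SxP: female vs. male). Each session comprises a 5-minute baseline with empty
chambers and a 5-minute encounter with the stimuli present. The pipeline
quantifies rhythmic activity in the theta (4–12 Hz) and gamma (30–80 Hz)
bands at three time scales — the whole session, investigation bouts, and
individual behavioral events — and asks how band power, inter-regional
coherence and directed (Granger) influences change with the social context.
Because desk-scale validation cannot use the original recordings, a synthetic
multi-region LFP generator with known ground truth accompanies every stage.

## Data model

A `recording_session` holds a regions × samples matrix (microvolts), region
labels from an 18-region vocabulary, the sampling rate, half-open
baseline/encounter intervals in seconds from session start, the
chamber-to-stimulus map, and stimulus insertion/removal times. A `bout_table`
lists timed investigation bouts toward labeled stimuli; baseline bouts toward
the still-empty chambers carry the reserved label `"empty"`. Signals within
±30 s of insertion or removal are excluded from all period statistics
("around" is read as a symmetric ±30 s window; the half-width is a
parameter). Region eligibility requires strictly more than 5 sessions across
at least 3 subjects; pair eligibility requires at least 5 joint sessions from
at least 2 subjects covering all three tasks. Only bouts strictly longer than
2 s are analyzed (the threshold is configurable; the strict reading was
chosen because short bouts preclude reliable theta-coherence estimation).
The relative discrimination index is RDI = (T_preferred − T_other) /
(T_preferred + T_other) over encounter investigation times; the formula
follows the protocol literature this index originates from.

On disk, a session is a directory holding an Arrow/Feather table of signal
columns, a JSON sidecar with the metadata, and a CSV bout table. Reading
validates every invariant and reports the offending file and field.

## Spectral power

Traces are decimated to 5 kHz with Butterworth anti-aliasing and low-passed at
300 Hz (order 4, applied forward–backward so filtering is zero-phase; the
order is a documented choice). Spectrograms use discrete prolate spheroidal
(Slepian) tapers on 2-s windows with 0.5 Hz frequency increments. The printed
combination of a 2-s window, 50% overlap and 0.5-s time bins is
self-contradictory; the 0.5-s output bin wins (stride 0.5 s, i.e. 75%
overlap) because the event-aligned Z-scores are defined on 0.5-s bins. The
taper configuration is time–bandwidth NW = 2 with the first 3 tapers
averaged, giving a ±1 Hz resolution bandwidth consistent with the 0.5 Hz
grid; this too is a documented choice where the source names only "dpss".
DPSS tapers are computed from the classical symmetric tridiagonal
eigenproblem (no installed package provides them); windows longer than 2049
samples use spline interpolation of a 2049-point solution followed by
re-orthonormalization, and taper quality is verified spectrally
(concentration of the third taper > 0.9 in tests).

Band power is the mean PSD over a band's frequency bins per 0.5-s time bin.
Session-wide change (∆θP, ∆γP) is the encounter-period mean minus the
baseline-period mean, masked bins excluded. Bout-locked power (^∆θP, ^∆γP)
is the average power per second over a stimulus's valid bouts minus the same
quantity over baseline empty-chamber bouts; "per second" is realized as the
duration-weighted mean over concatenated bout bins (total power-seconds /
total seconds), with a per-bout-then-average variant available. Event-aligned
analysis Z-scores each 0.5-s bin in [−5, +5] s around an event against the
mean and SD of the 5-s pre-event window, averages within a session per event
category, then across sessions; events with an incomplete pre-window or zero
pre-event SD are dropped. An exactly constant power trace therefore yields no
usable events rather than a 0/0 trace.

## Coherence

Magnitude-squared coherence is Welch-estimated:
MSC(f) = |S_xy(f)|² / (S_xx(f) · S_yy(f)). The source prints the
complex-valued coherency S_xy/√(S_xx S_yy) but names the magnitude-squared
estimator; the squared form is implemented. Session-wide spectra use 2-s Hann
segments with 50% overlap. The normalized change statistic is
∆Co = μ(d)/σ(d) with d(f) = MSC_encounter(f) − MSC_baseline(f) taken across
the band's frequency bins — the only axis that yields one number per pair and
session from the stated inputs; σ is the sample SD. A degenerate σ = 0 maps
to ∆Co = 0 with a flag. Bout-locked coherence uses 1-s sub-windows with 50%
overlap strictly inside bouts (a 2-s window would exclude most bouts despite
the > 2 s filter), pooled over a stimulus's bouts, referenced to the pooled
baseline empty-chamber bouts. Pooling sub-windows before averaging implements
the same duration weighting as the power analysis. With n independent
segments the MSC of incoherent signals has expectation ≈ 1/n; this bias floor
is part of the estimator's contract and is tested. Because the floor shrinks
with bout time, bout-locked values referenced to the long empty-chamber
segment carry a small positive offset that is common to all pairs and tasks;
the decoder's per-mouse normalization and the change statistics difference it
away.

## Granger causality

For directed influences the traces are further decimated to 500 Hz (steep FIR
anti-alias below the 250 Hz Nyquist, zero-phase by group-delay compensation).
The VAR pipeline mirrors the standard multivariate GC toolchain:

1. model order by BIC = ln det(Σ_p) + ln(T)·n²p/T, all orders fitted in one
   Levinson–Whittle pass (search range 1–30 by default; the boundary order is
   accepted for LFP, which is not a finite-order VAR);
2. VAR coefficients by the multichannel Levinson–Whittle recursion on sample
   autocovariances (demeaned per channel; ordinary least squares is retained
   as a cross-check and the two agree to 10⁻² on simulated VARs);
3. the model autocovariance sequence from the companion-form discrete
   Lyapunov equation (doubling iteration) extended by the Yule–Walker
   recursion, truncated on decay below 10⁻⁸ of Γ₀ and capped at 1500 lags;
4. spectral pairwise-conditional GC: for each source channel the reduced
   model (source omitted) is re-derived from the autocovariance submatrix by
   the same Whittle recursion, and the partitioned transfer-function formula
   gives Geweke's conditional spectral GC, non-negative by construction;
5. band values are bandwidth-normalized means over band bins, so values are
   comparable across bands; over the full range the trapezoidal average
   reproduces the time-domain GC (Geweke's equality, verified to 10⁻³).

The estimator battery is validated against a closed-form oracle: for the
bivariate VAR(1) "x drives y" system with coupling a and noise variances
σx², σy², the time-domain GC is ln(1 + a²σx²/σy²); a 3-channel chain
x→y→z must show conditional GC(x→z | y) ≈ 0.

Encounter-versus-baseline change fits separate models per period (each with
its own BIC order by default; a shared fixed order is available), splits
periods around the exclusion windows and treats the contiguous pieces as
multiple trials of one fit. Across sessions each directed pair is tested with
a two-sided paired Wilcoxon signed-rank test and BH correction — the source
does not name its test for these changes, so this conservative nonparametric
choice is declared here. Directional asymmetry tests
d = change(1→2) − change(2→1) against zero the same way.

## Screening statistics

Stimulus bias of a bout-locked metric is value(preferred) −
value(less-preferred) with the task's preferred stimulus fixed (SP: social,
EsP: isolated, SxP: female). Units crossing mean ± 1.5 SD of the bias
distribution are selected ("crossed" read strictly; boundary ties excluded).
Region over-representation among selected pairs uses the exact binomial tail
P(X ≥ k) with p₀ the region's share of the universe pairs. Octant
classification assigns each region its bias-sign triple across the three
tasks and reports the exact binomial tail probability of the observed
maximum-octant count under uniform 1/8 assignment — the transparent
construction; the original's "1-binomial" bound is ambiguous, so no attempt
is made to reproduce its printed value. Group comparisons screen normality
with Shapiro–Wilk and dispatch paired t / signed-rank, t / Mann–Whitney, or
ANOVA / Kruskal–Wallis with a hand-implemented Dunn post-hoc (no installed
package provides Dunn's test); multiple comparisons use Benjamini–Hochberg
throughout.

## Context decoder

Decoder rows are "average bouts": one row per session × stimulus with one
column per eligible region pair, holding that stimulus's mean bout coherence
change; pairs not recorded in a mouse are explicit missing entries. Mice with
fewer than 40 recorded pairs (of the study's 99) are excluded; at synthetic
scale (45 pairs from 10 regions) the threshold scales to 18, preserving the
~40% proportion. Per-mouse normalization averages the per-stimulus means of
each pair and subtracts that average — balancing stimuli so none is
over-represented — and the unweighted stimulus-mean of the normalized values
is exactly zero.

Imputation is iterative regression in the spirit of chained equations:
initialize missing entries with the pair's observed mean; then for 20
iterations visit pairs in fresh random order, draw a random predictor set of
other pairs of size min(⌊0.5·n_rows⌋ − 1, n_pairs − 1) — the source bounds
the set strictly below half the equation count yet reports 66 predictors for
131 rows, which violates its own bound, so the strict bound wins — fit least
squares with intercept on all rows (a fit-on-observed-only mode exists), and
overwrite originally-missing entries with predictions. Observed entries are
never altered; rank-deficient fits take the pivoted-QR solution with aliased
coefficients zeroed.

Classification is a leave-one-mouse-out random forest (80 trees, default
splitting elsewhere), class-balanced per repeat by random down-sampling, 100
repeats per mouse (20 in the reduced end-to-end runs); confusion matrices are
percentages of each ground-truth column. The null replaces the forest with
uniform random labels over the same folds: 83 null matrices per mouse, each
averaging 100 inner repeats, so every cell has expectation 100/K %. Per-cell
significance compares the 12 per-mouse real percentages with all per-mouse
null values by two-sided Mann–Whitney, dropping mice that lack a class, with
BH across cells. A diagonal cell is read as evidence of decoding only when it
is significant *and* above the chance level: because the trained classifier's
per-mouse percentages are far more dispersed than the tight random-classifier
null, a no-signal dataset occasionally yields a diagonal cell significantly
below chance (anti-learning on correlated rows), which is not decoding. The 6-stimulus and 3-context labelings share one imputed
table (labels play no role in imputation). All randomness — balancing,
predictor draws, forests, null labels — derives from one master seed through
named substreams, and every simulated session receives its own seed drawn
from a single master RNG stream (a seed table). The seed table matters:
deriving session seeds from label strings leaves residual correlations
between the streams of same-task sessions, strong enough to make a no-signal
dataset spuriously decodable in leave-one-mouse-out cross-validation; with
independent per-session seeds the zero-effect dataset shows no significant
confusion cells.

## Synthetic data generator

The generator is the pipeline's ground-truth source, not a fixture. Band
oscillators are band-limited Gaussian noise (4th-order Butterworth magnitude
profiles synthesized spectrally), not pure tones, so spectra resemble LFP and
coherence estimates are non-degenerate. Each region's band component mixes a
global shared source (weight w), optional pair-private signature sources, and
an independent remainder, normalized to unit band variance, so a pair's
oscillator coherency is the product of its shared weights and its MSC the
square of that. A pink (1/f) background sits underneath; because it dilutes
the mixed-oscillator coherence, target coherences are reached through a
simulated calibration map from weight to realized MSC rather than analytic
inversion. Defaults: 5 kHz sampling, 300 s + 300 s periods, theta amplitude
1.0, gamma 0.5, pink 0.6 (30 µV overall scale), shared weights 0.75/0.6
(baseline theta MSC ≈ 0.27 after dilution), encounter amplitude gains 1.3
(theta) and 1.15 (gamma) emulating the encounter-induced global state.

Bouts follow an alternating renewal process: exponential gaps (mean 10 s,
minimum 0.5 s), lognormal durations (median 4 s, σ_log = 0.5, so ~92% of
bouts pass the 2-s filter), stimulus chosen with preference odds 2:1 (RDI
≈ 1/3, within the range typical of these tasks). Context signatures add
pair-private shared sources during a task's encounter bouts while shrinking
the independent component, raising those pairs' bout coherence at constant
band power. Directed influences for GC scenarios add a scaled, lagged copy of
a source region's signal to a target during a chosen period. Per-subject
region dropout emulates mistargeted electrodes; ground truth records the
missingness map, realized in-band component variances and all applied gains.

What the generator does not emulate: volume conduction and its
distance–coherence structure, non-stationary drift, movement or chewing
artifacts, cross-frequency coupling, and spike leakage. Passing tests
therefore demonstrate estimator correctness and pipeline recovery of known
effects, not robustness to those real-data phenomena.

## Problem sizes and numerical choices

Pipeline-level simulations run at 500 Hz — the Granger stage's own analysis
rate, with both bands far below Nyquist — keeping full 300 s + 300 s sessions
and the complete 12-subject × 3-task × 3-session design for the end-to-end
decoding study (features are extracted streaming, one session in memory at a
time); the decoder's repeats are reduced to 20 there, and estimator oracles
use 10⁵-sample series. The 5 kHz default remains for the preprocessing path,
which is exercised separately. Numerical guards: spectral and band GC values
are clipped at zero from below (the partitioned formula is non-negative up to
rounding); unstable fitted VARs abort with the spectral radius; Lyapunov
solutions are checked for positive definiteness; degenerate coherence-change
SDs map to zero with a flag; zero-bias octant signs tie-break positive with a
warning.

## Known limitations

The μ/σ axis of the coherence-change statistic and the exact dpss taper
count are interpretations of underspecified methods text, flagged above. The
uniform-random-classifier null tests calibration of the confusion pipeline,
not of the feature distribution; a label-permutation null would bound chance
performance more tightly and is not part of the replicated design. Bout-MSC
bias depends on total bout time, so stimuli with little investigation carry a
larger positive offset; analyses difference this against a reference, but
very sparse stimuli are reported as missing rather than estimated. The
octant arrangement probability is reported for a fixed octant, which
under-counts the multiplicity of "any octant"; both numbers are computable
from the returned counts.
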