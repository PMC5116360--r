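---
title: "Matching-pursuit HRV features for short-term CHF screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching-pursuit HRV features for short-term CHF screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvmp)
```

## The problem

Congestive heart failure (CHF) alters the autonomic control of the heart,
and with it the structure of beat-to-beat (RR interval) variability.
Long-term (24 h) heart-rate-variability analysis discriminates CHF from
normal sinus rhythm (NSR) well, but requires continuous monitoring.
`hrvmp` implements a short-term alternative: a screening pipeline that works
from a single 256-beat (~5 minute) RR segment.

The pipeline is:

1. **Preprocessing** — a 256-beat segment is cubic-spline resampled onto
   1024 evenly spaced points and detrended with a smoothness-priors filter.
2. **Matching pursuit (MP)** — the segment is greedily decomposed over an
   overcomplete dictionary of Gabor atoms
   $\phi(t) = A\,e^{-\pi((t-u)/s)^2}\cos(w(t-u)+\varphi)$, 30 atoms per
   segment.
3. **Features** — 16 scalars summarise the decomposition: residual-energy
   decay per band and in total, Welch band powers of band-restricted
   reconstructions, energy entropies over the LF and HF atoms, and the
   distribution of atom centre frequencies over the VLF/LF/HF bands.
4. **Classification** — min-max scaling, a k-nearest-neighbour classifier
   under 23-fold cross-validation, and a genetic algorithm (GA) that
   searches the $2^{16}$ feature subsets for the lowest cross-validated
   error.

The discriminative idea is structural: NSR variability is noise-like
(*noncoherent*), so MP needs many atoms and the residual energy decays
slowly; CHF variability is dominated by a few slow coherent oscillations
that MP captures almost immediately.

## Preprocessing choices

**Grid convention.** A fixed-length input is required by the dictionary, so
the resampler always emits `n_out = 1024` samples spanning
$[0, \sum_k RR_k]$ and records the effective sampling rate
$f_s = (n_\text{out}-1)/\text{duration}$. The nominal design (4 Hz over
256 beats) only holds exactly when the segment lasts 255.75 s; for a mean
RR of 800 ms the effective rate is $1023/204.8 \approx 4.995$ Hz. All band
arithmetic downstream uses the recorded effective rate, so band edges in Hz
are exact for every heart rate.

**Spline dialect.** The tachogram knots are $(t_k, RR_k)$ with
$t_k = \sum_{i \le k} RR_i$; a natural cubic spline interpolates them, and
its natural (linear) extrapolation covers $[0, t_1)$. A natural spline
through collinear points reproduces the line exactly, which is the property
the tests pin down.

**Smoothness priors.** The trend is
$\hat z = (I + \lambda^2 D_2^\top D_2)^{-1} x$ with $D_2$ the
second-difference operator, solved sparsely; the detrended signal is
$x - \hat z$, mean-subtracted. $\lambda = 500$ — a widely used value for
~4 Hz HRV — puts the effective high-pass cutoff near 0.035 Hz, i.e. just
below the VLF/LF boundary. As $\lambda \to 0$ the trend converges to the
signal itself and the detrended output to zero; as $\lambda \to \infty$ it
converges to removal of a straight-line fit. Note the consequence: content
in the lower half of the VLF band is strongly attenuated before feature
extraction, so VLF features mostly reflect the 0.02–0.04 Hz range.

## Dictionary and matching pursuit

**Discretisation.** The dictionary uses the canonical dyadic grid: scales
$s = 2^j$ up to the signal length, translations every $s/2$ samples, and
angular frequencies $w = \pi k/s$, $k = 0..s$ — about 22,500 parameter
triples at $n = 1024$, comfortably overcomplete.

**Phase.** Phase is not discretised. For each $(s,u,w)$ the decomposition
projects the residual onto the quadrature (cosine/sine) pair and maximises
over their two-dimensional span in closed form:
$\max_\varphi \langle R, \phi_\varphi\rangle^2 =
(a^2 - 2\rho a b + b^2)/(1-\rho^2)$, where $a, b$ are the projections onto
the unit-normalised pair and $\rho$ their inner product. This is exact (the
tests confirm it against numeric phase search) and as cheap as one matrix
product per iteration. Frequencies $w = 0$ and $w = \pi$ have a vanishing
sine partner and are treated as cosine-only atoms. Selection ties break to
the lowest triple index, so decompositions are deterministic.

**Energy bookkeeping.** The residual energy is recomputed from the residual
vector after every iteration, so
$\|x\|^2 = \sum_n c_n^2 + \|R^M\|^2$ holds to floating-point accuracy, and
the recorded residual series — not the coefficient magnitudes, which MP
does not order in general — is the monotone quantity.

**Band attribution.** Each atom is assigned wholly to the band (Task Force
edges: VLF 0.003–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz) containing its centre
frequency $w f_s/2\pi$. For well-localised atoms this coincides with
integrating the atom's cross-term-free time-frequency density over the
band; a full Wigner–Ville treatment is deliberately out of scope.

## The sixteen features

In fixed order (`feature_names()`):

| group | features | definition |
|---|---|---|
| residual decay | `E_vlf, E_lf, E_hf, E_total` | iteration-averaged (band) residual energy, per unit signal energy |
| band power | `psd_vlf, psd_lf, psd_hf, psd_hf_vlf, psd_lf_hf` | Welch PSD sums of band subsignals (rectangular window, 256-sample frames, 50% overlap), per unit mean square; HF/VLF ratio; LF+HF sum |
| entropy | `H_lf, H_hf` | $-\sum_{n \in band} p_n \log_2 p_n$ with $p_n = c_n^2/\sum c_n^2$ |
| atom counts | `D_lf, D_hf, D_hf_vlf, D_vlf_lf, D_lf_hf` | band atom fractions out of $M = 30$, and their ratios |

Three conventions are worth flagging because the defining equations leave
them open:

* **Normalisation of absolute powers.** Band powers are stored per unit
  signal energy, making every feature invariant to positive rescaling of
  the input (ms vs s units); min-max scaling downstream would otherwise
  absorb the convention anyway, but invariance makes it testable.
* **Entropy normalisation is global.** $p_n$ is normalised over all 30
  atoms and only the summation is band-restricted; renormalising within the
  band would instead measure band-internal uniformity and lose the
  band-energy weighting. With global normalisation $H_w(band) = 0$ can mean
  either one dominant band atom or a nearly empty band — both CHF-like HF
  signatures.
* **Ratio policy.** Denominators below $10^{-12}$ are replaced by
  $10^{-12}$ and the ratio capped at $10^6$, keeping the table finite when
  a band is empty; min-max scaling compresses the caps.
* **LF+HF.** The feature inventory names the band-power sum; it is
  implemented literally as `psd_lf + psd_hf`.

**Welch estimator.** The defining recipe is a rectangular window of length
256 with 50% overlap; the often-cited `pwelch` defaults (Hamming, 8
segments) differ, so window and frame length are exposed as arguments. The
estimator is scaled so that the one-sided density integrates to the signal
mean square (Parseval), verified against a direct DFT periodogram in the
tests.

## Classifier and subset selection

**KNN.** Euclidean distances, odd `k` (default 5) so a two-class vote
cannot tie, distance ties to the lower training index. The implementation
is matrix-based and checked for exact agreement against an exhaustive
distance-sort oracle.

**Cross-validation.** 69 samples in 23 seeded folds of 3. Test predictions
are pooled into a single confusion matrix before computing sensitivity
(CHF positive), specificity and accuracy: with 3-sample folds, per-fold
averaging of Se/Sp is frequently undefined, so pooling is the only
well-defined reading. The GA fitness is $\theta = 1 - \text{Ac}/100$.
Min-max scaling is applied to the full table by default (the dataset-level
convention the configuration labels imply); `scale_in_fold = TRUE` gives
the leakage-free variant for comparison.

**Misprint note.** Published shorthand for sensitivity occasionally divides
by $TP + FP$; the standard forms $Se = TP/(TP+FN)$, $Sp = TN/(TN+FP)$ are
implemented.

**GA.** Binary chromosomes over the 16 features; population 300; at most
100 generations; double (two-point) crossover with probability 0.7;
per-bit mutation 0.05; linear-rank selection (pressure 2.0, a concrete
choice where only "rank-based" is specified) with 2-elitism; stop early
when the best-ever fitness has not strictly decreased for 30 generations.
Although the approach is sometimes labelled a filter, the fitness is the
wrapped classifier's CV error, so operationally it is a wrapper. Children
with an empty mask get the worst fitness (1) rather than being redrawn, and
fitness is memoised per mask — the mask space has only $2^{16}$ points, so
a default run typically evaluates a few thousand distinct subsets. Runs are
fully deterministic given the seed.

## The synthetic cohort

Real CHF/NSR recordings cannot ship with the package, so the generator
emulates the two populations' spectral signatures directly. Interval $k$
is

$$RR_k = \overline{RR} + \sum_{b \in \{VLF, LF, HF\}} A_b
\sin(2\pi f_b t_{k-1} + \varphi_b) + w_k + p_k,$$

with $t_{k-1}$ the cumulative beat time, $w_k$ white noise, $p_k$
1/f-coloured noise, random phases per realisation, and clipping to
[200, 2500] ms. Sinusoids at fixed frequencies make band-power ground
truth analytic.

Preset parameters (ms):

| class | mean RR | VLF | LF | HF | white | 1/f |
|---|---|---|---|---|---|---|
| NSR | 900 | 3 | 20 | 25 | 28 | 32 |
| CHF | 700 | 35 | 10 | 1.5 | 4 | 2 |

The presets were calibrated once so that the generated populations exhibit
the qualitative contrasts the method exploits, and then frozen: NSR is
noise-dominated (slow MP decay, high HF power and HF entropy, more LF
atoms), CHF is dominated by coherent slow oscillations (fast decay,
suppressed HF, elevated VLF). Both presets place the VLF modulation at
0.035 Hz rather than the generic 0.01 Hz default because the
smoothness-priors detrender ($\lambda = 500$) would remove a 0.01 Hz
component almost entirely — with only ~2 cycles in a 256-beat segment it is
also spectrally unresolvable. Cohorts apply ±10% uniform per-subject jitter
to the mean RR and the three amplitudes: enough within-class spread to be
non-trivial, not enough to destroy separability. The default cohort is 40
NSR + 29 CHF subjects, one segment each.

What the generator does **not** emulate: ectopic beats and artefacts,
respiratory frequency drift, nonstationary amplitude modulation,
inter-subject differences in band *frequencies*, or the selection of
segments from long recordings. Passing tests therefore demonstrate the
pipeline's internal correctness and its sensitivity to the intended
spectral-structural contrast — not clinical performance on real Holter
data, where class overlap is substantially larger.

## Problem sizes and numerical tolerances

The test-bench runs at the study's native sizes: 1024-sample segments,
30 atoms, 69-subject cohorts, 23 folds; the bound checks use a 200-segment
cohort, and the GA-versus-exhaustive comparison uses 8-feature tables
(255 subsets) with a reduced GA (population 50, 30 generations) across 10
seeds. Energy conservation is asserted at $10^{-6}$ relative (achieved:
~$10^{-16}$), planted-atom recovery at $10^{-6}$ relative L2, spline and
detrend oracles at $10^{-8}$–$10^{-9}$, and scale invariance of the
feature vector at $10^{-8}$.

## Known limitations

* MP optimality is greedy per iteration only; the 30-atom expansion is not
  the best 30-term approximation, which is the standard trade-off.
* Atom-to-band assignment ignores the spectral tails of short atoms that
  straddle band edges.
* The 23-fold design follows the study protocol; with folds of 3 the
  variance of the pooled metrics across fold seeds is non-negligible on
  harder data.
* Dataset-level min-max scaling leaks fold information by construction;
  the `scale_in_fold` flag quantifies the effect.

## A worked example

```{r example, eval = FALSE}
library(hrvmp)

cohort <- simulate_cohort(40, 29, seed = 1)
features <- extract_feature_table(cohort)
scaled <- minmax_scale(features)

folds <- make_folds(69, 23, seed = 1)
cross_validate(scaled, k = 5, folds = folds)

run <- run_ga(scaled, k = 5, cfg = ga_config(seed = 1), folds = folds)
glance(run)
autoplot(run)
```
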