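---
title: "Models, defaults and design choices in musclefrailty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, defaults and design choices in musclefrailty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclefrailty)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where conventions were genuinely
open.

## 1. Frailty phenotyping

Each mouse is scored on five criteria: treadmill distance to exhaustion
(m), grip strength (gf), rotarod latency to fall (s), body weight (g), and
a deficit-accumulation frailty index. Trial summaries follow the standard
instruments: grip is the mean of the three remaining trials after removing
exactly one instance of the maximum and one of the minimum (even when
duplicated — ties share a fate, and exactly one copy of each extremum is
dropped); rotarod is the plain mean of three trials; the frailty index is
the sum of 28 item scores, each in {0, 0.5, 1}, divided by 28.

A *positive frailty marker* is assigned per criterion from cohort
percentiles: strictly below the 20th percentile for the three performance
tests, strictly above the 80th for body weight and FI. Two conventions had
to be fixed where common practice varies:

* **Percentile algorithm.** We interpolate linearly between order
  statistics at rank $1 + (n-1)p$ (R's `quantile` type 7, the default of
  most desktop statistics software). The rule is exposed through
  `percentile_threshold()` and alternative thresholds can be passed to
  `assign_markers()` directly.
* **Boundary handling.** "Below"/"above" are read strictly: a value equal
  to the threshold is not flagged. Thresholds are computed on the whole
  cohort including the mouse being flagged (not leave-one-out), and a
  missing criterion value removes the mouse from that criterion's
  percentile pool and can never be flagged on it (with a warning).

Classification is **High** at $\ge 2$ markers, **Low** at $\le 1$; the two
classes partition the cohort by construction. Because the rule is purely
rank-based, classification is invariant to mouse ordering and to any
strictly monotone rescaling of a criterion — both properties are asserted
in the test-suite.

With five *independent* criteria each flagged at rate 0.2, the per-mouse
marker count is Binomial(5, 0.2) and the expected High fraction is
$1 - 0.8^5 - 5 \cdot 0.2 \cdot 0.8^4 = 0.26272$; for a 47-mouse cohort that
is 12.35 mice, so replicated simulation should (and does) round to a
12 / 35 High/Low split. This closed form anchors the acceptance
simulation (`simulate_marker_split()`).

## 2. The trace model

The generator is phenomenological, not biophysical: its purpose is to
produce traces whose *extracted metrics* have known closed forms, so every
extractor can be validated end to end. No cross-bridge or calcium dynamics
are modelled, and none of its distributions should be read as estimates of
any real animal population.

**Twitch.** $F(t) = A\,(e^{-t/\tau_r} - e^{-t/\tau_c})$ for $t \ge 0$, with
$0 < \tau_c < \tau_r$. The kernel is deliberately *unnormalized*: $A$ is a
force scale, not the peak force. That keeps the test oracles trivial — the
peak is at $t_p = \frac{\tau_c \tau_r}{\tau_r - \tau_c}\ln(\tau_r/\tau_c)$
and the maximal slope is $A(1/\tau_c - 1/\tau_r)$, attained at onset.
Defaults (EDL: $\tau_c$ = 10 ms, $\tau_r$ = 50 ms; soleus: 30 / 120 ms)
give fast- and slow-twitch-like kinetics.

**Tetanus.** A pulse train at frequency $f$ drives linear summation of
twitch kernels, $U(t) = \sum_j K(t - t_j)$, and the output saturates
hyperbolically: $F(t) = f_{max} U / (U + k_{1/2})$. Two parameters suffice
to give a plateau strictly below $f_{max}$ and a monotone, sigmoidal
force–frequency relation; the slow soleus kernel saturates at lower
frequencies, as real muscle does. Force–frequency protocols use the
muscle-specific frequency series (EDL 10–180 Hz, soleus 10–150 Hz).

**Fatigue.** $n$ tetani at 80 Hz, 0.5 s trains, 5 s rest; the $k$-th train
is scaled by $s_k = r + (1-r) e^{-(k-1)/\kappa}$ with floor $r$ and decay
constant $\kappa$ (in contractions). The protocol length is configurable;
the default is $n = 60$ contractions (5.5 min), long enough for the
envelope to approach its floor at the default $\kappa = 20$, $r = 0.35$.

**Recovery.** Ten stimulations at 5-minute intervals after fatigue end;
the stimulation at time $t$ is scaled by
$s(t) = s_{end} + (\text{plateau} - s_{end})(1 - e^{-t/\tau_{rec}})$
(default $\tau_{rec}$ = 400 s, plateau 0.85 of baseline). A plateau below
the fatigue floor encodes impaired recovery and must be enabled explicitly
(`allow_impaired = TRUE`).

**Noise.** Multiplicative normal noise on per-contraction peak scales
(CV 0.05 by default) plus additive white noise on samples (0.1 mN), and
lognormal between-mouse variation (CV 0.10) in force scale and muscle
mass. All randomness flows from one root seed through deterministic
sub-stream derivation (`stream_seed()`), with one stream per
cohort/mouse/muscle/protocol, so identical configurations are
byte-identical regardless of evaluation order.

**Effect sizes** are multiplicative modifiers per condition
(Low/High × Control/Run) on the simulator parameters. Defaults: running
raises twitch amplitude by 10% and mildly shortens $\tau_r$ (−8%) in both
strata; High-frailty mice have 12% smaller fast-muscle mass; and the
High × Run condition additionally halves $\kappa$ (faster fatigue),
doubles $\tau_{rec}$ (slower initial recovery), lowers the recovery
plateau by 15%, and shortens $\tau_r$ by 20% (shorter half-relaxation
time). These directions mirror the qualitative physiology the pipeline is
meant to detect — frail muscle fatigues faster and recovers more slowly
after eccentric stress — and their magnitudes were chosen once as
plausible; they are not fitted to any dataset. The multipliers apply to
both muscles; the generator's effect structure deliberately has no
muscle dimension (a simplification: in real data fast and slow muscles
need not respond alike).

**Cohort generation.** Each mouse has a latent standard-normal frailty
factor $Z$; criterion $j$ receives a standardized score
$c_j = \lambda_j Z + \sqrt{1-\lambda_j^2}\,\varepsilon_j$, marginally
standard normal, with performance criteria mapped so that higher $c$ means
worse performance, and weight/FI so that higher $c$ means heavier/frailer.
Loading $\lambda = 0.5$ by default (moderately correlated criteria);
$\lambda = 0$ gives exact independence, the regime of the acceptance
simulation. Unit mappings (grip ≈ 100 ± 15 gf, rotarod ≈ 120 s lognormal,
treadmill ≈ 420 m lognormal, weight ≈ 26 ± 3.5 g) are arbitrary but
realistic; only ranks matter for marker assignment. Deficit items are
drawn per item with a deficit probability increasing in $c_{fi}$
(severe = a quarter of deficits), giving typical aged-mouse FI scores
around 0.1–0.3. The empirical percentile rule always flags ~20% per
criterion regardless of $\lambda$; $\lambda$ instead controls how markers
concentrate on the same mice, i.e. the dispersion of marker counts and
hence the High fraction.

## 3. Metric extraction choices

* **RFD** is the maximum of the central-difference first derivative on the
  rising phase. Optional moving-average smoothing (off by default; ~5 ms
  suggested for noisy traces) precedes differentiation. At 10 kHz the
  discretized maximum sits ~1% below the analytic onset slope, inside the
  2% oracle tolerance.
* **HRT** is measured from the peak sample to the first crossing of half
  the peak, linearly interpolated between the bracketing samples; if force
  never falls below half-peak in the window, HRT is reported missing with
  a warning rather than extrapolated.
* **Peak detection** searches each event's window
  $[\text{onset}, \text{onset} + \text{duration} + 0.5\,\text{s}]$, so
  relaxation tails cannot bleed across the 5 s rests of the fatigue
  protocol.
* **Fatigue AUC** integrates the full baseline-subtracted trace
  (trapezoidal rule, negative excursions clamped to zero) from the first
  event onset to the last event end — not a peaks-only envelope. An
  envelope AUC (Σ peak × train duration) is provided as a secondary
  output, and is what the trace-free envelope simulation path reports.
* **Percent force recovered** defaults to the *gain* over the fatigue end
  relative to pre-fatigue baseline,
  $100(\text{peak}_{last} - F_{end})/F_{baseline}$; the absolute reading
  $100\,\text{peak}_{last}/F_{baseline}$ is available via
  `pct_mode = "absolute"`. Both readings of "total force recovered" are
  defensible; the difference form makes a flat recovery exactly 0%.
* **Damaged muscles.** Any protocol may be missing for a muscle;
  `contractile_profile()` emits a partial row and every downstream
  statistic drops missing outcomes listwise for that outcome only.

## 4. Statistical conventions

* **Two-way ANOVA** uses Type III sums of squares with sum-to-zero factor
  coding (the behavior of the commercial software this field mostly uses
  on unbalanced 2×2 designs). On balanced designs Type III coincides with
  sequential sums of squares — asserted in the tests. Empty design cells
  raise an explicit inestimability error naming the cell; zero residual
  variance reports the SS decomposition with F undefined.
* **Sidak post hoc** compares Run vs Control within each frailty stratum
  (m = 2) by default — the simple effects of interest — using the ANOVA
  residual mean square as pooled error; the six-comparison all-cells
  family is available. The post hoc is gated on interaction p < 0.05; the
  gate is configurable and can be disabled.
* **Percent-change t-test** uses Student's equal-variance test (again the
  desktop-software default) with the Welch variant behind a flag. Percent
  changes are computed for running mice only, against their stratum's
  control mean.
* **Recovery analysis** treats Contraction as a within-subject
  (repeated-measures) factor via a multivariate linear model with an
  intra-subject design — equivalent to subject blocking — with Frailty
  and Run between subjects. No sphericity correction is applied by
  default, matching the convention of reporting uncorrected
  repeated-measures F tests; Greenhouse–Geisser adjustment is available
  (`gg = TRUE`). The stratified follow-up (separate Contraction × Run
  ANOVAs per frailty stratum) runs only when the three-way interaction
  clears the gate, and per-contraction Sidak comparisons
  (family = number of contractions) run only when a stratum shows a
  Contraction × Run interaction. Mice with incomplete contraction series
  are excluded from the repeated-measures model with a warning.

## 5. Problem sizes used in validation

The test-suite validates stochastic behavior at sizes chosen to balance
Monte-Carlo resolution against desk-scale runtimes, as its own design
choice: the High/Low split simulation uses 2000 replicate 47-mouse
cohorts; null calibration of the two-way interaction uses 5000 replicates
at the unbalanced group sizes 19/16/7/5 and of the recovery three-way gate
1000 replicates; the power curve uses 50 cohorts per effect multiplier
(1, 1.5, 2) through the trace-free envelope path, writing its curve as a
CSV test artifact; and end-to-end determinism runs the full 47-mouse
trace-level study twice and compares serialized reports byte for byte.

## 6. What passing tests do and do not show

The generator reproduces the *structure* the analysis assumes — correlated
criteria, protocol timing, saturating force–frequency behavior,
exponential fatigue and recovery envelopes with condition effects — so
green tests demonstrate that the pipeline extracts and tests what it
claims to, with correct closed-form behavior and calibrated error rates.
They do not validate the generator against real muscle: real traces carry
baseline drift, movement artifacts, non-exponential fatigue, and
muscle-specific effect patterns that the model omits. Published
figure-level contrasts and exact p-values are likewise not reproducible at
the desk, because per-mouse raw data are not published; the acceptance
targets are therefore the cohort-split counts, which have a closed form.

## 7. Known limitations

* The deficit-item generator controls the FI distribution only through a
  single latent loading; item-level correlation structure is not modelled.
* The envelope simulation path reports the peaks-only AUC, which differs
  from the trace AUC by a protocol-dependent constant factor; the two are
  suitable for the same hypothesis tests but not interchangeable as
  absolute values.
* The repeated-measures machinery requires complete contraction series per
  mouse; mixed-effects alternatives that tolerate partial series are out
  of scope.
* L0 determination, stimulation hardware control, and transcriptomics are
  out of scope; muscle metadata (mass, L0) are inputs.
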