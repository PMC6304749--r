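---
title: "Methods: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabanet)
```

## The scientific question

Early in cortical development GABA-A signalling is depolarizing: the
intracellular chloride concentration is high, so the GABA-A reversal
potential sits near -40 mV and "inhibitory" interneurons in fact excite
their targets.  As KCC2 is up-regulated the reversal potential drops to
about -70 mV and the same synapses become hyperpolarizing.  `gabanet`
models this switch in a conductance-based leaky integrate-and-fire (LIF)
network and asks how it interacts with network geometry, external drive
and short-term synaptic plasticity (STP) in shaping the network's mean
spike frequency (MSF) — the quantity that multi-electrode-array (MEA)
recordings of developing cultures report.

## Neuron and synapse model

Subthreshold dynamics of each neuron:

$$\frac{dV}{dt} = \frac{E_{leak} - V}{\tau_m}
  + \frac{g_e (E_{exc} - V) + g_i (E_{GABA} - V)}{c_m},$$

with $\tau_m = 20$ ms, $E_{leak} = -70.6$ mV, threshold $-50.4$ mV, reset
$-74$ mV and an absolute refractory period of 5 ms during which the
membrane is clamped at the reset value.  Conductances jump by a fixed
per-spike increment ($g_{exc} = 4$ nS, $g_{inh} = 64$ nS, external drive
$g_{ext} = 200$ nS) and decay exponentially
($\tau_{exc} = 5$ ms, $\tau_{inh} = 10$ ms).  The maturation state is
nothing but $E_{GABA} = -40$ mV (immature) or $-70$ mV (mature); no
chloride dynamics are modelled.

Two parameter readings deserve a note:

* **$c_m$.**  The membrane equation divides the synaptic current by a
  capacitance while the leak term carries $1/\tau_m$; only the time
  constant is given a value in the source material.  We set
  $c_m = 281$ pF, the Brette–Gerstner value that the printed leak
  parameters ($-70.6$, $-50.4$ mV) come from, and treat $\tau_m = 20$ ms
  as authoritative.  Whether a single leak-conductance formulation was
  intended is not recoverable; this reading honours every printed number.
* **Conductance "decay constants".**  $g_{exc}$, $g_{inh}$ and $g_{ext}$
  are described as decay constants but carry nS units.  The only
  consistent reading — and the one implemented — is as per-spike
  conductance increments, with the decay governed separately by
  $\tau_{exc}$ and $\tau_{inh}$.
* **Reset vs leak potential.**  $-74$ mV is the reset/refractory clamp;
  $-70.6$ mV is the leak drive.  Both are kept, each in the role its
  defining sentence uses.

## Connectivity

$N$ neurons (4:1 excitatory:inhibitory) are placed uniformly at random on
a periodic 1 mm² lattice.  Each neuron receives exactly
$K = \mathrm{round}(\varepsilon N)$ recurrent synapses, with sources drawn
with probability proportional to the Gaussian profile
$e^{-r^2 / 2\sigma_c^2}$ of their minimum-image distance $r$.  The six
named scenarios fix $(\varepsilon, \sigma_c)$ as percentages of $N$ and
$L$: A-1 (1, 9), A-2 (1, 10), B-1 (9, 1), B-2 (10, 1), B-3 (19, 1),
B-4 (20, 1).  Delays are $d = d_{syn} + r/v$ with $d_{syn} = 0.2$ ms and
$v = 0.5$ m/s, so all delays lie in $[0.2, 1.615]$ ms.

**Sampling mechanism.**  The source material describes a rejection method:
propose a candidate, accept with the Gaussian probability.  With accepted
candidates removed from the pool (required for a distinct fixed in-degree),
that procedure is *exactly* weighted sampling without replacement with the
Gaussian weights — at every acceptance the next accepted source is $j$
with probability $w_j / \sum w$ over the remaining pool.  We implement it
as such (exponential-race keys), because literal uniform-proposal rejection
stalls unrecoverably for the B scenarios: with $\sigma_c = 1\%$ of $L$ the
Gaussian mass covers roughly $2\pi\sigma_c^2 N \approx 8$ neurons at
$N = 3000$, yet K reaches 600.  In that regime the distinct-K constraint
dominates and the realized wiring degrades gracefully toward
nearest-neighbour connectivity — which is what a fixed-K implementation on
the original configuration must also have produced.  Weights are rescaled
by the nearest candidate before computing keys so only genuinely
unreachable candidates underflow; if fewer than K candidates remain
reachable the sampler raises the stall error.

Self-connections and duplicate pairs are excluded (standard practice; the
source is silent).  A neuron's excitatory/inhibitory identity follows its
fixed class, not a per-class quota.  External Poisson drive is one extra
independent source per neuron and does not count toward K.

The normalization claim $\int_0^{L/2} \rho(r)\,dr = \varepsilon$ printed
for $\rho(r) = P(r) e^{-r^2/2\sigma_c^2}$ does not hold numerically for
the printed scenario pairs (for A-1 the raw integral is
$\approx 2\pi\sigma_c^2 \approx 0.05$, not 0.01).  $\varepsilon$ is
operative solely through K; `rho_profile()` exposes an explicit rescaling
so the normalized identity can be asserted as stated.

Wiring is bit-reproducible for a fixed seed.  Permutation covariance under
neuron relabelling holds in distribution only — the RNG stream is consumed
in candidate order — so it is verified distributionally, not bitwise.

## Short-term plasticity

Tsodyks–Markram recursion per presynaptic spike train, facilitate-then-
depress ordering: with $u^- = u\,e^{-\Delta t/\tau_{fac}}$ and
$x^- = 1 - (1 - x)e^{-\Delta t/\tau_{dep}}$,

$$u' = u^- + U(1 - u^-), \qquad
  \mathrm{eff} = u' x^-, \qquad x' = x^-(1 - u').$$

The applied weight is the nominal weight times $\mathrm{eff}/U$, so the
first spike from rest transmits the nominal weight — this makes the STP
conditions directly comparable to the static control.  The variants are
STD1 $(\tau_{dep}, \tau_{fac}) = (100, 1)$ ms, STD2 $(100, 10)$,
STF1 $(1, 100)$, STF2 $(10, 100)$.

$U$ is never printed; it defaults to 0.5, identical across variants so
that variants differ only by their time constants, and it is exposed in
configuration.  Which synapse populations carried STP is also not
recoverable; by default all recurrent synapses of the selected variant are
plastic, with an excitatory-only restriction available
(`stp_exc_only = TRUE`).  External synapses are always static.

At a regular interval $T$ the recursion has the closed-form fixed point
$u^* = U / (1 - (1-U)e^{-T/\tau_{fac}})$,
$x^* = (1 - e^{-T/\tau_{dep}}) / (1 - (1 - u^*)e^{-T/\tau_{dep}})$, used
as the analytic oracle for the iterated implementation
(`steady_state_efficacy()`).

## Integration engine

Clock-driven, $dt = 0.1$ ms by default (configurable; used by the
convergence tests).  Per step: deliver queued arrivals and external input,
then refractory clamp or forward-Euler membrane update, then
threshold/reset, then exact exponential conductance decay.  Spikes
detected while advancing step $k$ are stamped $(k+1)\,dt$; deliveries go
through a ring buffer with delays rounded **up** to the next step (maximum
quantization error 0.1 ms against delays up to 1.615 ms).  External
Poisson input is thinned per step with $p = 1 - e^{-\mathrm{IF}\,dt}$; the
analysis-side `poisson_train()` generates exact homogeneous trains, and
deterministic event lists can be injected for oracle tests.  All
randomness flows through R's RNG, so identical (network, config, seed)
triples give byte-identical spike records.  Initial potentials are drawn
uniformly in $[V_{reset}, V_{threshold})$ — the source is silent and a
fixed value would create artificial first-step synchrony.

The compiled engine is checked against a pure-R scalar stepper
(`membrane_step()`) spike-for-spike and against hand-scheduled two-neuron
delivery traces, including the STP efficacy factors.

## Analysis pipeline

* **MSF** is the network mean of per-neuron rates: total spikes after the
  burn-in divided by $N (T - t_{burn})$, with a 50 s burn-in at full
  scale.  Whether MSF was per-neuron or network-summed is never stated;
  per-neuron is the only reading compatible with the printed 6–150 Hz
  values.
* **Percent modulation** is $100 (\mathrm{before} - \mathrm{after}) /
  \mathrm{before}$, reported as a magnitude with a direction word, rounded
  half-even to one decimal as the worked examples print it.  Magnitudes
  below 1% get direction `"none"` — the printed examples contain no such
  case and the band keeps labels stable under trial noise.
* **Predicted vs unpredicted**: depression that reduces firing and
  facilitation that increases it are predicted; the reversals are
  unpredicted.
* **Band labels**: theta (3–7], alpha (7–12], beta (12–30], low-gamma
  (30–50], high-gamma (50–80], epsilon (80–250] Hz; shared edges belong to
  the lower band, matching "30 Hz: beta", "50 Hz: low gamma", "80 Hz:
  high gamma" in the worked examples.
* **PDF filter**: the exclusion rule for "significant variations in the
  PDF scale" has no operational definition in the source.  We fit a
  Gaussian to the 12 per-trial MSFs and exclude on a Shapiro–Wilk
  rejection at $\alpha = 0.05$ (the standard small-n normality test); test
  and level are configurable, and the choice is ours, not the original
  authors'.
* **Spike-distance matrices**: the metric behind the source's heat maps is
  never named.  We use the van Rossum distance with a causal exponential
  kernel, $\tau = 20$ ms, over 100 subsampled neurons, normalized so two
  single-spike trains at offset $\delta$ are at distance
  $\sqrt{1 - e^{-\delta/\tau}}$ — the simplest kernel metric with a
  closed-form oracle.  Flagged as non-authoritative.
* **Stage mapping**: an MSF maps to an MEA reference window
  (pre-shift 5–10 DIV: $7.86 \pm 1.30$ Hz; shift 11–17 DIV:
  $54.27 \pm 7.22$ Hz) when it falls within mean $\pm k \cdot$ SD
  ($k = 2$); the nearer mean wins ties and everything else is "outside".
* **ANOVA**: fixed-effects full factorial (2 or 3 factors) with
  sequential sums of squares; the sweep produces balanced designs, where
  Types I/II/III coincide.  Backed by `stats::aov` behind the module
  contract, with hand-computed textbook sums of squares as the test
  oracle.

## The synthetic world

`gen_msf_table()` emulates exactly the statistical structure the analysis
assumes: Gaussian per-trial MSF within a condition (12 trials per cell),
additive factorial structure over 6 scenarios x 2 maturation states x 5
STP classes, defaults of a 60 Hz grand mean and 5 Hz trial noise (central
to the 6–150 Hz range the model produces; the noise magnitude is what
the printed worked examples' trial scatter suggests).
`gen_spike_record()` produces independent Poisson trains with known rates,
optionally piecewise, for testing the MSF estimator and burn-in handling.
The bundled `modulation_catalog.csv` transcribes the printed before/after
MSF pairs; five rows whose printed percentage disagrees with round-half-
even recomputation at one decimal (three look like decimal truncations,
one is printed twice with different values, one is arithmetically wrong)
are flagged `consistent = FALSE` and excluded from exact-match tests.

What a green test does **not** establish: the generators contain no
network dynamics, no correlations between neurons, no heteroscedasticity
across cells and no IF dependence — so analysis tests certify the
pipeline's arithmetic and statistical calibration, not the simulator.  The
simulator is certified separately against scalar oracles and qualitative,
scaled-down claims.

## Scaling and what is reproduced

The printed configuration (N = 3000, 2000 s, 12 trials, the 5–100 Hz IF
grid — 14,400 sweep rows) is cluster-scale.  Tests and examples run a
desk scale (N = 300, tens of seconds); K scales as
$\mathrm{round}(\varepsilon N)$.  The original tables' specific p-values
are stochastic outcomes of the full-scale runs and are **not**
reproducible at desk scale; in their place the suite asserts (a) the
directional GABA-switch claim — immature networks outfire mature ones on
matched seeds at scaled size — and (b) the ANOVA machinery's type-I
calibration and power on synthetic tables of the full design.

## Known limitations

* No chloride dynamics, NMDA/GABA-B receptors, adaptive thresholds or
  structural plasticity; the developmental switch is two fixed reversal
  potentials.
* Forward-Euler membrane integration; first-order accurate (the suite
  asserts the error halves with dt).
* The B-scenario wiring is nearest-neighbour-dominated under the fixed-K
  constraint (see above); distance histograms for those scenarios should
  not be read as Gaussian-profile samples.
* The refractory-period robustness checks mentioned in the source give no
  alternative values; `tau_ref` is simply configurable.
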