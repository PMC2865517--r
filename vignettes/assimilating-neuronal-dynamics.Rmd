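---
title: "Assimilating neuronal dynamics: model, filter and twin experiments"
author: "neurokf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assimilating neuronal dynamics: model, filter and twin experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

neurokf estimates everything a whole-cell electrode cannot see.  Given a
single noisy membrane-potential recording from a hippocampal neuron, it
reconstructs the cell's channel gating variables, its intracellular and
extracellular ion concentrations, the parameters governing the potassium
microenvironment, and — for a coupled pyramidal-cell/interneuron pair —
the full state of a second, unrecorded neuron.  The machinery is a
biophysical conductance-based model embedded in a sigma-point (unscented)
Kalman filter, validated throughout by twin experiments in which the
"recording" is generated by the model itself so that every hidden
quantity has a known truth.

This vignette documents the science: the model equations and their
assumptions, the filter and its numerical safeguards, the synthetic-data
regimes and how they were chosen, and the operational definitions behind
every reported statistic.

## The biophysical model

### Membrane and gating

Each cell is a single compartment with modified Hodgkin-Huxley currents:

$$C_m \dot V = -I_{Na} - I_K - I_{Cl} + I_{app},$$

with $I_{Na} = (g_{Na} m^3 h + g_{NaL})(V - E_{Na})$,
$I_K = (g_K n^4 + g_{AHP}\,\mathrm{Ca}/(1+\mathrm{Ca}) + g_{KL})(V - E_K)$
and a chloride leak $g_{ClL}(V - E_{Cl})$.  The gating variables follow
$\dot x = \phi[\alpha_x(V)(1 - x) - \beta_x(V) x]$ with the standard rate
functions of this model family; the ratio-form rates $\alpha_m$ and
$\alpha_n$ have removable singularities (at $-30$ and $-34$ mV) that are
evaluated at their analytic limits.  The sodium activation gate $m$ is a
dynamic state, not an instantaneous $m_\infty$ approximation — the filter
tracks it like any other hidden variable.

The calcium-gated after-hyperpolarization current ($g_{AHP}$) exists only
in the pyramidal cell, where it produces spike-frequency adaptation;
intracellular calcium is carried in arbitrary units with a fixed reversal
$E_{Ca} = 120$ mV and 80 ms relaxation, so it functions as an adaptation
variable rather than a modelled ion pool.

### The potassium microenvironment

The slow dynamics that matter for seizures live in the ion
concentrations.  Extracellular potassium obeys

$$\dot{[K]}_o = \gamma\beta\, I_K \;-\; 2\beta\, I_{pump} \;-\; I_{glia}
\;-\; \varepsilon([K]_o - K_{bath}) \;+\; \delta([K]_o^{other} - [K]_o),$$

and intracellular sodium $\dot{[Na]}_i = -\gamma I_{Na} - 3 I_{pump}$.
The Na–K exchange pump is a product of saturating sigmoids in $[Na]_i$
and $[K]_o$ with maximal rate $\rho$; its $3\!:\!2$ factors are the
electrogenic stoichiometry (3 Na$^+$ out per 2 K$^+$ in) and hold exactly
in the code — the test suite asserts the ratio at machine precision.
Glial uptake is a single sigmoid of $[K]_o$ with maximal strength
$G_{glia}$ (midpoint 18 mM), and $\varepsilon$ is the Fick's-law coupling
to a distant reservoir at $K_{bath}$ (the bath in a slice, the
vasculature in vivo; 3 mM under physiological conditions).

Two bookkeeping identities close the system: electroneutrality ties
$[K]_i = 140 + (18 - [Na]_i)$, and sodium conservation across the
volume ratio $\beta = 7$ gives $[Na]_o = 144 - \beta([Na]_i - 18)$,
where 140/18/144 mM are the normal resting concentrations.  Reversal
potentials are Nernstian with a thermal factor of 26.64 mV (a
configuration value, not a hard-coded constant).

Units: membrane, gating and synaptic equations run in millivolts and
milliseconds; the ion equations are written per second and divided by
1000 inside the right-hand side so one time base is integrated.  This
mirrors the fast/slow split the dynamics rely on.

The conversion factor $\gamma = A/(F\,\mathrm{Vol}) \approx 0.0445$
mM·cm²/µC derives from a 7 µm spherical cell; `gamma_from_geometry()`
implements the derivation so the shipped value can be cross-checked, and
$\gamma\beta \approx 0.31$ is the factor scaling the potassium current.
`eps_from_geometry()` similarly derives $\varepsilon$ from the cortical
potassium diffusion constant and a 20 µm capillary distance.

### Stimulus conversion: why 18.6 µm and not 7 µm

A pipette current in picoamperes must become a density in µA/cm².  The
7 µm sphere that sets $\gamma$ describes the cell's *volume*; using its
area for the current conversion would make 100 pA a 16 µA/cm²
hyper-drive (≈ 260 Hz firing, $[K]_o$ transients above 15 mM) — nothing
like the moderate repetitive spiking a real CA1 pyramidal cell shows at
100 pA.  The electrical membrane of a pyramidal cell (soma plus proximal
dendrites) is far larger than the soma sphere, so
`stimulus_protocol()` defaults to an effective 18.6 µm radius
(≈ 4300 µm²).  This puts the model's rheobase at ≈ 96 pA — in the
measured range for these cells — so a 100 pA pulse is a *small* current
just above threshold that elicits ≈ 20 spikes/s.  The radius is a
configuration argument, not a constant.

### Synaptic coupling and depolarization block

The pair model couples a pyramidal cell (PC) and an
oriens-lacunosum-moleculare interneuron (IN) through GABA-ergic
inhibition (strength 0.84, reversal $-80$ mV) onto the PC, AMPA-ergic
excitation (strength 0.17, reversal 0 mV) onto the IN, and lateral
extracellular-potassium diffusion $\delta$ whose pair sum is conserved
exactly.  Each synaptic gate $s$ relaxes toward a sigmoid of its
presynaptic voltage with time constant $\tau_e = 4$ ms (PC output) or
$\tau_i = 8$ ms (IN output).

The functional form of the depolarization-block gate is not printed in
the source text, so it is an explicit design choice here: a slow
integrator $\eta$ relaxes (1 s time constant) toward a sigmoid of
presynaptic voltage centred at $-40$ mV.  Brief spikes leave $\eta$ near
zero; sustained depolarization — the block state, where the membrane
parks around $-20$ to $-40$ mV — drives it toward 1.  The gate
$\chi(\eta) = 1/(1 + e^{(\eta - 0.5)/0.05})$ then multiplies the
synaptic output: $\chi(0) \approx 1$, monotone decreasing, and
effectively 0 once $\eta$ exceeds ≈ 0.6.  When the IN locks into
depolarization block, $\chi(\eta_i) \to 0$ shuts off its inhibition and
releases the PC — the "loss of the inhibitory veto".

## The sigma-point filter

The filter is the plain equal-weight form: for a $D$-dimensional belief
$(\hat x, \hat P)$ it generates $2D$ points
$\hat x \pm \text{columns of } \sqrt{D\hat P}$ (lower-triangular
Cholesky, with a symmetric-eigendecomposition fallback after
conditioning), propagates each point through the model across one
observation interval (ten RK4 substeps of 0.01 ms per 0.1 ms
observation), and forms the a-priori mean and covariance as the plain
average and scatter plus process noise $Q$.  There is no central point
and there are no scaling parameters.  By default fresh sigma points are
drawn from the prior before the measurement update (a flag disables the
redraw, trading a little accuracy for speed).  The update is the
standard gain
$K = P_{xy}(P_{yy} + R)^{-1}$ applied to the innovation; the observation
function simply reads the voltage component.

Parameters are estimated by state augmentation: each tracked parameter
becomes an extra component with trivial dynamics, log-transformed by
default when it lives on a positive scale (conductances, rates,
concentrations).  On linear-Gaussian systems the whole machinery
collapses to the classical Kalman recursion, and the test suite holds it
to that oracle at $10^{-8}$ over 100 steps.

### Numerical safeguards

* Covariances are symmetrized every step and eigenvalue-floored at
  `jitter * trace(P)/D` when factorization fails; the conditioning
  operator is idempotent on valid input.
* Sigma points are clamped to the model's physical domain (gates in
  $[0,1]$, $[K]_o \ge 0.1$ mM, $[Na]_i \in [5, 38]$ mM so derived
  concentrations stay positive, $|V| \le 150$ mV) before, during and
  after propagation.  The *model* raises domain errors on unphysical
  input; keeping estimates physical is the filter's job, and the
  clamping implements exactly that division of labour.  The RK4 stage
  states are clamped inside the filter as well: a sigma point at the edge
  of the box can otherwise produce intermediate stage values whose rate
  functions overflow.
* Tracked parameters live in a generous transformed-scale box
  (initial value ± 6, i.e. a factor ≈ 400 each way on log scale).
* A non-finite state during propagation aborts the run and returns the
  partial result with a warning rather than failing silently.

### Choosing Q and R

The published form of the algorithm leaves $Q$, $R$ and $P_0$ open; they are
the levers that decide what a twin experiment can recover.  The package
defaults are documented in `assimilate()`; the experiment drivers
override them deliberately:

* Twin experiments use an exact model, so *state* process noise is kept
  small — large state noise lets the state absorb discrepancies that the
  tracked parameters should explain.
* In the model-inadequacy run the tracked $\log\alpha_m$ gets a
  relatively fast random walk (SD 0.02 per 0.1 ms step) because its
  hidden target swings with voltage.
* In the microenvironment run the three tracked parameters get noise
  matched to their sensitivity: $\varepsilon$ and $K_{bath}$ are
  strongly identified (quiet-phase balance and episode decay) and
  receive tight priors (log-SD 0.05) with slow walks; $G_{glia}$ is
  weakly identified at episode-peak potassium levels (the glial sigmoid
  is centred at 18 mM, so at 7 mM glia runs at ≈ 1% of capacity) and
  receives a loose prior (log-SD 0.3) with a faster walk.  With uniform
  settings the filter parks $G_{glia}$ on a compensation ridge with
  $\varepsilon$; the matched settings collapse the ridge, and the
  recovery test asserts all three terminal errors below 20%.
* $R$ defaults to the squared noise SD recorded by the fixture — the
  honest value in a twin setting.

## Synthetic regimes (and how they were chosen)

The package validates against three generated conditions, replacing
recordings that are not available.  All fixtures are bit-reproducible
from (preset, seed, dt), store every hidden state as a truth column, and
observe the voltage every 0.1 ms with 0.5 mV Gaussian noise by default
(the noise magnitude of the original recordings is unstated, so it is a
parameter, not an assertion).

**Current-injected spiking PC** — physiological microenvironment, 100 pA
for 1 s from the resting state; ≈ 20 spikes during the pulse; silence
after rest is re-established.

**Spontaneous seizure-like episodes** — chosen by a coarse scan over
$(G_{glia}, \varepsilon)$ at physiological $K_{bath} = 3$ mM
(`scan_seizure_regime()` is the scan, kept in the package).  The shipped
preset reduces glial buffering to 40 mM/s, sets $\varepsilon = 2$/s and
adds a 1.8 µA/cm² tonic drive representing the elevated excitability of
a spontaneously seizing slice.  The regime is a slow relaxation
oscillation whose full cycle exceeds 100 s — consistent with the
inter-event intervals reported for such preparations — with the recovery
phase a slow drainage of intracellular sodium.  Because simulating a
full cycle at the production step is wasteful, the fixture starts from a
stored late-inter-ictal state (`seizure_init_state()`, $[Na]_i = 19$ mM)
so that a 20 s window contains quiet baseline, one complete ≈ 12 s
episode and the post-ictal return.  Truth values: baseline
$[K]_o = 3.05$ mM, episode peak 7.1 mM.

**Interacting PC–IN pair** — the PC side uses the seizure preset; the IN
side carries much weaker buffering ($G_{glia} = 5$ mM/s,
$\varepsilon = 0.3$/s), expressing the prediction that the
interneuron layer's potassium microenvironment is weaker.  During the
episode the IN's $[K]_o$ rises far higher than the PC's (above 30 mM),
driving it through high-frequency firing into depolarization block for
≈ 5 s while the PC fires intensely through the released inhibition.

What these twins do *not* emulate: channel noise and biological
trial-to-trial variability, electrode artefacts, multi-compartment
morphology, network input beyond one partner cell, and a model-mismatch
between generator and filter (except where the experiment makes the
mismatch deliberate).  Passing twin tests therefore demonstrates that
the estimator is consistent and well-conditioned, not that the model is
an adequate description of any particular recording.

## Operational definitions behind the reported statistics

These choices are places where the informal target ("within 25%",
"correlation", "during the block") needed a precise operationalization;
each experiment reports the underlying raw quantities too, so the
definitions are auditable.

* **Tracked-$\alpha_m$ deviation (model-inadequacy twin).**  Median of
  $|\hat\alpha_m(t) - \alpha_m(V_{true}(t))| / \alpha_m(V_{true}(t))$
  over the driven, post-convergence epoch: from 250 ms after assimilation
  starts (the filter begins from arbitrary initial conditions and needs a
  few hundred milliseconds to converge — the same horizon the voltage-RMS
  convergence criterion uses) to the end of the pulse.  The stricter
  median restricted to first-true-spike-onward is also reported; it is
  dominated by after-hyperpolarization phases of the model's fast
  (≈ 50 Hz) limit cycle, where $m \approx 0$ and the voltage carries
  essentially no information about $\alpha_m$: a bound computed with the
  best *oracle constant* $\alpha$ shows no constant-parameter tracker can
  beat ≈ 50% median there, so that restriction measures an information
  limit of the regime, not filter quality.
* **Cross-cell voltage correlation.**  Computed on the 50 ms firing
  envelope (running mean of both series) as well as raw.  Spike timing
  of an unobserved neuron is not transferable through the synaptic and
  diffusive coupling, so the raw-grid correlation is bounded by the
  spike-energy fraction of the signal; the envelope is the physically
  reconstructable component.  Both numbers are reported.
* **Block-gate reconstruction.**  $\chi(\hat\eta_i) < 0.05$ is asserted
  on the interior of the true block interval (250 ms margin at each
  edge); a causal filter necessarily lags the block transitions.
* **Decoupled control.**  In a deterministic, autonomously episodic twin
  even uncoupled cells correlate (they share the regime and
  approximately the initial condition), so "correlation ≈ 0" is not the
  right null.  The control instead checks information flow directly:
  with coupling, the hidden cell's estimate must beat the deterministic
  prior trajectory (forward simulation of the filter's initial mean) in
  RMS; with the coupling removed from truth and filter, assimilation
  must not improve on that prior, because spurious gains then act on no
  information.  For the
  same reason the filter's initial belief deliberately mis-states the
  unobserved cell; a filter initialized at the exact truth would make
  the whole cross-cell experiment vacuous.
* **AIC comparison.**  $AIC = N\ln(RSS/N) + 2k$ with $RSS$ between the
  observed voltage and the filter's one-step-ahead predicted
  observation; $k = 4$ for the full model (its extra microenvironment
  parameters $\rho, G_{glia}, \varepsilon, K_{bath}$) and $k = 0$ for
  the variant with concentrations pinned at physiologically normal
  4 mM $[K]_o$ / 18 mM $[Na]_i$.
* **Episode detection.**  Threshold with hysteresis on the windowed
  firing rate (500 ms window; onset above 15 spikes/s, offset below 3);
  spikes are upward crossings of $-20$ mV for seizure traces, 0 mV for
  clean stimulus-evoked spikes.
* **Baseline / peak $[K]_o$.**  Baseline is the median reconstructed
  $[K]_o$ over inter-ictal samples; peak is the maximum inside the
  detected episode.

## Numerical choices

Fixed-step classical RK4 at dt = 0.01 ms, matching the filter's
substepping; the step-doubling test verifies fourth-order error scaling
on the single-cell model and halving dt changes a 1 s spiking trajectory
by < 0.01 mV.  Observation interval 0.1 ms.  Problem sizes used by the
shipped experiments: 1.2 s for the stimulus twins, 20 s (one episode)
for the seizure twins, 12 s for the pair; each fit reports its own
runtime in `summary()`.

A reference pure-R implementation of every model equation and of the
generic sigma-point filter ships alongside the compiled path; the test
suite holds the two to within $10^{-12}$ (right-hand sides) and
$10^{-5}$ (whole filter runs over 100 steps).  One real defect was
caught exactly this way: an index error in the compiled lateral
diffusion term that coupled the wrong ion pool.

## Known limitations

* $G_{glia}$ is close to unidentifiable from voltage alone in regimes
  whose $[K]_o$ stays below ≈ 10 mM; its recovery depends on the matched
  prior/noise settings described above, and from a 30% underestimate it
  converges only slowly.
* The model's f–I curve starts near 50–60 Hz under sustained drive from
  the drained rest state, so slow (5–15 Hz) tonic firing — common in
  real recordings — has no twin analog here.
* Spike-phase information does not cross the coupling; cross-cell
  reconstruction is an envelope-level claim.
* No smoothers, square-root filter forms, or adaptive noise estimation;
  the filter is strictly causal and the printed algorithm is implemented
  as printed.
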