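---
title: "Modelling VVD-mediated photoadaptation in Neurospora"
author: "vvdadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling VVD-mediated photoadaptation in Neurospora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vvdadapt)
```

## The biological problem

Blue-light responses in *Neurospora crassa* are driven by the White Collar
Complex (WCC), a transcription factor whose WC-1 subunit carries a
photosensory LOV domain. Light converts dark-form WCC into an activated
state (WCC*) that homodimerizes on light-response elements (LREs) and
switches on target genes, among them *vvd* and the clock gene *frq*. The
response is *adaptive*: expression spikes after a light step and then
falls back towards a basal level even though the light stays on, yet the
system keeps responding to further **relative** increases in intensity
over several orders of magnitude.

The small photoreceptor VIVID (VVD) is the key regulator. Light-activated
VVD* heterodimerizes with WCC*, blocking its homodimerization —
straightforward feedback inhibition. The puzzle is the second half of
adaptation: if VVD efficiently sequesters the activator, why does the
system stay responsive? The model implemented here captures the proposed
resolution: the LOV photoadduct in either partner of the WCC*–VVD*
heterodimer decays spontaneously, upon which the partners lose affinity;
decay on the WCC side returns *dark-form, light-activatable* WCC to the
pool. Sequestration followed by photoadduct decay is thus a *futile
cycle* that converts an inhibitor into a recycling device: VVD both
quenches the acute response and continuously replenishes the pool that
makes the next response possible.

## Model structure

The model tracks 14 species: three mRNAs (`m_wc1`, `m_frq`, `m_vvd`) and
eleven proteins — WCC in dark (`WCC_d`), activated (`WCC_a`), homodimeric
(`WCC_aa`) and phosphorylated (`WCC_p`) form, the WCC*–VVD* heterodimer
(`HET`), VVD in dark, activated and homodimeric form, and FRQ in
cytosolic, nuclear and phosphorylated form. Reactions are grouped into
three modules:

* **Transcription module.** Light activation is linear in intensity
  (rate `ka × I × [dark form]`); photon saturation is ignored because the
  protocols stay at or below 200 µmol photons m⁻² s⁻¹, far below LOV
  saturation. WCC* homodimerizes; the homodimer drives transcription of
  *wc-1*, *frq* and *vvd* through a saturating Hill function (coefficient
  2 by default, reflecting dimer–LRE binding). *wc-1* additionally has a
  constitutive basal rate, and *frq* a Clock-box (C-box) term activated by
  *dark-form* WCC — this asymmetry is what lets *frq* keep a basal dark
  level while *vvd* expression collapses in darkness. The transcriptionally
  active homodimer is degraded fast relative to dark forms.
* **Photoadduct-decay module.** WCC* and VVD* associate into the
  transcriptionally inactive heterodimer (`l1`, `l_minus1` ≡ `lm1`).
  Photoadduct decay in either partner dissolves the complex at rate `l5`
  per channel: decay on the WCC side yields `WCC_d + VVD_a` (the
  pool-replenishing branch), decay on the VVD side `WCC_a + VVD_d`. The
  two channels share one rate constant because the two LOV photoadducts
  decay on comparable time scales. Homodimer dissociation triggered by
  photoadduct decay is included symmetrically (`kpad_*`).
* **Phosphorylation module.** A minimal negative-feedback loop:
  FRQ is translated in the cytosol, enters the nucleus, and catalyses
  phosphorylation of dark WCC into an inactive, slowly recycling pool
  (`WCC_p`); phosphorylated FRQ is committed to degradation. Both the
  FRQ-catalysed phosphorylation and the dephosphorylation are
  Michaelis–Menten with configurable half-saturation constants (`K_ph`,
  `K_dp`); the defaults place them in the near-linear regime.

The right-hand side is defined once as a reaction list (rate law +
stoichiometry); `model_rhs()` is literally the stoichiometry matrix
applied to `reaction_fluxes()`. A compiled C implementation is used for
integration and is tested for exact agreement with the R reference.

### Units and normalization

Time is in minutes, light intensity in µmol photons m⁻² s⁻¹, and
concentrations in arbitrary units anchored by the convention that the
wild-type *vvd* mRNA level at the first light-on event (after 24 h of
darkness) equals 1. Because *vvd* has no dark WCC drive, a literal model
would put that anchor at zero; the package therefore includes a small
constitutive leak (`bas_vvd`) representing the measurable dark floor of a
qPCR assay. The WCC-driven LRE flux for *vvd* is still exactly zero in
darkness.

### Variants

`apply_variant()` implements the three genotypes/conditions studied:
`wild_type` (identity), `vvd_null` (translation of *vvd* set to zero —
the mutant allele is transcribed but makes no functional protein; all
other rates untouched) and `slow_cycling` (the heterodimer photoadduct
decay `l5`, and only `l5`, divided by 10 — an artificially stabilized
complex with intact VVD binding).

## The calibrated default parameter set

The package ships its own calibrated parameter set
(`default_parameters()`), obtained by numerical search against the
canonical photoadaptation phenotypes, simulated under the experimental
conditions (dark-equilibrated cultures, the 2/20/200 staircase,
two-pulse protocols, 48 h steady states):

* first mRNA peaks within 30 min of the first light step, with the
  abundance ordering *vvd* > *frq* > *wc-1*;
* repeated wild-type responses to the 10-fold intensity steps
  (step-2 and step-3 response ratios ≈ 0.52 and 0.32 of the first), lost
  in the vvd-null and slow-cycling variants (< 0.2);
* a slow-cycling first peak identical to wild type (within 0.5%) — VVD
  binding is untouched, only recycling is broken;
* a wild-type refractory period of ≈ 6 h (two-pulse peak ratio 0.19
  after 30 min of darkness, 0.51 after 6 h), with the mutant responding
  immediately; the refractory time scale is set by VVD clearance in the
  dark (`dg_vvd_*` ≈ 0.005–0.016 min⁻¹);
* light-to-dark transfer after two days of light: wild-type *vvd* and
  *frq* reach their dark baselines within 1 h, the mutant stays elevated
  for roughly 2–4 h, and in the long dark run *frq* settles at its C-box
  basal level while *vvd* collapses;
* a steady-state *vvd* dose response rising ≈ 5-fold from 2 to 200
  µmol m⁻² s⁻¹ in the wild type, ≈ 1.3-fold in the slow-cycling variant
  and flat in the mutant, with a light-activatable WCC pool that shrinks
  monotonically with intensity yet always stays far above the mutant's.

Key mechanistic levers found during calibration: the light activation of
WCC must dominate every other sink of dark WCC (otherwise the mutant's
dose response is not flat); the mutant's slow post-peak decline is set by
the degradation rate of the active WCC forms; and the wild-type dose
response is controlled almost entirely by `l5` — the futile-cycle
throughput — because steady-state *vvd* transcription traces the product
of intensity and the VVD-maintained activatable pool.

The slow-cycling dose response is the least constrained phenotype: in
this architecture it is structurally the wild-type curve evaluated at
`l5/10`, which pins it near ≈ 1.3-fold once the wild type is calibrated
to ≈ 5-fold; only its qualitative position (well below wild type, above
the flat mutant) should be relied upon.

## The circadian oscillator: a documented trade-off

In constant darkness the FRQ–WCC loop can generate self-sustained
circadian oscillations. Extensive joint calibration showed that, within
this minimal phosphorylation module, a robust dark limit cycle and the
VVD-set ≈ 6 h refractory period are mutually exclusive: a rhythm strong
enough to persist requires a deep swing of dark WCC whose trough falls in
the 6 h two-pulse recovery window (the clock, not VVD, then gates the
photoresponse), and its elevated FRQ levels quench the 48 h light steady
states. The default set therefore prioritizes photoadaptation; under it
the dark loop is damped and `steady_state()` reports a converged dark
fixed point.

An alternative calibration, `oscillatory_parameters()`, re-tunes only the
clock block — steeper C-box activation (Hill 4), near-zero-order
FRQ-catalysed WCC phosphorylation (`K_ph` far below the dark WCC level)
and slower FRQ turnover — and produces a robust free-running *frq* rhythm
(period ≈ 19 h, sustained amplitude, and a phase delay of several hours
in the vvd-null mutant, reflecting the prolonged activity of
light-activated WCC when VVD is absent). Its two-pulse discrimination is
correspondingly degraded. Both calibrations are exercised by the test
suite; the acceptance checks run against the defaults, where the
free-running-rhythm check documents this limitation by failing.

The C-box Hill coefficient deserves a note: a coefficient of 1 (simple
hyperbolic activation) leaves the loop unable to oscillate at all, so the
default uses 2 and the oscillatory set 4. The coefficient is an ordinary
configurable parameter (`hill_cbox`).

## Simulation machinery

Integration uses `deSolve::lsoda` on the compiled right-hand side,
segment by segment across the piecewise-constant light protocol so that
intensity switches are handled exactly rather than through event
detection. Default tolerances are `rtol = 1e-8`, `atol = 1e-12`; halving
them changes reported peak metrics by far less than 0.1%. Solver
round-off below zero is clipped at segment boundaries. The initial state
is placed at the first grid point, so protocols with a lit pre-history
must be simulated from `t = 0`.

The culture pre-history ("dark equilibration") mirrors the experimental
protocol: growth under constant light (48 h at 20 µmol m⁻² s⁻¹, long
enough to reach the photic steady state) followed by 24 h of darkness.

`steady_state()` integrates long, probes the last two simulated days for
sustained oscillation (frq peak-to-trough ratio > 1.2 — the package's
operational limit-cycle criterion) and otherwise polishes the fixed point
with a damped Newton iteration on the reference right-hand side.
`refractory_period()` bisects the dark interval of the two-pulse protocol
for the smallest gap at which the second *vvd* peak reaches 50% of the
first; the 50% recovery criterion and the 30-min pulse duration are this
package's operational choices, and both are function arguments. Peak
detection for
circadian analysis uses interior maxima with a 1% prominence filter and
quadratic refinement.

## Synthetic qRT–PCR data

`generate_timecourse()` emulates the calibration measurements: simulate
each strain, sample the three mRNAs (densely for two hours after each
light step, then hourly), multiply by gene-specific probe-efficiency
factors (defaults 1/0.7/0.4 for *vvd*/*frq*/*wc-1* — free knobs standing
in for the genomic-DNA dilution correction), apply lognormal noise with a
fixed coefficient of variation (default 0.2; qPCR noise is
multiplicative and typically assessed in triplicate, and the CV is a
free knob recorded in the dataset metadata), and normalize the whole
dataset so the mean wild-type *vvd* level at *t* = 0 is 1. Datasets are
reproducible bit-for-bit under a fixed seed and round-trip through CSV
with a YAML metadata sidecar.

What the generator does *not* emulate: amplification-curve artefacts,
between-run batch effects, time-point-dependent variance, and the
immediate post-pulse mRNA drop seen in mutant measurements, which lies
outside this model class altogether. Tests passing on
synthetic data therefore demonstrate correctness of the pipeline under
the stated noise model, not robustness to every pathology of real qPCR.

## Parameter estimation

The likelihood is Gaussian on log-transformed normalized levels (matching
multiplicative noise) with per-gene error variances profiled analytically;
the scale is switchable to linear. Predictions are normalized exactly as
the data are (by the predicted wild-type *vvd* level at *t* = 0), so the
anchor is never treated as a free unit. Solver failures map to `-Inf`
(rejected proposals).

`fit_mle()` is multi-start local optimization in log-parameter space.
`fit_mcmc()` is an adaptive random-walk Metropolis sampler: the proposal
covariance adapts to the empirical chain covariance during burn-in and is
frozen afterwards, keeping the retained chain Markovian; it reports the
post-adaptation acceptance rate (flagging < 1%) and a split-chain
potential-scale-reduction diagnostic. Default priors are independent
log-uniform over six decades centred on the starting values.
`two_stage_fit()` reproduces the study's protocol: stage 1 fits the
non-VVD parameters on vvd-null data (where VVD-related parameters are
structurally unidentifiable), stage 2 freezes them bit-for-bit and fits
only the VVD-related set (`vvd_parameter_names()`: synthesis, turnover,
photocycle, homo- and heterodimerization including `l1`, `lm1`, `l5`).

Posterior calibration is checked by simulation on the simplified
four-variable WCC–VVD model (fast enough for replication): across 20
seeded synthetic datasets with three free parameters, 95% credible
intervals cover the truth ~95% of the time.

## The simplified model and the adaptation motif

`simulate_simplified()` integrates the four-variable core (activatable
WCC, activated WCC, VVD, complex) in which VVD production is driven
directly by activated WCC and complex decay returns activatable WCC.
`exp_adaptation_scan()` classifies a grid over VVD production rate and
complex decay rate into `no_adaptation`, `adaptation_only` (the
slow-cycling phenotype) and `full_motif`, using two thresholds defined by
this package: adaptation means the response settles below 50% of its
first peak, re-responsiveness means a step-2 response above 20% of the
first. The scan reproduces the motif's requirements: both sufficient
inhibitor production *and* sufficiently fast complex decay are needed.

## Problem sizes used in the packaged analyses

Simulated experiments run on minute-resolution grids over 1–4 day
protocols; the coverage study uses 20 replicate fits of the simplified
model with 1200-iteration chains; MCMC demonstrations on the full model
use short chains with few free parameters. These sizes were chosen so the
full analysis suite re-runs in a couple of minutes on a laptop while
leaving every qualitative conclusion unchanged at larger sizes.

## Known limitations

* The reaction list, species enumeration and kinetic-law forms are this
  package's own canonical definition of the network; the SBML importer
  exists precisely so that an externally parameterized model file can be
  cross-checked against it.
* The default calibration does not sustain a free-running circadian
  rhythm (see the trade-off section above); clock-focused questions
  should use `oscillatory_parameters()` with the documented caveats.
* WC-2 is assumed non-limiting; WCC synthesis is driven by *wc-1* mRNA
  alone.
* No stochastic simulation and no nucleocytoplasmic compartment volumes
  beyond the FRQ cytosol/nucleus split; entrainment to light–dark cycles
  is out of scope.
* The immediate post-pulse drop of mRNA levels reported for the mutant
  lies outside this model class and hints at additional regulation of
  mRNA synthesis or turnover.
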