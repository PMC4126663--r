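---
title: "Methods: modelling MOI-dependent lysis-lysogeny decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling MOI-dependent lysis-lysogeny decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

Classical deterministic treatments of the lambda phage switch predict that
the lysis-lysogeny outcome depends on the *viral concentration* — the number
of infecting phage genomes (MOI) divided by the cell volume. Single-cell
experiments instead show that at the *same* concentration, cells infected by
more phage choose lysogeny at a different rate: the decision depends on MOI
directly. `lysolatch` implements a stochastic model of the early lambda
circuit built to probe the mechanisms that can produce such direct MOI
dependence: intrinsic copy-number noise, spatial segregation of the
infecting genomes, and growth-rate coupling.

## The circuit model

Three early genes are modelled: *cI*, *cro* and *cII*. Each protein
dimerises reversibly; CI2 and Cro2 compete for the lytic promoter PR, and a
CII multimer activates the establishment promoter PRE. Unbound PR
transcribes *cro* and *cII* constitutively (no activation needed); the
CI2-bound PR configuration transcribes *cI* (self-activation); the
CII-activated PRE configuration transcribes *cI*. Each mRNA decays at a
shared first-order rate and is translated at a common rate. Each infecting
genome contributes one PR and one PRE copy, so MOI enters as promoter
dosage, not as extra reactions: this is the core of the gene-dosage
question.

The baseline network has 14 species and 25 reactions. Three optional
variants probe robustness: CII tetramerisation (PRE activation by CII4),
deterministic genome replication (doubling every 3 minutes for the first
15), and CI self-repression (a second, ten-fold weaker CI2 operator that
silences the self-activated configuration while bound). An extrinsic-noise
option draws per-cell lognormal multipliers (given CV, mean 1) for all
transcription and translation rates, fixed for the cell's lifetime — a
simple model of cell-to-cell rate variability.

Dimers and promoter-bound complexes do not decay directly; turnover
proceeds by dissociation followed by monomer decay. This is the simplest
closure consistent with a three-rate protein-decay roster, and at the
nominal parameters the dimer pools are small, so the choice has little
effect on the readout.

## Simulation

`simulate_ssa()` draws statistically exact sample paths of the jump process
(direct-method Gillespie, C++ core with a Fenwick-tree propensity index).
Exactness, not algorithmic pedigree, is the contract: the suite checks the
sampler against closed-form birth-death moments and a directly solved
master equation for a closed dimerisation system. Scheduled events — late
infections, replication doublings — are applied at their exact times as
additions of free promoter copies. Time-varying volume enters through a
piecewise-constant refresh of the bimolecular propensities every 0.1 min,
a negligible bias at the growth rates considered (at most ~0.02/min,
i.e. < 0.2% volume change per refresh interval). `integrate_deterministic()`
solves the matching mean-field ODEs (mass action; promoter occupancies as
continuous fractions) with `deSolve::lsoda` at tolerances of 1e-8. In the
mean-field limit the equations depend on MOI and volume only through their
ratio — the deterministic model cannot produce direct MOI dependence, which
is exactly why it is the reference.

Reproducibility: every ensemble derives per-run seeds from one master seed
with a fixed golden-ratio stride modulo 2^31 - 1 (`seed_stream()`), so runs
are independent of ensemble size and identical inputs give bit-identical
outputs. The simulator uses its own mt19937-based generator, so results are
stable across platforms.

## The decision rule

A run is classified by comparing a CII statistic to a threshold K: either
the time-averaged CII concentration over a window (default 0-60 min; the
decision timescale is set at 60 minutes) or the concentration at the window
end. Ties count as lysis. The readout counts total CII protein equivalents
(monomer + 2 per dimer, bound or free, + 4 per tetramer) divided by the
standardized volume; switches for free-monomer or free-dimer readouts
exist. Under a Gaussian approximation with mean mu and SD sigma at the
decision time, the lysogeny probability is
P = (1 - erf((K - mu) / (sigma sqrt(2)))) / 2: raising noise raises the
rate when K is above the mean and lowers it below — the sign flip at K = mu
is the mechanism by which MOI acts at fixed concentration, since doubling
MOI and volume leaves the mean concentration unchanged but shrinks the
relative noise by roughly sqrt(2).

A phenomenological reference (`pheno_rate()`) expresses the empirical
unanimous-decision form: each of the `moi` phage votes for lysogeny with a
Hill function of the viral concentration and lysogeny requires unanimity.
Its constants (`K_half = 1`, `h = 2`) are free parameters here, chosen only
to reproduce the qualitative structure; no fitted values are claimed.

## Nominal parameters

The published parameter table for this model family is not legible in the
source material, so the package ships its own documented nominal set
(`default_parameters()`), chosen once against an explicit regime contract
and fully overridable through the YAML config. The contract: at MOI = 1,
V = 1 the deterministic [CII] rises from zero and stays high across the
60-minute window; copy numbers are in the tens-to-hundreds (so the Gaussian
picture is sensible and the ensemble mean tracks the mean-field ODE); and
promoter switching (unbinding at 3/min) is fast relative to the window.
Key values: mRNA lifetime 5 min; translation 1.5/min per mRNA; protein
decay 0.1, 0.15 and 0.3/min for CI, Cro and CII (CII is by far the least
stable of the three in vivo); dimerisation weak enough that monomers
dominate the pools. Simulation controls: output every 0.5 min; cell width
0.5 length units for the spherocylinder correction.

Because burst size and promoter kinetics shape how faithfully the ensemble
mean follows the ODE, these defaults deliberately avoid the
strong-bursting, slow-switching corner where fluctuation-nonlinearity
coupling shifts the stochastic mean by several percent. That regime is
still reachable through the config; the package's claims are stated for the
nominal set.

## Noise modulation: what the f-scaling does and does not change

`apply_noise_scaling(params, f)` multiplies translation and mRNA decay by
f. The stationary protein mean (tx * translation / (mrna_decay * decay)) is
invariant. Two further invariances are worth recording because they shaped
the experiment design. The burst size translation/mrna_decay is itself
invariant; what grows with f is the instantaneous protein Fano factor,
1 + f k_tl / (f d_m + d_p), saturating once f d_m >> d_p. And for a linear
expression cascade the zero-frequency spectral density of the protein —
equivalently, the variance of a long-window time average — is exactly
invariant under the joint scaling: both the shot-noise term and the
transmitted mRNA term lose their f dependence. Consequently the
time-averaged decision statistic barely responds to f, while the
single-time-point statistic responds strongly. The noise-modulation sweep
(`noise_sweep()`) therefore classifies on the single-time-point criterion
by default (a mode switch restores the time average); the two criteria give
very similar fate calls everywhere else, and the single-time readout is
also where the Gaussian analytic formula applies.

## Thresholds as SD offsets

Absolute threshold values are not transferable between parameter sets, so
sweeps express K as offsets from a pooled (or baseline, or per-set) mean in
matching SD units: "high" and "low" default to +1 and -1 SD. The
sensitivity scan fixes each perturbed set's threshold at its own pooled
mean + 1 SD from a calibration ensemble before estimating rates with fresh
runs, so the threshold choice never sees the data it classifies.

## Spatial model

The published spatial treatment used 3-D Brownian particle tracking. This
package deliberately substitutes a 1-D reaction-diffusion master equation:
the cell's long axis is split into compartments (default 11, odd so
"centre" is one slice), molecules hop between neighbours at D/h^2 with
reflecting ends, genomes stay in the slice they infected, and bimolecular
rates are rescaled to the compartment volume so the one-compartment case is
species-for-species the well-mixed model. The phenomenon under study — a
diffusion delay between spatially separated genomes along the axis — lives
in one dimension, and the RDME captures it at a small fraction of the
particle method's cost; binding-radius and timestep parameters of the
particle method are therefore out of scope. Diffusion defaults give a
unit-cell mRNA traversal of ~10 min and a protein traversal of ~12 s: the
physiological ordering (protein mixing is effectively instantaneous on the
decision timescale; mRNA mixing is not).

Two limits anchor the implementation: one compartment reduces exactly to
the well-mixed network, and fast diffusion (both coefficients x100)
reproduces the well-mixed ensemble mean for every phage placement. RDME
cost grows linearly in D, so the fast-diffusion check runs at a reduced,
documented scale — 5 compartments, a 20-minute horizon and a few dozen
runs per placement — which is where the comparison is feasible at desk
scale; the tolerance (2 standard errors) is unchanged and scales with the
run count.

## Growth coupling

A growing cell (`growth_model()`) elongates exponentially at rate g.
Dilution adds a first-order loss channel at rate g for free cytoplasmic
species (genomes are not diluted within a cycle); volume growth makes
bimolecular propensities use V(t) = V0 exp(g t); transcription coupling
multiplies all transcription rates by a factor interpolated linearly
between (g_slow, 2) and (g_fast, 1), with anchors at 90- and 30-minute
doubling times. The orientation — a two-fold enhancement at the slow-growth
end — is the one under which growth modulation by MOI reinforces the
experimentally observed direction (higher MOI, slower growth, more CII,
more lysogeny); the anchors and multipliers are configurable, and each
experiment records which orientation it used. Media sweeps assume the cell
cycle stays at or above the 60-minute decision window, an assumption
recorded rather than enforced.

## Synthetic cohorts

The time-lapse measurements that motivated the growth analysis are
emulated, not reproduced: `generate_cohort()` draws per-cell MOI (truncated
Poisson by default — the empirical MOI distribution is not published),
assigns an elongation rate g0 - moi * delta_g with an explicit per-MOI
non-grower probability, jitters the final-frame time cell to cell, grows
length exponentially between the two frames with multiplicative lognormal
measurement noise (median-unbiased, so the log-ratio estimator inherits no
systematic error from the noise model), draws fates from the
phenomenological model, and delays lysogens' final frame by a configurable
decision delay. Defaults: g0 = ln 2 / 60 per min, delta_g = 0.0015 per min
per phage (about 13% slowdown at MOI 5), noise CV 5%, 5% non-growers per
unit MOI, 5-minute frame-time jitter, 20-minute lysogeny delay — values picked once to mirror the
qualitative structure of the reanalysed movies (monotone growth-rate
decrease with MOI; delayed division in lysogens). The estimator
ln(Lf/L0)/dt is exact on noiseless exponential data and has O(CV^2) bias
under multiplicative noise; a linear-elongation generator and estimator
exist for robustness checks. Passing cohort tests shows the estimators
recover the generative structure — it says nothing about segmentation or
fluorescence-thresholding errors in real movies, which are out of scope.

## Problem sizes and numerical choices

Reference ensemble sizes follow the study design (5000 runs for the main
equal-concentration comparison, 2000 per sweep point, 200 sets x 500 runs
for the full sensitivity scan); the test suite and the CI profile run
scaled-down versions (50 x 200 for sensitivity, smaller spatial ensembles
as above) chosen so the whole suite completes on a laptop-class single
core. Ties at the threshold classify as lysis; the integer-count/volume
grid can produce exact ties. Binomial (Wald) standard errors accompany
every rate, with a Wilson interval available near 0 and 1. ODE integration
failures raise errors rather than truncating. The SSA refuses to run past
a configurable event cap (`max_steps`) so runaway parameter sets fail
loudly.

## Known limitations

CII levels in this model stay high across the hour, whereas measured CII
falls sharply by 60 minutes; the model is a minimal decision-circuit
caricature, adequate for threshold-crossing statistics but not for CII
kinetics per se. The single-gene, single-threshold decision rule is crude —
joint CI/Cro criteria and commitment-time estimation are out of scope. The
RDME is a 1-D abstraction: membrane interactions, diffusion-limited
rebinding and 3-D geometry are not represented. Phage replication adds
naked free promoters (any bound dimers stay on their template), a choice
the source material leaves open. Cells are followed only to the decision;
division with binomial partitioning is not modelled.
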