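---
title: "Quantitative pharmacology of gating-modifier peptide block of a dimeric proton channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pharmacology of gating-modifier peptide block of a dimeric proton channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvblock)
```

## The problem

The voltage-gated proton channel is a dimer in which each subunit is a
voltage-sensor domain carrying its own proton pathway.  Designer
peptide toxins built on the inhibitor-cystine-knot scaffold inhibit
the channel as gating modifiers: they bind the extracellular S3--S4
loop of each subunit, hold the voltage sensor in its resting ("down")
conformation, and thereby raise the voltage needed to open the
channel.  Because the binding site itself moves with the voltage
sensor, block is state dependent: affinity is high at rest and decays
with depolarization, almost entirely through an accelerated off-rate.

`hvblock` implements the complete quantitative layer of this kind of
study: the forward models (equilibrium block, gating, kinetics,
cooperativity, membrane partitioning), the estimators that invert
them, the mutational energetics used to map binding interfaces, a
seeded synthetic-data generator for every experiment class, and the
file-format/reporting plumbing that ties them into a pipeline.

## Models

### Equilibrium block

The fraction of unblocked current at equilibrium follows a Hill
relation,

$$F_{un}(C) = 1 - f_{max}\,\frac{C^{h}}{K_i^{h} + C^{h}},$$

with inhibition constant $K_i$ (mol/L), Hill coefficient $h$, and a
maximal blockable fraction $f_{max} \in (0, 1]$.  With
$f_{max} = 1$ this is the classical
$F_{un} = (1 + (C/K_i)^h)^{-1}$.  The extra parameter exists because a
state-dependent blocker need not silence the channel completely at
depolarized voltages: at +40 mV, saturating monomeric peptide blocks
only about half of the current even though the two-parameter fit is
what the field reports.  `fit_hill()` therefore defaults to the
literal two-parameter relation (`fix_fmax = TRUE`) and exposes
$f_{max}$ as an optional third parameter.

### Gating

Normalized conductance--voltage curves follow a Boltzmann function
$G/G_{max} = (1 + e^{-(V - V_{1/2})/k})^{-1}$ with midpoint $V_{1/2}$
and slope factor $k$ in mV.  Positive $k$ means activation by
depolarization, the convention appropriate for this channel.

### Kinetics and the state-dependent off-rate

Wash-in and washout of blocker at concentration $C$ relax as single
exponentials with

$$\tau_{on} = (k_{on} C + k_{off})^{-1}, \qquad
  \tau_{off} = k_{off}^{-1}, \qquad K_i = k_{off}/k_{on}.$$

These bimolecular relations are approximations for a two-site channel,
but they are the practical currency of the field and are what the
estimators report.  State dependence is modelled by coupling a
two-state (closed/open) gating equilibrium to state-specific
off-rates:

$$k_{off}(V) = (1 - P_o(V))\,k_{off}^{c} + P_o(V)\,k_{off}^{o},$$

with $P_o(V)$ the Boltzmann open probability, $k_{on}$ voltage
independent (the empirical observation for these peptides), and
$k_{off}^{o} \ge k_{off}^{c}$ enforced so that depolarization
accelerates dissociation.  The closed-state inhibition constant is the
linked quantity $K_c = k_{off}^{c}/k_{on}$, never a free parameter.

### Two-site occupancy

The dimer offers two allosterically coupled peptide sites.
`two_site_occupancy()` uses the intrinsic-site convention: each empty
site binds with intrinsic dissociation constant $K_{d1}$, and
occupancy of one site changes the other's intrinsic constant to
$K_{d1}/c$.  The statistical weights of 0, 1 and 2 bound peptides are

$$1 \;:\; 2\,C/K_{d1} \;:\; c\,(C/K_{d1})^2,$$

where the factor 2 counts the two equivalent singly bound
configurations.  This convention was chosen over the alternative that
puts a statistical factor on the doubly bound term because it is the
one under which independent sites ($c = 1$) reduce exactly to the
binomial identity $P_1^2 = 4 P_0 P_2$ at every concentration -- the
natural correctness anchor for a symmetric dimer.  With $c \approx 12$
(the fold-facilitation reported for the second binding event at
resting potential) the occupancy curve steepens to a midpoint Hill
slope above 1, as expected for positive cooperativity.

### Membrane partitioning

Depletion assays titrate lipid (large unilamellar vesicles) against a
fixed amount of peptide and measure the bound fraction $F_p$.  The
mole-fraction partition coefficient is
$K_p = \frac{F_p}{1-F_p}\,\frac{[W]}{[L]}$ with $[W] = 55.3$ mol/L the
molar concentration of water; `partition_fraction()` is its exact
inverse $F_p = K_p L / ([W] + K_p L)$, and `fit_partition()` estimates
$K_p$ from a titration (falling back to the closed form for a single
point).

### Energetics

Single-dose mutational scans convert two unblocked fractions measured
at a common dose into a $K_i$ ratio,

$$\frac{K_i^{mut}}{K_i^{ref}} =
  \left[\frac{(1 - F_{un}^{ref})\,F_{un}^{mut}}
             {(1 - F_{un}^{mut})\,F_{un}^{ref}}\right]^{1/h},$$

and then into $\Delta\Delta G = RT \ln (K_i^{mut}/K_i^{ref})$.  The
formula is exactly consistent with the Hill model: fractions generated
from $(K_i, h)$ and $(rK_i, h)$ return $r$ at any dose, which the test
suite asserts to $10^{-9}$.  Conventions: positive $\Delta\Delta G$
means weakened binding; the Hill coefficient is always the reference
construct's $h$ at the measurement voltage, never a per-variant value.
`classify_scan()` partitions panels with the consensus interface
cutoff of 2 kcal/mol for critical residues and a fourfold
$K_i$-improvement rule for enhancing ones.  Note the two rules meet at
$-RT\ln 4 \approx -0.82$ kcal/mol, so a variant assigned
$-0.9$ kcal/mol is classified enhancing.

Double-mutant cycles quantify non-additivity of a toxin-variant x
channel-mutant square:

$$\Omega = \frac{K_i^{ref,ref}\,K_i^{var,mut}}
                {K_i^{ref,mut}\,K_i^{var,ref}}, \qquad
  \Delta\Delta G_{coupling} = RT\ln\Omega.$$

Additive energetics give $\Omega = 1$ however large the single-mutant
effects; the coupling is symmetric under exchange of the toxin and
channel axes and negates under swapping one axis's labels (both are
property tests).  Couplings above 1 kcal/mol are the conventional
reporting threshold for direct contact pairs; it is a configurable
option, not hard-wired.

## Temperature

The gas constant is fixed at $R = 0.0019872$ kcal mol$^{-1}$
K$^{-1}$; temperature defaults to 298.15 K ($RT = 0.5925$ kcal/mol)
and is configurable everywhere through `binding_constants()` (CLI:
`--temperature-k`).  Published statements that equate a 43-fold
$K_i$ ratio with 2 kcal/mol imply a slightly smaller $RT$ than the
298 K value ($RT\ln 43 = 2.23$ kcal/mol); we treat that as rounding in
the source literature rather than evidence about the recording
temperature, and do not guess a different default.

## Estimation details

All fitters use Levenberg--Marquardt least squares (`minpack.lm`) with
a convergence tolerance of $10^{-10}$ on the relative RSS change, at
most $10^4$ function evaluations, and no internal randomness --
identical inputs give identical fits.

* **Parameterization.**  Scale parameters ($K_i$, $\tau$, $K_p$) are
  fitted on the log scale, which enforces positivity and makes the
  optimizer scale free; standard errors are mapped back by the delta
  method.  $h$ is bounded to $(0.05, 5)$ and $f_{max}$ to $(0, 1]$.
* **Multi-start.**  `fit_hill()` uses a fixed 3x3 grid:
  $K_i^{0} \in \{K_i^{init}/10, K_i^{init}, 10K_i^{init}\}$ (with
  $K_i^{init}$ the dose whose observed block is nearest half the
  maximal observed block) crossed with $h^0 \in \{0.5, 1, 2\}$; best
  RSS wins and ties break toward the smallest $h$.  The exponential
  and partition fitters use threefold start grids on the log scale;
  the Boltzmann fitter takes its slope sign from the data correlation
  and is bounded away from zero within that sign.
* **Standard errors** come from the Jacobian-based covariance at the
  optimum; a singular covariance yields `NA` with a
  `singular_covariance` flag, never silent zeros.  Optional
  inverse-variance weighting is applied when a `sem` column is
  present; the default is unweighted, since published per-point errors
  are SEMs over cells that cannot be reconstructed.
* **Degenerate inputs** are errors, not warnings: fewer than 3
  distinct doses (4 with free $f_{max}$), panels with no detectable
  block, flat conductance--voltage data (range < 0.1), all-zero
  depletion series, and wash-in/washout pairs with
  $\tau_{on} > \tau_{off}$ (inconsistent with a bimolecular scheme)
  all refuse to fit.  Two softer diagnostics are flags on the result:
  `short_window` when a kinetic record is shorter than the fitted
  $\tau$, and `nonmonotone` when a trace rebounds against its
  relaxation direction by more than both 6 locally estimated noise
  SDs (running-median detrend) and 20% of the fitted amplitude.

## The synthetic-data layer

Generators exist for every experiment class -- equilibrium
dose-response, kinetic trace pairs, full multi-voltage state-dependent
bundles, mutational scans, mutant-cycle squares, and depletion
titrations.  Design choices:

* **Noise model.**  Additive Gaussian noise on the observed fraction
  or normalized current, clipped to the physical interval, with sd
  0.02--0.03 by default.  Published data report SEMs over 3--12 cells
  but no per-point noise model, so this is an explicit synthetic
  convention chosen to make recovery tests meaningful, not an inferred
  property of the recordings.
* **Seeding.**  Every generator requires an explicit integer seed
  (`noise_spec(sd, seed)`); seeding is scoped with `withr`, so no
  global RNG state is disturbed, and identical (parameters, seed)
  produce byte-identical serialized output.  Bundles derive
  deterministic child seeds per sub-experiment.
* **State-model defaults.**  The CLI's `simulate-state` condition uses
  $V_{1/2} = 35$ mV, $k = 7$ mV, $k_{off}^{c} = 0.0015$ s$^{-1}$,
  $k_{off}^{o} = 0.04$ s$^{-1}$, $k_{on} = 3\times10^{5}$
  M$^{-1}$s$^{-1}$: the closed-state off-rate matches the measured
  0 mV value, and the open-state off-rate and gating midpoint were set
  once so that the apparent $k_{off}$ rises about 15-fold between 0
  and +40 mV, the hallmark fold change of state-dependent
  dissociation in this system.
* **What it does not emulate.**  Raw current traces with capacitive
  transients or leak, rundown/drift, cell-to-cell expression
  variability, pH-gradient effects on gating, and the mapping from
  tethered-toxin surface density to effective concentration (the only
  published calibration point equates one expression condition with
  ~30 uM free peptide; the mapping is a free generator parameter).
  Passing recovery tests therefore demonstrate estimator correctness
  under the stated noise model, not robustness to every artifact of
  real recordings.

## Problem sizes

The recovery studies run 200 seeded replicates per scenario at the
published designs: 8 log-spaced doses spanning 1--1000 nM (monomer,
$K_i$ 30.9 nM, $h$ 0.48) or 0.01--100 nM (bivalent peptide, 631 pM,
$h$ 1.01) with noise sd 0.03, and 6 lipid concentrations
(0.5--15 mM) with sd 0.02 for the partition coefficient
($K_p = 3.2\times10^{5}$).  Medians over replicates are compared to
the generating truth within 10%.  Module-level tests use 60
replicates; property tests sweep 20--200 random cases under fixed
seeds.

## Pipeline and formats

CSV schemas (comma-separated, UTF-8, '.' decimal, mandatory header)
carry units in explicit columns (`conc_unit`, `ki_unit`,
`lipid_unit`; accepted values M, mM, uM, nM, pM) and are normalized
to molar on read.  Validation rejects rather than coerces: missing or
unknown columns, non-numeric cells, unknown units, and domain
violations are itemized with row numbers, and no `NA` reaches a
fitter silently.  The YAML run configuration checks a schema version
and rejects unknown keys.  Every CLI invocation writes a run manifest
(package version, seeds, config hash, argument vector, status,
machine-readable error code); the manifest is the only output with a
timestamp, so config plus seed determine every other output byte.
Binary acquisition formats are out of scope by design; the documented
conversion point is the table schemas themselves.

## Known limitations

* The bimolecular relations are knowingly approximate for a dimeric
  channel whose two sites are coupled differently at different
  voltages; fitted $k_{off}/k_{on}$ and equilibrium $K_i$ can differ
  severalfold, as they do in the published condition at +40 mV.
* Hill coefficients below 1 are reported as observed; the package
  does not attempt to invert them into two-site parameters (the
  mapping is under-determined from a single dose-response).
* No error propagation from per-cell SEMs into $\Delta\Delta G$
  confidence intervals, no global fitting across voltages, and no
  hierarchical modelling over cells.
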