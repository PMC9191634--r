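# hvblock

Quantitative pharmacology of gating-modifier peptide block of the
dimeric voltage-gated proton channel.

Peptide toxins on the inhibitor-cystine-knot scaffold inhibit the
proton channel by clamping each subunit's voltage sensor in its
resting conformation. Characterizing such blockers means fitting the
same handful of models over and over: Hill dose–response curves for
the inhibition constant `K_i` and coefficient `h`, Boltzmann
conductance–voltage curves for gating (`V_1/2`, slope), single
exponentials for wash-in/washout kinetics with the bimolecular
relations

    tau_on  = 1 / (kon·C + koff)
    tau_off = 1 / koff
    K_i     = koff / kon

single-dose mutational energetics

    Ki_mut / Ki_ref = [ (1 − Fun_ref)·Fun_mut / ((1 − Fun_mut)·Fun_ref) ]^(1/h)
    ddG             = RT · ln(Ki_mut / Ki_ref)

thermodynamic double-mutant cycles (`Omega`, coupling
`ddG = RT·ln(Omega)`), and mole-fraction membrane partition
coefficients from liposome depletion assays
(`Kp = [Fp/(1−Fp)]·[W]/[L]`). `hvblock` packages all of these as
forward models plus matching estimators, adds a state-dependent
two-state model of voltage-dependent dissociation and a two-site
cooperative occupancy model for the dimer, and ships a seeded
synthetic-data generator for every experiment class so the whole
pipeline is testable end to end without recordings. It is aimed at
ion-channel electrophysiologists and peptide engineers who want the
arithmetic of such a study to be reproducible and unit-safe.

## Worked example

Simulate a noisy dose–response experiment at the wild-type +40 mV
parameters, fit it, extract rates from relaxation time constants, and
run a single-dose energetic comparison:

```r
library(hvblock)

doses <- 10^seq(log10(1e-9), log10(1e-6), length.out = 8)   # 1-1000 nM
d <- gen_dose_response(hill_params(ki = 31e-9, h = 0.48), doses,
                       noise_spec(sd = 0.03, seed = 2024))
fit_hill(d)
#> hill fit (n = 8, rss = 0.002324, converged = TRUE)
#>   ki     3.6211e-08 +/- 2.64e-09
#>   h      0.476497 +/- 0.019
#>   fmax   1
```

The fitted inhibition constant (36 nM) and Hill coefficient (0.48)
recover the generating values (31 nM, 0.48) to within the noise of a
single 8-dose experiment; the sub-unity Hill coefficient is the
signature of negatively coupled binding sites at depolarized voltage.

```r
rates_from_time_constants(tau_on = 10.3, tau_off = 45.5, C = 250e-9)
#> rates: kon = 3.004e+05 /M/s, koff = 0.02198 /s (Ki = koff/kon = 7.315e-08 M)

ratio <- ki_ratio_from_block(fun_ref = 0.35, fun_mut = 0.77, h_ref = 0.48)
ddg_from_ratio(ratio)
#> Ki ratio: 45.0,  ddG: 2.26 kcal/mol
```

A variant that drops inhibition from 65% to 23% at one dose weakens
binding 45-fold, i.e. 2.26 kcal/mol — past the 2 kcal/mol consensus
cutoff for an interface residue.

Fold-change reporting over a table of per-condition parameters
(shipped example: the published blockade parameters of the monomeric
and bivalent peptides on wild-type and mutant channels):

```r
tab <- read_experiment_table(system.file("extdata", "blockade_parameters.csv",
                                         package = "hvblock"), "results")
rep <- build_report(tab)
subset(rep$fold_changes, quantity == "koff" & axis == "voltage")[2, ]
#>   quantity    axis     context numerator denominator ratio fold
#> 9     koff voltage   C6 / hHv1    +40 mV       +0 mV  14.7 14.7
subset(rep$fold_changes, quantity == "ki" & axis == "peptide")[2, ]
#>    quantity    axis        context numerator denominator ratio fold
#> 16       ki peptide hHv1 at +40 mV        C6        C6_2  49.2 49.2
```

Dissociation of the monomer is ~15-fold faster at +40 mV than at
0 mV, and the bivalent peptide binds ~50-fold tighter than the
monomer at +40 mV — the avidity payoff of engaging both subunits at
once.

A command-line driver (`inst/cli/hvblock`, or `hvblock_cli()`
in-process) exposes the pipeline as subcommands:
`simulate-dose | simulate-kinetics | simulate-state | simulate-scan |
simulate-cycle | simulate-depletion | fit-dose | fit-kinetics |
fit-gv | fit-partition | scan | cycle | report`, each writing outputs
plus a run manifest under `--out`.

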