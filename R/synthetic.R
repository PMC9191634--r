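# Seeded generators emulating every experiment class the pipeline
# analyzes: equilibrium dose-response, wash-in/washout kinetics,
# state-dependent block across voltages, single-dose mutational scans,
# mutant-cycle Ki squares, and lipid depletion titrations.
#
# Every generator takes an explicit seed through a noise_spec; no
# global RNG state is touched (seeding is scoped with withr), and
# identical (parameters, seed) give identical output.

#' Gaussian noise specification for the synthetic generators
#'
#' @param sd standard deviation of additive Gaussian noise on the
#'   observed fraction or normalized current; >= 0.
#' @param seed integer RNG seed; mandatory, so every generated dataset
#'   is reproducible.
#' @param clip length-2 interval to which noisy observations are
#'   clamped (fractions live in \[0, 1\]).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0.03, seed, clip = c(0, 1)) {
  if (missing(seed)) stop("seed is mandatory for synthetic data",
                          call. = FALSE)
  stopifnot(is.numeric(sd), length(sd) == 1L, is.finite(sd), sd >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(clip), length(clip) == 2L, clip[1] < clip[2])
  structure(list(sd = sd, seed = as.integer(seed), clip = clip),
            class = "noise_spec")
}

# Add seeded, clipped Gaussian noise to a vector of model values.
.apply_noise <- function(values, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sd == 0) return(pmin(pmax(values, noise$clip[1]), noise$clip[2]))
  noisy <- withr::with_seed(
    noise$seed,
    values + stats::rnorm(length(values), sd = noise$sd)
  )
  pmin(pmax(noisy, noise$clip[1]), noise$clip[2])
}

# Derive a child seed so sub-experiments inside one bundle are
# independent yet reproducible; stays within 32-bit integer range.
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 2654435761) %% 2147483587) + 1L
}

#' Generate an equilibrium dose-response table
#'
#' Samples fraction-unblocked observations from the Hill forward model
#' plus clipped Gaussian noise, in the schema consumed by
#' [fit_hill()].
#'
#' @param p a [hill_params()] object (ground truth).
#' @param doses toxin concentrations, mol/L; all > 0.
#' @param noise a [noise_spec()].
#' @param replicates independent observations per dose.
#' @param condition label stored in the `condition` column.
#' @param voltage_mV recording voltage stored alongside (may be `NA`).
#' @return Data frame with columns `condition`, `voltage_mV`, `conc`,
#'   `conc_unit` ("M"), `fraction_unblocked`; the generating parameters
#'   are attached as attribute `truth`.
#' @examples
#' gen_dose_response(hill_params(31e-9, 0.48),
#'                   doses = 10^seq(-9, -6, length.out = 8),
#'                   noise = noise_spec(sd = 0.03, seed = 7))
#' @export
gen_dose_response <- function(p, doses, noise, replicates = 1,
                              condition = "synthetic",
                              voltage_mV = NA_real_) {
  stopifnot(inherits(p, "hill_params"), is.numeric(doses),
            replicates >= 1)
  if (length(doses) == 0L) stop("dose list is empty", call. = FALSE)
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    stop("doses must be finite and > 0 (mol/L)", call. = FALSE)
  }
  conc <- rep(doses, each = replicates)
  y <- .apply_noise(fraction_unblocked(conc, p), noise)
  out <- data.frame(condition = condition, voltage_mV = voltage_mV,
                    conc = conc, conc_unit = "M",
                    fraction_unblocked = y, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(ki = p$ki, h = p$h, fmax = p$fmax,
                             sd = noise$sd, seed = noise$seed)
  out
}

#' Generate a wash-in / washout kinetic trace pair
#'
#' Single-exponential relaxations of normalized current for acute
#' application and washout of a blocker at concentration C, with time
#' constants from [time_constants()] and an equilibrium block level
#' consistent with `Ki = koff/kon`.
#'
#' @param r a [rate_constants()] object (ground truth).
#' @param C bath toxin concentration during wash-in, mol/L; > 0.
#' @param noise a [noise_spec()].
#' @param duration wash-in record length, s; defaults to 5 wash-in
#'   time constants.  A record shorter than `tau_on / 5` triggers a
#'   warning.
#' @param duration_off washout record length, s; defaults to 3 washout
#'   time constants.
#' @param dt sampling interval, s; > 0.
#' @param condition label for the `condition` column.
#' @return List with elements `wash_in` and `wash_out`, each a data
#'   frame with columns `condition`, `phase`, `t_s`, `i_norm`, `conc`,
#'   `conc_unit`; ground truth attached as attribute `truth`.
#' @export
gen_kinetic_traces <- function(r, C, noise, duration = NULL,
                               duration_off = NULL, dt = 1,
                               condition = "synthetic") {
  stopifnot(inherits(r, "rate_constants"),
            is.numeric(C), length(C) == 1L, C > 0,
            is.numeric(dt), length(dt) == 1L, dt > 0)
  tc <- time_constants(r, C)
  if (is.null(duration)) duration <- 5 * tc$tau_on
  if (is.null(duration_off)) {
    duration_off <- if (is.finite(tc$tau_off)) 3 * tc$tau_off else duration
  }
  if (duration < tc$tau_on / 5) {
    warning("wash-in record shorter than tau_on/5: time constant poorly constrained")
  }
  y_eq <- ki_from_rates(r) / (ki_from_rates(r) + C)

  t_on <- seq(0, duration, by = dt)
  t_off <- seq(0, duration_off, by = dt)
  y_on <- y_eq + (1 - y_eq) * exp(-t_on / tc$tau_on)
  y_off <- 1 + (y_eq - 1) * exp(-t_off / tc$tau_off)
  noisy <- .apply_noise(c(y_on, y_off), noise)

  mk <- function(phase, t, y) {
    data.frame(condition = condition, phase = phase, t_s = t, i_norm = y,
               conc = if (phase == "wash_in") C else 0, conc_unit = "M",
               stringsAsFactors = FALSE)
  }
  out <- list(
    wash_in = mk("wash_in", t_on, noisy[seq_along(t_on)]),
    wash_out = mk("wash_out", t_off, noisy[length(t_on) + seq_along(t_off)])
  )
  attr(out, "truth") <- list(kon = r$kon, koff = r$koff,
                             tau_on = tc$tau_on, tau_off = tc$tau_off,
                             C = C, y_eq = y_eq, sd = noise$sd,
                             seed = noise$seed)
  out
}

#' Generate a full state-dependent block experiment
#'
#' Emulates the voltage dependence of gating-modifier block: at each
#' voltage the apparent rates come from [state_dependent_rates()], and
#' the bundle contains a per-voltage dose-response table (bimolecular
#' Hill, h = 1, Ki = koff(V)/kon), wash-in/washout traces at
#' `C_kinetic`, and a G-V table from the gating equilibrium.
#'
#' @param m a [state_model()] object (ground truth).
#' @param voltages recording voltages, mV.
#' @param doses dose-response concentrations, mol/L.
#' @param noise a [noise_spec()]; child seeds derived from its seed
#'   keep the sub-experiments independent but reproducible.
#' @param C_kinetic concentration for the kinetic traces, mol/L.
#' @param dt sampling interval for traces, s.
#' @return An `experiment_bundle`: list with `tables` (data frames
#'   `dose_response`, `traces`, `gv`) and `truth` (the generating
#'   parameters, always serialized alongside the data).
#' @export
gen_state_experiment <- function(m, voltages, doses, noise,
                                 C_kinetic = 250e-9, dt = 1) {
  stopifnot(inherits(m, "state_model"), is.numeric(voltages),
            length(voltages) >= 1L)
  dr <- list()
  tr <- list()
  truth_v <- list()
  for (i in seq_along(voltages)) {
    v <- voltages[i]
    r <- state_dependent_rates(m, v)
    ki_v <- ki_from_rates(r)
    p_v <- hill_params(ki = ki_v, h = 1)
    dr[[i]] <- gen_dose_response(
      p_v, doses,
      noise_spec(noise$sd, .child_seed(noise$seed, 2L * i), noise$clip),
      condition = sprintf("V%+g", v), voltage_mV = v
    )
    traces <- gen_kinetic_traces(
      r, C_kinetic,
      noise_spec(noise$sd, .child_seed(noise$seed, 2L * i + 1L), noise$clip),
      dt = dt, condition = sprintf("V%+g", v)
    )
    tr[[i]] <- do.call(rbind, traces)
    truth_v[[i]] <- list(voltage_mV = v, kon = r$kon, koff = r$koff,
                         ki = ki_v)
  }
  gv_tab <- data.frame(
    condition = "gating", voltage_mV = voltages,
    g_norm = boltzmann_conductance(voltages, m$gv),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      tables = list(
        dose_response = do.call(rbind, dr),
        traces = do.call(rbind, tr),
        gv = gv_tab
      ),
      truth = list(
        gv = list(vhalf = m$gv$vhalf, slope = m$gv$slope),
        koff_c = m$koff_c, koff_o = m$koff_o, kon = m$kon, kc = m$kc,
        per_voltage = truth_v, C_kinetic = C_kinetic,
        sd = noise$sd, seed = noise$seed
      )
    ),
    class = "experiment_bundle"
  )
}

#' Generate a single-dose mutational scan
#'
#' Each variant's inhibition constant is the reference Ki scaled by
#' `exp(ddG/RT)`; the observed unblocked fractions follow the Hill
#' relation at the screening dose plus clipped noise.
#'
#' @param panel named numeric vector: variant label -> true ddG
#'   (kcal/mol; positive = weakened binding).
#' @param reference a [hill_params()] object for the reference
#'   construct.
#' @param dose screening concentration, mol/L; > 0.
#' @param noise a [noise_spec()].
#' @param constants a [binding_constants()] object.
#' @return List of class `scan_experiment` with `scan` (data frame
#'   `variant`, `fraction_unblocked`), `fun_ref` (the noisy reference
#'   measurement) and `truth`.
#' @export
gen_scan <- function(panel, reference, dose, noise,
                     constants = binding_constants()) {
  stopifnot(is.numeric(panel), length(panel) >= 1L,
            !is.null(names(panel)), all(nzchar(names(panel))),
            inherits(reference, "hill_params"),
            is.numeric(dose), length(dose) == 1L, dose > 0)
  rt <- rt_kcal(constants)
  ki_var <- reference$ki * exp(panel / rt)
  fun_true <- vapply(
    ki_var,
    function(k) fraction_unblocked(dose, hill_params(k, reference$h,
                                                     reference$fmax)),
    numeric(1)
  )
  fun_ref_true <- fraction_unblocked(dose, reference)
  noisy <- .apply_noise(c(fun_ref_true, fun_true), noise)
  structure(
    list(
      scan = data.frame(variant = names(panel),
                        fraction_unblocked = unname(noisy[-1]),
                        stringsAsFactors = FALSE),
      fun_ref = unname(noisy[1]),
      truth = list(ddg = panel, ki = ki_var, fun_ref = fun_ref_true,
                   reference = reference, dose = dose,
                   sd = noise$sd, seed = noise$seed)
    ),
    class = "scan_experiment"
  )
}

#' Construct a mutant-cycle Ki square with known coupling
#'
#' Builds the four corner inhibition constants from single-mutation
#' free-energy perturbations and a prescribed coupling energy:
#' the double-mutant corner is
#' `ki_ref * exp((ddg_toxin + ddg_channel + coupling)/RT)`, so
#' [mutant_cycle()] recovers `coupling` exactly by construction.
#'
#' @param ddg_toxin single-mutation ddG of the toxin variant, kcal/mol.
#' @param ddg_channel single-mutation ddG of the channel mutant,
#'   kcal/mol.
#' @param coupling true coupling energy, kcal/mol.
#' @param ki_ref reference-corner Ki, mol/L.
#' @param labels named character vector with entries `ref_toxin`,
#'   `var_toxin`, `ref_channel`, `mut_channel`.
#' @param constants a [binding_constants()] object.
#' @return Data frame with columns `toxin`, `channel`, `ki_M` (four
#'   rows); the construction parameters are attached as attribute
#'   `truth`.
#' @export
gen_cycle <- function(ddg_toxin, ddg_channel, coupling, ki_ref = 31e-9,
                      labels = c(ref_toxin = "WT", var_toxin = "Var",
                                 ref_channel = "WT", mut_channel = "Mut"),
                      constants = binding_constants()) {
  stopifnot(is.numeric(ddg_toxin), is.numeric(ddg_channel),
            is.numeric(coupling), ki_ref > 0,
            all(c("ref_toxin", "var_toxin", "ref_channel",
                  "mut_channel") %in% names(labels)))
  rt <- rt_kcal(constants)
  out <- data.frame(
    toxin = c(labels[["ref_toxin"]], labels[["ref_toxin"]],
              labels[["var_toxin"]], labels[["var_toxin"]]),
    channel = c(labels[["ref_channel"]], labels[["mut_channel"]],
                labels[["ref_channel"]], labels[["mut_channel"]]),
    ki_M = ki_ref * exp(c(0, ddg_channel, ddg_toxin,
                          ddg_toxin + ddg_channel + coupling) / rt),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(ddg_toxin = ddg_toxin,
                             ddg_channel = ddg_channel,
                             coupling = coupling, ki_ref = ki_ref)
  out
}

#' Generate a lipid depletion titration
#'
#' Bound-fraction observations from the mole-fraction partition model
#' plus clipped noise, with an optional non-partitioning control series
#' (Kp = 0, emulating a pore-blocking toxin that stays in the aqueous
#' phase).
#'
#' @param Kp true mole-fraction partition coefficient; >= 0.
#' @param L lipid concentrations, mol/L.
#' @param noise a [noise_spec()]; the default clip for depletion data
#'   should keep fractions in \[0, 0.999\] so the fit domain is valid.
#' @param include_control add the Kp = 0 control series.
#' @param condition label for the test series.
#' @param constants a [binding_constants()] object.
#' @return Data frame with columns `condition`, `lipid_M`,
#'   `fraction_bound`; truth attached as attribute `truth`.
#' @export
gen_depletion <- function(Kp, L, noise, include_control = FALSE,
                          condition = "synthetic",
                          constants = binding_constants()) {
  stopifnot(is.numeric(Kp), length(Kp) == 1L, Kp >= 0, is.numeric(L))
  if (any(!is.finite(L)) || any(L < 0)) {
    stop("lipid concentrations must be finite and >= 0", call. = FALSE)
  }
  fp <- partition_fraction(Kp, L, constants)
  values <- if (include_control) c(fp, rep(0, length(L))) else fp
  noisy <- .apply_noise(values, noise)
  out <- data.frame(
    condition = rep(c(condition, if (include_control) "control_no_partition"),
                    each = length(L))[seq_along(values)],
    lipid_M = rep(L, times = if (include_control) 2L else 1L),
    fraction_bound = noisy,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(kp = Kp, sd = noise$sd, seed = noise$seed,
                             control = include_control)
  out
}
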