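# Forward (generative) equations: Hill block, Boltzmann gating, rate
# relations, state-dependent dissociation, two-site cooperative
# occupancy, and membrane partitioning.

#' Fraction of unblocked current at equilibrium
#'
#' Generalized Hill model of equilibrium block:
#' `F_un(C) = 1 - fmax * C^h / (Ki^h + C^h)`.  With `fmax = 1` this is
#' the classical relation `F_un = (1 + (C/Ki)^h)^-1`.  Monotone
#' non-increasing in C with infimum `1 - fmax`.
#'
#' @param C toxin concentration(s), mol/L; >= 0.  Vectorized.
#' @param p a [hill_params()] object.
#' @return Fraction(s) of unblocked current in \[0, 1\].
#' @examples
#' fraction_unblocked(250e-9, hill_params(31e-9, 0.48))  # ~0.27
#' @export
fraction_unblocked <- function(C, p) {
  stopifnot(inherits(p, "hill_params"), is.numeric(C))
  if (any(!is.finite(C)) || any(C < 0)) {
    stop("concentrations must be finite and >= 0 (mol/L)", call. = FALSE)
  }
  # (C/Ki)^h form is scale-invariant under joint rescaling of C and Ki
  x <- (C / p$ki)^p$h
  1 - p$fmax * x / (1 + x)
}

#' Normalized conductance from the Boltzmann activation curve
#'
#' `G/Gmax = 1 / (1 + exp(-(V - Vhalf)/slope))`; equals 0.5 at
#' `V = Vhalf` and, for positive slope, rises with depolarization.
#'
#' @param V membrane voltage(s), mV.  Vectorized.
#' @param gv a [gv_params()] object.
#' @return Normalized conductance(s) in \[0, 1\].
#' @export
boltzmann_conductance <- function(V, gv) {
  stopifnot(inherits(gv, "gv_params"), is.numeric(V))
  stats::plogis((V - gv$vhalf) / gv$slope)
}

#' Inhibition constant from rate constants
#'
#' `Ki = koff / kon` for a bimolecular binding reaction.
#'
#' @param r a [rate_constants()] object with `kon > 0`.
#' @return Ki in mol/L.
#' @examples
#' ki_from_rates(rate_constants(3e5, 0.022))  # 7.3e-8 M
#' @export
ki_from_rates <- function(r) {
  stopifnot(inherits(r, "rate_constants"))
  if (r$kon == 0) stop("kon must be > 0 to form Ki = koff/kon", call. = FALSE)
  r$koff / r$kon
}

#' Relaxation time constants of block and unblock
#'
#' For a bimolecular scheme at bath concentration C, the wash-in
#' relaxation is `tau_on = 1/(kon*C + koff)` and the washout is
#' `tau_off = 1/koff`; `tau_on <= tau_off` always, strictly when
#' `C * kon > 0`.
#'
#' @param r a [rate_constants()] object.
#' @param C toxin concentration, mol/L; >= 0.
#' @return A named list with `tau_on` and `tau_off` in seconds.
#' @examples
#' time_constants(rate_constants(3e5, 0.022), 250e-9)
#' @export
time_constants <- function(r, C) {
  stopifnot(inherits(r, "rate_constants"),
            is.numeric(C), length(C) == 1L, is.finite(C))
  if (C < 0) stop("C must be >= 0", call. = FALSE)
  if (r$koff == 0 && r$kon * C == 0) {
    stop("degenerate kinetics: both koff and kon*C are zero", call. = FALSE)
  }
  list(tau_on = 1 / (r$kon * C + r$koff),
       tau_off = if (r$koff > 0) 1 / r$koff else Inf)
}

#' Apparent rate constants of a state-dependent blocker at a voltage
#'
#' The apparent off-rate is the open-probability weighted mixture
#' `koff(V) = (1 - Po) * koff_c + Po * koff_o` with
#' `Po = boltzmann_conductance(V, gv)`; the on-rate is voltage
#' independent.  The apparent inhibition constant `koff(V)/kon` is
#' therefore non-decreasing in V when `koff_o >= koff_c`, reproducing
#' the loss of affinity on depolarization.
#'
#' @param m a [state_model()] object.
#' @param V membrane voltage, mV.
#' @return A [rate_constants()] object holding the apparent rates at V.
#' @export
state_dependent_rates <- function(m, V) {
  stopifnot(inherits(m, "state_model"),
            is.numeric(V), length(V) == 1L, is.finite(V))
  po <- boltzmann_conductance(V, m$gv)
  rate_constants(kon = m$kon, koff = (1 - po) * m$koff_c + po * m$koff_o)
}

#' Occupancy distribution for two cooperatively coupled sites
#'
#' Sequential binding of up to two toxins to a symmetric dimeric
#' channel, in the intrinsic-site convention: each empty site binds
#' with intrinsic dissociation constant `kd1`, and occupancy of one
#' site changes the intrinsic constant of the other to `kd1 / c`.
#' Statistical weights are `1 : 2*C/kd1 : c*(C/kd1)^2` for 0, 1 and 2
#' bound (the factor 2 counts the two equivalent singly bound
#' configurations), so at `c = 1` the sites are independent and the
#' binomial identity `P1^2 = 4*P0*P2` holds at every concentration.
#'
#' @param C free toxin concentration(s), mol/L; >= 0.  Vectorized.
#' @param p a [two_site_params()] object.
#' @return A data frame with columns `C`, `p0`, `p1`, `p2` summing to 1.
#' @export
two_site_occupancy <- function(C, p) {
  stopifnot(inherits(p, "two_site_params"), is.numeric(C))
  if (any(!is.finite(C)) || any(C < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  x <- C / p$kd1
  w0 <- rep(1, length(x))
  w1 <- 2 * x
  w2 <- p$c * x^2
  z <- w0 + w1 + w2
  data.frame(C = C, p0 = w0 / z, p1 = w1 / z, p2 = w2 / z)
}

#' Bound fraction from the mole-fraction partition coefficient
#'
#' Inverts the mole-fraction partition relation
#' `Kp = [Fp/(1-Fp)] * [W]/[L]` to give the fraction of peptide in the
#' membrane at lipid concentration L:
#' `Fp = Kp*L / (W + Kp*L)`.  Monotone increasing in both Kp and L.
#'
#' @param Kp mole-fraction partition coefficient, dimensionless; >= 0.
#' @param L accessible lipid concentration(s), mol/L; >= 0.  Vectorized.
#' @param constants a [binding_constants()] object (supplies `W`).
#' @return Bound fraction(s) in \[0, 1).
#' @examples
#' partition_fraction(3.2e5, 15e-3)  # ~0.99 at 15 mM lipid
#' @export
partition_fraction <- function(Kp, L, constants = binding_constants()) {
  stopifnot(is.numeric(Kp), length(Kp) == 1L, is.finite(Kp),
            inherits(constants, "binding_constants"), is.numeric(L))
  if (Kp < 0) stop("Kp must be >= 0", call. = FALSE)
  if (any(!is.finite(L)) || any(L < 0)) {
    stop("lipid concentrations must be finite and >= 0", call. = FALSE)
  }
  Kp * L / (constants$W + Kp * L)
}

#' Partition coefficient from a single depletion point
#'
#' Closed-form mole-fraction partition coefficient from one titration
#' point: `Kp = [Fp/(1-Fp)] * [W]/[L]`.
#'
#' @param Fp bound fraction in \[0, 1).
#' @param L lipid concentration, mol/L; > 0.
#' @param constants a [binding_constants()] object.
#' @return Kp, dimensionless.
#' @export
kp_from_point <- function(Fp, L, constants = binding_constants()) {
  stopifnot(is.numeric(Fp), length(Fp) == 1L, is.finite(Fp),
            is.numeric(L), length(L) == 1L, is.finite(L),
            inherits(constants, "binding_constants"))
  if (Fp < 0 || Fp >= 1) stop("Fp must be in [0, 1)", call. = FALSE)
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  (Fp / (1 - Fp)) * constants$W / L
}
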