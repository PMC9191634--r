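# Parameter containers for the forward binding models.  All
# concentrations are molar internally; unit conversion happens only in
# the I/O layer (see read_experiment_table).

#' Hill dose-response parameters
#'
#' Parameters of the (generalized) Hill model of equilibrium block,
#' `F_un(C) = 1 - fmax * C^h / (Ki^h + C^h)`.  With `fmax = 1` this is
#' the literal two-parameter Hill relation for the fraction of
#' unblocked current; `fmax < 1` describes partial maximal block, as
#' seen for state-dependent blockers at depolarized potentials.
#'
#' @param ki inhibition constant, mol/L; > 0.
#' @param h Hill coefficient, dimensionless; > 0.
#' @param fmax maximal blockable fraction in (0, 1]; default 1.
#' @return An object of class `hill_params`.
#' @examples
#' hill_params(ki = 31e-9, h = 0.48)
#' @export
hill_params <- function(ki, h, fmax = 1) {
  stopifnot(is.numeric(ki), length(ki) == 1L, is.finite(ki),
            is.numeric(h), length(h) == 1L, is.finite(h),
            is.numeric(fmax), length(fmax) == 1L, is.finite(fmax))
  if (ki <= 0) stop("ki must be > 0 (mol/L)", call. = FALSE)
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  if (fmax <= 0 || fmax > 1) stop("fmax must be in (0, 1]", call. = FALSE)
  structure(list(ki = ki, h = h, fmax = fmax), class = "hill_params")
}

#' Boltzmann conductance-voltage parameters
#'
#' Midpoint and slope factor of the Boltzmann activation curve
#' `G/Gmax = 1 / (1 + exp(-(V - Vhalf)/slope))`.  A positive slope
#' means activation by depolarization.
#'
#' @param vhalf half-activation voltage, mV.
#' @param slope slope factor, mV; non-zero.
#' @return An object of class `gv_params`.
#' @export
gv_params <- function(vhalf, slope) {
  stopifnot(is.numeric(vhalf), length(vhalf) == 1L, is.finite(vhalf),
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope == 0) stop("slope must be non-zero (mV)", call. = FALSE)
  structure(list(vhalf = vhalf, slope = slope), class = "gv_params")
}

#' Bimolecular rate constants
#'
#' @param kon association rate constant, M^-1 s^-1; >= 0.
#' @param koff dissociation rate constant, s^-1; >= 0.
#' @return An object of class `rate_constants`.
#' @examples
#' rate_constants(kon = 3e5, koff = 0.022)
#' @export
rate_constants <- function(kon, koff) {
  stopifnot(is.numeric(kon), length(kon) == 1L, is.finite(kon),
            is.numeric(koff), length(koff) == 1L, is.finite(koff))
  if (kon < 0) stop("kon must be >= 0", call. = FALSE)
  if (koff < 0) stop("koff must be >= 0", call. = FALSE)
  structure(list(kon = kon, koff = koff), class = "rate_constants")
}

#' Two-site cooperative binding parameters
#'
#' Intrinsic-site parameterization of sequential binding of two ligands
#' to a symmetric dimer: `kd1` is the intrinsic dissociation constant
#' of the first binding event and `c` the fold improvement in intrinsic
#' affinity of the second event (`c > 1` = positive cooperativity,
#' `c < 1` = negative).
#'
#' @param kd1 intrinsic dissociation constant of the first binding
#'   event, mol/L; > 0.
#' @param c cooperativity factor, dimensionless; > 0.
#' @return An object of class `two_site_params`.
#' @export
two_site_params <- function(kd1, c = 1) {
  stopifnot(is.numeric(kd1), length(kd1) == 1L, is.finite(kd1),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (kd1 <= 0) stop("kd1 must be > 0 (mol/L)", call. = FALSE)
  if (c <= 0) stop("c must be > 0", call. = FALSE)
  structure(list(kd1 = kd1, c = c), class = "two_site_params")
}

#' State-dependent block model
#'
#' A two-state (closed/open) gating scheme coupled to state-specific
#' toxin dissociation.  Channel opening follows a Boltzmann curve in
#' voltage; the apparent off-rate at voltage V is the open-probability
#' weighted mixture of the closed- and open-state off-rates, while the
#' association rate is voltage independent (the empirical behaviour of
#' gating-modifier peptides on the proton channel).  The closed-state
#' inhibition constant is linked, `Kc = koff_c / kon`, never free.
#'
#' @param gv a [gv_params()] object describing the gating equilibrium.
#' @param koff_c closed-state dissociation rate, s^-1.
#' @param koff_o open-state dissociation rate, s^-1; must be >=
#'   `koff_c` (depolarization accelerates dissociation).
#' @param kon state-independent association rate, M^-1 s^-1; > 0.
#' @return An object of class `state_model` with the derived
#'   closed-state inhibition constant `kc` (mol/L).
#' @examples
#' m <- state_model(gv_params(20, 10), koff_c = 0.0015, koff_o = 0.03,
#'                  kon = 3e5)
#' state_dependent_rates(m, 40)
#' @export
state_model <- function(gv, koff_c, koff_o, kon) {
  stopifnot(inherits(gv, "gv_params"),
            is.numeric(koff_c), length(koff_c) == 1L, is.finite(koff_c),
            is.numeric(koff_o), length(koff_o) == 1L, is.finite(koff_o),
            is.numeric(kon), length(kon) == 1L, is.finite(kon))
  if (koff_c < 0 || koff_o < 0) stop("off-rates must be >= 0", call. = FALSE)
  if (koff_o < koff_c) {
    stop("koff_o must be >= koff_c: depolarization accelerates dissociation",
         call. = FALSE)
  }
  if (kon <= 0) stop("kon must be > 0", call. = FALSE)
  structure(
    list(gv = gv, koff_c = koff_c, koff_o = koff_o, kon = kon,
         kc = koff_c / kon),
    class = "state_model"
  )
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: Ki = %.4g M, h = %.3g, fmax = %.3g\n",
              x$ki, x$h, x$fmax))
  invisible(x)
}

#' @export
print.gv_params <- function(x, ...) {
  cat(sprintf("Boltzmann G-V: Vhalf = %.4g mV, slope = %.4g mV\n",
              x$vhalf, x$slope))
  invisible(x)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("rates: kon = %.4g /M/s, koff = %.4g /s (Ki = koff/kon = %.4g M)\n",
              x$kon, x$koff, if (x$kon > 0) x$koff / x$kon else NA_real_))
  invisible(x)
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state model: koff_c = %.4g /s, koff_o = %.4g /s, kon = %.4g /M/s, Kc = %.4g M\n",
              x$koff_c, x$koff_o, x$kon, x$kc))
  print(x$gv)
  invisible(x)
}
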