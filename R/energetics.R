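# Mutational energetics: Ki ratios from single-dose block fractions,
# free-energy changes, scan classification, and thermodynamic
# double-mutant-cycle coupling.
#
# Sign convention: ddG > 0 means weakened binding (loss of
# inhibition); enhancing mutants carry negative ddG.

#' Ki ratio from single-dose block fractions
#'
#' For two constructs measured at the same dose with a shared Hill
#' coefficient, the Hill model gives the inhibition-constant ratio in
#' closed form from the two equilibrium unblocked fractions:
#' `Ki_mut/Ki_ref = [ (1-Fun_ref) * Fun_mut / ((1-Fun_mut) * Fun_ref) ]^(1/h)`.
#' This is exactly consistent with the Hill relation: fractions
#' generated from (Ki, h) and (r*Ki, h) at any common dose return r.
#'
#' @param fun_ref fraction unblocked for the reference construct,
#'   strictly inside (0, 1).  Vectorized with `fun_mut`.
#' @param fun_mut fraction unblocked for the variant, strictly inside
#'   (0, 1).
#' @param h_ref Hill coefficient of the reference construct at the
#'   measurement voltage; > 0.  The reference h is used for every
#'   variant, never a per-variant h.
#' @return Ki ratio(s), dimensionless; 1 when `fun_mut == fun_ref`.
#' @examples
#' ki_ratio_from_block(0.35, 0.77, 0.48)  # ~45-fold weakened
#' @export
ki_ratio_from_block <- function(fun_ref, fun_mut, h_ref) {
  stopifnot(is.numeric(fun_ref), is.numeric(fun_mut),
            is.numeric(h_ref), length(h_ref) == 1L, is.finite(h_ref))
  if (h_ref <= 0) stop("h_ref must be > 0", call. = FALSE)
  vals <- c(fun_ref, fun_mut)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("unblocked fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(vals == 0) || any(vals == 1)) {
    stop("Ki ratio undefined at complete block or zero block (fraction 0 or 1)",
         call. = FALSE)
  }
  (((1 - fun_ref) * fun_mut) / ((1 - fun_mut) * fun_ref))^(1 / h_ref)
}

#' Free-energy change from a Ki ratio
#'
#' `ddG = RT * ln(Ki_mut/Ki_ref)` in kcal/mol; positive for weakened
#' binding, negative for enhanced.  Log-additive:
#' `ddg(a*b) = ddg(a) + ddg(b)`.
#'
#' @param ratio Ki ratio(s); > 0.  Vectorized.
#' @param constants a [binding_constants()] object.
#' @return ddG in kcal/mol.
#' @examples
#' ddg_from_ratio(45)        # ~2.26 kcal/mol at 298.15 K
#' ddg_from_ratio(1.9 / 31)  # enhanced binding, ~-1.65 kcal/mol
#' @export
ddg_from_ratio <- function(ratio, constants = binding_constants()) {
  stopifnot(is.numeric(ratio), inherits(constants, "binding_constants"))
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("Ki ratio must be finite and > 0", call. = FALSE)
  }
  rt_kcal(constants) * log(ratio)
}

#' Classify a single-dose mutational scan by binding energetics
#'
#' Converts per-variant unblocked fractions (all measured at one dose,
#' against one reference construct) into Ki ratios and ddG values, then
#' partitions the panel: `critical` when ddG exceeds the cutoff
#' (default 2 kcal/mol, the consensus threshold for energetically
#' engaged interface residues), `enhancing` when inhibition improves
#' more than `enhancing_fold` (default 4), `neutral` otherwise.
#' Variants whose fractions sit on the measurement bounds cannot be
#' converted and are returned as flagged rows rather than aborting the
#' scan; an optional clamp pulls such values inside by `clamp_eps`.
#'
#' @param scan data frame with columns `variant` and
#'   `fraction_unblocked`.
#' @param fun_ref unblocked fraction of the reference construct at the
#'   same dose.
#' @param h_ref Hill coefficient of the reference construct.
#' @param threshold ddG cutoff for `critical`, kcal/mol.
#' @param enhancing_fold fold improvement in Ki below which a variant
#'   is `enhancing`.
#' @param constants a [binding_constants()] object.
#' @param clamp if `TRUE`, fractions equal to 0 or 1 are pulled inside
#'   the unit interval by `clamp_eps` instead of being flagged.
#' @param clamp_eps clamp margin; default 0.005.
#' @return Data frame with columns `variant`, `fraction_unblocked`,
#'   `ki_ratio`, `ddg_kcal_mol`, `class`
#'   (critical/enhancing/neutral/NA), `note`; sorted by |ddG|
#'   descending, flagged rows last.
#' @export
classify_scan <- function(scan, fun_ref, h_ref, threshold = 2,
                          enhancing_fold = 4,
                          constants = binding_constants(),
                          clamp = FALSE, clamp_eps = 0.005) {
  stopifnot(is.data.frame(scan),
            all(c("variant", "fraction_unblocked") %in% names(scan)),
            is.numeric(fun_ref), length(fun_ref) == 1L,
            is.numeric(h_ref), length(h_ref) == 1L, h_ref > 0,
            threshold > 0, enhancing_fold > 1)
  if (!is.finite(fun_ref) || fun_ref <= 0 || fun_ref >= 1) {
    stop("fun_ref must lie strictly inside (0, 1)", call. = FALSE)
  }
  fun <- scan$fraction_unblocked
  note <- character(nrow(scan))
  if (clamp) fun <- pmin(pmax(fun, clamp_eps), 1 - clamp_eps)
  ok <- is.finite(fun) & fun > 0 & fun < 1
  note[!ok] <- "fraction at measurement bound; Ki ratio undefined"

  ratio <- rep(NA_real_, nrow(scan))
  ratio[ok] <- ki_ratio_from_block(fun_ref, fun[ok], h_ref)
  ddg <- rep(NA_real_, nrow(scan))
  ddg[ok] <- ddg_from_ratio(ratio[ok], constants)

  cls <- rep(NA_character_, nrow(scan))
  cls[ok] <- "neutral"
  cls[ok & ddg > threshold] <- "critical"
  cls[ok & ratio < 1 / enhancing_fold] <- "enhancing"

  out <- data.frame(variant = scan$variant, fraction_unblocked = fun,
                    ki_ratio = ratio, ddg_kcal_mol = ddg, class = cls,
                    note = note, stringsAsFactors = FALSE)
  out[order(!ok, -abs(ifelse(is.na(ddg), -Inf, ddg))), , drop = FALSE]
}

#' Thermodynamic double-mutant-cycle coupling
#'
#' For the four inhibition constants of a toxin-variant x
#' channel-mutant square, the coupling coefficient is
#' `Omega = (Ki_ref_ref * Ki_var_mut) / (Ki_ref_mut * Ki_var_ref)` and
#' the coupling energy `ddG = RT * ln(Omega)`.  Additive (independent)
#' energetics give Omega = 1 and ddG = 0 regardless of the size of the
#' single-mutation effects.  The coupling is symmetric under exchange
#' of the toxin and channel axes and negates when the reference/mutant
#' labels of one axis are swapped.
#'
#' @param ki_ref_ref Ki of reference toxin on reference channel, mol/L.
#' @param ki_ref_mut Ki of reference toxin on mutant channel, mol/L.
#' @param ki_var_ref Ki of toxin variant on reference channel, mol/L.
#' @param ki_var_mut Ki of toxin variant on mutant channel, mol/L.
#' @param constants a [binding_constants()] object.
#' @return A list with `omega` and `ddg_kcal_mol`.
#' @examples
#' mutant_cycle(1e-9, 10e-9, 10e-9, 1000e-9)  # Omega = 10
#' @export
mutant_cycle <- function(ki_ref_ref, ki_ref_mut, ki_var_ref, ki_var_mut,
                         constants = binding_constants()) {
  ki <- c(ki_ref_ref, ki_ref_mut, ki_var_ref, ki_var_mut)
  if (!is.numeric(ki) || length(ki) != 4L || any(!is.finite(ki)) ||
      any(ki <= 0)) {
    stop("all four Ki values must be finite and > 0 (mol/L)", call. = FALSE)
  }
  omega <- (ki_ref_ref * ki_var_mut) / (ki_ref_mut * ki_var_ref)
  list(omega = omega, ddg_kcal_mol = ddg_from_ratio(omega, constants))
}

#' Mutant-cycle coupling from a cycle table
#'
#' Convenience wrapper running [mutant_cycle()] on a validated cycle
#' table (one row per toxin/channel corner, columns `toxin`, `channel`,
#' `ki_M`) in which the reference constructs are identified by label.
#'
#' @param cycle data frame with columns `toxin`, `channel`, `ki_M`
#'   covering all four combinations of reference and mutant labels.
#' @param ref_toxin,ref_channel labels of the reference toxin and
#'   channel; default `"WT"`.
#' @param constants a [binding_constants()] object.
#' @return As [mutant_cycle()], plus the corner labels.
#' @export
mutant_cycle_from_table <- function(cycle, ref_toxin = "WT",
                                    ref_channel = "WT",
                                    constants = binding_constants()) {
  stopifnot(is.data.frame(cycle),
            all(c("toxin", "channel", "ki_M") %in% names(cycle)))
  toxins <- unique(cycle$toxin)
  channels <- unique(cycle$channel)
  if (length(toxins) != 2L || length(channels) != 2L) {
    stop("cycle table must contain exactly two toxins and two channels",
         call. = FALSE)
  }
  if (!(ref_toxin %in% toxins) || !(ref_channel %in% channels)) {
    stop("reference toxin/channel label not present in the cycle table",
         call. = FALSE)
  }
  var_toxin <- setdiff(toxins, ref_toxin)
  mut_channel <- setdiff(channels, ref_channel)
  corner <- function(tx, ch) {
    i <- which(cycle$toxin == tx & cycle$channel == ch)
    if (length(i) != 1L) {
      stop(sprintf("cycle table needs exactly one row for (%s, %s)", tx, ch),
           call. = FALSE)
    }
    cycle$ki_M[i]
  }
  res <- mutant_cycle(corner(ref_toxin, ref_channel),
                      corner(ref_toxin, mut_channel),
                      corner(var_toxin, ref_channel),
                      corner(var_toxin, mut_channel),
                      constants)
  c(res, list(toxin_variant = var_toxin, channel_mutant = mut_channel))
}
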