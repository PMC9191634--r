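#' Physical constants for binding energetics
#'
#' Bundles the gas constant, the working temperature and the molar
#' concentration of water used throughout the energetics and partition
#' calculations.  The temperature is configurable; the gas constant and
#' water molarity are fixed conventions of the analysis (55.3 mol/L for
#' water, as used in mole-fraction partition coefficients).
#'
#' @param temperature_K temperature in Kelvin; must be positive.
#'   Defaults to 298.15 K (25 C), giving RT = 0.5925 kcal/mol.
#' @param water_M molar concentration of water, mol/L.  Override only
#'   for non-aqueous conventions.
#'
#' @return An object of class `binding_constants` with fields `R`
#'   (kcal mol^-1 K^-1), `T` (K) and `W` (mol/L).
#' @examples
#' k <- binding_constants()
#' rt_kcal(k)   # 0.5925 kcal/mol at 298.15 K
#' @export
binding_constants <- function(temperature_K = 298.15, water_M = 55.3) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.finite(temperature_K))
  if (temperature_K <= 0) {
    stop("temperature_K must be > 0 (Kelvin)", call. = FALSE)
  }
  stopifnot(is.numeric(water_M), length(water_M) == 1L, water_M > 0)
  structure(
    list(R = 0.0019872, T = temperature_K, W = water_M),
    class = "binding_constants"
  )
}

#' Thermal energy RT in kcal/mol
#'
#' @param constants a [binding_constants()] object.
#' @return RT in kcal/mol.
#' @export
rt_kcal <- function(constants = binding_constants()) {
  stopifnot(inherits(constants, "binding_constants"))
  constants$R * constants$T
}

#' @export
print.binding_constants <- function(x, ...) {
  cat(sprintf("binding constants: R = %.7g kcal/(mol K), T = %.4g K, RT = %.4f kcal/mol, [W] = %.3g M\n",
              x$R, x$T, rt_kcal(x), x$W))
  invisible(x)
}
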