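# Parameter estimation: Levenberg-Marquardt least squares for
# dose-response, G-V, exponential kinetics and partition titrations,
# plus closed-form rate extraction from relaxation time constants.
#
# All fitters are deterministic: fixed multi-start grids, no internal
# randomness.  Convergence tolerance is 1e-10 on the relative RSS
# change with at most 1e4 function evaluations; non-convergence is
# reported in the result, never silently accepted.

.lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                             maxfev = 10000, maxiter = 1024)
}

# Run nls.lm over a fixed start grid; keep the best RSS.  `tie_break`
# orders equally good solutions (e.g. smallest Hill slope first).
.lm_multistart <- function(residual, starts, lower, upper,
                           tie_break = NULL) {
  best <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = residual,
                         lower = lower, upper = upper,
                         control = .lm_control()),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best)) {
      best <- fit
      next
    }
    best_rss <- sum(best$fvec^2)
    tol <- 1e-9 * (1 + best_rss)
    if (rss < best_rss - tol) {
      best <- fit
    } else if (abs(rss - best_rss) <= tol && !is.null(tie_break) &&
               tie_break(fit$par) < tie_break(best$par)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  best
}

# Jacobian-based standard errors at the optimum; NA (plus a flag) when
# the approximate Hessian is singular.
.lm_se <- function(fit, n, p) {
  rss <- sum(fit$fvec^2)
  dof <- n - p
  se <- rep(NA_real_, p)
  singular <- TRUE
  if (dof > 0) {
    cov <- tryCatch(solve(fit$hessian) * rss / dof, error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      if (all(is.finite(d)) && all(d >= 0)) {
        se <- sqrt(d)
        singular <- FALSE
      }
    }
  }
  list(se = se, singular = singular)
}

.fit_result <- function(model, params, se, rss, n, converged,
                        flags = character()) {
  structure(
    list(model = model, params = params, se = se, rss = rss, n = n,
         converged = converged, flags = flags),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (n = %d, rss = %.4g, converged = %s)\n",
              x$model, x$n, x$rss, x$converged))
  for (nm in names(x$params)) {
    se <- x$se[[nm]]
    cat(sprintf("  %-6s %.6g%s\n", nm, x$params[[nm]],
                if (is.finite(se)) sprintf(" +/- %.3g", se) else ""))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.check_df <- function(data, cols, what) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop(sprintf("%s needs columns: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in cols) {
    if (!is.numeric(data[[col]]) || any(!is.finite(data[[col]]))) {
      stop(sprintf("column '%s' must be finite numeric", col), call. = FALSE)
    }
  }
  invisible(data)
}

.fit_weights <- function(data, weights) {
  if (weights == "none" || is.null(data$sem)) return(rep(1, nrow(data)))
  sem <- data$sem
  if (any(!is.finite(sem)) || any(sem <= 0)) {
    stop("inverse-variance weighting needs positive finite sem values",
         call. = FALSE)
  }
  1 / sem
}

#' Fit the Hill dose-response model
#'
#' Least-squares estimation of the inhibition constant and Hill
#' coefficient (and optionally the maximal blockable fraction) from
#' equilibrium fraction-unblocked measurements.  Initialization takes
#' Ki from the dose whose observed block is nearest half the maximal
#' observed block; a fixed 3x3 multi-start grid over
#' (Ki0/10, Ki0, 10 Ki0) x (h0 in 0.5, 1, 2) guards against local
#' minima at extreme Hill slopes, with RSS ties broken toward the
#' smallest h.
#'
#' @param data data frame with numeric columns `conc` (mol/L) and
#'   `fraction_unblocked`; an optional `sem` column enables
#'   inverse-variance weighting.
#' @param fix_fmax if `TRUE` (default) the maximal blockable fraction
#'   is fixed at 1 (the literal two-parameter Hill relation); if
#'   `FALSE`, fmax in (0, 1\] is estimated as a third parameter.
#' @param weights `"none"` (default) or `"inverse_variance"` (requires
#'   a `sem` column).
#' @return A `fit_result` whose `params` hold `ki` (mol/L), `h` and
#'   `fmax`; standard errors are Jacobian-based (delta method for `ki`,
#'   which is fitted on the log scale).
#' @examples
#' d <- gen_dose_response(hill_params(31e-9, 0.48),
#'                        doses = 10^seq(-9, -6, length.out = 8),
#'                        noise = noise_spec(sd = 0, seed = 1))
#' fit_hill(d)
#' @export
fit_hill <- function(data, fix_fmax = TRUE,
                     weights = c("none", "inverse_variance")) {
  weights <- match.arg(weights)
  .check_df(data, c("conc", "fraction_unblocked"), "fit_hill")
  C <- data$conc
  y <- data$fraction_unblocked
  if (any(C < 0)) stop("concentrations must be >= 0", call. = FALSE)
  n_par <- if (fix_fmax) 2L else 3L
  if (length(unique(C[C > 0])) < n_par + 1L) {
    stop(sprintf("under-determined design: need >= %d distinct non-zero doses",
                 n_par + 1L), call. = FALSE)
  }
  block <- 1 - y
  max_block <- max(block)
  if (max_block < 0.02) {
    stop("no detectable block in the data: cannot fit an inhibition constant",
         call. = FALSE)
  }
  w <- .fit_weights(data, weights)

  ki0 <- C[C > 0][which.min(abs(block[C > 0] - max_block / 2))]
  fmax0 <- min(max(max_block, 0.05), 1)
  starts <- list()
  for (f_ki in c(0.1, 1, 10)) {
    for (h0 in c(0.5, 1, 2)) {
      par <- c(lki = log(ki0 * f_ki), h = h0)
      if (!fix_fmax) par <- c(par, fmax = fmax0)
      starts[[length(starts) + 1L]] <- par
    }
  }
  lower <- c(-Inf, 0.05)
  upper <- c(Inf, 5)
  if (!fix_fmax) {
    lower <- c(lower, 1e-3)
    upper <- c(upper, 1)
  }
  residual <- function(par) {
    p <- hill_params(ki = exp(par[["lki"]]), h = par[["h"]],
                     fmax = if (fix_fmax) 1 else par[["fmax"]])
    w * (fraction_unblocked(C, p) - y)
  }
  fit <- .lm_multistart(residual, starts, lower, upper,
                        tie_break = function(par) par[["h"]])
  ki_hat <- exp(fit$par[["lki"]])
  se <- .lm_se(fit, length(y), n_par)
  params <- list(ki = ki_hat, h = fit$par[["h"]],
                 fmax = if (fix_fmax) 1 else fit$par[["fmax"]])
  se_list <- list(ki = ki_hat * se$se[1], h = se$se[2],
                  fmax = if (fix_fmax) NA_real_ else se$se[3])
  .fit_result("hill", params, se_list, sum(fit$fvec^2), length(y),
              converged = fit$info %in% 1:4,
              flags = if (se$singular) "singular_covariance" else character())
}

#' Fit the Boltzmann conductance-voltage curve
#'
#' Estimates the half-activation voltage and slope factor from
#' normalized conductance measurements.  The sign of the slope is taken
#' from the data (correlation of conductance with voltage); flat data
#' without a resolvable transition are rejected.
#'
#' @param data data frame with numeric columns `voltage_mV` and
#'   `g_norm` (normalized conductance); optional `sem` for weighting.
#' @param weights `"none"` or `"inverse_variance"`.
#' @return A `fit_result` with `vhalf` (mV) and `slope` (mV).
#' @export
fit_boltzmann <- function(data, weights = c("none", "inverse_variance")) {
  weights <- match.arg(weights)
  .check_df(data, c("voltage_mV", "g_norm"), "fit_boltzmann")
  V <- data$voltage_mV
  g <- data$g_norm
  if (length(unique(V)) < 3L) {
    stop("need >= 3 distinct voltages", call. = FALSE)
  }
  if (diff(range(g)) < 0.1) {
    stop("no resolvable activation transition: conductance range < 0.1",
         call. = FALSE)
  }
  w <- .fit_weights(data, weights)
  sgn <- sign(stats::cor(V, g))
  if (!is.finite(sgn) || sgn == 0) {
    stop("conductance does not vary with voltage", call. = FALSE)
  }
  vhalf0 <- V[which.min(abs(g - (min(g) + max(g)) / 2))]
  slope0 <- max(diff(range(V)) / 6, 1)
  starts <- lapply(c(1 / 3, 1, 3), function(f) {
    c(vhalf = vhalf0, slope = sgn * slope0 * f)
  })
  bound <- c(1e-3, 1e3)
  lower <- c(-Inf, if (sgn > 0) bound[1] else -bound[2])
  upper <- c(Inf, if (sgn > 0) bound[2] else -bound[1])
  residual <- function(par) {
    gv <- gv_params(par[["vhalf"]], par[["slope"]])
    w * (boltzmann_conductance(V, gv) - g)
  }
  fit <- .lm_multistart(residual, starts, lower, upper)
  se <- .lm_se(fit, length(g), 2L)
  .fit_result("boltzmann",
              list(vhalf = fit$par[["vhalf"]], slope = fit$par[["slope"]]),
              list(vhalf = se$se[1], slope = se$se[2]),
              sum(fit$fvec^2), length(g),
              converged = fit$info %in% 1:4,
              flags = if (se$singular) "singular_covariance" else character())
}

#' Fit a single-exponential relaxation to a block/unblock time course
#'
#' Fits `y(t) = y_inf + (y0 - y_inf) * exp(-(t - t0)/tau)` to a
#' normalized current trace.  By default `y0` is pinned to the first
#' sample (traces are normalized to the pre-application current); set
#' `free_y0 = TRUE` to estimate it.  A trace that reverses direction
#' beyond what the residual noise supports is flagged `nonmonotone`
#' (but still fitted); a record shorter than the fitted time constant
#' is flagged `short_window`.
#'
#' @param trace data frame with numeric columns `t_s` (strictly
#'   increasing, seconds) and `i_norm`.
#' @param free_y0 estimate the initial level instead of pinning it.
#' @return A `fit_result` with `tau` (s), `y_inf` and `y0`.
#' @export
fit_exponential <- function(trace, free_y0 = FALSE) {
  .check_df(trace, c("t_s", "i_norm"), "fit_exponential")
  t <- trace$t_s
  y <- trace$i_norm
  if (length(t) < 5L) stop("need >= 5 time points", call. = FALSE)
  if (any(diff(t) <= 0)) stop("t_s must be strictly increasing", call. = FALSE)
  tt <- t - t[1]
  y00 <- y[1]
  yinf0 <- mean(y[max(1L, length(y) - 2L):length(y)])
  span <- yinf0 - y00
  if (abs(span) < 1e-12) span <- 1e-3 * sign(span + 1e-30)
  crossed <- which(abs(y - y00) >= 0.63 * abs(span))
  tau0 <- if (length(crossed)) max(tt[crossed[1]], diff(range(tt)) / 50)
          else diff(range(tt)) / 3
  n_par <- if (free_y0) 3L else 2L
  starts <- lapply(c(0.3, 1, 3), function(f) {
    par <- c(ltau = log(tau0 * f), y_inf = yinf0)
    if (free_y0) par <- c(par, y0 = y00)
    par
  })
  lower <- rep(-Inf, n_par)
  upper <- rep(Inf, n_par)
  residual <- function(par) {
    y0 <- if (free_y0) par[["y0"]] else y00
    par[["y_inf"]] + (y0 - par[["y_inf"]]) * exp(-tt / exp(par[["ltau"]])) - y
  }
  fit <- .lm_multistart(residual, starts, lower, upper)
  tau_hat <- exp(fit$par[["ltau"]])
  yinf_hat <- fit$par[["y_inf"]]
  y0_hat <- if (free_y0) fit$par[["y0"]] else y00
  se <- .lm_se(fit, length(y), n_par)

  flags <- character()
  if (se$singular) flags <- c(flags, "singular_covariance")
  if (diff(range(tt)) < tau_hat) flags <- c(flags, "short_window")
  # sustained movement against the relaxation direction, judged
  # against locally estimated noise (running-median detrend)
  dir <- sign(yinf_hat - y0_hat)
  z <- dir * y
  rebound <- max(cummax(z) - z)
  sigma <- stats::mad(y - stats::runmed(y, 5))
  amp <- abs(yinf_hat - y0_hat)
  if (rebound > max(6 * sigma, 0.2 * amp, 0.02)) {
    flags <- c(flags, "nonmonotone")
  }
  .fit_result("exponential",
              list(tau = tau_hat, y_inf = yinf_hat, y0 = y0_hat),
              list(tau = tau_hat * se$se[1], y_inf = se$se[2],
                   y0 = if (free_y0) se$se[3] else NA_real_),
              sum(fit$fvec^2), length(y),
              converged = fit$info %in% 1:4, flags = flags)
}

#' Rate constants from wash-in/washout time constants
#'
#' Inverts the bimolecular relaxation relations: `koff = 1/tau_off`,
#' `kon = (1/tau_on - koff)/C`.  Requires `tau_on <= tau_off`; a
#' wash-in slower than the washout is inconsistent with a bimolecular
#' binding scheme and is rejected.
#'
#' @param tau_on wash-in time constant, s; > 0.
#' @param tau_off washout time constant, s; > 0.
#' @param C toxin concentration during wash-in, mol/L; > 0.
#' @return A [rate_constants()] object.
#' @examples
#' rates_from_time_constants(10.31, 45.45, 250e-9)
#' @export
rates_from_time_constants <- function(tau_on, tau_off, C) {
  stopifnot(is.numeric(tau_on), length(tau_on) == 1L, is.finite(tau_on),
            is.numeric(tau_off), length(tau_off) == 1L, is.finite(tau_off),
            is.numeric(C), length(C) == 1L, is.finite(C))
  if (tau_on <= 0 || tau_off <= 0) stop("time constants must be > 0",
                                        call. = FALSE)
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  koff <- 1 / tau_off
  excess <- 1 / tau_on - koff
  if (excess < -1e-12 * koff) {
    stop("kinetics inconsistent with bimolecular scheme: tau_on > tau_off",
         call. = FALSE)
  }
  rate_constants(kon = max(excess, 0) / C, koff = koff)
}

#' Fit the mole-fraction partition coefficient to a depletion titration
#'
#' Least-squares fit of `Fp(L) = Kp*L / (W + Kp*L)` to bound-fraction
#' measurements over a lipid titration.  A single titration point is
#' solved in closed form via [kp_from_point()].
#'
#' @param data data frame with numeric columns `lipid_M` (mol/L) and
#'   `fraction_bound` in \[0, 1); optional `sem` for weighting.
#' @param constants a [binding_constants()] object (supplies `W`).
#' @param weights `"none"` or `"inverse_variance"`.
#' @return A `fit_result` with `kp` (dimensionless).
#' @export
fit_partition <- function(data, constants = binding_constants(),
                          weights = c("none", "inverse_variance")) {
  weights <- match.arg(weights)
  .check_df(data, c("lipid_M", "fraction_bound"), "fit_partition")
  L <- data$lipid_M
  Fp <- data$fraction_bound
  if (any(L < 0)) stop("lipid concentrations must be >= 0", call. = FALSE)
  if (any(Fp < 0 | Fp >= 1)) stop("fraction_bound must be in [0, 1)",
                                  call. = FALSE)
  usable <- L > 0
  if (!any(usable)) stop("need at least one non-zero lipid concentration",
                         call. = FALSE)
  if (max(Fp) <= 0) {
    stop("no detectable partitioning: all bound fractions are zero",
         call. = FALSE)
  }
  if (sum(usable) == 1L) {
    i <- which(usable)
    kp <- kp_from_point(Fp[i], L[i], constants)
    return(.fit_result("partition", list(kp = kp), list(kp = NA_real_),
                       rss = 0, n = nrow(data), converged = TRUE,
                       flags = "closed_form_single_point"))
  }
  w <- .fit_weights(data, weights)
  pos <- usable & Fp > 0
  kp0 <- stats::median(mapply(kp_from_point, Fp[pos], L[pos],
                              MoreArgs = list(constants = constants)))
  starts <- lapply(c(0.1, 1, 10), function(f) c(lkp = log(kp0 * f)))
  residual <- function(par) {
    w * (partition_fraction(exp(par[["lkp"]]), L, constants) - Fp)
  }
  fit <- .lm_multistart(residual, starts, lower = -Inf, upper = Inf)
  kp_hat <- exp(fit$par[["lkp"]])
  se <- .lm_se(fit, nrow(data), 1L)
  .fit_result("partition", list(kp = kp_hat), list(kp = kp_hat * se$se[1]),
              sum(fit$fvec^2), nrow(data),
              converged = fit$info %in% 1:4,
              flags = if (se$singular) "singular_covariance" else character())
}
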