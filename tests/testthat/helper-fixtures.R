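# Shared fixtures: Monte-Carlo recovery runners and the published
# per-condition blockade parameter table shipped with the package.

# Deterministic child seeds for replicate datasets.
mc_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(1e8L, n))
}

# Median fitted Ki/h over seeded replicate Hill fits.
mc_hill_recovery <- function(ki, h, doses, sd, n_rep, master_seed,
                             fix_fmax = TRUE) {
  p <- hill_params(ki = ki, h = h)
  seeds <- mc_seeds(master_seed, n_rep)
  fits <- vapply(seeds, function(s) {
    d <- gen_dose_response(p, doses, noise_spec(sd = sd, seed = s))
    f <- fit_hill(d, fix_fmax = fix_fmax)
    c(f$params$ki, f$params$h)
  }, numeric(2))
  list(ki = stats::median(fits[1, ]), h = stats::median(fits[2, ]))
}

# Median fitted Kp over seeded replicate partition fits.
mc_partition_recovery <- function(kp, L, sd, n_rep, master_seed) {
  seeds <- mc_seeds(master_seed, n_rep)
  kps <- vapply(seeds, function(s) {
    d <- gen_depletion(kp, L, noise_spec(sd = sd, seed = s,
                                         clip = c(0, 0.999)))
    fit_partition(data.frame(lipid_M = d$lipid_M,
                             fraction_bound = d$fraction_bound))$params$kp
  }, numeric(1))
  stats::median(kps)
}

# Published per-condition blockade parameters (Ki, h, kon, koff at the
# recorded voltages), unit-normalized to molar.
published_blockade_table <- function() {
  read_experiment_table(
    system.file("extdata", "blockade_parameters.csv", package = "hvblock"),
    "results")
}

# Pull one fold-change row out of a report by labels.
fold_value <- function(report, quantity, axis, numerator, denominator,
                       context_re = NULL) {
  fc <- report$fold_changes
  sel <- fc$quantity == quantity & fc$axis == axis &
    fc$numerator == numerator & fc$denominator == denominator
  if (!is.null(context_re)) sel <- sel & grepl(context_re, fc$context)
  stopifnot(sum(sel) == 1L)
  fc$fold[sel]
}
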