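# Synthetic generators: determinism, exact noise-free forward values,
# and recoverability of the ground truth by the matching estimator.

test_that("noise_spec demands a seed and generators are seed-deterministic", {
  expect_error(noise_spec(sd = 0.03), "seed is mandatory")
  p <- hill_params(31e-9, 0.48)
  doses <- 10^seq(-9, -6, length.out = 8)
  d1 <- gen_dose_response(p, doses, noise_spec(0.03, seed = 99))
  d2 <- gen_dose_response(p, doses, noise_spec(0.03, seed = 99))
  d3 <- gen_dose_response(p, doses, noise_spec(0.03, seed = 100))
  expect_identical(d1, d2)
  expect_false(identical(d1$fraction_unblocked, d3$fraction_unblocked))
  # serialized output is byte-stable under a fixed seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_experiment_table(d1, f1, "dose_response")
  write_experiment_table(d2, f2, "dose_response")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("noise-free generator output equals the forward model exactly", {
  p <- hill_params(31e-9, 0.48)
  doses <- 10^seq(-9, -6, length.out = 8)
  d <- gen_dose_response(p, doses, noise_spec(0, seed = 1))
  expect_identical(d$fraction_unblocked, fraction_unblocked(doses, p))

  dep <- gen_depletion(3.2e5, c(0.5, 1, 5) * 1e-3, noise_spec(0, seed = 1))
  expect_identical(dep$fraction_bound,
                   partition_fraction(3.2e5, c(0.5, 1, 5) * 1e-3))
})

test_that("gen_dose_response supports the picomolar bivalent-peptide
          design", {
  doses <- 10^seq(log10(0.01e-9), log10(100e-9), length.out = 8)
  d <- gen_dose_response(hill_params(631e-12, 1.01), doses,
                         noise_spec(0.03, seed = 3), replicates = 2)
  expect_equal(nrow(d), 16)
  f <- fit_hill(gen_dose_response(hill_params(631e-12, 1.01), doses,
                                  noise_spec(0, seed = 3)))
  expect_equal(f$params$ki, 631e-12, tolerance = 1e-6)
  expect_error(gen_dose_response(hill_params(1e-9, 1), numeric(0),
                                 noise_spec(0, seed = 1)), "empty")
})

test_that("gen_kinetic_traces produces relaxations consistent with the
          rate constants", {
  r <- rate_constants(3e5, 0.022)
  tr <- gen_kinetic_traces(r, 250e-9, noise_spec(0, seed = 1), dt = 0.5)
  truth <- attr(tr, "truth")
  expect_equal(truth$tau_on, 10.3, tolerance = 1e-2)
  expect_equal(truth$tau_off, 45.5, tolerance = 1e-2)
  f_on <- fit_exponential(tr$wash_in)
  f_off <- fit_exponential(tr$wash_out)
  expect_equal(f_on$params$tau, truth$tau_on, tolerance = 1e-6)
  expect_equal(f_off$params$tau, truth$tau_off, tolerance = 1e-6)
  # equilibrium block level consistent with Ki = koff/kon
  expect_equal(f_on$params$y_inf, truth$y_eq, tolerance = 1e-6)
  rec <- rates_from_time_constants(f_on$params$tau, f_off$params$tau, 250e-9)
  expect_equal(rec$kon, 3e5, tolerance = 1e-6)
  expect_equal(rec$koff, 0.022, tolerance = 1e-6)

  # bivalent-like slow washout
  tr2 <- gen_kinetic_traces(rate_constants(9e5, 7e-4), 10e-9,
                            noise_spec(0, seed = 1), dt = 20)
  expect_equal(attr(tr2, "truth")$tau_off, 1429, tolerance = 1e-3)
  expect_warning(
    gen_kinetic_traces(r, 250e-9, noise_spec(0, seed = 1),
                       duration = 1, dt = 0.1),
    "shorter than tau_on/5")
})

test_that("gen_state_experiment reproduces the voltage dependence of
          dissociation", {
  gv <- gv_params(35, 7)
  m <- state_model(gv, koff_c = 0.0015, koff_o = 0.04, kon = 3e5)
  b <- gen_state_experiment(m, voltages = c(0, 40),
                            doses = 10^seq(-9, -6, length.out = 6),
                            noise = noise_spec(0, seed = 2), dt = 2)
  truth <- b$truth
  ratio <- truth$per_voltage[[2]]$koff / truth$per_voltage[[1]]$koff
  expect_equal(ratio, 15, tolerance = 0.1)
  # downstream kinetic analysis recovers the fold change
  fits <- lapply(c("V+0", "V+40"), function(cond) {
    tr <- b$tables$traces
    f_on <- fit_exponential(tr[tr$condition == cond &
                                 tr$phase == "wash_in", ])
    f_off <- fit_exponential(tr[tr$condition == cond &
                                  tr$phase == "wash_out", ])
    rates_from_time_constants(f_on$params$tau, f_off$params$tau, 250e-9)
  })
  expect_equal(fits[[2]]$koff / fits[[1]]$koff, ratio, tolerance = 1e-4)

  # degenerate control: equal off-rates make block voltage independent
  m0 <- state_model(gv, koff_c = 0.002, koff_o = 0.002, kon = 3e5)
  b0 <- gen_state_experiment(m0, voltages = c(0, 40),
                             doses = 10^seq(-9, -6, length.out = 6),
                             noise = noise_spec(0, seed = 2), dt = 2)
  expect_equal(b0$truth$per_voltage[[1]]$ki, b0$truth$per_voltage[[2]]$ki)

  # open-state-favoring gating shift raises the apparent Ki at +40 mV
  m_shift <- state_model(gv_params(35 - 57, 7), koff_c = 0.0015,
                         koff_o = 0.04, kon = 3e5)
  expect_gt(ki_from_rates(state_dependent_rates(m_shift, 40)),
            ki_from_rates(state_dependent_rates(m, 40)))
})

test_that("gen_scan embeds the assigned free-energy perturbations", {
  ref <- hill_params(31e-9, 0.48)
  s <- gen_scan(c(crit = 2.5, neut = 0, enh = -1.0), ref, dose = 250e-9,
                noise = noise_spec(0.02, seed = 4))
  r <- classify_scan(s$scan, s$fun_ref, h_ref = 0.48)
  expect_equal(r$class[match(c("crit", "neut", "enh"), r$variant)],
               c("critical", "neutral", "enhancing"))

  # a 45-fold-weakened variant at 65% reference inhibition shows ~23%
  dose65 <- 31e-9 * (0.65 / 0.35)^(1 / 0.48)
  ddg45 <- ddg_from_ratio(45)
  s45 <- gen_scan(c(v = ddg45), ref, dose = dose65,
                  noise = noise_spec(0, seed = 1))
  expect_equal(s45$fun_ref, 0.35, tolerance = 1e-6)
  expect_equal(1 - s45$scan$fraction_unblocked, 0.23, tolerance = 1e-2)
})

test_that("gen_cycle builds squares whose analysis returns the
          constructed coupling exactly", {
  cyc0 <- gen_cycle(1.2, -0.5, coupling = 0)
  expect_equal(mutant_cycle_from_table(cyc0)$omega, 1, tolerance = 1e-12)
  cyc <- gen_cycle(2, 2, coupling = 2.7)
  expect_equal(mutant_cycle_from_table(cyc)$ddg_kcal_mol, 2.7,
               tolerance = 1e-9)
})

test_that("gen_depletion covers partitioning and non-partitioning
          controls", {
  L <- c(0.5, 1, 2, 5, 10, 15) * 1e-3
  d <- gen_depletion(3.2e5, L, noise_spec(0, seed = 5),
                     include_control = TRUE)
  ctl <- d[d$condition == "control_no_partition", ]
  expect_true(all(ctl$fraction_bound == 0))
  test_series <- d[d$condition == "synthetic", ]
  f <- fit_partition(data.frame(lipid_M = test_series$lipid_M,
                                fraction_bound = test_series$fraction_bound))
  expect_equal(f$params$kp, 3.2e5, tolerance = 1e-6)

  # zwitterionic-only-like membranes partition ~3000-fold less
  d_popc <- gen_depletion(1.1e2, L, noise_spec(0, seed = 6))
  f_popc <- fit_partition(data.frame(lipid_M = d_popc$lipid_M,
                                     fraction_bound = d_popc$fraction_bound))
  expect_equal(f$params$kp / f_popc$params$kp, 2.909e3, tolerance = 1e-3)
})
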