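# Workflow layer: CSV schemas with strict validation and unit
# normalization, run configuration, summary report, CLI driver.

test_that("experiment tables round-trip losslessly through read/write", {
  dir <- withr::local_tempdir()
  doses <- 10^seq(-9, -6, length.out = 6)
  d <- gen_dose_response(hill_params(31e-9, 0.48), doses,
                         noise_spec(0.02, seed = 8))
  p1 <- file.path(dir, "a.csv"); p2 <- file.path(dir, "b.csv")
  write_experiment_table(d, p1, "dose_response")
  r1 <- read_experiment_table(p1, "dose_response")
  write_experiment_table(r1, p2, "dose_response")
  r2 <- read_experiment_table(p2, "dose_response")
  expect_identical(r1, r2)
})

test_that("concentration units normalize to molar on read", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dr.csv")
  writeLines(c("condition,voltage_mV,conc,conc_unit,fraction_unblocked",
               "a,40,250,nM,0.55",
               "a,40,1,uM,0.35",
               "a,40,50,pM,0.98"), path)
  d <- read_experiment_table(path, "dose_response")
  expect_equal(d$conc, c(250e-9, 1e-6, 50e-12))
  expect_true(all(d$conc_unit == "M"))
})

test_that("validation itemizes missing columns, bad units, non-numeric
          cells and domain violations with row numbers", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")

  writeLines(c("condition,conc,conc_unit", "a,1,nM"), path)
  expect_error(read_experiment_table(path, "dose_response"),
               "missing required column")

  writeLines(c("condition,voltage_mV,conc,conc_unit,fraction_unblocked",
               "a,40,250,furlongs,0.5"), path)
  expect_error(read_experiment_table(path, "dose_response"),
               "unrecognized unit 'furlongs'")

  writeLines(c("condition,voltage_mV,conc,conc_unit,fraction_unblocked",
               "a,40,250,nM,0.5", "a,40,oops,nM,0.6"), path)
  expect_error(read_experiment_table(path, "dose_response"),
               "non-numeric cell at row 2")

  writeLines(c("toxin,channel,ki,ki_unit",
               "WT,WT,31,nM", "WT,Mut,0,nM",
               "Var,WT,10,nM", "Var,Mut,100,nM"), path)
  expect_error(read_experiment_table(path, "cycle"),
               "row 2: ki must be > 0")

  writeLines(c("condition,voltage_mV,conc,conc_unit,fraction_unblocked,extra",
               "a,40,250,nM,0.5,1"), path)
  expect_error(read_experiment_table(path, "dose_response"),
               "unknown column")
})

test_that("run configuration enforces schema version and rejects unknown
          keys", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  writeLines(c("schema_version: 1", "temperature_K: 300", "seed: 7",
               "options:", "  fix_fmax: false"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$temperature_K, 300)
  expect_false(cfg$options$fix_fmax)
  expect_equal(cfg$options$ddg_threshold, 2)   # default filled in

  writeLines(c("schema_version: 1", "typo_key: 3"), path)
  expect_error(read_run_config(path), "unknown config key.*typo_key")
  writeLines("schema_version: 2", path)
  expect_error(read_run_config(path), "schema_version must be 1")
})

test_that("build_report derives time constants and a complete
          fold-change block from published parameters", {
  tab <- published_blockade_table()
  rep <- build_report(tab)
  # washout time constant at +40 mV: 1/koff
  row40 <- rep$summary[rep$summary$peptide == "C6" &
                         rep$summary$channel == "hHv1" &
                         rep$summary$voltage_mV == 40, ]
  expect_equal(row40$tau_off_s, 1 / 0.022)
  expect_equal(row40$tau_on_s, 1 / (3e5 * 250e-9 + 0.022))
  expect_equal(row40$ki_kinetic_M, 0.022 / 3e5)

  expect_equal(fold_value(rep, "koff", "voltage", "+40 mV", "+0 mV",
                          context_re = "^C6 / hHv1$"),
               0.022 / 0.0015)
  expect_equal(fold_value(rep, "ki", "peptide", "C6", "C6_2",
                          context_re = "hHv1 at \\+40"),
               31 / 0.63)
})

test_that("build_report with a single condition yields a valid report
          with an empty fold block", {
  tab <- published_blockade_table()[3, ]
  rep <- build_report(tab)
  expect_s3_class(rep, "summary_report")
  expect_equal(nrow(rep$fold_changes), 0)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("summary.csv",
                                               "fold_changes.csv",
                                               "report.json",
                                               "report.txt")))))
})

test_that("the CLI simulate/fit pipeline is seed-deterministic and
          round-trips", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  expect_equal(hvblock_cli(c("simulate-dose", "--seed", "1", "--out", out1,
                             "-q")), 0L)
  expect_equal(hvblock_cli(c("simulate-dose", "--seed", "1", "--out", out2,
                             "-q")), 0L)
  same <- function(f) {
    identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }
  expect_true(same("dose_response.csv"))
  expect_true(same("truth.json"))
  expect_true(file.exists(file.path(out1, "run_manifest.json")))

  status <- hvblock_cli(c("fit-dose", "--input",
                          file.path(out1, "dose_response.csv"),
                          "--out", out1, "-q"))
  expect_equal(status, 0L)
  fit <- jsonlite::read_json(file.path(out1, "fit_dose.json"))
  expect_equal(fit$params$ki, 31e-9, tolerance = 0.5)
  expect_lt(abs(fit$comparison$ki_relative_error), 0.5)
})

test_that("the CLI covers kinetics, scan, cycle, depletion and report
          stages", {
  out <- withr::local_tempdir()
  q <- function(...) hvblock_cli(c(..., "--out", out, "-q"))
  expect_equal(q("simulate-kinetics", "--seed", "2"), 0L)
  expect_equal(q("fit-kinetics", "--input", file.path(out, "traces.csv")),
               0L)
  kin <- jsonlite::read_json(file.path(out, "fit_kinetics.json"))
  expect_equal(kin[[1]]$koff, 0.022, tolerance = 0.2)

  expect_equal(q("simulate-scan", "--seed", "3"), 0L)
  expect_equal(q("scan", "--input", file.path(out, "scan.csv")), 0L)
  expect_true(file.exists(file.path(out, "scan_report.csv")))

  expect_equal(q("simulate-cycle"), 0L)
  expect_equal(q("cycle", "--input", file.path(out, "cycle.csv")), 0L)
  cyc <- jsonlite::read_json(file.path(out, "cycle_report.json"))
  expect_equal(cyc$ddg_kcal_mol, 2.7, tolerance = 1e-6)

  expect_equal(q("simulate-depletion", "--seed", "4"), 0L)
  expect_equal(q("fit-partition", "--input", file.path(out, "depletion.csv")),
               0L)
  part <- jsonlite::read_json(file.path(out, "fit_partition.json"))
  expect_equal(part[[1]]$params$kp, 3.2e5, tolerance = 0.2)

  expect_equal(q("report", "--input",
                 system.file("extdata", "blockade_parameters.csv",
                             package = "hvblock")), 0L)
  expect_true(file.exists(file.path(out, "summary.csv")))
})

test_that("CLI failures exit non-zero with a machine-readable error code
          in the manifest", {
  out <- withr::local_tempdir()
  bad <- file.path(out, "bad.csv")
  writeLines(c("condition,conc", "a,1"), bad)
  status <- hvblock_cli(c("fit-dose", "--input", bad, "--out", out, "-q"))
  expect_equal(status, 1L)
  manifest <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_equal(manifest$status, "error")
  expect_equal(manifest$error_code, "validation_error")

  expect_equal(suppressMessages(hvblock_cli(c("no-such-command"))), 1L)
  expect_equal(suppressMessages(hvblock_cli(character())), 2L)
})
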