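# Tabular I/O: documented CSV schemas with explicit unit columns,
# strict validation (reject, never coerce), and lossless round trips
# on unit-normalized tables.  Concentrations are molar in memory; unit
# conversion happens here and only here.

.hv_validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("hv_validation_error", "error")))
}

.conc_unit_factors <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6,
                        nM = 1e-9, pM = 1e-12)

# Schema registry.  `numeric` columns are validated as finite numbers;
# `unit_for` maps a unit column to the value column it scales.
.table_schemas <- list(
  dose_response = list(
    required = c("condition", "voltage_mV", "conc", "conc_unit",
                 "fraction_unblocked"),
    optional = "sem",
    numeric = c("conc", "fraction_unblocked", "sem"),
    numeric_or_na = "voltage_mV",
    unit_for = c(conc_unit = "conc"),
    check = function(df) {
      bad <- which(df$fraction_unblocked < 0 | df$fraction_unblocked > 1)
      if (length(bad)) sprintf("row %d: fraction_unblocked outside [0, 1]", bad)
    }
  ),
  kinetic_trace = list(
    required = c("condition", "phase", "t_s", "i_norm", "conc", "conc_unit"),
    optional = character(),
    numeric = c("t_s", "i_norm", "conc"),
    unit_for = c(conc_unit = "conc"),
    check = function(df) {
      msgs <- character()
      bad <- which(!df$phase %in% c("wash_in", "wash_out"))
      if (length(bad)) {
        msgs <- c(msgs, sprintf("row %d: phase must be wash_in or wash_out",
                                bad))
      }
      for (key in split(seq_len(nrow(df)), paste(df$condition, df$phase))) {
        if (any(diff(df$t_s[key]) <= 0)) {
          msgs <- c(msgs, sprintf(
            "rows %d-%d: t_s must be strictly increasing within a trace",
            min(key), max(key)))
        }
      }
      msgs
    }
  ),
  gv = list(
    required = c("condition", "voltage_mV", "g_norm"),
    optional = "sem",
    numeric = c("voltage_mV", "g_norm", "sem"),
    unit_for = c(),
    check = function(df) {
      bad <- which(df$g_norm < -0.05 | df$g_norm > 1.05)
      if (length(bad)) sprintf("row %d: g_norm far outside [0, 1]", bad)
    }
  ),
  scan = list(
    required = c("variant", "fraction_unblocked"),
    optional = "sem",
    numeric = c("fraction_unblocked", "sem"),
    unit_for = c(),
    check = function(df) {
      bad <- which(df$fraction_unblocked < 0 | df$fraction_unblocked > 1)
      if (length(bad)) sprintf("row %d: fraction_unblocked outside [0, 1]", bad)
    }
  ),
  cycle = list(
    required = c("toxin", "channel", "ki", "ki_unit"),
    optional = character(),
    numeric = "ki",
    unit_for = c(ki_unit = "ki"),
    check = function(df) {
      bad <- which(df$ki <= 0)
      if (length(bad)) sprintf("row %d: ki must be > 0", bad)
    }
  ),
  depletion = list(
    required = c("condition", "lipid_conc", "lipid_unit", "fraction_bound"),
    optional = "sem",
    numeric = c("lipid_conc", "fraction_bound", "sem"),
    unit_for = c(lipid_unit = "lipid_conc"),
    check = function(df) {
      bad <- which(df$fraction_bound < 0 | df$fraction_bound >= 1)
      if (length(bad)) sprintf("row %d: fraction_bound outside [0, 1)", bad)
    }
  ),
  results = list(
    required = c("peptide", "channel", "voltage_mV", "ki", "ki_unit"),
    optional = c("h", "kon", "koff", "conc", "conc_unit"),
    numeric = "ki",
    numeric_or_na = c("voltage_mV", "h", "kon", "koff", "conc"),
    unit_for = c(ki_unit = "ki", conc_unit = "conc"),
    check = function(df) {
      bad <- which(df$ki <= 0)
      if (length(bad)) sprintf("row %d: ki must be > 0", bad)
    }
  )
)

#' Documented CSV schemas
#'
#' Names and column contracts of the tabular formats the pipeline
#' reads and writes.  Units are carried in explicit `*_unit` columns
#' (`M`, `mM`, `uM`, `nM`, `pM`), never in headers; on read, unit
#' columns are normalized to molar and rewritten as `"M"`.
#'
#' @return Named list of schema definitions (required columns, optional
#'   columns, numeric columns, unit-column mapping).
#' @export
table_schemas <- function() {
  lapply(.table_schemas, function(s) s[c("required", "optional", "numeric",
                                         "unit_for")])
}

.validate_table <- function(df, schema_name, where = "table") {
  schema <- .table_schemas[[schema_name]]
  if (is.null(schema)) {
    .hv_validation_error("unknown schema '", schema_name, "'; available: ",
                         paste(names(.table_schemas), collapse = ", "))
  }
  msgs <- character()
  missing <- setdiff(schema$required, names(df))
  if (length(missing)) {
    msgs <- c(msgs, paste0("missing required column(s): ",
                           paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(df), c(schema$required, schema$optional))
  if (length(unknown)) {
    msgs <- c(msgs, paste0("unknown column(s): ",
                           paste(unknown, collapse = ", ")))
  }
  if (length(msgs)) {
    .hv_validation_error(where, " does not match schema '", schema_name,
                         "': ", paste(msgs, collapse = "; "))
  }
  for (col in intersect(schema$numeric, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      # locate the offending cells for the error message
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      msgs <- c(msgs, sprintf("column '%s': non-numeric cell at row %s",
                              col, paste(utils::head(bad, 5), collapse = ", ")))
    } else if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))
      msgs <- c(msgs, sprintf("column '%s': missing/non-finite at row %s",
                              col, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  for (col in intersect(schema$numeric_or_na, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      msgs <- c(msgs, sprintf("column '%s': must be numeric (NA allowed)", col))
    }
  }
  for (ucol in names(schema$unit_for)) {
    if (!ucol %in% names(df)) next
    units <- as.character(df[[ucol]])
    bad <- which(!units %in% names(.conc_unit_factors) & !is.na(units))
    if (length(bad)) {
      msgs <- c(msgs, sprintf(
        "column '%s': unrecognized unit '%s' at row %s (allowed: %s)",
        ucol, units[bad[1]], paste(utils::head(bad, 5), collapse = ", "),
        paste(setdiff(names(.conc_unit_factors), "µM"), collapse = ", ")))
    }
  }
  if (length(msgs) == 0 && is.function(schema$check)) {
    msgs <- schema$check(df)
  }
  if (length(msgs)) {
    .hv_validation_error(where, " failed validation (schema '", schema_name,
                         "'): ", paste(msgs, collapse = "; "))
  }
  invisible(df)
}

.normalize_units <- function(df, schema_name) {
  schema <- .table_schemas[[schema_name]]
  for (ucol in names(schema$unit_for)) {
    vcol <- schema$unit_for[[ucol]]
    if (!ucol %in% names(df) || !vcol %in% names(df)) next
    keep <- !is.na(df[[vcol]])
    df[[vcol]][keep] <- df[[vcol]][keep] *
      .conc_unit_factors[as.character(df[[ucol]][keep])]
    df[[ucol]] <- "M"
  }
  df
}

#' Read a validated, unit-normalized experiment table
#'
#' Reads a CSV in one of the documented schemas, validates it
#' (missing columns, unknown columns, non-numeric cells, unknown
#' units, domain violations - each reported with row numbers), and
#' normalizes every concentration column to mol/L.  Validation rejects
#' rather than coerces; no NA ever reaches a fitter silently.
#'
#' @param path CSV file path.
#' @param schema one of `names(table_schemas())`.
#' @return The validated data frame, concentrations in molar.
#' @export
read_experiment_table <- function(path, schema) {
  if (!file.exists(path)) .hv_validation_error("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_table(df, schema, where = path)
  .normalize_units(df, schema)
}

#' Write an experiment table
#'
#' Validates against the schema, then writes comma-separated UTF-8
#' with a header row and '.' decimal.  `write` after `read` is
#' lossless: reading the written file returns the same normalized
#' table.
#'
#' @param df the table (already unit-normalized or with explicit unit
#'   columns).
#' @param path output CSV path.
#' @param schema one of `names(table_schemas())`.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(df, path, schema) {
  .validate_table(df, schema, where = "in-memory table")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a synthetic experiment bundle to disk
#'
#' Serializes the tables of a [gen_state_experiment()] bundle as CSVs
#' plus the ground-truth parameter record as a JSON sidecar
#' (`truth.json`), so generated data are always accompanied by the
#' parameters that produced them.
#'
#' @param bundle an `experiment_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_experiment_table(bundle$tables$dose_response,
                         file.path(dir, "dose_response.csv"), "dose_response")
  write_experiment_table(bundle$tables$traces,
                         file.path(dir, "traces.csv"), "kinetic_trace")
  write_experiment_table(bundle$tables$gv, file.path(dir, "gv.csv"), "gv")
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a run configuration
#'
#' Loads a YAML run configuration, checks the schema version, and
#' rejects unknown keys with a clear error.  Recognized top-level
#' keys: `schema_version` (must be 1), `temperature_K`, `inputs`
#' (named file paths), `options` (`fix_fmax`, `ddg_threshold`,
#' `enhancing_fold`, `coupling_threshold`, `h_ref`), `outdir`, `seed`,
#' `verbosity`.
#'
#' @param path YAML file path.
#' @return A `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .hv_validation_error("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("schema_version", "temperature_K", "inputs", "options",
             "outdir", "seed", "verbosity")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    .hv_validation_error("unknown config key(s): ",
                         paste(unknown, collapse = ", "),
                         " (known: ", paste(known, collapse = ", "), ")")
  }
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    .hv_validation_error("config schema_version must be 1")
  }
  opt_known <- c("fix_fmax", "ddg_threshold", "enhancing_fold",
                 "coupling_threshold", "h_ref")
  unknown_opt <- setdiff(names(cfg$options), opt_known)
  if (length(unknown_opt)) {
    .hv_validation_error("unknown option key(s): ",
                         paste(unknown_opt, collapse = ", "))
  }
  defaults <- list(fix_fmax = TRUE, ddg_threshold = 2, enhancing_fold = 4,
                   coupling_threshold = 1, h_ref = NULL)
  opts <- utils::modifyList(defaults, as.list(cfg$options))
  structure(
    list(schema_version = 1,
         temperature_K = if (is.null(cfg$temperature_K)) 298.15
                         else cfg$temperature_K,
         inputs = as.list(cfg$inputs),
         options = opts,
         outdir = if (is.null(cfg$outdir)) "." else cfg$outdir,
         seed = cfg$seed,
         verbosity = if (is.null(cfg$verbosity)) 1L else cfg$verbosity,
         path = path),
    class = "run_config"
  )
}

#' Write a run manifest
#'
#' Records provenance for a pipeline invocation: package version, R
#' version, seeds, config hash, argument vector, status and
#' machine-readable error code.  The manifest is the only output that
#' carries a timestamp.
#'
#' @param dir output directory.
#' @param seed seed(s) used, or `NULL`.
#' @param config_path configuration file path, or `NULL`; hashed with
#'   MD5 when present.
#' @param argv character vector of CLI arguments (if any).
#' @param status `"ok"` or `"error"`.
#' @param error_code machine-readable error code, or `NULL`.
#' @param error_message human-readable message, or `NULL`.
#' @return Path of the written manifest, invisibly.
#' @export
write_run_manifest <- function(dir, seed = NULL, config_path = NULL,
                               argv = character(), status = "ok",
                               error_code = NULL, error_message = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "hvblock",
    package_version = as.character(utils::packageVersion("hvblock")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    argv = as.list(argv),
    seed = seed,
    config = if (!is.null(config_path)) {
      list(path = config_path,
           md5 = unname(tools::md5sum(config_path)))
    },
    status = status,
    error_code = error_code,
    error_message = error_message
  )
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
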