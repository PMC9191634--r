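# Summary reporting: per-condition blockade parameters with derived
# time constants, and a fold-change block comparing rates and
# affinities across voltages, peptides and channels, each row carrying
# the operands it was computed from.

.fold_row <- function(quantity, axis, context, num_label, den_label,
                      num, den) {
  ratio <- num / den
  data.frame(quantity = quantity, axis = axis, context = context,
             numerator = num_label, denominator = den_label,
             ratio = ratio, fold = max(ratio, 1 / ratio),
             stringsAsFactors = FALSE)
}

.fold_block <- function(tab) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  qty <- c(ki = "ki_M", kon = "kon", koff = "koff")

  # across voltages, within one peptide/channel: numerator is always
  # the more depolarized condition
  for (key in split(tab, paste(tab$peptide, tab$channel, sep = "|"))) {
    key <- key[!is.na(key$voltage_mV), , drop = FALSE]
    if (nrow(key) < 2L) next
    key <- key[order(key$voltage_mV), , drop = FALSE]
    for (i in seq_len(nrow(key) - 1L)) {
      for (j in seq(i + 1L, nrow(key))) {
        for (q in names(qty)) {
          hi <- key[[qty[[q]]]][j]
          lo <- key[[qty[[q]]]][i]
          if (is.na(hi) || is.na(lo) || lo <= 0) next
          add(.fold_row(q, "voltage",
                        sprintf("%s / %s", key$peptide[1], key$channel[1]),
                        sprintf("%+g mV", key$voltage_mV[j]),
                        sprintf("%+g mV", key$voltage_mV[i]), hi, lo))
        }
      }
    }
  }
  # across peptides, within one channel/voltage
  for (key in split(tab, paste(tab$channel, tab$voltage_mV, sep = "|"))) {
    if (nrow(key) < 2L) next
    key <- key[order(key$peptide), , drop = FALSE]
    for (i in seq_len(nrow(key) - 1L)) {
      for (j in seq(i + 1L, nrow(key))) {
        for (q in names(qty)) {
          a <- key[[qty[[q]]]][i]
          b <- key[[qty[[q]]]][j]
          if (is.na(a) || is.na(b) || b <= 0) next
          add(.fold_row(q, "peptide",
                        sprintf("%s at %+g mV", key$channel[1],
                                key$voltage_mV[1]),
                        key$peptide[i], key$peptide[j], a, b))
        }
      }
    }
  }
  # across channels, within one peptide/voltage
  for (key in split(tab, paste(tab$peptide, tab$voltage_mV, sep = "|"))) {
    if (nrow(key) < 2L) next
    key <- key[order(key$channel), , drop = FALSE]
    for (i in seq_len(nrow(key) - 1L)) {
      for (j in seq(i + 1L, nrow(key))) {
        for (q in names(qty)) {
          a <- key[[qty[[q]]]][i]
          b <- key[[qty[[q]]]][j]
          if (is.na(a) || is.na(b) || b <= 0) next
          add(.fold_row(q, "channel",
                        sprintf("%s at %+g mV", key$peptide[1],
                                key$voltage_mV[1]),
                        key$channel[i], key$channel[j], a, b))
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(quantity = character(), axis = character(),
                      context = character(), numerator = character(),
                      denominator = character(), ratio = numeric(),
                      fold = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Assemble a blockade summary report
#'
#' Takes a per-condition results table (one row per peptide x channel
#' x voltage, with the inhibition constant and, where measured, Hill
#' coefficient and rate constants) and derives: washout and wash-in
#' time constants (the latter at the supplied working concentration),
#' the kinetic estimate `Ki = koff/kon`, and a fold-change block with
#' every pairwise rate/affinity ratio across voltages, peptides and
#' channels.  Each fold-change row records the quantity, the axis of
#' comparison, the fixed context and both operand labels, so every
#' number is traceable to its inputs.
#'
#' @param results data frame in the `results` schema, concentrations
#'   already molar (as from
#'   `read_experiment_table(..., "results")`): columns `peptide`,
#'   `channel`, `voltage_mV`, `ki` (with `ki_unit` "M"), optional `h`,
#'   `kon`, `koff`, `conc`.
#' @param constants a [binding_constants()] object (recorded in the
#'   provenance block).
#' @return A `summary_report`: list with `summary` (per-condition
#'   table), `fold_changes`, and `provenance`.
#' @export
build_report <- function(results, constants = binding_constants()) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("peptide", "channel", "voltage_mV", "ki") %in%
                  names(results)))
  if (!is.null(results$ki_unit) && !all(results$ki_unit == "M")) {
    .hv_validation_error("build_report expects molar ki values ",
                         "(read the table through the 'results' schema)")
  }
  n <- nrow(results)
  get_col <- function(nm) {
    if (is.null(results[[nm]])) rep(NA_real_, n) else as.numeric(results[[nm]])
  }
  kon <- get_col("kon")
  koff <- get_col("koff")
  conc <- get_col("conc")
  tau_off <- ifelse(koff > 0, 1 / koff, NA_real_)
  tau_on <- ifelse(!is.na(kon) & !is.na(koff) & !is.na(conc),
                   1 / (kon * conc + koff), NA_real_)
  summary <- data.frame(
    peptide = results$peptide, channel = results$channel,
    voltage_mV = results$voltage_mV,
    ki_M = results$ki, h = get_col("h"),
    kon = kon, koff = koff,
    tau_on_s = tau_on, tau_off_s = tau_off,
    ki_kinetic_M = ifelse(!is.na(kon) & kon > 0, koff / kon, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(
    list(summary = summary,
         fold_changes = .fold_block(summary),
         provenance = list(
           package_version = as.character(utils::packageVersion("hvblock")),
           temperature_K = constants$T,
           n_conditions = n)),
    class = "summary_report"
  )
}

#' @export
print.summary_report <- function(x, ...) {
  cat("Blockade summary (", x$provenance$n_conditions, " conditions)\n",
      sep = "")
  print(x$summary, digits = 4)
  if (nrow(x$fold_changes)) {
    cat("\nFold changes:\n")
    print(x$fold_changes, digits = 4)
  } else {
    cat("\nFold changes: none (single condition)\n")
  }
  invisible(x)
}

#' Write a summary report to disk
#'
#' Emits the report as CSV (summary and fold-change tables), JSON
#' (full double precision plus display-rounded twins), and a
#' human-readable text rendering.
#'
#' @param report a `summary_report` from [build_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "summary_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$fold_changes, file.path(dir, "fold_changes.csv"),
                   row.names = FALSE)
  json <- list(
    summary = report$summary,
    summary_display = format(report$summary, digits = 4),
    fold_changes = report$fold_changes,
    fold_changes_display = format(report$fold_changes, digits = 4),
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  txt <- file.path(dir, "report.txt")
  con <- file(txt, open = "wt", encoding = "UTF-8")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  invisible(dir)
}
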