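#' Default contraceptive use-effectiveness table
#'
#' Bongaarts' standard use-effectiveness schedule: the proportionate
#' reduction in conception risk achieved by each method in typical use.
#' Sterilization 1.00; IUD 0.95; pill, injection and implant 0.90; condom,
#' diaphragm, foam/jelly and LAM 0.70; rhythm, withdrawal, folk and other
#' traditional methods 0.50. Fully overridable through the config file.
#'
#' @return Named numeric vector mapping method (excluding `"none"`) to
#'   effectiveness in `[0, 1]`.
#' @export
default_effectiveness <- function() {
  c(sterilization = 1.00, iud = 0.95,
    pill = 0.90, injection = 0.90, implant = 0.90,
    condom = 0.70, diaphragm = 0.70, foam_jelly = 0.70, lam = 0.70,
    rhythm = 0.50, withdrawal = 0.50, folk = 0.50, other_traditional = 0.50)
}

#' Analysis configuration
#'
#' Bundles the tunable constants of the decomposition. The defaults are the
#' model's standard constants: total fecundity TF = 15.3 births, sterility
#' correction 1.08, total abortion rate TA = 0 (hence Ca = 1), and a
#' 36-month births reference window.
#'
#' @param window_months Births reference window in months (>= 12).
#' @param tf Total fecundity, births per woman (> 0).
#' @param sterility_correction Multiplier on u*e in the contraception index
#'   (in (0, 1.2]).
#' @param ta Total abortion rate (>= 0).
#' @param effectiveness Named numeric method -> effectiveness table.
#' @param cm_method `"formula"` (weighted-sum over age groups) or `"ratio"`
#'   (TFR/TMFR).
#' @param i_estimator `"prevalence_incidence"` (current-status) or
#'   `"reported_duration"`.
#' @param min_stratum_n Unweighted-n warning threshold for strata.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(window_months = 36L,
                            tf = 15.3,
                            sterility_correction = 1.08,
                            ta = 0,
                            effectiveness = default_effectiveness(),
                            cm_method = c("formula", "ratio"),
                            i_estimator = c("prevalence_incidence",
                                            "reported_duration"),
                            min_stratum_n = 100L) {
  cm_method <- match.arg(cm_method)
  i_estimator <- match.arg(i_estimator)
  window_months <- as.integer(window_months)
  if (is.na(window_months) || window_months < 12L)
    stop("window_months must be an integer >= 12")
  if (!is.numeric(tf) || tf <= 0) stop("tf must be > 0")
  if (sterility_correction <= 0 || sterility_correction > 1.2)
    stop("sterility_correction must lie in (0, 1.2]")
  if (ta < 0) stop("ta must be >= 0")
  if (any(effectiveness < 0 | effectiveness > 1))
    stop("effectiveness values must lie in [0, 1]")
  structure(list(window_months = window_months, tf = tf,
                 sterility_correction = sterility_correction, ta = ta,
                 effectiveness = effectiveness, cm_method = cm_method,
                 i_estimator = i_estimator,
                 min_stratum_n = as.integer(min_stratum_n)),
            class = "analysis_config")
}

#' Load an analysis configuration from a YAML/JSON key-value file
#'
#' Absent keys take the standard defaults (`tf` 15.3, sterility correction
#' 1.08, `ta` 0, 36-month window). The `effectiveness` key may override
#' individual methods; unnamed methods keep their default effectiveness.
#'
#' @param path File path, or `NULL` for pure defaults.
#' @return An `analysis_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(analysis_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  valid <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), valid)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(valid, collapse = ", "))
  }
  if (!is.null(raw$effectiveness)) {
    eff <- default_effectiveness()
    ov <- unlist(raw$effectiveness)
    bad <- setdiff(names(ov), names(eff))
    if (length(bad)) stop("unknown method(s) in effectiveness: ",
                          paste(bad, collapse = ", "))
    eff[names(ov)] <- ov
    raw$effectiveness <- eff
  }
  do.call(analysis_config, raw)
}

parse_births_field <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(integer())
    as.integer(strsplit(trimws(s), "[;[:space:]]+")[[1]])
  })
}

#' Read a women's-records CSV
#'
#' Reads the documented flat schema: one row per woman of reproductive age
#' with columns `woman_id, weight, dob_cm, interview_cm, marital_status,
#' current_method, insusceptible_now`, a birth history, and any number of
#' stratifier columns. Two birth-history dialects are accepted: a single
#' delimited `births_cm` field (semicolon- or space-separated month
#' indices) or wide columns `b1_cm ... bK_cm` (blank for no birth). Rows
#' violating hard invariants are rejected and counted in the load report.
#'
#' For real DHS women's-recode exports, `column_map` renames source columns
#' to schema names (e.g. `c(weight = "v005")`); note that DHS `v005` must
#' be divided by 1e6 before use, which this reader does *not* do.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param column_map Optional named character vector, schema name ->
#'   source column name.
#' @return Validated women's data frame with a `births` list-column and a
#'   `load_report` attribute (see [validate_women()]).
#' @export
read_women_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (schema_name in names(column_map)) {
      src <- column_map[[schema_name]]
      if (!src %in% names(raw)) stop("column_map source column not in file: ", src)
      names(raw)[names(raw) == src] <- schema_name
    }
  }
  missing <- setdiff(women_core_columns(), names(raw))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  wide <- grep("^b[0-9]+_cm$", names(raw), value = TRUE)
  if ("births_cm" %in% names(raw)) {
    raw$births <- parse_births_field(raw$births_cm)
    raw$births_cm <- NULL
  } else if (length(wide)) {
    wide <- wide[order(as.integer(sub("^b([0-9]+)_cm$", "\\1", wide)))]
    mat <- as.matrix(raw[wide])
    raw$births <- lapply(seq_len(nrow(raw)), function(i) {
      b <- suppressWarnings(as.integer(mat[i, ]))
      sort(b[!is.na(b)])
    })
    raw[wide] <- NULL
  } else {
    raw$births <- rep(list(integer()), nrow(raw))
  }
  raw$births <- lapply(raw$births, function(b) sort(as.integer(b)))
  raw$weight <- as.numeric(raw$weight)
  raw$dob_cm <- as.integer(raw$dob_cm)
  raw$interview_cm <- as.integer(raw$interview_cm)
  raw$insusceptible_now <- as.logical(raw$insusceptible_now)
  out <- validate_women(raw)
  rep <- attr(out, "load_report")
  message(sprintf("read %d rows: kept %d, rejected %d",
                  rep$rows_read, rep$rows_kept, rep$rows_rejected))
  out
}

#' Write a women's table to CSV
#'
#' Serialises the `births` list-column as a semicolon-delimited `births_cm`
#' field; [read_women_csv()] of the output reproduces the table.
#'
#' @param women Validated women's data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_women_csv <- function(women, path) {
  out <- women[setdiff(names(women), "births")]
  out$births_cm <- vapply(women$births, paste, character(1), collapse = ";")
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Published Uganda index estimates (2006 and 2011 DHS)
#'
#' Loads the published national and stratum-level Bongaarts index estimates
#' for Uganda computed from the 2006 and 2011 DHS women's recodes: Cm, Cc,
#' Ci, Ca and the TFR, by religion, region, residence, wealth quintile and
#' education, plus the national totals. Used as worked-example inputs for
#' the aggregate model (the underlying microdata are registration-gated).
#'
#' @return Data frame with columns `year, variable, category, cm, cc, ci,
#'   ca, tfr`.
#' @export
uganda_reference_indices <- function() {
  read.csv(system.file("extdata", "uganda_indices_2006_2011.csv",
                       package = "proxfert"),
           stringsAsFactors = FALSE)
}
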