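# Half-up rounding for rendered tables (R's round() is half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a decomposition as a fixed-width text table
#'
#' Mirrors the conventional presentation of proximate-determinant
#' decompositions: one row per stratum, indices to 6 decimals, TFR to 1
#' decimal, half-up rounding.
#'
#' @param decomp A `decomposition` data frame from [decompose()].
#' @param tfr Which TFR column to print: predicted (default) or observed.
#' @return Character vector of table lines, invisibly printed with `cat`
#'   by [print()]; returned visibly here.
#' @export
render_decomposition <- function(decomp, tfr = c("predicted", "observed")) {
  tfr <- match.arg(tfr)
  col <- paste0("tfr_", tfr)
  fmt6 <- function(x) ifelse(is.na(x), "      --",
                             sprintf("%.6f", round_half_up(x, 6)))
  fmt1 <- function(x) ifelse(is.na(x), " --",
                             sprintf("%.1f", round_half_up(x, 1)))
  header <- sprintf("%-16s %-12s %9s %9s %9s %9s %6s",
                    "Variable", "Category", "Cm", "Cc", "Ci", "Ca", "TFR")
  lines <- sprintf("%-16s %-12s %9s %9s %9s %9s %6s",
                   decomp$variable, decomp$category,
                   fmt6(decomp$cm), fmt6(decomp$cc), fmt6(decomp$ci),
                   fmt6(decomp$ca), fmt1(decomp[[col]]))
  c(header, strrep("-", nchar(header)), lines)
}

#' Run manifest
#'
#' Records what produced a set of output files: a config snapshot, an
#' input digest (md5 of the input file, when given), the package version,
#' a timestamp, the output file list and a warnings summary.
#'
#' @param outputs Character vector of output file paths.
#' @param config The `analysis_config` used.
#' @param input Optional input file path to digest.
#' @param warnings Character vector of warnings raised during the run.
#' @param extra Optional named list merged into the manifest (e.g. the
#'   simulation seed).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(outputs, config = NULL, input = NULL,
                         warnings = character(0), extra = list()) {
  cfg <- if (is.null(config)) NULL else {
    c(unclass(config)[setdiff(names(config), "effectiveness")],
      list(effectiveness = as.list(config$effectiveness)))
  }
  digest <- if (!is.null(input) && file.exists(input)) {
    unname(tools::md5sum(input))
  } else NULL
  structure(c(list(package = "proxfert",
                   version = as.character(packageVersion("proxfert")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   input = input, input_md5 = digest,
                   outputs = as.list(outputs), config = cfg,
                   warnings = as.list(warnings)),
              extra),
            class = "run_manifest")
}

#' Write a decomposition with its rendered table and manifest
#'
#' Emits the three conventional artifacts under `dir`: the long-format CSV
#' (`<stem>.csv`), the rendered fixed-width table (`<stem>.txt`) and a JSON
#' run manifest (`<stem>_manifest.json`). Input files are never mutated;
#' rerunning with the same inputs reproduces the CSV and table bytes
#' (the manifest timestamp differs).
#'
#' @param decomp A `decomposition` from [decompose()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"decomposition"`).
#' @param config,input Passed to [run_manifest()].
#' @return Named character vector of the three paths, invisibly.
#' @export
write_decomposition <- function(decomp, dir, stem = "decomposition",
                                config = NULL, input = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(csv = file.path(dir, paste0(stem, ".csv")),
             table = file.path(dir, paste0(stem, ".txt")),
             manifest = file.path(dir, paste0(stem, "_manifest.json")))
  write.csv(decomp, paths[["csv"]], row.names = FALSE, quote = TRUE)
  writeLines(render_decomposition(decomp), paths[["table"]])
  flags <- decomp$flags[nzchar(decomp$flags)]
  manifest <- run_manifest(unname(paths[c("csv", "table")]), config = config,
                           input = input, warnings = unique(flags))
  jsonlite::write_json(unclass(manifest), paths[["manifest"]],
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(paths)
}
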