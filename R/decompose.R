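#' Re-bin education for decomposition
#'
#' Survey ingest carries four education levels (none, primary, secondary,
#' higher); decomposition tables conventionally pool the top levels. The
#' default map collapses to `{none, primary, secondary+}`.
#'
#' @param women Women's data frame with an `education` column.
#' @param map Named character vector, source level -> output level.
#' @return The data frame with `education` re-binned.
#' @export
rebin_education <- function(women,
                            map = c(none = "none", primary = "primary",
                                    secondary = "secondary+",
                                    higher = "secondary+")) {
  if (is.null(women$education)) return(women)
  known <- women$education %in% names(map)
  women$education[known] <- unname(map[women$education[known]])
  women
}

#' Stratified decomposition of the proximate-determinant indices
#'
#' Fits the full index set within each category of each requested
#' stratifier variable, plus a TOTAL row over all records. A failure in one
#' stratum (e.g. an undefined index in a tiny group) is recorded as a flag
#' and does not abort the other strata. Missing stratifier values form an
#' explicit `"(missing)"` category. Strata with unweighted n below
#' `config$min_stratum_n` are flagged.
#'
#' @param women Validated women's data frame.
#' @param by_variables Character vector of stratifier column names.
#' @param config An `analysis_config`.
#' @return Data frame of class `decomposition`, one row per (variable,
#'   category) and a final `total`/`TOTAL` row, with columns `variable,
#'   category, u, e, i, ta, cm, cc, ci, ca, tf, tfr_observed,
#'   tfr_predicted, n_unweighted, n_weighted, flags`.
#' @export
decompose <- function(women, by_variables, config = analysis_config()) {
  avail <- stratifier_names(women)
  unknown <- setdiff(by_variables, avail)
  if (length(unknown)) {
    stop("unknown stratifier variable(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  }
  fit_row <- function(sub, variable, category) {
    flags <- character(0)
    if (nrow(sub) < config$min_stratum_n) {
      flags <- c(flags, sprintf("small stratum (n = %d)", nrow(sub)))
    }
    row <- tryCatch({
      fit <- suppressMessages(fit_index_set(sub, config))
      r <- index_set_row(fit)
      if (nzchar(r$warnings)) flags <- c(flags, r$warnings)
      r$warnings <- NULL
      r
    }, error = function(e) {
      flags <<- c(flags, conditionMessage(e))
      as.data.frame(setNames(as.list(rep(NA_real_, 13L)),
                             c("u", "e", "i", "ta", "cm", "cc", "ci", "ca",
                               "tf", "tfr_observed", "tfr_predicted",
                               "n_unweighted", "n_weighted")))
    })
    cbind(data.frame(variable = variable, category = category,
                     stringsAsFactors = FALSE),
          row,
          data.frame(flags = paste(flags, collapse = " | "),
                     stringsAsFactors = FALSE))
  }
  rows <- list()
  for (v in by_variables) {
    val <- women[[v]]
    val[is.na(val) | !nzchar(as.character(val))] <- "(missing)"
    for (cat in unique(as.character(val))) {
      sub <- women[val == cat, , drop = FALSE]
      rows[[length(rows) + 1L]] <- fit_row(sub, v, cat)
    }
  }
  rows[[length(rows) + 1L]] <- fit_row(women, "total", "TOTAL")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("decomposition", class(out))
  out
}

#' Weighted one-way frequency tabulation
#'
#' @param women Validated women's data frame.
#' @param variable Stratifier column name.
#' @return Data frame with `category`, unweighted `n`, `weighted_n` and
#'   `percent` (weighted, summing to 100 within rounding).
#' @export
tabulate_weighted <- function(women, variable) {
  if (!variable %in% names(women)) {
    stop("unknown variable: ", variable, "; available: ",
         paste(stratifier_names(women), collapse = ", "))
  }
  val <- as.character(women[[variable]])
  val[is.na(val) | !nzchar(val)] <- "(missing)"
  cats <- unique(val)
  w <- vapply(cats, function(cat) sum(women$weight[val == cat]), numeric(1))
  data.frame(category = cats,
             n = as.integer(table(factor(val, levels = cats))[cats]),
             weighted_n = unname(w),
             percent = unname(100 * w / sum(w)),
             row.names = NULL, stringsAsFactors = FALSE)
}
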