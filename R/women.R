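MARITAL_LEVELS <- c("never_married", "married", "formerly_married")

#' Recognised contraceptive methods
#'
#' The method vocabulary of the women's-records schema. `"none"` denotes no
#' current use; "married" pools formal marriage and consensual unions at
#' ingest, so use is always classified against current method alone.
#'
#' @return Character vector of method codes, `"none"` first.
#' @export
contraceptive_methods <- function() {
  c("none", "pill", "iud", "injection", "diaphragm", "condom",
    "sterilization", "implant", "foam_jelly", "lam", "rhythm",
    "withdrawal", "folk", "other_traditional")
}

#' Core (non-stratifier) columns of a women's table
#'
#' @return Character vector of mandatory column names.
#' @export
women_core_columns <- function() {
  c("woman_id", "weight", "dob_cm", "interview_cm", "marital_status",
    "current_method", "insusceptible_now")
}

#' Stratifier columns of a women's table
#'
#' Any column that is not a core field or birth-history field is treated as
#' a stratifier (residence, region, education, religion, wealth_quintile,
#' and any extras).
#'
#' @param women A women's data frame.
#' @return Character vector of stratifier column names.
#' @export
stratifier_names <- function(women) {
  setdiff(names(women),
          c(women_core_columns(), "births", "births_cm", "insusc_duration"))
}

#' Completed age at interview
#'
#' @param women A women's data frame.
#' @return Integer vector of completed years, `floor((interview_cm - dob_cm)/12)`.
#' @export
age_at_interview <- function(women) {
  (women$interview_cm - women$dob_cm) %/% 12L
}

#' Validate a women's table
#'
#' Checks the hard row invariants of the schema: month ordering
#' (`interview_cm > dob_cm`, every birth after the mother's own birth and
#' not after the interview), age at interview within 15-49, nonnegative
#' weight, and recognised category levels. Rows failing a hard invariant
#' are dropped and counted; soft problems (a woman flagged postpartum
#' insusceptible with an empty birth history) produce warnings only.
#'
#' @param women Data frame with the core columns and a `births` list-column
#'   of integer birth-month indices.
#' @return The validated data frame with rejected rows removed; a
#'   `load_report` attribute lists rows read, rejected (with reasons) and
#'   warnings.
#' @export
validate_women <- function(women) {
  missing <- setdiff(women_core_columns(), names(women))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(women$births)) women$births <- rep(list(integer()), nrow(women))
  n0 <- nrow(women)
  reasons <- character(0)
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) reasons <<- c(reasons, setNames(rep(why, sum(cond)),
                                                   which(cond)))
    cond
  }
  age <- (women$interview_cm - women$dob_cm) %/% 12L
  birth_ok <- vapply(seq_len(nrow(women)), function(i) {
    b <- women$births[[i]]
    !length(b) ||
      (all(b > women$dob_cm[i]) && all(b <= women$interview_cm[i]))
  }, logical(1))
  drop <- bad(women$interview_cm <= women$dob_cm, "interview before birth") |
    bad(age < 15L | age > 49L, "age out of range") |
    bad(women$weight < 0, "negative weight") |
    bad(!women$marital_status %in% MARITAL_LEVELS, "unknown marital status") |
    bad(!women$current_method %in% contraceptive_methods(),
        "unknown contraceptive method") |
    bad(!birth_ok, "birth month outside (dob, interview]")
  warnings <- character(0)
  n_odd <- sum(women$insusceptible_now & !drop &
                 !vapply(women$births, function(b) length(b) > 0, logical(1)))
  if (n_odd > 0) {
    msg <- paste0(n_odd, " woman/women flagged insusceptible with empty ",
                  "birth history")
    warnings <- c(warnings, msg)
    warning(msg)
  }
  out <- women[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "load_report") <- list(
    rows_read = n0, rows_kept = nrow(out), rows_rejected = sum(drop),
    reject_reasons = reasons, warnings = warnings)
  out
}
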