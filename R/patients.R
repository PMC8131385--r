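PATIENT_COLUMNS <- c("patient_id", "years_post_onset", "age_at_testing",
                     "l2_aoa", "pct_lifetime_L1", "pct_lifetime_L2",
                     "pct_use_L1", "pct_use_L2", "bnt_L1", "bnt_L2", "papt",
                     "treated_language", "n_sessions")

BNT_MAX <- 60L
PAPT_MAX <- 52L

validate_patient_table <- function(df) {
  missing <- setdiff(PATIENT_COLUMNS, names(df))
  if (length(missing) > 0)
    stop_bilex("patient table is missing column(s): ",
               paste(missing, collapse = ", "))
  chk <- function(ok, col, msg) {
    bad <- which(!ok)
    if (length(bad) > 0)
      stop_bilex("patient table row ", bad[1], " (", df$patient_id[bad[1]],
                 "), column '", col, "': ", msg)
  }
  chk(df$years_post_onset >= 0, "years_post_onset", "must be >= 0")
  chk(df$age_at_testing > 0, "age_at_testing", "must be positive")
  chk(df$l2_aoa >= 0 & df$l2_aoa <= df$age_at_testing, "l2_aoa",
      "must be in [0, age_at_testing]")
  chk(abs(df$pct_lifetime_L1 + df$pct_lifetime_L2 - 100) <= 1,
      "pct_lifetime_L1/L2", "lifetime exposure must sum to 100 (+/- 1)")
  chk(abs(df$pct_use_L1 + df$pct_use_L2 - 100) <= 1, "pct_use_L1/L2",
      "poststroke use must sum to 100 (+/- 1)")
  chk(df$bnt_L1 >= 0 & df$bnt_L1 <= BNT_MAX, "bnt_L1",
      "must be within 0-60")
  chk(df$bnt_L2 >= 0 & df$bnt_L2 <= BNT_MAX, "bnt_L2",
      "must be within 0-60")
  chk(df$papt >= 0 & df$papt <= PAPT_MAX, "papt", "must be within 0-52")
  chk(df$treated_language %in% c("L1", "L2"), "treated_language",
      "must be 'L1' or 'L2'")
  chk(df$n_sessions >= 1, "n_sessions", "must be >= 1")
  invisible(df)
}

#' Load or write a patient profile table
#'
#' The CSV carries one row per patient: demographics (years post onset, age
#' at testing, L2 age of acquisition), percent lifetime exposure and percent
#' poststroke use per language, naming scores per language (out of 60),
#' a semantic-association score (out of 52), treated language and number of
#' treatment sessions. All invariants are validated on load; violations are
#' reported with the offending row and column.
#'
#' @param path CSV file path.
#' @return `load_patient_table` returns a validated data frame with one row
#'   per patient.
#' @export
load_patient_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_patient_table(df)
  df
}

#' @rdname load_patient_table
#' @param profiles a patient table (data frame).
#' @export
write_patient_table <- function(profiles, path) {
  validate_patient_table(profiles)
  utils::write.csv(profiles[, PATIENT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Bundled 13-patient study profile table
#'
#' Returns the package's bundled table of the 13 retrospective
#' Spanish-English bilingual aphasia profiles that drive all patient-level
#' simulations (L1 = Spanish, L2 = English).
#'
#' @return a validated data frame with 13 rows.
#' @export
bilex_patients <- function() {
  load_patient_table(system.file("extdata", "patients_table1.csv",
                                 package = "bilexr", mustWork = TRUE))
}

#' Read / write per-session naming-probe series
#'
#' Probe series hold, per patient and session (session 0 is the pre-treatment
#' baseline), the naming proportion on the treatment set in each language.
#'
#' @param path CSV path with columns `patient_id`, `session`, `score_L1`,
#'   `score_L2`.
#' @return `read_probe_series` returns a named list of per-patient data
#'   frames with columns `session`, `score_L1`, `score_L2`.
#' @export
read_probe_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "session", "score_L1", "score_L2")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop_bilex("probe series file is missing column(s): ",
               paste(missing, collapse = ", "))
  out <- split(df[, c("session", "score_L1", "score_L2")], df$patient_id)
  lapply(out, function(s) {
    s <- s[order(s$session), ]
    rownames(s) <- NULL
    validate_probe_series(s)
    s
  })
}

#' @rdname read_probe_series
#' @param series named list of per-patient probe data frames.
#' @export
write_probe_series <- function(series, path) {
  long <- do.call(rbind, lapply(names(series), function(p) {
    cbind(patient_id = p, series[[p]][, c("session", "score_L1", "score_L2")])
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_probe_series <- function(s) {
  if (!identical(as.integer(s$session), seq.int(0L, nrow(s) - 1L)))
    stop_bilex("probe sessions must be consecutive starting at 0 (baseline)")
  if (any(s$score_L1 < 0 | s$score_L1 > 1 | s$score_L2 < 0 | s$score_L2 > 1))
    stop_bilex("probe scores must be proportions in [0, 1]")
  invisible(s)
}
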