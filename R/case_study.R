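# A bundled set of five gold/predicted query pairs illustrating how
# logic-form and execution accuracy diverge: join-table order (execution
# still matches), select-column order (execution breaks), a wrong
# condition value, a semantically close but wrong condition column, and a
# flipped comparison operator. The paired synthetic fixture is built so
# the last three pairs return different results.

#' Example gold/predicted pairs with divergent metrics
#'
#' @return Data frame with `question`, `gold`, `pred`.
#' @export
case_study_pairs <- function() {
  data.frame(
    question = c(
      "let me know the short title and icd9 codes of diagnoses for patient john gartman.",
      "tell me which primary disease the patient walter locher is suffering from and whether he is still alive or not.",
      "calculate the number of dead patients who were admitted to hospital before 2123.",
      "how many american indian/alaska native ethnic background patients were born before 2148?",
      "find the minimum number of days of hospital stay for patients born before the year 2200."),
    gold = c(
      'select diagnoses."icd9_code", diagnoses."short_title" from demographic inner join diagnoses on demographic.hadm_id = diagnoses.hadm_id where demographic."name" = "john gartman"',
      'select demographic."expire_flag", demographic."diagnosis" from demographic where demographic."name" = "walter locher"',
      'select count(distinct demographic."subject_id") from demographic where demographic."expire_flag" = "1" and demographic."admityear" < "2123"',
      'select count(distinct demographic."subject_id") from demographic where demographic."ethnicity" = "american indian/alaska native" and demographic."admityear" < "2148"',
      'select min(demographic."days_stay") from demographic where demographic."dob_year" > "2200"'),
    pred = c(
      'select diagnoses."icd9_code", diagnoses."short_title" from diagnoses inner join demographic on diagnoses.hadm_id = demographic.hadm_id where demographic."name" = "john gartman"',
      'select demographic."diagnosis", demographic."expire_flag" from demographic where demographic."name" = "walter locher"',
      'select count(distinct demographic."subject_id") from demographic where demographic."expire_flag" = "0" and demographic."admityear" < "2123"',
      'select count(distinct demographic."subject_id") from demographic where demographic."ethnicity" = "american indian/alaska native" and demographic."dob_year" < "2184"',
      'select min(demographic."days_stay") from demographic where demographic."dob_year" < "2200"'),
    stringsAsFactors = FALSE)
}

#' Synthetic fixture database for the example pairs
#'
#' Four patients constructed so that the value-error, column-error and
#' operator-error pairs each return different results while the
#' join-order pair still matches.
#'
#' @param path SQLite path (default in-memory).
#' @return A `medsql_db`.
#' @export
case_study_fixture <- function(path = ":memory:") {
  schema <- make_schema()
  demo_cols <- schema$tables$demographic$columns$name
  blank <- function(n) rep("", n)
  demo <- data.frame(
    subject_id = 1:4, hadm_id = 101:104,
    name = c("john gartman", "walter locher", "alice smith", "bob jones"),
    expire_flag = c(1, 0, 1, 0),
    admityear = c(2120, 2125, 2100, 2147),
    dob_year = c(2080, 2201, 2202, 2100),
    days_stay = c(5, 8, 2, 20),
    age = c(40, 45, 50, 47),
    ethnicity = c("white", "asian",
                  "american indian/alaska native",
                  "american indian/alaska native"),
    diagnosis = c("sepsis", "pneumonia", "asthma", "stroke"),
    dod_year = c(2120, NA, 2100, NA),
    stringsAsFactors = FALSE)
  for (cn in setdiff(demo_cols, names(demo))) demo[[cn]] <- blank(4)
  demo <- demo[, demo_cols]
  diag <- data.frame(
    subject_id = c(1, 1, 2), hadm_id = c(101, 101, 102),
    icd9_code = c("4019", "5849", "486"),
    short_title = c("hypertension nos", "acute kidney failure", "pneumonia nos"),
    long_title = c("essential hypertension", "acute kidney failure nos",
                   "pneumonia organism unspecified"),
    stringsAsFactors = FALSE)
  build_fixture_db(schema, list(demographic = demo, diagnoses = diag), path)
}
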