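# Synthetic corpus generator: an EMR-style five-table schema, seeded
# synthetic patient records, and template-instantiated question-SQL pairs
# in which every condition value appears verbatim in the question. The
# templates cover all 24 grammar productions; optional paraphrase noise
# emulates crowd-sourced rephrasing without touching value spans.

#' The bundled EMR-style schema
#'
#' Five tables — demographic, diagnoses, procedures, prescriptions, lab —
#' with 23/5/5/7/9 columns, all joined to demographic on the admission key
#' `hadm_id` (a star join graph).
#'
#' @return A `medsql_schema`.
#' @export
make_schema <- function() {
  col <- function(name, kind = "text", join_key = FALSE)
    data.frame(name = name, kind = kind, join_key = join_key,
               stringsAsFactors = FALSE)
  demo_cols <- rbind(
    col("subject_id", "numeric"), col("hadm_id", "numeric", TRUE),
    col("name"), col("marital_status"), col("age", "numeric"), col("dob"),
    col("gender"), col("language"), col("religion"), col("admission_type"),
    col("days_stay", "numeric"), col("insurance"), col("ethnicity"),
    col("expire_flag", "numeric"), col("admission_location"),
    col("discharge_location"), col("diagnosis"), col("dod"),
    col("dob_year", "numeric"), col("dod_year", "numeric"),
    col("admittime"), col("dischtime"), col("admityear", "numeric"))
  diag_cols <- rbind(col("subject_id", "numeric"), col("hadm_id", "numeric", TRUE),
                     col("icd9_code"), col("short_title"), col("long_title"))
  proc_cols <- diag_cols
  pres_cols <- rbind(col("subject_id", "numeric"), col("hadm_id", "numeric", TRUE),
                     col("icustay_id", "numeric"), col("drug_type"), col("drug"),
                     col("formulary_drug_cd"), col("route"))
  lab_cols <- rbind(col("subject_id", "numeric"), col("hadm_id", "numeric", TRUE),
                    col("itemid"), col("charttime"), col("flag"),
                    col("value_unit"), col("label"), col("fluid"), col("category"))
  medsql_schema(
    tables = list(
      list(name = "demographic", columns = demo_cols),
      list(name = "diagnoses", columns = diag_cols),
      list(name = "procedures", columns = proc_cols),
      list(name = "prescriptions", columns = pres_cols),
      list(name = "lab", columns = lab_cols)),
    joins = data.frame(
      left = "demographic",
      right = c("diagnoses", "procedures", "prescriptions", "lab"),
      key = "hadm_id", stringsAsFactors = FALSE))
}

# Value pools (lower-cased, as stored in the database).
#' @keywords internal
value_pools <- function() {
  list(
    first = c("james", "john", "robert", "michael", "william", "david",
              "mary", "patricia", "jennifer", "linda", "elizabeth", "susan",
              "walter", "harold", "douglas", "peter", "frank", "gloria",
              "ruth", "alice", "henry", "carl", "anna", "paul", "laura",
              "martha", "ralph", "eugene", "diane", "joyce"),
    last = c("sloan", "gartman", "locher", "smith", "johnson", "williams",
             "brown", "jones", "garcia", "miller", "davis", "wilson",
             "anderson", "thomas", "taylor", "moore", "jackson", "martin",
             "lee", "perez", "thompson", "white", "harris", "sanchez",
             "clark", "ramirez", "lewis", "robinson", "walker", "young"),
    marital = c("married", "single", "divorced", "widowed", "separated"),
    gender = c("female", "male"),
    language = c("english", "spanish", "russian", "mandarin", "portuguese"),
    religion = c("catholic", "protestant", "jewish", "buddhist", "unspecified"),
    adm_type = c("emergency", "elective", "urgent", "newborn"),
    insurance = c("private", "medicare", "medicaid", "government", "self pay"),
    ethnicity = c("white", "black/african american", "asian", "hispanic or latino",
                  "american indian/alaska native", "other"),
    adm_loc = c("emergency room admit", "transfer from hospital",
                "clinic referral", "physician referral"),
    dis_loc = c("home", "home health care", "snf", "rehab", "dead/expired"),
    diagnosis = c("sepsis", "pneumonia", "heart failure", "chest pain",
                  "renal failure", "gastrointestinal bleed", "stroke",
                  "coronary artery disease", "liver failure", "asthma"),
    short_title = c("hypertension nos", "atrial fibrillation", "acute kidney failure",
                    "diabetes uncomp", "anemia nos", "cardiac arrest",
                    "septic shock", "pleural effusion", "urinary infection",
                    "respiratory failure"),
    proc_title = c("venous catheter nec", "insert endotracheal tube",
                   "hemodialysis", "blood transfusion", "coronary bypass",
                   "spinal tap", "appendectomy", "colonoscopy"),
    drug = c("aspirin", "heparin", "warfarin", "insulin", "metoprolol",
             "furosemide", "vancomycin", "morphine", "lisinopril", "potassium chloride"),
    drug_type = c("main", "base", "additive"),
    route = c("po", "iv", "im", "oral", "sc"),
    lab_label = c("hematocrit", "hemoglobin", "platelet count", "creatinine",
                  "sodium", "potassium", "glucose", "white blood cells"),
    lab_fluid = c("blood", "urine", "cerebrospinal fluid", "pleural"),
    lab_category = c("hematology", "chemistry", "blood gas"),
    lab_flag = c("normal", "abnormal", "delta"),
    lab_unit = c("g/dl", "mg/dl", "meq/l", "k/ul", "iu/l")
  )
}

#' Sample synthetic patient records
#'
#' One admission per patient with referential integrity on `hadm_id`
#' across the four child tables; deterministic under `seed`.
#'
#' @param schema The schema from [make_schema()].
#' @param n_patients Number of patients (each with 1-2 rows per child table).
#' @param seed Integer seed.
#' @return Named list of data frames, one per table.
#' @export
sample_records <- function(schema, n_patients, seed = 1L) {
  stopifnot(n_patients >= 1L)
  set.seed(seed)
  p <- value_pools()
  n <- n_patients
  subject_id <- seq_len(n)
  hadm_id <- 100000L + seq_len(n)
  dob_year <- sample(2050:2150, n, replace = TRUE)
  admityear <- dob_year + sample(20:70, n, replace = TRUE)
  age <- admityear - dob_year
  days_stay <- sample(1:60, n, replace = TRUE)
  expire_flag <- sample(0:1, n, replace = TRUE)
  demographic <- data.frame(
    subject_id = subject_id, hadm_id = hadm_id,
    name = paste(sample(p$first, n, TRUE), sample(p$last, n, TRUE)),
    marital_status = sample(p$marital, n, TRUE), age = age,
    dob = sprintf("%d-01-01", dob_year),
    gender = sample(p$gender, n, TRUE), language = sample(p$language, n, TRUE),
    religion = sample(p$religion, n, TRUE),
    admission_type = sample(p$adm_type, n, TRUE), days_stay = days_stay,
    insurance = sample(p$insurance, n, TRUE),
    ethnicity = sample(p$ethnicity, n, TRUE), expire_flag = expire_flag,
    admission_location = sample(p$adm_loc, n, TRUE),
    discharge_location = sample(p$dis_loc, n, TRUE),
    diagnosis = sample(p$diagnosis, n, TRUE),
    dod = ifelse(expire_flag == 1, sprintf("%d-06-30", admityear), ""),
    dob_year = dob_year,
    dod_year = ifelse(expire_flag == 1, admityear, NA_real_),
    admittime = sprintf("%d-03-15", admityear),
    dischtime = sprintf("%d-03-%02d", admityear, pmin(15 + days_stay, 28)),
    admityear = admityear, stringsAsFactors = FALSE)

  child_rows <- function(make_row) {
    rows <- list()
    for (i in seq_len(n)) {
      for (k in seq_len(sample(1:2, 1))) {
        rows[[length(rows) + 1L]] <- make_row(i)
      }
    }
    do.call(rbind, rows)
  }
  diagnoses <- child_rows(function(i) data.frame(
    subject_id = subject_id[i], hadm_id = hadm_id[i],
    icd9_code = sprintf("%04d", sample(1000:9999, 1)),
    short_title = sample(p$short_title, 1),
    long_title = paste("chronic", sample(p$short_title, 1)),
    stringsAsFactors = FALSE))
  procedures <- child_rows(function(i) data.frame(
    subject_id = subject_id[i], hadm_id = hadm_id[i],
    icd9_code = sprintf("%03d", sample(100:999, 1)),
    short_title = sample(p$proc_title, 1),
    long_title = paste("surgical", sample(p$proc_title, 1)),
    stringsAsFactors = FALSE))
  prescriptions <- child_rows(function(i) data.frame(
    subject_id = subject_id[i], hadm_id = hadm_id[i],
    icustay_id = 200000L + i,
    drug_type = sample(p$drug_type, 1), drug = sample(p$drug, 1),
    formulary_drug_cd = sprintf("fd%04d", sample(1:9999, 1)),
    route = sample(p$route, 1), stringsAsFactors = FALSE))
  lab <- child_rows(function(i) data.frame(
    subject_id = subject_id[i], hadm_id = hadm_id[i],
    itemid = sprintf("it%04d", sample(1:9999, 1)),
    charttime = sprintf("%d-03-16", admityear[i]),
    flag = sample(p$lab_flag, 1), value_unit = sample(p$lab_unit, 1),
    label = sample(p$lab_label, 1), fluid = sample(p$lab_fluid, 1),
    category = sample(p$lab_category, 1), stringsAsFactors = FALSE))
  list(demographic = demographic, diagnoses = diagnoses,
       procedures = procedures, prescriptions = prescriptions, lab = lab)
}

#' Generation configuration
#'
#' @param n_pairs Number of question-SQL pairs.
#' @param n_patients Number of synthetic patients.
#' @param seed Integer seed; fixes records, templates, noise and splits.
#' @param paraphrase_rate Fraction of questions receiving paraphrase noise.
#' @param split Train/validation/test ratios (must sum to 1).
#' @return A `medsql_genconfig` list.
#' @export
gen_config <- function(n_pairs = 1000L, n_patients = 200L, seed = 1L,
                       paraphrase_rate = 0.3, split = c(0.8, 0.1, 0.1)) {
  stopifnot(n_pairs >= 1L, n_patients >= 1L,
            paraphrase_rate >= 0, paraphrase_rate <= 1,
            length(split) == 3L, abs(sum(split) - 1) < 1e-9)
  structure(list(n_pairs = as.integer(n_pairs),
                 n_patients = as.integer(n_patients),
                 seed = as.integer(seed), paraphrase_rate = paraphrase_rate,
                 split = split), class = "medsql_genconfig")
}

# Build an IR tree directly from select components and a condition struct
# (the parser's `cmp`/`conn` representation).
#' @keywords internal
components_to_tree <- function(select, where, schema, grammar = sql_grammar()) {
  cols <- schema_columns(schema)
  tabs <- schema_tables(schema)
  a_node <- function(agg, table, column) {
    cid <- match(paste(table, column, sep = "."), cols$qualified)
    ir_node("A", grammar_rule_id(grammar, "A", agg),
            list(ir_leaf_c(cid), ir_leaf_t(match(table, tabs))))
  }
  sel <- ir_node("Select",
                 grammar_rule_id(grammar, "Select", NA, n_children = length(select)),
                 lapply(select, function(it) a_node(it$agg, it$table, it$column)))
  build_filter <- function(cnd) {
    if (cnd$type == "conn") {
      ir_node("Filter", grammar_rule_id(grammar, "Filter", cnd$conn),
              list(build_filter(cnd$left), build_filter(cnd$right)))
    } else {
      ch <- list(a_node("none", cnd$table, cnd$column))
      for (v in cnd$values) ch[[length(ch) + 1L]] <- ir_leaf_v(text = v)
      ir_node("Filter", grammar_rule_id(grammar, "Filter", cnd$op), ch)
    }
  }
  r_children <- list(sel)
  if (!is.null(where)) r_children[[2L]] <- build_filter(where)
  r <- ir_node("R", grammar_rule_id(grammar, "R", NA, n_children = length(r_children)),
               r_children)
  ir_node("Z", grammar_rule_id(grammar, "Z"), list(r))
}

# Template inventory -------------------------------------------------------

# Each template returns list(q, select, where). `ctx` exposes the sampled
# records plus helpers. Weights steer the corpus toward ~1.1 select
# columns and ~1.7 conditions per query on average.
#' @keywords internal
sel1 <- function(agg, table, column) list(list(agg = agg, table = table, column = column))
#' @keywords internal
cmp <- function(table, column, op, ...) {
  list(type = "cmp", op = op, table = table, column = column,
       values = as.character(c(...)))
}
#' @keywords internal
conn <- function(c0, left, right) list(type = "conn", conn = c0, left = left, right = right)

#' @keywords internal
question_templates <- function() {
  demo_attr <- c(insurance = "insurance", ethnicity = "ethnicity",
                 religion = "religion", language = "language",
                 "marital status" = "marital_status",
                 "admission type" = "admission_type",
                 "primary disease" = "diagnosis",
                 "admission location" = "admission_location",
                 "discharge location" = "discharge_location")
  pick_attr <- function(k = 1L) {
    i <- sample(seq_along(demo_attr), k)
    list(phrase = names(demo_attr)[i], col = unname(demo_attr[i]))
  }
  t <- list()
  add <- function(id, weight, n_sel, n_cond, build)
    t[[length(t) + 1L]] <<- list(id = id, weight = weight, n_sel = n_sel,
                                 n_cond = n_cond, build = build)

  add("attr_of_name", 2, 1, 1, function(ctx) {
    a <- pick_attr(); nm <- ctx$patient()$name
    list(q = sprintf("tell me the %s of patient %s.", a$phrase, nm),
         select = sel1("none", "demographic", a$col),
         where = cmp("demographic", "name", "eq", nm))
  })
  add("two_attrs_of_name", 1, 2, 1, function(ctx) {
    a <- pick_attr(2); nm <- ctx$patient()$name
    list(q = sprintf("tell me the %s and %s of patient %s.",
                     a$phrase[1], a$phrase[2], nm),
         select = c(sel1("none", "demographic", a$col[1]),
                    sel1("none", "demographic", a$col[2])),
         where = cmp("demographic", "name", "eq", nm))
  })
  add("three_attrs_of_name", 0.4, 3, 1, function(ctx) {
    a <- pick_attr(3); nm <- ctx$patient()$name
    list(q = sprintf("list the %s , %s and %s of patient %s.",
                     a$phrase[1], a$phrase[2], a$phrase[3], nm),
         select = c(sel1("none", "demographic", a$col[1]),
                    sel1("none", "demographic", a$col[2]),
                    sel1("none", "demographic", a$col[3])),
         where = cmp("demographic", "name", "eq", nm))
  })
  add("diag_title_of_name", 2, 1, 1, function(ctx) {
    nm <- ctx$child_patient("diagnoses")$name
    list(q = sprintf("what is the short title of diagnoses for patient %s?", nm),
         select = sel1("none", "diagnoses", "short_title"),
         where = cmp("demographic", "name", "eq", nm))
  })
  add("diag_code_title_of_name", 0.8, 2, 1, function(ctx) {
    nm <- ctx$child_patient("diagnoses")$name
    list(q = sprintf("let me know the icd9 code and short title of diagnoses for patient %s.", nm),
         select = c(sel1("none", "diagnoses", "icd9_code"),
                    sel1("none", "diagnoses", "short_title")),
         where = cmp("demographic", "name", "eq", nm))
  })
  add("proc_title_of_name", 2, 1, 1, function(ctx) {
    nm <- ctx$child_patient("procedures")$name
    list(q = sprintf("give me the long title of procedures for patient %s.", nm),
         select = sel1("none", "procedures", "long_title"),
         where = cmp("demographic", "name", "eq", nm))
  })
  add("drug_via_route", 4, 1, 2, function(ctx) {
    r <- ctx$child_row("prescriptions")
    list(q = sprintf("which drug was prescribed via route %s to patient %s?",
                     r$row$route, r$name),
         select = sel1("none", "prescriptions", "drug"),
         where = conn("and", cmp("demographic", "name", "eq", r$name),
                      cmp("prescriptions", "route", "eq", r$row$route)))
  })
  add("lab_unit_of_label", 4, 1, 2, function(ctx) {
    r <- ctx$child_row("lab")
    list(q = sprintf("what is the value unit of lab test %s for patient %s?",
                     r$row$label, r$name),
         select = sel1("none", "lab", "value_unit"),
         where = conn("and", cmp("demographic", "name", "eq", r$name),
                      cmp("lab", "label", "eq", r$row$label)))
  })
  add("count_admit_before", 1.5, 1, 1, function(ctx) {
    y <- ctx$year("admityear")
    list(q = sprintf("calculate the number of patients whose admission year is less than %s.", y),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = cmp("demographic", "admityear", "lt", y))
  })
  add("count_ethnicity_born_before", 8, 1, 2, function(ctx) {
    e <- ctx$value("demographic", "ethnicity"); y <- ctx$year("dob_year")
    list(q = sprintf("how many %s ethnic background patients were born before the year %s?", e, y),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = conn("and", cmp("demographic", "ethnicity", "eq", e),
                      cmp("demographic", "dob_year", "lt", y)))
  })
  add("count_insurance", 1.5, 1, 1, function(ctx) {
    v <- ctx$value("demographic", "insurance")
    list(q = sprintf("count the number of hospital admissions with insurance %s.", v),
         select = sel1("count", "demographic", "hadm_id"),
         where = cmp("demographic", "insurance", "eq", v))
  })
  add("min_stay_born_before", 2, 1, 1, function(ctx) {
    y <- ctx$year("dob_year")
    list(q = sprintf("find the minimum number of days of hospital stay for patients born before the year %s.", y),
         select = sel1("min", "demographic", "days_stay"),
         where = cmp("demographic", "dob_year", "lt", y))
  })
  add("max_age_admit_after", 1.5, 1, 1, function(ctx) {
    y <- ctx$year("admityear")
    list(q = sprintf("find the maximum age of patients whose admission year is greater than %s.", y),
         select = sel1("max", "demographic", "age"),
         where = cmp("demographic", "admityear", "gt", y))
  })
  add("avg_age_insurance", 1.5, 1, 1, function(ctx) {
    v <- ctx$value("demographic", "insurance")
    list(q = sprintf("what is the average age of patients with insurance %s?", v),
         select = sel1("avg", "demographic", "age"),
         where = cmp("demographic", "insurance", "eq", v))
  })
  add("sum_stay_ethnicity", 1.5, 1, 1, function(ctx) {
    e <- ctx$value("demographic", "ethnicity")
    list(q = sprintf("what is the total of days of hospital stay for patients of ethnicity %s?", e),
         select = sel1("sum", "demographic", "days_stay"),
         where = cmp("demographic", "ethnicity", "eq", e))
  })
  add("count_admit_ge", 1.5, 1, 1, function(ctx) {
    y <- ctx$year("admityear")
    list(q = sprintf("how many patients were admitted in the year %s or later?", y),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = cmp("demographic", "admityear", "ge", y))
  })
  add("count_age_le", 1.5, 1, 1, function(ctx) {
    a <- ctx$year("age")
    list(q = sprintf("count the patients whose age is %s or lower.", a),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = cmp("demographic", "age", "le", a))
  })
  add("count_insurance_ne", 1.5, 1, 1, function(ctx) {
    v <- ctx$value("demographic", "insurance")
    list(q = sprintf("how many patients hold an insurance other than %s?", v),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = cmp("demographic", "insurance", "ne", v))
  })
  add("count_diagnosis_like", 1.5, 1, 1, function(ctx) {
    v <- ctx$value("demographic", "diagnosis")
    list(q = sprintf("how many patients have a primary disease like %s?", v),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = cmp("demographic", "diagnosis", "like", v))
  })
  add("count_diagnosis_not_like", 1.5, 1, 1, function(ctx) {
    v <- ctx$value("demographic", "diagnosis")
    list(q = sprintf("how many patients have a primary disease not like %s?", v),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = cmp("demographic", "diagnosis", "nlike", v))
  })
  add("count_stay_between", 2, 1, 1, function(ctx) {
    d1 <- sample(1:25, 1); d2 <- d1 + sample(5:30, 1)
    list(q = sprintf("how many patients stayed in hospital between %d and %d days?", d1, d2),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = cmp("demographic", "days_stay", "between", d1, d2))
  })
  add("count_insurance_or", 3, 1, 2, function(ctx) {
    v <- ctx$two_values("demographic", "insurance")
    list(q = sprintf("count the patients whose insurance is %s or whose insurance is %s.",
                     v[1], v[2]),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = conn("or", cmp("demographic", "insurance", "eq", v[1]),
                      cmp("demographic", "insurance", "eq", v[2])))
  })
  add("all_diagnosis", 1, 1, 0, function(ctx) {
    list(q = "show the primary disease of all patients.",
         select = sel1("none", "demographic", "diagnosis"), where = NULL)
  })
  add("count_all_patients", 1, 1, 0, function(ctx) {
    list(q = "count the distinct subject id of all patients.",
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = NULL)
  })
  add("count_three_conditions", 3, 1, 3, function(ctx) {
    v <- ctx$value("demographic", "insurance"); y <- ctx$year("dob_year")
    d <- sample(2:20, 1)
    list(q = sprintf("how many patients with insurance %s were born before the year %s and stayed more than %d days?",
                     v, y, d),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = conn("and", cmp("demographic", "insurance", "eq", v),
                      conn("and", cmp("demographic", "dob_year", "lt", y),
                           cmp("demographic", "days_stay", "gt", d))))
  })
  add("lab_flag_of_label", 3.5, 1, 2, function(ctx) {
    r <- ctx$child_row("lab")
    list(q = sprintf("tell me the flag of lab test %s for patient %s.",
                     r$row$label, r$name),
         select = sel1("none", "lab", "flag"),
         where = conn("and", cmp("demographic", "name", "eq", r$name),
                      cmp("lab", "label", "eq", r$row$label)))
  })
  add("proc_code_of_name", 1.5, 1, 1, function(ctx) {
    nm <- ctx$child_patient("procedures")$name
    list(q = sprintf("give me the icd9 code of procedures for patient %s.", nm),
         select = sel1("none", "procedures", "icd9_code"),
         where = cmp("demographic", "name", "eq", nm))
  })
  add("avg_stay_marital", 1.5, 1, 1, function(ctx) {
    v <- ctx$value("demographic", "marital_status")
    list(q = sprintf("what is the average of days of hospital stay for %s patients?", v),
         select = sel1("avg", "demographic", "days_stay"),
         where = cmp("demographic", "marital_status", "eq", v))
  })
  add("language_of_gender", 1.5, 1, 1, function(ctx) {
    v <- ctx$value("demographic", "gender")
    list(q = sprintf("list the language of %s patients.", v),
         select = sel1("none", "demographic", "language"),
         where = cmp("demographic", "gender", "eq", v))
  })
  add("drug_type_of_drug", 3.5, 1, 2, function(ctx) {
    r <- ctx$child_row("prescriptions")
    list(q = sprintf("what is the drug type of %s prescribed to patient %s?",
                     r$row$drug, r$name),
         select = sel1("none", "prescriptions", "drug_type"),
         where = conn("and", cmp("demographic", "name", "eq", r$name),
                      cmp("prescriptions", "drug", "eq", r$row$drug)))
  })
  add("count_born_before_long_stay", 6, 1, 2, function(ctx) {
    y <- ctx$year("dob_year"); d <- sample(2:30, 1)
    list(q = sprintf("how many patients born before the year %s stayed more than %d days in hospital?", y, d),
         select = sel1("count_distinct", "demographic", "subject_id"),
         where = conn("and", cmp("demographic", "dob_year", "lt", y),
                      cmp("demographic", "days_stay", "gt", d)))
  })
  t
}

# Paraphrase noise: seeded synonym substitution plus dropout of filler
# words, never touching tokens inside value spans.
#' @keywords internal
paraphrase_tokens <- function(tokens, protected) {
  syn <- list(tell = "show", calculate = "compute", find = "get",
              list = "show", give = "show", count = "tally",
              many = "numerous", total = "sum", know = "learn")
  out <- tokens
  for (i in seq_along(out)) {
    if (i %in% protected) next
    w <- out[i]
    if (!is.null(syn[[w]]) && stats::runif(1) < 0.5) out[i] <- syn[[w]]
  }
  drop <- logical(length(out))
  for (i in seq_along(out)) {
    if (i %in% protected) next
    if (out[i] %in% c("the", ".") && stats::runif(1) < 0.3) drop[i] <- TRUE
  }
  out[!drop]
}

#' Generate a template-based question-SQL corpus
#'
#' Instantiates weighted templates with values drawn from the stored
#' records, so that every condition value appears verbatim in the question,
#' every query parses under the grammar, converts to a gold action
#' sequence, and executes on the paired fixture database.
#'
#' @param schema The schema ([make_schema()]).
#' @param records Records from [sample_records()].
#' @param cfg A [gen_config()].
#' @param db_path Where to create the fixture database (default in-memory).
#' @return List with `examples` (each: `question`, `tokens`, `sql`,
#'   `actions`, `split`, `template`), `db` (a `medsql_db`), `schema`, `cfg`.
#' @export
generate_pairs <- function(schema, records, cfg = gen_config(),
                           db_path = ":memory:") {
  db <- build_fixture_db(schema, records, db_path)
  grammar <- sql_grammar()
  set.seed(cfg$seed + 1L)
  demo <- records$demographic
  # context helpers visible to template builders
  ctx <- list(
    patient = function() demo[sample(nrow(demo), 1), ],
    child_patient = function(tab) {
      r <- records[[tab]][sample(nrow(records[[tab]]), 1), ]
      demo[match(r$hadm_id, demo$hadm_id), ]
    },
    child_row = function(tab) {
      r <- records[[tab]][sample(nrow(records[[tab]]), 1), ]
      list(row = r, name = demo$name[match(r$hadm_id, demo$hadm_id)])
    },
    value = function(tab, col) sample(unique(records[[tab]][[col]]), 1),
    two_values = function(tab, col) {
      u <- unique(records[[tab]][[col]])
      if (length(u) < 2L) c(u, u) else sample(u, 2)
    },
    year = function(col) sample(unique(records$demographic[[col]]), 1)
  )
  templates <- question_templates()
  weights <- vapply(templates, `[[`, numeric(1), "weight")
  examples <- vector("list", cfg$n_pairs)
  for (i in seq_len(cfg$n_pairs)) {
    ti <- sample(length(templates), 1, prob = weights)
    tm <- templates[[ti]]
    inst <- tm$build(ctx)
    tree <- components_to_tree(inst$select, inst$where, schema, grammar)
    sql <- tree_to_sql(tree, schema, grammar = grammar)$sql
    tokens <- tokenize_question(inst$q)
    # paraphrase noise, protecting value spans
    if (cfg$paraphrase_rate > 0 && stats::runif(1) < cfg$paraphrase_rate) {
      protected <- integer()
      for (v in condition_values(tree)) {
        sp <- find_token_span(v, tokens)
        if (!is.null(sp)) protected <- c(protected, (sp[1] + 1L):(sp[2] + 1L))
      }
      tokens <- paraphrase_tokens(tokens, protected)
    }
    actions <- tree_to_actions(tree, tokens)
    examples[[i]] <- list(question = detokenize(tokens), tokens = tokens,
                          sql = sql, actions = actions, template = tm$id)
  }
  # deterministic split 0.8/0.1/0.1 by shuffled index
  idx <- sample(cfg$n_pairs)
  n_tr <- floor(cfg$split[1] * cfg$n_pairs)
  n_va <- floor(cfg$split[2] * cfg$n_pairs)
  split <- character(cfg$n_pairs)
  split[idx[seq_len(n_tr)]] <- "train"
  split[idx[n_tr + seq_len(n_va)]] <- "val"
  split[split == ""] <- "test"
  for (i in seq_len(cfg$n_pairs)) examples[[i]]$split <- split[i]
  list(examples = examples, db = db, schema = schema, cfg = cfg)
}

#' @keywords internal
condition_values <- function(tree) {
  out <- character()
  walk <- function(node) {
    if (node$sym == "V" && !is.null(node$text)) out <<- c(out, node$text)
    if (!is.null(node$children)) for (ch in node$children) walk(ch)
  }
  walk(tree)
  out
}

#' Write a corpus to JSON lines
#'
#' One object per pair: `question`, `sql`, `actions`, `split`, `template`.
#'
#' @param examples The `examples` element of [generate_pairs()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(examples, path) {
  lines <- vapply(examples, function(e) {
    jsonlite::toJSON(list(question = e$question, sql = e$sql,
                          actions = e$actions, split = e$split,
                          template = e$template), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a corpus from JSON lines
#' @param path Corpus path.
#' @return List of examples (with `tokens` recomputed).
#' @export
read_corpus <- function(path) {
  lapply(readLines(path), function(l) {
    e <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    acts <- lapply(e$actions, function(a) {
      if (a$t == "val") action_val(a$start, a$end)
      else if (a$t == "rule") action_rule(a$id)
      else if (a$t == "col") action_col(a$id)
      else action_tab(a$id)
    })
    list(question = e$question, tokens = tokenize_question(e$question),
         sql = e$sql, actions = acts, split = e$split, template = e$template)
  })
}
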