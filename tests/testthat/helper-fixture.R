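# Shared fixtures, built once per test run.
.cache <- new.env(parent = emptyenv())

calib <- function() {
  if (is.null(.cache$calib)) {
    fix <- build_calibration_fixture()
    scr <- screen_cohort(fix$cohort)
    adj <- build_ade_records(fix$cohort, scr, fix$adjudication)
    .cache$calib <- list(fix = fix, cohort = fix$cohort,
                         adjudication = fix$adjudication,
                         screen = scr, adjudicated = adj)
  }
  .cache$calib
}

# A tiny hand-built cohort for unit tests: two admissions with controlled
# labs, meds and events.
tiny_cohort <- function(...) {
  patients <- data.frame(
    patient_id = c("A", "B"),
    sex = c("male", "female"),
    age = c(70L, 82L),
    admit_date = c("2023-03-01", "2023-05-20"),
    discharge_date = c("2023-03-08", "2023-05-25"),
    conditions = c("HTN;T2DM", "HTN;CKD;CAD"),
    n_medications = c(7L, 12L), stringsAsFactors = FALSE)
  labs <- data.frame(
    patient_id = c("A", "A", "B"),
    analyte = c("K", "SCR", "SCR"),
    value = c(3.2, 100, 100),
    unit = c("mmol/L", "umol/L", "umol/L"),
    observed_at = c("2023-03-02 08:00:00", "2023-03-03 08:00:00",
                    "2023-05-21 08:00:00"), stringsAsFactors = FALSE)
  meds <- data.frame(
    patient_id = "A", drug_code = "VITK", drug_name = "vitamin K1",
    drug_class = "other", start = "2023-03-02", stop = "2023-03-03",
    stringsAsFactors = FALSE)
  events <- data.frame(
    patient_id = "B", event_code = "edema",
    observed_at = "2023-05-22 10:00:00", stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]])
  new_cohort(patients, labs, meds, events)
}

# Independent brute-force trigger evaluator: nested loops over every record
# and every atom, no shared code with the package's screener.
brute_force_hits <- function(cohort, triggers) {
  out <- list()
  for (def in triggers) {
    for (pid in cohort$patients$patient_id) {
      sex <- cohort$patients$sex[cohort$patients$patient_id == pid]
      atom_fired <- logical(length(def$atoms))
      for (ai in seq_along(def$atoms)) {
        atom <- def$atoms[[ai]]
        fired <- FALSE
        if (atom$kind %in% c("lab", "tdm")) {
          rows <- cohort$labs[cohort$labs$patient_id == pid &
                              cohort$labs$analyte == atom$analyte, ]
          for (v in rows$value) {
            ok <- switch(atom$op, "<" = v < atom$threshold,
                         ">" = v > atom$threshold,
                         "<=" = v <= atom$threshold, ">=" = v >= atom$threshold)
            if (ok && (is.na(atom$sex) || atom$sex == sex)) fired <- TRUE
          }
        } else if (atom$kind == "med") {
          rows <- cohort$meds[cohort$meds$patient_id == pid, ]
          for (dc in rows$drug_code) if (dc %in% atom$drugs) fired <- TRUE
        } else {
          rows <- cohort$events[cohort$events$patient_id == pid, ]
          for (ec in rows$event_code) if (ec == atom$event) fired <- TRUE
        }
        atom_fired[ai] <- fired
      }
      hit <- if (def$combinator == "all_of") all(atom_fired) else any(atom_fired)
      if (hit) {
        out[[length(out) + 1]] <- data.frame(
          patient_id = pid, trigger_id = def$trigger_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(0), trigger_id = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$trigger_id, res$patient_id), ]
}

# Random small cohort generator for oracle-equivalence properties.
random_small_cohort <- function(n = 10) {
  ids <- sprintf("R%02d", seq_len(n))
  analytes <- names(analyte_units())
  labs <- data.frame(
    patient_id = sample(ids, 4 * n, replace = TRUE),
    analyte = sample(analytes, 4 * n, replace = TRUE),
    stringsAsFactors = FALSE)
  ranges <- list(K = c(2.5, 6), "NA" = c(130, 155), APTT = c(20, 60),
                 INR = c(0.8, 2), BG = c(2, 10), CK = c(50, 400),
                 BUN = c(3, 20), SCR = c(40, 200), ALT = c(5, 100),
                 AST = c(5, 100), ALP = c(30, 300), TBIL = c(5, 60),
                 WBC = c(1, 15), PLT = c(50, 400), TC = c(2, 9),
                 HGB = c(80, 200), TSH = c(0.1, 10), TH = c(40, 200),
                 DIGOXIN_CONC = c(0.5, 4), VANCO_CONC = c(2, 20),
                 GENTA_CONC = c(2, 20))
  labs$value <- vapply(labs$analyte, function(a) {
    r <- ranges[[a]]; round(stats::runif(1, r[1], r[2]), 2)
  }, 1)
  labs$unit <- unname(analyte_units()[labs$analyte])
  labs$observed_at <- "2023-06-02 08:00:00"
  med_pool <- c("VITK", "FLUMAZENIL", "NALOXONE", "MONTELUKAST", "PROTAMINE",
                "EPINEPHRINE", "GLYCEROL_ENEMA", "METOCLOPRAMIDE",
                "AMLODIPINE", "METFORMIN")
  meds <- data.frame(
    patient_id = sample(ids, 2 * n, replace = TRUE),
    drug_code = sample(med_pool, 2 * n, replace = TRUE),
    stringsAsFactors = FALSE)
  meds$drug_name <- tolower(meds$drug_code)
  meds$drug_class <- "other"
  meds$start <- "2023-06-02"; meds$stop <- "2023-06-04"
  events <- data.frame(
    patient_id = sample(ids, n, replace = TRUE),
    event_code = sample(event_codes(), n, replace = TRUE),
    observed_at = "2023-06-03 10:00:00", stringsAsFactors = FALSE)
  patients <- data.frame(
    patient_id = ids,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = sample(65:96, n, replace = TRUE),
    admit_date = "2023-06-01",
    discharge_date = as.character(as.Date("2023-06-01") + sample(2:20, n, TRUE)),
    conditions = "HTN;T2DM",
    n_medications = sample(5:30, n, replace = TRUE),
    stringsAsFactors = FALSE)
  new_cohort(patients, labs, meds, events)
}
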