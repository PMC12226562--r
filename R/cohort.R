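#' Canonical analytes and controlled vocabularies
#'
#' The screening engine operates on a closed set of laboratory analytes
#' (each with a single canonical reporting unit; no unit conversion is ever
#' performed), a closed clinical-event vocabulary, an eight-level drug-class
#' taxonomy and a ten-level organ-system taxonomy.
#'
#' @return `analyte_units()` returns a named character vector mapping analyte
#'   codes to canonical units; the other helpers return character vectors of
#'   allowed codes.
#' @export
analyte_units <- function() {
  c(K = "mmol/L", "NA" = "mmol/L", APTT = "s", INR = "ratio", BG = "mmol/L",
    CK = "U/L", BUN = "mmol/L", SCR = "umol/L", ALT = "U/L", AST = "U/L",
    ALP = "U/L", TBIL = "umol/L", WBC = "10^9/L", PLT = "10^9/L",
    TC = "mmol/L", HGB = "g/L", TSH = "mU/L", TH = "nmol/L",
    DIGOXIN_CONC = "ng/mL", VANCO_CONC = "mg/L", GENTA_CONC = "mg/L")
}

#' @rdname analyte_units
#' @export
event_codes <- function() {
  c("edema", "rash_itch", "agitation_cluster", "neuro_cluster",
    "cognitive_impairment", "dehydration", "urinary_retention", "joint_pain",
    "fall", "hypotension", "oversedation", "icu_transfer", "readmission_30d",
    "abrupt_discontinuation", "cdiff_positive_stool")
}

#' @rdname analyte_units
#' @export
drug_classes <- function() {
  c("cardiovascular", "blood_and_hematopoietic", "endocrine",
    "nervous_system", "systemic_anti_infective", "urinary", "digestive",
    "other")
}

#' @rdname analyte_units
#' @export
organ_systems <- function() {
  c("metabolic_nutritional", "hematologic_lymphatic", "other_edema",
    "cardiovascular", "gastrointestinal", "neurological", "skin_appendages",
    "hepatobiliary", "psychiatric", "musculoskeletal")
}

.cohort_schemas <- list(
  patients = c("patient_id", "sex", "age", "admit_date", "discharge_date",
               "conditions", "n_medications"),
  labs     = c("patient_id", "analyte", "value", "unit", "observed_at"),
  meds     = c("patient_id", "drug_code", "drug_name", "drug_class",
               "start", "stop"),
  events   = c("patient_id", "event_code", "observed_at")
)

.empty_table <- function(which) {
  cols <- .cohort_schemas[[which]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  if (which == "patients") {
    df$age <- integer(0); df$n_medications <- integer(0)
    df$admit_date <- as.Date(character(0))
    df$discharge_date <- as.Date(character(0))
  }
  if (which == "labs") df$value <- numeric(0)
  if (which == "meds") { df$start <- as.Date(character(0)); df$stop <- as.Date(character(0)) }
  df
}

.check_columns <- function(df, which) {
  missing <- setdiff(.cohort_schemas[[which]], names(df))
  if (length(missing)) {
    abort_adetrigger(
      sprintf("%s table is missing required column(s): %s", which,
              paste(missing, collapse = ", ")),
      "adetrigger_schema_error")
  }
  df[, .cohort_schemas[[which]], drop = FALSE]
}

#' Assemble a validated inpatient cohort
#'
#' A cohort is four linked tables: one row per admission in `patients`, and
#' long-format `labs`, `meds` and `events` keyed by `patient_id`. Structural
#' problems (missing columns, non-canonical laboratory units, unknown event
#' codes or drug classes, medication orders with `stop < start`) are hard
#' errors. Inclusion-criteria violations (age < 65, fewer than 2 chronic
#' conditions, too few medications, length of stay < 2 days, duplicated
#' patient ids) are rejected record-by-record: offending admissions are
#' removed from the cohort and itemised in `attr(cohort, "violations")`,
#' with a warning.
#'
#' @param patients,labs,meds,events data frames following the on-disk schema
#'   (see [read_cohort()]).
#' @param min_medications inclusion threshold on the recorded number of
#'   distinct medications (polypharmacy criterion).
#' @param strict_medications if `TRUE` the criterion is
#'   `n_medications > min_medications` rather than `>=`.
#' @return An object of class `gtt_cohort`.
#' @export
new_cohort <- function(patients, labs = NULL, meds = NULL, events = NULL,
                       min_medications = 5, strict_medications = FALSE) {
  labs <- labs %||% .empty_table("labs")
  meds <- meds %||% .empty_table("meds")
  events <- events %||% .empty_table("events")
  patients <- .check_columns(as.data.frame(patients), "patients")
  labs <- .check_columns(as.data.frame(labs), "labs")
  meds <- .check_columns(as.data.frame(meds), "meds")
  events <- .check_columns(as.data.frame(events), "events")

  patients$patient_id <- as.character(patients$patient_id)
  patients$sex <- as.character(patients$sex)
  patients$age <- as.integer(patients$age)
  patients$admit_date <- as.Date(patients$admit_date)
  patients$discharge_date <- as.Date(patients$discharge_date)
  patients$conditions <- as.character(patients$conditions)
  patients$n_medications <- as.integer(patients$n_medications)
  labs$patient_id <- as.character(labs$patient_id)
  labs$value <- as.numeric(labs$value)
  meds$patient_id <- as.character(meds$patient_id)
  meds$start <- as.Date(meds$start)
  meds$stop <- as.Date(meds$stop)
  events$patient_id <- as.character(events$patient_id)

  bad_sex <- !patients$sex %in% c("male", "female")
  if (any(bad_sex)) {
    abort_adetrigger(
      sprintf("invalid sex value(s): %s",
              paste(unique(patients$sex[bad_sex]), collapse = ", ")),
      "adetrigger_schema_error")
  }

  units <- analyte_units()
  known <- labs$analyte %in% names(units)
  if (any(known)) {
    expected <- unname(units[labs$analyte[known]])
    bad <- labs$unit[known] != expected
    if (any(bad)) {
      i <- which(known)[which(bad)[1]]
      abort_adetrigger(
        sprintf("non-canonical unit for analyte %s: found '%s', expected '%s'",
                labs$analyte[i], labs$unit[i], units[[labs$analyte[i]]]),
        "adetrigger_unit_error")
    }
  }
  if (any(!is.finite(labs$value)) || any(labs$value < 0)) {
    abort_adetrigger("laboratory values must be finite and non-negative",
                     "adetrigger_schema_error")
  }
  bad_event <- !events$event_code %in% event_codes()
  if (any(bad_event)) {
    abort_adetrigger(
      sprintf("unknown event code(s): %s",
              paste(unique(events$event_code[bad_event]), collapse = ", ")),
      "adetrigger_schema_error")
  }
  bad_class <- !meds$drug_class %in% drug_classes()
  if (any(bad_class)) {
    abort_adetrigger(
      sprintf("unknown drug class(es): %s",
              paste(unique(meds$drug_class[bad_class]), collapse = ", ")),
      "adetrigger_schema_error")
  }
  if (any(meds$stop < meds$start)) {
    abort_adetrigger("medication order with stop date before start date",
                     "adetrigger_schema_error")
  }

  los <- as.integer(patients$discharge_date - patients$admit_date)
  n_cond <- lengths(strsplit(patients$conditions, ";", fixed = TRUE))
  n_cond[!nzchar(patients$conditions)] <- 0L
  med_ok <- if (strict_medications) patients$n_medications > min_medications
            else patients$n_medications >= min_medications

  viol_entry <- function(bad, rule, values) {
    data.frame(patient_id = patients$patient_id[bad], rule = rep(rule, sum(bad)),
               value = as.character(values)[bad], stringsAsFactors = FALSE)
  }
  viol <- rbind(
    viol_entry(patients$age < 65, "age >= 65", patients$age),
    viol_entry(n_cond < 2, ">= 2 chronic conditions", n_cond),
    viol_entry(!med_ok,
               sprintf("n_medications %s %d",
                       if (strict_medications) ">" else ">=", min_medications),
               patients$n_medications),
    viol_entry(los < 2, "length of stay >= 2 days", los),
    viol_entry(duplicated(patients$patient_id), "unique patient_id",
               patients$patient_id))
  rownames(viol) <- NULL

  if (nrow(viol)) {
    drop_ids <- unique(viol$patient_id)
    warning(sprintf(
      "%d admission(s) rejected for inclusion-criteria violations (see attr(cohort, 'violations')): %s",
      length(drop_ids), paste(utils::head(drop_ids, 5), collapse = ", ")),
      call. = FALSE)
    keep <- !patients$patient_id %in% drop_ids
    patients <- patients[keep, , drop = FALSE]
    labs <- labs[labs$patient_id %in% patients$patient_id, , drop = FALSE]
    meds <- meds[meds$patient_id %in% patients$patient_id, , drop = FALSE]
    events <- events[events$patient_id %in% patients$patient_id, , drop = FALSE]
  }

  orphan <- setdiff(c(labs$patient_id, meds$patient_id, events$patient_id),
                    patients$patient_id)
  if (length(orphan)) {
    abort_adetrigger(
      sprintf("records reference unknown patient id(s): %s",
              paste(utils::head(orphan, 5), collapse = ", ")),
      "adetrigger_schema_error")
  }

  rownames(patients) <- rownames(labs) <- rownames(meds) <- rownames(events) <- NULL
  structure(
    list(patients = patients, labs = labs, meds = meds, events = events),
    violations = viol,
    class = "gtt_cohort")
}

#' Read and write a cohort in the on-disk schema
#'
#' The delimited format is a directory of four UTF-8 tab-separated tables
#' with header rows (`patients.tsv`, `labs.tsv`, `meds.tsv`, `events.tsv`);
#' dates are ISO-8601 and chronic conditions are semicolon-joined codes. The
#' structured-record format is a single JSON file with the same fields
#' nested per patient.
#'
#' @param path directory (delimited) or file (json).
#' @param format `"delimited"` or `"json"`.
#' @param ... passed to [new_cohort()] (inclusion-threshold switches).
#' @return [read_cohort()] returns a validated `gtt_cohort`;
#'   [write_cohort()] returns `path` invisibly.
#' @export
read_cohort <- function(path, format = c("delimited", "json"), ...) {
  format <- match.arg(format)
  if (format == "delimited") {
    files <- file.path(path, paste0(names(.cohort_schemas), ".tsv"))
    names(files) <- names(.cohort_schemas)
    if (!file.exists(files[["patients"]])) {
      abort_adetrigger(sprintf("patients table not found at %s", files[["patients"]]),
                       "adetrigger_schema_error")
    }
    tabs <- lapply(names(files), function(nm) {
      f <- files[[nm]]
      if (!file.exists(f)) return(.empty_table(nm))
      df <- tryCatch(
        utils::read.delim(f, colClasses = "character",
                          na.strings = character(0), check.names = FALSE),
        error = function(e) abort_adetrigger(
          sprintf("cannot parse %s: %s", f, conditionMessage(e)),
          "adetrigger_schema_error"))
      if (nrow(df) == 0 && ncol(df) == 0) {
        abort_adetrigger(sprintf("%s is empty (no header row)", f),
                         "adetrigger_schema_error")
      }
      df
    })
    names(tabs) <- names(files)
    if (nrow(tabs$patients) == 0) {
      abort_adetrigger("patients table contains no records",
                       "adetrigger_schema_error")
    }
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)$patients
    if (is.null(recs) || NROW(recs) == 0) {
      abort_adetrigger("no patient records in structured-record file",
                       "adetrigger_schema_error")
    }
    unnest <- function(field) {
      parts <- recs[[field]]
      keep <- vapply(parts, NROW, 1L) > 0
      if (!any(keep)) return(.empty_table(field))
      out <- do.call(rbind, lapply(which(keep), function(i) {
        cbind(patient_id = recs$patient_id[i], parts[[i]],
              stringsAsFactors = FALSE)
      }))
      out
    }
    pts <- recs[, .cohort_schemas$patients, drop = FALSE]
    tabs <- list(patients = pts, labs = unnest("labs"),
                 meds = unnest("meds"), events = unnest("events"))
  }
  new_cohort(tabs$patients, tabs$labs, tabs$meds, tabs$events, ...)
}

#' @rdname read_cohort
#' @param cohort a `gtt_cohort`.
#' @export
write_cohort <- function(cohort, path, format = c("delimited", "json")) {
  stopifnot(inherits(cohort, "gtt_cohort"))
  format <- match.arg(format)
  if (format == "delimited") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(.cohort_schemas)) {
      utils::write.table(cohort[[nm]], file.path(path, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
    }
  } else {
    pts <- cohort$patients
    nested <- lapply(seq_len(nrow(pts)), function(i) {
      id <- pts$patient_id[i]
      rec <- as.list(pts[i, , drop = FALSE])
      rec$admit_date <- as.character(rec$admit_date)
      rec$discharge_date <- as.character(rec$discharge_date)
      rec$labs <- cohort$labs[cohort$labs$patient_id == id,
                              setdiff(.cohort_schemas$labs, "patient_id")]
      m <- cohort$meds[cohort$meds$patient_id == id,
                       setdiff(.cohort_schemas$meds, "patient_id")]
      m$start <- as.character(m$start); m$stop <- as.character(m$stop)
      rec$meds <- m
      rec$events <- cohort$events[cohort$events$patient_id == id,
                                  setdiff(.cohort_schemas$events, "patient_id")]
      rec
    })
    jsonlite::write_json(list(patients = nested), path, auto_unbox = TRUE,
                         dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' Length of stay per admission
#'
#' Whole days between admission and discharge (calendar-date difference).
#' @param cohort a `gtt_cohort`.
#' @return integer vector aligned with `cohort$patients`.
#' @export
length_of_stay <- function(cohort) {
  as.integer(cohort$patients$discharge_date - cohort$patients$admit_date)
}

#' Summarise a cohort
#'
#' Counts, central tendency and ranges for the demographic and utilisation
#' variables, total patient-days (the exact sum of lengths of stay, the
#' denominator of the per-1,000-patient-days ADE rate) and the multi-label
#' chronic-condition frequency table. Means are reported half-up to 2
#' decimals.
#'
#' @param cohort a `gtt_cohort`.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "gtt_cohort"))
  pts <- cohort$patients
  if (nrow(pts) == 0) {
    abort_adetrigger("cannot summarise an empty cohort",
                     "adetrigger_empty_cohort_error")
  }
  los <- length_of_stay(cohort)
  conds <- unlist(strsplit(pts$conditions, ";", fixed = TRUE))
  cond_freq <- sort(table(conds), decreasing = TRUE)
  out <- list(
    n_patients = nrow(pts),
    sex = c(male = sum(pts$sex == "male"), female = sum(pts$sex == "female")),
    age = c(mean = round_half_up(mean(pts$age), 2),
            min = min(pts$age), max = max(pts$age)),
    los = c(mean = round_half_up(mean(los), 2),
            min = min(los), max = max(los)),
    medications = c(mean = round_half_up(mean(pts$n_medications), 2),
                    min = min(pts$n_medications), max = max(pts$n_medications)),
    patient_days = sum(los),
    conditions = as.data.frame(cond_freq, responseName = "n",
                               stringsAsFactors = FALSE)
  )
  names(out$conditions)[1] <- "condition"
  structure(out, class = "cohort_summary")
}

#' @export
print.gtt_cohort <- function(x, ...) {
  cat(sprintf("<gtt_cohort> %d admissions | %d lab results | %d medication orders | %d clinical events\n",
              nrow(x$patients), nrow(x$labs), nrow(x$meds), nrow(x$events)))
  v <- attr(x, "violations")
  if (!is.null(v) && nrow(v)) {
    cat(sprintf("  %d record(s) rejected at validation\n", nrow(v)))
  }
  invisible(x)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  admissions:    %d (male %d / female %d)\n",
              x$n_patients, x$sex[["male"]], x$sex[["female"]]))
  cat(sprintf("  age (years):   mean %.2f, range %d-%d\n",
              x$age[["mean"]], x$age[["min"]], x$age[["max"]]))
  cat(sprintf("  stay (days):   mean %.2f, range %d-%d; total patient-days %d\n",
              x$los[["mean"]], x$los[["min"]], x$los[["max"]], x$patient_days))
  cat(sprintf("  medications:   mean %.2f, range %d-%d\n",
              x$medications[["mean"]], x$medications[["min"]],
              x$medications[["max"]]))
  cat(sprintf("  chronic conditions: %d distinct codes\n", nrow(x$conditions)))
  invisible(x)
}
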