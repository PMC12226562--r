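#' Load a trigger set
#'
#' Triggers are declarative screening rules. Each has an integer id, a
#' category (`lab_threshold`, `medication_use`, `antidote_use`, `symptom`,
#' `outcome`, `tdm`), and a predicate built from atoms: laboratory
#' comparisons (analyte, strict or non-strict comparator, threshold,
#' optional sex restriction), medication-use atoms (any administration of a
#' listed drug code during the stay), clinical-event atoms, and
#' therapeutic-drug-monitoring atoms. Compound predicates combine atoms with
#' `any_of` (any abnormal signal fires the trigger) or `all_of` (the full
#' biochemical pattern must be present, e.g. the paired TSH/thyroid-hormone
#' rules).
#'
#' `"default"` loads the packaged 38-rule registry tuned for elderly
#' multimorbid inpatients; a user YAML file with the same layout may add,
#' remove or re-tune rules without code changes.
#'
#' @param config `"default"` or path to a YAML trigger file.
#' @return An object of class `trigger_set` (a named list of definitions).
#' @export
load_trigger_set <- function(config = "default") {
  path <- if (identical(config, "default")) {
    system.file("extdata", "triggers_default.yaml", package = "adetrigger",
                mustWork = TRUE)
  } else config
  if (!file.exists(path)) {
    abort_adetrigger(sprintf("trigger config not found: %s", path),
                     "adetrigger_config_error")
  }
  raw <- yaml::read_yaml(path)$triggers
  if (is.null(raw) || !length(raw)) {
    abort_adetrigger("trigger config contains no triggers",
                     "adetrigger_config_error")
  }
  ids <- vapply(raw, function(t) as.integer(t$id), 1L)
  if (anyDuplicated(ids)) {
    abort_adetrigger(
      sprintf("duplicate trigger id(s): %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "adetrigger_config_error")
  }
  cats <- c("lab_threshold", "medication_use", "antidote_use", "symptom",
            "outcome", "tdm")
  units <- analyte_units()
  defs <- lapply(raw, function(t) {
    if (!t$category %in% cats) {
      abort_adetrigger(sprintf("trigger %s: unknown category '%s'",
                               t$id, t$category),
                       "adetrigger_config_error")
    }
    comb <- t$predicate$combinator %||% "atom"
    if (!comb %in% c("atom", "any_of", "all_of")) {
      abort_adetrigger(sprintf("trigger %s: unknown combinator '%s'",
                               t$id, comb),
                       "adetrigger_config_error")
    }
    atoms <- lapply(t$predicate$atoms, function(a) {
      kind <- a$kind %||% ""
      if (kind %in% c("lab", "tdm")) {
        if (!a$analyte %in% names(units)) {
          abort_adetrigger(sprintf("trigger %s: unknown analyte '%s'",
                                   t$id, a$analyte),
                           "adetrigger_config_error")
        }
        if (!a$op %in% c("<", ">", "<=", ">=")) {
          abort_adetrigger(sprintf("trigger %s: invalid comparator '%s'",
                                   t$id, a$op),
                           "adetrigger_config_error")
        }
        list(kind = kind, analyte = a$analyte, op = a$op,
             threshold = as.numeric(a$threshold),
             unit = a$unit %||% unname(units[[a$analyte]]),
             sex = a$sex %||% NA_character_)
      } else if (kind == "med") {
        list(kind = "med", drugs = as.character(unlist(a$drugs)))
      } else if (kind == "event") {
        if (!a$event %in% event_codes()) {
          abort_adetrigger(sprintf("trigger %s: unknown event code '%s'",
                                   t$id, a$event),
                           "adetrigger_config_error")
        }
        list(kind = "event", event = a$event)
      } else {
        abort_adetrigger(sprintf("trigger %s: unknown atom kind '%s'",
                                 t$id, kind),
                         "adetrigger_config_error")
      }
    })
    if (!length(atoms)) {
      abort_adetrigger(sprintf("trigger %s has no atoms", t$id),
                       "adetrigger_config_error")
    }
    list(trigger_id = as.integer(t$id), name = t$name,
         category = t$category,
         interpretation = t$interpretation %||% "",
         combinator = comb, atoms = atoms)
  })
  names(defs) <- as.character(ids)
  structure(defs[order(ids)], class = "trigger_set")
}

#' @export
print.trigger_set <- function(x, ...) {
  cat(sprintf("<trigger_set> %d triggers\n", length(x)))
  for (t in x) {
    cat(sprintf("  [%2d] %-12s %s\n", t$trigger_id, t$category, t$name))
  }
  invisible(x)
}

.compare <- function(values, op, threshold) {
  switch(op,
         "<"  = values <  threshold,
         ">"  = values >  threshold,
         "<=" = values <= threshold,
         ">=" = values >= threshold)
}

# Per-atom satisfying records across the whole cohort. Returns a data frame
# (patient_id, evidence, observed_at), at most one row per patient (the
# earliest satisfying record; ties broken by row order).
.atom_hits <- function(atom, cohort) {
  if (atom$kind %in% c("lab", "tdm")) {
    labs <- cohort$labs
    rows <- labs$analyte == atom$analyte & .compare(labs$value, atom$op, atom$threshold)
    if (!is.na(atom$sex)) {
      sex <- cohort$patients$sex[match(labs$patient_id, cohort$patients$patient_id)]
      rows <- rows & sex == atom$sex
    }
    hits <- labs[rows, , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    hits$evidence <- sprintf("%s=%g %s", hits$analyte, hits$value, hits$unit)
  } else if (atom$kind == "med") {
    meds <- cohort$meds
    hits <- meds[meds$drug_code %in% atom$drugs, , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    hits$evidence <- sprintf("med:%s", hits$drug_code)
    hits$observed_at <- as.character(hits$start)
  } else {
    ev <- cohort$events
    hits <- ev[ev$event_code == atom$event, , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    hits$evidence <- sprintf("event:%s", hits$event_code)
  }
  hits <- hits[order(hits$patient_id, hits$observed_at), , drop = FALSE]
  hits <- hits[!duplicated(hits$patient_id), , drop = FALSE]
  data.frame(patient_id = hits$patient_id, evidence = hits$evidence,
             observed_at = as.character(hits$observed_at),
             stringsAsFactors = FALSE)
}

# All patients firing one trigger, with evidence. any_of keeps the earliest
# firing atom per patient; all_of requires every atom and reports the
# completing (latest) observation with concatenated evidence.
.trigger_hits <- function(def, cohort) {
  per_atom <- lapply(def$atoms, .atom_hits, cohort = cohort)
  per_atom <- per_atom[!vapply(per_atom, is.null, TRUE)]
  if (!length(per_atom)) return(NULL)
  if (def$combinator == "all_of") {
    if (length(per_atom) < length(def$atoms)) return(NULL)
    ids <- Reduce(intersect, lapply(per_atom, `[[`, "patient_id"))
    if (!length(ids)) return(NULL)
    out <- do.call(rbind, lapply(ids, function(id) {
      rows <- lapply(per_atom, function(a) a[a$patient_id == id, , drop = FALSE])
      data.frame(
        patient_id = id,
        evidence = paste(vapply(rows, `[[`, "", "evidence"), collapse = "; "),
        observed_at = max(vapply(rows, `[[`, "", "observed_at")),
        stringsAsFactors = FALSE)
    }))
  } else {
    all_rows <- do.call(rbind, per_atom)
    all_rows <- all_rows[order(all_rows$patient_id, all_rows$observed_at), ,
                         drop = FALSE]
    out <- all_rows[!duplicated(all_rows$patient_id), , drop = FALSE]
  }
  out$trigger_id <- def$trigger_id
  out[, c("patient_id", "trigger_id", "evidence", "observed_at")]
}

#' Screen a cohort for positive triggers
#'
#' Evaluates every trigger over every admission. A laboratory or TDM atom
#' fires if any in-stay result satisfies its comparison (strict comparators
#' as configured; boundary values do not fire); a medication atom fires on
#' any administration of a listed drug during the stay; sex-restricted atoms
#' are evaluated against the patient's sex. A trigger counts at most once
#' per admission regardless of how many records satisfy it. Laboratory
#' results for analytes outside the canonical registry are ignored with a
#' warning; screening never aborts on extraneous data.
#'
#' @param cohort a `gtt_cohort`.
#' @param triggers a `trigger_set` (default: the packaged registry).
#' @return An object of class `screen_result` with elements `hits`
#'   (patient_id, trigger_id, evidence, observed_at), `per_trigger`
#'   (trigger_id, name, category, positives), `patient_positive` (named
#'   logical over all patients) and `positive_rate` (trigger-positive
#'   patients / all patients).
#' @export
screen_cohort <- function(cohort, triggers = load_trigger_set("default")) {
  stopifnot(inherits(cohort, "gtt_cohort"), inherits(triggers, "trigger_set"))
  if (nrow(cohort$patients) == 0) {
    abort_adetrigger("cannot screen an empty cohort",
                     "adetrigger_empty_cohort_error")
  }
  unknown <- setdiff(unique(cohort$labs$analyte), names(analyte_units()))
  if (length(unknown)) {
    warning(sprintf("ignoring lab results for unknown analyte(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  hit_list <- lapply(triggers, .trigger_hits, cohort = cohort)
  hit_list <- hit_list[!vapply(hit_list, is.null, TRUE)]
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    data.frame(patient_id = character(0), trigger_id = integer(0),
               evidence = character(0), observed_at = character(0),
               stringsAsFactors = FALSE)
  hits <- hits[order(hits$trigger_id, hits$patient_id), , drop = FALSE]
  rownames(hits) <- NULL

  ids <- vapply(triggers, `[[`, 1L, "trigger_id")
  per_trigger <- data.frame(
    trigger_id = ids,
    name = vapply(triggers, `[[`, "", "name"),
    category = vapply(triggers, `[[`, "", "category"),
    positives = vapply(ids, function(i) sum(hits$trigger_id == i), 1L),
    stringsAsFactors = FALSE, row.names = NULL)

  all_ids <- cohort$patients$patient_id
  patient_positive <- setNames(all_ids %in% hits$patient_id, all_ids)
  structure(
    list(hits = hits, per_trigger = per_trigger,
         patient_positive = patient_positive,
         positive_rate = mean(patient_positive)),
    class = "screen_result")
}

#' Evaluate a single admission against a trigger set
#'
#' @param cohort a `gtt_cohort` containing the patient.
#' @param patient_id the admission to evaluate.
#' @param triggers a `trigger_set`.
#' @return The hits data frame for that admission (possibly zero rows).
#' @export
evaluate_patient <- function(cohort, patient_id,
                             triggers = load_trigger_set("default")) {
  stopifnot(inherits(cohort, "gtt_cohort"))
  if (!patient_id %in% cohort$patients$patient_id) {
    abort_adetrigger(sprintf("unknown patient id: %s", patient_id),
                     "adetrigger_schema_error")
  }
  sub <- structure(list(
    patients = cohort$patients[cohort$patients$patient_id == patient_id, ,
                               drop = FALSE],
    labs = cohort$labs[cohort$labs$patient_id == patient_id, , drop = FALSE],
    meds = cohort$meds[cohort$meds$patient_id == patient_id, , drop = FALSE],
    events = cohort$events[cohort$events$patient_id == patient_id, ,
                           drop = FALSE]),
    class = "gtt_cohort")
  suppressWarnings(screen_cohort(sub, triggers)$hits)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d hits | %d/%d trigger-positive patients (%.2f%%)\n",
              nrow(x$hits), sum(x$patient_positive),
              length(x$patient_positive), 100 * x$positive_rate))
  pos <- x$per_trigger[x$per_trigger$positives > 0, ]
  pos <- pos[order(-pos$positives), ]
  for (i in seq_len(min(5, nrow(pos)))) {
    cat(sprintf("  [%2d] %-55s %3d\n", pos$trigger_id[i],
                substr(pos$name[i], 1, 55), pos$positives[i]))
  }
  if (nrow(pos) > 5) cat(sprintf("  ... and %d more positive triggers\n", nrow(pos) - 5))
  invisible(x)
}
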