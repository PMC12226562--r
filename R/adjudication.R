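#' Naranjo causality score
#'
#' Scores the 10-item Naranjo adverse-drug-reaction probability scale with
#' the canonical published item weights: Q1 yes +1; Q2 yes +2 / no -1;
#' Q3 yes +1; Q4 yes +2 / no -1; Q5 yes -1 / no +2; Q6 yes -1 / no +1;
#' Q7-Q10 yes +1; "unknown" (do not know) scores 0 everywhere, as do "no"
#' answers on items without a listed no-weight. The total lies in [-4, 13].
#'
#' @param answers character vector of exactly 10 answers, each one of
#'   `"yes"`, `"no"`, `"unknown"`.
#' @return integer score.
#' @export
naranjo_score <- function(answers) {
  if (length(answers) != 10) {
    abort_adetrigger(sprintf("Naranjo assessment requires exactly 10 answers, got %d",
                             length(answers)),
                     "adetrigger_arity_error")
  }
  answers <- tolower(as.character(answers))
  bad <- !answers %in% c("yes", "no", "unknown")
  if (any(bad)) {
    abort_adetrigger(sprintf("invalid Naranjo answer(s): %s",
                             paste(unique(answers[bad]), collapse = ", ")),
                     "adetrigger_arity_error")
  }
  w_yes <- c(1, 2, 1, 2, -1, -1, 1, 1, 1, 1)
  w_no  <- c(0, -1, 0, -1, 2, 1, 0, 0, 0, 0)
  as.integer(sum(w_yes[answers == "yes"]) + sum(w_no[answers == "no"]))
}

#' Naranjo causality category
#'
#' Maps a Naranjo score to its causality category: definite (score >= 9),
#' probable (5-8), possible (1-4), doubtful (<= 0). Doubtful events are
#' considered non-drug-related and are excluded from ADE analyses.
#'
#' @param score integer score(s).
#' @return character vector of categories.
#' @export
naranjo_category <- function(score) {
  stopifnot(is.numeric(score))
  ifelse(score >= 9, "definite",
         ifelse(score >= 5, "probable",
                ifelse(score >= 1, "possible", "doubtful")))
}

#' Read an adjudication table
#'
#' One row per candidate ADE: `patient_id`, `suspect_drug`, `drug_class`,
#' `organ_system`, `grade` (NCC MERP E-I), `linked_trigger_ids`
#' (semicolon-joined, possibly empty) and the ten Naranjo answers
#' `q1`..`q10`.
#'
#' @param path a tab-delimited UTF-8 file with header.
#' @return data frame.
#' @export
read_adjudication <- function(path) {
  if (!file.exists(path)) {
    abort_adetrigger(sprintf("adjudication file not found: %s", path),
                     "adetrigger_schema_error")
  }
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = character(0), check.names = FALSE)
  need <- c("patient_id", "suspect_drug", "drug_class", "organ_system",
            "grade", "linked_trigger_ids", paste0("q", 1:10))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_adetrigger(sprintf("adjudication file is missing column(s): %s",
                             paste(missing, collapse = ", ")),
                     "adetrigger_schema_error")
  }
  df[, need, drop = FALSE]
}

#' @rdname read_adjudication
#' @param adjudication an adjudication data frame.
#' @export
write_adjudication <- function(adjudication, path) {
  utils::write.table(adjudication, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble adjudicated ADE records
#'
#' Joins the review panel's adjudication table to a screened cohort:
#' computes each candidate's Naranjo score and category, validates the NCC
#' MERP grade (E-I only; A-D involve no substantive harm and are out of
#' scope), the drug-class and organ-system codes, patient membership, and
#' the consistency of trigger links (every linked trigger must be a
#' screening hit of that patient). Doubtful candidates (score <= 0) are
#' excluded from the ADE list but retained in an audit list.
#'
#' @param cohort a `gtt_cohort`.
#' @param screen a `screen_result` for the same cohort.
#' @param adjudication data frame from [read_adjudication()] (or built in
#'   code with the same columns).
#' @return An object of class `adjudicated_cohort`: `ades` (non-doubtful
#'   records with `score`, `category` and parsed `linked_trigger_ids`),
#'   `doubtful` (audit list), and `per_patient` (ADE counts per patient).
#' @export
build_ade_records <- function(cohort, screen, adjudication) {
  stopifnot(inherits(cohort, "gtt_cohort"), inherits(screen, "screen_result"))
  adj <- as.data.frame(adjudication, stringsAsFactors = FALSE)

  bad_grade <- !adj$grade %in% c("E", "F", "G", "H", "I")
  if (any(bad_grade)) {
    abort_adetrigger(sprintf("severity grade outside E-I: %s",
                             paste(unique(adj$grade[bad_grade]), collapse = ", ")),
                     "adetrigger_validation_error")
  }
  bad_class <- !adj$drug_class %in% drug_classes()
  if (any(bad_class)) {
    abort_adetrigger(sprintf("unknown drug class: %s",
                             paste(unique(adj$drug_class[bad_class]), collapse = ", ")),
                     "adetrigger_validation_error")
  }
  bad_organ <- !adj$organ_system %in% organ_systems()
  if (any(bad_organ)) {
    abort_adetrigger(sprintf("unknown organ system: %s",
                             paste(unique(adj$organ_system[bad_organ]), collapse = ", ")),
                     "adetrigger_validation_error")
  }
  bad_pt <- !adj$patient_id %in% cohort$patients$patient_id
  if (any(bad_pt)) {
    abort_adetrigger(sprintf("adjudication references unknown patient(s): %s",
                             paste(unique(adj$patient_id[bad_pt]), collapse = ", ")),
                     "adetrigger_validation_error")
  }

  qcols <- paste0("q", 1:10)
  adj$score <- vapply(seq_len(nrow(adj)), function(i) {
    naranjo_score(unlist(adj[i, qcols], use.names = FALSE))
  }, 1L)
  adj$category <- naranjo_category(adj$score)

  links <- strsplit(adj$linked_trigger_ids, ";", fixed = TRUE)
  links <- lapply(links, function(x) as.integer(x[nzchar(x)]))
  hit_key <- paste(screen$hits$patient_id, screen$hits$trigger_id)
  for (i in seq_along(links)) {
    if (length(links[[i]])) {
      missing <- setdiff(paste(adj$patient_id[i], links[[i]]), hit_key)
      if (length(missing)) {
        abort_adetrigger(
          sprintf("adjudication row %d links trigger(s) with no screening hit for patient %s: %s",
                  i, adj$patient_id[i],
                  paste(sub("^\\S+ ", "", missing), collapse = ", ")),
          "adetrigger_consistency_error")
      }
    }
  }
  adj$linked_trigger_ids <- I(links)

  keep <- adj$category != "doubtful"
  ades <- adj[keep, , drop = FALSE]
  doubtful <- adj[!keep, , drop = FALSE]
  rownames(ades) <- rownames(doubtful) <- NULL

  counts <- table(factor(ades$patient_id, levels = cohort$patients$patient_id))
  per_patient <- data.frame(patient_id = names(counts),
                            n_ades = as.integer(counts),
                            stringsAsFactors = FALSE)

  structure(list(cohort = cohort, ades = ades, doubtful = doubtful,
                 per_patient = per_patient),
            class = "adjudicated_cohort")
}

#' @export
print.adjudicated_cohort <- function(x, ...) {
  n_pat <- sum(x$per_patient$n_ades > 0)
  cat(sprintf("<adjudicated_cohort> %d ADEs in %d patients (%d doubtful candidates excluded)\n",
              nrow(x$ades), n_pat, nrow(x$doubtful)))
  if (nrow(x$ades)) {
    tb <- table(x$ades$category)
    cat("  causality:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "), "\n")
    tg <- table(x$ades$grade)
    cat("  severity: ", paste(sprintf("%s %d", names(tg), tg), collapse = ", "), "\n")
  }
  invisible(x)
}
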