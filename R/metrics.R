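#' Trigger-positivity by ADE-status contingency table
#'
#' Cross-classifies every admission by trigger positivity (at least one
#' positive trigger) and ADE status (at least one non-doubtful ADE).
#'
#' @param screen a `screen_result`.
#' @param adjudicated an `adjudicated_cohort` on the same cohort.
#' @return An object of class `two_by_two` with integer fields `tp`
#'   (trigger-positive with ADE), `fp` (trigger-positive without), `fn`
#'   (trigger-negative with ADE) and `tn` (neither).
#' @export
two_by_two <- function(screen, adjudicated) {
  stopifnot(inherits(screen, "screen_result"),
            inherits(adjudicated, "adjudicated_cohort"))
  ids <- names(screen$patient_positive)
  ade <- adjudicated$per_patient$n_ades[match(ids, adjudicated$per_patient$patient_id)] > 0
  pos <- screen$patient_positive
  new_two_by_two(sum(pos & ade), sum(pos & !ade), sum(!pos & ade), sum(!pos & !ade))
}

#' @rdname two_by_two
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @export
new_two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("trigger+", "trigger-"), c("ADE+", "ADE-")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
         dimnames = list(c("trigger_pos", "trigger_neg"), c("ade", "no_ade")))
}

#' Screening-test evaluation of trigger positivity against adjudicated ADEs
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, compliance
#' rate (overall accuracy) `(tp+tn)/N`, Cohen's unweighted kappa and the
#' patient-level positive predictive value `tp/(tp+fp)`. All quantities are
#' evaluated in exact integer arithmetic; the `percent` element carries each
#' metric on the 0-100 scale rounded half-up to 2 decimals. A metric whose
#' denominator is zero is `NA` and flagged in `undefined`.
#'
#' @param table a `two_by_two`.
#' @return An object of class `screening_evaluation`.
#' @export
evaluate_screening <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n <- tp + fp + fn + tn
  if (n == 0) {
    abort_adetrigger("empty contingency table", "adetrigger_degenerate_table_error")
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  rpct <- function(num, den) if (den > 0) pct2(num, den) else NA_real_

  pe_num <- (tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)
  kappa_num <- n * (tp + tn) - pe_num
  kappa_den <- n^2 - pe_num

  out <- list(
    table = table,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    compliance = ratio(tp + tn, n),
    kappa = if (kappa_den != 0) kappa_num / kappa_den else NA_real_,
    ppv_patient = ratio(tp, tp + fp))
  out$percent <- c(
    sensitivity = rpct(tp, tp + fn),
    specificity = rpct(tn, tn + fp),
    compliance = rpct(tp + tn, n),
    kappa = if (kappa_den != 0) rational_round(100 * kappa_num, kappa_den, 2) else NA_real_,
    ppv_patient = rpct(tp, tp + fp))
  out$undefined <- names(out$percent)[is.na(out$percent)]
  structure(out, class = "screening_evaluation")
}

#' @export
print.screening_evaluation <- function(x, ...) {
  cat("Screening evaluation (trigger positivity vs adjudicated ADE status)\n")
  lbl <- c(sensitivity = "Sensitivity", specificity = "Specificity",
           compliance = "Compliance rate", kappa = "Cohen's kappa",
           ppv_patient = "PPV (patient-level)")
  for (nm in names(lbl)) {
    v <- x$percent[[nm]]
    cat(sprintf("  %-20s %s\n", lbl[[nm]],
                if (is.na(v)) "undefined (zero denominator)" else sprintf("%.2f%%", v)))
  }
  invisible(x)
}

#' GTT rate report
#'
#' The three standard trigger-tool rates: ADEs per 1,000 patient-days
#' (`1000 * n_ades / patient_days`), ADEs per 100 admissions
#' (`100 * n_ades / n_patients`), and the patient-level ADE incidence
#' (`n_ade_patients / n_patients`). Reported values are rounded half-up to
#' 2 decimals; `incidence_pct` is on the percentage scale.
#'
#' @param n_ades number of adjudicated ADE events.
#' @param n_ade_patients number of patients with at least one ADE.
#' @param n_patients cohort size.
#' @param patient_days total patient-days (sum of lengths of stay).
#' @return An object of class `rate_report`.
#' @export
compute_rates <- function(n_ades, n_ade_patients, n_patients, patient_days) {
  if (n_patients <= 0 || patient_days <= 0) {
    abort_adetrigger("rate denominators must be positive",
                     "adetrigger_degenerate_table_error")
  }
  if (n_ade_patients > n_patients) {
    abort_adetrigger("more ADE patients than patients",
                     "adetrigger_validation_error")
  }
  structure(list(
    n_ades = n_ades, n_ade_patients = n_ade_patients,
    n_patients = n_patients, patient_days = patient_days,
    per_1000_patient_days = rational_round(1000 * n_ades, patient_days, 2),
    per_100_patients = rational_round(100 * n_ades, n_patients, 2),
    incidence = n_ade_patients / n_patients,
    incidence_pct = pct2(n_ade_patients, n_patients)),
    class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat("GTT rates\n")
  cat(sprintf("  ADEs / 1,000 patient-days: %.2f  (%d/%d)\n",
              x$per_1000_patient_days, x$n_ades, x$patient_days))
  cat(sprintf("  ADEs / 100 admissions:     %.2f  (%d/%d)\n",
              x$per_100_patients, x$n_ades, x$n_patients))
  cat(sprintf("  ADE incidence:             %.2f%% (%d/%d)\n",
              x$incidence_pct, x$n_ade_patients, x$n_patients))
  invisible(x)
}

#' Per-trigger performance table
#'
#' For each trigger: positive firings, ADE cases (screening hits of that
#' trigger that are linked to at least one non-doubtful ADE) and the
#' per-trigger positive predictive value `ade_cases/positives` as a
#' percentage. Triggers with zero positives report a PPV of 0.00 with a
#' zero-denominator flag. The overall row divides total ADE cases by total
#' positive firings.
#'
#' @param screen a `screen_result`.
#' @param adjudicated an `adjudicated_cohort`.
#' @return An object of class `trigger_performance`: `per_trigger` data
#'   frame plus `overall` (positives, ade_cases, ppv_pct).
#' @export
trigger_performance <- function(screen, adjudicated) {
  stopifnot(inherits(screen, "screen_result"),
            inherits(adjudicated, "adjudicated_cohort"))
  ades <- adjudicated$ades
  linked <- if (nrow(ades)) {
    unique(do.call(rbind, lapply(seq_len(nrow(ades)), function(i) {
      tid <- ades$linked_trigger_ids[[i]]
      if (!length(tid)) return(NULL)
      data.frame(patient_id = ades$patient_id[i], trigger_id = tid,
                 stringsAsFactors = FALSE)
    })))
  } else NULL

  per <- screen$per_trigger
  per$ade_cases <- if (is.null(linked)) 0L else
    vapply(per$trigger_id, function(t) sum(linked$trigger_id == t), 1L)
  bad <- per$ade_cases > per$positives
  if (any(bad)) {
    abort_adetrigger(
      sprintf("trigger(s) with more ADE cases than positive firings: %s",
              paste(per$trigger_id[bad], collapse = ", ")),
      "adetrigger_consistency_error")
  }
  per$ppv_pct <- ifelse(per$positives > 0,
                        rational_round(100 * per$ade_cases,
                                       pmax(per$positives, 1), 2), 0)
  per$zero_denominator <- per$positives == 0

  tot_pos <- sum(per$positives); tot_ade <- sum(per$ade_cases)
  overall <- list(positives = tot_pos, ade_cases = tot_ade,
                  ppv_pct = if (tot_pos > 0) pct2(tot_ade, tot_pos) else 0,
                  zero_denominator = tot_pos == 0)
  structure(list(per_trigger = per, overall = overall),
            class = "trigger_performance")
}

#' @export
print.trigger_performance <- function(x, ...) {
  cat(sprintf("Trigger performance: %d positives, %d ADE cases, overall PPV %.2f%%\n",
              x$overall$positives, x$overall$ade_cases, x$overall$ppv_pct))
  invisible(x)
}

#' Severity, drug-class and organ-system distributions of ADEs
#'
#' Counts and percentages over all non-doubtful ADE events for the NCC MERP
#' grade, the eight-class drug taxonomy and the ten-level organ-system
#' taxonomy. Percentages use the total ADE count as denominator and are
#' rounded half-up to 2 decimals.
#'
#' @param adjudicated an `adjudicated_cohort` with at least one ADE.
#' @return A list of three data frames (`severity`, `drug_class`,
#'   `organ_system`), each with columns `level`, `n`, `pct`.
#' @export
ade_distributions <- function(adjudicated) {
  stopifnot(inherits(adjudicated, "adjudicated_cohort"))
  ades <- adjudicated$ades
  if (nrow(ades) == 0) {
    abort_adetrigger("no ADEs to tabulate", "adetrigger_validation_error")
  }
  tab <- function(values, levels) {
    counts <- table(factor(values, levels = levels))
    counts <- counts[counts > 0 | names(counts) %in% unique(values)]
    df <- data.frame(level = names(counts), n = as.integer(counts),
                     pct = rational_round(100 * as.integer(counts), nrow(ades), 2),
                     stringsAsFactors = FALSE)
    df[order(-df$n, df$level), , drop = FALSE]
  }
  list(severity = tab(ades$grade, c("E", "F", "G", "H", "I")),
       drug_class = tab(ades$drug_class, drug_classes()),
       organ_system = tab(ades$organ_system, organ_systems()))
}

#' Write the full GTT report
#'
#' Emits the complete quantitative output of a trigger-tool run to a
#' directory: cohort summary, per-trigger performance table, the 2x2
#' screening evaluation, the three GTT rates and the severity/drug-class/
#' organ-system distributions, as tab-delimited tables plus a human-readable
#' `report.txt`.
#'
#' @param cohort a `gtt_cohort`.
#' @param screen a `screen_result`.
#' @param adjudicated an `adjudicated_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, a list of the computed report components.
#' @export
write_gtt_report <- function(cohort, screen, adjudicated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- summarize_cohort(cohort)
  tb <- two_by_two(screen, adjudicated)
  ev <- evaluate_screening(tb)
  perf <- trigger_performance(screen, adjudicated)
  n_ade_patients <- sum(adjudicated$per_patient$n_ades > 0)
  rates <- compute_rates(nrow(adjudicated$ades), n_ade_patients,
                         summ$n_patients, summ$patient_days)
  dists <- ade_distributions(adjudicated)

  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  perf_out <- perf$per_trigger
  perf_out <- rbind(perf_out,
                    data.frame(trigger_id = NA_integer_, name = "Total",
                               category = "", positives = perf$overall$positives,
                               ade_cases = perf$overall$ade_cases,
                               ppv_pct = perf$overall$ppv_pct,
                               zero_denominator = perf$overall$zero_denominator))
  wt(perf_out, "trigger_performance.tsv")
  wt(data.frame(metric = names(ev$percent), percent = unname(ev$percent)),
     "screening_evaluation.tsv")
  wt(data.frame(tp = tb$tp, fp = tb$fp, fn = tb$fn, tn = tb$tn), "two_by_two.tsv")
  wt(data.frame(rate = c("per_1000_patient_days", "per_100_patients", "incidence_pct"),
                value = c(rates$per_1000_patient_days, rates$per_100_patients,
                          rates$incidence_pct)), "rates.tsv")
  wt(dists$severity, "severity_distribution.tsv")
  wt(dists$drug_class, "drug_class_distribution.tsv")
  wt(dists$organ_system, "organ_system_distribution.tsv")
  wt(screen$hits, "hits.tsv")

  txt <- file.path(dir, "report.txt")
  con <- file(txt, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  cat("=== Adverse drug event trigger-tool report ===\n\n")
  print(summ); cat("\n")
  print(tb); cat("\n")
  print(ev); cat("\n")
  print(rates); cat("\n")
  print(perf); cat("\n")
  cat("Severity distribution:\n"); print(dists$severity, row.names = FALSE)
  cat("\nDrug-class distribution:\n"); print(dists$drug_class, row.names = FALSE)
  cat("\nOrgan-system distribution:\n"); print(dists$organ_system, row.names = FALSE)

  invisible(list(summary = summ, two_by_two = tb, evaluation = ev,
                 rates = rates, performance = perf, distributions = dists))
}
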