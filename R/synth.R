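# Per-trigger firing and ADE-case reference counts for the 480-admission
# calibration cohort (positives sum to 204, ADE cases to 93).
.table2_counts <- function() {
  data.frame(
    trigger_id = 1:38,
    positives = c(0L, 10L, 2L, 10L, 9L, 1L, 0L, 0L, 0L, 0L, 1L, 5L, 43L, 7L,
                  17L, 5L, 21L, 11L, 5L, 1L, 1L, 8L, 0L, 0L, 8L, 3L, 7L, 2L,
                  1L, 2L, 1L, 20L, 0L, 0L, 2L, 0L, 0L, 1L),
    ade_cases = c(0L, 7L, 2L, 7L, 5L, 1L, 0L, 0L, 0L, 0L, 1L, 3L, 24L, 4L,
                  4L, 3L, 7L, 6L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 2L, 0L, 2L,
                  1L, 2L, 0L, 8L, 0L, 0L, 2L, 0L, 0L, 1L))
}

#' Calibration manifest
#'
#' The exact target counts the deterministic calibration cohort must
#' reproduce: cohort size and sex split, trigger-positive patients, the
#' trigger-positivity x ADE 2x2, total trigger hits and their per-trigger
#' breakdown, ADE totals, causality-category counts, patient-days, severity
#' grades, and drug-class / organ-system counts.
#'
#' @return a named list of targets.
#' @export
calibration_manifest <- function() {
  list(
    n_patients = 480L, sex = c(male = 263L, female = 217L),
    trigger_positive_patients = 123L,
    two_by_two = c(tp = 51L, fp = 72L, fn = 14L, tn = 343L),
    total_hits = 204L,
    per_trigger = .table2_counts(),
    n_ades = 93L, n_ade_patients = 65L, patients_with_one_ade = 46L,
    naranjo_categories = c(definite = 2L, probable = 5L, possible = 86L),
    n_doubtful = 2L,
    patient_days = 4062L,
    grades = c(E = 90L, F = 3L),
    drug_class_counts = c(cardiovascular = 36L, blood_and_hematopoietic = 20L,
                          other = 13L, endocrine = 8L, nervous_system = 6L,
                          systemic_anti_infective = 4L, urinary = 4L,
                          digestive = 2L),
    organ_counts = c(metabolic_nutritional = 47L, hematologic_lymphatic = 20L,
                     other_edema = 8L, cardiovascular = 6L,
                     gastrointestinal = 4L, neurological = 3L,
                     skin_appendages = 2L, hepatobiliary = 1L,
                     psychiatric = 1L, musculoskeletal = 1L),
    age_strata = c(303L, 147L, 30L),
    ade_by_age_stratum = c(17L, 28L, 20L))
}

# Evidence recipes: the records that make a given trigger fire, with
# laboratory values placed one least-significant unit past the (strict)
# threshold so boundary semantics are exercised.
.evidence_recipes <- function() {
  lab <- function(analyte, value) list(kind = "lab", analyte = analyte,
                                       value = value,
                                       unit = unname(analyte_units()[[analyte]]))
  med <- function(code, name, class) list(kind = "med", drug_code = code,
                                          drug_name = name, drug_class = class)
  evt <- function(code) list(kind = "event", event = code)
  list(
    `1` = list(evt("cdiff_positive_stool")),
    `2` = list(lab("APTT", 39.1)),
    `3` = list(lab("INR", 1.3)),
    `4` = list(lab("BG", 3.8)),
    `5` = list(lab("CK", 165)),
    `6` = list(med("VITK", "vitamin K1 injection", "other")),
    `7` = list(med("FLUMAZENIL", "flumazenil", "other")),
    `8` = list(med("NALOXONE", "naloxone", "other")),
    `9` = list(evt("oversedation")),
    `10` = list(evt("abrupt_discontinuation")),
    `11` = list(lab("ALT", 36)),
    `12` = list(lab("K", 5.4)),
    `13` = list(lab("K", 3.4)),
    `14` = list(lab("NA", 148)),
    `15` = list(lab("NA", 136)),
    `16` = list(lab("WBC", 3.4)),
    `17` = list(lab("PLT", 124)),
    `18` = list(lab("TC", 5.3)),
    `19` = list(lab("HGB", 176)),
    `20` = list(lab("TSH", 0.55), lab("TH", 153)),
    `21` = list(lab("TSH", 6.0), lab("TH", 69)),
    `22` = list(med("MONTELUKAST", "montelukast", "other")),
    `23` = list(med("PROTAMINE", "protamine sulfate", "other")),
    `24` = list(med("EPINEPHRINE", "epinephrine", "other")),
    `25` = list(med("GLYCEROL_ENEMA", "glycerol enema", "digestive")),
    `26` = list(med("METOCLOPRAMIDE", "metoclopramide", "digestive")),
    `27` = list(evt("icu_transfer")),
    `28` = list(evt("rash_itch")),
    `29` = list(evt("agitation_cluster")),
    `30` = list(evt("neuro_cluster")),
    `31` = list(evt("cognitive_impairment")),
    `32` = list(evt("edema")),
    `33` = list(evt("dehydration")),
    `34` = list(evt("urinary_retention")),
    `35` = list(lab("DIGOXIN_CONC", 2.1)),
    `36` = list(lab("VANCO_CONC", 10.5)),
    `37` = list(lab("GENTA_CONC", 10.5)),
    `38` = list(evt("joint_pain")))
}

# Build labs/meds/events rows that realise a hit assignment.
# assign: data.frame(patient_id, trigger_id, date) with `date` a Date.
.make_evidence <- function(assign) {
  recipes <- .evidence_recipes()
  labs <- list(); meds <- list(); events <- list()
  for (tid in unique(assign$trigger_id)) {
    sub <- assign[assign$trigger_id == tid, , drop = FALSE]
    for (rec in recipes[[as.character(tid)]]) {
      if (rec$kind == "lab") {
        labs[[length(labs) + 1]] <- data.frame(
          patient_id = sub$patient_id, analyte = rec$analyte,
          value = rec$value, unit = rec$unit,
          observed_at = paste(as.character(sub$date), "08:00:00"),
          stringsAsFactors = FALSE)
      } else if (rec$kind == "med") {
        meds[[length(meds) + 1]] <- data.frame(
          patient_id = sub$patient_id, drug_code = rec$drug_code,
          drug_name = rec$drug_name, drug_class = rec$drug_class,
          start = as.character(sub$date), stop = as.character(sub$date + 1),
          stringsAsFactors = FALSE)
      } else {
        events[[length(events) + 1]] <- data.frame(
          patient_id = sub$patient_id, event_code = rec$event,
          observed_at = paste(as.character(sub$date), "10:00:00"),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(labs = if (length(labs)) do.call(rbind, labs) else NULL,
       meds = if (length(meds)) do.call(rbind, meds) else NULL,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

# Deterministic bin packing: hand each item its k units from distinct bins,
# always drawing from the bin with the largest remaining capacity (ties by
# bin id). Errors if the capacities cannot be exhausted exactly.
.greedy_assign <- function(capacity, k_per_item, what) {
  cap <- capacity
  out <- vector("list", length(k_per_item))
  for (i in seq_along(k_per_item)) {
    k <- k_per_item[i]
    if (k == 0) { out[[i]] <- integer(0); next }
    avail <- names(cap)[cap > 0]
    if (length(avail) < k) {
      abort_adetrigger(sprintf("calibration packing infeasible (%s): item %d needs %d distinct bins, %d available",
                               what, i, k, length(avail)),
                       "adetrigger_manifest_error")
    }
    pick <- avail[order(-cap[avail], as.integer(avail))][seq_len(k)]
    cap[pick] <- cap[pick] - 1L
    out[[i]] <- sort(as.integer(pick))
  }
  if (any(cap != 0)) {
    abort_adetrigger(sprintf("calibration packing infeasible (%s): leftover capacity in bins %s",
                             what, paste(names(cap)[cap != 0], collapse = ", ")),
                     "adetrigger_manifest_error")
  }
  out
}

.naranjo_templates <- function() {
  list(
    definite = c("yes", "yes", "yes", "yes", "no", "unknown", "yes",
                 "unknown", "unknown", "unknown"),                   # score 9
    probable = c("yes", "yes", "yes", "yes", rep("unknown", 6)),     # score 6
    possible = c("yes", "yes", rep("unknown", 8)),                   # score 3
    doubtful = rep("unknown", 10))                                   # score 0
}

.suspect_drug_by_class <- c(
  cardiovascular = "spironolactone", blood_and_hematopoietic = "warfarin",
  other = "potassium chloride", endocrine = "insulin aspart",
  nervous_system = "zolpidem", systemic_anti_infective = "ceftriaxone",
  urinary = "tamsulosin", digestive = "lactulose")

#' Build the deterministic calibration cohort
#'
#' Constructs (never samples) a 480-admission cohort plus its adjudication
#' table such that screening with the default trigger set and adjudicating
#' with the returned table reproduces every calibration-manifest count
#' exactly: 204 trigger hits with the reference per-trigger breakdown, 123
#' trigger-positive patients, the (51, 72, 14, 343) contingency table, 93
#' ADEs in 65 patients (46 with exactly one), causality categories 2/5/86
#' plus 2 excluded doubtful candidates, 4,062 patient-days, severity grades
#' 90 E / 3 F, and the reference drug-class and organ-system counts.
#' Laboratory evidence sits one least-significant unit past each strict
#' threshold. Generation fails loudly if any manifest sum is unsatisfiable.
#'
#' Fourteen ADE patients carry no positive trigger; so that per-trigger ADE
#' cases still sum to 93, fourteen ADEs of trigger-positive patients are
#' linked to two (distinct) triggers each.
#'
#' @return list with elements `cohort` (a `gtt_cohort`) and `adjudication`
#'   (a data frame accepted by [build_ade_records()]).
#' @export
build_calibration_fixture <- function() {
  man <- calibration_manifest()
  tab2 <- man$per_trigger
  n <- man$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  ## --- patient attributes -------------------------------------------------
  # ADE patients: 51 trigger-positive (P001-P051), 14 trigger-negative
  # (P124-P137); trigger-positive patients are P001-P123.
  ade_patients <- c(1:51, 124:137)
  # sex: 32 male / 33 female among ADE patients, margins 263/217 overall
  sex <- rep(NA_character_, n)
  sex[ade_patients[1:32]] <- "male"
  sex[ade_patients[33:65]] <- "female"
  non_ade <- setdiff(seq_len(n), ade_patients)
  sex[non_ade[1:231]] <- "male"
  sex[non_ade[232:415]] <- "female"

  # age strata 1:65-75, 2:76-85, 3:>=86 sized 303/147/30 with ADE counts
  # 17/28/20 (oldest stratum enriched, as in the reference risk table)
  stratum <- rep(NA_integer_, n)
  stratum[ade_patients[1:20]] <- 3L
  stratum[ade_patients[21:48]] <- 2L
  stratum[ade_patients[49:65]] <- 1L
  stratum[non_ade[1:10]] <- 3L
  stratum[non_ade[11:129]] <- 2L
  stratum[non_ade[130:415]] <- 1L
  age_pool <- list(`1` = 65:75, `2` = 76:85, `3` = 86:96)
  age <- integer(n)
  for (s in 1:3) {
    idx <- which(stratum == s)
    pool <- age_pool[[as.character(s)]]
    age[idx] <- pool[((seq_along(idx) - 1) %% length(pool)) + 1]
  }

  # lengths of stay summing to 4,062 within 2-24 days
  los <- rep(8L, n)
  los[1:53] <- 12L
  los[478] <- 24L
  los[479] <- 2L
  stopifnot(sum(los) == man$patient_days)

  admit <- as.Date("2023-01-01") + ((seq_len(n) - 1) %% 360)
  discharge <- admit + los

  # multi-label chronic conditions with the reference frequencies
  # (392/315/192/93/47); every patient carries at least two codes
  has <- function(idx) seq_len(n) %in% idx
  cond_mat <- cbind(
    HTN = has(1:392), T2DM = has(166:480),
    CAD = has(c(1:165, 454:480)), HLD = has(c(393:453, 1:32)),
    CKD = has(1:47))
  conditions <- apply(cond_mat, 1, function(r) paste(colnames(cond_mat)[r],
                                                     collapse = ";"))

  n_medications <- 5L + ((seq_len(n) * 3L) %% 42L)

  ## --- trigger hits -------------------------------------------------------
  pos_triggers <- tab2[tab2$positives > 0, ]
  # ADE-linked hits: 93 links on the 51 trigger-positive ADE patients;
  # patients P001-P009 hold 3 ADEs, P010-P019 two, P020-P051 one; the 14
  # double-linked ADEs sit on P020-P033.
  ade_counts_pos <- c(rep(3L, 9), rep(2L, 10), rep(1L, 32))
  link_counts <- c(rep(3L, 9), rep(2L, 10), rep(2L, 14), rep(1L, 18))
  link_cap <- setNames(pos_triggers$ade_cases, pos_triggers$trigger_id)
  link_cap <- link_cap[link_cap > 0]
  links <- .greedy_assign(link_cap, link_counts, "ADE links")

  # remaining hits on the 72 trigger-positive non-ADE patients (P052-P123)
  rem_cap <- setNames(pos_triggers$positives - pos_triggers$ade_cases,
                      pos_triggers$trigger_id)
  rem_cap <- rem_cap[rem_cap > 0]
  n_extra <- sum(rem_cap) - 72L
  extra_counts <- c(rep(2L, n_extra), rep(1L, 72L - n_extra))
  extras <- .greedy_assign(rem_cap, extra_counts, "non-ADE hits")

  assign <- rbind(
    data.frame(idx = rep(1:51, lengths(links)),
               trigger_id = unlist(links)),
    data.frame(idx = rep(52:123, lengths(extras)),
               trigger_id = unlist(extras)))
  assign$patient_id <- ids[assign$idx]
  assign$date <- admit[assign$idx] + 1
  stopifnot(nrow(assign) == man$total_hits,
            !anyDuplicated(assign[, c("idx", "trigger_id")]))
  hit_check <- table(factor(assign$trigger_id, levels = 1:38))
  if (!all(as.integer(hit_check) == tab2$positives)) {
    abort_adetrigger("calibration fixture violates the per-trigger hit counts",
                     "adetrigger_manifest_error")
  }

  evid <- .make_evidence(assign[, c("patient_id", "trigger_id", "date")])

  patients <- data.frame(
    patient_id = ids, sex = sex, age = age,
    admit_date = as.character(admit), discharge_date = as.character(discharge),
    conditions = conditions, n_medications = n_medications,
    stringsAsFactors = FALSE)
  baseline_meds <- data.frame(
    patient_id = ids, drug_code = "AMLODIPINE", drug_name = "amlodipine",
    drug_class = "cardiovascular", start = as.character(admit),
    stop = as.character(discharge), stringsAsFactors = FALSE)
  meds <- rbind(baseline_meds, evid$meds)

  cohort <- new_cohort(patients, evid$labs, meds, evid$events)
  stopifnot(nrow(cohort$patients) == n)

  ## --- adjudication table -------------------------------------------------
  # one ADE row per event, in patient order; the first ADE of each
  # double-linked patient carries both triggers
  ade_rows <- list()
  for (j in seq_along(ade_counts_pos)) {
    k <- ade_counts_pos[j]
    trig <- links[[j]]
    if (j >= 20 && j <= 33) {
      row_links <- list(trig)              # one ADE, two linked triggers
    } else {
      row_links <- as.list(trig)           # one link per ADE
    }
    stopifnot(length(row_links) == k)
    for (l in row_links) {
      ade_rows[[length(ade_rows) + 1]] <- list(idx = j, links = l)
    }
  }
  for (j in 124:137) {
    ade_rows[[length(ade_rows) + 1]] <- list(idx = j, links = integer(0))
  }
  stopifnot(length(ade_rows) == man$n_ades)

  class_seq <- rep(names(man$drug_class_counts), man$drug_class_counts)
  organ_seq <- rep(names(man$organ_counts), man$organ_counts)
  grade_seq <- c(rep("F", man$grades[["F"]]), rep("E", man$grades[["E"]]))
  cat_seq <- rep(names(man$naranjo_categories), man$naranjo_categories)
  tpl <- .naranjo_templates()

  adjudication <- do.call(rbind, lapply(seq_along(ade_rows), function(i) {
    r <- ade_rows[[i]]
    ans <- tpl[[cat_seq[i]]]
    cbind(data.frame(
      patient_id = ids[r$idx],
      suspect_drug = unname(.suspect_drug_by_class[class_seq[i]]),
      drug_class = class_seq[i], organ_system = organ_seq[i],
      grade = grade_seq[i],
      linked_trigger_ids = paste(r$links, collapse = ";"),
      stringsAsFactors = FALSE),
      as.data.frame(setNames(as.list(ans), paste0("q", 1:10)),
                    stringsAsFactors = FALSE))
  }))

  # two doubtful candidates on trigger-positive non-ADE patients, linked to
  # one of their hits, to exercise the exclusion path
  doubtful <- do.call(rbind, lapply(52:53, function(j) {
    trig <- assign$trigger_id[assign$idx == j][1]
    cbind(data.frame(
      patient_id = ids[j], suspect_drug = "potassium chloride",
      drug_class = "other", organ_system = "metabolic_nutritional",
      grade = "E", linked_trigger_ids = as.character(trig),
      stringsAsFactors = FALSE),
      as.data.frame(setNames(as.list(tpl$doubtful), paste0("q", 1:10)),
                    stringsAsFactors = FALSE))
  }))
  adjudication <- rbind(adjudication, doubtful)
  rownames(adjudication) <- NULL

  list(cohort = cohort, adjudication = adjudication)
}

#' Simulation configuration for stochastic cohorts
#'
#' Defaults emulate the calibration cohort: age-stratum weights 303/147/30,
#' sex ratio 263/217, integer lengths of stay on 2-24 days with mean about
#' 8.4, medication counts on 5-46 with mean about 16, per-trigger firing
#' probabilities equal to the reference counts over 480, and an ADE risk
#' model that is logistic in the age stratum and trigger positivity. The
#' default coefficients were calibrated once, by least squares, to the
#' reference stratum-specific ADE rates (5.61%, 19.05%, 66.67%) and the
#' trigger-margin rates (41.46% positive, 3.92% negative) under independent
#' trigger firing.
#'
#' @param n_patients cohort size.
#' @param trigger_probs named per-trigger firing probabilities.
#' @param ade_model list with `intercept`, `beta_age` (per stratum step),
#'   `beta_trigger` and `predictor` (`"indicator"` or `"count"`).
#' @param ... overrides for the remaining fields (see the returned list).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 480,
                       trigger_probs = NULL,
                       ade_model = list(intercept = -5.53, beta_age = 2.70,
                                        beta_trigger = 3.73,
                                        predictor = "indicator"),
                       ...) {
  tab2 <- .table2_counts()
  if (is.null(trigger_probs)) {
    trigger_probs <- setNames(tab2$positives / 480, tab2$trigger_id)
  }
  cfg <- list(
    n_patients = n_patients,
    sex_prob_male = 263 / 480,
    age_stratum_probs = c(303, 147, 30) / 480,
    los_support = 2:24, los_meanlog = 2.0196, los_sdlog = 0.52,
    meds_support = 5:46, meds_meanlog = 2.6932, meds_sdlog = 0.42,
    condition_probs = c(HTN = 392, T2DM = 315, CAD = 192, HLD = 93,
                        CKD = 47) / 480,
    trigger_probs = trigger_probs,
    ade_model = ade_model,
    ades_per_patient_probs = c(46, 10, 9) / 65,
    naranjo_probs = c(definite = 2, probable = 5, possible = 86) / 93,
    grade_probs = c(E = 90, F = 3) / 93,
    drug_class_probs = c(cardiovascular = 36, blood_and_hematopoietic = 20,
                         other = 13, endocrine = 8, nervous_system = 6,
                         systemic_anti_infective = 4, urinary = 4,
                         digestive = 2) / 93,
    organ_probs = c(metabolic_nutritional = 47, hematologic_lymphatic = 20,
                    other_edema = 8, cardiovascular = 6, gastrointestinal = 4,
                    neurological = 3, skin_appendages = 2, hepatobiliary = 1,
                    psychiatric = 1, musculoskeletal = 1) / 93,
    doubtful_rate = 2 / 95)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort_adetrigger(sprintf("unknown sim_config field(s): %s",
                             paste(unknown, collapse = ", ")),
                     "adetrigger_config_error")
  }
  cfg[names(dots)] <- dots
  probs <- c(cfg$trigger_probs, cfg$age_stratum_probs, cfg$sex_prob_male,
             cfg$condition_probs, cfg$doubtful_rate)
  if (any(probs < 0 | probs > 1)) {
    abort_adetrigger("sim_config probabilities must lie in [0, 1]",
                     "adetrigger_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a stochastic cohort with a known ADE-risk model
#'
#' Draws demographics, per-trigger firings (independent Bernoulli with the
#' configured probabilities, realised as evidence records one unit past each
#' threshold) and ADE outcomes from the configured logistic model, so that
#' downstream risk-factor fits can attempt parameter recovery against a
#' known truth. Reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `cohort`, `adjudication` and `truth` (the generating
#'   coefficients plus the per-patient design used to draw outcomes).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  if (n <= 0) {
    abort_adetrigger("n_patients must be positive", "adetrigger_config_error")
  }
  set.seed(seed)
  ids <- sprintf("S%06d", seq_len(n))

  sex <- ifelse(stats::runif(n) < config$sex_prob_male, "male", "female")
  stratum <- sample.int(3, n, replace = TRUE, prob = config$age_stratum_probs)
  age_pool <- list(65:75, 76:85, 86:96)
  age <- vapply(stratum, function(s) sample(age_pool[[s]], 1), 1L)
  dweights <- function(support, meanlog, sdlog) {
    w <- stats::dlnorm(support, meanlog, sdlog); w / sum(w)
  }
  los <- sample(config$los_support, n, replace = TRUE,
                prob = dweights(config$los_support, config$los_meanlog,
                                config$los_sdlog))
  nmed <- sample(config$meds_support, n, replace = TRUE,
                 prob = dweights(config$meds_support, config$meds_meanlog,
                                 config$meds_sdlog))
  admit <- as.Date("2023-01-01") + sample.int(360, n, replace = TRUE) - 1

  cond_mat <- vapply(names(config$condition_probs), function(cn) {
    stats::runif(n) < config$condition_probs[[cn]]
  }, logical(n))
  cond_mat <- matrix(cond_mat, nrow = n,
                     dimnames = list(NULL, names(config$condition_probs)))
  short <- rowSums(cond_mat) < 2
  cond_mat[short, c("HTN", "T2DM")] <- TRUE  # enforce multimorbidity
  conditions <- apply(cond_mat, 1, function(r) {
    paste(colnames(cond_mat)[r], collapse = ";")
  })

  fires <- lapply(as.integer(names(config$trigger_probs)), function(tid) {
    p <- config$trigger_probs[[as.character(tid)]]
    which(stats::runif(n) < p)
  })
  names(fires) <- names(config$trigger_probs)
  assign <- do.call(rbind, lapply(names(fires), function(tid) {
    idx <- fires[[tid]]
    if (!length(idx)) return(NULL)
    data.frame(idx = idx, trigger_id = as.integer(tid))
  }))
  if (is.null(assign)) {
    assign <- data.frame(idx = integer(0), trigger_id = integer(0))
  }
  assign$patient_id <- ids[assign$idx]
  assign$date <- admit[assign$idx] + 1

  n_hits <- tabulate(assign$idx, nbins = n)
  trig_ind <- as.integer(n_hits > 0)
  am <- config$ade_model
  x2 <- if (identical(am$predictor, "count")) n_hits else trig_ind
  eta <- am$intercept + am$beta_age * (stratum - 1) + am$beta_trigger * x2
  p_ade <- stats::plogis(eta)
  ade <- stats::runif(n) < p_ade

  patients <- data.frame(
    patient_id = ids, sex = sex, age = age,
    admit_date = as.character(admit),
    discharge_date = as.character(admit + los),
    conditions = conditions, n_medications = nmed, stringsAsFactors = FALSE)
  evid <- if (nrow(assign)) {
    .make_evidence(assign[, c("patient_id", "trigger_id", "date")])
  } else list(labs = NULL, meds = NULL, events = NULL)
  meds <- rbind(
    data.frame(patient_id = ids, drug_code = "AMLODIPINE",
               drug_name = "amlodipine", drug_class = "cardiovascular",
               start = as.character(admit), stop = as.character(admit + los),
               stringsAsFactors = FALSE),
    evid$meds)
  cohort <- new_cohort(patients, evid$labs, meds, evid$events)

  tpl <- .naranjo_templates()
  ade_idx <- which(ade)
  adjudication <- NULL
  if (length(ade_idx)) {
    n_per <- sample(1:3, length(ade_idx), replace = TRUE,
                    prob = config$ades_per_patient_probs)
    rows <- lapply(seq_along(ade_idx), function(j) {
      i <- ade_idx[j]
      own <- assign$trigger_id[assign$idx == i]
      do.call(rbind, lapply(seq_len(n_per[j]), function(k) {
        cls <- sample(names(config$drug_class_probs), 1,
                      prob = config$drug_class_probs)
        cat <- sample(names(config$naranjo_probs), 1,
                      prob = config$naranjo_probs)
        link <- if (length(own)) own[sample.int(length(own), 1)] else integer(0)
        cbind(data.frame(
          patient_id = ids[i],
          suspect_drug = unname(.suspect_drug_by_class[cls]),
          drug_class = cls,
          organ_system = sample(names(config$organ_probs), 1,
                                prob = config$organ_probs),
          grade = sample(names(config$grade_probs), 1,
                         prob = config$grade_probs),
          linked_trigger_ids = paste(link, collapse = ";"),
          stringsAsFactors = FALSE),
          as.data.frame(setNames(as.list(tpl[[cat]]), paste0("q", 1:10)),
                        stringsAsFactors = FALSE))
      }))
    })
    adjudication <- do.call(rbind, rows)
  }
  n_doubt <- stats::rbinom(1, max(NROW(adjudication), 1), config$doubtful_rate)
  cand <- setdiff(which(trig_ind == 1), ade_idx)
  if (n_doubt > 0 && length(cand)) {
    doubt <- do.call(rbind, lapply(utils::head(cand, n_doubt), function(i) {
      own <- assign$trigger_id[assign$idx == i]
      cbind(data.frame(
        patient_id = ids[i], suspect_drug = "potassium chloride",
        drug_class = "other", organ_system = "metabolic_nutritional",
        grade = "E", linked_trigger_ids = as.character(own[1]),
        stringsAsFactors = FALSE),
        as.data.frame(setNames(as.list(tpl$doubtful), paste0("q", 1:10)),
                      stringsAsFactors = FALSE))
    }))
    adjudication <- rbind(adjudication, doubt)
  }
  if (is.null(adjudication)) {
    adjudication <- cbind(
      data.frame(patient_id = character(0), suspect_drug = character(0),
                 drug_class = character(0), organ_system = character(0),
                 grade = character(0), linked_trigger_ids = character(0),
                 stringsAsFactors = FALSE),
      as.data.frame(setNames(rep(list(character(0)), 10), paste0("q", 1:10))))
  }
  rownames(adjudication) <- NULL

  list(cohort = cohort, adjudication = adjudication,
       truth = list(
         coefficients = c(intercept = am$intercept, beta_age = am$beta_age,
                          beta_trigger = am$beta_trigger),
         predictor = am$predictor,
         design = data.frame(patient_id = ids, stratum = stratum,
                             trigger_positive = trig_ind, n_hits = n_hits,
                             p_ade = p_ade, ade = as.integer(ade))))
}

#' Systematic time-based random sampling
#'
#' Splits records into half-month periods by admission date (days 1-15 vs
#' the remainder of each month), assigns each record an independent uniform
#' pseudo-random number, and keeps the `k_per_period` lowest per period.
#' Periods with fewer than `k_per_period` records contribute all their
#' records, with a warning naming the shortfall.
#'
#' @param records data frame with an admission-date column.
#' @param k_per_period records to keep per half-month.
#' @param seed integer seed.
#' @param date_col name of the admission-date column.
#' @return the sampled subset of `records` (original row order within
#'   periods of the draw order), with the period key in
#'   `attr(, "period")`.
#' @export
periodic_random_sample <- function(records, k_per_period = 20, seed = 1,
                                   date_col = "admit_date") {
  stopifnot(is.data.frame(records), date_col %in% names(records),
            k_per_period >= 0)
  d <- as.Date(records[[date_col]])
  period <- sprintf("%s-%s", format(d, "%Y-%m"),
                    ifelse(as.integer(format(d, "%d")) <= 15, "H1", "H2"))
  set.seed(seed)
  u <- stats::runif(nrow(records))
  keep <- unlist(lapply(split(seq_len(nrow(records)), period), function(idx) {
    if (length(idx) < k_per_period) {
      warning(sprintf("period %s has only %d record(s) (< %d); keeping all",
                      period[idx[1]], length(idx), k_per_period),
              call. = FALSE)
      return(idx)
    }
    idx[order(u[idx])][seq_len(k_per_period)]
  }), use.names = FALSE)
  out <- records[sort(keep), , drop = FALSE]
  attr(out, "period") <- period[sort(keep)]
  out
}
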