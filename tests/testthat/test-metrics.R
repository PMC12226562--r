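test_that("the screening evaluation reproduces the reference 2x2 exactly", {
  ev <- evaluate_screening(new_two_by_two(51, 72, 14, 343))
  expect_equal(ev$percent[["sensitivity"]], 78.46)
  expect_equal(ev$percent[["specificity"]], 82.65)
  expect_equal(ev$percent[["compliance"]], 82.08)  # (51+343)/480
  expect_equal(ev$percent[["kappa"]], 44.40)
  expect_equal(ev$percent[["ppv_patient"]], 41.46)
})

test_that("degenerate and boundary 2x2 tables behave as defined", {
  perfect <- evaluate_screening(new_two_by_two(30, 0, 0, 50))
  expect_equal(unname(perfect$percent[c("sensitivity", "specificity",
                                        "compliance", "ppv_patient")]),
               rep(100, 4))
  expect_equal(perfect$kappa, 1)

  chance <- evaluate_screening(new_two_by_two(10, 10, 10, 10))
  expect_equal(chance$kappa, 0)

  no_pos <- evaluate_screening(new_two_by_two(0, 0, 5, 95))
  expect_true("ppv_patient" %in% no_pos$undefined)
  expect_true(is.na(no_pos$percent[["ppv_patient"]]))
  expect_error(evaluate_screening(new_two_by_two(0, 0, 0, 0)),
               class = "adetrigger_degenerate_table_error")
})

test_that("kappa agrees with a brute-force margin oracle on random tables", {
  kappa_oracle <- function(tp, fp, fn, tn) {
    n <- tp + fp + fn + tn
    po <- (tp + tn) / n
    pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
    (po - pe) / (1 - pe)
  }
  set.seed(11)
  for (i in 1:1000) {
    cells <- stats::rpois(4, sample(c(3, 20, 80), 1)) + 1
    ev <- evaluate_screening(new_two_by_two(cells[1], cells[2],
                                            cells[3], cells[4]))
    expect_equal(ev$kappa, kappa_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    expect_true(ev$kappa >= -1 && ev$kappa <= 1)
  }
})

test_that("2x2 symmetries: label exchange swaps sensitivity and specificity, kappa invariant", {
  set.seed(12)
  for (i in 1:50) {
    cells <- stats::rpois(4, 30) + 1
    a <- evaluate_screening(new_two_by_two(cells[1], cells[2],
                                           cells[3], cells[4]))
    # exchanging the positive/negative labels on both margins
    swapped <- evaluate_screening(new_two_by_two(cells[4], cells[3],
                                                 cells[2], cells[1]))
    expect_equal(a$sensitivity, swapped$specificity)
    expect_equal(a$specificity, swapped$sensitivity)
    expect_equal(a$kappa, swapped$kappa, tolerance = 1e-12)
    # transposing the table swaps sensitivity with PPV; kappa is symmetric
    transposed <- evaluate_screening(new_two_by_two(cells[1], cells[3],
                                                    cells[2], cells[4]))
    expect_equal(a$sensitivity, transposed$ppv_patient)
    expect_equal(a$ppv_patient, transposed$sensitivity)
    expect_equal(a$kappa, transposed$kappa, tolerance = 1e-12)
  }
})

test_that("GTT rates reproduce the reference values and scale linearly", {
  r <- compute_rates(93, 65, 480, 4062)
  expect_equal(r$per_1000_patient_days, 22.90)
  expect_equal(r$per_100_patients, 19.38)
  expect_equal(r$incidence_pct, 13.54)

  expect_equal(compute_rates(0, 0, 100, 800)$per_1000_patient_days, 0)
  expect_equal(compute_rates(0, 0, 100, 800)$incidence_pct, 0)
  expect_equal(compute_rates(10, 10, 100, 1000)$per_1000_patient_days, 10.00)

  # linear in the numerator, inverse-linear in the denominators
  base <- compute_rates(10, 8, 100, 1000)
  expect_equal(compute_rates(20, 8, 100, 1000)$per_1000_patient_days,
               2 * base$per_1000_patient_days)
  expect_equal(compute_rates(10, 8, 100, 2000)$per_1000_patient_days,
               base$per_1000_patient_days / 2)
  expect_equal(compute_rates(10, 8, 200, 1000)$per_100_patients,
               base$per_100_patients / 2)
  expect_error(compute_rates(1, 1, 0, 10),
               class = "adetrigger_degenerate_table_error")
  expect_error(compute_rates(5, 20, 10, 100),
               class = "adetrigger_validation_error")
})

test_that("half-up percentage rounding matches printed-value conventions", {
  expect_equal(adetrigger:::pct2(93, 480), 19.38)  # 19.375 rounds up
  expect_equal(adetrigger:::rational_round(1000 * 93, 4062, 2), 22.90)
  expect_equal(adetrigger:::pct2(1, 3), 33.33)
  expect_equal(adetrigger:::pct2(2, 3), 66.67)
})

test_that("per-trigger performance totals close and zero-positive triggers are flagged", {
  cb <- calib()
  perf <- trigger_performance(cb$screen, cb$adjudicated)
  man <- calibration_manifest()
  expect_equal(perf$per_trigger$positives, man$per_trigger$positives)
  expect_equal(perf$per_trigger$ade_cases, man$per_trigger$ade_cases)
  expect_equal(perf$overall$positives, 204)
  expect_equal(perf$overall$ade_cases, 93)
  expect_equal(perf$overall$ppv_pct, 45.59)

  t13 <- perf$per_trigger[perf$per_trigger$trigger_id == 13, ]
  expect_equal(t13$ppv_pct, 55.81)

  zero <- perf$per_trigger[perf$per_trigger$positives == 0, ]
  expect_true(all(zero$ppv_pct == 0))
  expect_true(all(zero$zero_denominator))
  expect_false(any(perf$per_trigger$zero_denominator[
    perf$per_trigger$positives > 0]))
  # ade_cases can never exceed positives
  expect_true(all(perf$per_trigger$ade_cases <= perf$per_trigger$positives))
})

test_that("distribution tables are complete partitions of the ADE count", {
  cb <- calib()
  d <- ade_distributions(cb$adjudicated)
  for (nm in names(d)) {
    expect_equal(sum(d[[nm]]$n), nrow(cb$adjudicated$ades), info = nm)
  }
  expect_equal(d$severity$n[d$severity$level == "E"], 90)
  expect_equal(d$severity$pct[d$severity$level == "E"], 96.77)
  expect_equal(d$drug_class$pct[d$drug_class$level == "cardiovascular"], 38.71)
  expect_equal(d$organ_system$pct[d$organ_system$level == "metabolic_nutritional"],
               50.54)

  # single-ADE cohort: the lone class carries 100%
  one <- cb$adjudication[3, , drop = FALSE]
  adj1 <- build_ade_records(cb$cohort, cb$screen, one)
  d1 <- ade_distributions(adj1)
  expect_equal(d1$drug_class$pct, 100)
})

test_that("the report writer emits the full set of tables and a text report", {
  cb <- calib()
  dir <- withr::local_tempdir()
  out <- write_gtt_report(cb$cohort, cb$screen, cb$adjudicated, dir)
  files <- c("trigger_performance.tsv", "screening_evaluation.tsv",
             "two_by_two.tsv", "rates.tsv", "severity_distribution.tsv",
             "drug_class_distribution.tsv", "organ_system_distribution.tsv",
             "hits.tsv", "report.txt")
  expect_true(all(file.exists(file.path(dir, files))))
  perf <- utils::read.delim(file.path(dir, "trigger_performance.tsv"))
  expect_equal(perf$positives[perf$name == "Total"], 204)
  expect_equal(out$rates$per_1000_patient_days, 22.90)
  # deterministic: a re-run writes byte-identical outputs
  dir2 <- withr::local_tempdir()
  write_gtt_report(cb$cohort, cb$screen, cb$adjudicated, dir2)
  for (f in files) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
})
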