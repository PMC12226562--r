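test_that("the default registry holds 38 well-formed triggers with strict lab comparators", {
  trig <- load_trigger_set("default")
  expect_length(trig, 38)
  expect_equal(vapply(trig, `[[`, 1L, "trigger_id"), setNames(1:38, 1:38))
  lab_ops <- unlist(lapply(trig, function(t) {
    if (t$category %in% c("lab_threshold", "tdm")) {
      vapply(t$atoms, `[[`, "", "op")
    }
  }))
  expect_true(all(lab_ops %in% c("<", ">")))
})

test_that("user configs are validated: duplicate ids and unknown codes are errors", {
  base <- yaml::read_yaml(system.file("extdata", "triggers_default.yaml",
                                      package = "adetrigger"))
  dup <- base
  dup$triggers[[2]]$id <- 13
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(dup, f)
  expect_error(load_trigger_set(f), "duplicate trigger id",
               class = "adetrigger_config_error")

  bad <- base
  bad$triggers[[2]]$predicate$atoms[[1]]$analyte <- "CRP"
  yaml::write_yaml(bad, f)
  expect_error(load_trigger_set(f), "unknown analyte",
               class = "adetrigger_config_error")
  expect_error(load_trigger_set("/nonexistent/triggers.yaml"),
               class = "adetrigger_config_error")

  # removing rules is a supported revision scenario
  pruned <- base
  pruned$triggers <- base$triggers[1:10]
  yaml::write_yaml(pruned, f)
  expect_length(load_trigger_set(f), 10)
})

test_that("strict thresholds: a boundary value does not fire, one unit past does", {
  co <- tiny_cohort()
  hits <- evaluate_patient(co, "A")
  expect_true(13 %in% hits$trigger_id)   # K = 3.2 < 3.5

  labs_boundary <- tiny_cohort()$labs
  labs_boundary$value[labs_boundary$analyte == "K"] <- 3.5
  co2 <- tiny_cohort(labs = labs_boundary)
  co2 <- new_cohort(co2$patients, labs_boundary, co2$meds, co2$events)
  expect_false(13 %in% evaluate_patient(co2, "A")$trigger_id)
})

test_that("sex-restricted creatinine atoms use the patient's sex", {
  co <- tiny_cohort()
  # SCr = 100 for both: above the female threshold (81), below the male (111)
  expect_false(5 %in% evaluate_patient(co, "A")$trigger_id)  # male
  expect_true(5 %in% evaluate_patient(co, "B")$trigger_id)   # female
})

test_that("compound predicates: any_of fires on one abnormal atom, all_of needs the pattern", {
  co <- tiny_cohort()
  labs <- data.frame(
    patient_id = c("A", "A", "B"),
    analyte = c("TSH", "TH", "TSH"),
    value = c(0.5, 153, 0.5),
    unit = c("mU/L", "nmol/L", "mU/L"),
    observed_at = "2023-03-02 08:00:00", stringsAsFactors = FALSE)
  co2 <- new_cohort(co$patients, labs)
  hits_a <- evaluate_patient(co2, "A")
  hits_b <- evaluate_patient(co2, "B")
  expect_true(20 %in% hits_a$trigger_id)    # both TSH and TH abnormal
  expect_false(20 %in% hits_b$trigger_id)   # TSH alone is not the pattern

  labs_alt <- data.frame(patient_id = "A", analyte = "AST", value = 41,
                         unit = "U/L", observed_at = "2023-03-02 08:00:00",
                         stringsAsFactors = FALSE)
  co3 <- new_cohort(co$patients, labs_alt)
  expect_true(11 %in% evaluate_patient(co3, "A")$trigger_id)  # any_of via AST
})

test_that("one hit per (patient, trigger) regardless of how many records qualify", {
  co <- tiny_cohort()
  labs <- rbind(co$labs,
                data.frame(patient_id = "A", analyte = "K", value = 3.0,
                           unit = "mmol/L", observed_at = "2023-03-04 08:00:00"))
  co2 <- new_cohort(co$patients, labs, co$meds, co$events)
  hits <- evaluate_patient(co2, "A")
  expect_equal(sum(hits$trigger_id == 13), 1)
  # earliest qualifying record supplies the evidence
  expect_match(hits$evidence[hits$trigger_id == 13], "K=3.2")
})

test_that("unknown analytes are ignored with a warning; screening never aborts", {
  co <- tiny_cohort()
  labs <- rbind(co$labs,
                data.frame(patient_id = "A", analyte = "CRP", value = 12,
                           unit = "mg/L", observed_at = "2023-03-02 08:00:00"))
  co2 <- new_cohort(co$patients, labs, co$meds, co$events)
  expect_warning(scr <- screen_cohort(co2), "unknown analyte")
  expect_true(13 %in% scr$hits$trigger_id)
})

test_that("a cohort with no labs, meds or events yields zero hits and zero positive rate", {
  co <- tiny_cohort()
  empty <- new_cohort(co$patients)
  scr <- screen_cohort(empty)
  expect_equal(nrow(scr$hits), 0)
  expect_equal(scr$positive_rate, 0)
  expect_equal(sum(scr$per_trigger$positives), 0)
})

test_that("screening matches an independent brute-force evaluator on random small cohorts", {
  trig <- load_trigger_set("default")
  set.seed(42)
  for (rep in 1:8) {
    co <- random_small_cohort(n = sample(3:25, 1))
    got <- suppressWarnings(screen_cohort(co, trig))$hits
    got <- got[order(got$trigger_id, got$patient_id),
               c("patient_id", "trigger_id")]
    rownames(got) <- NULL
    want <- brute_force_hits(co, trig)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("screening is idempotent and monotone in added evidence and removed triggers", {
  co <- random_small_cohort(n = 15)
  trig <- load_trigger_set("default")
  s1 <- screen_cohort(co, trig)
  s2 <- screen_cohort(co, trig)
  expect_identical(s1$hits, s2$hits)

  # adding a lab result never removes a hit
  labs2 <- rbind(co$labs,
                 data.frame(patient_id = co$patients$patient_id[1],
                            analyte = "K", value = 3.0, unit = "mmol/L",
                            observed_at = "2023-06-05 08:00:00"))
  co2 <- new_cohort(co$patients, labs2, co$meds, co$events)
  s3 <- screen_cohort(co2, trig)
  old_pairs <- paste(s1$hits$patient_id, s1$hits$trigger_id)
  new_pairs <- paste(s3$hits$patient_id, s3$hits$trigger_id)
  expect_true(all(old_pairs %in% new_pairs))

  # dropping a trigger leaves every other trigger's hits unchanged
  pruned <- structure(trig[as.character(setdiff(1:38, 13))],
                      class = "trigger_set")
  s4 <- screen_cohort(co, pruned)
  expect_identical(s4$hits, s1$hits[s1$hits$trigger_id != 13, ],
                   ignore_attr = TRUE)
  expect_equal(rownames(s4$hits), as.character(seq_len(nrow(s4$hits))))
})

test_that("the calibration cohort reproduces the reference per-trigger counts", {
  cb <- calib()
  man <- calibration_manifest()
  expect_equal(cb$screen$per_trigger$positives, man$per_trigger$positives)
  expect_equal(nrow(cb$screen$hits), man$total_hits)
  expect_equal(sum(cb$screen$patient_positive), man$trigger_positive_patients)
  expect_equal(sum(cb$screen$per_trigger$positives), nrow(cb$screen$hits))
})
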