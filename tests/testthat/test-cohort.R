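test_that("load_events drops concept_id 0 rows and unsupported tables", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,concept_id,date,source_table",
               "p1,101,2020-01-03,measurement",
               "p1,0,2020-01-04,measurement",
               "p2,202,2020-01-05,drug_exposure"), f)
  ev <- load_events(f)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$concept_id, c("101", "202"))
  expect_true(is.integer(ev$date))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,concept_id,date,source_table",
               "p1,101,100,measurement",
               "p1,102,101,visit_occurrence"), f2)
  expect_warning(ev2 <- load_events(f2), "visit_occurrence")
  expect_equal(nrow(ev2), 1)
})

test_that("load_events handles the empty file and reports format errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,concept_id,date,source_table", f)
  expect_equal(nrow(load_events(f)), 0)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,concept_id,source_table", "p1,101,measurement"), f2)
  expect_error(load_events(f2), "date")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,concept_id,date,source_table",
               "p1,101,notadate,measurement"), f3)
  expect_error(load_events(f3), "row")
})

test_that("pregnancy window spans 280 days and ends at sampling or a seeded draw", {
  # omics: start = delivery - 280, end = sampling
  w <- pregnancy_window(280L, "omics", sampling_date = 240L)
  expect_equal(unname(w[1, ]), c(0L, 240L))
  # sampling on the delivery day is the boundary case
  w2 <- pregnancy_window(280L, "omics", sampling_date = 280L)
  expect_equal(unname(w2[1, ]), c(0L, 280L))
  expect_error(pregnancy_window(280L, "omics", sampling_date = -10L),
               "precedes")
  # pretraining: end within the last 100 days, reproducible under a seed
  d <- rep(280L, 200)
  w3 <- pregnancy_window(d, "pretraining", seed = 9)
  expect_true(all(w3[, "end"] >= 180L & w3[, "end"] <= 280L))
  w4 <- pregnancy_window(d, "pretraining", seed = 9)
  expect_identical(w3, w4)
  # draws cover most of the 100-day range (uniform on whole days)
  expect_gte(diff(range(w3[, "end"])), 80L)
})

test_that("cancer window keeps all history up to the anchor", {
  w <- cancer_window("omics", sampling_date = 500)
  expect_equal(unname(w[1, ]), c(-Inf, 500))
  w2 <- cancer_window("pretraining", diagnosis_date = 400)
  expect_equal(unname(w2[1, ]), c(-Inf, 400))
  expect_error(cancer_window("pretraining"), "anchor")
})

test_that("assemble_cohort partitions patients and derives outcomes", {
  events <- data.frame(
    patient_id = rep(sprintf("p%d", 1:10), each = 3),
    concept_id = rep(c("a", "b", "c"), 10),
    date = rep(c(150L, 200L, 250L), 10),
    source_table = "condition_occurrence")
  anchors <- data.frame(patient_id = sprintf("p%d", 1:10),
                        delivery_date = 280L)
  omics <- data.frame(sample_id = c("s1", "s2", "s3"),
                      patient_id = c("p1", "p2", "p3"),
                      sampling_date = c(240L, 260L, 280L),
                      A1 = 1:3, A2 = 4:6)
  ch <- assemble_cohort(events, anchors, omics, task = "pregnancy", seed = 3)
  ct <- comet:::cohort_table(ch)
  # partition: every patient in exactly one cohort, counts add up
  expect_equal(sum(ct$cohort == "omics"), 3)
  expect_equal(sum(ct$cohort == "pretraining"), 7)
  expect_length(intersect(ct$patient_id[ct$cohort == "omics"],
                          ct$patient_id[ct$cohort == "pretraining"]), 0)
  # pregnancy outcome: days from window end to delivery
  expect_equal(ch$records[["s1"]]$outcome, 40)
  # no event leakage past the window end
  for (r in ch$records) {
    if (nrow(r$events)) expect_lte(max(r$events$day), r$window[2])
  }
  # windowing is reproducible bit-for-bit under the seed
  ch2 <- assemble_cohort(events, anchors, omics, task = "pregnancy", seed = 3)
  expect_identical(lapply(ch$records, `[[`, "window"),
                   lapply(ch2$records, `[[`, "window"))
  expect_error(
    assemble_cohort(events, anchors,
                    data.frame(sample_id = "sX", patient_id = "p99",
                               sampling_date = 200L, A1 = 1, A2 = 2),
                    task = "pregnancy"),
    "p99")
})

test_that("multiple omics samples become multiple records of one patient", {
  events <- data.frame(patient_id = "p1", concept_id = "a", date = 100L,
                       source_table = "measurement")
  anchors <- data.frame(patient_id = sprintf("p%d", 1:7),
                        delivery_date = 280L)
  omics <- data.frame(sample_id = c("s1", "s2", "s3"),
                      patient_id = "p1",
                      sampling_date = c(200L, 240L, 270L), A1 = 1:3)
  expect_warning(ch <- assemble_cohort(events, anchors, omics,
                                       task = "pregnancy"),
                 "no events")
  om <- cohort_subset(ch, "omics")
  expect_length(om$records, 3)
  expect_equal(unique(vapply(om$records, `[[`, "", "patient_id")), "p1")
})

test_that("records with all events outside the window are kept, with a warning", {
  events <- data.frame(patient_id = c("p1", "p2"), concept_id = "a",
                       date = c(270L, 100L),
                       source_table = "condition_occurrence")
  anchors <- data.frame(patient_id = c("p1", "p2"), diagnosis_date = NA,
                        delivery_date = NA)
  anchors$diagnosis_date <- c(200L, 200L)
  expect_warning(
    ch <- assemble_cohort(events, anchors, task = "cancer",
                          outcomes = data.frame(patient_id = c("p1", "p2"),
                                                outcome = c(0, 1))),
    "no events")
  expect_length(ch$records, 2)
  expect_equal(nrow(ch$records[["p1"]]$events), 0)
})

test_that("cohort bundles round-trip through the plain-text format", {
  gen <- tiny_gen()
  dir <- withr::local_tempdir()
  write_cohort(gen$cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(length(back$records), length(gen$cohort$records))
  expect_equal(back$task, gen$cohort$task)
  r0 <- gen$cohort$records[[45]]
  r1 <- back$records[[r0$record_id]]
  expect_equal(r1$events$code, r0$events$code)
  expect_equal(r1$outcome, r0$outcome, tolerance = 1e-12)
  om0 <- Filter(function(r) !is.null(r$omics), gen$cohort$records)[[1]]
  expect_equal(back$records[[om0$record_id]]$omics, om0$omics,
               tolerance = 1e-12)
})
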