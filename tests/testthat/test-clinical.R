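base_record <- function(...) {
  rec <- data.frame(subject_id = "s1", cohort = 2L, tumor = TRUE,
                    age_dx = 60, histology = "serous",
                    neoadjuvant = FALSE, recurrent_tissue = FALSE,
                    measurable_disease = TRUE,
                    lesion_response = "complete",
                    ca125_normalized_4wk = NA, ca125_drop_gt50_4wk = NA,
                    dx_date = as.Date("2005-01-01"),
                    last_contact_or_death_date = as.Date("2010-01-01"),
                    vital_status = "alive", stage = "III",
                    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

test_that("analysis-set filter applies the three exclusion rules", {
  recs <- rbind(base_record(subject_id = "keep"),
                base_record(subject_id = "neo", neoadjuvant = TRUE),
                base_record(subject_id = "muc", histology = "mucinous"),
                base_record(subject_id = "rec", recurrent_tissue = TRUE))
  kept <- filter_analysis_set(recs, quiet = TRUE)
  expect_equal(kept$subject_id, "keep")
  excl <- attr(kept, "exclusions")
  expect_equal(unname(excl[c("non_serous", "neoadjuvant",
                             "recurrent_tissue")]), c(1, 1, 1))
  # benign records pass through regardless of histology
  ben <- base_record(subject_id = "ben", tumor = FALSE, histology = "benign")
  expect_equal(nrow(filter_analysis_set(rbind(recs, ben), quiet = TRUE)), 2)
})

test_that("exclusion filters commute", {
  set.seed(1)
  recs <- do.call(rbind, lapply(1:40, function(i) base_record(
    subject_id = paste0("s", i),
    histology = sample(c("serous", "mucinous", "endometrioid"), 1),
    neoadjuvant = sample(c(TRUE, FALSE), 1),
    recurrent_tissue = sample(c(TRUE, FALSE), 1))))
  one_filter <- function(recs, which) {
    drop <- switch(which,
                   hist = recs$histology != "serous",
                   neo = recs$neoadjuvant,
                   rec = recs$recurrent_tissue)
    recs[!drop, , drop = FALSE]
  }
  for (ord in list(c("hist", "neo", "rec"), c("rec", "hist", "neo"),
                   c("neo", "rec", "hist"))) {
    stepwise <- Reduce(one_filter, ord, recs)
    expect_equal(sort(stepwise$subject_id),
                 sort(filter_analysis_set(recs, quiet = TRUE)$subject_id))
  }
})

test_that("response classification follows the CR/IR definitions", {
  expect_equal(classify_response(base_record()), "CR")
  expect_equal(classify_response(base_record(lesion_response = "partial")),
               "IR")
  expect_equal(classify_response(base_record(lesion_response = "stable")),
               "IR")
  expect_equal(classify_response(
    base_record(lesion_response = "progression")), "IR")
  # no measurable lesion: CA-125 rules
  expect_equal(classify_response(base_record(
    measurable_disease = FALSE, lesion_response = NA,
    ca125_normalized_4wk = TRUE)), "CR")
  expect_equal(classify_response(base_record(
    measurable_disease = FALSE, lesion_response = NA,
    ca125_normalized_4wk = FALSE, ca125_drop_gt50_4wk = TRUE)), "IR")
  # indeterminate when the fields are missing
  expect_true(is.na(classify_response(base_record(
    measurable_disease = FALSE, lesion_response = NA))))
  # contradictory fields error out
  expect_error(classify_response(base_record(
    lesion_response = "progression", ca125_normalized_4wk = TRUE)),
    "contradictory")
})

test_that("overall survival is date difference in 30.4375-day months", {
  rec <- base_record(dx_date = as.Date("2000-01-01"),
                     last_contact_or_death_date = as.Date("2003-05-15"),
                     vital_status = "dead")
  os <- compute_os(rec)
  expect_equal(os$os_months, 1230 / 30.4375) # 1230 days by the calendar
  expect_equal(os$os_event, 1L)
  # diagnosis day itself, alive: 0 months censored
  rec2 <- base_record(last_contact_or_death_date = as.Date("2005-01-01"))
  expect_equal(compute_os(rec2)$os_months, 0)
  expect_equal(compute_os(rec2)$os_event, 0L)
  expect_error(compute_os(base_record(
    last_contact_or_death_date = as.Date("2004-12-31"))), "precedes")
})

test_that("survivor grouping partitions every case", {
  expect_equal(assign_survival_group(70, 0), "long")
  expect_equal(assign_survival_group(70, 1), "long")
  expect_equal(assign_survival_group(30, 1), "short")
  expect_equal(assign_survival_group(45, 1), "excluded")  # died 36-60 mo
  expect_equal(assign_survival_group(30, 0), "excluded")  # short follow-up
  expect_equal(assign_survival_group(199.0, 0), "long")
  # property: exactly one group per case over a grid
  grid <- expand.grid(os = seq(0, 120, by = 6), event = 0:1)
  g <- assign_survival_group(grid$os, grid$event)
  expect_true(all(g %in% c("long", "short", "excluded")))
})

test_that("annotate_clinical degrades to available columns", {
  recs <- rbind(base_record(), base_record(subject_id = "s2"))
  ann <- annotate_clinical(recs, quiet = TRUE)
  expect_true(all(c("response", "os_months", "survival_group",
                    "age_group", "stage_group") %in% names(ann)))
  slim <- recs[, c("subject_id", "histology", "tumor", "neoadjuvant",
                   "recurrent_tissue")]
  ann2 <- annotate_clinical(slim, quiet = TRUE)
  expect_false("os_months" %in% names(ann2))
  expect_equal(nrow(ann2), 2)
})
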