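small_cfg <- function(...) generator_config(n_practices = 15, mean_patients = 40, ...)

test_that("the generator is deterministic under a fixed seed", {
  a <- generate_ehr(small_cfg(), seed = 123)
  b <- generate_ehr(small_cfg(), seed = 123)
  for (nm in c("patients", "episodes", "prescriptions", "acq", "truth")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c <- generate_ehr(small_cfg(), seed = 124)
  expect_false(identical(a$prescriptions, c$prescriptions))
})

test_that("generated tables survive the file round trip", {
  ehr <- generate_ehr(small_cfg(), seed = 9)
  dir <- withr::local_tempdir()
  write_ehr(ehr, dir)
  back <- read_ehr(dir)
  for (nm in c("patients", "episodes", "prescriptions", "acq")) {
    for (col in names(ehr[[nm]])) {
      expect_equal(back[[nm]][[col]], ehr[[nm]][[col]], ignore_attr = TRUE)
    }
  }
})

test_that("the pipeline recovers the generator's discrete truth exactly", {
  ehr <- generate_ehr(generator_config(n_practices = 20, mean_patients = 50),
                      seed = 314)
  res <- build_analysis_dataset(ehr[1:4])
  d <- res$data
  tr <- ehr$truth[match(d$patient_id, ehr$truth$patient_id), ]
  expect_true(all(is.na(tr$decoy)))          # decoys never reach the cohort
  expect_identical(d$saba_n, tr$saba_n)      # SABA counts round-trip
  expect_identical(d$n_courses, tr$n_courses)  # OCS courses round-trip
  expect_identical(d$controlled, tr$controlled)  # control status round-trip
  expect_identical(is.na(d$controlled), !tr$acq_available)
  expect_equal(as.character(d$comed_cat), tr$comed_cat)
  expect_equal(as.character(d$comorb_cat), tr$comorb_cat)
  expect_equal(as.character(d$gina_class), tr$gina_class)
  expect_equal(as.character(d$age_group), tr$age_group)
  # derived CMA7 tracks the latent implementation level
  ok <- !is.na(d$cma7_pct)
  expect_gt(cor(d$cma7_pct[ok], tr$a[ok], method = "spearman"), 0.9)
})

test_that("every decoy type is removed at its intended filter", {
  ehr <- generate_ehr(small_cfg(frac_r95 = 0.05, frac_underage = 0.05,
                                frac_single_rx = 0.05, frac_missing_dose = 0.05),
                      seed = 88)
  sel <- select_patients(ehr$patients, ehr$episodes, ehr$prescriptions,
                         window_2016())
  m <- dplyr::left_join(sel$members, ehr$truth[, c("patient_id", "decoy")],
                        by = "patient_id")
  expect_true(all(m$exclusion_reason[m$decoy %in% "r95"] == "no_copd"))
  expect_true(all(m$exclusion_reason[m$decoy %in% "underage"] == "age_ok"))
  expect_true(all(m$exclusion_reason[m$decoy %in% "single_rx"] ==
                    "enough_inhalation_rx"))
  expect_true(all(m$member[m$decoy %in% "missing_dose"]))  # caught later
  part <- exclude_uncomputable_adherence(sel$members, ehr$prescriptions,
                                         window_2016())
  expect_setequal(part$excluded$patient_id,
                  ehr$truth$patient_id[ehr$truth$decoy %in% "missing_dose"])
})

test_that("derived covariate marginals converge to the configured marginals", {
  ehr <- generate_ehr(generator_config(n_practices = 50, mean_patients = 60),
                      seed = 2718)
  res <- build_analysis_dataset(ehr[1:4])
  d <- res$data
  cfg <- ehr$config$covariate_marginals
  # binomial noise at n ~ 3000 stays well inside 2.5 points per level
  for (pair in list(list("sex", cfg$sex), list("age_group", cfg$age_group),
                    list("comed_cat", cfg$comed_cat),
                    list("comorb_cat", cfg$comorb_cat))) {
    got <- prop.table(table(d[[pair[[1]]]]))
    expect_lt(max(abs(as.numeric(got[names(pair[[2]])]) -
                        as.numeric(pair[[2]]))), 0.025)
  }
})

test_that("refill streams encode the latent adherence level", {
  w <- window_2016()
  cfg <- small_cfg(jitter_sd = 1e-9, p_prewindow_fill = 0)
  # a = 1: back-to-back fills, gap-free coverage from the first fill onwards
  set.seed(1); d1 <- asthmaCMA:::refill_dates(1, w, cfg)
  expect_true(all(diff(as.integer(d1)) == cfg$fill_days))
  ev1 <- rx_tbl(patient_id = "x", issue_date = as.character(d1))
  uncovered_head <- as.integer(min(d1) - w$start)
  expect_equal(cma7(ev1, w)$covered_days, 366L - uncovered_head)
  # a = 0.5 without jitter: a fill every 60 days, CMA7 near 50
  set.seed(2); d2 <- asthmaCMA:::refill_dates(0.5, w, cfg)
  expect_true(all(diff(as.integer(d2)) == 60))
  ev2 <- rx_tbl(patient_id = "x", issue_date = as.character(d2))
  expect_lt(abs(cma7(ev2, w)$cma7_pct - 50), 2)
  # with jitter, the population mean CMA7 stays near 100 a
  cfgj <- small_cfg()
  set.seed(3)
  pct <- vapply(1:300, function(i) {
    ev <- rx_tbl(patient_id = "x",
                 issue_date = as.character(asthmaCMA:::refill_dates(0.7, w, cfgj)))
    cma7(ev, w)$cma7_pct
  }, numeric(1))
  expect_lt(abs(mean(pct) - 70), 3)
})

test_that("generated ACQ items are consistent with the drawn control status", {
  ehr <- generate_ehr(small_cfg(), seed = 55)
  ctrl <- derive_control(ehr$acq, unique(ehr$acq$patient_id), window_2016())
  tr <- ehr$truth[match(ctrl$patient_id, ehr$truth$patient_id), ]
  expect_identical(ctrl$controlled, tr$controlled)
  expect_true(all(ctrl$acq5[ctrl$controlled] < 0.75))
  expect_true(all(ctrl$acq5[!ctrl$controlled] >= 0.75))
})

test_that("intercept calibration hits the target rate (Monte-Carlo oracle)", {
  coefs <- list(f1 = c(b = log(2.0), c = log(0.5)), f2 = c(y = log(3.0)))
  probs <- list(f1 = c(a = 0.5, b = 0.3, c = 0.2), f2 = c(x = 0.6, y = 0.4))
  sigma2 <- 0.25
  b0 <- calibrate_intercept(coefs, probs, sigma2, target_rate = 0.15)
  set.seed(40); n <- 4e5
  lp <- b0 +
    c(a = 0, coefs$f1)[sample(names(probs$f1), n, TRUE, probs$f1)] +
    c(x = 0, coefs$f2)[sample(names(probs$f2), n, TRUE, probs$f2)] +
    rnorm(n, 0, sqrt(sigma2))
  expect_equal(mean(plogis(lp)), 0.15, tolerance = 0.01)
})

test_that("generated outcome rates land near the configured targets", {
  # tolerances are ~3 sigma for this design (60 practices dominate the
  # noise in the exacerbation rate; the ACQ subsample is ~570 patients)
  ehr <- generate_ehr(generator_config(n_practices = 60, mean_patients = 60),
                      seed = 1618)
  tr <- ehr$truth[is.na(ehr$truth$decoy), ]
  expect_lt(abs(mean(tr$any_exacerbation) - ehr$config$exac_model$target_rate),
            0.025)
  expect_lt(abs(mean(tr$controlled[tr$acq_available]) -
                  ehr$config$control_model$target_rate), 0.07)
})
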