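w2016 <- window_2016()

test_that("SABA counts map onto the five use categories", {
  expect_equal(as.character(saba_category(c(0, 2, 3, 13))),
               c("0", "1-2", "3-6", ">=13"))
  rx <- dplyr::bind_rows(
    rx_tbl(patient_id = "p1", atc = "R03AC02", quantity = 200,
           doses_per_day = NA, issue_date = c("2016-02-01", "2016-09-01")),
    rx_tbl(patient_id = "p1", atc = "R03AC02", quantity = 200,
           doses_per_day = NA, issue_date = "2015-12-01"),  # outside window
    rx_tbl(patient_id = "p1", atc = "R03BA02")               # not SABA
  )
  out <- count_saba(rx, c("p1", "p9"), w2016)
  expect_equal(out$saba_n, c(2L, 0L))
  expect_equal(as.character(out$saba_cat), c("1-2", "0"))
  # every count maps to exactly one category
  expect_false(anyNA(saba_category(0:40)))
})

ocs_tbl <- function(..., atc = "H02AB06") rx_tbl(..., atc = atc)

test_that("OCS qualification needs >=20 mg/day or tapering plus the diagnosis rule", {
  # 5 mg x 6/day linked to asthma: qualifies
  q <- qualify_ocs(ocs_tbl(strength_mg = 5, doses_per_day = 6,
                           linked_icpc = "R96"))
  expect_true(q)
  # 10 mg/day, no taper: below threshold
  expect_false(qualify_ocs(ocs_tbl(strength_mg = 5, doses_per_day = 2,
                                   linked_icpc = "R96")))
  # tapering qualifies regardless of dose
  expect_true(qualify_ocs(ocs_tbl(strength_mg = 5, doses_per_day = 2,
                                  linked_icpc = "R96", tapering = TRUE)))
  # linked COPD never qualifies
  expect_false(qualify_ocs(ocs_tbl(strength_mg = 5, doses_per_day = 6,
                                   linked_icpc = "R95")))
  # unlinked prescription, other OCS linked to a non-respiratory diagnosis
  ev <- dplyr::bind_rows(
    ocs_tbl(strength_mg = 10, doses_per_day = 2, linked_icpc = NA_character_),
    ocs_tbl(strength_mg = 5, doses_per_day = 2, linked_icpc = "L99"))
  expect_equal(qualify_ocs(ev), c(FALSE, FALSE))
  # unlinked prescription with no other known diagnosis: included
  expect_true(qualify_ocs(ocs_tbl(strength_mg = 10, doses_per_day = 2,
                                  linked_icpc = NA_character_)))
  # no dose fields and no tapering flag: non-qualifying with a warning
  expect_warning(
    q2 <- qualify_ocs(ocs_tbl(strength_mg = NA, doses_per_day = NA,
                              linked_icpc = "R96")),
    "non-qualifying")
  expect_false(q2)
})

test_that("prescriptions within 14 days chain-merge into one course", {
  expect_equal(nrow(build_ocs_courses(as.Date("2016-01-01"))), 1L)
  c2 <- build_ocs_courses(as.Date(c("2016-01-01", "2016-01-10", "2016-01-30")))
  expect_equal(nrow(c2), 2L)
  expect_equal(c2$n_rx, c(2L, 1L))
  # gaps of 13 and 14 days both chain
  c1 <- build_ocs_courses(as.Date(c("2016-01-01", "2016-01-14", "2016-01-28")))
  expect_equal(nrow(c1), 1L)
  # permutation invariance
  set.seed(5)
  d <- as.Date("2016-01-01") + sample(0:200, 12)
  expect_equal(nrow(build_ocs_courses(d)), nrow(build_ocs_courses(sample(d))))
})

test_that("chain merging equals brute-force transitive clustering", {
  set.seed(202)
  for (rep in 1:250) {
    n <- sample(1:12, 1)
    d <- as.Date("2016-01-01") + sample(0:330, n, replace = TRUE)
    expect_equal(nrow(build_ocs_courses(d)), oracle_course_count(d))
  }
})

test_that("widening the merge gap never increases the course count", {
  set.seed(303)
  for (rep in 1:40) {
    d <- as.Date("2016-01-01") + sample(0:330, sample(2:10, 1), replace = TRUE)
    n14 <- nrow(build_ocs_courses(d, gap_days = 14L))
    n21 <- nrow(build_ocs_courses(d, gap_days = 21L))
    n7 <- nrow(build_ocs_courses(d, gap_days = 7L))
    expect_lte(n21, n14)
    expect_gte(n7, n14)
  }
})

test_that("exacerbation derivation counts qualifying courses only", {
  rx <- dplyr::bind_rows(
    ocs_tbl(patient_id = "p1", strength_mg = 5, doses_per_day = 6,
            linked_icpc = "R96",
            issue_date = c("2016-02-01", "2016-02-10", "2016-06-01")),
    ocs_tbl(patient_id = "p2", strength_mg = 5, doses_per_day = 2,
            linked_icpc = "L88", issue_date = "2016-03-01"))
  out <- derive_exacerbations(rx, c("p1", "p2"), w2016)
  expect_equal(out$n_courses, c(2L, 0L))
  expect_equal(as.character(out$exac_cat), c("2", "0"))
  expect_equal(out$any_exacerbation, c(TRUE, FALSE))
})

test_that("ACQ record selection prefers the last 2016 score, then early 2017", {
  rec <- acq_tbl(date = c("2016-03-01", "2016-11-20", "2017-02-01"))
  sel <- select_acq_record(rec, w2016)
  expect_equal(sel$date, as.Date("2016-11-20"))
  rec2 <- acq_tbl(date = "2017-02-15")
  expect_equal(select_acq_record(rec2, w2016)$date, as.Date("2017-02-15"))
  rec3 <- acq_tbl(date = "2017-05-01")
  expect_null(select_acq_record(rec3, w2016))
  # same-date tie breaks to the later input row
  rec4 <- acq_tbl(date = c("2016-06-01", "2016-06-01"), items = c(0, 0, 0, 0, 0))
  rec4$item1 <- c(0, 3)
  expect_equal(select_acq_record(rec4, w2016)$item1, 3)
})

test_that("ACQ-5 is the mean of the first five items against the 0.75 cut-point", {
  expect_equal(acq5_score(acq_tbl(items = c(0, 0, 0, 0, 0))),
               list(acq5 = 0, controlled = TRUE))
  expect_equal(acq5_score(acq_tbl(items = c(1, 1, 1, 1, 1))),
               list(acq5 = 1, controlled = FALSE))
  # a score of exactly 0.75 is uncontrolled
  at_cut <- acq5_score(acq_tbl(items = c(1, 1, 1, 0.75, 0)))
  expect_false(at_cut$controlled)
  # sum mode scales the cut-point by 5
  expect_false(acq5_score(acq_tbl(items = c(1, 1, 1, 1, 0)), mode = "sum")$controlled)
  expect_true(acq5_score(acq_tbl(items = c(1, 1, 1, 0, 0)), mode = "sum")$controlled)
  expect_error(acq5_score(acq_tbl(items = c(1, NA, 1, 1, 1))), "unusable")
})
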