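test_that("detection frequency uses the fixed roster denominator", {
  ids <- sprintf("s%02d", 1:60)
  m52 <- measurement_table(ids[1:52], "bdcm", 1)
  expect_equal(detection_frequency(m52, "bdcm", 60), 86.7)
  expect_equal(detection_frequency(m52, "absent", 60), 0)
  m60 <- measurement_table(ids, "barium", 50)
  expect_equal(detection_frequency(m60, "barium", 60), 100)
  expect_error(detection_frequency(m52, "bdcm", 0), "positive")
})

test_that("constituent summaries run over detected values only", {
  m <- measurement_table(c("a", "b", "c", "d"), "x",
                         c(1, 2, 3, NA),
                         status = c(rep("detected", 3), "nondetect"))
  cs <- constituent_summary(m, "x", 4)
  expect_equal(cs$median_detected, 2)
  expect_equal(c(cs$min_detected, cs$max_detected), c(1, 3))

  single <- measurement_table("a", "d24", 0.050)
  cs1 <- constituent_summary(single, "d24", 60)
  expect_equal(cs1$median_detected, 0.050)
  expect_equal(cs1$min_detected, cs1$max_detected)

  none <- constituent_summary(m, "ghost", 4)
  expect_true(is.na(none$median_detected))
  expect_equal(none$n_detected, 0)
})

test_that("exceedance screening: strict inequality, de facto zero rule", {
  m <- measurement_table(sprintf("s%d", 1:5), "x", c(10, 70, 70.1, 50, 3))
  # positive benchmark: strictly greater only
  expect_equal(screen_exceedances(m, "x", 70)$count, 1)
  # zero benchmark: every detection is a de facto exceedance
  expect_equal(screen_exceedances(m, "x", 0)$count, 5)
  # missing benchmark is an empty result, not an error
  expect_true(is.na(screen_exceedances(m, "x", NA)$count))
  # chloroform worked example: all detections below the 70 ug/L MCLG
  chl <- measurement_table(sprintf("s%d", 1:51), "chloroform",
                           seq(0.04, 50.6, length.out = 51))
  expect_equal(screen_exceedances(chl, "chloroform", 70)$count, 0)
})

test_that("exceedance counts are monotone non-increasing in the benchmark", {
  set.seed(9)
  m <- measurement_table(sprintf("s%d", 1:40), "x", rlnorm(40, 1, 1))
  counts <- vapply(c(0, 0.5, 1, 2, 5, 10, 50),
                   function(b) screen_exceedances(m, "x", b)$count, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-sample regulatory profiles match an independent recount", {
  ds <- forced_count_study()
  meas <- dplyr::bind_rows(ds$measurements,
                           tthm_measurements(ds$measurements, ds$samples))
  prof <- per_sample_regulatory_profile(meas, ds$benchmarks, ds$samples)
  # brute-force recount straight from the tables
  for (s in c("site_001", "site_030", "site_053", "site_060")) {
    det <- meas[meas$sample_id == s & meas$status == "detected", ]
    n_mclg <- 0L
    for (i in seq_len(nrow(det))) {
      bm <- ds$benchmarks[ds$benchmarks$analyte_id == det$analyte_id[i] &
                            ds$benchmarks$benchmark_type == "MCLG", ]
      if (nrow(bm) == 0) next
      if (bm$value_ugL[1] == 0 || det$value_ugL[i] > bm$value_ugL[1]) {
        n_mclg <- n_mclg + 1L
      }
    }
    expect_equal(prof$n_mclg_exceeded[prof$sample_id == s], n_mclg)
  }
  # a sample with detections of two zero-MCLG DBPs only
  two <- measurement_table(c("p1", "p1"),
                           c("bromodichloromethane", "bromoform"),
                           c(1.0, 1.0))
  prof2 <- per_sample_regulatory_profile(
    two, ds$benchmarks, sample_meta("p1", "SELA", source_water = "mixed"))
  expect_equal(prof2$n_mclg_exceeded, 2L)
  expect_equal(prof2$mclg_drivers, "bromodichloromethane,bromoform")
  # no benchmarked detections -> zeros
  nb <- measurement_table("p1", "bromoform", NA, status = "nondetect")
  prof3 <- per_sample_regulatory_profile(
    nb, ds$benchmarks, sample_meta("p1", "SELA", source_water = "mixed"))
  expect_equal(prof3$n_mclg_exceeded + prof3$n_mcl_exceeded, 0L)
})

test_that("TTHM totals sum detected THMs and stay nondetect otherwise", {
  m <- measurement_table(rep("s1", 4), thm4(), c(0.78, 1.07, 1.55, 2.50))
  expect_equal(tthm_total(m, "s1"), 5.90)
  none <- measurement_table("s2", "chloroform", NA, status = "nondetect")
  expect_true(is.na(tthm_total(none, "s2")))
  one <- measurement_table("s3", "bromoform", 206)
  expect_equal(tthm_total(one, "s3"), 206)
  tt <- tthm_measurements(
    dplyr::bind_rows(m, none, one),
    sample_meta(c("s1", "s2", "s3"), rep("Kern", 3), source_water = "GW"))
  expect_equal(tt$status, c("detected", "nondetect", "detected"))
})

test_that("ER trigger comparison is strict at 3.8 ng E2-equivalents/L", {
  expect_equal(er_trigger_check(1.0), "not_exceeds")
  expect_equal(er_trigger_check(3.8), "not_exceeds")
  expect_equal(er_trigger_check(5.0), "exceeds")
  expect_error(er_trigger_check(-0.1), ">= 0")
})
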