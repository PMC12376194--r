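test_that("molar conversion and the EAR ratio are plain arithmetic", {
  expect_equal(to_molar(100, 100), 1.0)
  expect_equal(to_molar(0, 250), 0)
  expect_equal(to_molar(163.9, 163.8), 1.0006, tolerance = 1e-4)
  expect_error(to_molar(1, -5), "positive")
  expect_equal(ear_ratio(2, 2), 1.0)
  expect_equal(ear_ratio(0.001 * 5, 5), 0.001)
  # 3 assays, ACCs {1, 2, 10} uM at 2 uM -> EARs {2, 1, 0.2}, max 2
  expect_equal(ear_ratio(2, c(1, 2, 10)), c(2, 1, 0.2))
})

test_that("assay exclusion flags drive filtering", {
  acc <- acc_table(rep("1-1-1", 5), sprintf("ep%d", 1:5), c(1, 2, 3, 4, 5),
                   exclusion_reason = c("none", "baseline", "none",
                                        "unreliable_curve", "none"))
  kept <- filter_assays(acc)
  expect_equal(nrow(kept), 3)
  expect_false(any(kept$excluded))
})

test_that("sample ΣEAR sums chemical maxima and classifies against thresholds", {
  analytes <- analyte_table(c("chemA", "chemB"), c("pesticide", "DBP"),
                            cas = c("100-00-1", "200-00-2"),
                            molecular_weight = c(100, 200))
  # chemA: 60 ug/L = 0.6 uM vs ACC 1 -> max EAR 0.6
  # chemB: 100 ug/L = 0.5 uM vs ACCs {1, 5} -> max EAR 0.5
  acc <- acc_table(c("100-00-1", "200-00-2", "200-00-2"),
                   c("ep1", "ep1", "ep2"), c(1, 1, 5))
  det <- measurement_table(c("s1", "s1"), c("chemA", "chemB"), c(60, 100))
  r <- sample_sum_ear(det, analytes, acc)
  expect_equal(r$sum_ear, 1.1)
  expect_equal(r$class, "above_action")
  expect_equal(r$chem_max$analyte_id[1], "chemA")  # driver ranked first

  empty <- det[0, ]
  r0 <- sample_sum_ear(empty, analytes, acc)
  expect_equal(r0$sum_ear, 0)
  expect_equal(r0$class, "below")

  all_excluded <- acc_table("100-00-1", "ep1", 1,
                            exclusion_reason = "baseline")
  expect_warning(
    r_na <- sample_sum_ear(measurement_table("s1", "chemA", 60),
                           analytes, all_excluded),
    "coverage")
  expect_equal(r_na$sum_ear, 0)
})

test_that("both aggregation modes match a brute-force enumeration", {
  analytes <- analyte_table(c("c1", "c2", "c3"),
                            rep("pesticide", 3),
                            cas = c("1-1-1", "2-2-2", "3-3-3"),
                            molecular_weight = c(100, 100, 100))
  acc <- acc_table(rep(c("1-1-1", "2-2-2", "3-3-3"), each = 2),
                   rep(c("epA", "epB"), 3),
                   c(0.5, 2, 1, 0.25, 4, 8))
  det <- measurement_table(rep("s1", 3), c("c1", "c2", "c3"), c(50, 20, 80))
  conc_um <- c(0.5, 0.2, 0.8)
  ear_tab <- rbind(conc_um / c(0.5, 1, 4),    # epA row per chemical
                   conc_um / c(2, 0.25, 8))   # epB row per chemical
  exp_chemsum <- sum(apply(ear_tab, 2, max))
  exp_epmax <- max(rowSums(ear_tab))
  r1 <- sample_sum_ear(det, analytes, acc, mode = "sum_of_chemical_max")
  r2 <- sample_sum_ear(det, analytes, acc, mode = "max_endpoint_sum")
  expect_equal(r1$sum_ear, exp_chemsum)
  expect_equal(r2$sum_ear, exp_epmax)
  expect_lte(r2$sum_ear, r1$sum_ear)
})

test_that("ΣEAR is additive in chemicals and linear in concentration", {
  analytes <- analyte_table(c("c1", "c2"), rep("DBP", 2),
                            cas = c("1-1-1", "2-2-2"),
                            molecular_weight = c(150, 250))
  acc <- acc_table(c("1-1-1", "1-1-1", "2-2-2"), c("epA", "epB", "epA"),
                   c(0.3, 0.9, 1.7))
  det <- measurement_table(c("s1", "s1"), c("c1", "c2"), c(12, 30))
  full <- sample_sum_ear(det, analytes, acc)
  solo_c2 <- sample_sum_ear(det[det$analyte_id == "c2", ], analytes, acc)
  c1_max <- full$chem_max$max_ear[full$chem_max$analyte_id == "c1"]
  expect_equal(full$sum_ear - c1_max, solo_c2$sum_ear)

  doubled <- det
  doubled$value_ugL <- doubled$value_ugL * 2
  expect_equal(sample_sum_ear(doubled, analytes, acc)$sum_ear,
               2 * full$sum_ear)
})

test_that("ΣEAR classification thresholds follow the screening levels", {
  expect_equal(classify_ear(11.1), "above_action")
  expect_equal(classify_ear(0.203), "above_precaution")
  expect_equal(classify_ear(0.0005), "below")
  expect_equal(classify_ear(1), "above_precaution")  # strictly above 1 only
  expect_error(classify_ear(-1), ">= 0")
})

test_that("coverage report counts CAS matches among detected organics", {
  ds <- tiny_study()
  ds$acc <- acc_table(c("67-66-3", "67-66-3"), c("ep1", "ep2"), c(1, 2),
                      exclusion_reason = c("none", "baseline"))
  cov <- acc_coverage(ds)
  # detected organics: chloroform, PFOA; only chloroform has an ACC match
  expect_equal(cov$n_detected_organics, 2)
  expect_equal(cov$n_cas_matched, 1)
  expect_equal(cov$n_with_included_assay, 1)
  expect_equal(cov$unmatched, "PFOA")
})
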