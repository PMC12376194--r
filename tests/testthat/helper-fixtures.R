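# Shared in-code fixtures; nothing is read from disk except packaged extdata.

# A minimal consistent study: 3 samples (one private well), 4 analytes.
tiny_study <- function() {
  analytes <- analyte_table(
    analyte_id = c("chloroform", "atrazine", "PFOA", "arsenic"),
    analyte_class = c("DBP", "pesticide", "PFAS", "trace_element"),
    cas = c("67-66-3", "1912-24-9", "335-67-1", "7440-38-2"),
    molecular_weight = c(119.38, 215.68, 414.07, NA),
    native_unit = c("ug/L", "ug/L", "ng/L", "ug/L")
  )
  samples <- sample_meta(
    sample_id = c("s1", "s2", "s3"),
    region = c("GoldCountry", "SELA", "Kern"),
    infrastructure = c("private_well", "PWS", "PWS"),
    source_water = c("GW", "mixed", "GW"),
    service_population = c(NA, 50000L, 800L)
  )
  meas <- measurement_table(
    sample_id = c("s1", "s2", "s2", "s3"),
    analyte_id = c("arsenic", "chloroform", "PFOA", "atrazine"),
    value_ugL = c(5, 0.78, 0.008, NA),
    status = c("detected", "detected", "detected", "nondetect")
  )
  study_dataset(analytes, samples, meas)
}

# 60-sample dataset whose per-constituent detection counts are the
# integer counts forced by the published detection frequencies
# (round(freq * 60 / 100)); concentrations are the published medians.
# THM detections are laid out so the TTHM aggregate is detected in
# exactly 54 samples.
forced_count_study <- function() {
  ids <- sprintf("site_%03d", 1:60)
  samples <- sample_meta(ids, region = rep(study_regions(),
                                           c(12, 6, 10, 10, 22)))
  analytes <- analyte_table(
    analyte_id = c("bromodichloromethane", "bromoform", "chloroform",
                   "dibromochloromethane", "PFOA", "PFOS", "arsenic",
                   "lead", "uranium"),
    analyte_class = c("DBP", "DBP", "DBP", "DBP", "PFAS", "PFAS",
                      "trace_element", "trace_element", "trace_element"),
    native_unit = c(rep("ug/L", 4), "ng/L", "ng/L", rep("ug/L", 3))
  )
  block <- function(analyte, idx, value) {
    measurement_table(ids[idx], analyte, value)
  }
  meas <- dplyr::bind_rows(
    block("bromodichloromethane", 1:52, 1.07),   # 86.7% of 60
    block("chloroform", 1:51, 0.78),             # 85.0%, all <= 50.6
    block("dibromochloromethane", 1:45, 1.55),   # 75.0%
    block("bromoform", 12:54, 2.50),             # 71.7%; union of THMs = 54
    block("PFOA", 1:10, 0.008),                  # 16.7%
    block("PFOS", 1:10, 0.008),
    block("arsenic", 1:6, 7.0),                  # 10.0%
    block("lead", 1:11, 1.2),                    # 18.3%
    block("uranium", 1:8, 6.5)                   # 13.3%
  )
  class(meas) <- c("tapscreen_measurements", class(meas))
  study_dataset(analytes, samples, meas, benchmarks = benchmarks_npdwr())
}

# Small generator config: same five-region layout, handful of analytes.
small_config <- function(p_dbp = 0.8) {
  recipe <- tibble::tibble(
    analyte_id = c("bromodichloromethane", "chloroform", "atrazine",
                   "arsenic", "nitrate_N", "manganese", "lead", "uranium",
                   "lithium", "copper"),
    analyte_class = c("DBP", "DBP", "pesticide", "trace_element",
                      "major_element", "trace_element", "trace_element",
                      "trace_element", "trace_element", "trace_element"),
    cas = c("75-27-4", "67-66-3", "1912-24-9", "", "", "", "", "", "", ""),
    molecular_weight = c(163.83, 119.38, 215.68, NA, NA, NA, NA, NA, NA, NA),
    native_unit = c("ug/L", "ug/L", "ug/L", "ug/L", "mg/L", "ug/L", "ug/L",
                    "ug/L", "ug/L", "ug/L"),
    p_detect = c(p_dbp, p_dbp, 0.3, 0.1, 0.8, 0.8, 0.2, 0.13, 1.0, 0.9),
    median_ugL = c(1.07, 0.78, 0.03, 7, 1560, 1.8, 1.2, 6.5, 3.67, 15.3),
    sdlog = c(0.9, 0.9, 1.1, 0.3, 1.0, 1.2, 0.4, 0.3, 1.2, 1.3),
    min_ugL = c(0.04, 0.04, 0.001, 4, 18, 0.2, 0.5, 4, 0.06, 1),
    max_ugL = c(70.7, 50.6, 0.165, 9, 6190, 104, 2, 8, 37.1, 287)
  )
  generator_config(recipe = recipe)
}

empty_benchmarks <- function() {
  benchmark_table(character(), character(), numeric())
}

empty_acc <- function() {
  acc_table(character(), character(), numeric())
}
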