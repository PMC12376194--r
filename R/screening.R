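#' Percent detection frequency for one analyte
#'
#' 100 x (number of detected results) / (number of samples on the fixed
#' roster), reported to one decimal place. Censored and missing results
#' count as non-detects; the denominator is the full roster, not the
#' number of reported records.
#'
#' @param measurements Measurement table.
#' @param analyte_id Analyte to summarise.
#' @param n_samples Size of the sample roster (> 0).
#' @return Percent detection frequency, rounded to one decimal.
#' @examples
#' # 52 detections out of 60 samples -> 86.7
#' @export
detection_frequency <- function(measurements, analyte_id, n_samples) {
  if (n_samples <= 0) stop("n_samples must be positive", call. = FALSE)
  n_det <- sum(measurements$analyte_id == analyte_id &
                 measurements$status == "detected")
  round(100 * n_det / n_samples, 1)
}

#' Occurrence and exceedance summary for one constituent
#'
#' Median and range are computed over detected values only; when an
#' analyte was never detected the concentration fields are `NA`.
#' Exceedance counts follow [screen_exceedances()] against the analyte's
#' MCLG and MCL rows (NA when no such benchmark exists).
#'
#' @param measurements Measurement table (ug/L).
#' @param analyte_id Analyte to summarise.
#' @param n_samples Sample roster size.
#' @param benchmarks Optional benchmark table for the exceedance columns.
#' @return One-row tibble: analyte_id, n_samples, detection_frequency_pct,
#'   n_detected, median_detected, min_detected, max_detected,
#'   mclg_exceedances, mcl_exceedances.
#' @export
constituent_summary <- function(measurements, analyte_id, n_samples,
                                benchmarks = NULL) {
  det <- measurements$value_ugL[measurements$analyte_id == analyte_id &
                                  measurements$status == "detected"]
  count_for <- function(type) {
    if (is.null(benchmarks)) return(NA_integer_)
    row <- benchmarks[benchmarks$analyte_id == analyte_id &
                        benchmarks$benchmark_type == type, ]
    if (nrow(row) == 0) return(NA_integer_)
    screen_exceedances(measurements, analyte_id, row$value_ugL[1])$count
  }
  tibble(
    analyte_id = analyte_id,
    n_samples = n_samples,
    detection_frequency_pct = detection_frequency(measurements, analyte_id,
                                                  n_samples),
    n_detected = length(det),
    median_detected = if (length(det)) median(det) else NA_real_,
    min_detected = if (length(det)) min(det) else NA_real_,
    max_detected = if (length(det)) max(det) else NA_real_,
    mclg_exceedances = count_for("MCLG"),
    mcl_exceedances = count_for("MCL")
  )
}

#' Count benchmark exceedances for one analyte
#'
#' A positive benchmark is exceeded by detected values strictly greater
#' than it (a result exactly at the benchmark is compliant). A benchmark
#' of zero — an MCLG with no identified safe-exposure level — is exceeded
#' de facto by every detection.
#'
#' @param measurements Measurement table (ug/L).
#' @param analyte_id Analyte screened.
#' @param benchmark_ugL Benchmark concentration in ug/L (>= 0).
#' @return List with `count` and a tibble `flags` (sample_id, exceeds).
#' @export
screen_exceedances <- function(measurements, analyte_id, benchmark_ugL) {
  if (is.na(benchmark_ugL)) {
    return(list(count = NA_integer_,
                flags = tibble(sample_id = character(), exceeds = logical())))
  }
  det <- measurements[measurements$analyte_id == analyte_id &
                        measurements$status == "detected", ]
  exceeds <- if (benchmark_ugL == 0) {
    rep(TRUE, nrow(det))
  } else {
    det$value_ugL > benchmark_ugL
  }
  list(count = sum(exceeds),
       flags = tibble(sample_id = det$sample_id, exceeds = exceeds))
}

#' Per-sample counts of MCL and MCLG exceedances
#'
#' Screens every benchmarked analyte and rolls results up by sample:
#' how many MCLs and MCLGs each residence's tapwater exceeded, and which
#' analytes drove them.
#'
#' @param measurements Measurement table (ug/L).
#' @param benchmarks Benchmark table.
#' @param samples Sample metadata (fixes the roster; samples with no
#'   exceedances report zeros).
#' @return Tibble: sample_id, n_mcl_exceeded, n_mclg_exceeded,
#'   mcl_drivers, mclg_drivers (comma-separated analyte lists).
#' @export
per_sample_regulatory_profile <- function(measurements, benchmarks, samples) {
  hits <- list()
  for (type in c("MCL", "MCLG")) {
    rows <- benchmarks[benchmarks$benchmark_type == type, ]
    for (i in seq_len(nrow(rows))) {
      sc <- screen_exceedances(measurements, rows$analyte_id[i],
                               rows$value_ugL[i])
      ex <- sc$flags$sample_id[sc$flags$exceeds]
      if (length(ex)) {
        hits[[length(hits) + 1]] <- tibble(sample_id = ex,
                                           analyte_id = rows$analyte_id[i],
                                           type = type)
      }
    }
  }
  base <- tibble(sample_id = samples$sample_id,
                 n_mcl_exceeded = 0L, n_mclg_exceeded = 0L,
                 mcl_drivers = "", mclg_drivers = "")
  if (length(hits) == 0) return(base)
  h <- bind_rows(hits)
  agg <- h %>%
    group_by(.data$sample_id, .data$type) %>%
    summarise(n = dplyr::n(),
              drivers = paste(sort(.data$analyte_id), collapse = ","),
              .groups = "drop")
  for (i in seq_len(nrow(agg))) {
    j <- match(agg$sample_id[i], base$sample_id)
    if (agg$type[i] == "MCL") {
      base$n_mcl_exceeded[j] <- agg$n[i]
      base$mcl_drivers[j] <- agg$drivers[i]
    } else {
      base$n_mclg_exceeded[j] <- agg$n[i]
      base$mclg_drivers[j] <- agg$drivers[i]
    }
  }
  base
}

#' The four regulated trihalomethanes
#'
#' @return Character vector of the analyte ids summed into TTHM.
#' @export
thm4 <- function() {
  c("chloroform", "bromodichloromethane", "dibromochloromethane", "bromoform")
}

#' Total trihalomethane concentration for one sample
#'
#' Sum of the detected concentrations of the four regulated THMs
#' (chloroform, bromodichloromethane, dibromochloromethane, bromoform).
#' When none of the four is detected the total is a non-detect (`NA`)
#' rather than zero, preserving detection-frequency semantics for the
#' TTHM aggregate.
#'
#' @param measurements Measurement table (ug/L).
#' @param sample_id Sample to total.
#' @return TTHM in ug/L, or `NA_real_` when no THM was detected.
#' @export
tthm_total <- function(measurements, sample_id) {
  det <- measurements[measurements$sample_id == sample_id &
                        measurements$analyte_id %in% thm4() &
                        measurements$status == "detected", ]
  if (nrow(det) == 0) return(NA_real_)
  sum(det$value_ugL)
}

#' Derived TTHM measurement records for all samples
#'
#' @param measurements Measurement table (ug/L).
#' @param samples Sample metadata.
#' @return A `tapscreen_measurements` table with analyte_id `"TTHM"`.
#' @export
tthm_measurements <- function(measurements, samples) {
  vals <- vapply(samples$sample_id, function(s) tthm_total(measurements, s),
                 numeric(1))
  measurement_table(
    sample_id = samples$sample_id,
    analyte_id = "TTHM",
    value_ugL = vals,
    status = ifelse(is.na(vals), "nondetect", "detected")
  )
}

#' Estrogen-receptor bioassay trigger comparison
#'
#' Compares a sample's estradiol-equivalent ER bioactivity to the
#' effects-based trigger value of 3.8 ng E2-equivalents per litre;
#' exceedance requires a value strictly above the trigger.
#'
#' @param e2_equiv_ngL Measured E2-equivalents in ng/L (>= 0).
#' @param trigger_ngL Trigger value, default 3.8 ng/L.
#' @return `"exceeds"` or `"not_exceeds"` (vectorised).
#' @export
er_trigger_check <- function(e2_equiv_ngL, trigger_ngL = 3.8) {
  if (any(e2_equiv_ngL < 0, na.rm = TRUE)) {
    stop("E2-equivalent concentration must be >= 0", call. = FALSE)
  }
  ifelse(e2_equiv_ngL > trigger_ngL, "exceeds", "not_exceeds")
}
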