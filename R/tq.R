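#' Most protective benchmark for an analyte, with zero-MCLG surrogates
#'
#' Implements the precautionary benchmark selection: zero-valued MCLGs
#' (no identified safe-exposure level) are first replaced by a surrogate
#' concentration — 0.0001 ug/L for PFOA and PFOS, 0.1 ug/L for other
#' zero-MCLG analytes (DBPs, arsenic, lead, uranium) — and only then is
#' the minimum taken across all available benchmark entries, so a literal
#' zero never wins and toxicity quotients are always well defined.
#'
#' @param analyte_id Analyte to resolve.
#' @param benchmarks Benchmark table (all entries for all analytes).
#' @param config A [screening_config()] providing the surrogate constants.
#' @return One-row tibble: analyte_id, value_ugL, source_type,
#'   surrogate_applied; or zero rows when the analyte has no benchmark
#'   (it is then excluded from ΣTQ).
#' @export
effective_benchmark <- function(analyte_id, benchmarks,
                                config = screening_config()) {
  entries <- benchmarks[benchmarks$analyte_id == analyte_id, ]
  if (nrow(entries) == 0) {
    return(tibble(analyte_id = character(), value_ugL = numeric(),
                  source_type = character(), surrogate_applied = logical()))
  }
  zero_mclg <- entries$benchmark_type == "MCLG" & entries$value_ugL == 0
  surrogate <- if (analyte_id %in% c("PFOA", "PFOS")) {
    config$mclg_zero_surrogate_pfoa_pfos_ugL
  } else {
    config$mclg_zero_surrogate_default_ugL
  }
  entries$value_ugL[zero_mclg] <- surrogate
  i <- which.min(entries$value_ugL)
  tibble(analyte_id = analyte_id,
         value_ugL = entries$value_ugL[i],
         source_type = entries$benchmark_type[i],
         surrogate_applied = zero_mclg[i])
}

#' Effective benchmarks for every benchmarked analyte
#'
#' @param benchmarks Benchmark table.
#' @param config A [screening_config()].
#' @return Tibble, one row per analyte with at least one entry.
#' @export
effective_benchmarks <- function(benchmarks, config = screening_config()) {
  ids <- unique(benchmarks$analyte_id)
  bind_rows(lapply(ids, effective_benchmark, benchmarks = benchmarks,
                   config = config))
}

#' Toxicity quotient
#'
#' Ratio of a detected concentration to its health-based benchmark, both
#' in ug/L. Non-detects contribute no quotient (they are simply absent
#' from ΣTQ).
#'
#' @param conc_ugL Detected concentration(s).
#' @param benchmark_ugL Effective benchmark (positive).
#' @return conc_ugL / benchmark_ugL.
#' @export
tq_ratio <- function(conc_ugL, benchmark_ugL) {
  if (any(benchmark_ugL <= 0, na.rm = TRUE)) {
    stop("benchmark must be positive (apply zero-MCLG surrogates first)",
         call. = FALSE)
  }
  conc_ugL / benchmark_ugL
}

#' Classify a cumulative toxicity quotient
#'
#' ΣTQ at or above 1 indicates a high probability of risk (`high_risk`);
#' below 0.1 indicates no risk (`negligible`); values between are
#' `intermediate`.
#'
#' @param sum_tq Non-negative ΣTQ value(s).
#' @param config A [screening_config()].
#' @return Character class per value.
#' @export
classify_tq <- function(sum_tq, config = screening_config()) {
  ifelse(sum_tq >= config$tq_action_threshold, "high_risk",
         ifelse(sum_tq < config$tq_negligible_threshold, "negligible",
                "intermediate"))
}

#' Cumulative toxicity quotient (hazard index) for one sample
#'
#' Sums toxicity quotients of individual detections — organic and
#' inorganic alike — against each analyte's most protective benchmark
#' (after zero-MCLG surrogate substitution), under the non-interactive
#' concentration-addition mixture model. Detected analytes with no
#' benchmark are excluded and reported.
#'
#' @param detections Measurement rows for one sample.
#' @param benchmarks Benchmark table.
#' @param config A [screening_config()].
#' @return List of class `tq_result`: `sample_id`, `sum_tq`, `class`,
#'   `per_analyte` (tibble analyte_id, conc_ugL, benchmark_ugL, tq,
#'   ranked by descending TQ — the drivers), `n_individual_tq_over_1`,
#'   `unbenchmarked` (detected analytes without benchmarks).
#' @export
sample_sum_tq <- function(detections, benchmarks, config = screening_config()) {
  sample_id <- unique(detections$sample_id)
  if (length(sample_id) > 1) {
    stop("detections must belong to a single sample", call. = FALSE)
  }
  if (length(sample_id) == 0) sample_id <- NA_character_
  det <- detections[detections$status == "detected", ]
  eb <- effective_benchmarks(benchmarks, config)
  bm <- eb$value_ugL[match(det$analyte_id, eb$analyte_id)]
  has_bm <- !is.na(bm)
  per <- tibble(
    analyte_id = det$analyte_id[has_bm],
    conc_ugL = det$value_ugL[has_bm],
    benchmark_ugL = bm[has_bm]
  )
  per$tq <- if (nrow(per)) tq_ratio(per$conc_ugL, per$benchmark_ugL) else numeric()
  per <- per[order(-per$tq), , drop = FALSE]
  sum_tq <- sum(per$tq)
  structure(list(
    sample_id = sample_id,
    sum_tq = sum_tq,
    class = classify_tq(sum_tq, config),
    per_analyte = per,
    n_individual_tq_over_1 = sum(per$tq > 1),
    unbenchmarked = unique(det$analyte_id[!has_bm])
  ), class = "tq_result")
}

#' @export
print.tq_result <- function(x, ...) {
  cat(sprintf("<tq_result> sample %s: ΣTQ = %.4g (%s), %d analyte(s) with TQ > 1\n",
              x$sample_id, x$sum_tq, x$class, x$n_individual_tq_over_1))
  invisible(x)
}

#' ΣTQ hazard-index screen across all samples of a study
#'
#' @param dataset A [study_dataset()].
#' @param config A [screening_config()].
#' @return Tibble: sample_id, sum_tq, class, n_individual_tq_over_1,
#'   top_driver.
#' @export
study_sum_tq <- function(dataset, config = screening_config()) {
  res <- lapply(dataset$samples$sample_id, function(s) {
    det <- dataset$measurements[dataset$measurements$sample_id == s, ]
    r <- sample_sum_tq(det, dataset$benchmarks, config)
    tibble(sample_id = s, sum_tq = r$sum_tq, class = r$class,
           n_individual_tq_over_1 = r$n_individual_tq_over_1,
           top_driver = if (nrow(r$per_analyte)) r$per_analyte$analyte_id[1]
                        else NA_character_)
  })
  bind_rows(res)
}

#' EPA four-PFAS mixture hazard index
#'
#' HI = sum over detected mixture components of concentration divided by
#' the component's health-based water concentration (HBWC). The mixture
#' rule applies to two or more of the four components (PFNA, PFBS,
#' PFHxS, GenX): the sample is flagged only when HI is strictly above 1
#' and at least two components were detected. HBWC values must be
#' supplied by the caller (via `config$pfas_hi_components`, a named
#' vector in ug/L); no defaults are packaged.
#'
#' @param detections Measurement rows for one sample.
#' @param config A [screening_config()] with `pfas_hi_components` set.
#' @return List: `hi`, `n_components_detected`, `flagged`.
#' @export
pfas_hazard_index <- function(detections, config) {
  hbwc <- config$pfas_hi_components
  if (is.null(hbwc) || length(hbwc) == 0 || is.null(names(hbwc))) {
    stop("pfas_hi_components (named HBWC vector, ug/L) must be configured",
         call. = FALSE)
  }
  if (any(hbwc <= 0)) stop("HBWC values must be positive", call. = FALSE)
  det <- detections[detections$status == "detected" &
                      detections$analyte_id %in% names(hbwc), ]
  hi <- if (nrow(det)) {
    sum(det$value_ugL / hbwc[det$analyte_id])
  } else 0
  n_comp <- length(unique(det$analyte_id))
  list(hi = unname(hi), n_components_detected = n_comp,
       flagged = hi > 1 && n_comp >= 2)
}
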