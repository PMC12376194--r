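#' Drop excluded bioassay rows from an ACC table
#'
#' Non-specific endpoints, baseline responses and unreliable
#' concentration-response curves are flagged on ingest and removed here
#' before any EAR arithmetic.
#'
#' @param acc A `tapscreen_acc` table.
#' @return The subset with `excluded == FALSE`.
#' @export
filter_assays <- function(acc) {
  acc[!acc$excluded, , drop = FALSE]
}

#' Exposure-activity ratio for a single chemical x assay pair
#'
#' Ratio of the detected water concentration (converted to micromolar)
#' to the assay's activity concentration at cutoff.
#'
#' @param conc_um Detected concentration in uM.
#' @param acc_um ACC in uM (positive).
#' @return conc_um / acc_um (vectorised).
#' @export
ear_ratio <- function(conc_um, acc_um) {
  if (any(acc_um <= 0, na.rm = TRUE)) stop("acc_um must be positive", call. = FALSE)
  conc_um / acc_um
}

#' Classify a cumulative EAR against screening thresholds
#'
#' ΣEAR above 1 indicates exposure expected to modulate a molecular
#' target in vitro (`above_action`); above 0.001 is the precautionary
#' screening level (`above_precaution`); otherwise `below`.
#'
#' @param sum_ear Non-negative ΣEAR value(s).
#' @param config A [screening_config()].
#' @return Character class per value.
#' @export
classify_ear <- function(sum_ear, config = screening_config()) {
  if (any(sum_ear < 0, na.rm = TRUE)) stop("sum_ear must be >= 0", call. = FALSE)
  ifelse(sum_ear > config$ear_action_threshold, "above_action",
         ifelse(sum_ear > config$ear_precaution_threshold, "above_precaution",
                "below"))
}

# Per-chemical x endpoint EAR rows for one sample's detections.
# Chemicals without a CAS match in the ACC table, without a molecular
# weight, or with all assays excluded contribute no rows.
.ear_rows <- function(detections, analytes, acc) {
  acc_in <- filter_assays(acc)
  det <- detections[detections$status == "detected", ]
  if (nrow(det) == 0 || nrow(acc_in) == 0) {
    return(tibble(sample_id = character(), analyte_id = character(),
                  assay_endpoint_id = character(), ear = numeric()))
  }
  ai <- match(det$analyte_id, analytes$analyte_id)
  mw <- analytes$molecular_weight[ai]
  cas <- analytes$cas[ai]
  ok <- !is.na(mw) & !is.na(cas) & cas != "" & cas %in% acc_in$analyte_cas
  det <- det[ok, ]
  if (nrow(det) == 0) {
    return(tibble(sample_id = character(), analyte_id = character(),
                  assay_endpoint_id = character(), ear = numeric()))
  }
  mw <- mw[ok]; cas <- cas[ok]
  conc_um <- to_molar(det$value_ugL, mw)
  out <- vector("list", nrow(det))
  for (i in seq_len(nrow(det))) {
    rows <- acc_in[acc_in$analyte_cas == cas[i], ]
    out[[i]] <- tibble(sample_id = det$sample_id[i],
                       analyte_id = det$analyte_id[i],
                       assay_endpoint_id = rows$assay_endpoint_id,
                       ear = conc_um[i] / rows$acc_um)
  }
  bind_rows(out)
}

#' Cumulative exposure-activity ratio for one sample
#'
#' Sums individual EARs under the non-interactive concentration-addition
#' mixture model. Two aggregation conventions are offered:
#' \describe{
#'   \item{`sum_of_chemical_max`}{(default) each detected chemical
#'     contributes its maximum EAR over included assays; ΣEAR is the sum
#'     of those maxima.}
#'   \item{`max_endpoint_sum`}{chemical EARs are summed within each assay
#'     endpoint; ΣEAR is the maximum endpoint sum. Never larger than the
#'     default convention on the same input.}
#' }
#' Detected chemicals lacking molecular weight or ACC coverage contribute
#' zero and are listed in the coverage fields.
#'
#' @param detections Measurement rows for one sample (detections only are
#'   used; substituted non-detects must not be passed in).
#' @param analytes Analyte catalogue (molecular weights, CAS).
#' @param acc ACC table.
#' @param mode `"sum_of_chemical_max"` or `"max_endpoint_sum"`.
#' @param config A [screening_config()] for thresholds.
#' @return List of class `ear_result`: `sample_id`, `sum_ear`, `class`,
#'   `mode`, `chem_max` (tibble analyte_id, max_ear, ranked descending —
#'   the driver chemicals), `n_detected`, `n_covered`, `uncovered`
#'   (detected analytes with no usable EAR).
#' @export
sample_sum_ear <- function(detections, analytes, acc,
                           mode = c("sum_of_chemical_max", "max_endpoint_sum"),
                           config = screening_config()) {
  mode <- match.arg(mode)
  sample_id <- unique(detections$sample_id)
  if (length(sample_id) > 1) {
    stop("detections must belong to a single sample", call. = FALSE)
  }
  if (length(sample_id) == 0) sample_id <- NA_character_
  rows <- .ear_rows(detections, analytes, acc)
  detected <- unique(detections$analyte_id[detections$status == "detected"])
  covered <- unique(rows$analyte_id)
  if (nrow(rows) == 0) {
    if (length(detected) > 0) {
      warning("no detected chemical has usable ACC coverage; ΣEAR set to 0",
              call. = FALSE)
    }
    chem_max <- tibble(analyte_id = character(), max_ear = numeric())
    sum_ear <- 0
  } else {
    chem_max <- rows %>%
      group_by(.data$analyte_id) %>%
      summarise(max_ear = max(.data$ear), .groups = "drop") %>%
      arrange(dplyr::desc(.data$max_ear))
    sum_ear <- if (mode == "sum_of_chemical_max") {
      sum(chem_max$max_ear)
    } else {
      ep <- rows %>%
        group_by(.data$assay_endpoint_id) %>%
        summarise(ep_sum = sum(.data$ear), .groups = "drop")
      max(ep$ep_sum)
    }
  }
  structure(list(
    sample_id = sample_id,
    sum_ear = sum_ear,
    class = classify_ear(sum_ear, config),
    mode = mode,
    chem_max = chem_max,
    n_detected = length(detected),
    n_covered = length(covered),
    uncovered = setdiff(detected, covered)
  ), class = "ear_result")
}

#' @export
print.ear_result <- function(x, ...) {
  cat(sprintf("<ear_result> sample %s: ΣEAR = %.4g (%s, mode=%s)\n",
              x$sample_id, x$sum_ear, x$class, x$mode))
  cat(sprintf("  ACC coverage: %d of %d detected chemicals\n",
              x$n_covered, x$n_detected))
  invisible(x)
}

#' ΣEAR screen across all samples of a study
#'
#' @param dataset A [study_dataset()] (measurements should already be
#'   blank-censored).
#' @param mode,config Passed to [sample_sum_ear()].
#' @return Tibble: sample_id, sum_ear, class, n_detected, n_covered,
#'   top_driver (analyte with the largest chemical-max EAR).
#' @export
study_sum_ear <- function(dataset, mode = "sum_of_chemical_max",
                          config = screening_config()) {
  res <- lapply(dataset$samples$sample_id, function(s) {
    det <- dataset$measurements[dataset$measurements$sample_id == s, ]
    r <- suppressWarnings(
      sample_sum_ear(det, dataset$analytes, dataset$acc, mode = mode,
                     config = config))
    tibble(sample_id = s, sum_ear = r$sum_ear, class = r$class,
           n_detected = r$n_detected, n_covered = r$n_covered,
           top_driver = if (nrow(r$chem_max)) r$chem_max$analyte_id[1]
                        else NA_character_)
  })
  bind_rows(res)
}

#' ACC coverage summary for a study
#'
#' Reports, for the chemicals detected anywhere in the study, how many
#' have an exact CAS match in the ACC table and how many of those carry
#' at least one included (non-excluded) assay.
#'
#' @param dataset A [study_dataset()].
#' @return List: `n_detected_organics`, `n_cas_matched`, `n_with_included_assay`,
#'   `unmatched` (analyte ids).
#' @export
acc_coverage <- function(dataset) {
  det_ids <- unique(
    dataset$measurements$analyte_id[dataset$measurements$status == "detected"])
  a <- dataset$analytes[dataset$analytes$analyte_id %in% det_ids &
                          dataset$analytes$analyte_class %in% .organic_classes, ]
  matched <- a$cas != "" & !is.na(a$cas) & a$cas %in% dataset$acc$analyte_cas
  inc <- filter_assays(dataset$acc)
  with_assay <- a$cas %in% inc$analyte_cas
  list(
    n_detected_organics = nrow(a),
    n_cas_matched = sum(matched),
    n_with_included_assay = sum(with_assay),
    unmatched = a$analyte_id[!matched]
  )
}
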