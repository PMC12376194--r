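#' Censor sample results to regional field-blank maxima
#'
#' For each (region, analyte) with at least one field-blank detection,
#' every sample result from that region at or below the highest blank
#' value is set to `censored_by_blank` with its value cleared. Results
#' above the blank maximum, and analytes with no blank detection in the
#' sample's region, are unchanged. The operation is whole-record
#' censoring, not blank subtraction, and is idempotent.
#'
#' @param measurements A `tapscreen_measurements` table (ug/L).
#' @param blanks A `tapscreen_blanks` table (ug/L).
#' @param samples A `tapscreen_samples` table supplying each sample's
#'   region; an error is raised for measurements whose sample is absent.
#' @return The measurement table with statuses/values updated.
#' @export
censor_to_blanks <- function(measurements, blanks, samples) {
  if (nrow(blanks) == 0) return(measurements)
  region <- samples$region[match(measurements$sample_id, samples$sample_id)]
  if (anyNA(region)) {
    miss <- unique(measurements$sample_id[is.na(region)])
    stop("no region metadata for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  blank_max <- blanks %>%
    group_by(.data$region, .data$analyte_id) %>%
    summarise(blank_max = max(.data$value_ugL), .groups = "drop")
  key <- paste(region, measurements$analyte_id, sep = "\r")
  bkey <- paste(blank_max$region, blank_max$analyte_id, sep = "\r")
  bmax <- blank_max$blank_max[match(key, bkey)]
  hit <- !is.na(bmax) & measurements$status == "detected" &
    !is.na(measurements$value_ugL) & measurements$value_ugL <= bmax
  measurements$status[hit] <- "censored_by_blank"
  measurements$value_ugL[hit] <- NA_real_
  measurements
}

#' Packaged non-detect substitution rules
#'
#' The fixed constants assigned to non-detections for the statistics
#' stage only: pesticides, pharmaceuticals and PFAS get 0.0001 ug/L;
#' DBPs (and cumulative-organic aggregates) 0.01 ug/L; manganese,
#' nitrate and lead 0.01 ug/L; arsenic and uranium 0.1 ug/L. Rules match
#' by `analyte_id` first, then by `analyte_class`; users may supply their
#' own table with the same two-column-key layout.
#'
#' @return Tibble with columns `key_type` (`"analyte_id"` or
#'   `"analyte_class"`), `key`, `substitute_ugL`.
#' @export
substitution_rules <- function() {
  path <- system.file("extdata", "substitution_rules.csv",
                      package = "tapscreen")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Substitute non-detects to form a complete numeric matrix
#'
#' Builds the complete sample x analyte concentration matrix used by the
#' group-comparison statistics: detected values pass through; non-detects
#' (including blank-censored results) are replaced by fixed constants
#' looked up in the rule table. Pairs with no measurement record at all
#' are treated as non-detects. An analyte with a non-detect and no
#' applicable rule raises an error naming it, so callers extend the rule
#' table deliberately rather than silently dropping data.
#'
#' Substitution feeds only the statistics stage; exceedance screening and
#' the EAR/TQ mixture screens operate on detected concentrations alone.
#'
#' @param measurements Measurement table after [censor_to_blanks()].
#' @param analytes Analyte catalogue (for class lookup).
#' @param samples Sample metadata (fixes the row roster).
#' @param analyte_ids Analytes to include as matrix columns; defaults to
#'   all analytes appearing in `measurements`.
#' @param rules Substitution rule table; defaults to [substitution_rules()].
#' @return Numeric matrix (rows = sample_id, cols = analyte_id), ug/L,
#'   no missing cells.
#' @export
substitute_nondetects <- function(measurements, analytes, samples,
                                  analyte_ids = NULL,
                                  rules = substitution_rules()) {
  if (is.null(analyte_ids)) analyte_ids <- sort(unique(measurements$analyte_id))
  sample_ids <- samples$sample_id
  cls <- analytes$analyte_class[match(analyte_ids, analytes$analyte_id)]
  if (anyNA(cls)) {
    stop("unknown analyte_id: ",
         paste(analyte_ids[is.na(cls)], collapse = ", "), call. = FALSE)
  }
  id_rules <- rules[rules$key_type == "analyte_id", ]
  cl_rules <- rules[rules$key_type == "analyte_class", ]
  sub_val <- id_rules$substitute_ugL[match(analyte_ids, id_rules$key)]
  use_cl <- is.na(sub_val)
  sub_val[use_cl] <- cl_rules$substitute_ugL[match(cls[use_cl], cl_rules$key)]

  mat <- matrix(NA_real_, nrow = length(sample_ids), ncol = length(analyte_ids),
                dimnames = list(sample_ids, analyte_ids))
  det <- measurements[measurements$status == "detected" &
                        measurements$analyte_id %in% analyte_ids, ]
  mat[cbind(match(det$sample_id, sample_ids),
            match(det$analyte_id, analyte_ids))] <- det$value_ugL

  need_sub <- colSums(is.na(mat)) > 0
  no_rule <- need_sub & is.na(sub_val)
  if (any(no_rule)) {
    stop("no substitution rule for analyte(s) with non-detects: ",
         paste(analyte_ids[no_rule], collapse = ", "), call. = FALSE)
  }
  for (j in which(need_sub)) {
    mat[is.na(mat[, j]), j] <- sub_val[j]
  }
  mat
}
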