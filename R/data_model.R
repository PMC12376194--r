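#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% filter mutate select arrange group_by summarise ungroup
#'   left_join anti_join bind_rows distinct n rename
#' @importFrom rlang .data
#' @importFrom stats median quantile rbinom rlnorm runif setNames pchisq
#' @importFrom utils read.csv write.csv
NULL

# Controlled vocabularies shared across the pipeline
.regions <- c("GoldCountry", "BayArea", "MercedFresno", "Kern", "SELA")
.analyte_classes <- c("DBP", "pesticide", "PFAS", "pharmaceutical",
                      "trace_element", "major_element", "other_inorganic")
.organic_classes <- c("DBP", "pesticide", "PFAS", "pharmaceutical")
.infrastructures <- c("PWS", "private_well")
.source_waters <- c("GW", "SW", "mixed", "unknown")
.statuses <- c("detected", "nondetect", "censored_by_blank")
.benchmark_types <- c("MCL", "MCLG", "WHO_GV", "WHO_pGV", "HBSL", "HA", "state")

#' Study regions and analyte classes
#'
#' Controlled vocabularies used throughout: the five sampled regions
#' (Gold Country, San Francisco Bay Area, Merced/Fresno, Kern, southeast
#' Los Angeles) and the analyte classes (four organic classes plus
#' inorganic groupings).
#'
#' @return Character vector of labels.
#' @export
study_regions <- function() .regions

#' @rdname study_regions
#' @export
analyte_classes <- function() .analyte_classes

#' Construct an analyte catalogue
#'
#' One row per analyte: identity, class, molecular weight (g/mol; required
#' for organics entering the exposure-activity-ratio screen) and the unit
#' concentrations are reported in natively. An optional reporting limit
#' (ug/L) may be carried; none is asserted by default.
#'
#' @param analyte_id Character, unique short names.
#' @param analyte_class One of [analyte_classes()] per analyte.
#' @param cas CAS registry number string, or `""`/`NA` when not available.
#' @param molecular_weight g/mol, `NA` when unknown.
#' @param native_unit Reporting unit, one of `"ug/L"`, `"ng/L"`, `"mg/L"`.
#' @param reporting_limit Optional reporting limit in ug/L (`NA` default).
#' @return A tibble of class `tapscreen_analytes`.
#' @export
analyte_table <- function(analyte_id, analyte_class, cas = "",
                          molecular_weight = NA_real_,
                          native_unit = "ug/L",
                          reporting_limit = NA_real_) {
  tab <- tibble(
    analyte_id = as.character(analyte_id),
    cas = as.character(cas),
    analyte_class = as.character(analyte_class),
    molecular_weight = as.numeric(molecular_weight),
    native_unit = as.character(native_unit),
    reporting_limit = as.numeric(reporting_limit)
  )
  if (anyDuplicated(tab$analyte_id)) {
    stop("analyte_id must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(tab$analyte_class), .analyte_classes)
  if (length(bad)) stop("unknown analyte_class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  unit_to_ugL_factor(tab$native_unit)  # errors on unknown unit
  class(tab) <- c("tapscreen_analytes", class(tab))
  tab
}

#' Construct per-sample site metadata
#'
#' `size_class` is derived from the served population: small systems serve
#' fewer than 10,000 people, large systems 10,000 or more. Private wells
#' have no size class and are groundwater-sourced by definition.
#'
#' @param sample_id Character sample identifiers (unique).
#' @param region One of [study_regions()] per sample.
#' @param infrastructure `"PWS"` or `"private_well"`.
#' @param source_water `"GW"`, `"SW"`, `"mixed"` or `"unknown"`.
#' @param service_population Integer people served (`NA` for private wells).
#' @return A tibble of class `tapscreen_samples` with derived `size_class`.
#' @export
sample_meta <- function(sample_id, region, infrastructure = "PWS",
                        source_water = "unknown",
                        service_population = NA_integer_) {
  tab <- tibble(
    sample_id = as.character(sample_id),
    region = as.character(region),
    infrastructure = as.character(infrastructure),
    source_water = as.character(source_water),
    service_population = as.integer(service_population)
  )
  if (anyDuplicated(tab$sample_id)) stop("sample_id must be unique", call. = FALSE)
  bad <- setdiff(unique(tab$region), .regions)
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(tab$infrastructure), .infrastructures)
  if (length(bad)) stop("unknown infrastructure: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(tab$source_water), .source_waters)
  if (length(bad)) stop("unknown source_water: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tab$size_class <- ifelse(
    tab$infrastructure == "private_well", NA_character_,
    ifelse(is.na(tab$service_population), NA_character_,
           ifelse(tab$service_population < 10000, "small", "large"))
  )
  class(tab) <- c("tapscreen_samples", class(tab))
  tab
}

#' Construct measurement records
#'
#' One row per (sample, analyte) pair observed by the laboratory.
#' Values are concentrations on the internal ug/L scale; semi-quantified
#' results are treated as detections, mirroring field practice where
#' results between the detection and quantitation limits are reported.
#'
#' @param sample_id,analyte_id Keys into the sample and analyte tables.
#' @param value_ugL Concentration in ug/L; `NA` for non-detects.
#' @param status `"detected"`, `"nondetect"` or `"censored_by_blank"`.
#' @param qualifier `"quantified"` or `"semiquantified"`.
#' @return A tibble of class `tapscreen_measurements`.
#' @export
measurement_table <- function(sample_id, analyte_id, value_ugL,
                              status = "detected",
                              qualifier = "quantified") {
  tab <- tibble(
    sample_id = as.character(sample_id),
    analyte_id = as.character(analyte_id),
    value_ugL = as.numeric(value_ugL),
    status = as.character(status),
    qualifier = as.character(qualifier)
  )
  bad <- setdiff(unique(tab$status), .statuses)
  if (length(bad)) stop("unknown status: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab[c("sample_id", "analyte_id")])) {
    stop("duplicate (sample_id, analyte_id) measurement", call. = FALSE)
  }
  class(tab) <- c("tapscreen_measurements", class(tab))
  tab
}

#' Construct field-blank detection records
#'
#' Only blank detections are recorded; a blank with no detections
#' contributes no rows. Values are in ug/L.
#'
#' @param region Region the blank was collected in.
#' @param analyte_id Analyte detected in the blank.
#' @param value_ugL Detected blank concentration (positive, ug/L).
#' @return A tibble of class `tapscreen_blanks`.
#' @export
blank_table <- function(region = character(), analyte_id = character(),
                        value_ugL = numeric()) {
  tab <- tibble(
    region = as.character(region),
    analyte_id = as.character(analyte_id),
    value_ugL = as.numeric(value_ugL)
  )
  if (any(!is.na(tab$value_ugL) & tab$value_ugL <= 0)) {
    stop("blank detections must be positive", call. = FALSE)
  }
  class(tab) <- c("tapscreen_blanks", class(tab))
  tab
}

#' Construct a benchmark table
#'
#' Health and regulatory benchmark concentrations per analyte, in ug/L on
#' the internal scale. An MCLG of zero is allowed (no identified
#' safe-exposure level); only the MCL is enforceable.
#'
#' @param analyte_id Analyte the benchmark applies to.
#' @param benchmark_type One of `"MCL"`, `"MCLG"`, `"WHO_GV"`, `"WHO_pGV"`,
#'   `"HBSL"`, `"HA"`, `"state"`.
#' @param value_ugL Benchmark concentration in ug/L (>= 0).
#' @param note Free-text annotation (e.g. the lead value is an Action
#'   Level carried as an MCL-type row).
#' @return A tibble of class `tapscreen_benchmarks` with an `enforceable`
#'   column (TRUE only for MCL rows).
#' @export
benchmark_table <- function(analyte_id, benchmark_type, value_ugL, note = "") {
  tab <- tibble(
    analyte_id = as.character(analyte_id),
    benchmark_type = as.character(benchmark_type),
    value_ugL = as.numeric(value_ugL),
    note = as.character(note)
  )
  bad <- setdiff(unique(tab$benchmark_type), .benchmark_types)
  if (length(bad)) stop("unknown benchmark_type: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(tab$value_ugL < 0, na.rm = TRUE)) {
    stop("benchmark values must be >= 0", call. = FALSE)
  }
  tab$enforceable <- tab$benchmark_type == "MCL"
  class(tab) <- c("tapscreen_benchmarks", class(tab))
  tab
}

#' Construct an ACC (activity concentration at cutoff) table
#'
#' Schema mirrors ToxCast invitroDB exports: one row per chemical x assay
#' endpoint with the ACC in micromolar and exclusion flags for
#' non-specific endpoints, baseline responses and unreliable curves.
#'
#' @param analyte_cas CAS registry number of the chemical.
#' @param assay_endpoint_id Assay endpoint identifier.
#' @param acc_um ACC in micromolar (positive).
#' @param exclusion_reason `"none"` for usable rows, otherwise one of
#'   `"nonspecific_endpoint"`, `"baseline"`, `"unreliable_curve"`.
#' @return A tibble of class `tapscreen_acc` with derived `excluded` flag.
#' @export
acc_table <- function(analyte_cas, assay_endpoint_id, acc_um,
                      exclusion_reason = "none") {
  reasons <- c("nonspecific_endpoint", "baseline", "unreliable_curve", "none")
  tab <- tibble(
    analyte_cas = as.character(analyte_cas),
    assay_endpoint_id = as.character(assay_endpoint_id),
    acc_um = as.numeric(acc_um),
    exclusion_reason = as.character(exclusion_reason)
  )
  bad <- setdiff(unique(tab$exclusion_reason), reasons)
  if (length(bad)) stop("unknown exclusion_reason: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(tab$acc_um <= 0, na.rm = TRUE)) stop("acc_um must be positive", call. = FALSE)
  tab$excluded <- tab$exclusion_reason != "none"
  class(tab) <- c("tapscreen_acc", class(tab))
  tab
}

#' Screening thresholds and surrogate constants
#'
#' Bundles the screening-level constants: the cumulative
#' exposure-activity-ratio level expected to modulate a molecular target
#' in vitro (1) and the precautionary level (0.001); the cumulative
#' toxicity-quotient level indicating high probability of risk (1) and
#' the negligible-risk level (0.1); and the surrogates substituted for
#' zero-valued MCLGs before benchmark minimisation (0.1 ug/L for DBPs,
#' arsenic, lead and uranium; 0.0001 ug/L for PFOA and PFOS).
#'
#' @param ear_action_threshold,ear_precaution_threshold ΣEAR class cut-offs.
#' @param tq_action_threshold,tq_negligible_threshold ΣTQ class cut-offs.
#' @param mclg_zero_surrogate_default_ugL Surrogate for zero MCLGs
#'   (DBPs, arsenic, lead, uranium).
#' @param mclg_zero_surrogate_pfoa_pfos_ugL Surrogate for PFOA/PFOS zero MCLGs.
#' @param pfas_hi_components Named numeric vector of health-based water
#'   concentrations (ug/L) for the four-PFAS mixture hazard index
#'   (PFNA, PFBS, PFHxS, GenX); values are user-supplied, no defaults
#'   are asserted.
#' @return A list of class `screening_config`.
#' @export
screening_config <- function(ear_action_threshold = 1.0,
                             ear_precaution_threshold = 0.001,
                             tq_action_threshold = 1.0,
                             tq_negligible_threshold = 0.1,
                             mclg_zero_surrogate_default_ugL = 0.1,
                             mclg_zero_surrogate_pfoa_pfos_ugL = 0.0001,
                             pfas_hi_components = NULL) {
  stopifnot(ear_action_threshold > 0, ear_precaution_threshold > 0,
            tq_action_threshold > 0, tq_negligible_threshold > 0,
            mclg_zero_surrogate_default_ugL > 0,
            mclg_zero_surrogate_pfoa_pfos_ugL > 0)
  if (ear_precaution_threshold >= ear_action_threshold) {
    stop("precaution threshold must be below action threshold", call. = FALSE)
  }
  if (tq_negligible_threshold >= tq_action_threshold) {
    stop("negligible threshold must be below action threshold", call. = FALSE)
  }
  structure(list(
    ear_action_threshold = ear_action_threshold,
    ear_precaution_threshold = ear_precaution_threshold,
    tq_action_threshold = tq_action_threshold,
    tq_negligible_threshold = tq_negligible_threshold,
    mclg_zero_surrogate_default_ugL = mclg_zero_surrogate_default_ugL,
    mclg_zero_surrogate_pfoa_pfos_ugL = mclg_zero_surrogate_pfoa_pfos_ugL,
    pfas_hi_components = pfas_hi_components
  ), class = "screening_config")
}

#' Bundle tables into a study dataset
#'
#' @param analytes,samples,measurements,blanks,benchmarks,acc Tables built
#'   by the respective constructors (or data frames with the same columns).
#' @return A list of class `study_dataset`.
#' @export
study_dataset <- function(analytes, samples, measurements,
                          blanks = blank_table(),
                          benchmarks = benchmark_table(character(), character(), numeric()),
                          acc = acc_table(character(), character(), numeric())) {
  ds <- structure(list(
    analytes = analytes, samples = samples, measurements = measurements,
    blanks = blanks, benchmarks = benchmarks, acc = acc
  ), class = "study_dataset")
  ds
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat("  samples:     ", nrow(x$samples), " (",
      paste(table(x$samples$region), names(table(x$samples$region)),
            collapse = ", "), ")\n", sep = "")
  cat("  analytes:    ", nrow(x$analytes), "\n", sep = "")
  cat("  measurements:", nrow(x$measurements),
      sprintf(" (%d detected)", sum(x$measurements$status == "detected")), "\n")
  cat("  blanks:      ", nrow(x$blanks), " detections\n", sep = "")
  cat("  benchmarks:  ", nrow(x$benchmarks), " entries\n", sep = "")
  cat("  acc:         ", nrow(x$acc), " rows\n", sep = "")
  invisible(x)
}

#' Validate a study dataset against its invariants
#'
#' Checks every record-level invariant and returns violations as data,
#' one row per failed rule, rather than raising errors: positive detected
#' values; known statuses; unique (sample, analyte) keys; referential
#' integrity of sample and analyte ids; private wells being
#' groundwater-sourced with no size class; positive molecular weights;
#' positive ACC values; non-negative benchmarks.
#'
#' @param dataset A [study_dataset()].
#' @return Tibble with columns `table`, `record`, `rule`; zero rows when
#'   the dataset is fully consistent.
#' @export
validate_study <- function(dataset) {
  v <- list()
  add <- function(table, record, rule) {
    tibble(table = table, record = as.character(record), rule = rule)
  }
  m <- dataset$measurements
  bad <- m$status == "detected" & (is.na(m$value_ugL) | m$value_ugL <= 0)
  if (any(bad)) {
    v[[length(v) + 1]] <- add("measurements",
      paste(m$sample_id[bad], m$analyte_id[bad], sep = "/"),
      "detected measurement must have value > 0")
  }
  dup <- duplicated(m[c("sample_id", "analyte_id")])
  if (any(dup)) {
    v[[length(v) + 1]] <- add("measurements",
      paste(m$sample_id[dup], m$analyte_id[dup], sep = "/"),
      "duplicate (sample_id, analyte_id)")
  }
  unk <- !(m$analyte_id %in% dataset$analytes$analyte_id)
  if (any(unk)) {
    v[[length(v) + 1]] <- add("measurements", unique(m$analyte_id[unk]),
                              "unknown analyte_id")
  }
  unk <- !(m$sample_id %in% dataset$samples$sample_id)
  if (any(unk)) {
    v[[length(v) + 1]] <- add("measurements", unique(m$sample_id[unk]),
                              "unknown sample_id")
  }
  s <- dataset$samples
  bad <- s$infrastructure == "private_well" & s$source_water != "GW"
  if (any(bad)) {
    v[[length(v) + 1]] <- add("samples", s$sample_id[bad],
                              "private well must be groundwater-sourced")
  }
  bad <- s$infrastructure == "private_well" & !is.na(s$size_class)
  if (any(bad)) {
    v[[length(v) + 1]] <- add("samples", s$sample_id[bad],
                              "private well has no size class")
  }
  exp_small <- ifelse(is.na(s$service_population), NA_character_,
                      ifelse(s$service_population < 10000, "small", "large"))
  bad <- s$infrastructure == "PWS" & !is.na(s$size_class) &
    !is.na(exp_small) & s$size_class != exp_small
  if (any(bad)) {
    v[[length(v) + 1]] <- add("samples", s$sample_id[bad],
                              "size_class inconsistent with service_population")
  }
  a <- dataset$analytes
  bad <- !is.na(a$molecular_weight) & a$molecular_weight <= 0
  if (any(bad)) {
    v[[length(v) + 1]] <- add("analytes", a$analyte_id[bad],
                              "molecular_weight must be > 0")
  }
  b <- dataset$blanks
  if (nrow(b)) {
    bad <- is.na(b$value_ugL) | b$value_ugL <= 0
    if (any(bad)) {
      v[[length(v) + 1]] <- add("blanks",
        paste(b$region[bad], b$analyte_id[bad], sep = "/"),
        "blank detection must be > 0")
    }
  }
  bm <- dataset$benchmarks
  if (nrow(bm)) {
    bad <- is.na(bm$value_ugL) | bm$value_ugL < 0
    if (any(bad)) {
      v[[length(v) + 1]] <- add("benchmarks",
        paste(bm$analyte_id[bad], bm$benchmark_type[bad], sep = "/"),
        "benchmark value must be >= 0")
    }
  }
  if (length(v) == 0) {
    tibble(table = character(), record = character(), rule = character())
  } else {
    bind_rows(v)
  }
}

.delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_tibble(read.csv(path, sep = .delim_for(path), stringsAsFactors = FALSE,
                     check.names = FALSE))
}

.write_delim <- function(tab, path) {
  tab <- as.data.frame(tab)
  num <- vapply(tab, is.numeric, logical(1))
  # full precision so a text round-trip reproduces doubles bit-identically
  tab[num] <- lapply(tab[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  })
  write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a study dataset from delimited text files
#'
#' Chemistry values are given in each analyte's native unit and are
#' normalised to ug/L on ingest (original units stay on the analyte
#' catalogue). Comma vs tab is auto-detected from the file extension
#' (`.tsv`/`.txt` are tab-separated).
#'
#' Expected columns:
#' \describe{
#'   \item{analytes}{analyte_id, analyte_class, cas, molecular_weight,
#'     native_unit, reporting_limit}
#'   \item{chemistry}{sample_id, analyte_id, value (native unit), status,
#'     qualifier}
#'   \item{metadata}{sample_id, region, infrastructure, source_water,
#'     service_population}
#'   \item{blanks}{region, analyte_id, value (native unit)}
#'   \item{benchmarks}{analyte_id, benchmark_type, value_ugL, note}
#'   \item{acc}{analyte_cas (or cas), assay_endpoint (or
#'     assay_endpoint_id), acc_um, exclusion_reason}
#' }
#'
#' @param chemistry,metadata,analytes Paths (required).
#' @param blanks,benchmarks,acc Paths (optional).
#' @return A validated [study_dataset()]; referential or vocabulary
#'   problems raise errors naming the offending rows.
#' @export
read_study <- function(chemistry, metadata, analytes,
                       blanks = NULL, benchmarks = NULL, acc = NULL) {
  araw <- .read_delim(analytes)
  atab <- analyte_table(
    analyte_id = araw$analyte_id,
    analyte_class = araw$analyte_class,
    cas = if ("cas" %in% names(araw)) araw$cas else "",
    molecular_weight = if ("molecular_weight" %in% names(araw))
      araw$molecular_weight else NA_real_,
    native_unit = if ("native_unit" %in% names(araw)) araw$native_unit else "ug/L",
    reporting_limit = if ("reporting_limit" %in% names(araw))
      araw$reporting_limit else NA_real_
  )

  mraw <- .read_delim(metadata)
  stab <- sample_meta(
    sample_id = mraw$sample_id, region = mraw$region,
    infrastructure = mraw$infrastructure, source_water = mraw$source_water,
    service_population = if ("service_population" %in% names(mraw))
      mraw$service_population else NA_integer_
  )

  craw <- .read_delim(chemistry)
  unk <- setdiff(unique(craw$analyte_id), atab$analyte_id)
  if (length(unk)) {
    stop("chemistry references unknown analyte_id: ",
         paste(unk, collapse = ", "), call. = FALSE)
  }
  unk <- setdiff(unique(craw$sample_id), stab$sample_id)
  if (length(unk)) {
    stop("chemistry references unknown sample_id: ",
         paste(unk, collapse = ", "), call. = FALSE)
  }
  # archives carry the internal ug/L scale directly (value_ugL column);
  # hand-built chemistry files carry native-unit values (value column)
  val_ugL <- if ("value_ugL" %in% names(craw)) {
    as.numeric(craw$value_ugL)
  } else {
    fac <- unit_to_ugL_factor(atab$native_unit[match(craw$analyte_id,
                                                     atab$analyte_id)])
    as.numeric(craw$value) * fac
  }
  mtab <- measurement_table(
    sample_id = craw$sample_id, analyte_id = craw$analyte_id,
    value_ugL = val_ugL,
    status = craw$status,
    qualifier = if ("qualifier" %in% names(craw)) craw$qualifier else "quantified"
  )

  btab <- blank_table()
  if (!is.null(blanks)) {
    braw <- .read_delim(blanks)
    if (nrow(braw)) {
      bad <- setdiff(unique(braw$region), .regions)
      if (length(bad)) stop("blanks reference unknown region: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      bval <- if ("value_ugL" %in% names(braw)) {
        as.numeric(braw$value_ugL)
      } else {
        fac <- unit_to_ugL_factor(atab$native_unit[match(braw$analyte_id,
                                                         atab$analyte_id)])
        if (anyNA(fac)) {
          stop("blanks reference unknown analyte_id", call. = FALSE)
        }
        as.numeric(braw$value) * fac
      }
      btab <- blank_table(braw$region, braw$analyte_id, bval)
    }
  }

  bmtab <- benchmark_table(character(), character(), numeric())
  if (!is.null(benchmarks)) {
    bmraw <- .read_delim(benchmarks)
    if (nrow(bmraw)) {
      bmtab <- benchmark_table(bmraw$analyte_id, bmraw$benchmark_type,
                               bmraw$value_ugL,
                               note = if ("note" %in% names(bmraw)) bmraw$note else "")
    }
  }

  acctab <- acc_table(character(), character(), numeric())
  if (!is.null(acc)) {
    accraw <- .read_delim(acc)
    if (nrow(accraw)) {
      cas_col <- if ("analyte_cas" %in% names(accraw)) "analyte_cas" else "cas"
      ep_col <- if ("assay_endpoint_id" %in% names(accraw))
        "assay_endpoint_id" else "assay_endpoint"
      acctab <- acc_table(accraw[[cas_col]], accraw[[ep_col]], accraw$acc_um,
                          exclusion_reason = if ("exclusion_reason" %in% names(accraw))
                            accraw$exclusion_reason else "none")
    }
  }

  study_dataset(atab, stab, mtab, btab, bmtab, acctab)
}

#' Write a study dataset as a delimited-text archive directory
#'
#' Writes the six component tables plus a small JSON manifest to `dir`.
#' Chemistry and blank values are written on the internal ug/L scale at
#' full double precision (17 significant digits), so [read_study()] of
#' the archive reproduces the dataset bit-identically.
#'
#' @param dataset A [study_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  .write_delim(dataset$analytes, p("analytes.csv"))
  .write_delim(dataset$samples[, c("sample_id", "region", "infrastructure",
                                   "source_water", "service_population")],
               p("metadata.csv"))
  # archives keep the internal ug/L scale so read_study() reproduces the
  # dataset without a lossy unit round-trip
  chem <- tibble(
    sample_id = dataset$measurements$sample_id,
    analyte_id = dataset$measurements$analyte_id,
    value_ugL = dataset$measurements$value_ugL,
    status = dataset$measurements$status,
    qualifier = dataset$measurements$qualifier
  )
  .write_delim(chem, p("chemistry.csv"))
  .write_delim(dataset$blanks[, c("region", "analyte_id", "value_ugL")],
               p("blanks.csv"))
  .write_delim(dataset$benchmarks[, c("analyte_id", "benchmark_type",
                                      "value_ugL", "note")],
               p("benchmarks.csv"))
  .write_delim(dataset$acc[, c("analyte_cas", "assay_endpoint_id", "acc_um",
                               "exclusion_reason")],
               p("acc.csv"))
  manifest <- list(
    format = "tapscreen-study-archive",
    version = 1L,
    files = c("analytes.csv", "metadata.csv", "chemistry.csv", "blanks.csv",
              "benchmarks.csv", "acc.csv"),
    n_samples = nrow(dataset$samples),
    n_analytes = nrow(dataset$analytes)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Read a study archive written by [write_study()]
#'
#' @param dir Archive directory.
#' @return A [study_dataset()].
#' @export
read_study_archive <- function(dir) {
  p <- function(f) file.path(dir, f)
  read_study(chemistry = p("chemistry.csv"), metadata = p("metadata.csv"),
             analytes = p("analytes.csv"), blanks = p("blanks.csv"),
             benchmarks = p("benchmarks.csv"), acc = p("acc.csv"))
}
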