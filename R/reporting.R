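#' Render a regulatory summary table of detected, benchmarked constituents
#'
#' One row per constituent that was detected at least once and has an
#' MCLG or MCL entry: percent detection frequency, median and range of
#' detected concentrations rendered in the analyte's native unit, and
#' each benchmark with its exceedance count in parentheses ("Zero(52)"
#' for de facto zero-MCLG exceedances). The TTHM aggregate row is
#' included when the four THMs are present.
#'
#' @param dataset A [study_dataset()] (measurements blank-censored).
#' @param benchmarks Benchmark table (default: the dataset's own).
#' @return Tibble: analyte_id, analyte_class, detection_frequency,
#'   median_range, mclg, mcl (display strings) plus the underlying
#'   numeric columns from [constituent_summary()].
#' @export
build_table1 <- function(dataset, benchmarks = dataset$benchmarks) {
  meas <- dataset$measurements
  if (all(thm4() %in% dataset$analytes$analyte_id) &&
      !("TTHM" %in% meas$analyte_id)) {
    meas <- bind_rows(meas, tthm_measurements(meas, dataset$samples))
  }
  n <- nrow(dataset$samples)
  ids <- intersect(unique(benchmarks$analyte_id), unique(meas$analyte_id))
  rows <- list()
  for (id in ids) {
    cs <- constituent_summary(meas, id, n, benchmarks)
    if (cs$n_detected == 0) next  # only detected constituents are listed
    if (id == "TTHM") {
      unit <- "ug/L"; fac <- 1
      cls <- "DBP"
    } else {
      ai <- match(id, dataset$analytes$analyte_id)
      unit <- dataset$analytes$native_unit[ai]
      fac <- unit_to_ugL_factor(unit)
      cls <- dataset$analytes$analyte_class[ai]
    }
    fmt <- function(x) format(x / fac, digits = 3, scientific = FALSE,
                              trim = TRUE)
    bm_str <- function(type, count) {
      row <- benchmarks[benchmarks$analyte_id == id &
                          benchmarks$benchmark_type == type, ]
      if (nrow(row) == 0) return("")
      val <- if (row$value_ugL[1] == 0) "Zero" else
        paste0(fmt(row$value_ugL[1]), " ", unit)
      sprintf("%s(%d)", val, count)
    }
    rows[[length(rows) + 1]] <- mutate(
      cs,
      analyte_class = cls,
      detection_frequency = sprintf("%.1f %%", cs$detection_frequency_pct),
      median_range = if (cs$min_detected == cs$max_detected) {
        paste0(fmt(cs$median_detected), " ", unit)
      } else {
        sprintf("%s %s (%s-%s)", fmt(cs$median_detected), unit,
                fmt(cs$min_detected), fmt(cs$max_detected))
      },
      mclg = bm_str("MCLG", cs$mclg_exceedances),
      mcl = bm_str("MCL", cs$mcl_exceedances)
    )
  }
  if (length(rows) == 0) {
    return(tibble(analyte_id = character()))
  }
  out <- bind_rows(rows)
  out[order(match(out$analyte_class, .analyte_classes), out$analyte_id),
      c("analyte_id", "analyte_class", "detection_frequency", "median_range",
        "mclg", "mcl", "n_samples", "detection_frequency_pct", "n_detected",
        "median_detected", "min_detected", "max_detected",
        "mclg_exceedances", "mcl_exceedances")]
}

#' Run the full screening pipeline and write a results archive
#'
#' Executes the stages in study order — field-blank censoring, TTHM
#' aggregation, regulatory summary, per-sample exceedance profiles,
#' ΣEAR and ΣTQ mixture screens, and the two-stage group statistics by
#' region — and writes each result as delimited text plus a JSON run
#' manifest (seed, config digest, table sizes) under `out_dir`.
#'
#' Group statistics run on the substituted concentration matrix
#' restricted to analytes with substitution coverage (the four organic
#' classes plus the named inorganics in the rule table); stages
#' needing at least two detections per group are skipped for degenerate
#' inputs and noted in the manifest.
#'
#' @param dataset A [study_dataset()].
#' @param config A [screening_config()].
#' @param out_dir Output directory.
#' @param n_perm,seed Permutation count and seed for the statistics stage.
#' @return Invisibly, a list with all stage results (`table1`,
#'   `profiles`, `ear`, `tq`, `stats`, `censored`), also written to disk.
#' @export
run_pipeline <- function(dataset, config = screening_config(), out_dir,
                         n_perm = 9999, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  meas <- censor_to_blanks(dataset$measurements, dataset$blanks,
                           dataset$samples)
  cen <- dataset
  cen$measurements <- meas

  tab1 <- build_table1(cen)
  .write_delim(tab1, p("table1.csv"))

  meas_tthm <- bind_rows(meas, tthm_measurements(meas, dataset$samples))
  profiles <- per_sample_regulatory_profile(meas_tthm, dataset$benchmarks,
                                            dataset$samples)
  .write_delim(profiles, p("exceedance_profiles.csv"))

  ear <- study_sum_ear(cen, config = config)
  .write_delim(ear, p("sum_ear.csv"))

  tq <- study_sum_tq(cen, config = config)
  .write_delim(tq, p("sum_tq.csv"))

  mix <- left_join(ear, tq, by = "sample_id",
                   suffix = c("_ear", "_tq"))
  .write_delim(mix, p("mixture_screen.csv"))

  stats_note <- "ok"
  stats_res <- NULL
  rules <- substitution_rules()
  covered <- dataset$analytes$analyte_id[
    dataset$analytes$analyte_class %in% .organic_classes |
      dataset$analytes$analyte_id %in%
        rules$key[rules$key_type == "analyte_id"]]
  covered <- intersect(covered, unique(meas$analyte_id))
  grp <- dataset$samples$region
  if (sum(meas$status == "detected") == 0) {
    stats_note <- "skipped: no detections"
  } else if (min(table(grp)) < 2 || length(unique(grp)) < 2) {
    stats_note <- "skipped: need >= 2 groups with >= 2 samples"
  } else {
    mat <- substitute_nondetects(meas, dataset$analytes, dataset$samples,
                                 analyte_ids = covered, rules = rules)
    stats_res <- compare_groups(mat, grp, n_perm = n_perm, seed = seed)
    st <- tibble(
      test = "PERMANOVA_region",
      statistic = stats_res$permanova$pseudo_F,
      p_value = stats_res$permanova$p_value,
      n_permutations = stats_res$permanova$n_permutations
    )
    if (!is.null(stats_res$kruskal)) {
      st <- bind_rows(st, tibble(test = "KruskalWallis_region",
                                 statistic = stats_res$kruskal$H,
                                 p_value = stats_res$kruskal$p_value,
                                 n_permutations = NA_integer_))
    }
    .write_delim(st, p("stats_tests.csv"))
    if (!is.null(stats_res$dunn)) {
      .write_delim(stats_res$dunn$pairs, p("stats_dunn_pairs.csv"))
      .write_delim(tibble(group = names(stats_res$dunn$letters),
                          letters = unname(stats_res$dunn$letters)),
                   p("stats_letters.csv"))
    }
  }

  manifest <- list(
    seed = seed,
    n_permutations = n_perm,
    config = unclass(config)[c("ear_action_threshold",
                               "ear_precaution_threshold",
                               "tq_action_threshold",
                               "tq_negligible_threshold",
                               "mclg_zero_surrogate_default_ugL",
                               "mclg_zero_surrogate_pfoa_pfos_ugL")],
    n_samples = nrow(dataset$samples),
    n_analytes = nrow(dataset$analytes),
    n_benchmark_entries = nrow(dataset$benchmarks),
    n_acc_rows = nrow(dataset$acc),
    stats = stats_note,
    files = c("table1.csv", "exceedance_profiles.csv", "sum_ear.csv",
              "sum_tq.csv", "mixture_screen.csv")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(table1 = tab1, profiles = profiles, ear = ear, tq = tq,
                 stats = stats_res, censored = cen))
}
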