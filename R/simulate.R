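# Run expr with a local RNG stream so callers' RNG state is untouched.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Build a synthetic-study generator configuration
#'
#' Describes the distributional recipe for a synthetic tapwater campaign:
#' per-region sample counts, the analyte recipe table (detection
#' probability, lognormal concentration body winsorised to a printed
#' range, optional per-region probability overrides), infrastructure mix,
#' metadata distributions and field-blank contamination.
#'
#' @param region_n Named integer vector of samples per region; the
#'   default mirrors the campaign layout (12/6/10/10/22).
#' @param n_private_wells Number of private wells, all placed in Gold
#'   Country (default 5).
#' @param recipe Analyte recipe tibble with columns: analyte_id,
#'   analyte_class, cas, molecular_weight, native_unit, p_detect,
#'   median_ugL, sdlog, min_ugL, max_ugL. Optional per-region detection
#'   probabilities are supplied via `region_p`.
#' @param region_p Named list: analyte_id -> named numeric vector of
#'   per-region detection probabilities overriding `p_detect`.
#' @param n_small_pws,n_sw,n_gw Counts shaping PWS metadata: small
#'   systems (<10,000 served) among PWS, surface-water-only and
#'   groundwater-only sourced homes (the rest are mixed).
#' @param blanks_per_region Named integer vector of field-blank events
#'   per region (default 2 everywhere except 1 in the Bay Area).
#' @param blank_p Probability that a contamination-prone analyte shows up
#'   in any one blank event.
#' @param blank_analytes Analyte ids eligible for blank contamination.
#' @param dbp_latent_rho Correlation strength (0-1) of the shared
#'   per-sample disinfection-intensity factor inducing DBP co-occurrence
#'   in concentrations.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(region_n = c(GoldCountry = 12L, BayArea = 6L,
                                          MercedFresno = 10L, Kern = 10L,
                                          SELA = 22L),
                             n_private_wells = 5L,
                             recipe,
                             region_p = list(),
                             n_small_pws = 19L, n_sw = 10L, n_gw = 18L,
                             blanks_per_region = c(GoldCountry = 2L, BayArea = 1L,
                                                   MercedFresno = 2L, Kern = 2L,
                                                   SELA = 2L),
                             blank_p = 0.15,
                             blank_analytes = c("nitrate_N", "copper", "iron",
                                                "manganese", "zinc"),
                             dbp_latent_rho = 0.5) {
  stopifnot(all(region_n > 0), n_private_wells >= 0,
            blank_p >= 0, blank_p <= 1,
            dbp_latent_rho >= 0, dbp_latent_rho <= 1)
  bad <- setdiff(names(region_n), .regions)
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(recipe$p_detect < 0 | recipe$p_detect > 1)) {
    stop("p_detect must lie in [0, 1]", call. = FALSE)
  }
  for (a in names(region_p)) {
    if (any(region_p[[a]] < 0 | region_p[[a]] > 1)) {
      stop("region_p for ", a, " must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(
    region_n = region_n, n_private_wells = n_private_wells,
    recipe = recipe, region_p = region_p,
    n_small_pws = n_small_pws, n_sw = n_sw, n_gw = n_gw,
    blanks_per_region = blanks_per_region, blank_p = blank_p,
    blank_analytes = blank_analytes, dbp_latent_rho = dbp_latent_rho
  ), class = "generator_config")
}

# Named analyte recipe calibrated to the campaign's printed occurrence
# statistics (detection frequencies, medians, detected ranges, ug/L).
.preset_recipe <- function() {
  r <- function(id, cls, cas, mw, unit, p, med, lo, hi, sdlog = 0.9) {
    tibble(analyte_id = id, analyte_class = cls, cas = cas,
           molecular_weight = mw, native_unit = unit, p_detect = p,
           median_ugL = med, sdlog = sdlog, min_ugL = lo, max_ugL = hi)
  }
  named <- bind_rows(
    r("bromodichloromethane", "DBP", "75-27-4", 163.83, "ug/L", 0.867, 1.07, 0.04, 70.7),
    r("bromoform",            "DBP", "75-25-2", 252.73, "ug/L", 0.717, 2.50, 0.04, 47.7),
    r("chloroform",           "DBP", "67-66-3", 119.38, "ug/L", 0.850, 0.78, 0.04, 50.6),
    r("dibromochloromethane", "DBP", "124-48-1", 208.28, "ug/L", 0.750, 1.55, 0.04, 65.8),
    r("dichloroacetonitrile", "DBP", "3018-12-0", 109.94, "ug/L", 0.30, 0.35, 0.04, 5.0),
    r("trichloronitromethane","DBP", "76-06-2", 164.38, "ug/L", 0.15, 0.20, 0.04, 3.0),
    r("atrazine",    "pesticide", "1912-24-9", 215.68, "ug/L", 0.283, 0.030, 0.001, 0.165, 1.1),
    r("simazine",    "pesticide", "122-34-9", 201.66, "ug/L", 0.217, 0.058, 0.005, 0.340, 1.1),
    r("d24",         "pesticide", "94-75-7", 221.04, "ug/L", 0.017, 0.050, 0.050, 0.050, 0.5),
    r("metolachlor", "pesticide", "51218-45-2", 283.79, "ug/L", 0.05, 0.020, 0.001, 0.100, 1.1),
    r("PFOA", "PFAS", "335-67-1", 414.07, "ng/L", 0.167, 0.008, 0.002, 0.014, 0.5),
    r("PFOS", "PFAS", "1763-23-1", 500.13, "ng/L", 0.167, 0.008, 0.002, 0.018, 0.5),
    r("PFBA", "PFAS", "375-22-4", 214.04, "ng/L", 0.200, 0.006, 0.002, 0.024, 0.5),
    r("PFHxS", "PFAS", "355-46-4", 400.12, "ng/L", 0.050, 0.005, 0.005, 0.005, 0.3),
    r("PFNA",  "PFAS", "375-95-1", 464.08, "ng/L", 0.033, 0.002, 0.002, 0.002, 0.3),
    r("carbamazepine", "pharmaceutical", "298-46-4", 236.27, "ug/L", 0.117, 0.010, 0.001, 0.374, 1.2),
    r("gabapentin",    "pharmaceutical", "60142-96-3", 171.24, "ug/L", 0.017, 0.010, 0.001, 0.100, 1.0),
    r("fluticasone_propionate", "pharmaceutical", "80474-14-2", 500.57, "ug/L", 0.05, 0.005, 0.001, 0.050, 1.0),
    r("arsenic",  "trace_element", "7440-38-2", NA, "ug/L", 0.100, 7.0, 4.0, 9.0, 0.3),
    r("barium",   "trace_element", "7440-39-3", NA, "ug/L", 1.000, 68.5, 0.110, 323, 1.2),
    r("cadmium",  "trace_element", "7440-43-9", NA, "ug/L", 0.050, 2.0, 1.0, 3.0, 0.4),
    r("chromium", "trace_element", "7440-47-3", NA, "ug/L", 0.583, 2.0, 1.0, 11.0, 0.7),
    r("copper",   "trace_element", "7440-50-8", NA, "ug/L", 0.950, 15.3, 1.0, 287, 1.3),
    r("lead",     "trace_element", "7439-92-1", NA, "ug/L", 0.183, 1.2, 0.5, 2.0, 0.4),
    r("uranium",  "trace_element", "7440-61-1", NA, "ug/L", 0.133, 6.5, 4.0, 8.0, 0.3),
    r("manganese","trace_element", "7439-96-5", NA, "ug/L", 0.783, 1.80, 0.20, 104, 1.2),
    r("lithium",  "trace_element", "7439-93-2", NA, "ug/L", 1.000, 3.67, 0.06, 37.1, 1.2),
    r("zinc",     "trace_element", "7440-66-6", NA, "ug/L", 0.60, 20, 1.0, 500, 1.2),
    r("iron",     "trace_element", "7439-89-6", NA, "ug/L", 0.40, 30, 2.0, 800, 1.2),
    r("fluoride", "major_element", "16984-48-8", NA, "mg/L", 0.850, 290, 10, 760, 0.8),
    r("nitrate_N","major_element", "14797-55-8", NA, "mg/L", 0.783, 1560, 18, 6190, 1.0)
  )
  # pad with never-detected analytes so class totals mirror the campaign's
  # analytical scope: 251 organics (13-ish DBP, ~80 pesticides, 32 PFAS,
  # 113 pharmaceuticals) and 32 inorganics
  pad <- function(cls, prefix, n, unit = "ug/L", mw = 250) {
    if (n <= 0) return(NULL)
    r(sprintf("%s_%03d", prefix, seq_len(n)), cls, "", mw, unit, 0, 0.01,
      0.001, 1, 1)
  }
  n_named <- table(named$analyte_class)
  filler <- bind_rows(
    pad("DBP", "dbp_x", 26 - n_named[["DBP"]]),
    pad("pesticide", "pest_x", 80 - n_named[["pesticide"]]),
    pad("PFAS", "pfas_x", 32 - n_named[["PFAS"]], unit = "ng/L", mw = 400),
    pad("pharmaceutical", "pharm_x", 113 - n_named[["pharmaceutical"]], mw = 300)
  )
  filler$molecular_weight <- as.numeric(filler$molecular_weight)
  inorg_pad <- r(sprintf("inorg_x_%03d",
                         seq_len(32 - sum(named$analyte_class %in%
                                            c("trace_element", "major_element")))),
                 "other_inorganic", "", NA, "ug/L", 0, 0.01, 0.001, 1, 1)
  bind_rows(named, filler, inorg_pad)
}

#' Generator preset calibrated to the California campaign
#'
#' Detection probabilities and concentration bodies are set to the
#' published per-constituent occurrence statistics (e.g.
#' bromodichloromethane 86.7%, lithium 100%, arsenic 10%), with
#' lognormal bodies centred on the printed medians and winsorised to the
#' printed detected ranges (clipping keeps the configured medians exact). Regional structure is encoded as per-region
#' probability overrides: PFAS detections concentrate in SELA, arsenic
#' in Kern; private wells (Gold Country only) never receive DBPs.
#' The analyte roster is padded with never-detected analytes so the
#' analytical scope matches the campaign (251 organics, 32 inorganics).
#'
#' @return A [generator_config()].
#' @export
preset_california <- function() {
  region_p <- list(
    # overall frequencies preserved: sum(n_r * p_r) / 60 matches p_detect
    PFOA = c(GoldCountry = 0.035, BayArea = 0.035, MercedFresno = 0.035,
             Kern = 0.035, SELA = 0.40),
    PFOS = c(GoldCountry = 0.035, BayArea = 0.035, MercedFresno = 0.035,
             Kern = 0.035, SELA = 0.40),
    PFBA = c(GoldCountry = 0, BayArea = 0, MercedFresno = 0, Kern = 0,
             SELA = 0.545),
    PFHxS = c(GoldCountry = 0, BayArea = 0, MercedFresno = 0.08, Kern = 0,
              SELA = 0.10),
    PFNA = c(GoldCountry = 0, BayArea = 0, MercedFresno = 0.05, Kern = 0,
             SELA = 0.07),
    arsenic = c(GoldCountry = 0.04, BayArea = 0.04, MercedFresno = 0.04,
                Kern = 0.40, SELA = 0.04),
    carbamazepine = c(GoldCountry = 0, BayArea = 0, MercedFresno = 0.20,
                      Kern = 0, SELA = 0.23)
  )
  generator_config(recipe = .preset_recipe(), region_p = region_p)
}

#' Packaged NPDWR benchmark table
#'
#' MCLG and MCL entries (ug/L) for the 21 detected constituents with
#' National Primary Drinking Water Regulation standards, plus the USGS
#' HBSL for lithium. The lead "MCL" row is the non-health-based Action
#' Level, noted as such.
#'
#' @return A `tapscreen_benchmarks` table.
#' @export
benchmarks_npdwr <- function() {
  path <- system.file("extdata", "benchmarks_npdwr.csv", package = "tapscreen")
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  benchmark_table(raw$analyte_id, raw$benchmark_type, raw$value_ugL, raw$note)
}

#' Packaged synthetic ACC table
#'
#' A small synthetic activity-concentration-at-cutoff table,
#' schema-compatible with invitroDB exports, covering the screen's
#' driver chemicals (DBPs, common pesticides, fluticasone propionate)
#' with plausible ACC magnitudes and exclusion flags. It is a synthetic
#' stand-in for testing and examples, not ToxCast data; users supply a
#' real ACC export in the same layout for production screening.
#'
#' @return A `tapscreen_acc` table.
#' @export
acc_synthetic <- function() {
  path <- system.file("extdata", "acc_synthetic.csv", package = "tapscreen")
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  acc_table(raw$analyte_cas, raw$assay_endpoint_id, raw$acc_um,
            raw$exclusion_reason)
}

# Lognormal body centred on the configured median, winsorised (clipped)
# to [lo, hi]; clipping keeps the configured median exact whenever it
# lies inside the envelope, unlike tail truncation which shifts it.
# z is an optional correlated standard-normal deviate (shared latent
# disinfection-intensity factor).
.rtrunc_lnorm <- function(n, median_ugL, sdlog, lo, hi, z = NULL, rho = 0) {
  meanlog <- log(median_ugL)
  dev <- if (is.null(z) || rho == 0) {
    stats::rnorm(n)
  } else {
    rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  }
  pmin(pmax(exp(meanlog + sdlog * dev), lo), hi)
}

#' Generate the sample-metadata table for a config
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A `tapscreen_samples` table.
#' @export
generate_samples <- function(config, seed = 1L) {
  .with_seed(seed, {
    region <- rep(names(config$region_n), config$region_n)
    n <- length(region)
    sample_id <- sprintf("site_%03d", seq_len(n))
    infrastructure <- rep("PWS", n)
    gc_idx <- which(region == "GoldCountry")
    pw <- gc_idx[seq_len(min(config$n_private_wells, length(gc_idx)))]
    infrastructure[pw] <- "private_well"
    pws_idx <- which(infrastructure == "PWS")
    source_water <- rep("mixed", n)
    source_water[pw] <- "GW"
    sw_pick <- sample(pws_idx, min(config$n_sw, length(pws_idx)))
    source_water[sw_pick] <- "SW"
    gw_pool <- setdiff(pws_idx, sw_pick)
    gw_pick <- sample(gw_pool, min(config$n_gw, length(gw_pool)))
    source_water[gw_pick] <- "GW"
    service_population <- rep(NA_integer_, n)
    small_pick <- sample(pws_idx, min(config$n_small_pws, length(pws_idx)))
    service_population[small_pick] <- as.integer(round(runif(length(small_pick),
                                                             330, 9999)))
    large <- setdiff(pws_idx, small_pick)
    service_population[large] <- as.integer(round(exp(runif(length(large),
                                                            log(10000),
                                                            log(3.95e6)))))
    sample_meta(sample_id, region, infrastructure, source_water,
                service_population)
  })
}

#' Generate a synthetic study dataset
#'
#' Draws detection indicators per (sample, analyte) from Bernoulli
#' probabilities (regional overrides applied; DBP probabilities forced
#' to zero for private wells, which receive no disinfection), detected
#' concentrations from lognormal bodies winsorised to the configured
#' ranges, and field blanks per region. DBP concentrations within a
#' sample share a latent disinfection-intensity factor so they co-occur
#' at correlated levels. The same seed always reproduces the same
#' dataset.
#'
#' @param config A [generator_config()], e.g. [preset_california()].
#' @param seed Integer seed.
#' @param benchmarks,acc Tables attached to the dataset (defaults:
#'   packaged NPDWR benchmarks and the synthetic ACC fixture).
#' @return A [study_dataset()] that passes [validate_study()] cleanly.
#' @export
generate_study <- function(config, seed = 1L,
                           benchmarks = benchmarks_npdwr(),
                           acc = acc_synthetic()) {
  samples <- generate_samples(config, seed = seed)
  recipe <- config$recipe
  analytes <- analyte_table(recipe$analyte_id, recipe$analyte_class,
                            cas = recipe$cas,
                            molecular_weight = recipe$molecular_weight,
                            native_unit = recipe$native_unit)
  meas <- .with_seed(seed + 1L, {
    n_s <- nrow(samples)
    z_dbp <- stats::rnorm(n_s)  # shared disinfection-intensity factor
    rows <- vector("list", nrow(recipe))
    for (k in seq_len(nrow(recipe))) {
      rec <- recipe[k, ]
      p <- rep(rec$p_detect, n_s)
      rp <- config$region_p[[rec$analyte_id]]
      if (!is.null(rp)) p <- unname(rp[samples$region])
      if (rec$analyte_class == "DBP") {
        p[samples$infrastructure == "private_well"] <- 0
      }
      hit <- runif(n_s) < p
      val <- rep(NA_real_, n_s)
      if (any(hit)) {
        if (rec$analyte_class == "DBP") {
          val[hit] <- .rtrunc_lnorm(sum(hit), rec$median_ugL, rec$sdlog,
                                    rec$min_ugL, rec$max_ugL,
                                    z = z_dbp[hit], rho = config$dbp_latent_rho)
        } else {
          val[hit] <- .rtrunc_lnorm(sum(hit), rec$median_ugL, rec$sdlog,
                                    rec$min_ugL, rec$max_ugL)
        }
      }
      rows[[k]] <- tibble(sample_id = samples$sample_id,
                          analyte_id = rec$analyte_id,
                          value_ugL = val,
                          status = ifelse(hit, "detected", "nondetect"))
    }
    all_rows <- bind_rows(rows)
    measurement_table(all_rows$sample_id, all_rows$analyte_id,
                      all_rows$value_ugL, all_rows$status)
  })
  blanks <- generate_blanks(config, seed = seed + 2L)$detections
  study_dataset(analytes, samples, meas, blanks, benchmarks, acc)
}

#' Generate regional field-blank events and detections
#'
#' The default layout collects two blanks per region except one in the
#' Bay Area (nine blank events). Each event can pick up each
#' contamination-prone analyte with probability `blank_p`; contamination
#' magnitudes are drawn low relative to the analyte's concentration body
#' (around a fifth of the configured median).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List: `events` (tibble region, blank_id) and `detections`
#'   (a `tapscreen_blanks` table; empty when nothing was contaminated).
#' @export
generate_blanks <- function(config, seed = 1L) {
  .with_seed(seed, {
    events <- tibble(
      region = rep(names(config$blanks_per_region), config$blanks_per_region)
    )
    events$blank_id <- sprintf("blank_%02d", seq_len(nrow(events)))
    rec <- config$recipe[config$recipe$analyte_id %in% config$blank_analytes, ]
    det <- list()
    for (i in seq_len(nrow(events))) {
      for (k in seq_len(nrow(rec))) {
        if (runif(1) < config$blank_p) {
          mag <- .rtrunc_lnorm(1, rec$median_ugL[k] / 5, rec$sdlog[k],
                               rec$min_ugL[k] / 10, rec$max_ugL[k] / 5)
          det[[length(det) + 1]] <- tibble(region = events$region[i],
                                           analyte_id = rec$analyte_id[k],
                                           value_ugL = mag)
        }
      }
    }
    detections <- if (length(det)) {
      d <- bind_rows(det)
      blank_table(d$region, d$analyte_id, d$value_ugL)
    } else blank_table()
    list(events = events, detections = detections)
  })
}
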