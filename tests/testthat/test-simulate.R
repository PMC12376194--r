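test_that("generation is deterministic given the seed", {
  cfg <- small_config()
  d1 <- generate_study(cfg, seed = 3, benchmarks = empty_benchmarks(),
                       acc = empty_acc())
  d2 <- generate_study(cfg, seed = 3, benchmarks = empty_benchmarks(),
                       acc = empty_acc())
  expect_identical(d1$measurements, d2$measurements)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$blanks, d2$blanks)
  d3 <- generate_study(cfg, seed = 4, benchmarks = empty_benchmarks(),
                       acc = empty_acc())
  expect_false(identical(d1$measurements$status, d3$measurements$status))
})

test_that("degenerate detection probabilities are honoured exactly", {
  cfg <- small_config()
  cfg$recipe$p_detect[cfg$recipe$analyte_id == "lithium"] <- 1
  cfg$recipe$p_detect[cfg$recipe$analyte_id == "uranium"] <- 0
  ds <- generate_study(cfg, seed = 5, benchmarks = empty_benchmarks(),
                       acc = empty_acc())
  expect_equal(detection_frequency(ds$measurements, "lithium", 60), 100)
  expect_equal(detection_frequency(ds$measurements, "uranium", 60), 0)
  expect_error(generator_config(recipe = within(cfg$recipe, p_detect[1] <- 1.2)),
               "p_detect")
})

test_that("generated studies always pass validation", {
  cfg <- small_config()
  for (seed in c(1, 17, 99)) {
    ds <- generate_study(cfg, seed = seed, benchmarks = benchmarks_npdwr(),
                         acc = acc_synthetic())
    expect_equal(nrow(validate_study(ds)), 0)
  }
})

test_that("detection counts follow the binomial oracle across replicates", {
  # one DBP at p = 0.867 over 60 samples; mean count over replicates
  # should sit near 52.02 (binomial mean), within Monte-Carlo error
  cfg <- small_config(p_dbp = 0.867)
  cfg$recipe <- cfg$recipe[cfg$recipe$analyte_id == "bromodichloromethane", ]
  cfg$n_private_wells <- 0L  # DBP probability is forced to zero in wells
  n_rep <- 400
  counts <- vapply(seq_len(n_rep), function(i) {
    ds <- generate_study(cfg, seed = 1000 + i,
                         benchmarks = empty_benchmarks(), acc = empty_acc())
    sum(ds$measurements$status == "detected")
  }, numeric(1))
  se_mean <- sqrt(60 * 0.867 * 0.133) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - 60 * 0.867), 4 * se_mean)
})

test_that("the private wells sit in Gold Country and never see DBPs", {
  ds <- generate_study(preset_california(), seed = 21)
  pw <- ds$samples$sample_id[ds$samples$infrastructure == "private_well"]
  expect_equal(length(pw), 5)
  expect_true(all(ds$samples$region[ds$samples$sample_id %in% pw] ==
                    "GoldCountry"))
  dbp_ids <- ds$analytes$analyte_id[ds$analytes$analyte_class == "DBP"]
  dbp_in_pw <- ds$measurements$status[ds$measurements$sample_id %in% pw &
                                        ds$measurements$analyte_id %in% dbp_ids]
  expect_true(all(dbp_in_pw == "nondetect"))
})

test_that("the California preset mirrors the campaign structure", {
  cfg <- preset_california()
  ds <- generate_study(cfg, seed = 8)
  expect_equal(nrow(ds$samples), 60)
  expect_equal(as.integer(table(ds$samples$region)[study_regions()]),
               c(12L, 6L, 10L, 10L, 22L))
  # analytical scope: 251 organics + 32 inorganics
  organic <- ds$analytes$analyte_class %in% c("DBP", "pesticide", "PFAS",
                                              "pharmaceutical")
  expect_equal(sum(organic), 251)
  expect_equal(sum(!organic), 32)
  # lithium configured at 100% detection
  expect_equal(detection_frequency(ds$measurements, "lithium", 60), 100)
  # PFBA only ever appears in SELA under the regional weighting
  pfba <- ds$measurements[ds$measurements$analyte_id == "PFBA" &
                            ds$measurements$status == "detected", ]
  if (nrow(pfba)) {
    expect_true(all(ds$samples$region[match(pfba$sample_id,
                                            ds$samples$sample_id)] == "SELA"))
  }
  # arsenic detections concentrate in Kern
  ars <- ds$measurements[ds$measurements$analyte_id == "arsenic" &
                           ds$measurements$status == "detected", ]
  reg <- ds$samples$region[match(ars$sample_id, ds$samples$sample_id)]
  expect_gte(sum(reg == "Kern"), sum(reg != "Kern"))
})

test_that("blank layout follows the per-region configuration", {
  cfg <- small_config()
  bl <- generate_blanks(cfg, seed = 2)
  expect_equal(nrow(bl$events), 9)  # 2 per region, 1 in the Bay Area
  expect_equal(as.integer(table(bl$events$region)[names(cfg$blanks_per_region)]),
               unname(cfg$blanks_per_region))

  cfg0 <- cfg
  cfg0$blank_p <- 0
  bl0 <- generate_blanks(cfg0, seed = 2)
  expect_equal(nrow(bl0$detections), 0)
  # and with no blank detections, censoring is a no-op
  ds <- generate_study(cfg0, seed = 2, benchmarks = empty_benchmarks(),
                       acc = empty_acc())
  expect_identical(censor_to_blanks(ds$measurements, ds$blanks, ds$samples),
                   ds$measurements)
})

test_that("a forced regional blank censors only its own region", {
  cfg <- small_config()
  ds <- generate_study(cfg, seed = 13, benchmarks = empty_benchmarks(),
                       acc = empty_acc())
  big_blank <- blank_table("Kern", "nitrate_N", 1e7)  # above every sample
  cen <- censor_to_blanks(ds$measurements, big_blank, ds$samples)
  kern <- ds$samples$sample_id[ds$samples$region == "Kern"]
  nitrate <- cen[cen$analyte_id == "nitrate_N", ]
  in_kern <- nitrate$sample_id %in% kern
  was_det <- ds$measurements$status[ds$measurements$analyte_id == "nitrate_N"] ==
    "detected"
  expect_true(all(nitrate$status[in_kern & was_det] == "censored_by_blank"))
  expect_true(all(nitrate$status[!in_kern] ==
                    ds$measurements$status[ds$measurements$analyte_id ==
                                             "nitrate_N"][!in_kern]))
})

test_that("concentration bodies recover configured medians at scale", {
  # scale the campaign layout up so each analyte accumulates ~1000 detections
  cfg <- small_config()
  cfg$region_n <- c(GoldCountry = 240L, BayArea = 120L, MercedFresno = 200L,
                    Kern = 200L, SELA = 440L)
  cfg$n_private_wells <- 0L
  keep <- c("bromodichloromethane", "lithium", "manganese")
  cfg$recipe <- cfg$recipe[cfg$recipe$analyte_id %in% keep, ]
  cfg$recipe$p_detect <- 1
  cfg$dbp_latent_rho <- 0  # isolate the marginal body
  ds <- generate_study(cfg, seed = 6, benchmarks = empty_benchmarks(),
                       acc = empty_acc())
  det <- ds$measurements[ds$measurements$status == "detected", ]
  for (a in keep) {
    vals <- det$value_ugL[det$analyte_id == a]
    med_cfg <- cfg$recipe$median_ugL[cfg$recipe$analyte_id == a]
    # truncation keeps the median in place; allow Monte-Carlo slack
    expect_lt(abs(log(median(vals) / med_cfg)), 0.15)
    expect_true(all(vals >= cfg$recipe$min_ugL[cfg$recipe$analyte_id == a]))
    expect_true(all(vals <= cfg$recipe$max_ugL[cfg$recipe$analyte_id == a]))
  }
})
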