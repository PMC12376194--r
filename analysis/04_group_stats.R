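#!/usr/bin/env Rscript
# Stage 4: group comparisons.
#
# Builds the complete concentration matrix by the fixed non-detect
# substitution rules, then applies the two-stage protocol per grouping
# variable (region; PWS size class; source water): one-way PERMANOVA
# (9999 permutations, Euclidean distance), gated Kruskal-Wallis on the
# per-sample cumulative concentration, and a Dunn post hoc with
# Bonferroni correction and compact significance letters.

suppressPackageStartupMessages({
  library(optparse)
  library(tapscreen)
  library(dplyr)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--study", type = "character", default = "results/study"),
  make_option("--out", type = "character", default = "results"),
  make_option("--nperm", type = "integer", default = 9999L),
  make_option("--seed", type = "integer", default = 1L)
)))

ds <- read_study_archive(opts$study)
ds$measurements <- censor_to_blanks(ds$measurements, ds$blanks, ds$samples)

rules <- substitution_rules()
covered <- ds$analytes$analyte_id[
  ds$analytes$analyte_class %in% c("DBP", "pesticide", "PFAS",
                                   "pharmaceutical") |
    ds$analytes$analyte_id %in% rules$key[rules$key_type == "analyte_id"]]
covered <- intersect(covered, unique(ds$measurements$analyte_id))

rows <- list()
letters_rows <- list()
for (by in c("region", "size_class", "source_water")) {
  keep <- !is.na(ds$samples[[by]])
  samples <- ds$samples[keep, ]
  meas <- ds$measurements[ds$measurements$sample_id %in% samples$sample_id, ]
  labels <- samples[[by]]
  if (length(unique(labels)) < 2 || min(table(labels)) < 2) {
    cat(sprintf("%s: skipped (needs >= 2 groups with >= 2 samples)\n", by))
    next
  }
  mat <- substitute_nondetects(meas, ds$analytes, samples,
                               analyte_ids = covered, rules = rules)
  res <- compare_groups(mat, labels, n_perm = opts$nperm, seed = opts$seed)
  cat(sprintf("\n%s: PERMANOVA pseudo-F = %.3f, p = %.4f\n",
              by, res$permanova$pseudo_F, res$permanova$p_value))
  rows[[by]] <- tibble(grouping = by, test = "PERMANOVA",
                       statistic = res$permanova$pseudo_F,
                       p_value = res$permanova$p_value,
                       n_permutations = opts$nperm)
  if (!is.null(res$kruskal)) {
    cat(sprintf("  Kruskal-Wallis on cumulative concentration: H = %.3f, p = %.4f\n",
                res$kruskal$H, res$kruskal$p_value))
    rows[[paste0(by, "_kw")]] <- tibble(grouping = by, test = "KruskalWallis",
                                        statistic = res$kruskal$H,
                                        p_value = res$kruskal$p_value,
                                        n_permutations = NA_integer_)
  }
  if (!is.null(res$dunn)) {
    cat("  Dunn letters:",
        paste(names(res$dunn$letters), res$dunn$letters, sep = "=",
              collapse = "  "), "\n")
    letters_rows[[by]] <- tibble(grouping = by,
                                 group = names(res$dunn$letters),
                                 letters = unname(res$dunn$letters))
  }
}

write.csv(bind_rows(rows), file.path(opts$out, "stats_tests.csv"),
          row.names = FALSE)
if (length(letters_rows)) {
  write.csv(bind_rows(letters_rows), file.path(opts$out, "stats_letters.csv"),
            row.names = FALSE)
}
cat("\nStatistics written under", opts$out, "\n")
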