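#!/usr/bin/env Rscript
# Cohort-level summaries: per-patient burden and VAF tiers, gene
# recurrence, VAF heterogeneity across patients, the coverage-vs-burden
# artifact check, and hotspot screening of the separate 57-patient cohort.

suppressMessages(library(nkdriver))

retained <- read_variants("results/retained_variants.tsv")
merged <- read_variants("results/merged_variants.tsv")
ann <- read_annotations("results/bundle/annotations.tsv")
patients <- utils::read.delim("results/bundle/patients.tsv")
cfg <- filter_config(population_by_patient =
                       stats::setNames(patients$population,
                                       patients$patient_id))

prof <- build_patient_profiles(
  retained,
  coverages = patients[, c("patient_id", "mean_tumor_coverage",
                           "mean_normal_coverage")],
  config = cfg)
utils::write.table(prof$profiles, "results/patient_profiles.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(prof$radar, "results/radar_table.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

rec <- recurrence_table(retained)
utils::write.table(rec$genes, "results/gene_recurrence.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Recurrently mutated genes (>= 2 patients):",
    sum(rec$genes$recurrent), "\n")
print(as.data.frame(rec$genes[rec$genes$recurrent, ]), row.names = FALSE)

# heterogeneity is assessed on the full deleterious set (including
# sub-threshold VAFs), where the subclonal structure lives
cascade <- run_cascade(annotate_variants(merged, ann), cfg)
kw <- vaf_heterogeneity_test(cascade$deleterious$vaf,
                             cascade$deleterious$patient_id)
cat(sprintf("VAF heterogeneity across patients: H = %.1f, p = %.3g (%d variants)\n",
            kw$statistic, kw$p_value, kw$n_obs))

counts <- as.data.frame(table(patient_id = cascade$deleterious$patient_id))
m <- merge(counts, patients, by = "patient_id")
for (sample in c("tumor", "normal")) {
  covcol <- paste0("mean_", sample, "_coverage")
  ct <- coverage_burden_correlation(m$Freq, m[[covcol]], sample = sample)
  cat(sprintf("Burden vs %s coverage: rho = %.2f, p = %.2f -> %s\n",
              sample, ct$estimate, ct$p_value,
              if (ct$significant) "SIGNIFICANT (artifact suspected)"
              else "no significant correlation"))
}

hs <- read_hotspots("results/bundle/hotspots.json")
screening <- utils::read.delim("results/bundle/screening_variants.tsv")
hits <- hotspot_screen(screening, hs)
utils::write.table(hits, "results/hotspot_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
prev <- screen_prevalence(length(unique(hits$patient_id)), 57)
cat(sprintf("Hotspot screening: %d/%d patients (%d%%) carry hotspot mutations\n",
            prev$n_hit, prev$n, prev$percent))
cat("Wrote patient_profiles, radar_table, gene_recurrence, hotspot_hits\n")
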