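#!/usr/bin/env Rscript
# Apply the prioritization cascade to the merged variants: discard
# population-common (>5% in the patient-matched gnomAD-style population),
# ClinVar-benign and non-deleterious variants, then retain VAF >= 0.05.

suppressMessages(library(nkdriver))

merged <- read_variants("results/merged_variants.tsv")
ann <- read_annotations("results/bundle/annotations.tsv")
patients <- utils::read.delim("results/bundle/patients.tsv")
cfg <- filter_config(population_by_patient =
                       stats::setNames(patients$population,
                                       patients$patient_id))

res <- run_cascade(annotate_variants(merged, ann), cfg)
write_variants(res$retained, "results/retained_variants.tsv")
utils::write.table(res$funnel, "results/funnel.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cohort <- res$funnel[res$funnel$scope == "cohort", ]
cat("Filter funnel (cohort):\n")
print(as.data.frame(cohort), row.names = FALSE)
cat(sprintf("Retained %d variants (VAF >= %.2f) in %d genes\n",
            nrow(res$retained), cfg$retain_vaf,
            length(unique(res$retained$gene))))
print(table(res$retained$tier))
cat("Wrote results/retained_variants.tsv and results/funnel.tsv\n")
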