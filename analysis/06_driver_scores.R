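#!/usr/bin/env Rscript
# Nominate putative driver genes: combine VAF, predicted impact,
# expression, recurrence and external driver labels into a per-gene
# score; assign the wet-lab validation method per variant and flag genes
# with approved drugs.

suppressMessages(library(nkdriver))

retained <- read_variants("results/retained_variants.tsv")
expr <- read_expression("results/bundle/expression.tsv")
labels <- read_driver_labels("results/bundle/driver_labels.tsv")
drugs <- read_drug_interactions("results/bundle/drug_interactions.tsv")

scores <- score_genes(retained, expr, labels)
utils::write.table(scores, "results/driver_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

prominent <- retained[retained$tier == "prominent", ]
prominent$validation <- validation_assignment(prominent$vaf)
utils::write.table(
  prominent[, c("patient_id", "gene", "vaf", "validation")],
  "results/validation_plan.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

cat("Top driver candidates:\n")
print(as.data.frame(head(scores, 8)), row.names = FALSE)
cat(sprintf("Validation plan: %d prominent variants (%d Sanger, %d ARMS PCR)\n",
            nrow(prominent), sum(prominent$validation == "sanger"),
            sum(prominent$validation == "arms_pcr")))
flags <- drug_target_flag(head(scores$gene, 10), drugs)
hit <- flags[lengths(flags) > 0]
cat("Approved drug interactions among top candidates:\n")
for (g in names(hit)) cat("  ", g, "->", paste(hit[[g]], collapse = ", "), "\n")
cat("Wrote results/driver_scores.tsv and results/validation_plan.tsv\n")
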