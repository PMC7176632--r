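#!/usr/bin/env Rscript
# Generate the synthetic CLPD-NK-like study cohort: 13 tumor-normal pairs,
# three caller dialects per patient, annotation/expression/PPI/pathway
# side tables and a ground-truth table. Everything downstream reads the
# bundle written here.

suppressMessages(library(nkdriver))

out_dir <- "results/bundle"
cfg <- simulation_config(seed = 1)
bundle <- simulate_cohort(cfg, out_dir = out_dir)

tr <- bundle$truth
som <- tr[tr$role %in% c("clonal_driver", "prominent",
                         "subclonal_passenger"), ]
cat("Simulated cohort written to", out_dir, "\n")
cat(sprintf("  patients: %d, planted variants: %d (%d somatic, %d decoys)\n",
            cfg$n_patients, nrow(tr), nrow(som), nrow(tr) - nrow(som)))
cat(sprintf("  mean depth: tumor %.1fx / normal %.1fx\n",
            mean(tr$tumor_depth), mean(tr$normal_depth)))
cat(sprintf("  somatic variants below VAF 0.05: %.1f%%\n",
            100 * mean(som$true_vaf < 0.05)))
cat(sprintf("  detected by at least one caller: %.1f%%\n",
            100 * mean(nzchar(som$detected_by))))
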