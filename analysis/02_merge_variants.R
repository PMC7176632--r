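#!/usr/bin/env Rscript
# Read every per-patient caller VCF, normalize variant keys, and merge the
# three callers by union with the 10-read coverage gate on both samples.

suppressMessages(library(nkdriver))

merged <- load_bundle_variants("results/bundle", min_coverage = 10)
write_variants(merged, "results/merged_variants.tsv")

cat("Merged somatic variants:", nrow(merged), "\n")
cat("  by caller support:\n")
print(table(sapply(strsplit(merged$callers, ","), length)))
cat(sprintf("  single best caller would have given at most %d variants\n",
            max(table(merged$count_source))))
cat(sprintf("  SNVs: %d, indels: %d\n",
            sum(merged$variant_class == "snp"),
            sum(merged$variant_class == "indel")))
cat("Wrote results/merged_variants.tsv\n")
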