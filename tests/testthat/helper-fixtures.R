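# Shared fixtures and independent oracles used across the suite.

validated_variants_path <- function() {
  system.file("extdata", "validated_variants.tsv", package = "nkdriver")
}

read_validated_variants <- function() {
  tibble::as_tibble(utils::read.delim(validated_variants_path()))
}

# Closed-form Kruskal-Wallis H with tie correction; independent of
# stats::kruskal.test (rank-sum formula evaluated directly).
kw_H_oracle <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)
  H / C
}

# Monte-Carlo permutation p-value for the Kruskal-Wallis statistic.
kw_perm_p <- function(x, g, B = 10000) {
  obs <- kw_H_oracle(x, g)
  hits <- 0L
  for (b in seq_len(B)) {
    if (kw_H_oracle(x, sample(g)) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# Brute-force evaluation of each cascade rule on an annotated variant
# table; returns pass flags and the first failing stage per variant.
cascade_oracle <- function(df, pop_by_patient, max_pop_af = 0.05,
                           retain_vaf = 0.05) {
  n <- nrow(df)
  pass <- matrix(NA, n, 4,
                 dimnames = list(NULL, c("population_af", "clinvar_benign",
                                         "deleteriousness", "vaf_threshold")))
  for (i in seq_len(n)) {
    af <- df[[paste0("af_", pop_by_patient[[df$patient_id[i]]])]][i]
    pass[i, 1] <- is.na(af) || af <= max_pop_af
    pass[i, 2] <- !(isTRUE(df$clinvar[i] %in% c("benign", "likely_benign")))
    pass[i, 3] <- df$snpeff_impact[i] %in% c("HIGH", "MODERATE") &&
      (isTRUE(df$metasvm[i] == "deleterious") || is.na(df$metasvm[i]) ||
         isTRUE(df$metasvm[i] == "missing"))
    pass[i, 4] <- df$vaf[i] >= retain_vaf
  }
  first_fail <- apply(pass, 1, function(p) {
    w <- which(!p)
    if (length(w)) colnames(pass)[w[1]] else NA_character_
  })
  list(pass_all = apply(pass, 1, all), first_fail = first_fail)
}

# Minimal handcrafted MuTect-style VCF writer for parser tests.
write_test_vcf_mutect <- function(path, records,
                                  samples = c("TUMOR", "NORMAL")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=500000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
}

# Random annotated variant table covering all filter outcomes.
random_annotated_variants <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sample(c("A", "B"), n, replace = TRUE),
    chrom = "chr1", pos = sample(1e5, n), ref = "A", alt = "G",
    gene = sprintf("G%03d", seq_len(n)),
    vaf = round(runif(n, 0, 0.5), 3),
    snpeff_impact = sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                           n, replace = TRUE),
    metasvm = sample(c("deleterious", "tolerated", NA), n, replace = TRUE),
    af_nfe = ifelse(runif(n) < 0.5, NA, round(runif(n, 0, 0.2), 3)),
    af_fin = ifelse(runif(n) < 0.5, NA, round(runif(n, 0, 0.2), 3)),
    clinvar = sample(c("benign", "likely_benign", "other", NA),
                     n, replace = TRUE))
}

random_pop_map <- c(A = "nfe", B = "fin")

# Toy gene-network fragment from explicit evidence rows.
ev_row <- function(g1, g2, cls, prov) {
  tibble::tibble(gene1 = g1, gene2 = g2, edge_class = cls, provenance = prov)
}
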