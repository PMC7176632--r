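test_that("compute_vaf handles the standard cases and rejects impossible counts", {
  expect_equal(compute_vaf(0, 100), 0)
  expect_equal(compute_vaf(50, 100), 0.5)
  expect_equal(compute_vaf(38, 100), 0.38)
  expect_equal(compute_vaf(0, 0), 0)
  expect_equal(compute_vaf(c(1, 2), c(10, 10)), c(0.1, 0.2))
  expect_error(compute_vaf(11, 10), "invariant")
})

test_that("normalize_variant trims to the parsimonious left-aligned form", {
  expect_equal(as.list(normalize_variant("chr1", 100, "A", "G")),
               list(chrom = "chr1", pos = 100L, ref = "A", alt = "G"))
  expect_equal(as.list(normalize_variant("chr1", 100, "CTT", "CT")),
               list(chrom = "chr1", pos = 100L, ref = "CT", alt = "C"))
  # MNV with no shared bases is untouched
  expect_equal(as.list(normalize_variant("chr1", 100, "AC", "GT")),
               list(chrom = "chr1", pos = 100L, ref = "AC", alt = "GT"))
  # suffix trimmed first (left alignment), anchor base kept
  n <- normalize_variant("chr2", 50, "TAG", "TG")
  expect_equal(n$pos, 50L)
  expect_equal(n$ref, "TA")
  expect_equal(n$alt, "T")
  # pure shared prefix advances the coordinate
  n2 <- normalize_variant("chr2", 50, "TAC", "TA")
  expect_equal(n2$pos, 51L)
  expect_equal(n2$ref, "AC")
  expect_equal(n2$alt, "A")
  expect_error(normalize_variant("chr1", 1, "A", "A"), "differ")
})

test_that("normalization preserves the edited haplotype and is minimal", {
  # oracle: apply both representations to a random sequence context and
  # compare resulting strings; then check no further shared affix remains
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  apply_variant <- function(seq, pos, ref, alt) {
    stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
    paste0(substr(seq, 1, pos - 1L), alt,
           substr(seq, pos + nchar(ref), nchar(seq)))
  }
  for (i in 1:50) {
    core_ref <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                      collapse = "")
    core_alt <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                      collapse = "")
    if (core_ref == core_alt) next
    pad_l <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    pad_r <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    ref <- paste0(pad_l, core_ref, pad_r)
    alt <- paste0(pad_l, core_alt, pad_r)
    ctx_l <- paste(sample(bases, 10, replace = TRUE), collapse = "")
    ctx_r <- paste(sample(bases, 10, replace = TRUE), collapse = "")
    seq <- paste0(ctx_l, ref, ctx_r)
    n <- normalize_variant("chr1", 11, ref, alt)
    expect_equal(apply_variant(seq, 11, ref, alt),
                 apply_variant(seq, n$pos, n$ref, n$alt))
    # minimality: no shared suffix/prefix unless one allele is length 1
    if (nchar(n$ref) > 1L && nchar(n$alt) > 1L) {
      expect_false(substr(n$ref, 1, 1) == substr(n$alt, 1, 1))
      expect_false(substr(n$ref, nchar(n$ref), nchar(n$ref)) ==
                     substr(n$alt, nchar(n$alt), nchar(n$alt)))
    }
  }
})

test_that("parse_caller_vcf reads the MuTect dialect and splits multi-allelics", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf_mutect(f, c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:62,38\t0/0:70,0",
    "chr1\t200\t.\tC\tA,G\t.\tPASS\t.\tGT:AD\t0/1:50,30,20\t0/0:80,0,0",
    "chr1\t300\t.\tT\tC\t.\tLowQual\t.\tGT:AD\t0/1:40,10\t0/0:60,0"))
  calls <- parse_caller_vcf(f, "mutect", "P01")
  expect_equal(nrow(calls), 3L)  # multi-allelic split, non-PASS dropped
  one <- calls[calls$pos == 100, ]
  expect_equal(one$tumor_alt_count, 38L)
  expect_equal(one$tumor_depth, 100L)
  expect_equal(one$normal_depth, 70L)
  # manual per-allele enumeration of the multi-allelic record
  ma <- calls[calls$pos == 200, ]
  expect_equal(ma$alt, c("A", "G"))
  expect_equal(ma$tumor_alt_count, c(30L, 20L))
  expect_equal(ma$tumor_depth, c(100L, 100L))
  expect_true(all(ma$ref == "C"))
  # non-PASS kept when requested
  all_calls <- parse_caller_vcf(f, "mutect", "P01", pass_only = FALSE)
  expect_equal(nrow(all_calls), 4L)
  expect_true("LowQual" %in% all_calls$filter_status)
})

test_that("parse_caller_vcf handles header-only files and bad sample names", {
  f <- tempfile(fileext = ".vcf")
  write_test_vcf_mutect(f, character())
  expect_equal(nrow(parse_caller_vcf(f, "mutect2", "P01")), 0L)
  f2 <- tempfile(fileext = ".vcf")
  write_test_vcf_mutect(f2, "chr1\t1\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:5,5\t0/0:9,0",
                        samples = c("S1", "S2"))
  expect_error(parse_caller_vcf(f2, "mutect", "P01"), "sample columns")
  expect_error(parse_caller_vcf(f, "varscan", "P01"))
})

test_that("strelka2 dialect reads tier-1 base counts and TAR/TIR", {
  calls <- tibble::tibble(
    patient_id = "P01", chrom = "chr1", pos = c(100L, 200L),
    ref = c("A", "CT"), alt = c("G", "C"),
    tumor_depth = c(120L, 90L), tumor_alt_count = c(30L, 18L),
    normal_depth = c(100L, 80L), normal_alt_count = c(0L, 0L),
    filter_status = "PASS", caller = "strelka2")
  f <- tempfile(fileext = ".vcf")
  write_caller_vcf(calls, "strelka2", f)
  back <- parse_caller_vcf(f, "strelka2", "P01")
  back <- back[order(back$pos), ]
  expect_equal(back$tumor_alt_count, c(30L, 18L))
  expect_equal(back$tumor_depth, c(120L, 90L))
  expect_equal(back$normal_alt_count, c(0L, 0L))
  # sample columns are resolved by name (strelka order is NORMAL, TUMOR)
  expect_equal(back$normal_depth, c(100L, 80L))
})

test_that("merge_caller_calls takes the union with coverage gating", {
  base <- tibble::tibble(
    patient_id = "P01", chrom = "chr1", pos = 100L, ref = "A", alt = "G",
    tumor_depth = 100L, tumor_alt_count = 30L,
    normal_depth = 90L, normal_alt_count = 0L, filter_status = "PASS")
  calls <- dplyr::bind_rows(
    dplyr::mutate(base, caller = "mutect"),
    dplyr::mutate(base, caller = "strelka2", tumor_alt_count = 28L))
  m <- merge_caller_calls(calls, min_coverage = 10)
  expect_equal(nrow(m), 1L)
  expect_equal(m$callers, "mutect,strelka2")
  # read counts come from the priority caller (strelka2 > mutect)
  expect_equal(m$tumor_alt_count, 28L)
  expect_equal(m$count_source, "strelka2")
  # coverage gate drops depth 9 in either sample
  low <- dplyr::mutate(base, caller = "mutect", tumor_depth = 9L,
                       tumor_alt_count = 5L)
  expect_equal(nrow(merge_caller_calls(low, min_coverage = 10)), 0L)
  low_n <- dplyr::mutate(base, caller = "mutect", normal_depth = 9L)
  expect_equal(nrow(merge_caller_calls(low_n, min_coverage = 10)), 0L)
  expect_error(merge_caller_calls(
    dplyr::bind_rows(dplyr::mutate(base, caller = "mutect"),
                     dplyr::mutate(base, caller = "mutect",
                                   patient_id = "P02"))), "single patient")
})

test_that("merging matches brute-force key union and respects union bounds", {
  set.seed(7)
  mk_calls <- function(caller, positions) {
    tibble::tibble(
      patient_id = "P01", caller = caller, chrom = "chr1",
      pos = positions, ref = "A", alt = "G",
      tumor_depth = 100L, tumor_alt_count = 20L,
      normal_depth = 100L, normal_alt_count = 0L, filter_status = "PASS")
  }
  shared <- sample(1000:2000, 4)
  sets <- list(mutect = c(shared, sample(3000:4000, 1)),
               mutect2 = c(shared, sample(5000:6000, 2)),
               strelka2 = c(shared, sample(7000:8000, 3)))
  calls <- dplyr::bind_rows(mapply(mk_calls, names(sets), sets,
                                   SIMPLIFY = FALSE))
  m <- merge_caller_calls(calls)
  expect_equal(nrow(m), length(Reduce(union, sets)))  # brute-force union
  per_caller <- lengths(sets)
  expect_gte(nrow(m), max(per_caller))
  expect_lte(nrow(m), sum(per_caller))
  # callers sets are subsets of input callers
  expect_true(all(unlist(strsplit(m$callers, ",")) %in% names(sets)))
  # idempotence: re-merging the merged output changes nothing
  again <- tidyr::separate_rows(m, "callers", sep = ",") |>
    dplyr::rename(caller = "callers") |>
    dplyr::mutate(filter_status = "PASS")
  m2 <- merge_caller_calls(again)
  expect_equal(m2[, c("chrom", "pos", "ref", "alt", "callers")],
               m[, c("chrom", "pos", "ref", "alt", "callers")])
  # intersection mode keeps only the shared keys
  mi <- merge_caller_calls(calls, mode = "intersection")
  expect_equal(sort(mi$pos), sort(shared))
})

test_that("equivalent indel spellings from different callers merge to one variant", {
  mk <- function(caller, pos, ref, alt) {
    tibble::tibble(patient_id = "P01", caller = caller, chrom = "chr1",
                   pos = pos, ref = ref, alt = alt,
                   tumor_depth = 100L, tumor_alt_count = 25L,
                   normal_depth = 100L, normal_alt_count = 0L,
                   filter_status = "PASS")
  }
  calls <- dplyr::bind_rows(mk("mutect2", 100L, "CT", "C"),
                            mk("strelka2", 100L, "CTT", "CT"))
  m <- merge_caller_calls(calls)
  expect_equal(nrow(m), 1L)
  expect_equal(m$ref, "CT")
  expect_equal(m$alt, "C")
  expect_equal(m$callers, "mutect2,strelka2")
  expect_equal(m$variant_class, "indel")
})

test_that("merged variants round-trip through the TSV interchange format", {
  b <- simulate_cohort(simulation_config(n_patients = 2, seed = 3))
  m <- cohort_from_calls(b$calls)
  f <- tempfile(fileext = ".tsv")
  write_variants(m, f)
  back <- read_variants(f)
  expect_equal(as.data.frame(back), as.data.frame(m))
})
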