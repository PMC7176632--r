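#' @importFrom rlang .data
NULL

CALLERS <- c("mutect", "mutect2", "strelka2")

#' Compute a variant allele frequency
#'
#' VAF is the fraction of reads at a site supporting the alternate allele,
#' the standard proxy for the clonal fraction of a somatic mutation in a
#' purified tumor sample.
#'
#' @param alt_count Integer vector of alternate-supporting read counts.
#' @param depth Integer vector of total read depths at the site.
#' @return Numeric vector of fractions in `[0, 1]`; 0 where `depth == 0`.
#' @examples
#' compute_vaf(38, 100)
#' @export
compute_vaf <- function(alt_count, depth) {
  if (any(alt_count < 0 | depth < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  if (any(alt_count > depth, na.rm = TRUE)) {
    stop("alt_count exceeds depth: invariant violation")
  }
  ifelse(depth == 0, 0, alt_count / depth)
}

#' Normalize a variant representation
#'
#' Reduces each (pos, ref, alt) to the parsimonious left-aligned form used
#' as the merge key across callers: the shared allele suffix is trimmed
#' first, then the shared prefix (advancing `pos`), always keeping at least
#' one base in both alleles. SNVs and MNVs without shared bases are returned
#' unchanged. Callers emit indels in different but equivalent spellings;
#' without this step identical indels would fail to merge.
#'
#' @param chrom,pos,ref,alt Vectors describing variants (1-based `pos`).
#' @return A tibble with normalized `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("chr1", 100, "CTT", "CT")
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(ref == alt)) stop("ref and alt must differ")
  pos <- as.integer(pos)
  for (i in seq_along(ref)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    # trim shared suffix
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # trim shared prefix, advancing the coordinate
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Read somatic calls from a caller-specific tumor-normal VCF
#'
#' Parses a VCF 4.x with one tumor and one normal sample column and returns
#' one call per (record x alternate allele). Read-count evidence is
#' extracted per caller dialect:
#' * `mutect`, `mutect2`: per-sample allelic depths (`AD`); depth is the sum
#'   over alleles, alt count the entry for the split allele.
#' * `strelka2` SNVs: tier-1 per-base counts (`AU`/`CU`/`GU`/`TU`); depth is
#'   the tier-1 sum over the four bases.
#' * `strelka2` indels: tier-1 ref- and indel-supporting counts
#'   (`TAR`/`TIR`); depth is their sum.
#'
#' @param path Path to a plain or bgzipped VCF.
#' @param caller One of `"mutect"`, `"mutect2"`, `"strelka2"`.
#' @param patient_id Identifier attached to every call.
#' @param tumor_sample,normal_sample Sample column names in the VCF.
#' @param pass_only Drop records whose FILTER is not PASS/`.` (default TRUE).
#' @return A tibble of calls: `patient_id`, `caller`, `chrom`, `pos`, `ref`,
#'   `alt`, `tumor_depth`, `tumor_alt_count`, `normal_depth`,
#'   `normal_alt_count`, `filter_status`.
#' @export
parse_caller_vcf <- function(path, caller, patient_id,
                             tumor_sample = "TUMOR", normal_sample = "NORMAL",
                             pass_only = TRUE) {
  caller <- match.arg(caller, CALLERS)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- tibble::tibble(
    patient_id = character(), caller = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    tumor_depth = integer(), tumor_alt_count = integer(),
    normal_depth = integer(), normal_alt_count = integer(),
    filter_status = character()
  )
  if (nrow(vcf@fix) == 0L) return(empty)
  gt <- vcf@gt
  samples <- colnames(gt)[-1L]
  if (!all(c(tumor_sample, normal_sample) %in% samples)) {
    stop(sprintf("VCF '%s' lacks tumor/normal sample columns '%s'/'%s' (found: %s)",
                 path, tumor_sample, normal_sample, paste(samples, collapse = ", ")))
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(fix))
  if (pass_only) keep <- fix$FILTER %in% c("PASS", ".") | is.na(fix$FILTER)
  if (!any(keep)) return(empty)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    tum <- strsplit(gt[i, tumor_sample], ":", fixed = TRUE)[[1]]
    nor <- strsplit(gt[i, normal_sample], ":", fixed = TRUE)[[1]]
    names(tum) <- fmt[seq_along(tum)]
    names(nor) <- fmt[seq_along(nor)]
    per_alt <- lapply(seq_along(alts), function(k) {
      tc <- .extract_counts(caller, fix$REF[i], alts[k], k, tum)
      nc <- .extract_counts(caller, fix$REF[i], alts[k], k, nor)
      tibble::tibble(
        patient_id = patient_id, caller = caller,
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        tumor_depth = tc$depth, tumor_alt_count = tc$alt,
        normal_depth = nc$depth, normal_alt_count = nc$alt,
        filter_status = ifelse(is.na(fix$FILTER[i]), ".", fix$FILTER[i])
      )
    })
    rows[[i]] <- dplyr::bind_rows(per_alt)
  }
  dplyr::bind_rows(rows)
}

# Dialect-specific read-count extraction for one sample of one record.
.extract_counts <- function(caller, ref, alt, alt_index, fields) {
  int1 <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]][1L])
  if (caller %in% c("mutect", "mutect2")) {
    ad <- as.integer(strsplit(fields[["AD"]], ",", fixed = TRUE)[[1]])
    return(list(depth = sum(ad), alt = ad[alt_index + 1L]))
  }
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  if (is_snv) {
    bases <- c(A = "AU", C = "CU", G = "GU", T = "TU")
    counts <- vapply(bases, function(f) int1(fields[[f]]), integer(1))
    return(list(depth = sum(counts), alt = unname(counts[alt])))
  }
  tar <- int1(fields[["TAR"]])
  tir <- int1(fields[["TIR"]])
  list(depth = tar + tir, alt = tir)
}

#' Merge per-caller somatic calls into a consensus variant set
#'
#' Calls from up to three callers are keyed by the normalized
#' (chrom, pos, ref, alt) and combined by UNION: a variant is kept when any
#' caller reports it, which maximizes discovery power for low-VAF somatic
#' events. Tumor read counts are taken from the highest-priority caller
#' reporting the variant (`mutect2 > strelka2 > mutect` by default, the
#' order of completeness of allelic-depth reporting). Variants whose
#' recorded tumor or normal depth falls below `min_coverage` are dropped.
#'
#' @param calls Tibble of calls from [parse_caller_vcf()], one patient.
#' @param min_coverage Minimum read depth required in both tumor and normal
#'   (default 10).
#' @param mode `"union"` (default) keeps variants seen by any caller;
#'   `"intersection"` requires all callers present in `calls`.
#' @param priority Caller order used to pick the recorded read counts.
#' @return A tibble of merged somatic variants: `patient_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `variant_class` (`snp`/`indel`), `callers`
#'   (comma-joined), `tumor_depth`, `tumor_alt_count`, `normal_depth`,
#'   `normal_alt_count`, `vaf`, `count_source`.
#' @export
merge_caller_calls <- function(calls, min_coverage = 10,
                               mode = c("union", "intersection"),
                               priority = c("mutect2", "strelka2", "mutect")) {
  mode <- match.arg(mode)
  if (nrow(calls) == 0L) return(.empty_variants())
  if (length(unique(calls$patient_id)) > 1L) {
    stop("merge_caller_calls expects calls from a single patient; got: ",
         paste(unique(calls$patient_id), collapse = ", "))
  }
  norm <- normalize_variant(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls <- dplyr::mutate(calls,
    chrom = norm$chrom, pos = norm$pos, ref = norm$ref, alt = norm$alt,
    .rank = match(.data$caller, priority)
  )
  n_callers_in <- length(unique(calls$caller))
  merged <- calls |>
    dplyr::group_by(.data$patient_id, .data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::arrange(.data$.rank, .by_group = TRUE) |>
    dplyr::summarise(
      callers = paste(sort(unique(.data$caller)), collapse = ","),
      n_callers = length(unique(.data$caller)),
      tumor_depth = .data$tumor_depth[1L],
      tumor_alt_count = .data$tumor_alt_count[1L],
      normal_depth = .data$normal_depth[1L],
      normal_alt_count = .data$normal_alt_count[1L],
      count_source = .data$caller[1L],
      .groups = "drop"
    )
  if (mode == "intersection") {
    merged <- dplyr::filter(merged, .data$n_callers == n_callers_in)
  }
  merged |>
    dplyr::filter(.data$tumor_depth >= min_coverage,
                  .data$normal_depth >= min_coverage) |>
    dplyr::mutate(
      variant_class = ifelse(nchar(.data$ref) == 1L & nchar(.data$alt) == 1L,
                             "snp", "indel"),
      vaf = compute_vaf(.data$tumor_alt_count, .data$tumor_depth)
    ) |>
    dplyr::select("patient_id", "chrom", "pos", "ref", "alt", "variant_class",
                  "callers", "tumor_depth", "tumor_alt_count",
                  "normal_depth", "normal_alt_count", "vaf", "count_source") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
}

.empty_variants <- function() {
  tibble::tibble(
    patient_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), variant_class = character(),
    callers = character(), tumor_depth = integer(), tumor_alt_count = integer(),
    normal_depth = integer(), normal_alt_count = integer(),
    vaf = numeric(), count_source = character()
  )
}

#' Write / read the merged-variant table
#'
#' Plain TSV round-trip of the merged variant set, the interchange format
#' between the merging and filtering stages.
#'
#' @param variants Tibble from [merge_caller_calls()] (possibly annotated).
#' @param path Output TSV path.
#' @return `write_variants` returns `path` invisibly; `read_variants`
#'   returns the tibble.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "", colClasses = NA)
  df$pos <- as.integer(df$pos)
  tibble::as_tibble(df)
}
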