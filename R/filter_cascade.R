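#' Filter-cascade configuration
#'
#' Bundles every threshold of the variant prioritization cascade. Defaults
#' follow the study design: coverage gate at 10 reads, population allele
#' frequency cut at 5% (strictly greater is discarded), retention of
#' variants with VAF >= 0.05, prominence at VAF >= 0.1, and Sanger
#' validation eligibility at VAF >= 0.2 (below that, ARMS PCR).
#'
#' @param min_coverage Minimum tumor and normal depth (reads).
#' @param max_pop_af Population allele frequency above which a variant is
#'   discarded as a likely germline polymorphism.
#' @param retain_vaf Minimum VAF for a variant to be retained for analysis.
#' @param prominent_vaf Minimum VAF for the prominent tier (radar plots).
#' @param sanger_vaf Minimum VAF at which Sanger sequencing can validate a
#'   variant; lower VAFs require allele-specific ARMS PCR.
#' @param population_by_patient Named character vector mapping patient id to
#'   the gnomAD-style population key used for that patient (e.g. `"nfe"`
#'   for non-Finnish European, `"fin"` for Finnish).
#' @param metasvm_missing_passes Should variants without a MetaSVM label
#'   (frameshift, splice, stop-gain classes have no missense score) pass the
#'   deleteriousness filter? Default TRUE; FALSE gives the strict reading.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_coverage = 10, max_pop_af = 0.05,
                          retain_vaf = 0.05, prominent_vaf = 0.1,
                          sanger_vaf = 0.2,
                          population_by_patient = character(),
                          metasvm_missing_passes = TRUE) {
  stopifnot(retain_vaf > 0, retain_vaf <= prominent_vaf,
            prominent_vaf <= sanger_vaf, sanger_vaf <= 1,
            max_pop_af >= 0, max_pop_af <= 1, min_coverage >= 0)
  structure(
    list(min_coverage = min_coverage, max_pop_af = max_pop_af,
         retain_vaf = retain_vaf, prominent_vaf = prominent_vaf,
         sanger_vaf = sanger_vaf,
         population_by_patient = population_by_patient,
         metasvm_missing_passes = metasvm_missing_passes),
    class = "filter_config"
  )
}

#' Read an annotation table and attach it to merged variants
#'
#' The annotation TSV carries one row per variant key with columns
#' `chrom, pos, ref, alt, gene, consequence, snpeff_impact, metasvm,
#' af_nfe, af_fin, clinvar, dbsnp_id, cosmic_id, hgvs_c, hgvs_p`
#' (empty cell = missing). dbSNP/COSMIC identifiers are carried along as
#' annotations only; being "known" never by itself discards a variant.
#'
#' @param path Annotation TSV path.
#' @return Tibble of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "")
  df$pos <- as.integer(df$pos)
  tibble::as_tibble(df)
}

#' @param variants Merged variant tibble.
#' @param annotations Annotation tibble from [read_annotations()].
#' @rdname read_annotations
#' @export
annotate_variants <- function(variants, annotations) {
  dplyr::left_join(variants, annotations,
                   by = c("chrom", "pos", "ref", "alt"))
}

#' Cascade predicates
#'
#' Each predicate is a stateless keep/drop rule evaluated per variant; the
#' cascade applies them in order but the final retained set is
#' order-independent.
#'
#' * `population_filter`: drop when the allele frequency in the patient's
#'   reference population is known and strictly exceeds `max_pop_af`;
#'   an unobserved frequency means a novel variant and is kept.
#' * `clinvar_filter`: drop unambiguous `benign` / `likely_benign` classes;
#'   conflicting or absent classifications are kept.
#' * `deleteriousness_filter`: keep predicted-impact HIGH or MODERATE
#'   variants that MetaSVM labels deleterious; variants without a MetaSVM
#'   score (non-missense classes) pass unless `missing_passes = FALSE`.
#'
#' @param pop_af Numeric vector of population allele frequencies (NA =
#'   unobserved).
#' @param max_pop_af Discard threshold (strict inequality).
#' @return Logical vector: TRUE = keep.
#' @export
population_filter <- function(pop_af, max_pop_af = 0.05) {
  is.na(pop_af) | pop_af <= max_pop_af
}

#' @param clinvar Character vector of ClinVar classes (`benign`,
#'   `likely_benign`, `other`, `unannotated` or NA).
#' @rdname population_filter
#' @export
clinvar_filter <- function(clinvar) {
  !(clinvar %in% c("benign", "likely_benign"))
}

#' @param snpeff_impact Character vector of predicted impact classes.
#' @param metasvm Character vector of MetaSVM labels (`deleterious`,
#'   `tolerated`, `missing` or NA).
#' @param missing_passes Pass-through rule for score-less variants.
#' @rdname population_filter
#' @export
deleteriousness_filter <- function(snpeff_impact, metasvm,
                                   missing_passes = TRUE) {
  metasvm_ok <- metasvm %in% "deleterious" |
    (missing_passes & (is.na(metasvm) | metasvm %in% "missing"))
  snpeff_impact %in% c("HIGH", "MODERATE") & metasvm_ok
}

#' Assign VAF tiers
#'
#' Tiers partition the VAF axis: `subclonal` below the retention threshold,
#' `retained` in `[retain_vaf, prominent_vaf)`, `prominent` at or above
#' `prominent_vaf`. A separate flag marks variants whose VAF is high enough
#' for Sanger validation.
#'
#' @param vaf Numeric vector of VAFs in `[0, 1]`.
#' @param config A [filter_config()].
#' @return Tibble with columns `tier` (factor subclonal/retained/prominent)
#'   and `sanger_eligible` (logical).
#' @export
vaf_tier <- function(vaf, config = filter_config()) {
  stopifnot(all(vaf >= 0 & vaf <= 1))
  tier <- dplyr::case_when(
    vaf < config$retain_vaf ~ "subclonal",
    vaf < config$prominent_vaf ~ "retained",
    TRUE ~ "prominent"
  )
  tibble::tibble(
    tier = factor(tier, levels = c("subclonal", "retained", "prominent")),
    sanger_eligible = vaf >= config$sanger_vaf
  )
}

CASCADE_STAGES <- c("population_af", "clinvar_benign", "deleteriousness",
                    "vaf_threshold")

#' Run the ordered filter cascade
#'
#' Applies, in order: population-frequency filter, ClinVar benign filter,
#' deleteriousness filter, and the VAF retention threshold. Every variant
#' is attributed to the first stage it fails; the funnel report accounts
#' for each stage per patient and cohort-wide.
#'
#' @param variants Annotated merged variant tibble (see
#'   [annotate_variants()]).
#' @param config A [filter_config()]; `population_by_patient` must cover
#'   every patient present.
#' @return A list with `retained` (variants passing all stages, with `tier`
#'   and `sanger_eligible` columns), `deleterious` (variants passing the
#'   three annotation filters regardless of VAF — the set cohort-level VAF
#'   distributions are described on), and `funnel` (tibble `scope`,
#'   `stage`, `n_in`, `n_dropped`, `n_out`).
#' @export
run_cascade <- function(variants, config = filter_config()) {
  if (nrow(variants) == 0L) {
    funnel <- tibble::tibble(scope = "cohort", stage = CASCADE_STAGES,
                             n_in = 0L, n_dropped = 0L, n_out = 0L)
    retained <- dplyr::bind_cols(variants, vaf_tier(numeric(0), config))
    return(list(retained = retained, deleterious = retained, funnel = funnel))
  }
  if (!"gene" %in% names(variants) || anyNA(variants$gene)) {
    bad <- if ("gene" %in% names(variants)) {
      v <- variants[is.na(variants$gene), ]
      paste(v$chrom, v$pos, v$ref, v$alt, sep = ":", collapse = "; ")
    } else "all (no annotation columns)"
    stop("unannotated variants reached the cascade: ", bad)
  }
  pats <- unique(variants$patient_id)
  missing_pop <- setdiff(pats, names(config$population_by_patient))
  if (length(missing_pop) > 0L) {
    stop("no population key configured for patient(s): ",
         paste(missing_pop, collapse = ", "))
  }
  pop_key <- config$population_by_patient[variants$patient_id]
  af_col <- paste0("af_", pop_key)
  missing_col <- setdiff(unique(af_col), names(variants))
  if (length(missing_col) > 0L) {
    stop("annotation table lacks population AF column(s): ",
         paste(missing_col, collapse = ", "))
  }
  pop_af <- vapply(seq_len(nrow(variants)),
                   function(i) as.numeric(variants[[af_col[i]]][i]),
                   numeric(1))
  keep <- cbind(
    population_af   = population_filter(pop_af, config$max_pop_af),
    clinvar_benign  = clinvar_filter(variants$clinvar),
    deleteriousness = deleteriousness_filter(variants$snpeff_impact,
                                             variants$metasvm,
                                             config$metasvm_missing_passes),
    vaf_threshold   = variants$vaf >= config$retain_vaf
  )
  # first failing stage (NA = passes all)
  first_fail <- apply(keep, 1L, function(k) {
    w <- which(!k)
    if (length(w) == 0L) NA_integer_ else w[1L]
  })
  funnel_for <- function(idx, scope) {
    n_in <- length(idx)
    out <- vector("list", length(CASCADE_STAGES))
    for (s in seq_along(CASCADE_STAGES)) {
      n_dropped <- sum(first_fail[idx] %in% s)
      out[[s]] <- tibble::tibble(scope = scope, stage = CASCADE_STAGES[s],
                                 n_in = n_in, n_dropped = n_dropped,
                                 n_out = n_in - n_dropped)
      n_in <- n_in - n_dropped
    }
    dplyr::bind_rows(out)
  }
  funnel <- dplyr::bind_rows(
    funnel_for(seq_len(nrow(variants)), "cohort"),
    dplyr::bind_rows(lapply(pats, function(p) {
      funnel_for(which(variants$patient_id == p), p)
    }))
  )
  pass <- is.na(first_fail)
  retained <- variants[pass, , drop = FALSE]
  retained <- dplyr::bind_cols(retained, vaf_tier(retained$vaf, config))
  pre_vaf <- is.na(first_fail) | first_fail == match("vaf_threshold",
                                                     CASCADE_STAGES)
  deleterious <- variants[pre_vaf, , drop = FALSE]
  deleterious <- dplyr::bind_cols(deleterious,
                                  vaf_tier(deleterious$vaf, config))
  list(retained = retained, deleterious = deleterious, funnel = funnel)
}
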