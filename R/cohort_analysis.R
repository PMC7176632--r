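#' Gene recurrence across patients
#'
#' A gene's recurrence is counted at the patient level: each patient
#' contributes at most once per gene regardless of how many distinct
#' variants of that gene it carries. Genes mutated in at least two patients
#' form the recurrent subset.
#'
#' @param variants Tibble with `gene`, `patient_id`, `vaf` columns
#'   (typically the retained set from [run_cascade()]).
#' @return List with `genes` (tibble `gene`, `n_patients`, `max_vaf`,
#'   `recurrent`) and `per_patient` (tibble `gene`, `patient_id`,
#'   `max_vaf`).
#' @export
recurrence_table <- function(variants) {
  per_patient <- variants |>
    dplyr::group_by(.data$gene, .data$patient_id) |>
    dplyr::summarise(max_vaf = max(.data$vaf), .groups = "drop")
  genes <- per_patient |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_patients = dplyr::n(), max_vaf = max(.data$max_vaf),
                     .groups = "drop") |>
    dplyr::mutate(recurrent = .data$n_patients >= 2L) |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$gene)
  list(genes = genes, per_patient = per_patient)
}

#' Test VAF heterogeneity across patients
#'
#' Kruskal-Wallis rank-sum test of whether the VAF distribution differs
#' between patients, with the standard tie correction. When every
#' observation is identical there is no rank variation; the statistic is
#' defined as 0 with a degenerate flag rather than NaN.
#'
#' @param vaf Numeric vector of VAFs.
#' @param group Grouping vector (patient ids), same length as `vaf`.
#' @return List: `statistic` (H), `p_value`, `method`, `n_groups`, `n_obs`,
#'   `degenerate`.
#' @export
vaf_heterogeneity_test <- function(vaf, group) {
  stopifnot(length(vaf) == length(group))
  group <- as.character(group)
  n_groups <- length(unique(group))
  if (n_groups < 2L) stop("need at least 2 non-empty groups")
  if (length(unique(vaf)) == 1L) {
    return(list(statistic = 0, p_value = 1,
                method = "Kruskal-Wallis rank sum test (degenerate: all tied)",
                n_groups = n_groups, n_obs = length(vaf), degenerate = TRUE))
  }
  kt <- stats::kruskal.test(vaf, factor(group))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       method = kt$method, n_groups = n_groups, n_obs = length(vaf),
       degenerate = FALSE)
}

#' Check for a coverage-driven mutation-burden artifact
#'
#' Rank (Spearman) correlation between per-patient somatic variant counts
#' and mean sequencing coverage. A significant correlation would indicate
#' that apparent mutational burden tracks sequencing depth rather than
#' biology; the convenience flag reports "no significant correlation" at
#' the chosen alpha. Constant inputs make the rank correlation undefined;
#' the statistic is reported as 0 with a degenerate flag.
#'
#' @param counts Integer vector of per-patient variant counts.
#' @param coverages Numeric vector of per-patient mean coverages.
#' @param sample Which sample the coverages describe (`tumor`/`normal`).
#' @param alpha Significance level for the convenience flag.
#' @return List: `estimate` (rho), `p_value`, `method`, `n`, `sample`,
#'   `significant`, `degenerate`.
#' @export
coverage_burden_correlation <- function(counts, coverages,
                                        sample = c("tumor", "normal"),
                                        alpha = 0.05) {
  sample <- match.arg(sample)
  stopifnot(length(counts) == length(coverages))
  if (length(counts) < 3L) stop("need at least 3 patients")
  if (stats::sd(counts) == 0 || stats::sd(coverages) == 0) {
    return(list(estimate = 0, p_value = NA_real_,
                method = "Spearman rank correlation (degenerate: constant input)",
                n = length(counts), sample = sample,
                significant = FALSE, degenerate = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(counts, coverages, method = "spearman",
                    alternative = "two.sided", exact = FALSE)
  )
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = ct$method, n = length(counts), sample = sample,
       significant = ct$p.value < alpha, degenerate = FALSE)
}

#' Read hotspot region definitions
#'
#' Hotspot coordinates are genome-build-dependent configuration, supplied
#' as JSON: `[{gene, chrom, intervals: [[start, end], ...], label}]` with
#' 1-based closed intervals.
#'
#' @param path Hotspot JSON path.
#' @return Tibble with one row per interval: `gene`, `chrom`, `start`,
#'   `end`, `label`.
#' @export
read_hotspots <- function(path) {
  regions <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  dplyr::bind_rows(lapply(regions, function(r) {
    iv <- do.call(rbind, lapply(r$intervals, unlist))
    tibble::tibble(gene = r$gene, chrom = r$chrom,
                   start = as.integer(iv[, 1]), end = as.integer(iv[, 2]),
                   label = r$label)
  }))
}

#' Screen variants against hotspot regions
#'
#' A variant hits a region iff it lies on the same chromosome and its
#' position falls within any of the region's closed intervals. The result
#' is invariant under input ordering.
#'
#' @param variants Tibble with `patient_id`, `chrom`, `pos` (and optionally
#'   `hgvs_p`).
#' @param regions Hotspot tibble from [read_hotspots()].
#' @return Tibble of hits: `patient_id`, `gene`, `hgvs_p`, `label`,
#'   `chrom`, `pos`.
#' @export
hotspot_screen <- function(variants, regions) {
  hgvs <- if ("hgvs_p" %in% names(variants)) variants$hgvs_p
          else rep(NA_character_, nrow(variants))
  hits <- lapply(seq_len(nrow(regions)), function(j) {
    in_region <- variants$chrom == regions$chrom[j] &
      variants$pos >= regions$start[j] & variants$pos <= regions$end[j]
    if (!any(in_region)) return(NULL)
    tibble::tibble(patient_id = variants$patient_id[in_region],
                   gene = regions$gene[j], hgvs_p = hgvs[in_region],
                   label = regions$label[j],
                   chrom = variants$chrom[in_region],
                   pos = variants$pos[in_region])
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(patient_id = character(), gene = character(),
                          hgvs_p = character(), label = character(),
                          chrom = character(), pos = integer()))
  }
  dplyr::arrange(dplyr::distinct(out), .data$patient_id, .data$gene, .data$pos)
}

#' Screening prevalence
#'
#' Fraction of the cohort with at least one hit, reported also as an
#' integer percentage rounded half-up (5/57 -> 9%, 2/13 -> 15%).
#'
#' @param hits Logical vector of per-patient hit flags, or a single integer
#'   count of patients with hits.
#' @param cohort_size Number of patients screened.
#' @return List: `n_hit`, `n`, `fraction`, `percent`.
#' @export
screen_prevalence <- function(hits, cohort_size) {
  if (cohort_size < 1L) stop("cohort size must be at least 1")
  n_hit <- if (is.logical(hits)) sum(hits) else as.integer(hits)
  stopifnot(n_hit >= 0L, n_hit <= cohort_size)
  fraction <- n_hit / cohort_size
  list(n_hit = n_hit, n = cohort_size, fraction = fraction,
       percent = as.integer(floor(fraction * 100 + 0.5)))
}

#' Per-patient mutation profiles and radar table
#'
#' Summarizes, per patient, the variant count in each VAF tier and the
#' prominent genes (VAF >= `prominent_vaf`) with their maximum VAF, the
#' data behind per-patient radar displays. Patients with no prominent
#' variants still appear in the profile table with an empty radar entry.
#'
#' @param variants Tiered variant tibble (columns `patient_id`, `gene`,
#'   `vaf`, `tier`).
#' @param coverages Optional tibble `patient_id`, `mean_tumor_coverage`,
#'   `mean_normal_coverage`.
#' @param config A [filter_config()] (supplies the prominence threshold
#'   when `tier` is absent).
#' @return List with `profiles` (per-patient tier counts and coverages) and
#'   `radar` (tibble `patient_id`, `gene`, `max_vaf`, sorted by VAF
#'   descending then gene).
#' @export
build_patient_profiles <- function(variants, coverages = NULL,
                                   config = filter_config()) {
  if (!"tier" %in% names(variants)) {
    variants <- dplyr::bind_cols(variants, vaf_tier(variants$vaf, config))
  }
  profiles <- variants |>
    dplyr::count(.data$patient_id, .data$tier, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "tier", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  radar <- variants |>
    dplyr::filter(.data$tier == "prominent") |>
    dplyr::group_by(.data$patient_id, .data$gene) |>
    dplyr::summarise(max_vaf = max(.data$vaf), .groups = "drop") |>
    dplyr::arrange(.data$patient_id, dplyr::desc(.data$max_vaf), .data$gene)
  if (!is.null(coverages)) {
    profiles <- dplyr::left_join(profiles, coverages, by = "patient_id")
  }
  list(profiles = profiles, radar = radar)
}
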