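#' Default driver-score weights
#'
#' Weights over the five evidence components: maximum VAF, predicted
#' impact, expression, recurrence, and an external driver-prediction label.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_driver_weights <- function() {
  c(vaf = 0.30, impact = 0.20, expression = 0.15,
    recurrence = 0.15, external = 0.20)
}

#' Score the putative driver role of a mutated gene
#'
#' A weighted combination, in `[0, 1]`, of the evidence lines used to judge
#' driver roles: mutation VAF (saturating at 0.5, a fully clonal
#' heterozygous variant), predicted impact (HIGH = 1, MODERATE = 0.6),
#' expression in the tumor lineage, patient-level recurrence, and an
#' external driver-prediction label (driver = 1, unknown = 0.5,
#' passenger = 0). The functional form and default weights are this
#' package's own construction — the underlying study judged driver roles
#' qualitatively from the same evidence — and are fully configurable.
#' The score is deterministic and monotone non-decreasing in `max_vaf`.
#'
#' @param max_vaf Numeric vector of per-gene maximum VAFs in `[0, 1]`.
#' @param impact_class `"HIGH"` or `"MODERATE"` (LOW/MODIFIER never reach
#'   scoring: the cascade removes them).
#' @param expressed Logical: normalized expression at/above threshold.
#' @param recurrent Logical: mutated in >= 2 patients.
#' @param external_label `"driver"`, `"passenger"` or `"unknown"`.
#' @param weights Named non-negative weights (`vaf`, `impact`,
#'   `expression`, `recurrence`, `external`) summing to 1.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
driver_score <- function(max_vaf, impact_class, expressed, recurrent,
                         external_label = "unknown",
                         weights = default_driver_weights()) {
  req <- c("vaf", "impact", "expression", "recurrence", "external")
  stopifnot(all(req %in% names(weights)), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("driver-score weights must sum to 1 (got ", sum(weights), ")")
  }
  stopifnot(all(max_vaf >= 0 & max_vaf <= 1),
            all(impact_class %in% c("HIGH", "MODERATE")),
            all(external_label %in% c("driver", "passenger", "unknown")))
  vaf_part <- pmin(max_vaf / 0.5, 1)
  imp_part <- ifelse(impact_class == "HIGH", 1, 0.6)
  ext_part <- c(driver = 1, unknown = 0.5, passenger = 0)[external_label]
  unname(weights[["vaf"]] * vaf_part +
         weights[["impact"]] * imp_part +
         weights[["expression"]] * as.numeric(expressed) +
         weights[["recurrence"]] * as.numeric(recurrent) +
         weights[["external"]] * ext_part)
}

#' Assign the validation method for a variant
#'
#' Sanger sequencing resolves variants with VAF at or above `sanger_vaf`
#' (default 0.2, inclusive); lower-VAF variants require allele-specific
#' ARMS PCR.
#'
#' @param vaf Numeric vector of VAFs in `[0, 1]`.
#' @param sanger_vaf Sanger eligibility threshold.
#' @return Character vector, `"sanger"` or `"arms_pcr"`.
#' @export
validation_assignment <- function(vaf, sanger_vaf = 0.2) {
  stopifnot(all(vaf >= 0 & vaf <= 1))
  ifelse(vaf >= sanger_vaf, "sanger", "arms_pcr")
}

#' Flag genes with approved drug interactions
#'
#' Looks mutated genes up in a drug-gene interaction table and reports only
#' approved drugs; genes without any approved interaction map to empty
#' vectors.
#'
#' @param genes Character vector of gene symbols.
#' @param interactions Tibble with columns `gene`, `drug`, `approved`
#'   (logical).
#' @return Named list mapping each gene to a character vector of approved
#'   drugs.
#' @export
drug_target_flag <- function(genes, interactions) {
  out <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    hit <- interactions$gene == g & interactions$approved
    out[[g]] <- sort(unique(interactions$drug[hit]))
  }
  out
}

#' Read driver labels and drug interactions
#'
#' `read_driver_labels()`: TSV `gene`, `label` in
#' {driver, passenger, unknown} — an export from an external
#' driver-prediction service. `read_drug_interactions()`: TSV `gene`,
#' `drug`, `approved` (true/false).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_driver_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(df$label %in% c("driver", "passenger", "unknown")))
  tibble::as_tibble(df[, c("gene", "label")])
}

#' @rdname read_driver_labels
#' @export
read_drug_interactions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  df$approved <- as.logical(df$approved)
  tibble::as_tibble(df[, c("gene", "drug", "approved")])
}

#' Score every gene in a retained variant set
#'
#' Convenience wrapper assembling per-gene evidence (max VAF, best impact,
#' expression, recurrence, external label) from the retained variants and
#' the auxiliary tables, then applying [driver_score()].
#'
#' @param retained Tiered retained-variant tibble (needs `gene`,
#'   `patient_id`, `vaf`, `snpeff_impact`).
#' @param expression Tibble `gene`, `nx_value`.
#' @param labels Tibble `gene`, `label` (missing genes -> `unknown`).
#' @param expression_threshold Expression cut for the `expressed` flag.
#' @param weights Passed to [driver_score()].
#' @return Tibble `gene`, `max_vaf`, `impact_class`, `expressed`,
#'   `recurrent`, `external_label`, `driver_score`, sorted by score.
#' @export
score_genes <- function(retained, expression = NULL, labels = NULL,
                        expression_threshold = 1,
                        weights = default_driver_weights()) {
  rec <- recurrence_table(retained)$genes
  ev <- retained |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      max_vaf = max(.data$vaf),
      impact_class = ifelse(any(.data$snpeff_impact == "HIGH"),
                            "HIGH", "MODERATE"),
      .groups = "drop") |>
    dplyr::left_join(rec[, c("gene", "recurrent")], by = "gene")
  expr <- if (is.null(expression)) rep(TRUE, nrow(ev)) else {
    nx <- stats::setNames(expression$nx_value, expression$gene)
    !is.na(nx[ev$gene]) & nx[ev$gene] >= expression_threshold
  }
  lab <- if (is.null(labels)) rep("unknown", nrow(ev)) else {
    l <- stats::setNames(labels$label, labels$gene)[ev$gene]
    ifelse(is.na(l), "unknown", l)
  }
  ev |>
    dplyr::mutate(
      expressed = unname(expr), external_label = unname(lab),
      driver_score = driver_score(.data$max_vaf, .data$impact_class,
                                  .data$expressed, .data$recurrent,
                                  .data$external_label, weights)) |>
    dplyr::arrange(dplyr::desc(.data$driver_score), .data$gene)
}
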