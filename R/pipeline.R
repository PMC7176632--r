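#' Merge per-caller calls for a whole cohort
#'
#' Splits a multi-patient call table by patient and applies
#' [merge_caller_calls()] to each, returning one merged somatic-variant
#' table for the cohort.
#'
#' @param calls Call tibble (as from [parse_caller_vcf()] or the
#'   simulator's `calls` table) covering one or more patients.
#' @param min_coverage,mode,priority Passed to [merge_caller_calls()].
#' @return Merged variant tibble for all patients.
#' @export
cohort_from_calls <- function(calls, min_coverage = 10, mode = "union",
                              priority = c("mutect2", "strelka2", "mutect")) {
  dplyr::bind_rows(lapply(split(calls, calls$patient_id),
                          merge_caller_calls, min_coverage = min_coverage,
                          mode = mode, priority = priority))
}

#' Read and merge a bundle's VCFs
#'
#' Parses every `vcf/<patient>_<caller>.vcf` under a bundle directory and
#' merges per patient. The caller and patient are taken from the file
#' name, the layout [simulate_cohort()] writes.
#'
#' @param bundle_dir Bundle directory containing a `vcf/` folder.
#' @param min_coverage Coverage gate passed to the merge.
#' @return Merged cohort variant tibble.
#' @export
load_bundle_variants <- function(bundle_dir, min_coverage = 10) {
  files <- list.files(file.path(bundle_dir, "vcf"), pattern = "\\.vcf$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no VCFs found under ", bundle_dir, "/vcf")
  meta <- sub("\\.vcf$", "", basename(files))
  patient <- sub("_(mutect2|mutect|strelka2)$", "", meta)
  caller <- sub("^.*_", "", meta)
  calls <- dplyr::bind_rows(lapply(seq_along(files), function(i) {
    parse_caller_vcf(files[i], caller[i], patient[i])
  }))
  cohort_from_calls(calls, min_coverage = min_coverage)
}

#' Run the full prioritization on a simulated bundle
#'
#' Convenience wrapper chaining merge, annotation and the filter cascade
#' for an in-memory bundle from [simulate_cohort()].
#'
#' @param bundle List from [simulate_cohort()].
#' @param config Optional [filter_config()]; defaults to one built from the
#'   bundle's population assignment.
#' @param from_files Re-read the calls from the written VCFs (requires the
#'   bundle to have been written with `out_dir`) instead of using the
#'   in-memory call table.
#' @return List with `variants` (merged, annotated), `retained`, `funnel`,
#'   `config`.
#' @export
prioritize_bundle <- function(bundle, config = NULL, from_files = FALSE) {
  if (is.null(config)) {
    config <- filter_config(
      population_by_patient = bundle$population_by_patient)
  }
  merged <- if (from_files) {
    load_bundle_variants(dirname(dirname(bundle$paths$vcf[1])),
                         min_coverage = config$min_coverage)
  } else {
    cohort_from_calls(bundle$calls, min_coverage = config$min_coverage)
  }
  annotated <- annotate_variants(merged, bundle$annotations)
  res <- run_cascade(annotated, config)
  list(variants = annotated, retained = res$retained,
       deleterious = res$deleterious, funnel = res$funnel, config = config)
}

#' Build the mutated-gene meta-network for a retained variant set
#'
#' Selects the pathways touching mutated genes, converts each to a gene
#' graph, merges them, overlays PPIs, applies the expression filter and
#' extracts the induced mutated-gene subnetwork.
#'
#' @param retained Retained variant tibble (needs `gene`).
#' @param topologies List of `pathway_topology` objects.
#' @param ppi PPI pair tibble (or NULL).
#' @param expression Expression tibble `gene`, `nx_value` (or NULL to skip
#'   the filter).
#' @param expression_threshold Minimum kept expression.
#' @param max_compound_hops Passed to [topology_to_gene_graph()].
#' @return List: `meta` (the filtered meta-network), `network` (induced
#'   mutated subnetwork), `summary`.
#' @export
build_mutation_network <- function(retained, topologies, ppi = NULL,
                                   expression = NULL,
                                   expression_threshold = 1,
                                   max_compound_hops = 3) {
  mutated <- unique(retained$gene)
  selected <- select_pathways(topologies, mutated)
  fragments <- lapply(selected, topology_to_gene_graph,
                      max_compound_hops = max_compound_hops)
  meta <- merge_networks(fragments)
  meta <- integrate_ppi(meta, ppi)
  if (!is.null(expression)) {
    meta <- expression_filter(meta, expression,
                              threshold = expression_threshold)
  }
  sub <- mutated_subnetwork(meta, mutated)
  list(meta = meta, network = sub$network, summary = sub$summary)
}
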