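#' Simulation configuration for a synthetic CLPD-NK-like cohort
#'
#' Defaults emulate the study design being analyzed: 13 tumor-normal pairs
#' at ~159x/142x mean depth, 13-37 retained (VAF >= 0.05) deleterious
#' variants per patient, 80% of somatic variants below VAF 0.05, clonal
#' drivers at VAF 0.2-0.48, and three somatic callers whose sensitivity is
#' logistic in the tumor alt-read count with per-caller midpoints.
#'
#' @param n_patients Number of tumor-normal pairs.
#' @param mean_tumor_depth,mean_normal_depth Poisson means for per-site
#'   read depth (reads).
#' @param subclonal_fraction Fraction of somatic variants below the
#'   retention VAF threshold.
#' @param retained_per_patient_range Inclusive range the per-patient
#'   retained count is drawn from.
#' @param clonal_vaf_range,prominent_vaf_range,subclonal_vaf_range VAF
#'   bands for clonal drivers, prominent variants and sub-threshold
#'   passengers.
#' @param n_decoy_common,n_decoy_benign,n_decoy_low_impact Per-patient
#'   decoys engineered to fail exactly one cascade stage each (population
#'   AF, ClinVar benign, deleteriousness).
#' @param caller_sensitivity_midpoints Named alt-read counts at which each
#'   caller reaches 50% detection probability.
#' @param sensitivity_scale Logistic scale of the detection curve (reads).
#' @param indel_fraction Fraction of planted somatic variants that are
#'   indels.
#' @param retain_vaf Retention threshold the bands are calibrated against.
#' @param patient_depth_sd Between-patient standard deviation of the mean
#'   depth (centered so the cohort-wide means stay at the configured
#'   values).
#' @param seed Integer seed; a fixed seed makes the bundle byte-identical.
#' @return A `simulation_config` object (list).
#' @export
simulation_config <- function(n_patients = 13,
                              mean_tumor_depth = 159,
                              mean_normal_depth = 142,
                              subclonal_fraction = 0.8,
                              retained_per_patient_range = c(13L, 37L),
                              clonal_vaf_range = c(0.2, 0.48),
                              prominent_vaf_range = c(0.1, 0.2),
                              subclonal_vaf_range = c(0.01, 0.05),
                              n_decoy_common = 2,
                              n_decoy_benign = 2,
                              n_decoy_low_impact = 2,
                              caller_sensitivity_midpoints =
                                c(mutect = 5, mutect2 = 3, strelka2 = 4),
                              sensitivity_scale = 1,
                              indel_fraction = 0.08,
                              retain_vaf = 0.05,
                              patient_depth_sd = 12,
                              seed = 1L) {
  stopifnot(n_patients >= 1,
            subclonal_fraction > 0, subclonal_fraction < 1,
            retained_per_patient_range[1] <= retained_per_patient_range[2],
            clonal_vaf_range[1] <= clonal_vaf_range[2],
            subclonal_vaf_range[1] <= subclonal_vaf_range[2],
            all(CALLERS %in% names(caller_sensitivity_midpoints)))
  structure(as.list(environment()), class = "simulation_config")
}

CONTIGS <- c(chr1 = 500000L, chr2 = 500000L, chr3 = 500000L)
BASES <- c("A", "C", "G", "T")

# deterministic per-patient RNG substream
.patient_seed <- function(seed, i) (as.integer(seed) + 7919L * i) %% 2147483647L

# sample a binomial alt count conditioned on which side of `thr` the
# observed VAF falls; tiers are observed quantities, so band membership is
# enforced on the realized count (bounded retries, then clamped).
.rbinom_band <- function(depth, p, thr, side = c("none", "ge", "lt")) {
  side <- match.arg(side)
  x <- stats::rbinom(1L, depth, p)
  if (side == "none" || depth == 0L) return(x)
  for (try in 1:50) {
    ok <- if (side == "ge") x / depth >= thr else x / depth < thr
    if (ok) return(x)
    x <- stats::rbinom(1L, depth, p)
  }
  if (side == "ge") as.integer(ceiling(thr * depth)) else
    max(as.integer(ceiling(thr * depth)) - 1L, 0L)
}

.random_hgvs <- function(n) {
  list(c = sprintf("c.%dA>G", sample(100:9999, n, replace = TRUE)),
       p = sprintf("p.Ala%dGly", sample(10:999, n, replace = TRUE)))
}

# Cohort-level design: per-patient retained counts, subclonal mixture
# multipliers (centered so the cohort subclonal fraction matches the
# configured value exactly) and per-patient mean depths (centered on the
# configured cohort means).
.cohort_design <- function(cfg) {
  set.seed(.patient_seed(cfg$seed, 0L))
  n <- cfg$n_patients
  rng <- cfg$retained_per_patient_range
  r <- sample(seq(rng[1], rng[2]), n, replace = TRUE)
  odds <- cfg$subclonal_fraction / (1 - cfg$subclonal_fraction)
  # subclonal/clonal mixture weight: stratified across patients (every
  # cohort contains both subclonal-dominated and clonal-heavy profiles),
  # then centered so the cohort subclonal fraction matches the
  # configured value
  m <- 0.45 + (2.2 - 0.45) * (sample(n) - stats::runif(n)) / n
  m <- m * sum(r) / sum(m * r)
  n_below <- pmax(round(odds * r * m), 1L)
  # per-patient mean depths, centered (weighted by per-patient record
  # counts) so the record-wide cohort means equal the configured values
  tot <- r + n_below +
    cfg$n_decoy_common + cfg$n_decoy_benign + cfg$n_decoy_low_impact
  td <- stats::rnorm(n, 0, cfg$patient_depth_sd)
  td <- td - stats::weighted.mean(td, tot)
  nd <- stats::rnorm(n, 0, cfg$patient_depth_sd)
  nd <- nd - stats::weighted.mean(nd, tot)
  # subclonal peak locations stratified across the envelope, so every
  # simulated cohort spans the diversity of clonal architectures (from
  # near-detection-floor subclones to near-threshold ones)
  env <- cfg$subclonal_vaf_range
  peak_lo <- env[1] + 0.8 * (env[2] - env[1]) *
    (sample(n) - stats::runif(n)) / n
  list(r = r, n_below = n_below, peak_lo = peak_lo,
       mean_td = cfg$mean_tumor_depth + td,
       mean_nd = cfg$mean_normal_depth + nd,
       population = stats::setNames(
         rep(c("nfe", "fin"), length.out = n)[order(stats::runif(n))],
         sprintf("P%02d", seq_len(n))))
}

# one patient's planted variant table (truth rows, pre gene-override)
.simulate_patient <- function(cfg, i, patient_id, r, n_below,
                              mean_td, mean_nd, peak_lo) {
  set.seed(.patient_seed(cfg$seed, i))
  # patients range from fully subclonal profiles to heavily clonal ones
  n_clonal <- min(sample(0:10, 1L, prob = c(1, 3, 4, 4, 3, 3, 2, 2, 1, 1, 1)),
                  r - 2L)
  n_prom <- min(sample(1:6, 1L), r - n_clonal)
  n_band <- r - n_clonal - n_prom
  roles <- c(rep("clonal_driver", n_clonal),
             rep("prominent", n_prom),
             rep("subclonal_passenger", n_band + n_below),
             rep("decoy_common", cfg$n_decoy_common),
             rep("decoy_benign", cfg$n_decoy_benign),
             rep("decoy_low_impact", cfg$n_decoy_low_impact))
  n_v <- length(roles)
  # patient-specific clonal architecture: each patient carries a narrow
  # clone-specific VAF peak inside every configured envelope, with a
  # per-patient shape skew; binomial read noise supplies the observed
  # spread. This makes the cohort VAF distribution heterogeneous across
  # patients (as observed in real leukemic clones) even after caller
  # sensitivity truncates the lowest VAFs.
  skew <- stats::runif(1L, 0.25, 3.5)
  rband <- function(n, lo, hi) lo + (hi - lo) * stats::runif(n)^skew
  env <- cfg$subclonal_vaf_range
  w_env <- env[2] - env[1]
  peak_w <- stats::runif(1L, 0.05 * w_env, 0.15 * w_env)
  sub_band <- c(peak_lo, min(peak_lo + peak_w, env[2]))
  # retained band: a narrow patient peak inside [retain_vaf, prominent)
  renv <- c(cfg$retain_vaf, cfg$prominent_vaf_range[1])
  rw_env <- renv[2] - renv[1]
  ret_lo <- stats::runif(1L, renv[1], renv[1] + 0.76 * rw_env)
  ret_w <- stats::runif(1L, 0.08 * rw_env, 0.24 * rw_env)
  ret_band <- c(ret_lo, min(ret_lo + ret_w, renv[2]))
  # prominent band: peak location varies across patients
  penv <- cfg$prominent_vaf_range
  prom_lo <- stats::runif(1L, penv[1], penv[2] - 0.3 * (penv[2] - penv[1]))
  true_vaf <- c(
    rband(n_clonal, cfg$clonal_vaf_range[1], cfg$clonal_vaf_range[2]),
    rband(n_prom, prom_lo, min(prom_lo + 0.3 * (penv[2] - penv[1]),
                               penv[2])),
    rband(n_band, ret_band[1], ret_band[2]),
    rband(n_below, sub_band[1], sub_band[2]),
    rep(0.5, cfg$n_decoy_common),                       # germline leakage
    stats::runif(cfg$n_decoy_benign + cfg$n_decoy_low_impact, 0.1, 0.3))
  band_side <- c(rep("ge", n_clonal + n_prom + n_band),
                 rep("lt", n_below),
                 rep("ge", cfg$n_decoy_common + cfg$n_decoy_benign +
                       cfg$n_decoy_low_impact))
  # unique sites: disjoint per-patient position blocks, clear of the toy
  # hotspot coordinates
  block_start <- 100000L + (i - 1L) * 30000L
  pos <- sample(seq(block_start, block_start + 29999L), n_v)
  chrom <- sample(names(CONTIGS), n_v, replace = TRUE)
  is_indel <- stats::runif(n_v) < cfg$indel_fraction &
    !roles %in% c("decoy_common", "decoy_benign", "decoy_low_impact")
  ref <- character(n_v); alt <- character(n_v)
  for (k in seq_len(n_v)) {
    if (is_indel[k]) {
      anchor <- sample(BASES, 1L)
      extra <- paste(sample(BASES, sample(1:3, 1L), replace = TRUE),
                     collapse = "")
      if (stats::runif(1) < 0.5) {            # deletion
        ref[k] <- paste0(anchor, extra); alt[k] <- anchor
      } else {                                # insertion
        ref[k] <- anchor; alt[k] <- paste0(anchor, extra)
      }
    } else {
      ref[k] <- sample(BASES, 1L)
      alt[k] <- sample(setdiff(BASES, ref[k]), 1L)
    }
  }
  tumor_depth <- stats::rpois(n_v, mean_td)
  normal_depth <- stats::rpois(n_v, mean_nd)
  tumor_alt <- integer(n_v)
  for (k in seq_len(n_v)) {
    tumor_alt[k] <- .rbinom_band(tumor_depth[k], true_vaf[k],
                                 cfg$retain_vaf, band_side[k])
  }
  normal_p <- ifelse(roles == "decoy_common", 0.5, 0)
  normal_alt <- stats::rbinom(n_v, normal_depth, normal_p)
  # per-caller detection, logistic in tumor alt-read count
  det <- matrix(FALSE, n_v, length(CALLERS),
                dimnames = list(NULL, CALLERS))
  for (cl in CALLERS) {
    m <- cfg$caller_sensitivity_midpoints[[cl]]
    p_det <- stats::plogis((tumor_alt - m) / cfg$sensitivity_scale)
    det[, cl] <- stats::runif(n_v) < p_det
  }
  tibble::tibble(
    patient_id = patient_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    role = roles, true_vaf = true_vaf,
    tumor_depth = tumor_depth, tumor_alt_count = tumor_alt,
    normal_depth = normal_depth, normal_alt_count = normal_alt,
    obs_vaf = compute_vaf(tumor_alt, tumor_depth),
    detected_by = apply(det, 1L, function(d) {
      paste(CALLERS[d], collapse = ",")
    })
  )
}

#' Simulate a synthetic CLPD-NK-like cohort bundle
#'
#' Generates, from a single seed, everything the pipeline consumes:
#' per-patient tumor-normal VCFs in three caller dialects, the variant
#' annotation table, expression / PPI / driver-label / drug tables, planted
#' pathway topologies with their expected induced network, toy hotspot
#' regions with a separate screening cohort, patient metadata, and a truth
#' table recording every planted variant's role, realized read counts,
#' per-caller detection mask and expected cascade outcome (`expected_pass`:
#' detected by at least one caller, tumor and normal depth at the coverage
#' gate, no engineered annotation decoy, observed VAF at or above the
#' retention threshold).
#'
#' Decoys fail exactly one cascade stage each: population-common variants
#' (germline leakage, high reference-population AF), ClinVar benign
#' records, and low-impact/tolerated records. Six reserved genes are
#' planted as the recurrently mutated set (retained variants in >= 2
#' patients); all other genes are unique to a single variant.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given the full file bundle is
#'   written there (with a MANIFEST) and paths are returned alongside the
#'   in-memory tables.
#' @return A list: `truth`, `calls`, `annotations`, `expression`, `ppi`,
#'   `pathways`, `network_truth`, `hotspots`, `screening`, `driver_labels`,
#'   `drug_interactions`, `patients`, `population_by_patient`, `config`,
#'   and `paths` when `out_dir` is used.
#' @export
simulate_cohort <- function(config = simulation_config(), out_dir = NULL) {
  cfg <- config
  if (cfg$n_patients < 1) stop("configuration error: zero patients")
  ids <- sprintf("P%02d", seq_len(cfg$n_patients))
  design <- .cohort_design(cfg)
  truth <- dplyr::bind_rows(lapply(seq_len(cfg$n_patients), function(i) {
    .simulate_patient(cfg, i, ids[i], design$r[i], design$n_below[i],
                      design$mean_td[i], design$mean_nd[i],
                      design$peak_lo[i])
  }))
  # Italy/Finland-style population assignment
  population_by_patient <- design$population
  set.seed(.patient_seed(cfg$seed, 0L) + 1L)
  truth$expected_pass <-
    nzchar(truth$detected_by) &
    truth$tumor_depth >= 10 & truth$normal_depth >= 10 &
    truth$role %in% c("clonal_driver", "prominent", "subclonal_passenger") &
    truth$obs_vaf >= cfg$retain_vaf

  # gene assignment: unique genes, then plant 6 recurrent + 2 pathway genes
  truth$gene <- sprintf("GENE%04d", 100L + seq_len(nrow(truth)))
  rec_genes <- sprintf("GENE%04d", 1:6)
  path_extra <- sprintf("GENE%04d", 7:8)
  eligible <- which(truth$expected_pass)
  by_patient <- split(eligible, truth$patient_id[eligible])
  for (j in if (length(by_patient) >= 2L) seq_along(rec_genes) else integer()) {
    k <- sample(2:min(3L, length(by_patient)), 1L)
    pats <- sample(names(by_patient), k)
    for (p in pats) {
      free <- by_patient[[p]][!truth$gene[by_patient[[p]]] %in%
                                c(rec_genes, path_extra)]
      idx <- free[sample.int(length(free), 1L)]
      truth$gene[idx] <- rec_genes[j]
    }
  }
  p1 <- names(by_patient)[1]
  free <- by_patient[[p1]][!truth$gene[by_patient[[p1]]] %in%
                             c(rec_genes, path_extra)]
  truth$gene[free[1:2]] <- path_extra

  annotations <- .simulate_annotations(truth, population_by_patient)
  pw <- simulate_pathways(mutated_genes = c(rec_genes, path_extra),
                          unexpressed_gene = path_extra[2],
                          seed = .patient_seed(cfg$seed, 990L))
  # expression: every planted gene expressed except the planted
  # unexpressed pathway gene
  all_genes <- unique(c(truth$gene, pw$all_genes))
  expression <- tibble::tibble(
    gene = all_genes,
    nx_value = round(stats::runif(length(all_genes), 1, 60), 2))
  expression$nx_value[expression$gene == path_extra[2]] <- 0.5

  driver_labels <- tibble::tibble(
    gene = c(rec_genes, path_extra),
    label = c("driver", "driver", "passenger", rep("unknown", 5)))
  drug_interactions <- tibble::tibble(
    gene = c(rec_genes[1], rec_genes[1], rec_genes[2], rec_genes[4]),
    drug = c("drugA", "drugB", "drugC", "drugD"),
    approved = c(TRUE, FALSE, TRUE, TRUE))

  hotspots <- tibble::tibble(
    gene = c("STAT3", "STAT3", "STAT3", "STAT5B"),
    chrom = "chr3",
    start = c(10000L, 11000L, 12000L, 50000L),
    end = c(10500L, 11400L, 12500L, 50800L),
    label = c(rep("STAT3 exons 19-21", 3), "STAT5B exon 16"))
  screening <- .simulate_screening(cfg)

  calls <- .truth_to_calls(truth)
  patients <- truth |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(mean_tumor_coverage = mean(.data$tumor_depth),
                     mean_normal_coverage = mean(.data$normal_depth),
                     .groups = "drop") |>
    dplyr::mutate(population = unname(
      population_by_patient[.data$patient_id]))

  bundle <- list(truth = truth, calls = calls, annotations = annotations,
                 expression = expression, ppi = pw$ppi,
                 pathways = pw$topologies, network_truth = pw$network_truth,
                 hotspots = hotspots, screening = screening,
                 driver_labels = driver_labels,
                 drug_interactions = drug_interactions,
                 patients = patients,
                 population_by_patient = population_by_patient,
                 config = cfg)
  if (!is.null(out_dir)) bundle$paths <- .write_bundle(bundle, out_dir)
  bundle
}

.simulate_annotations <- function(truth, population_by_patient) {
  n <- nrow(truth)
  own_pop <- unname(population_by_patient[truth$patient_id])
  is_indel <- nchar(truth$ref) != nchar(truth$alt)
  impact <- character(n); metasvm <- character(n)
  consequence <- character(n); clinvar <- rep(NA_character_, n)
  af_nfe <- rep(NA_real_, n); af_fin <- rep(NA_real_, n)
  dbsnp <- rep(NA_character_, n); cosmic <- rep(NA_character_, n)
  hg <- .random_hgvs(n)
  for (k in seq_len(n)) {
    role <- truth$role[k]
    if (role == "decoy_low_impact") {
      if (stats::runif(1) < 0.5) {
        impact[k] <- "LOW"; metasvm[k] <- NA; consequence[k] <- "synonymous_variant"
      } else {
        impact[k] <- "MODERATE"; metasvm[k] <- "tolerated"
        consequence[k] <- "missense_variant"
      }
    } else if (is_indel[k]) {
      impact[k] <- "HIGH"; metasvm[k] <- NA       # no missense score
      consequence[k] <- "frameshift_variant"
    } else if (stats::runif(1) < 0.15) {
      impact[k] <- "HIGH"; metasvm[k] <- NA
      consequence[k] <- sample(c("stop_gained", "splice_acceptor_variant"), 1L)
    } else {
      impact[k] <- "MODERATE"; metasvm[k] <- "deleterious"
      consequence[k] <- "missense_variant"
    }
    if (role == "decoy_benign") {
      clinvar[k] <- sample(c("benign", "likely_benign"), 1L)
      dbsnp[k] <- sprintf("rs%07d", sample(1e6, 1L))
    } else if (stats::runif(1) < 0.2) {
      clinvar[k] <- "other"
    }
    af_own <- NA_real_
    if (role == "decoy_common") {
      af_own <- round(stats::runif(1, 0.06, 0.4), 4)
      dbsnp[k] <- sprintf("rs%07d", sample(1e6, 1L))
    } else if (stats::runif(1) < 0.3) {
      af_own <- round(stats::runif(1, 0, 0.05), 4)
    }
    if (own_pop[k] == "nfe") af_nfe[k] <- af_own else af_fin[k] <- af_own
    # occasionally common only in the other population: must be kept
    if (role != "decoy_common" && stats::runif(1) < 0.08) {
      if (own_pop[k] == "nfe") af_fin[k] <- round(stats::runif(1, 0.06, 0.2), 4)
      else af_nfe[k] <- round(stats::runif(1, 0.06, 0.2), 4)
    }
    if (role == "clonal_driver") cosmic[k] <- sprintf("COSM%06d", sample(1e6, 1L))
  }
  tibble::tibble(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                 alt = truth$alt, gene = truth$gene,
                 consequence = consequence, snpeff_impact = impact,
                 metasvm = metasvm, af_nfe = af_nfe, af_fin = af_fin,
                 clinvar = clinvar, dbsnp_id = dbsnp, cosmic_id = cosmic,
                 hgvs_c = hg$c, hgvs_p = hg$p)
}

# a 57-patient hotspot-screening cohort: 5 STAT3 SH2 hits, no STAT5B
.simulate_screening <- function(cfg) {
  set.seed(.patient_seed(cfg$seed, 991L))
  sids <- sprintf("S%02d", 1:57)
  hit_pat <- sample(sids, 5L)
  hits <- tibble::tibble(
    patient_id = hit_pat, chrom = "chr3",
    pos = sample(12000:12500, 5L),
    gene = "STAT3",
    hgvs_p = c("p.Tyr640Phe", "p.Tyr640Phe", "p.Asp661Tyr",
               "p.Asn647Ile", "p.Ser614Arg"))
  negatives <- tibble::tibble(
    patient_id = sample(setdiff(sids, hit_pat), 6L), chrom = "chr1",
    pos = sample(1000:5000, 6L), gene = "OTHER",
    hgvs_p = NA_character_)
  dplyr::bind_rows(hits, negatives)
}

# expand truth rows into the per-caller call table the VCFs encode;
# strelka2 spells indels with a padded (non-parsimonious) allele pair
.truth_to_calls <- function(truth) {
  det <- strsplit(truth$detected_by, ",", fixed = TRUE)
  rows <- lapply(seq_len(nrow(truth)), function(k) {
    cls <- det[[k]]
    if (length(cls) == 0L || identical(cls, "")) return(NULL)
    out <- truth[rep(k, length(cls)),
                 c("patient_id", "chrom", "pos", "ref", "alt",
                   "tumor_depth", "tumor_alt_count",
                   "normal_depth", "normal_alt_count")]
    out$caller <- cls
    pad_idx <- out$caller == "strelka2" & nchar(out$ref) != nchar(out$alt)
    if (any(pad_idx)) {
      out$ref[pad_idx] <- paste0(out$ref[pad_idx], "A")
      out$alt[pad_idx] <- paste0(out$alt[pad_idx], "A")
    }
    out$filter_status <- "PASS"
    out
  })
  dplyr::bind_rows(rows)[, c("patient_id", "caller", "chrom", "pos", "ref",
                             "alt", "tumor_depth", "tumor_alt_count",
                             "normal_depth", "normal_alt_count",
                             "filter_status")]
}

#' Plant pathway topologies with a known induced mutated-gene network
#'
#' Builds small typed topologies exercising every conversion rule — a
#' regulatory chain (direct edges), a 4-member complex bound to a gene
#' (clique plus cross edges), a two-compound biosynthetic chain (one
#' indirect edge) — plus a decoy pathway containing no mutated gene, a PPI
#' table adding one novel predicted edge and one duplicate of a direct
#' edge, and one planted unexpressed gene whose edges must vanish. The
#' accompanying truth table lists the expected edges of the
#' expression-filtered induced mutated-gene network.
#'
#' @param mutated_genes Character vector (>= 8 genes used positionally).
#' @param unexpressed_gene One of `mutated_genes` planted as unexpressed.
#' @param seed Integer seed.
#' @return List: `topologies`, `ppi`, `network_truth` (tibble `gene1`,
#'   `gene2`, `edge_class`), `all_genes`.
#' @export
simulate_pathways <- function(mutated_genes, unexpressed_gene = NULL,
                              seed = 1L) {
  set.seed(seed)
  stopifnot(length(mutated_genes) >= 8L)
  m <- mutated_genes[1:8]
  if (is.null(unexpressed_gene)) unexpressed_gene <- m[8]
  x <- c("PWX1", "PWX2", "PWX3")
  gene_node <- function(id) list(node_id = id, node_type = "gene",
                                 members = list())
  mk <- function(pathway_id, name, source, nodes, edges) {
    topo <- structure(list(
      pathway_id = pathway_id, name = name, source = source,
      nodes = dplyr::bind_rows(lapply(nodes, function(n) {
        tibble::tibble(node_id = n$node_id, node_type = n$node_type,
                       members = list(as.character(unlist(n$members))))
      })),
      edges = if (length(edges)) dplyr::bind_rows(edges) else
        tibble::tibble(src = character(), dst = character(),
                       relation = character(), directed = logical())
    ), class = "pathway_topology")
    validate_topology(topo)
    topo
  }
  e <- function(src, dst, relation, directed = TRUE) {
    tibble::tibble(src = src, dst = dst, relation = relation,
                   directed = directed)
  }
  p1 <- mk("path_regulatory", "regulatory chain", "kegg_like",
           lapply(c(m[1:3], x[1], m[8]), gene_node),
           list(e(m[1], m[2], "activation"),
                e(m[2], m[3], "inhibition"),
                e(m[3], x[1], "activation"),
                e(x[1], m[8], "activation")))
  p2 <- mk("path_complex", "complex participation", "reactome_like",
           c(list(list(node_id = "CX1", node_type = "complex",
                       members = as.list(m[c(1, 4, 5, 6)]))),
             list(gene_node(x[1]))),
           list(e("CX1", x[1], "binding", directed = FALSE)))
  p3 <- mk("path_compound", "biosynthetic chain", "kegg_like",
           c(lapply(c(m[2], m[7]), gene_node),
             list(list(node_id = "cmp1", node_type = "compound",
                       members = list()),
                  list(node_id = "cmp2", node_type = "compound",
                       members = list()))),
           list(e(m[2], "cmp1", "compound_flow"),
                e("cmp1", "cmp2", "compound_flow"),
                e("cmp2", m[7], "compound_flow")))
  p4 <- mk("path_decoy", "no mutated gene", "kegg_like",
           lapply(x[2:3], gene_node),
           list(e(x[2], x[3], "activation")))
  ppi <- tibble::tibble(gene1 = c(m[3], m[1], m[1]),
                        gene2 = c(m[7], m[2], m[8]),
                        score = round(stats::runif(3), 3))
  canon <- function(a, b) {
    s <- a > b
    tibble::tibble(gene1 = ifelse(s, b, a), gene2 = ifelse(s, a, b))
  }
  direct_pairs <- dplyr::bind_rows(
    canon(m[1], m[2]), canon(m[2], m[3]),
    canon(m[4], m[5]), canon(m[4], m[6]), canon(m[5], m[6]),
    canon(m[1], m[4]), canon(m[1], m[5]), canon(m[1], m[6]))
  truth <- dplyr::bind_rows(
    dplyr::mutate(direct_pairs, edge_class = "direct"),
    dplyr::mutate(canon(m[2], m[7]), edge_class = "indirect"),
    dplyr::mutate(canon(m[3], m[7]), edge_class = "predicted")) |>
    dplyr::arrange(.data$gene1, .data$gene2)
  # the unexpressed gene's edges (x1-m8 direct, m1-m8 ppi) must not appear
  truth <- truth[truth$gene1 != unexpressed_gene &
                   truth$gene2 != unexpressed_gene, , drop = FALSE]
  list(topologies = list(p1, p2, p3, p4), ppi = ppi,
       network_truth = truth, all_genes = unique(c(m, x)))
}

# ---- bundle file output --------------------------------------------------

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "pathways"), showWarnings = FALSE)
  paths <- list()
  for (p in unique(bundle$calls$patient_id)) {
    for (cl in CALLERS) {
      sub <- bundle$calls[bundle$calls$patient_id == p &
                            bundle$calls$caller == cl, ]
      f <- file.path(out_dir, "vcf", sprintf("%s_%s.vcf", p, cl))
      write_caller_vcf(sub, cl, f)
      paths$vcf <- c(paths$vcf, f)
    }
  }
  paths$annotations <- .write_tsv(bundle$annotations,
                                  file.path(out_dir, "annotations.tsv"))
  paths$truth <- .write_tsv(bundle$truth, file.path(out_dir, "truth.tsv"))
  paths$expression <- .write_tsv(bundle$expression,
                                 file.path(out_dir, "expression.tsv"))
  paths$ppi <- .write_tsv(bundle$ppi, file.path(out_dir, "ppi.tsv"))
  paths$driver_labels <- .write_tsv(bundle$driver_labels,
                                    file.path(out_dir, "driver_labels.tsv"))
  paths$drug_interactions <- .write_tsv(
    bundle$drug_interactions, file.path(out_dir, "drug_interactions.tsv"))
  paths$patients <- .write_tsv(bundle$patients,
                               file.path(out_dir, "patients.tsv"))
  paths$screening <- .write_tsv(bundle$screening,
                                file.path(out_dir, "screening_variants.tsv"))
  paths$network_truth <- .write_tsv(bundle$network_truth,
                                    file.path(out_dir, "network_truth.tsv"))
  hs <- bundle$hotspots
  hs_json <- lapply(split(hs, hs$gene), function(g) {
    list(gene = g$gene[1], chrom = g$chrom[1],
         intervals = lapply(seq_len(nrow(g)),
                            function(i) c(g$start[i], g$end[i])),
         label = g$label[1])
  })
  paths$hotspots <- file.path(out_dir, "hotspots.json")
  jsonlite::write_json(unname(hs_json), paths$hotspots, auto_unbox = TRUE)
  for (topo in bundle$pathways) {
    f <- file.path(out_dir, "pathways", paste0(topo$pathway_id, ".json"))
    .write_topology_json(topo, f)
    paths$pathways <- c(paths$pathways, f)
  }
  manifest <- c(
    "Synthetic CLPD-NK-like cohort bundle (all files seeded, plain text)",
    "vcf/<patient>_<caller>.vcf  tumor-normal somatic VCFs, 3 caller dialects",
    "annotations.tsv             per-variant annotation table",
    "truth.tsv                   planted variants with roles and expected_pass",
    "expression.tsv              normalized gene expression",
    "ppi.tsv                     protein-protein interaction pairs",
    "pathways/*.json             typed pathway topologies",
    "network_truth.tsv           expected induced mutated-gene network",
    "hotspots.json               toy hotspot regions (STAT3/STAT5B style)",
    "screening_variants.tsv      57-patient hotspot-screening cohort",
    "driver_labels.tsv           external driver predictions",
    "drug_interactions.tsv       drug-gene interactions",
    "patients.tsv                patient metadata and mean coverages")
  writeLines(manifest, file.path(out_dir, "MANIFEST.txt"))
  paths
}

.write_topology_json <- function(topo, path) {
  obj <- list(
    pathway_id = topo$pathway_id, name = topo$name, source = topo$source,
    nodes = lapply(seq_len(nrow(topo$nodes)), function(i) {
      n <- list(node_id = topo$nodes$node_id[i],
                node_type = topo$nodes$node_type[i])
      if (n$node_type == "complex") n$members <- topo$nodes$members[[i]]
      n
    }),
    edges = lapply(seq_len(nrow(topo$edges)), function(i) {
      list(src = topo$edges$src[i], dst = topo$edges$dst[i],
           relation = topo$edges$relation[i],
           directed = topo$edges$directed[i])
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
}

#' Write a caller-dialect somatic VCF
#'
#' Emits a minimal but syntactically valid VCF 4.2 for one patient and one
#' caller, using that caller's read-count encoding (AD for MuTect-style
#' callers; tier counts AU/CU/GU/TU and TAR/TIR for Strelka2). Sample
#' column order differs by caller (Strelka2 puts NORMAL first) so readers
#' must resolve samples by name.
#'
#' @param calls Call tibble rows for one patient and caller.
#' @param caller Caller dialect.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, caller, path) {
  caller <- match.arg(caller, CALLERS)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=%s-synthetic", caller),
    sprintf("##contig=<ID=%s,length=%d>", names(CONTIGS), CONTIGS),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">")
  if (caller %in% c("mutect", "mutect2")) {
    header <- c(header,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
    samples <- c("TUMOR", "NORMAL")
  } else {
    header <- c(header,
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AU,Number=2,Type=Integer,Description=\"A tier counts\">",
      "##FORMAT=<ID=CU,Number=2,Type=Integer,Description=\"C tier counts\">",
      "##FORMAT=<ID=GU,Number=2,Type=Integer,Description=\"G tier counts\">",
      "##FORMAT=<ID=TU,Number=2,Type=Integer,Description=\"T tier counts\">",
      "##FORMAT=<ID=TAR,Number=2,Type=Integer,Description=\"Ref tier counts\">",
      "##FORMAT=<ID=TIR,Number=2,Type=Integer,Description=\"Indel tier counts\">")
    samples <- c("NORMAL", "TUMOR")
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samples),
                            collapse = "\t"))
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  body <- vapply(seq_len(nrow(calls)), function(i) {
    v <- calls[i, ]
    if (caller %in% c("mutect", "mutect2")) {
      fmt <- "GT:AD:DP"
      sm <- c(
        TUMOR = sprintf("0/1:%d,%d:%d", v$tumor_depth - v$tumor_alt_count,
                        v$tumor_alt_count, v$tumor_depth),
        NORMAL = sprintf("0/0:%d,%d:%d", v$normal_depth - v$normal_alt_count,
                         v$normal_alt_count, v$normal_depth))
    } else if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) {
      fmt <- "DP:AU:CU:GU:TU"
      enc <- function(depth, altc) {
        counts <- stats::setNames(rep(0L, 4), BASES)
        counts[v$ref] <- depth - altc
        counts[v$alt] <- altc
        sprintf("%d:%s", depth,
                paste(sprintf("%d,%d", counts, counts), collapse = ":"))
      }
      sm <- c(TUMOR = enc(v$tumor_depth, v$tumor_alt_count),
              NORMAL = enc(v$normal_depth, v$normal_alt_count))
    } else {
      fmt <- "DP:TAR:TIR"
      enc <- function(depth, altc) {
        sprintf("%d:%d,%d:%d,%d", depth, depth - altc, depth - altc,
                altc, altc)
      }
      sm <- c(TUMOR = enc(v$tumor_depth, v$tumor_alt_count),
              NORMAL = enc(v$normal_depth, v$normal_alt_count))
    }
    paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", v$filter_status,
            "SOMATIC", fmt, sm[samples]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
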