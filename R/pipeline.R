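## End-to-end pipeline: cohort (generated or loaded) -> QC -> empirical
## index -> preselection -> SNP and temperament sets -> kernel
## association -> relations + permutation null -> health fusion ->
## heritability. Driven by one config and one seed; outputs are
## deterministic text files.

#' Default pipeline configuration
#'
#' @return Named list of pipeline parameters; see the methods vignette
#'   for units and rationale.
#' @export
default_config <- function() {
  list(
    cohort = list(n_subjects = 300L, n_snps = 400L, n_blocks = 3L,
                  n_clusters = 3L, link_blocks = TRUE, h2_target = NULL,
                  missing_rate = 0.02, fst = 0.01, fidelity = 0.9,
                  subjects_per_block = 60L, snps_per_block = 15L,
                  effect_beta = 6, effect_trait = "profile",
                  genetic_model = "block"),
    # planted allele-pattern blocks are deliberately out of HWE, so the
    # demo pipeline disables the HWE filter; real-data runs should not
    qc = list(maf_min = 0.01, call_rate_min = 0.9, hwe_p_min = 0),
    preselect = list(p_threshold = 0.01),
    cluster = list(k_min = 2L, k_max = 6L, n_restarts = 3L,
                   consensus_restarts = 15L, temp_k_max = 8L),
    associate = list(threshold = 4e-4, weights_beta = c(1, 25)),
    relate = list(p_threshold = 1e-3, permutations = 500L),
    heritability = list(trim_fraction = 0.05, n_folds = 5L, n_boot = 0L)
  )
}

#' Run the full uncovering pipeline on a synthetic cohort
#'
#' Generates a seeded cohort (planted blocks linked to temperament
#' profiles, a target heritability), then runs QC, ancestry PCs, the
#' empirical temperament index, single-SNP preselection, SNP-set and
#' temperament-set discovery, super-set rank selection, kernel set
#' association with the significance screen, hypergeometric relation
#' mapping with the permutation null and health fusion, the SNP-set
#' network, and heritability estimation. All outputs are tibbles; when
#' `out_dir` is given they are also written as TSV/JSON with fully
#' deterministic bytes for a fixed `(config, seed)`.
#'
#' @param config list as from [default_config()] (missing entries are
#'   filled with defaults); or a path to a YAML file with the same
#'   structure.
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @return List of class `temperanet_run` with elements `cohort`, `qc`,
#'   `covariates`, `index`, `preselect`, `snp_sweep`, `temp_sweep`,
#'   `rank_selection`, `associations`, `significant`, `relations`,
#'   `network`, `hubs`, `health`, `h2`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_config(), config)
  cc <- cfg$cohort
  effect_map <- if (cc$n_blocks > 0 && cc$effect_beta != 0) {
    tibble::tibble(block_id = sprintf("B%02d", seq_len(cc$n_blocks)),
                   trait = cc$effect_trait %||% "profile",
                   beta = cc$effect_beta)
  } else NULL
  cohort <- simulate_cohort(
    n_subjects = cc$n_subjects, n_snps = cc$n_snps,
    n_blocks = cc$n_blocks, n_clusters = cc$n_clusters,
    link_blocks = cc$link_blocks, h2_target = cc$h2_target,
    missing_rate = cc$missing_rate, fst = cc$fst, fidelity = cc$fidelity,
    subjects_per_block = cc$subjects_per_block,
    snps_per_block = cc$snps_per_block,
    effect_map = effect_map, genetic_model = cc$genetic_model, seed = seed)

  qc <- qc_filter(cohort$genotypes, cfg$qc$maf_min, cfg$qc$call_rate_min,
                  cfg$qc$hwe_p_min)
  cov <- covariate_table(qc$genotypes, cohort$covariates, k = 3L)
  idx <- empirical_index(cohort$phenotypes)
  y <- idx$index
  pres <- preselect_snps(qc$genotypes, y, cov,
                         p_threshold = cfg$preselect$p_threshold)
  g_sel <- subset_genotypes(qc$genotypes, snps = which(pres$selected))

  kr <- seq.int(cfg$cluster$k_min, cfg$cluster$k_max)
  snp_sw <- snp_sets(qc$genotypes, k_range = kr,
                     n_restarts = cfg$cluster$n_restarts, seed = seed)
  snp_sw$catalog <- catalog_signatures(snp_sw$catalog, cohort$phenotypes)
  temp_sw <- temperament_sets(
    cohort$phenotypes,
    k_range = seq.int(cfg$cluster$k_min, cfg$cluster$temp_k_max),
    n_restarts = cfg$cluster$n_restarts,
    consensus_restarts = cfg$cluster$consensus_restarts, seed = seed)
  temp_sw$catalog <- catalog_signatures(temp_sw$catalog, cohort$phenotypes)
  tmat <- as.matrix(cohort$phenotypes[, tci_subscales("temperament")])
  rownames(tmat) <- cohort$phenotypes$subject_id
  ranksel <- select_superset_rank(temp_sw, temp_sw$catalog, data = tmat)

  assoc <- associate_sets(snp_sw$catalog, qc$genotypes, y, cov,
                          weights_beta = cfg$associate$weights_beta)
  sig <- significance_screen(assoc, threshold = cfg$associate$threshold)

  health <- health_flags(cohort$phenotypes)
  rel <- relation_screen(snp_sw$catalog, temp_sw$catalog,
                         N = length(qc$genotypes$subject_ids),
                         p_threshold = cfg$relate$p_threshold,
                         health = health)
  if (nrow(rel)) {
    rel <- permutation_null(rel, snp_sw$catalog, temp_sw$catalog,
                            qc$genotypes$subject_ids,
                            R = cfg$relate$permutations, seed = seed)
  }
  net <- build_network(snp_sw$catalog,
                       n_subjects = length(qc$genotypes$subject_ids),
                       n_snps = ncol(qc$genotypes$values))
  hubs <- find_hubs(net)
  h2 <- if (ncol(g_sel$values) >= 2) {
    estimate_h2(g_sel, y, env = cohort$environment,
                trim_fraction = cfg$heritability$trim_fraction,
                n_folds = cfg$heritability$n_folds,
                n_boot = cfg$heritability$n_boot, seed = seed)
  } else NULL

  run <- structure(list(
    cohort = cohort, qc = qc, covariates = cov, index = idx,
    preselect = pres, snp_sweep = snp_sw, temp_sweep = temp_sw,
    rank_selection = ranksel, associations = assoc, significant = sig,
    relations = rel, network = net, hubs = hubs, health = health,
    h2 = h2, config = cfg, seed = seed
  ), class = "temperanet_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.temperanet_run <- function(x, ...) {
  cat("<temperanet_run>\n")
  cat(sprintf("  SNP sets: %d (%d significant at p < %g)\n",
              nrow(x$snp_sweep$catalog), nrow(x$significant),
              x$config$associate$threshold))
  cat(sprintf("  temperament sets: %d; chosen super-set rank k = %d\n",
              nrow(x$temp_sweep$catalog), x$rank_selection$k))
  cat(sprintf("  relations: %d; h2 = %s\n", nrow(x$relations),
              if (is.null(x$h2)) "NA" else sprintf("%.3f", x$h2$h2)))
  invisible(x)
}

# serialize a set catalog without list-columns (TSV) plus a JSON
# membership file
catalog_tsv <- function(catalog) {
  out <- catalog[, intersect(c("label", "k", "order", "cohesion",
                               "n_subjects", "n_features", "profile"),
                             names(catalog)), drop = FALSE]
  if ("signature" %in% names(catalog)) {
    out$signature <- vapply(catalog$signature, function(s) {
      marked <- s[s != "unmarked"]
      paste(names(marked), substr(marked, 1, 1), sep = ":", collapse = ",")
    }, character(1))
  }
  out
}

#' Write pipeline outputs as deterministic text files
#'
#' @param run a `temperanet_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) readr::write_tsv(
    dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                    ~ signif(.x, 10))),
    file.path(out_dir, name))
  w(run$qc$report, "qc_report.tsv")
  w(run$preselect, "preselect.tsv")
  w(catalog_tsv(run$snp_sweep$catalog), "snp_sets.tsv")
  w(catalog_tsv(run$temp_sweep$catalog), "temperament_sets.tsv")
  w(run$associations, "associations.tsv")
  w(run$significant, "significant_sets.tsv")
  if (nrow(run$relations)) w(run$relations, "relations.tsv")
  w(run$hubs, "network_hubs.tsv")
  w(run$network$edges, "network_edges.tsv")
  w(run$health, "health_flags.tsv")
  membership <- lapply(seq_len(nrow(run$snp_sweep$catalog)), function(i)
    list(label = run$snp_sweep$catalog$label[i],
         subjects = run$snp_sweep$catalog$subject_ids[[i]],
         snps = run$snp_sweep$catalog$feature_ids[[i]]))
  jsonlite::write_json(membership, file.path(out_dir, "snp_set_members.json"),
                       auto_unbox = TRUE, digits = NA)
  summary <- list(
    seed = run$seed,
    n_snp_sets = nrow(run$snp_sweep$catalog),
    n_temp_sets = nrow(run$temp_sweep$catalog),
    chosen_k = run$rank_selection$k,
    n_significant = nrow(run$significant),
    n_relations = nrow(run$relations),
    h2 = if (is.null(run$h2)) NULL else signif(run$h2$h2, 10)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
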