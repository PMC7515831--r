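# shared fixture builders; everything is generated in code at test time

# small genotype matrix with given dosage columns
toy_genotypes <- function(n = 100, m = 20, maf = 0.3, seed = 1) {
  set.seed(seed)
  v <- matrix(rbinom(n * m, 2L, maf), n, m)
  genotype_matrix(v)
}

# cohort with linked blocks and profile effects: the standard planted
# association fixture used across relation / replication tests
linked_cohort <- function(seed, n_subjects = 300, n_snps = 300,
                          n_blocks = 3, beta = 6) {
  em <- tibble::tibble(block_id = sprintf("B%02d", seq_len(n_blocks)),
                       trait = "profile", beta = beta)
  simulate_cohort(n_subjects = n_subjects, n_snps = n_snps,
                  n_blocks = n_blocks, n_clusters = 3,
                  link_blocks = TRUE, effect_map = em,
                  genetic_model = "block",
                  subjects_per_block = 60, snps_per_block = 15,
                  seed = seed)
}

# discover SNP sets with signatures attached; optionally keep only the
# significance-screened sets (the discovery-side replication universe --
# replication targets stay unscreened, as sets need only be identified,
# not re-significant, in a replication sample)
discovered_catalog <- function(cohort, seed, k_range = 2:6,
                               screen = FALSE, threshold = 1e-3) {
  sw <- snp_sets(cohort$genotypes, k_range = k_range, n_restarts = 2,
                 seed = seed)
  sw$catalog <- catalog_signatures(sw$catalog, cohort$phenotypes)
  if (!screen) return(sw$catalog)
  idx <- empirical_index(cohort$phenotypes)
  assoc <- associate_sets(sw$catalog, cohort$genotypes, idx)
  sig <- significance_screen(assoc, threshold = threshold)
  sw$catalog[sw$catalog$label %in% sig$set_label, , drop = FALSE]
}

# best min(subject, feature) Jaccard between a catalog and one block
block_recovery <- function(catalog, truth, b) {
  vapply(seq_len(nrow(catalog)), function(i) {
    min(jaccard(catalog$subject_ids[[i]], truth$blocks$subject_ids[[b]]),
        jaccard(catalog$feature_ids[[i]], truth$blocks$snp_ids[[b]]))
  }, numeric(1)) |> max()
}

# exhaustive hypergeometric upper-tail by enumerating every draw of B
enum_hyper_p <- function(N, n_a, n_b, k) {
  if (n_b == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n_b)
  hits <- colSums(draws <= n_a)   # A = {1..n_a}
  mean(hits >= k)
}
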