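# shared heritability fixture: additive effects over 5 planted SNP groups
h2_cohort <- function(h2t, seed, n = 800) {
  em <- tibble::tibble(block_id = sprintf("B%02d", 1:5), trait = "index",
                       beta = 1)
  simulate_cohort(n_subjects = n, n_snps = 120, n_blocks = 5,
                  n_clusters = 1, subjects_per_block = 40,
                  snps_per_block = 10, effect_map = em, h2_target = h2t,
                  genetic_model = "additive", seed = seed)
}

test_that("pure-noise phenotypes give near-zero heritability and trimming is a no-op without outliers", {
  co <- simulate_cohort(n_subjects = 600, n_snps = 80, n_blocks = 0,
                        n_clusters = 1, seed = 41)
  idx <- empirical_index(co$phenotypes)
  est <- estimate_h2(co$genotypes, idx, n_boot = 25, seed = 41)
  expect_lte(est$h2, 0.05)
  expect_true(est$se >= 0)

  co2 <- h2_cohort(0.4, seed = 42)
  idx2 <- empirical_index(co2$phenotypes)
  g2 <- subset_genotypes(co2$genotypes,
                         snps = unique(unlist(co2$truth$blocks$snp_ids)))
  e_trim <- estimate_h2(g2, idx2, trim_fraction = 0.05, n_boot = 25,
                        seed = 42)
  e_notrim <- estimate_h2(g2, idx2, trim_fraction = 0, n_boot = 0,
                          seed = 42)
  expect_lt(abs(e_trim$h2 - e_notrim$h2), max(2 * e_trim$se, 0.05))
  expect_error(estimate_h2(g2, idx2, trim_fraction = 0.6), "below 0.5")
})

test_that("heritability estimates are invariant to subject order and affine rescaling of the index", {
  co <- h2_cohort(0.4, seed = 43, n = 500)
  idx <- empirical_index(co$phenotypes)
  g <- subset_genotypes(co$genotypes,
                        snps = unique(unlist(co$truth$blocks$snp_ids)))
  base <- estimate_h2(g, idx, n_boot = 0, seed = 7)
  set.seed(1)
  perm <- sample(500)
  gp <- subset_genotypes(g, subjects = perm)
  idx_p <- idx[perm, ]
  e_perm <- estimate_h2(gp, idx_p, n_boot = 0, seed = 7)
  expect_lt(abs(base$h2 - e_perm$h2), 0.05)   # folds differ, estimate stable

  y_affine <- idx
  y_affine$index <- 3.7 * y_affine$index - 11
  e_aff <- estimate_h2(g, y_affine, n_boot = 0, seed = 7)
  expect_equal(base$h2, e_aff$h2, tolerance = 1e-6)
})

test_that("environment partialling leaves uncorrelated-environment estimates alone and absorbs planted confounding", {
  co <- h2_cohort(0.4, seed = 44, n = 600)
  idx <- empirical_index(co$phenotypes)
  g <- subset_genotypes(co$genotypes,
                        snps = unique(unlist(co$truth$blocks$snp_ids)))
  est0 <- estimate_h2(g, idx, env = co$environment, n_boot = 25, seed = 3)
  expect_lt(abs(est0$adjusted_h2 - est0$h2), max(3 * est0$se, 0.06))

  # an environment built to absorb part of the genetic signal lowers the
  # adjusted estimate
  env_conf <- tibble::tibble(
    subject_id = co$genotypes$subject_ids,
    exposure = 0.8 * scale(co$truth$genetic_values)[, 1] +
      0.6 * rnorm(600))
  est1 <- estimate_h2(g, idx, env = env_conf, n_boot = 0, seed = 3)
  expect_lt(est1$adjusted_h2, est1$h2 - 0.05)

  # zero-variance environment columns change nothing
  env0 <- tibble::tibble(subject_id = co$genotypes$subject_ids, flat = 1)
  est2 <- estimate_h2(g, idx, env = env0, n_boot = 0, seed = 3)
  expect_equal(est2$adjusted_h2, est2$h2)
  adj <- gxe_adjustment(est0)
  expect_named(adj, c("h2", "adjusted_h2", "difference", "se"))
})

test_that("tidy and glance methods expose the estimate as tibbles", {
  co <- h2_cohort(0.4, seed = 45, n = 400)
  idx <- empirical_index(co$phenotypes)
  g <- subset_genotypes(co$genotypes,
                        snps = unique(unlist(co$truth$blocks$snp_ids)))
  est <- estimate_h2(g, idx, n_boot = 10, seed = 1)
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_true("h2" %in% td$term)
  gl <- glance(est)
  expect_equal(gl$n, 400)
  expect_s3_class(autoplot(est), "ggplot")
})

test_that("environment sets recover planted environment clusters", {
  co <- simulate_cohort(n_subjects = 500, n_snps = 20, n_blocks = 0,
                        n_clusters = 3, seed = 46)
  # 8 variables: four strongly tied to cluster 2, four null
  spec <- tibble::tibble(
    name = c(paste0("exp", 1:4), paste0("nul", 1:4)),
    cluster = c(2L, 2L, 2L, 2L, NA, NA, NA, NA),
    target_r = c(0.85, 0.85, 0.8, 0.8, 0, 0, 0, 0),
    type = "continuous")
  env <- generate_environment(co$truth, spec, seed = 46)
  sw <- suppressWarnings(env_sets(env, k_range = 2:4, n_restarts = 3,
                                  seed = 46))
  expect_true(all(grepl("^E_\\d+_\\d+$", sw$catalog$label)))
  cl2 <- co$phenotypes$subject_id[co$truth$cluster_assignments == 2]
  js <- vapply(sw$catalog$subject_ids, jaccard, numeric(1), b = cl2)
  expect_gt(max(js), 0.7)
  # the exposed-cluster set is built from exposure variables only
  expect_true(all(sw$catalog$feature_ids[[which.max(js)]] %in%
                    paste0("exp", 1:4)))
})

test_that("a whole-cohort environment stratum reproduces the marginal relations", {
  co <- linked_cohort(seed = 47)
  ssw <- snp_sets(co$genotypes, k_range = 2:4, n_restarts = 2, seed = 47)
  tsw <- temperament_sets(co$phenotypes, k_range = 2:4, n_restarts = 2,
                          consensus = FALSE, seed = 47)
  marginal <- relation_screen(ssw$catalog, tsw$catalog, N = 300)
  env_cat <- tibble::tibble(label = "E_1_1",
                            subject_ids = list(co$genotypes$subject_ids),
                            feature_ids = list("env1"))
  med <- mediated_relations(ssw$catalog, tsw$catalog, env_cat, N = 300)
  expect_setequal(paste(med$snp_set_label, med$temp_set_label),
                  paste(marginal$snp_set_label, marginal$temp_set_label))
  expect_false(any(med$mediated_only))
  # undersized strata are skipped with a message
  env_small <- tibble::tibble(label = "E_1_2",
                              subject_ids = list(co$genotypes$subject_ids[1:5]),
                              feature_ids = list("env1"))
  expect_message(
    out <- mediated_relations(ssw$catalog, tsw$catalog, env_small, N = 300),
    "skipped")
  expect_equal(nrow(out), 0)
})
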