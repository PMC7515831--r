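test_that("generated cohorts are seed-deterministic and planted blocks are faithful", {
  co1 <- simulate_cohort(n_subjects = 200, n_snps = 500, n_blocks = 3,
                         seed = 7)
  co2 <- simulate_cohort(n_subjects = 200, n_snps = 500, n_blocks = 3,
                         seed = 7)
  expect_identical(co1$genotypes$values, co2$genotypes$values)
  expect_identical(co1$phenotypes, co2$phenotypes)
  expect_identical(co1$environment, co2$environment)

  # brute-force scan over planted coordinates: cell-level fidelity ~0.9
  # (modulo the 2% missing calls)
  tr <- co1$truth
  for (b in seq_len(nrow(tr$blocks))) {
    si <- match(tr$blocks$subject_ids[[b]], co1$genotypes$subject_ids)
    sj <- match(tr$blocks$snp_ids[[b]], co1$genotypes$snp_meta$snp_id)
    cells <- co1$genotypes$values[si, sj]
    pat <- matrix(tr$blocks$allele_pattern[[b]], length(si), length(sj),
                  byrow = TRUE)
    fid <- mean(cells == pat, na.rm = TRUE)
    expect_gt(fid, 0.85)
  }
})

test_that("missing_rate 0 produces no missing calls and missingness scales with the rate", {
  g0 <- generate_genotypes(100, 50, missing_rate = 0, seed = 1)$genotypes
  expect_false(anyNA(g0$values))
  g5 <- generate_genotypes(400, 200, missing_rate = 0.05, seed = 1)$genotypes
  expect_gt(mean(is.na(g5$values)), 0.04)
  expect_lt(mean(is.na(g5$values)), 0.06)
  expect_error(generate_genotypes(50, 10, missing_rate = 0.5, seed = 1),
               "missing_rate")
})

test_that("background allele frequencies match the configured MAF", {
  gen <- generate_genotypes(600, 300, blocks = NULL, missing_rate = 0,
                            fst = 0, seed = 3)
  af <- colMeans(gen$genotypes$values) / 2
  maf <- gen$truth$maf
  sd3 <- 3 * sqrt(maf * (1 - maf) / (2 * 600))
  expect_gt(mean(abs(af - maf) <= sd3), 0.98)
})

test_that("phenotypes equal templates in the zero-noise limit and h2 bookkeeping hits the target", {
  co <- simulate_cohort(n_subjects = 90, n_snps = 20, n_blocks = 0,
                        n_clusters = 3, noise_sd = 1e-9, seed = 2)
  temp <- as.matrix(co$phenotypes[, tci_subscales("temperament")])
  tmpl <- default_templates()
  for (c in 1:3) {
    members <- co$truth$cluster_assignments == c
    expect_equal(colMeans(temp[members, , drop = FALSE]),
                 tmpl[c, ], tolerance = 1e-6, ignore_attr = TRUE)
  }

  em <- tibble::tibble(block_id = sprintf("B%02d", 1:5), trait = "index",
                       beta = 1)
  co2 <- simulate_cohort(n_subjects = 1000, n_snps = 150, n_blocks = 5,
                         n_clusters = 1, subjects_per_block = 50,
                         snps_per_block = 10, effect_map = em,
                         h2_target = 0.5, genetic_model = "additive",
                         seed = 4)
  expect_gt(co2$truth$h2_bookkeeping$h2_realized, 0.48)
  expect_lt(co2$truth$h2_bookkeeping$h2_realized, 0.52)
})

test_that("an infeasible h2 target errors with the maximum achievable value", {
  em <- tibble::tibble(block_id = "B01", trait = "index", beta = 0.5)
  expect_error(
    simulate_cohort(n_subjects = 300, n_snps = 60, n_blocks = 1,
                    n_clusters = 3, effect_map = em, h2_target = 0.6,
                    genetic_model = "additive", seed = 1),
    "maximum achievable")
})

test_that("cluster median-split signatures reproduce the generating templates", {
  ok <- 0L
  tmpl <- default_templates()
  for (s in 1:5) {
    co <- simulate_cohort(n_subjects = 300, n_snps = 20, n_blocks = 0,
                          n_clusters = 3, noise_sd = 7.5, seed = s)
    ids <- co$phenotypes$subject_id
    good <- TRUE
    for (c in 1:3) {
      sig <- set_signature(ids[co$truth$cluster_assignments == c],
                           co$phenotypes)
      want <- ifelse(tmpl[c, ] > 50, "high",
                     ifelse(tmpl[c, ] < 50, "low", "unmarked"))
      marked <- want != "unmarked"
      if (!all(sig$flags[marked] == want[marked])) good <- FALSE
      if (sig$profile != rownames(tmpl)[c]) good <- FALSE
    }
    ok <- ok + good
  }
  expect_gte(ok, 4L)
})

test_that("environment variables realize their correlation targets", {
  co <- simulate_cohort(n_subjects = 1000, n_snps = 20, n_blocks = 0,
                        n_clusters = 3, seed = 11)
  spec <- tibble::tibble(
    name = c("null1", "null2", "income_low", "rural"),
    cluster = c(NA, NA, 2L, 2L),
    target_r = c(0, 0, 0.3, -0.25),
    type = c("continuous", "continuous", "continuous", "binary"))
  env <- generate_environment(co$truth, spec, seed = 11)
  z <- as.numeric(co$truth$cluster_assignments == 2)
  expect_lt(abs(cor(env$null1, z)), 0.1)
  expect_lt(abs(cor(env$null2, z)), 0.1)
  expect_gt(cor(env$income_low, z), 0.25)
  expect_lt(cor(env$income_low, z), 0.35)
  expect_lt(cor(env$rural, z), 0)          # binary keeps the sign
  expect_error(
    generate_environment(co$truth,
                         tibble::tibble(name = "bad", cluster = 1L,
                                        target_r = 1.2,
                                        type = "continuous"),
                         seed = 1),
    "bad")
})

test_that("PLINK trio and TSV round-trips preserve genotypes", {
  g <- toy_genotypes(37, 11, seed = 5)
  g$values[cbind(c(1, 5, 20), c(2, 3, 11))] <- NA_integer_
  dir <- withr::local_tempdir()
  write_plink(g, file.path(dir, "x"))
  g2 <- read_plink(file.path(dir, "x"))
  expect_identical(unname(g$values), unname(g2$values))
  expect_identical(g$snp_meta$snp_id, g2$snp_meta$snp_id)
  write_genotypes_tsv(g, file.path(dir, "x.tsv"))
  g3 <- read_genotypes_tsv(file.path(dir, "x.tsv"))
  expect_identical(unname(g$values), unname(g3$values))
})

test_that("write_cohort emits the full artifact set with reloadable truth", {
  co <- simulate_cohort(n_subjects = 60, n_snps = 30, n_blocks = 2,
                        subjects_per_block = 15, snps_per_block = 5,
                        seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "cohort.bed", "cohort.bim", "cohort.fam", "phenotypes.tsv",
    "covariates.tsv", "environment.tsv", "truth.json")))))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$n_subjects, 60)
  expect_length(tr$blocks, 2)
  expect_identical(sort(unlist(tr$blocks[[1]]$subject_ids)),
                   sort(co$truth$blocks$subject_ids[[1]]))
})

test_that("replicate cohorts share block SNPs but draw fresh subjects", {
  co1 <- linked_cohort(seed = 3)
  co2 <- simulate_replicate_cohort(co1, seed = 104)
  expect_identical(co1$truth$blocks$snp_ids, co2$truth$blocks$snp_ids)
  subj_j <- jaccard(co1$truth$blocks$subject_ids[[1]],
                    co2$truth$blocks$subject_ids[[1]])
  expect_lt(subj_j, 0.6)
  expect_false(identical(co1$genotypes$values, co2$genotypes$values))
})
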