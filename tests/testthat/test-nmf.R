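test_that("multiplicative updates decrease the objective monotonically and fit exact low rank", {
  set.seed(1)
  w <- matrix(runif(40), 20, 2); h <- matrix(runif(30), 2, 15)
  x <- w %*% h
  fit <- suppressWarnings(
    nmf_factorize(x, 2, n_restarts = 3, max_iter = 500, tol = 1e-12,
                  seed = 1))
  expect_true(all(diff(fit$trace) <= 1e-8))
  expect_lt(fit$error / norm(x, "F"), 1e-3)

  # rank-1 outer product is reconstructed essentially exactly
  x1 <- outer(runif(25), runif(12))
  fit1 <- nmf_factorize(x1, 1, n_restarts = 2, max_iter = 2000,
                        tol = 1e-14, seed = 2)
  expect_lt(fit1$error, 1e-6)
})

test_that("factorization is seed-deterministic and block-diagonal input is classified perfectly", {
  x <- matrix(0.01, 40, 30)
  x[1:20, 1:15] <- 1
  x[21:40, 16:30] <- 1
  f1 <- nmf_factorize(x, 2, seed = 5)
  f2 <- nmf_factorize(x, 2, seed = 5)
  expect_identical(f1$W, f2$W)
  a <- max.col(f1$W)
  expect_length(unique(a[1:20]), 1L)
  expect_length(unique(a[21:40]), 1L)
  expect_false(a[1] == a[21])
  expect_error(nmf_factorize(-x, 2, seed = 1), "non-negative")
})

test_that("set labels follow the <prefix>_k_i convention and cohesion is 1 on noiseless blocks", {
  gen <- generate_genotypes(120, 60,
    blocks = plant_blocks(120, 60, 2, subjects_per_block = 30,
                          snps_per_block = 10, seed = 1),
    missing_rate = 0, fidelity = 1, maf_range = c(0.05, 0.15), seed = 1)
  sw <- snp_sets(gen$genotypes, k_range = 13, n_restarts = 2, seed = 1)
  expect_true(all(grepl("^G_13_\\d+$", sw$catalog$label)))
  expect_identical(sw$catalog$order, seq_len(nrow(sw$catalog)))
  # order is descending cohesion
  expect_true(all(diff(sw$catalog$cohesion) <= 1e-12))
  # the sets recovering the noiseless planted blocks are fully cohesive
  for (b in 1:2) {
    i <- which.max(vapply(seq_len(nrow(sw$catalog)), function(i)
      jaccard(sw$catalog$subject_ids[[i]],
              gen$truth$blocks$subject_ids[[b]]), numeric(1)))
    expect_gt(sw$catalog$cohesion[i], 0.97)
  }
})

test_that("extraction is invariant to simultaneous subject and SNP permutation", {
  gen <- generate_genotypes(100, 80,
    blocks = plant_blocks(100, 80, 2, subjects_per_block = 25,
                          snps_per_block = 12, seed = 2),
    missing_rate = 0, seed = 2)
  sw <- snp_sets(gen$genotypes, k_range = 3, n_restarts = 2, seed = 9)
  set.seed(3)
  pi_s <- sample(100); pi_m <- sample(80)
  gp <- subset_genotypes(gen$genotypes, subjects = pi_s, snps = pi_m)
  swp <- snp_sets(gp, k_range = 3, n_restarts = 2, seed = 9)
  # random initialization is not itself permuted, so factors match up to
  # optimization noise: the planted blocks must be recovered equivalently
  expect_equal(nrow(sw$catalog), nrow(swp$catalog))
  for (b in 1:2) {
    bs <- gen$truth$blocks$subject_ids[[b]]
    best1 <- sw$catalog$subject_ids[[
      which.max(vapply(sw$catalog$subject_ids, jaccard, numeric(1), b = bs))]]
    best2 <- swp$catalog$subject_ids[[
      which.max(vapply(swp$catalog$subject_ids, jaccard, numeric(1), b = bs))]]
    expect_gte(jaccard(best1, best2), 0.9)
  }
})

test_that("near-duplicate sets are dropped but the best block match survives", {
  gen <- generate_genotypes(150, 100,
    blocks = plant_blocks(150, 100, 2, subjects_per_block = 40,
                          snps_per_block = 15, seed = 4),
    missing_rate = 0, seed = 4)
  sw <- snp_sets(gen$genotypes, k_range = 2:6, n_restarts = 2, seed = 4)
  expect_gt(length(sw$dropped), 0)    # the same blocks recur across ranks
  for (b in 1:2) expect_gt(block_recovery(sw$catalog, gen$truth, b), 0.8)
  # no two retained sets are near-duplicates on both axes
  n <- nrow(sw$catalog)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    js <- jaccard(sw$catalog$subject_ids[[i]], sw$catalog$subject_ids[[j]])
    jf <- jaccard(sw$catalog$feature_ids[[i]], sw$catalog$feature_ids[[j]])
    expect_false(js > 0.95 && jf > 0.95)
  }
})

test_that("the elbow criterion recovers the planted number of profiles", {
  picks <- vapply(1:3, function(s) {
    co <- simulate_cohort(n_subjects = 300, n_snps = 20, n_blocks = 0,
                          n_clusters = 3, seed = s)
    sw <- temperament_sets(co$phenotypes, k_range = 2:8, n_restarts = 2,
                           consensus = FALSE, seed = s)
    select_superset_rank(sw)$k
  }, numeric(1))
  expect_true(all(picks == 3))
  picks2 <- vapply(1:3, function(s) {
    co <- simulate_cohort(n_subjects = 300, n_snps = 20, n_blocks = 0,
                          n_clusters = 2, seed = s)
    sw <- temperament_sets(co$phenotypes, k_range = 2:8, n_restarts = 2,
                           consensus = FALSE, seed = s)
    select_superset_rank(sw)$k
  }, numeric(1))
  expect_true(all(picks2 == 2))
})

test_that("consensus matrices are valid and stability criteria break ties to the smallest rank", {
  co <- simulate_cohort(n_subjects = 120, n_snps = 20, n_blocks = 0,
                        n_clusters = 3, seed = 6)
  sw <- temperament_sets(co$phenotypes, k_range = 2:4, n_restarts = 2,
                         consensus = TRUE, consensus_restarts = 8,
                         seed = 6)
  for (cm in sw$consensus$consensus) {
    expect_true(all(cm >= 0 & cm <= 1))
    expect_equal(cm, t(cm))
    expect_true(all(diag(cm) == 1))
  }
  expect_true(all(sw$consensus$rho_coph >= -1 & sw$consensus$rho_coph <= 1))
  tied <- tibble::tibble(k = c(3, 2, 5), rho_coph = c(1, 1, 1))
  expect_message(sel <- select_superset_rank(tied, criterion = "stability"),
                 "tie")
  expect_equal(sel$k, 2)
  # super-set assignment: sets from the same planted cluster co-assign
  sel2 <- select_superset_rank(sw, sw$catalog,
                               data = {
                                 m <- as.matrix(
                                   co$phenotypes[, tci_subscales("temperament")])
                                 rownames(m) <- co$phenotypes$subject_id
                                 m
                               })
  expect_length(sel2$superset, nrow(sw$catalog))
})

test_that("median-split signatures behave at the degenerate and antisymmetric limits", {
  # self-reference: with a symmetric unimodal score distribution the
  # whole-cohort mean sits at the median, so no flag marks
  co_sym <- simulate_cohort(n_subjects = 200, n_snps = 20, n_blocks = 0,
                            n_clusters = 1, seed = 8)
  sig_all <- set_signature(co_sym$phenotypes$subject_id, co_sym$phenotypes)
  expect_true(all(sig_all$flags == "unmarked"))

  co <- simulate_cohort(n_subjects = 200, n_snps = 20, n_blocks = 0,
                        n_clusters = 3, seed = 8)
  ids <- co$phenotypes$subject_id[co$truth$cluster_assignments == 2]
  sig <- set_signature(ids, co$phenotypes)
  flipped <- co$phenotypes
  flipped$NS1 <- -flipped$NS1
  sigf <- set_signature(ids, flipped)
  swap <- c(high = "low", low = "high", unmarked = "unmarked")
  expect_identical(unname(sigf$flags["NS1"]), unname(swap[sig$flags["NS1"]]))

  tiny <- set_signature(co$phenotypes$subject_id[1:2], co$phenotypes)
  expect_true(tiny$low_confidence)
})
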