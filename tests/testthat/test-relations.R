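test_that("hypergeometric enrichment matches closed forms and boundary behavior", {
  # worked example: N=20, both sets of 5, complete overlap
  e <- hypergeom_relation(1:5, 1:5, 20)
  expect_equal(e$p_hyper, 1 / choose(20, 5) * choose(15, 0) * choose(5, 5)
               * choose(20, 5) / choose(20, 5))
  expect_equal(e$p_hyper, 1 / 15504, tolerance = 1e-12)
  # zero overlap has probability-1 upper tail
  expect_equal(hypergeom_relation(1:4, 5:9, 30)$k_overlap, 0)
  expect_equal(hypergeom_relation(1:4, 5:9, 30)$p_hyper, 1)
})

test_that("health flags mark exactly floor(N/10) subjects and are rank-invariant", {
  set.seed(5)
  n <- 137
  phen <- tibble::tibble(subject_id = sprintf("S%04d", 1:n))
  for (s in tci_subscales("character")) phen[[s]] <- rnorm(n, 50, 10)
  hf <- health_flags(phen)
  expect_equal(sum(hf$well_being), floor(n / 10))
  expect_equal(sum(hf$ill_being), floor(n / 10))

  # a common positive rescaling is monotone in both underlying scores
  phen2 <- phen
  for (s in tci_subscales("character")) phen2[[s]] <- 1.7 * phen2[[s]]
  hf2 <- health_flags(phen2)
  expect_identical(hf$ill_being, hf2$ill_being)
  expect_identical(hf$well_being, hf2$well_being)

  # degenerate ties: identical scores flag the first floor(N/10)
  phen3 <- phen
  for (s in tci_subscales("character")) phen3[[s]] <- 50
  expect_message(hf3 <- health_flags(phen3), "ties")
  expect_equal(which(hf3$well_being), seq_len(floor(n / 10)))
  expect_error(health_flags(phen[1:5, ]), "at least 10")
})

test_that("the relation screen retains planted block-profile links and respects thresholds", {
  co <- linked_cohort(seed = 17)
  ssw <- snp_sets(co$genotypes, k_range = 2:5, n_restarts = 2, seed = 17)
  tsw <- temperament_sets(co$phenotypes, k_range = 2:5, n_restarts = 2,
                          consensus = FALSE, seed = 17)
  rel <- relation_screen(ssw$catalog, tsw$catalog, N = 300,
                         health = health_flags(co$phenotypes))
  expect_gt(nrow(rel), 0)
  expect_true(all(rel$p_hyper < 1e-3))
  expect_true(all(rel$k_overlap <= pmin(rel$n_a, rel$n_b)))
  expect_true(all(is.na(rel$wb_joint) | (rel$wb_joint >= 0 & rel$wb_joint <= 1)))
  expect_equal(nrow(relation_screen(ssw$catalog, tsw$catalog, N = 300,
                                    p_threshold = 0)), 0)
})

test_that("permutation p-values hit the extreme-case floor and track the hypergeometric ranking", {
  co <- linked_cohort(seed = 23)
  ssw <- snp_sets(co$genotypes, k_range = 2:5, n_restarts = 2, seed = 23)
  tsw <- temperament_sets(co$phenotypes, k_range = 2:5, n_restarts = 2,
                          consensus = FALSE, seed = 23)
  rel <- relation_screen(ssw$catalog, tsw$catalog, N = 300,
                         p_threshold = 0.05)
  rel <- permutation_null(rel, ssw$catalog, tsw$catalog,
                          co$genotypes$subject_ids, R = 500, seed = 1)
  expect_true(all(rel$p_perm >= 1 / 501))
  # strongly dependent pairs sit at the floor
  expect_true(any(rel$p_perm == 1 / 501))
  ok <- rel$p_hyper > 0
  if (sum(ok) > 10) {
    expect_gt(cor(rank(rel$p_hyper[ok]), rank(rel$p_perm[ok])), 0.5)
  }
  expect_error(permutation_null(rel, ssw$catalog, tsw$catalog,
                                co$genotypes$subject_ids, R = 10), "100")
})

test_that("network construction finds star hubs and leaves disjoint catalogs unconnected", {
  subjects <- sprintf("S%03d", 1:200)
  star <- tibble::tibble(
    label = c("hub", paste0("leaf", 1:6), "iso"),
    subject_ids = c(list(subjects[1:60]),
                    lapply(0:5, function(i) subjects[(i * 10 + 1):(i * 10 + 10)]),
                    list(subjects[150:160])),
    feature_ids = c(list(paste0("rs", 1:30)),
                    lapply(1:6, function(i) paste0("x", i, "_", 1:5)),
                    list(paste0("y", 1:5))))
  net <- build_network(star, n_subjects = 200, n_snps = 500,
                       p_threshold = 1e-3)
  hubs <- find_hubs(net)
  expect_true(hubs$is_hub[hubs$label == "hub"])
  expect_equal(hubs$degree[hubs$label == "hub"], 6)
  expect_equal(hubs$degree[hubs$label == "iso"], 0)

  disjoint <- tibble::tibble(
    label = paste0("s", 1:4),
    subject_ids = lapply(0:3, function(i) subjects[(i * 50 + 1):(i * 50 + 20)]),
    feature_ids = lapply(0:3, function(i) paste0("r", i, "_", 1:10)))
  net0 <- build_network(disjoint, n_subjects = 200, n_snps = 500)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(igraph::count_components(net0$graph), 4)
})

test_that("trait pipelines mark composite traits fed by several profiles", {
  temp_catalog <- tibble::tibble(
    label = c("T_3_1", "T_3_2", "T_3_3"),
    signature = list(
      c(NS1 = "high", NS2 = "high", HA1 = "unmarked", RD1 = "low",
        PS1 = "low"),
      c(NS1 = "high", NS2 = "unmarked", HA1 = "high", RD1 = "high",
        PS1 = "unmarked"),
      c(NS1 = "low", NS2 = "low", HA1 = "low", RD1 = "high",
        PS1 = "high")),
    profile = c("Antisocial", "Sensitive", "Reliable"))
  # pad signatures to the full subscale set
  temp_catalog$signature <- lapply(temp_catalog$signature, function(s) {
    full <- setNames(rep("unmarked", 12), tci_subscales("temperament"))
    full[names(s)] <- s
    full
  })
  edges <- tibble::tibble(
    snp_set_label = c("G_5_1", "G_5_2", "G_7_1"),
    temp_set_label = c("T_3_1", "T_3_2", "T_3_3"))
  pipes <- trait_pipelines(edges, temp_catalog)
  ns_high <- pipes[pipes$trait == "NS" & pipes$direction == "high", ]
  expect_equal(ns_high$n_relations, 2)
  expect_true(ns_high$composite)       # Antisocial + Sensitive converge
  ps_high <- pipes[pipes$trait == "PS" & pipes$direction == "high", ]
  expect_false(ps_high$composite)
  empty <- trait_pipelines(edges[0, ], temp_catalog)
  expect_true(all(empty$n_relations == 0))
})

test_that("joint genotype+phenotype grouping separates planted ill-being at least as well as phenotype alone", {
  em <- tibble::tibble(block_id = "B01",
                       trait = c(paste0("SD", 1:5), paste0("CO", 1:5)),
                       beta = -10)
  co <- simulate_cohort(n_subjects = 300, n_snps = 200, n_blocks = 3,
                        n_clusters = 3, link_blocks = TRUE,
                        effect_map = em, genetic_model = "block",
                        subjects_per_block = 60, snps_per_block = 15,
                        seed = 31)
  hf <- health_flags(co$phenotypes)
  ib_score <- hf$sd_total + hf$co_total
  cl <- factor(co$truth$cluster_assignments)
  in_block <- co$genotypes$subject_ids %in% co$truth$blocks$subject_ids[[1]]
  f_pheno <- summary(aov(ib_score ~ cl))[[1]]$`F value`[1]
  f_joint <- summary(aov(ib_score ~ cl * in_block))[[1]]$`F value`[1:3]
  # adding genotype grouping explains additional ill-being variance
  expect_gt(sum(f_joint, na.rm = TRUE), f_pheno)
})

test_that("switch features flag SNPs that split a set by well-being", {
  set.seed(2)
  n <- 200
  g <- toy_genotypes(n, 10, maf = 0.3, seed = 2)
  phen <- tibble::tibble(subject_id = g$subject_ids)
  for (s in tci_subscales("character")) phen[[s]] <- rnorm(n, 50, 5)
  carrier <- g$values[, 1] == 2
  for (s in paste0("SD", 1:5)) phen[[s]] <- phen[[s]] + 15 * carrier
  hf <- health_flags(phen)
  set_row <- tibble::tibble(label = "G_2_1",
                            subject_ids = list(g$subject_ids),
                            feature_ids = list(g$snp_meta$snp_id),
                            modal_genotype = list(rep(2L, 10)))
  sf <- switch_features(set_row, g, hf)
  expect_true(sf$switch[1])
  expect_lt(mean(sf$switch[-1]), 0.5)
})
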