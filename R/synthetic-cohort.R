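## Synthetic cohort generator
##
## Emulates the statistical structure the uncovering analysis assumes:
## overlapping subject x SNP biclusters with shared allele patterns,
## subject clusters with distinct temperament subscale profiles, planted
## set-level genotype-phenotype associations, sex and 2-subpopulation
## confounding, environment variables correlated with cluster membership,
## and a target SNP heritability with analytic variance bookkeeping.

#' TCI subscale names
#'
#' Twelve temperament subscales (Novelty Seeking NS1-4, Harm Avoidance
#' HA1-4, Reward Dependence RD1-3, Persistence PS1) and thirteen character
#' subscales (Self-directedness SD1-5, Cooperativeness CO1-5,
#' Self-transcendence ST1-3).
#'
#' @param which `"temperament"`, `"character"` or `"all"`.
#' @return Character vector of subscale names.
#' @export
tci_subscales <- function(which = c("temperament", "character", "all")) {
  which <- match.arg(which)
  temp <- c(paste0("NS", 1:4), paste0("HA", 1:4), paste0("RD", 1:3), "PS1")
  char <- c(paste0("SD", 1:5), paste0("CO", 1:5), paste0("ST", 1:3))
  switch(which, temperament = temp, character = char, all = c(temp, char))
}

#' Default temperament profile templates
#'
#' Mean subscale vectors for the three classical temperament profiles on a
#' 0-100 percentile-like scale centred at 50. Reliable: high Reward
#' Dependence and Persistence, low Novelty Seeking and Harm Avoidance.
#' Antisocial: high Novelty Seeking, low Reward Dependence and Persistence.
#' Sensitive: high Harm Avoidance, Novelty Seeking and Reward Dependence.
#'
#' @param gap half-distance between a "high" and a "low" template mean
#'   (default 15 scale points).
#' @return A 3 x 12 numeric matrix, rows named by profile.
#' @export
default_templates <- function(gap = 15) {
  sub <- tci_subscales("temperament")
  base <- matrix(50, 3, length(sub), dimnames = list(
    c("Reliable", "Antisocial", "Sensitive"), sub))
  hi <- function(p, s) base[p, s] <<- 50 + gap
  lo <- function(p, s) base[p, s] <<- 50 - gap
  ns <- paste0("NS", 1:4); ha <- paste0("HA", 1:4); rd <- paste0("RD", 1:3)
  hi("Reliable", rd); hi("Reliable", "PS1"); lo("Reliable", ns); lo("Reliable", ha)
  hi("Antisocial", ns); lo("Antisocial", rd); lo("Antisocial", "PS1")
  hi("Sensitive", ha); hi("Sensitive", ns); hi("Sensitive", rd)
  base
}

#' Plant subject x SNP biclusters
#'
#' Draws block memberships for a cohort. Blocks may overlap in subjects
#' and/or SNPs; each block carries a per-SNP dominant genotype code (the
#' shared allele pattern its member subjects exhibit).
#'
#' @param n_subjects,n_snps cohort dimensions.
#' @param n_blocks number of planted blocks.
#' @param subjects_per_block,snps_per_block block sizes (recycled).
#' @param allele_code dominant genotype code for planted cells, in
#'   `{0,1,2}` (default 2, homozygous minor: maximally distinct from a
#'   low-MAF background).
#' @param overlap if `TRUE`, blocks are drawn independently and may
#'   overlap; if `FALSE`, memberships are disjoint.
#' @param cluster_link optional integer vector (recycled) giving, per
#'   block, the phenotype cluster its subjects are preferentially drawn
#'   from, or `NA` for no link; used with `link_strength`.
#' @param cluster_assignments required when `cluster_link` is set: integer
#'   cluster id per subject.
#' @param link_strength fraction of block subjects drawn from the linked
#'   cluster (default 0.9).
#' @param seed integer seed.
#' @return Tibble with one row per block: `block_id`, `subject_ids`,
#'   `snp_ids` (list-columns), `allele_pattern` (list), `cluster_link`.
#' @export
plant_blocks <- function(n_subjects, n_snps, n_blocks,
                         subjects_per_block = max(10L, round(n_subjects / 5)),
                         snps_per_block = max(5L, round(n_snps / 10)),
                         allele_code = 2L, overlap = FALSE,
                         cluster_link = NA_integer_,
                         cluster_assignments = NULL,
                         link_strength = 0.9, seed = 1L) {
  set.seed(child_seed(seed, "blocks"))
  spb <- rep_len(subjects_per_block, n_blocks)
  mpb <- rep_len(snps_per_block, n_blocks)
  code <- rep_len(allele_code, n_blocks)
  link <- rep_len(cluster_link, n_blocks)
  subj_pool <- seq_len(n_subjects)
  snp_pool <- seq_len(n_snps)
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    if (!is.na(link[b])) {
      if (is.null(cluster_assignments)) {
        stop("cluster_link requires cluster_assignments")
      }
      in_cl <- which(cluster_assignments == link[b])
      n_in <- min(length(in_cl), round(link_strength * spb[b]))
      subj <- c(sample(in_cl, n_in),
                sample(setdiff(subj_pool, in_cl), spb[b] - n_in))
    } else if (overlap) {
      subj <- sample(subj_pool, spb[b])
    } else {
      avail <- setdiff(subj_pool, unlist(lapply(rows, `[[`, "subject_idx")))
      if (length(avail) < spb[b]) stop("not enough subjects for disjoint blocks")
      subj <- sample(avail, spb[b])
    }
    if (overlap || !is.na(link[b])) {
      snps <- sample(snp_pool, mpb[b])
    } else {
      avail <- setdiff(snp_pool, unlist(lapply(rows, `[[`, "snp_idx")))
      if (length(avail) < mpb[b]) stop("not enough SNPs for disjoint blocks")
      snps <- sample(avail, mpb[b])
    }
    rows[[b]] <- list(subject_idx = sort(subj), snp_idx = sort(snps),
                      pattern = rep(code[b], mpb[b]))
  }
  tibble::tibble(
    block_id = sprintf("B%02d", seq_len(n_blocks)),
    subject_ids = lapply(rows, function(r) sprintf("S%04d", r$subject_idx)),
    snp_ids = lapply(rows, function(r) sprintf("rs%05d", r$snp_idx)),
    allele_pattern = lapply(rows, `[[`, "pattern"),
    cluster_link = link
  )
}

#' Generate genotypes with planted biclusters and population structure
#'
#' Background genotypes are drawn under Hardy-Weinberg equilibrium per SNP
#' within each of two subpopulations whose allele frequencies diverge under
#' a Balding-Nichols model with the given Fst. Inside each planted block,
#' member subjects carry the block's allele pattern at member SNPs with
#' probability `fidelity`; the remaining cells revert to background.
#' Missingness is completely at random.
#'
#' @param n_subjects,n_snps cohort dimensions.
#' @param blocks tibble from [plant_blocks()] (may be zero-row).
#' @param missing_rate fraction of calls set missing, in `[0, 0.2)`.
#' @param fst Balding-Nichols divergence between the two subpopulations.
#' @param fidelity probability a planted cell carries the block pattern.
#' @param maf_range range the per-SNP ancestral minor-allele frequencies
#'   are drawn from.
#' @param seed integer seed.
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (a `cohort_truth` carrying blocks, covariates, MAFs and the seed).
#' @export
generate_genotypes <- function(n_subjects, n_snps, blocks = NULL,
                               missing_rate = 0.02, fst = 0.01,
                               fidelity = 0.9, maf_range = c(0.05, 0.5),
                               seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 0.2) {
    stop("missing_rate must be in [0, 0.2)")
  }
  assert_fraction(fidelity, "fidelity")
  set.seed(child_seed(seed, "genotypes"))
  subj_ids <- sprintf("S%04d", seq_len(n_subjects))
  snp_ids <- sprintf("rs%05d", seq_len(n_snps))
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  subpop <- rep(1:2, length.out = n_subjects)
  # Balding-Nichols subpopulation frequencies around the ancestral MAF
  p_pop <- matrix(NA_real_, 2, n_snps)
  for (k in 1:2) {
    if (fst > 0) {
      a <- maf * (1 - fst) / fst
      b <- (1 - maf) * (1 - fst) / fst
      p_pop[k, ] <- pmin(pmax(rbeta(n_snps, a, b), 0.001), 0.999)
    } else {
      p_pop[k, ] <- maf
    }
  }
  p_subj <- p_pop[subpop, , drop = FALSE]
  v <- matrix(rbinom(n_subjects * n_snps, 2L, p_subj), n_subjects, n_snps)
  # overlay planted blocks; earlier block_id wins on conflicting cells
  conflicts <- 0L
  claimed <- NULL
  if (!is.null(blocks) && nrow(blocks)) {
    claimed <- matrix(FALSE, n_subjects, n_snps)
    for (b in order(blocks$block_id)) {
      si <- match(blocks$subject_ids[[b]], subj_ids)
      sj <- match(blocks$snp_ids[[b]], snp_ids)
      if (anyNA(si) || anyNA(sj)) stop("block members outside cohort bounds")
      pat <- blocks$allele_pattern[[b]]
      keep <- matrix(runif(length(si) * length(sj)) < fidelity,
                     length(si), length(sj))
      already <- claimed[si, sj, drop = FALSE]
      conflicts <- conflicts + sum(keep & already)
      keep <- keep & !already
      patm <- matrix(pat, length(si), length(sj), byrow = TRUE)
      sub <- v[si, sj, drop = FALSE]
      sub[keep] <- patm[keep]
      v[si, sj] <- sub
      claimed[si, sj] <- already | keep
    }
    if (conflicts > 0) {
      message("generate_genotypes: ", conflicts,
              " overlapping planted cells resolved by block_id order")
    }
  }
  if (missing_rate > 0) {
    v[runif(length(v)) < missing_rate] <- NA_integer_
  }
  g <- genotype_matrix(
    v,
    snp_meta = tibble::tibble(snp_id = snp_ids, chrom = 1L,
                              pos = seq_len(n_snps), allele1 = "A",
                              allele2 = "B"),
    subject_ids = subj_ids
  )
  truth <- structure(list(
    blocks = blocks %||% tibble::tibble(),
    maf = stats::setNames(maf, snp_ids),
    covariates = tibble::tibble(
      subject_id = subj_ids,
      sex = rep_len(c(0L, 1L), n_subjects),
      subpop = subpop
    ),
    fidelity = fidelity, fst = fst, missing_rate = missing_rate,
    n_subjects = n_subjects, n_snps = n_snps,
    n_conflicts = conflicts, seed = seed
  ), class = "cohort_truth")
  list(genotypes = g, truth = truth)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "<cohort_truth> %d subjects, %d SNPs, %d planted blocks (seed %d)\n",
    x$n_subjects, x$n_snps,
    if (is.null(x$blocks)) 0L else nrow(x$blocks), x$seed))
  invisible(x)
}

#' Assign subjects to phenotype clusters
#'
#' @param truth a `cohort_truth`.
#' @param n_clusters number of temperament clusters.
#' @param seed integer seed.
#' @return The truth object with `cluster_assignments` added (integer per
#'   subject, balanced random assignment).
#' @export
assign_clusters <- function(truth, n_clusters = 3L, seed = 1L) {
  set.seed(child_seed(seed, "clusters"))
  n <- truth$n_subjects
  truth$cluster_assignments <- sample(rep_len(seq_len(n_clusters), n))
  truth$n_clusters <- n_clusters
  truth
}

#' Generate TCI subscale phenotypes from planted structure
#'
#' Each subject's 12 temperament subscales are its cluster template plus a
#' genetic effect plus Gaussian noise. Genetic effects follow either the
#' block model (members of a block mapped to a trait gain its effect size)
#' or an additive model (per-SNP dosage effects over block SNPs). When
#' `h2_target` is set, the noise standard deviation on the composite index
#' scale is solved analytically so the genetic fraction of index variance
#' equals the target; the realized decomposition is recorded in
#' `truth$h2_bookkeeping`. Thirteen character subscales are generated
#' alongside (correlated with cluster membership) solely to feed the
#' well-being and ill-being indices.
#'
#' @param truth a `cohort_truth` with `cluster_assignments` (see
#'   [assign_clusters()]).
#' @param genotypes the cohort's [genotype_matrix()] (needed for genetic
#'   effects; may be omitted when `effect_map` is empty).
#' @param templates profile template matrix as from [default_templates()],
#'   rows recycled over clusters.
#' @param effect_map tibble with `block_id`, `trait` (subscale name or
#'   `"index"`), `beta` (effect size, subscale scale units); zero-row for
#'   no genetic effects.
#' @param char_shift magnitude of the character-subscale shift separating
#'   the healthy (cluster 1, `+char_shift`) and unhealthy (cluster 2,
#'   `-char_shift`) profiles; 0 removes cluster-driven health structure.
#' @param noise_sd per-subscale noise standard deviation (ignored for the
#'   index-direction component when `h2_target` is set).
#' @param h2_target optional target genetic fraction of composite-index
#'   variance, in `[0, 1)`.
#' @param genetic_model `"block"` (membership effects) or `"additive"`
#'   (per-SNP dosage effects within block SNPs).
#' @param seed integer seed.
#' @return List with `phenotypes` (tibble: `subject_id` + 25 subscales)
#'   and the updated `truth` (bookkeeping, genetic values).
#' @export
generate_phenotypes <- function(truth, genotypes = NULL,
                                templates = default_templates(),
                                effect_map = NULL, noise_sd = 7.5,
                                char_shift = 8, h2_target = NULL,
                                genetic_model = c("block", "additive"),
                                seed = 1L) {
  genetic_model <- match.arg(genetic_model)
  if (is.null(truth$cluster_assignments)) {
    stop("truth lacks cluster_assignments; call assign_clusters() first")
  }
  set.seed(child_seed(seed, "phenotypes"))
  n <- truth$n_subjects
  cl <- truth$cluster_assignments
  sub <- tci_subscales("temperament")
  csub <- tci_subscales("character")
  k <- max(cl)
  tmpl <- templates[rep_len(seq_len(nrow(templates)), k), , drop = FALSE]
  base <- tmpl[cl, sub, drop = FALSE]

  # genetic component per subject on each mapped trait (temperament or
  # character subscale, or the composite index direction)
  gmat <- matrix(0, n, length(sub) + length(csub),
                 dimnames = list(NULL, c(sub, csub)))
  g_index <- numeric(n)   # effects mapped to the composite index direction
  if (!is.null(effect_map) && nrow(effect_map)) {
    if (is.null(truth$blocks) || !nrow(truth$blocks)) {
      stop("effect_map given but truth has no blocks")
    }
    for (r in seq_len(nrow(effect_map))) {
      b <- match(effect_map$block_id[r], truth$blocks$block_id)
      if (is.na(b)) stop("effect_map references unknown block ",
                         effect_map$block_id[r])
      members <- match(truth$blocks$subject_ids[[b]],
                       sprintf("S%04d", seq_len(n)))
      if (genetic_model == "block") {
        val <- numeric(n); val[members] <- effect_map$beta[r]
      } else {
        if (is.null(genotypes)) stop("additive model requires genotypes")
        sj <- match(truth$blocks$snp_ids[[b]], genotypes$snp_meta$snp_id)
        dos <- impute_genotypes(genotypes)[, sj, drop = FALSE]
        w <- rnorm(length(sj))
        score <- drop(scale(dos %*% w))
        val <- effect_map$beta[r] * score
      }
      tr <- effect_map$trait[r]
      if (identical(tr, "index")) {
        g_index <- g_index + val
      } else if (identical(tr, "profile")) {
        # push carriers along their block's linked profile direction
        link <- truth$blocks$cluster_link[b]
        if (is.na(link)) stop("trait 'profile' needs a cluster-linked block")
        d <- tmpl[link, sub] - colMeans(tmpl[, sub, drop = FALSE])
        d <- d / sqrt(mean(d^2))
        gmat[, sub] <- gmat[, sub] + outer(val, d)
      } else {
        gmat[, tr] <- gmat[, tr] + val
      }
    }
  }

  # index direction = equal-weight mean of the 12 temperament subscales
  p <- length(sub)
  bookkeeping <- NULL
  noise_idx_sd <- NULL
  if (!is.null(h2_target)) {
    assert_fraction(h2_target, "h2_target", 0, 1)
    g_tot <- g_index + rowMeans(gmat[, sub, drop = FALSE])
    var_g <- var(g_tot)
    if (var_g == 0 && h2_target > 0) {
      stop("h2_target > 0 but no genetic effects mapped")
    }
    var_t <- var(rowMeans(base))
    # index variance: var_g + var_t + var_noise_index = var_g / h2
    var_noise_idx <- if (h2_target > 0) var_g * (1 - h2_target) / h2_target - var_t
                     else var_t + noise_sd^2 / p  # h2 = 0: any noise works
    if (h2_target > 0 && var_noise_idx < 0) {
      max_h2 <- var_g / (var_g + var_t)
      stop(sprintf(
        "h2_target %.3f infeasible given template variance; maximum achievable is %.3f",
        h2_target, max_h2))
    }
    noise_idx_sd <- sqrt(max(var_noise_idx, 0))
  }

  noise <- matrix(rnorm(n * p, sd = noise_sd), n, p)
  if (!is.null(noise_idx_sd)) {
    # replace the noise component along the index direction with one of the
    # solved variance: project out the row mean, add back a controlled one
    noise <- noise - rowMeans(noise)
    noise <- noise + rnorm(n, sd = noise_idx_sd)
  }
  temp <- base + gmat[, sub, drop = FALSE] + g_index + noise
  if (!is.null(h2_target)) {
    g_tot <- g_index + rowMeans(gmat[, sub, drop = FALSE])
    idx <- rowMeans(temp[, sub, drop = FALSE])
    bookkeeping <- list(
      var_genetic = var(g_tot),
      var_template = var(rowMeans(base)),
      var_noise_index = var(rowMeans(noise)),
      h2_realized = if (h2_target > 0) var(g_tot) / var(idx) else 0,
      h2_target = h2_target
    )
  }

  # character subscales: cluster-shifted so health indices are informative
  cshift <- matrix(0, k, length(csub), dimnames = list(NULL, csub))
  # profile 1 (Reliable-like) healthy, profile 2 (Antisocial-like) unhealthy
  cshift[1L, ] <- char_shift
  if (k >= 2) cshift[2L, ] <- -char_shift
  char <- 50 + cshift[cl, , drop = FALSE] + gmat[, csub, drop = FALSE] +
    matrix(rnorm(n * length(csub), sd = noise_sd), n, length(csub))

  phen <- tibble::as_tibble(cbind(temp, char))
  phen <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%04d", seq_len(n))), phen)
  truth$h2_bookkeeping <- bookkeeping
  truth$genetic_values <- g_index + rowMeans(gmat[, sub, drop = FALSE])
  truth$templates <- tmpl
  truth$effect_map <- effect_map
  list(phenotypes = phen, truth = truth)
}

#' Generate environment variables correlated with cluster membership
#'
#' Each variable is built to realize a stated point-biserial correlation
#' with the indicator of one phenotype cluster: the noise component is
#' orthogonalized against the indicator exactly, so the realized
#' correlation of a continuous variable equals the target up to floating
#' point. Binary variables threshold the continuous construct at its
#' median, which attenuates the magnitude but preserves the sign.
#'
#' @param truth a `cohort_truth` with `cluster_assignments`.
#' @param env_spec tibble: `name`, `cluster` (linked cluster id, `NA` for
#'   none), `target_r` in `(-1, 1)`, `type` (`"continuous"` or
#'   `"binary"`).
#' @param seed integer seed.
#' @return Tibble `subject_id` + one column per environment variable.
#' @export
generate_environment <- function(truth, env_spec, seed = 1L) {
  if (is.null(truth$cluster_assignments)) {
    stop("truth lacks cluster_assignments")
  }
  if (any(abs(env_spec$target_r) >= 1)) {
    bad <- env_spec$name[abs(env_spec$target_r) >= 1][1]
    stop("correlation target for ", bad, " must be in (-1, 1)")
  }
  set.seed(child_seed(seed, "environment"))
  n <- truth$n_subjects
  out <- list(subject_id = sprintf("S%04d", seq_len(n)))
  for (r in seq_len(nrow(env_spec))) {
    tr <- env_spec$target_r[r]
    e <- rnorm(n)
    if (!is.na(env_spec$cluster[r]) && tr != 0) {
      z <- as.numeric(truth$cluster_assignments == env_spec$cluster[r])
      z <- standardize(z, "cluster indicator")
      e <- resid(lm(e ~ z))               # exact orthogonal noise
      e <- e / sd(e)
      x <- tr * z + sqrt(1 - tr^2) * e
    } else {
      x <- e
    }
    if (identical(env_spec$type[r], "binary")) {
      x <- as.numeric(x > median(x))
    }
    out[[env_spec$name[r]]] <- x
  }
  tibble::as_tibble(out)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper chaining [plant_blocks()], [assign_clusters()],
#' [generate_genotypes()], [generate_phenotypes()] and
#' [generate_environment()] under one seed.
#'
#' @param n_subjects,n_snps cohort dimensions.
#' @param n_blocks number of planted SNP-set biclusters.
#' @param n_clusters number of temperament clusters (profiles).
#' @param effect_map optional genetic effect map (see
#'   [generate_phenotypes()]).
#' @param env_spec optional environment spec (see
#'   [generate_environment()]); default two null variables.
#' @param link_blocks if `TRUE`, each block's subjects are preferentially
#'   drawn from cluster `1 + (block - 1) %% n_clusters`, planting
#'   block-profile relations.
#' @param h2_target,noise_sd,char_shift,missing_rate,fst,fidelity passed through.
#' @param subjects_per_block,snps_per_block passed to [plant_blocks()].
#' @param templates passed to [generate_phenotypes()].
#' @param genetic_model passed to [generate_phenotypes()].
#' @param seed integer seed; fully determines the cohort.
#' @return A list of class `synthetic_cohort`: `genotypes`, `phenotypes`,
#'   `covariates`, `environment`, `truth`.
#' @export
simulate_cohort <- function(n_subjects = 300L, n_snps = 600L, n_blocks = 4L,
                            n_clusters = 3L, effect_map = NULL,
                            env_spec = NULL, link_blocks = FALSE,
                            h2_target = NULL, noise_sd = 7.5,
                            char_shift = 8,
                            missing_rate = 0.02, fst = 0.01, fidelity = 0.9,
                            subjects_per_block = NULL, snps_per_block = NULL,
                            templates = default_templates(),
                            genetic_model = "block", seed = 1L) {
  spb <- subjects_per_block %||% max(10L, round(n_subjects / 5))
  mpb <- snps_per_block %||% max(5L, round(n_snps / 10))
  # clusters first so blocks can be linked to them
  pre <- structure(list(n_subjects = n_subjects), class = "cohort_truth")
  pre <- assign_clusters(pre, n_clusters, seed = seed)
  blocks <- if (n_blocks > 0) {
    plant_blocks(
      n_subjects, n_snps, n_blocks,
      subjects_per_block = spb, snps_per_block = mpb,
      cluster_link = if (link_blocks)
        1L + (seq_len(n_blocks) - 1L) %% n_clusters else NA_integer_,
      cluster_assignments = pre$cluster_assignments,
      overlap = link_blocks, seed = seed
    )
  } else NULL
  gen <- generate_genotypes(n_subjects, n_snps, blocks,
                            missing_rate = missing_rate, fst = fst,
                            fidelity = fidelity, seed = seed)
  gen$truth$cluster_assignments <- pre$cluster_assignments
  gen$truth$n_clusters <- n_clusters
  ph <- generate_phenotypes(gen$truth, genotypes = gen$genotypes,
                            templates = templates, effect_map = effect_map,
                            noise_sd = noise_sd, char_shift = char_shift,
                            h2_target = h2_target,
                            genetic_model = genetic_model, seed = seed)
  env_spec <- env_spec %||% tibble::tibble(
    name = c("env1", "env2"), cluster = NA_integer_, target_r = 0,
    type = "continuous")
  env <- generate_environment(ph$truth, env_spec, seed = seed)
  structure(list(
    genotypes = gen$genotypes,
    phenotypes = ph$phenotypes,
    covariates = gen$truth$covariates,
    environment = env,
    truth = ph$truth
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d SNPs, %d blocks, %d clusters\n",
    x$truth$n_subjects, x$truth$n_snps,
    if (is.null(x$truth$blocks)) 0L else nrow(x$truth$blocks),
    x$truth$n_clusters %||% NA_integer_))
  invisible(x)
}

#' Simulate a replication cohort from an existing cohort's genetic truth
#'
#' Draws a new cohort over the same SNP universe whose planted blocks
#' keep the original SNP memberships and allele patterns but acquire
#' fresh subject memberships (replication samples share variants, not
#' people). Phenotype and environment structure are regenerated under
#' the new seed with the same templates and effect map.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param seed new integer seed (must differ from the original for a
#'   genuinely independent sample).
#' @param n_subjects size of the replication cohort (default: same).
#' @param link_strength block-cluster link strength for the redrawn
#'   subject memberships.
#' @return A `synthetic_cohort` over the same SNP ids.
#' @export
simulate_replicate_cohort <- function(cohort, seed,
                                      n_subjects = NULL,
                                      link_strength = 0.9) {
  tr <- cohort$truth
  n <- n_subjects %||% tr$n_subjects
  ncl <- tr$n_clusters %||% 1L
  pre <- structure(list(n_subjects = n), class = "cohort_truth")
  pre <- assign_clusters(pre, ncl, seed = seed)
  blocks <- tr$blocks
  if (!is.null(blocks) && nrow(blocks)) {
    set.seed(child_seed(seed, "replicate-subjects"))
    for (b in seq_len(nrow(blocks))) {
      size <- length(blocks$subject_ids[[b]])
      link <- blocks$cluster_link[b]
      if (!is.na(link)) {
        in_cl <- which(pre$cluster_assignments == link)
        n_in <- min(length(in_cl), round(link_strength * size))
        subj <- c(sample(in_cl, n_in),
                  sample(setdiff(seq_len(n), in_cl), size - n_in))
      } else {
        subj <- sample(seq_len(n), size)
      }
      blocks$subject_ids[[b]] <- sprintf("S%04d", sort(subj))
    }
  }
  gen <- generate_genotypes(n, tr$n_snps, blocks,
                            missing_rate = tr$missing_rate, fst = tr$fst,
                            fidelity = tr$fidelity, seed = seed)
  gen$truth$cluster_assignments <- pre$cluster_assignments
  gen$truth$n_clusters <- ncl
  ph <- generate_phenotypes(gen$truth, genotypes = gen$genotypes,
                            templates = tr$templates %||% default_templates(),
                            effect_map = tr$effect_map,
                            seed = seed)
  env <- generate_environment(
    ph$truth,
    tibble::tibble(name = c("env1", "env2"), cluster = NA_integer_,
                   target_r = 0, type = "continuous"),
    seed = seed)
  structure(list(
    genotypes = gen$genotypes, phenotypes = ph$phenotypes,
    covariates = gen$truth$covariates, environment = env,
    truth = ph$truth
  ), class = "synthetic_cohort")
}

#' Write a cohort to disk (PLINK trio + TSVs + truth JSON)
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plink(cohort$genotypes, file.path(dir, "cohort"))
  readr::write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  readr::write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  readr::write_tsv(cohort$environment, file.path(dir, "environment.tsv"))
  tr <- cohort$truth
  tr_json <- list(
    n_subjects = tr$n_subjects, n_snps = tr$n_snps, seed = tr$seed,
    fidelity = tr$fidelity, fst = tr$fst, missing_rate = tr$missing_rate,
    cluster_assignments = tr$cluster_assignments,
    blocks = if (!is.null(tr$blocks) && nrow(tr$blocks)) lapply(
      seq_len(nrow(tr$blocks)), function(b) list(
        block_id = tr$blocks$block_id[b],
        subject_ids = tr$blocks$subject_ids[[b]],
        snp_ids = tr$blocks$snp_ids[[b]],
        allele_pattern = tr$blocks$allele_pattern[[b]]
      )) else list(),
    h2_bookkeeping = tr$h2_bookkeeping
  )
  jsonlite::write_json(tr_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
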