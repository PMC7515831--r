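## Genotype quality control, ancestry principal components, and
## covariate-adjusted single-SNP preselection.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on the conditional (Levene-Haldane) distribution
#' of the heterozygote count given the allele counts: the p-value sums the
#' probabilities of all heterozygote counts no more likely than the
#' observed one. Vectorized over SNPs.
#'
#' @param n_aa,n_ab,n_bb genotype counts (aa = homozygous minor).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n == 0L) return(1)
    n_a <- 2L * aa + ab           # minor-allele count
    # heterozygote counts with the parity of n_a, within feasible range
    h <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
    # log P(het = h | allele counts) up to a constant
    lp <- h * log(2) - lfactorial((n_a - h) / 2) - lfactorial(h) -
      lfactorial(n - (n_a + h) / 2)
    p <- exp(lp - max(lp)); p <- p / sum(p)
    obs <- p[match(ab, h)]
    sum(p[p <= obs + 1e-12])
  }, n_aa, n_ab, n_bb)
}

#' Filter SNPs by MAF, call rate and Hardy-Weinberg equilibrium
#'
#' Retains SNPs with minor-allele frequency at least `maf_min`, call rate
#' at least `call_rate_min` and HWE exact p-value at least `hwe_p_min`.
#' Every removal is listed with its reason (first failing criterion, in
#' the order maf, call_rate, hwe).
#'
#' @param g a [genotype_matrix()].
#' @param maf_min,call_rate_min,hwe_p_min thresholds; field-standard
#'   defaults MAF >= 0.01, call rate >= 0.95, HWE p >= 1e-6.
#' @return List of class `qc_result`: `genotypes` (filtered), `report`
#'   (tibble `snp_id`, `maf`, `call_rate`, `hwe_p`, `removed`, `reason`).
#' @export
qc_filter <- function(g, maf_min = 0.01, call_rate_min = 0.95,
                      hwe_p_min = 1e-6) {
  st <- snp_stats(g)
  st$hwe_p <- hwe_exact_p(st$n_aa, st$n_ab, st$n_bb)
  reason <- rep(NA_character_, nrow(st))
  maf_ok <- !is.na(st$maf) & st$maf >= maf_min
  reason[!maf_ok] <- "maf"
  cr_ok <- st$call_rate >= call_rate_min
  reason[is.na(reason) & !cr_ok] <- "call_rate"
  hwe_ok <- st$hwe_p >= hwe_p_min
  reason[is.na(reason) & !hwe_ok] <- "hwe"
  removed <- !is.na(reason)
  if (all(removed)) stop("all SNPs removed by QC; loosen thresholds")
  report <- dplyr::mutate(st[, c("snp_id", "maf", "call_rate", "hwe_p")],
                          removed = removed, reason = reason)
  structure(list(
    genotypes = subset_genotypes(g, snps = which(!removed)),
    report = report
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d SNPs retained, %d removed\n",
              sum(!x$report$removed), sum(x$report$removed)))
  if (any(x$report$removed)) {
    print(table(reason = x$report$reason[x$report$removed]))
  }
  invisible(x)
}

#' Ancestry principal components
#'
#' PCs of the centered, variance-standardized genotype matrix (missing
#' calls mean-imputed for this computation only). By default SNPs with
#' outlying loadings are iteratively excluded and the PCs recomputed, so
#' that a handful of strongly correlated SNPs (a local structure or a
#' planted set) cannot masquerade as genome-wide ancestry — the analogue
#' of the usual pruning of high-loading regions before ancestry PCA.
#' The sign of each PC is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param g a [genotype_matrix()].
#' @param k number of components (study convention: 3).
#' @param exclude_outlier_loadings drop SNPs whose summed squared loading
#'   across the `k` PCs exceeds `loading_factor` times the mean, then
#'   recompute (at most 3 rounds).
#' @param loading_factor outlier threshold multiplier.
#' @return Tibble `subject_id`, `PC1` ... `PCk`.
#' @export
ancestry_pcs <- function(g, k = 3L, exclude_outlier_loadings = TRUE,
                         loading_factor = 5) {
  v <- impute_genotypes(g)
  if (nrow(v) < k + 1L) stop("need at least k + 1 subjects")
  sds <- apply(v, 2, sd)
  keep <- sds > 0
  if (!any(keep)) {
    # no variable SNPs: centered matrix is zero, so all PCs are zero
    out <- tibble::as_tibble(matrix(0, nrow(v), k),
                             .name_repair = "minimal")
    names(out) <- paste0("PC", seq_len(k))
    return(dplyr::bind_cols(tibble::tibble(subject_id = g$subject_ids),
                            out))
  }
  v <- scale(v[, keep, drop = FALSE])
  pc <- prcomp(v, center = FALSE, scale. = FALSE, rank. = k)
  if (ncol(pc$x) < k) stop("k exceeds the rank of the genotype matrix")
  if (exclude_outlier_loadings) {
    for (it in 1:3) {
      load2 <- rowSums(pc$rotation[, seq_len(min(k, ncol(pc$rotation))),
                                   drop = FALSE]^2)
      drop_snps <- load2 >= loading_factor * mean(load2)
      if (!any(drop_snps) || sum(!drop_snps) <= k + 1L) break
      v <- v[, !drop_snps, drop = FALSE]
      pc <- prcomp(v, center = FALSE, scale. = FALSE, rank. = k)
      if (ncol(pc$x) < k) stop("k exceeds the rank after loading pruning")
    }
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  out <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(out) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble::tibble(subject_id = g$subject_ids), out)
}

#' Build a covariate table (sex + ancestry PCs)
#'
#' @param g a [genotype_matrix()].
#' @param sex tibble with `subject_id` and `sex`, or a numeric vector
#'   aligned to subjects.
#' @param k number of ancestry PCs.
#' @return Tibble `subject_id`, `sex`, `PC1..PCk`.
#' @export
covariate_table <- function(g, sex, k = 3L) {
  pcs <- ancestry_pcs(g, k)
  if (is.data.frame(sex)) {
    sex <- sex$sex[match(g$subject_ids, sex$subject_id)]
  }
  dplyr::bind_cols(tibble::tibble(subject_id = g$subject_ids,
                                  sex = as.numeric(sex)),
                   pcs[, -1, drop = FALSE])
}

# design matrix (intercept + covariates) from a covariate tibble aligned
# to the given subject ids
covariate_design <- function(cov, subject_ids) {
  idx <- match(subject_ids, cov$subject_id)
  if (anyNA(idx)) stop("covariates missing for some subjects")
  X <- as.matrix(cov[idx, setdiff(names(cov), "subject_id"), drop = FALSE])
  cbind(`(Intercept)` = 1, X)
}

#' Preselect SNPs by covariate-adjusted single-SNP association
#'
#' Fits `y ~ genotype + covariates` per SNP by ordinary least squares
#' (missing genotypes excluded pairwise) and retains SNPs whose Wald
#' p-value for the additive genotype term is below `p_threshold`,
#' uncorrected — a generously inclusive screen, not an inference step.
#'
#' @param g a [genotype_matrix()].
#' @param y numeric phenotype (e.g. the empirical temperament index),
#'   aligned to subjects.
#' @param cov covariate tibble (`subject_id`, `sex`, PCs), or `NULL`.
#' @param p_threshold retention threshold (default 0.01).
#' @return Tibble `snp_id`, `beta`, `se`, `p`, `selected`, sorted by the
#'   input SNP order.
#' @export
preselect_snps <- function(g, y, cov = NULL, p_threshold = 0.01) {
  if (sd(y) == 0) stop("phenotype is constant")
  n <- length(g$subject_ids)
  stopifnot(length(y) == n)
  X0 <- if (is.null(cov)) matrix(1, n, 1) else covariate_design(cov, g$subject_ids)
  m <- ncol(g$values)
  beta <- se <- p <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    gj <- g$values[, j]
    ok <- !is.na(gj)
    if (sum(ok) < ncol(X0) + 2L || sd(gj[ok]) == 0) next
    Xf <- cbind(X0[ok, , drop = FALSE], geno = gj[ok])
    XtX <- crossprod(Xf)
    XtXinv <- tryCatch(solve(XtX), error = function(e) NULL)
    if (is.null(XtXinv)) next
    bhat <- XtXinv %*% crossprod(Xf, y[ok])
    rss <- sum((y[ok] - Xf %*% bhat)^2)
    df <- sum(ok) - ncol(Xf)
    if (df <= 0) next
    last <- ncol(Xf)
    beta[j] <- bhat[last]
    se[j] <- sqrt(rss / df * XtXinv[last, last])
    p[j] <- 2 * stats::pt(abs(beta[j] / se[j]), df, lower.tail = FALSE)
  }
  tibble::tibble(
    snp_id = g$snp_meta$snp_id, beta = beta, se = se, p = p,
    selected = !is.na(p) & p < p_threshold
  )
}
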