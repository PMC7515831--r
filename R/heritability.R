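## SNP heritability of the empirical temperament index by trimmed,
## cross-validated ridge regression, plus environment sets and
## environment-mediated relations.

#' Estimate SNP heritability by trimmed cross-validated ridge regression
#'
#' The multi-SNP predictor is a ridge regression of the empirical index
#' on the selected SNP dosages (penalty chosen by inner cross-validation,
#' `glmnet`). Heritability is the out-of-sample R-squared over held-out
#' folds; within each training fold the `trim_fraction` of subjects with
#' the largest absolute residuals from a preliminary fit are excluded
#' before the final fit (outlier control), while held-out folds are never
#' trimmed, so the reported R-squared is honest. The in-sample R-squared
#' is reported alongside. When environment columns are supplied, the
#' estimate is repeated with the environment partialled out of the index
#' on identical folds (`adjusted_h2`, the gene-environment correlation
#' adjustment). Estimates are clamped to `[0, 1]` (clamping recorded).
#'
#' @param g_selected [genotype_matrix()] restricted to the significant-set
#'   SNPs (missing mean-imputed for the fit).
#' @param y numeric index aligned to subjects, or an [empirical_index()]
#'   tibble.
#' @param env optional environment tibble (`subject_id` + variables).
#' @param trim_fraction fraction of largest-residual training subjects
#'   excluded, in `[0, 0.5)`.
#' @param n_folds outer cross-validation folds.
#' @param n_boot bootstrap resamples for the standard error (0 skips).
#' @param seed integer seed.
#' @return Object of class `h2_estimate`: `h2`, `h2_insample`,
#'   `adjusted_h2`, `se`, `trim_fraction`, `n`, `m`, `clamped`.
#' @export
estimate_h2 <- function(g_selected, y, env = NULL, trim_fraction = 0.05,
                        n_folds = 5L, n_boot = 200L, seed = 1L) {
  if (trim_fraction >= 0.5) stop("trim_fraction must be below 0.5")
  assert_fraction(trim_fraction, "trim_fraction", 0, 0.5)
  if (is.data.frame(y)) {
    y <- y$index[match(g_selected$subject_ids, y$subject_id)]
  }
  X <- impute_genotypes(g_selected)
  n <- nrow(X)
  if (n <= 2L * n_folds) stop("too few subjects for cross-validation")
  set.seed(child_seed(seed, "h2"))
  point <- h2_cv_r2(X, y, trim_fraction, n_folds)
  adjusted <- NA_real_
  if (!is.null(env)) {
    E <- as.matrix(env[match(g_selected$subject_ids, env$subject_id),
                       setdiff(names(env), "subject_id"), drop = FALSE])
    keepc <- apply(E, 2, sd) > 0
    if (any(keepc)) {
      y_adj <- resid(lm(y ~ E[, keepc, drop = FALSE]))
      adjusted <- h2_cv_r2(X, y_adj, trim_fraction, n_folds,
                           folds = point$folds)$h2
    } else {
      adjusted <- point$h2
    }
  }
  se <- NA_real_
  if (n_boot > 0L) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      h2_cv_r2(X[idx, , drop = FALSE], y[idx], trim_fraction, n_folds)$h2
    }, numeric(1))
    se <- sd(boots)
  }
  clamped <- point$raw < 0 || point$raw > 1
  structure(list(
    h2 = point$h2, h2_insample = point$insample,
    adjusted_h2 = adjusted, se = se,
    trim_fraction = trim_fraction, n = n, m = ncol(X),
    clamped = clamped, raw = point$raw, n_folds = n_folds
  ), class = "h2_estimate")
}

# cross-validated out-of-sample R2 of a ridge predictor with
# training-fold residual trimming; folds reusable for paired comparisons
h2_cv_r2 <- function(X, y, trim_fraction, n_folds, folds = NULL) {
  n <- nrow(X)
  folds <- folds %||% sample(rep_len(seq_len(n_folds), n))
  pred <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (trim_fraction > 0) {
      fit0 <- glmnet::cv.glmnet(Xtr, ytr, alpha = 0, nfolds = 5)
      res0 <- abs(ytr - predict(fit0, Xtr, s = "lambda.min")[, 1])
      keep <- res0 <= quantile(res0, 1 - trim_fraction)
      Xtr <- Xtr[keep, , drop = FALSE]; ytr <- ytr[keep]
    }
    fit <- glmnet::cv.glmnet(Xtr, ytr, alpha = 0, nfolds = 5)
    pred[te] <- predict(fit, X[te, , drop = FALSE], s = "lambda.min")[, 1]
  }
  raw <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  # in-sample: one fit on all (trimmed) data, scored on everyone
  fit_all <- glmnet::cv.glmnet(X, y, alpha = 0, nfolds = 5)
  pin <- predict(fit_all, X, s = "lambda.min")[, 1]
  ins <- 1 - sum((y - pin)^2) / sum((y - mean(y))^2)
  list(h2 = min(max(raw, 0), 1), raw = raw,
       insample = min(max(ins, 0), 1), folds = folds)
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf(
    "<h2_estimate> h2 = %.3f (cross-validated%s), in-sample %.3f%s%s\n",
    x$h2, if (x$clamped) ", clamped" else "", x$h2_insample,
    if (!is.na(x$adjusted_h2))
      sprintf(", env-adjusted %.3f", x$adjusted_h2) else "",
    if (!is.na(x$se)) sprintf(", bootstrap SE %.3f", x$se) else ""))
  invisible(x)
}

#' @export
tidy.h2_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("h2", "h2_insample", "adjusted_h2"),
    estimate = c(x$h2, x$h2_insample, x$adjusted_h2),
    std.error = c(x$se, NA_real_, NA_real_)
  )
}

#' @export
glance.h2_estimate <- function(x, ...) {
  tibble::tibble(h2 = x$h2, adjusted_h2 = x$adjusted_h2, se = x$se,
                 trim_fraction = x$trim_fraction, n = x$n, m = x$m,
                 clamped = x$clamped)
}

#' Gene-environment correlation adjustment
#'
#' Convenience accessor pairing the unadjusted and environment-adjusted
#' heritability of an estimate (see [estimate_h2()]'s partialling step).
#'
#' @param h2_result an `h2_estimate` computed with `env` supplied.
#' @return Tibble `h2`, `adjusted_h2`, `difference`, `se`.
#' @export
gxe_adjustment <- function(h2_result) {
  stopifnot(inherits(h2_result, "h2_estimate"))
  tibble::tibble(h2 = h2_result$h2, adjusted_h2 = h2_result$adjusted_h2,
                 difference = h2_result$h2 - h2_result$adjusted_h2,
                 se = h2_result$se)
}

#' Discover environment sets
#'
#' Applies the NMF rank-sweep machinery to the environment variable
#' matrix (shifted non-negative), labeling sets `E_k_i`.
#'
#' @param env environment tibble (`subject_id` + variables).
#' @param k_range ranks to sweep.
#' @param ... passed to [sweep_ranks()].
#' @return An `nmf_sweep` whose catalog's `feature_ids` are environment
#'   variables.
#' @export
env_sets <- function(env, k_range = 2:5, ...) {
  vars <- setdiff(names(env), "subject_id")
  x <- as.matrix(env[, vars, drop = FALSE])
  if (any(x < 0)) x <- x - min(x)
  rownames(x) <- env$subject_id
  sweep_ranks(x, env$subject_id, vars, k_range, prefix = "E",
              onehot = FALSE, ...)
}

#' Environment-mediated genotype-phenotype relations
#'
#' For each environment set with enough members, re-screens SNP-set x
#' temperament-set relations within that stratum and reports relations
#' significant within the stratum but not marginally — associations
#' uncovered only when environmental exposure is used as a mediator.
#'
#' @param snp_catalog,temp_catalog set catalogs.
#' @param env_catalog environment-set catalog (from [env_sets()]).
#' @param N cohort size.
#' @param p_threshold significance threshold for both screens.
#' @param min_stratum strata smaller than this are skipped (logged).
#' @return Relation tibble with `env_set_label` and `mediated_only`
#'   columns; zero rows when nothing is uncovered.
#' @export
mediated_relations <- function(snp_catalog, temp_catalog, env_catalog,
                               N, p_threshold = 1e-3, min_stratum = 20L) {
  marginal <- relation_screen(snp_catalog, temp_catalog, N,
                              p_threshold = p_threshold)
  marginal_keys <- paste(marginal$snp_set_label, marginal$temp_set_label)
  out <- list()
  for (e in seq_len(nrow(env_catalog))) {
    stratum <- env_catalog$subject_ids[[e]]
    if (length(stratum) < min_stratum) {
      message("mediated_relations: stratum ", env_catalog$label[e],
              " below ", min_stratum, " subjects; skipped")
      next
    }
    restrict <- function(cat) {
      cat$subject_ids <- lapply(cat$subject_ids, intersect, y = stratum)
      cat[lengths(cat$subject_ids) > 0L, , drop = FALSE]
    }
    sc <- restrict(snp_catalog); tc <- restrict(temp_catalog)
    if (!nrow(sc) || !nrow(tc)) next
    med <- relation_screen(sc, tc, length(stratum),
                           p_threshold = p_threshold)
    if (!nrow(med)) next
    med$env_set_label <- env_catalog$label[e]
    med$mediated_only <- !(paste(med$snp_set_label, med$temp_set_label)
                           %in% marginal_keys)
    out[[length(out) + 1L]] <- med
  }
  if (!length(out)) {
    return(tibble::tibble())
  }
  dplyr::bind_rows(out)
}
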