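## Cross-cohort replication of discovered sets under Pareto
## multi-objective ranking, and classification of phenotype membership
## from SNP-set membership.

#' Non-domination (Pareto) ranks
#'
#' Ranks candidate points over objectives that are all maximized: rank 1
#' points are dominated by nobody, rank 2 by rank-1 points only, and so
#' on.
#'
#' @param objectives numeric matrix, one row per candidate, one column
#'   per objective (larger is better).
#' @return Integer vector of Pareto ranks (>= 1).
#' @export
pareto_rank <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  rank <- integer(n)
  remaining <- seq_len(n)
  level <- 0L
  while (length(remaining)) {
    level <- level + 1L
    obj <- objectives[remaining, , drop = FALSE]
    nondom <- vapply(seq_along(remaining), function(i) {
      diffs <- sweep(obj, 2, obj[i, ])
      # i dominated if some j is >= on all objectives and > on one
      !any(rowSums(diffs >= 0) == ncol(obj) & rowSums(diffs > 0) > 0)
    }, logical(1))
    rank[remaining[nondom]] <- level
    remaining <- remaining[!nondom]
  }
  rank
}

# cosine similarity of two signature flag vectors ({high, low, unmarked}
# encoded +1 / -1 / 0); 0 when either is all unmarked
signature_cosine <- function(a, b) {
  enc <- function(s) ifelse(s == "high", 1, ifelse(s == "low", -1, 0))
  va <- enc(a); vb <- enc(b)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

#' Match discovered sets across cohorts
#'
#' For each source set, scores every target set on two objectives —
#' `-log10` of the hypergeometric probability of the shared SNP ids
#' within the shared universe, and the cosine similarity of the
#' temperament signatures — computes Pareto non-domination ranks over the
#' candidates, and counts the source set replicated when a rank-1 match
#' passes both floors.
#'
#' @param catalog_a source catalog (with `signature` columns; see
#'   [catalog_signatures()]).
#' @param catalog_b target catalog.
#' @param snp_universe shared SNP id universe (intersection of the two
#'   cohorts' arrays).
#' @param p_floor maximum identity p for a replicating match (default
#'   1e-4).
#' @param cosine_floor minimum signature cosine (default 0.7).
#' @return List of class `set_matches`: `matches` tibble (`source_label`,
#'   `target_label`, `snp_identity_p`, `profile_similarity`,
#'   `pareto_rank`, `replicates`), `replication_rate`, `replicated`
#'   (per-source logical).
#' @export
match_sets <- function(catalog_a, catalog_b, snp_universe,
                       p_floor = 1e-4, cosine_floor = 0.7) {
  if (!length(snp_universe)) stop("shared SNP universe is empty")
  has_sig <- "signature" %in% names(catalog_a) &&
    "signature" %in% names(catalog_b)
  N <- length(snp_universe)
  rows <- list()
  replicated <- logical(nrow(catalog_a))
  for (i in seq_len(nrow(catalog_a))) {
    fa <- intersect(catalog_a$feature_ids[[i]], snp_universe)
    obj <- matrix(NA_real_, nrow(catalog_b), 2,
                  dimnames = list(NULL, c("neglog_p", "cosine")))
    for (j in seq_len(nrow(catalog_b))) {
      fb <- intersect(catalog_b$feature_ids[[j]], snp_universe)
      p <- hypergeom_relation(fa, fb, N)$p_hyper
      obj[j, 1] <- -log10(max(p, 1e-300))
      obj[j, 2] <- if (has_sig)
        signature_cosine(catalog_a$signature[[i]],
                         catalog_b$signature[[j]]) else 1
    }
    pr <- pareto_rank(obj)
    pass <- 10^(-obj[, 1]) <= p_floor & obj[, 2] >= cosine_floor
    replicated[i] <- any(pr == 1L & pass)
    rows[[i]] <- tibble::tibble(
      source_label = catalog_a$label[i],
      target_label = catalog_b$label,
      snp_identity_p = 10^(-obj[, 1]),
      profile_similarity = obj[, 2],
      pareto_rank = pr,
      replicates = pr == 1L & pass)
  }
  structure(list(
    matches = dplyr::bind_rows(rows),
    replicated = replicated,
    replication_rate = mean(replicated)
  ), class = "set_matches")
}

#' @export
print.set_matches <- function(x, ...) {
  cat(sprintf("<set_matches> %d source sets, replication rate %.1f%%\n",
              length(x$replicated), 100 * x$replication_rate))
  invisible(x)
}

#' Subject x SNP-set membership indicator matrix
#'
#' @param catalog SNP-set catalog tibble.
#' @param subject_ids cohort subject ids (row order).
#' @return Binary matrix, one column per catalogued set.
#' @export
membership_matrix <- function(catalog, subject_ids) {
  m <- vapply(catalog$subject_ids, function(s) subject_ids %in% s,
              logical(length(subject_ids))) * 1
  dimnames(m) <- list(subject_ids, catalog$label)
  m
}

#' Classify phenotype membership from SNP-set membership
#'
#' Regularized (ridge) logistic — or multinomial, for super-set labels —
#' classifier on the set-membership indicators, scored by stratified
#' cross-validated AUC. In semi-supervised mode, subjects with missing
#' labels are first given labels by propagation: a ridge model fit on the
#' labeled subjects labels the unlabeled ones whose predicted class
#' probability is confident, iterating until stable, and the final model
#' uses both (the held-out AUC is always computed on originally labeled
#' subjects only).
#'
#' @param x membership indicator matrix (see [membership_matrix()]), or
#'   any numeric feature matrix.
#' @param labels factor / logical / numeric labels; `NA` marks unlabeled
#'   subjects (triggers label propagation).
#' @param n_folds stratified cross-validation folds.
#' @param confidence propagation confidence threshold.
#' @param seed integer seed.
#' @return Object of class `set_classifier`: `auc` (named per class for
#'   multiclass, scalar for binary), `probabilities` tibble, `labels`,
#'   `n_propagated`.
#' @export
classify_membership <- function(x, labels, n_folds = 5L, confidence = 0.9,
                                seed = 1L) {
  x <- as.matrix(x)
  lab <- as.factor(labels)
  obs <- !is.na(labels)
  if (nlevels(droplevels(lab[obs])) < 2L) {
    stop("need at least 2 classes among labeled subjects")
  }
  set.seed(child_seed(seed, "classify"))
  n_prop <- 0L
  if (any(!obs)) {
    # label propagation: confident self-training from the labeled core
    work <- lab
    repeat {
      known <- !is.na(work)
      if (all(known)) break
      fit <- glmnet::cv.glmnet(x[known, , drop = FALSE],
                               droplevels(work[known]),
                               family = if (nlevels(droplevels(work[known])) > 2)
                                 "multinomial" else "binomial",
                               alpha = 0, nfolds = 4)
      pr <- predict(fit, x[!known, , drop = FALSE], s = "lambda.min",
                    type = "response")
      if (length(dim(pr)) == 3L) {
        pr <- pr[, , 1]
      } else {
        p1 <- as.numeric(pr)
        pr <- cbind(p1 * 0 + (1 - p1), p1)
        colnames(pr) <- levels(droplevels(work[known]))
      }
      conf <- apply(pr, 1, max)
      take <- conf >= confidence
      if (!any(take)) break
      cls <- colnames(pr)[max.col(pr)]
      idx_unknown <- which(!known)
      work[idx_unknown[take]] <- cls[take]
      n_prop <- n_prop + sum(take)
    }
    lab <- work
  }
  known <- !is.na(lab)
  lab_k <- droplevels(lab[known])
  xk <- x[known, , drop = FALSE]
  multi <- nlevels(lab_k) > 2L
  # stratified folds
  folds <- integer(nrow(xk))
  for (lv in levels(lab_k)) {
    idx <- which(lab_k == lv)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  prob <- matrix(NA_real_, nrow(xk), nlevels(lab_k),
                 dimnames = list(NULL, levels(lab_k)))
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- folds == f
    if (nlevels(droplevels(lab_k[tr])) < 2L) next
    fit <- glmnet::cv.glmnet(xk[tr, , drop = FALSE], lab_k[tr],
                             family = if (multi) "multinomial" else "binomial",
                             alpha = 0, nfolds = 4)
    pr <- predict(fit, xk[te, , drop = FALSE], s = "lambda.min",
                  type = "response")
    if (multi) prob[te, colnames(pr[, , 1])] <- pr[, , 1]
    else {
      prob[te, 2] <- pr[, 1]
      prob[te, 1] <- 1 - pr[, 1]
    }
  }
  eval_on <- obs[known]   # originally labeled subjects only
  auc <- vapply(levels(lab_k), function(lv) {
    truth_bin <- as.numeric(lab_k == lv)[eval_on]
    pr <- prob[eval_on, lv]
    ok <- !is.na(pr)
    if (length(unique(truth_bin[ok])) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(truth_bin[ok], pr[ok], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  if (!multi) auc <- auc[2L]
  probs <- tibble::as_tibble(prob, .name_repair = "minimal")
  probs <- dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(xk) %||%
                     as.character(seq_len(nrow(xk)))), probs)
  structure(list(auc = auc, probabilities = probs,
                 labels = lab_k, n_propagated = n_prop,
                 multi = multi),
            class = "set_classifier")
}

#' @export
print.set_classifier <- function(x, ...) {
  cat(sprintf("<set_classifier> cross-validated AUC %s%s\n",
              paste(sprintf("%.3f", x$auc), collapse = " / "),
              if (x$n_propagated)
                sprintf(" (%d labels propagated)", x$n_propagated) else ""))
  invisible(x)
}

#' @export
tidy.set_classifier <- function(x, ...) {
  tibble::tibble(class = names(x$auc) %||% "positive",
                 auc = unname(x$auc))
}

#' @export
glance.set_classifier <- function(x, ...) {
  tibble::tibble(mean_auc = mean(x$auc, na.rm = TRUE),
                 n_classes = if (x$multi) length(x$auc) else 2L,
                 n_propagated = x$n_propagated,
                 n = nrow(x$probabilities))
}
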