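## Non-negative matrix factorization biclustering
##
## Discovers labeled, possibly overlapping SNP sets (genotype biclusters)
## and temperament sets (phenotype clusters) by rank-swept NMF, with
## consensus clustering and cophenetic-correlation rank selection for the
## super-set level.

#' Factorize a non-negative matrix by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error `||X - W H||` over
#' non-negative factors, restarting from `n_restarts` random
#' initializations and keeping the best final error. The objective is
#' monotone non-increasing across iterations.
#'
#' @param x non-negative numeric matrix (subjects x features).
#' @param k factorization rank, `2 <= k < min(dim(x))` (rank 1 allowed for
#'   degenerate fixtures).
#' @param n_restarts random restarts (best kept).
#' @param max_iter,tol stopping rule: stop when the relative objective
#'   change falls below `tol` or after `max_iter` iterations.
#' @param seed integer seed.
#' @return List of class `nmf_fit`: `W` (subjects x k), `H` (k x
#'   features), `error`, `trace` (objective per iteration of the best
#'   restart), `converged`, `k`.
#' @export
nmf_factorize <- function(x, k, n_restarts = 5L, max_iter = 300L,
                          tol = 1e-5, seed = 1L) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("x must be non-negative")
  if (k < 1 || k >= min(dim(x)) + 1) stop("k out of range for matrix")
  set.seed(child_seed(seed, paste0("nmf", k)))
  best <- NULL
  scale0 <- sqrt(mean(x) / k)
  for (r in seq_len(n_restarts)) {
    W0 <- matrix(runif(nrow(x) * k, 0.1, 1), nrow(x), k) * scale0
    H0 <- matrix(runif(k * ncol(x), 0.1, 1), k, ncol(x)) * scale0
    fit <- .nmf_mu(x, W0, H0, as.integer(max_iter), tol)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  if (!best$converged) {
    warning("NMF did not converge within ", max_iter,
            " iterations; returning best iterate")
  }
  structure(c(best, list(k = k)), class = "nmf_fit")
}

# one-hot (3 columns per SNP) non-negative encoding of genotypes; missing
# calls are soft-encoded by the SNP's genotype-state frequencies so they
# neither anchor nor repel any factor. Sets are defined by shared allele
# patterns, which additive 0/1/2 coding cannot represent non-negatively.
encode_genotypes_onehot <- function(g) {
  v <- g$values
  n <- nrow(v); m <- ncol(v)
  out <- matrix(0, n, 3L * m)
  for (s in 0:2) {
    block <- (v == s) * 1
    freq <- colMeans(block, na.rm = TRUE)
    freq[is.nan(freq)] <- 0
    na_idx <- which(is.na(block), arr.ind = TRUE)
    if (nrow(na_idx)) block[na_idx] <- freq[na_idx[, 2L]]
    out[, seq.int(s + 1L, by = 3L, length.out = m)] <- block
  }
  colnames(out) <- paste0(rep(g$snp_meta$snp_id, each = 3L), ":", 0:2)
  out
}

# map one-hot column index back to (snp, genotype state)
onehot_snp <- function(j) (j - 1L) %/% 3L + 1L
onehot_state <- function(j) (j - 1L) %% 3L

#' Extract cohesive subject sets from an NMF fit
#'
#' For each factor, members are the subjects (and features) whose loading
#' exceeds `mean + threshold_sd * sd` of that factor's loading vector.
#' For genotype biclusters (one-hot encoded input) feature columns are
#' mapped back to SNPs and the per-SNP modal genotype defines the set's
#' allele pattern; cohesion is the fraction of member cells that match the
#' modal genotype. For plain feature matrices cohesion is the mean
#' within-set feature correlation mapped to \[0, 1\]. Factors are labeled
#' `"<prefix>_<k>_<i>"` with `i` the selection order (descending
#' cohesion); empty factors are skipped.
#'
#' @param fit an `nmf_fit` from [nmf_factorize()].
#' @param subject_ids,feature_ids labels for rows / columns of the
#'   factorized matrix.
#' @param data the matrix that was factorized (for cohesion).
#' @param prefix `"G"` for genotype sets, `"T"` for temperament sets,
#'   `"E"` for environment sets.
#' @param onehot whether columns are one-hot genotype states.
#' @param threshold_sd membership threshold in SD units above the mean
#'   loading (default 1).
#' @param min_members minimum subject and feature members for a set to be
#'   kept.
#' @return A set catalog tibble: `label`, `k`, `order`, `subject_ids`,
#'   `feature_ids` (list-columns), `membership` (list of soft weights),
#'   `modal_genotype` (list; `NA` unless one-hot), `cohesion`,
#'   `n_subjects`, `n_features`.
#' @export
extract_sets <- function(fit, subject_ids, feature_ids, data,
                         prefix = "G", onehot = FALSE, threshold_sd = 1,
                         min_members = 3L) {
  k <- fit$k
  rows <- list()
  # feature score = specificity x strength: the loading normalized across
  # factors (a feature belongs to a factor when it loads on it
  # specifically — every factor reconstructs the cohort-wide background)
  # times the raw loading (rare background states are specific but weak)
  Hn <- if (k >= 2L) {
    sweep(fit$H, 2, colSums(fit$H) + 1e-12, `/`) * fit$H
  } else fit$H
  for (i in seq_len(k)) {
    w <- fit$W[, i]
    h <- Hn[i, ]
    subj <- which(w > mean(w) + threshold_sd * sd(w))
    feat <- which(h > mean(h) + threshold_sd * sd(h))
    if (length(subj) < min_members || length(feat) < 1L) next
    if (onehot) {
      snps <- onehot_snp(feat)
      states <- onehot_state(feat)
      # per SNP keep the state with the largest loading as the modal code
      ord <- order(snps, -h[feat])
      keep <- !duplicated(snps[ord])
      snp_idx <- snps[ord][keep]
      modal <- states[ord][keep]
      o2 <- order(snp_idx)
      snp_idx <- snp_idx[o2]; modal <- modal[o2]
      if (length(snp_idx) < 1L) next
      sub <- data[subj, 3L * (snp_idx - 1L) + modal + 1L, drop = FALSE]
      cohesion <- mean(sub)
      rows[[length(rows) + 1L]] <- list(
        factor = i, subject_idx = subj, feature_idx = snp_idx,
        modal = modal, membership = w[subj], cohesion = cohesion)
    } else {
      sub <- data[subj, feat, drop = FALSE]
      if (length(subj) > 1L && length(feat) > 1L) {
        cc <- suppressWarnings(cor(t(sub)))
        cohesion <- (mean(cc[upper.tri(cc)], na.rm = TRUE) + 1) / 2
        if (is.nan(cohesion)) cohesion <- 1
      } else cohesion <- 1
      rows[[length(rows) + 1L]] <- list(
        factor = i, subject_idx = subj, feature_idx = feat,
        modal = NULL, membership = w[subj], cohesion = cohesion)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      label = character(), k = integer(), order = integer(),
      subject_ids = list(), feature_ids = list(), membership = list(),
      modal_genotype = list(), cohesion = numeric(),
      n_subjects = integer(), n_features = integer()))
  }
  ord <- order(-vapply(rows, `[[`, numeric(1), "cohesion"))
  rows <- rows[ord]
  feat_ids_of <- if (onehot) function(r) feature_ids[r$feature_idx]
                 else function(r) feature_ids[r$feature_idx]
  tibble::tibble(
    label = sprintf("%s_%d_%d", prefix, k, seq_along(rows)),
    k = k,
    order = seq_along(rows),
    subject_ids = lapply(rows, function(r) subject_ids[r$subject_idx]),
    feature_ids = lapply(rows, feat_ids_of),
    membership = lapply(rows, `[[`, "membership"),
    modal_genotype = lapply(rows, function(r) r$modal %||% NA_integer_),
    cohesion = vapply(rows, `[[`, numeric(1), "cohesion"),
    n_subjects = vapply(rows, function(r) length(r$subject_idx), integer(1)),
    n_features = vapply(rows, function(r) length(r$feature_idx), integer(1))
  )
}

#' Sweep factorization ranks and build a deduplicated set catalog
#'
#' Runs [nmf_factorize()] and [extract_sets()] for each rank in `k_range`,
#' unions the extracted sets, and drops near-duplicates (a set whose
#' subject AND feature Jaccard with an earlier-catalogued set both exceed
#' `dedup_jaccard`). Optionally computes a consensus matrix per rank from
#' restart co-clustering (hard assignment by argmax subject loading) and
#' its cophenetic correlation, for rank selection.
#'
#' @param x non-negative matrix (subjects x features).
#' @param subject_ids,feature_ids row / column labels.
#' @param k_range inclusive integer range of ranks.
#' @param n_restarts restarts per rank for the factorization itself.
#' @param consensus whether to compute consensus matrices.
#' @param consensus_restarts restarts used for co-clustering frequencies.
#' @param prefix,onehot,threshold_sd,min_members passed to
#'   [extract_sets()].
#' @param dedup_jaccard near-duplicate threshold on both axes.
#' @param max_iter,tol,seed passed to [nmf_factorize()].
#' @return List of class `nmf_sweep`: `catalog` (set tibble across ranks),
#'   `consensus` (tibble `k`, `rho_coph`, `consensus` list-column), and
#'   `dropped` (labels removed as near-duplicates).
#' @export
sweep_ranks <- function(x, subject_ids, feature_ids, k_range,
                        n_restarts = 5L, consensus = FALSE,
                        consensus_restarts = 30L, prefix = "G",
                        onehot = FALSE, threshold_sd = 1, min_members = 3L,
                        dedup_jaccard = 0.95, max_iter = 300L, tol = 1e-5,
                        seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  catalogs <- list()
  cons_rows <- list()
  errors <- numeric(0)
  for (k in k_range) {
    fit <- nmf_factorize(x, k, n_restarts = n_restarts,
                         max_iter = max_iter, tol = tol, seed = seed)
    errors[as.character(k)] <- fit$error
    catalogs[[as.character(k)]] <- extract_sets(
      fit, subject_ids, feature_ids, x, prefix = prefix, onehot = onehot,
      threshold_sd = threshold_sd, min_members = min_members)
    if (consensus) {
      cm <- consensus_matrix(x, k, n_restarts = consensus_restarts,
                             max_iter = max_iter, tol = tol, seed = seed)
      cons_rows[[as.character(k)]] <- tibble::tibble(
        k = k, rho_coph = cophenetic_rho(cm), consensus = list(cm))
    }
  }
  catalog <- dplyr::bind_rows(catalogs)
  dropped <- character()
  if (nrow(catalog) > 1L) {
    keep <- rep(TRUE, nrow(catalog))
    for (i in seq_len(nrow(catalog))[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j]) next
        js <- jaccard(catalog$subject_ids[[i]], catalog$subject_ids[[j]])
        if (js <= dedup_jaccard) next
        jf <- jaccard(catalog$feature_ids[[i]], catalog$feature_ids[[j]])
        if (jf > dedup_jaccard) { keep[i] <- FALSE; break }
      }
    }
    dropped <- catalog$label[!keep]
    catalog <- catalog[keep, , drop = FALSE]
  }
  structure(list(
    catalog = catalog,
    consensus = if (length(cons_rows)) dplyr::bind_rows(cons_rows) else NULL,
    errors = tibble::tibble(k = k_range, error = unname(errors)),
    dropped = dropped, k_range = k_range
  ), class = "nmf_sweep")
}

#' @export
print.nmf_sweep <- function(x, ...) {
  cat(sprintf("<nmf_sweep> %d sets over ranks %d..%d (%d near-duplicates dropped)\n",
              nrow(x$catalog), min(x$k_range), max(x$k_range),
              length(x$dropped)))
  invisible(x)
}

# consensus co-clustering matrix over random NMF restarts at one rank:
# entry (i, j) is the fraction of restarts assigning subjects i and j to
# the same argmax factor
consensus_matrix <- function(x, k, n_restarts = 30L, max_iter = 300L,
                             tol = 1e-5, seed = 1L) {
  n <- nrow(x)
  acc <- matrix(0, n, n)
  for (r in seq_len(n_restarts)) {
    fit <- nmf_factorize(x, k, n_restarts = 1L, max_iter = max_iter,
                         tol = tol,
                         seed = child_seed(seed, paste0("cons", k, "_", r)))
    a <- max.col(fit$W, ties.method = "first")
    acc <- acc + outer(a, a, `==`)
  }
  acc / n_restarts
}

# cophenetic correlation of a consensus matrix: agreement between the
# consensus distance (1 - consensus) and the cophenetic distances of its
# average-linkage dendrogram
cophenetic_rho <- function(cm) {
  d <- as.dist(1 - cm)
  if (all(d == d[1])) return(1)   # perfectly stable (or degenerate) case
  hc <- hclust(d, method = "average")
  suppressWarnings(cc <- cor(d, cophenetic(hc)))
  if (is.na(cc)) 1 else cc
}

#' Choose the super-set rank from the rank sweep
#'
#' Three criteria are available. `"elbow"` (default): the knee of the
#' factorization error curve — the largest rank whose error gain over the
#' previous rank still clearly exceeds the noise floor (1.5 times the
#' median of the last three gains); genuine structure produces gains far
#' above the floor, pure noise produces gains at it. `"stability"` /
#' `"minimize"`: the rank with the largest / smallest cophenetic
#' correlation between the restart-consensus distances and their
#' average-linkage dendrogram. Ties break to the smallest rank.
#' Fine-grained sets are then assigned to super-sets by average-linkage
#' hierarchical clustering of their mean feature profiles cut at the
#' chosen rank.
#'
#' @param sweep an `nmf_sweep` (from [sweep_ranks()]; needs
#'   `consensus = TRUE` for the rho-based criteria), or a consensus
#'   tibble with `k` and `rho_coph` columns (rho criteria only).
#' @param catalog optional set catalog to assign to super-sets.
#' @param profiles optional matrix of per-set mean feature profiles
#'   (rows aligned with `catalog`); computed from `data` if omitted.
#' @param data matrix used to compute per-set profiles when `profiles` is
#'   missing.
#' @param criterion `"elbow"`, `"stability"` or `"minimize"`.
#' @param elbow_factor gain-over-noise-floor factor for the elbow rule.
#' @return List: `k` (chosen rank), `rho` (its cophenetic correlation,
#'   `NA` if unavailable), `superset` (integer assignment per catalog
#'   row, `NULL` without a catalog), `criterion`.
#' @export
select_superset_rank <- function(sweep, catalog = NULL, profiles = NULL,
                                 data = NULL,
                                 criterion = c("elbow", "stability",
                                               "minimize"),
                                 elbow_factor = 1.5) {
  criterion <- match.arg(criterion)
  consensus <- if (inherits(sweep, "nmf_sweep")) sweep$consensus else sweep
  errors <- if (inherits(sweep, "nmf_sweep")) sweep$errors else NULL
  if (criterion == "elbow") {
    if (is.null(errors) || nrow(errors) < 3L) {
      stop("elbow criterion needs an nmf_sweep over at least 3 ranks")
    }
    ks <- errors$k
    gain <- -diff(errors$error)          # gain[i]: improvement into ks[i+1]
    floor_est <- median(utils::tail(gain, 3L))
    above <- which(gain >= elbow_factor * floor_est)
    k <- if (length(above)) ks[max(above) + 1L] else ks[1L]
  } else {
    if (is.null(consensus) || nrow(consensus) < 2L) {
      stop("need consensus results over at least 2 candidate ranks")
    }
    rho <- consensus$rho_coph
    target <- if (criterion == "stability") max(rho) else min(rho)
    cand <- consensus$k[abs(rho - target) < 1e-12]
    if (length(cand) > 1L) {
      message("select_superset_rank: tie among k = ",
              paste(cand, collapse = ", "), "; choosing smallest")
    }
    k <- min(cand)
  }
  superset <- NULL
  if (!is.null(catalog) && nrow(catalog)) {
    if (is.null(profiles)) {
      if (is.null(data)) stop("need `profiles` or `data` to assign super-sets")
      profiles <- t(vapply(seq_len(nrow(catalog)), function(i) {
        colMeans(data[match(catalog$subject_ids[[i]], rownames(data)), ,
                      drop = FALSE])
      }, numeric(ncol(data))))
    }
    if (nrow(profiles) <= k) {
      superset <- seq_len(nrow(profiles))
    } else {
      hc <- hclust(dist(profiles), method = "average")
      superset <- cutree(hc, k = k)
    }
  }
  rho_k <- if (!is.null(consensus) && k %in% consensus$k) {
    consensus$rho_coph[match(k, consensus$k)]
  } else NA_real_
  list(k = k, rho = rho_k, superset = superset, criterion = criterion)
}

#' Temperament signature of a subject set by median split
#'
#' Flags each temperament subscale `high` or `low` when the set members'
#' mean falls above or below the cohort median by more than `margin`
#' cohort SDs (`unmarked` otherwise), and assigns the nearest profile
#' template by agreement of the flag pattern.
#'
#' @param subject_ids member subject ids.
#' @param phenotypes phenotype tibble (`subject_id` + subscales).
#' @param subscales which subscales to flag (default the 12 temperament
#'   subscales).
#' @param templates profile template matrix for profile assignment
#'   (`NULL` to skip).
#' @param margin dead zone around the median, in cohort SD units.
#' @return List of class `temperament_signature`: `flags` (named character
#'   vector `high`/`low`/`unmarked`), `profile`, `low_confidence` (fewer
#'   than 3 members).
#' @export
set_signature <- function(subject_ids, phenotypes,
                          subscales = tci_subscales("temperament"),
                          templates = default_templates(), margin = 0.1) {
  stopifnot(all(subscales %in% names(phenotypes)))
  idx <- match(subject_ids, phenotypes$subject_id)
  if (anyNA(idx)) stop("unknown subject id in set")
  flags <- vapply(subscales, function(s) {
    x <- phenotypes[[s]]
    m <- mean(x[idx]) - median(x)
    tol <- margin * sd(x)
    if (m > tol) "high" else if (m < -tol) "low" else "unmarked"
  }, character(1))
  profile <- NA_character_
  if (!is.null(templates)) {
    tflags <- apply(templates[, subscales, drop = FALSE], 1, function(row) {
      ifelse(row > 50, "high", ifelse(row < 50, "low", "unmarked"))
    })
    # agreement: marked flags matching; unmarked neutral
    score <- apply(tflags, 2, function(tf) {
      sum(flags == tf & flags != "unmarked") -
        sum(flags != tf & flags != "unmarked" & tf != "unmarked")
    })
    profile <- rownames(templates)[which.max(score)]
  }
  structure(list(flags = flags, profile = profile,
                 low_confidence = length(subject_ids) < 3L),
            class = "temperament_signature")
}

#' @export
print.temperament_signature <- function(x, ...) {
  marked <- x$flags[x$flags != "unmarked"]
  cat(sprintf("<temperament_signature> profile %s%s\n  %s\n",
              x$profile %||% "unassigned",
              if (x$low_confidence) " (low confidence)" else "",
              if (length(marked))
                paste(names(marked), marked, sep = "=", collapse = ", ")
              else "all unmarked"))
  invisible(x)
}

#' Add signatures and profiles to a set catalog
#'
#' @param catalog a set catalog tibble (from [sweep_ranks()] or
#'   [extract_sets()]).
#' @param phenotypes phenotype tibble.
#' @param templates,margin passed to [set_signature()].
#' @return The catalog with `signature` (list-column of flag vectors) and
#'   `profile` columns added.
#' @export
catalog_signatures <- function(catalog, phenotypes,
                               templates = default_templates(),
                               margin = 0.1) {
  sigs <- lapply(catalog$subject_ids, set_signature, phenotypes = phenotypes,
                 templates = templates, margin = margin)
  catalog$signature <- lapply(sigs, `[[`, "flags")
  catalog$profile <- vapply(sigs, `[[`, character(1), "profile")
  catalog
}

#' Discover SNP sets (genotype biclusters)
#'
#' One-hot encodes the genotype matrix and runs the rank sweep with
#' genotype-set labeling (`G_k_i`).
#'
#' @param g a [genotype_matrix()].
#' @param k_range ranks to sweep (the study-convention 2..15 is often
#'   wider than needed at desk scale).
#' @param ... passed to [sweep_ranks()].
#' @return An `nmf_sweep` whose catalog's `feature_ids` are SNP ids.
#' @export
snp_sets <- function(g, k_range = 2:8, ...) {
  x <- encode_genotypes_onehot(g)
  rownames(x) <- g$subject_ids
  sweep_ranks(x, g$subject_ids, g$snp_meta$snp_id, k_range,
              prefix = "G", onehot = TRUE, ...)
}

#' Discover temperament sets (phenotype clusters)
#'
#' Runs the rank sweep on the (non-negative) temperament subscale matrix
#' with temperament-set labeling (`T_k_i`) and consensus matrices for
#' super-set rank selection.
#'
#' @param phenotypes phenotype tibble (`subject_id` + subscales).
#' @param subscales columns to use (default the 12 temperament
#'   subscales).
#' @param k_range ranks to sweep (study convention 2..15).
#' @param consensus compute consensus matrices (default `TRUE`).
#' @param ... passed to [sweep_ranks()].
#' @return An `nmf_sweep` whose catalog's `feature_ids` are subscales.
#' @export
temperament_sets <- function(phenotypes,
                             subscales = tci_subscales("temperament"),
                             k_range = 2:15, consensus = TRUE, ...) {
  x <- as.matrix(phenotypes[, subscales, drop = FALSE])
  if (any(x < 0)) x <- x - min(x)
  rownames(x) <- phenotypes$subject_id
  sweep_ranks(x, phenotypes$subject_id, subscales, k_range,
              prefix = "T", onehot = FALSE, consensus = consensus, ...)
}
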