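## Many-to-many genotype-phenotype relation mapping: hypergeometric
## set-overlap tests with a permutation null, health-index fusion, and the
## SNP-set network.

#' Well-being and ill-being flags from character scores
#'
#' Well-being marks the top decile of the product of the three character
#' trait totals (Self-directedness x Cooperativeness x
#' Self-transcendence); ill-being marks the bottom decile of
#' Self-directedness + Cooperativeness. Exactly `floor(N / 10)` subjects
#' carry each flag; ties are broken by stable subject order (and logged).
#'
#' @param phenotypes phenotype tibble carrying the 13 character subscales
#'   (`SD1..SD5`, `CO1..CO5`, `ST1..ST3`).
#' @return Tibble `subject_id`, `sd_total`, `co_total`, `st_total`,
#'   `well_being`, `ill_being` (logical flags).
#' @export
health_flags <- function(phenotypes) {
  n <- nrow(phenotypes)
  if (n < 10L) stop("need at least 10 subjects for decile flags")
  sdt <- rowSums(phenotypes[, paste0("SD", 1:5), drop = FALSE])
  cot <- rowSums(phenotypes[, paste0("CO", 1:5), drop = FALSE])
  stt <- rowSums(phenotypes[, paste0("ST", 1:3), drop = FALSE])
  k <- floor(n / 10)
  wb_score <- sdt * cot * stt
  ib_score <- sdt + cot
  flag_top <- function(score, decreasing) {
    ord <- order(score, decreasing = decreasing)
    cut <- score[ord[k]]
    if (k < n && score[ord[k + 1L]] == cut) {
      message("health_flags: ties at the decile boundary broken by subject order")
    }
    flags <- rep(FALSE, n)
    flags[ord[seq_len(k)]] <- TRUE
    flags
  }
  wb <- flag_top(wb_score, decreasing = TRUE)
  ib <- flag_top(ib_score, decreasing = FALSE)
  if (any(wb & ib)) {
    message("health_flags: ", sum(wb & ib),
            " subject(s) carry both flags (overlapping decile boundaries)")
  }
  tibble::tibble(subject_id = phenotypes$subject_id,
                 sd_total = sdt, co_total = cot, st_total = stt,
                 well_being = wb, ill_being = ib)
}

#' Hypergeometric enrichment of two subject sets
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, n_A, n_B)`: the chance that two random sets of
#' the observed sizes share at least the observed number of subjects.
#'
#' @param a,b member id vectors.
#' @param N cohort size.
#' @return One-row tibble: `N`, `n_a`, `n_b`, `k_overlap`, `p_hyper`.
#' @export
hypergeom_relation <- function(a, b, N) {
  a <- unique(a); b <- unique(b)
  n_a <- length(a); n_b <- length(b)
  if (n_a > N || n_b > N) stop("set larger than cohort")
  k <- length(intersect(a, b))
  p <- phyper(k - 1L, n_a, N - n_a, n_b, lower.tail = FALSE)
  tibble::tibble(N = N, n_a = n_a, n_b = n_b, k_overlap = k,
                 p_hyper = min(p, 1))
}

#' Screen all SNP-set x temperament-set pairs for subject enrichment
#'
#' Tests every pair with the one-sided hypergeometric test and retains
#' edges below `p_threshold`. When health flags are supplied, the joint
#' well-/ill-being probabilities among shared subjects are reported per
#' edge (the study's health fusion).
#'
#' @param snp_catalog,temp_catalog set catalog tibbles.
#' @param N cohort size.
#' @param p_threshold retention threshold (study convention 1e-3).
#' @param health optional tibble from [health_flags()].
#' @return Relation edge tibble: `snp_set_label`, `temp_set_label`, `N`,
#'   `n_a` (SNP set), `n_b` (temperament set), `k_overlap`, `p_hyper`,
#'   and with health `wb_joint`, `ib_joint`, `wb_snp`, `ib_snp`,
#'   `wb_temp`, `ib_temp`.
#' @export
relation_screen <- function(snp_catalog, temp_catalog, N,
                            p_threshold = 1e-3, health = NULL) {
  if (!nrow(snp_catalog) || !nrow(temp_catalog)) {
    stop("catalogs must be non-empty")
  }
  grid <- tidyr::expand_grid(ai = seq_len(nrow(snp_catalog)),
                             bi = seq_len(nrow(temp_catalog)))
  edges <- purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    ai <- grid$ai[r]; bi <- grid$bi[r]
    subj_a <- snp_catalog$subject_ids[[ai]]
    subj_b <- temp_catalog$subject_ids[[bi]]
    e <- hypergeom_relation(subj_a, subj_b, N)
    e$snp_set_label <- snp_catalog$label[ai]
    e$temp_set_label <- temp_catalog$label[bi]
    if (!is.null(health)) {
      rate <- function(ids, col) {
        if (!length(ids)) return(NA_real_)
        mean(health[[col]][match(ids, health$subject_id)])
      }
      joint <- intersect(subj_a, subj_b)
      e$wb_joint <- rate(joint, "well_being")
      e$ib_joint <- rate(joint, "ill_being")
      e$wb_snp <- rate(subj_a, "well_being")
      e$ib_snp <- rate(subj_a, "ill_being")
      e$wb_temp <- rate(subj_b, "well_being")
      e$ib_temp <- rate(subj_b, "ill_being")
    }
    e
  })
  edges <- edges[edges$p_hyper < p_threshold, , drop = FALSE]
  front <- c("snp_set_label", "temp_set_label")
  edges[, c(front, setdiff(names(edges), front)), drop = FALSE]
}

#' Permutation empirical p-values for relation edges
#'
#' Permutes subjects' temperament-set memberships as whole assignment
#' vectors (subject labels are shuffled once per permutation, preserving
#' within-subject correlations between temperament sets) and recomputes
#' each edge's overlap. `p_perm = (1 + #{k* >= k_obs}) / (R + 1)`.
#'
#' @param edges relation tibble from [relation_screen()].
#' @param snp_catalog,temp_catalog the catalogs behind the edges.
#' @param subject_ids full cohort subject ids.
#' @param R number of permutations (>= 100; default 2000 resolves the
#'   study's 4.6e-3 bound).
#' @param seed integer seed.
#' @return `edges` with a `p_perm` column appended.
#' @export
permutation_null <- function(edges, snp_catalog, temp_catalog, subject_ids,
                             R = 2000L, seed = 1L) {
  if (R < 100L) stop("R must be at least 100")
  if (R < 1 / 4.6e-3) {
    warning("R = ", R, " cannot resolve empirical p below ",
            signif(1 / (R + 1), 2))
  }
  set.seed(child_seed(seed, "perm"))
  n <- length(subject_ids)
  ai <- match(edges$snp_set_label, snp_catalog$label)
  bi <- match(edges$temp_set_label, temp_catalog$label)
  a_idx <- lapply(snp_catalog$subject_ids, match, table = subject_ids)
  b_mask <- lapply(temp_catalog$subject_ids, function(s)
    subject_ids %in% s)
  exceed <- integer(nrow(edges))
  for (r in seq_len(R)) {
    perm <- sample.int(n)
    for (e in seq_len(nrow(edges))) {
      k_star <- sum(b_mask[[bi[e]]][perm[a_idx[[ai[e]]]]])
      if (k_star >= edges$k_overlap[e]) exceed[e] <- exceed[e] + 1L
    }
  }
  edges$p_perm <- (1 + exceed) / (R + 1)
  edges
}

#' Build the SNP-set network
#'
#' Nodes are SNP sets; an edge links two sets whose shared SNPs and/or
#' shared subjects are hypergeometrically enriched below `p_threshold`.
#' Edge type records which axis (or both) linked the pair.
#'
#' @param catalog SNP-set catalog tibble.
#' @param n_subjects cohort size (subject-overlap universe).
#' @param n_snps SNP universe size.
#' @param p_threshold edge threshold.
#' @return List of class `set_network`: `graph` (igraph), `edges`
#'   (tibble: labels, `p_subjects`, `p_snps`, `type`), `nodes`.
#' @export
build_network <- function(catalog, n_subjects, n_snps, p_threshold = 1e-3) {
  m <- nrow(catalog)
  rows <- list()
  if (m > 1L) {
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      ps <- hypergeom_relation(catalog$subject_ids[[i]],
                               catalog$subject_ids[[j]], n_subjects)$p_hyper
      pf <- hypergeom_relation(catalog$feature_ids[[i]],
                               catalog$feature_ids[[j]], n_snps)$p_hyper
      if ((ps < p_threshold) || (pf < p_threshold)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          from = catalog$label[i], to = catalog$label[j],
          p_subjects = ps, p_snps = pf,
          type = c("subjects", "snps", "both")[
            (ps < p_threshold) + 2L * (pf < p_threshold)])
      }
    }
  }
  edges <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(from = character(), to = character(),
                   p_subjects = numeric(), p_snps = numeric(),
                   type = character())
  gph <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = catalog$label))
  structure(list(graph = gph, edges = edges, nodes = catalog$label),
            class = "set_network")
}

#' @export
print.set_network <- function(x, ...) {
  cat(sprintf("<set_network> %d nodes, %d edges, %d components\n",
              length(x$nodes), nrow(x$edges),
              igraph::count_components(x$graph)))
  invisible(x)
}

#' Hub SNP sets of a network
#'
#' The node(s) of maximal degree within each connected component
#' (components of a single node have no hub).
#'
#' @param net a `set_network` from [build_network()].
#' @return Tibble `label`, `component`, `degree`, `is_hub`.
#' @export
find_hubs <- function(net) {
  comp <- igraph::components(net$graph)
  deg <- igraph::degree(net$graph)
  out <- tibble::tibble(
    label = names(deg),
    component = comp$membership[names(deg)],
    degree = as.integer(deg)
  )
  out <- dplyr::group_by(out, .data$component)
  out <- dplyr::mutate(out,
    is_hub = .data$degree > 0 & .data$degree == max(.data$degree))
  dplyr::ungroup(out)
}

#' Group relations into per-trait pipelines
#'
#' For each temperament dimension and direction (high/low), collects the
#' relations whose temperament set's signature carries that flag, and
#' marks the pipeline `composite` when more than one profile contributes
#' (heterogeneity: several gene sets converging on one trait).
#'
#' @param edges relation tibble (needs `temp_set_label`).
#' @param temp_catalog temperament catalog with `signature` and `profile`
#'   columns (see [catalog_signatures()]).
#' @param traits named list mapping trait names to their subscales;
#'   default the four TCI temperament dimensions.
#' @return Tibble `trait`, `direction`, `n_relations`, `profiles`
#'   (list-column), `composite`, `relations` (list-column of edge
#'   subsets).
#' @export
trait_pipelines <- function(edges, temp_catalog,
                            traits = list(
                              NS = paste0("NS", 1:4),
                              HA = paste0("HA", 1:4),
                              RD = paste0("RD", 1:3),
                              PS = "PS1")) {
  rows <- list()
  for (tr in names(traits)) for (dir in c("high", "low")) {
    carry <- vapply(seq_len(nrow(temp_catalog)), function(i) {
      sig <- temp_catalog$signature[[i]]
      any(sig[traits[[tr]]] == dir)
    }, logical(1))
    labs <- temp_catalog$label[carry]
    sub <- edges[edges$temp_set_label %in% labs, , drop = FALSE]
    profs <- unique(temp_catalog$profile[carry & temp_catalog$label %in%
                                           sub$temp_set_label])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      trait = tr, direction = dir, n_relations = nrow(sub),
      profiles = list(profs), composite = length(profs) > 1L,
      relations = list(sub))
  }
  dplyr::bind_rows(rows)
}

#' Flag switch features within a SNP set
#'
#' Set-level contrast: for each SNP of a set, tests whether member
#' subjects carrying the set's modal genotype at that SNP differ in
#' well-being score from members who do not (rank-sum test). SNPs with
#' p below `p_threshold` are flagged as "switch" features whose presence
#' splits the set into high- vs low-well-being subgroups.
#'
#' @param set one catalog row (tibble slice with `subject_ids`,
#'   `feature_ids`, `modal_genotype`).
#' @param g a [genotype_matrix()].
#' @param health tibble from [health_flags()].
#' @param score health score column to contrast (default the well-being
#'   product scale `sd_total * co_total * st_total`).
#' @param p_threshold rank-sum flag threshold (default 0.01).
#' @return Tibble `snp_id`, `p_ranksum`, `switch`.
#' @export
switch_features <- function(set, g, health, score = NULL,
                            p_threshold = 0.01) {
  subj <- match(set$subject_ids[[1]], g$subject_ids)
  snps <- match(set$feature_ids[[1]], g$snp_meta$snp_id)
  modal <- set$modal_genotype[[1]]
  if (all(is.na(modal))) modal <- rep(2L, length(snps))
  hscore <- score %||%
    (health$sd_total * health$co_total * health$st_total)[
      match(set$subject_ids[[1]], health$subject_id)]
  res <- purrr::map_dfr(seq_along(snps), function(j) {
    gj <- g$values[subj, snps[j]]
    carrier <- !is.na(gj) & gj == modal[j]
    p <- if (sum(carrier) >= 2 && sum(!carrier, na.rm = TRUE) >= 2) {
      suppressWarnings(
        wilcox.test(hscore[carrier], hscore[!carrier])$p.value)
    } else NA_real_
    tibble::tibble(snp_id = g$snp_meta$snp_id[snps[j]], p_ranksum = p)
  })
  res$switch <- !is.na(res$p_ranksum) & res$p_ranksum < p_threshold
  res
}
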