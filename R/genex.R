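#' Preprocess single-cell qPCR Ct readings into expression values
#'
#' For each (cell, gene) the minimum Ct over the duplicate wells is taken;
#' missing values are replaced by the ceiling Ct (default 32); the data are
#' then transformed so the ceiling becomes 0: Et = ceiling - min(Ct,
#' ceiling). Cells with zero expression in all genes are removed (with a
#' message). Ct readings above 40 are implausible and treated as missing,
#' with a warning.
#'
#' @param ct Long data frame of raw readings: columns `cell_id`, `gene`,
#'   `replicate` (1 or 2) and `ct` (positive Ct value or `NA`).
#' @param cell_meta Optional data frame of per-cell metadata (`cell_id`
#'   plus e.g. `donor_id`, `cohort`, `phenotype`) joined onto the result.
#' @param ceiling_ct Detection ceiling (default 32).
#' @return Wide tibble: one row per retained cell, metadata columns first,
#'   then one Et column per gene. The gene names are stored in the
#'   `"genes"` attribute (see [genex_genes()]).
#' @export
preprocess_ct <- function(ct, cell_meta = NULL, ceiling_ct = 32) {
  stopifnot(all(c("cell_id", "gene", "ct") %in% names(ct)))
  ct <- as_tibble(ct)
  too_high <- !is.na(ct$ct) & ct$ct > 40
  if (any(too_high)) {
    warn(sprintf("%d Ct reading(s) above 40 treated as missing",
                 sum(too_high)))
    ct$ct[too_high] <- NA_real_
  }
  if (any(!is.na(ct$ct) & ct$ct <= 0)) abort("Ct values must be positive")
  et_long <- ct %>%
    group_by(.data$cell_id, .data$gene) %>%
    summarise(ct_min = if (all(is.na(.data$ct))) ceiling_ct
              else min(.data$ct, na.rm = TRUE),
              .groups = "drop") %>%
    mutate(et = ceiling_ct - pmin(.data$ct_min, ceiling_ct))
  genes <- sort(unique(et_long$gene))
  wide <- et_long %>%
    select("cell_id", "gene", "et") %>%
    tidyr::pivot_wider(names_from = "gene", values_from = "et",
                       values_fill = 0) %>%
    select("cell_id", all_of(genes))
  all_zero <- rowSums(as.matrix(wide[, genes, drop = FALSE])) == 0
  if (any(all_zero)) {
    inform(sprintf("%d cell(s) removed (zero expression in all genes)",
                   sum(all_zero)))
    wide <- wide[!all_zero, , drop = FALSE]
  }
  if (!is.null(cell_meta)) {
    wide <- left_join(wide, as_tibble(cell_meta), by = "cell_id") %>%
      select("cell_id", all_of(setdiff(names(cell_meta), "cell_id")),
             all_of(genes))
  }
  wide <- arrange(wide, .data$cell_id)
  attr(wide, "genes") <- genes
  wide
}

#' Gene columns of an expression table
#'
#' @param et Expression tibble from [preprocess_ct()].
#' @return Character vector of gene names.
#' @export
genex_genes <- function(et) {
  g <- attr(et, "genes")
  if (is.null(g)) abort("not an expression table: missing 'genes' attribute")
  g
}

# Two-part hurdle likelihood-ratio statistics for one gene, one
# cluster-vs-rest contrast. y: Et values; in_cluster: logical.
hurdle_core <- function(y, in_cluster) {
  z <- y > 0
  n1 <- sum(in_cluster); n0 <- sum(!in_cluster)
  z1 <- sum(z[in_cluster]); z0 <- sum(z[!in_cluster])
  ll_bin <- function(k, n) {
    if (n == 0) return(0)
    p <- k / n
    t1 <- if (k > 0) k * log(p) else 0
    t2 <- if (k < n) (n - k) * log(1 - p) else 0
    t1 + t2
  }
  chisq_disc <- 2 * (ll_bin(z1, n1) + ll_bin(z0, n0) - ll_bin(z1 + z0, n1 + n0))
  chisq_disc <- max(chisq_disc, 0)

  y1 <- y[in_cluster & z]; y0 <- y[!in_cluster & z]
  if (length(y1) == 0 || length(y0) == 0) {
    chisq_cont <- NA_real_
    p_cont <- 1
    df <- 1L
  } else {
    ye <- c(y1, y0)
    rss0 <- sum((ye - mean(ye))^2)
    rss1 <- sum((y1 - mean(y1))^2) + sum((y0 - mean(y0))^2)
    if (rss0 <= .Machine$double.eps) {
      chisq_cont <- 0
    } else if (rss1 <= .Machine$double.eps) {
      chisq_cont <- Inf
    } else {
      chisq_cont <- length(ye) * log(rss0 / rss1)
    }
    chisq_cont <- max(chisq_cont, 0)
    p_cont <- pchisq(chisq_cont, df = 1, lower.tail = FALSE)
    df <- 2L
  }
  p_disc <- pchisq(chisq_disc, df = 1, lower.tail = FALSE)
  total <- chisq_disc + if (is.na(chisq_cont)) 0 else chisq_cont
  p_overall <- pchisq(total, df = df, lower.tail = FALSE)
  list(
    p_continuous = p_cont, p_discrete = p_disc, p_overall = p_overall,
    chisq_discrete = chisq_disc, chisq_continuous = chisq_cont, df = df,
    avg_logFC = mean(y[in_cluster]) - mean(y[!in_cluster]),
    n_in = n1, n_out = n0
  )
}

#' Hurdle-model test of one gene for one cluster against all other cells
#'
#' Two-part test on Et expression values for a cluster-vs-rest contrast:
#' a discrete component (likelihood-ratio test on the detection rate,
#' Et > 0, via group-wise Bernoulli maximum likelihood, 1 df) and a
#' continuous component (likelihood-ratio test on Et among expressing
#' cells under a common-variance Gaussian model, 1 df). The overall
#' p-value combines the two chi-square deviances (2 df; 1 df when the
#' continuous part cannot be fit because one group has no expressing
#' cells). The average log fold change is the difference of group means on
#' the Et scale, which is log2-like since Ct cycles are log2 of template.
#'
#' @param et Expression tibble from [preprocess_ct()] with a cluster
#'   label column.
#' @param cluster Cluster label defining the in-group.
#' @param gene Gene name (one of [genex_genes()]).
#' @param cluster_col Name of the cluster label column (default
#'   `"genex_cluster"`).
#' @return A `hurdle_fit` object; use [generics::tidy()] for a one-row
#'   tibble of p-values and fold change.
#' @export
hurdle_test <- function(et, cluster, gene, cluster_col = "genex_cluster") {
  stopifnot(cluster_col %in% names(et), gene %in% genex_genes(et))
  in_cluster <- et[[cluster_col]] == cluster
  if (sum(in_cluster) < 3 || sum(!in_cluster) < 3) {
    abort("need at least 3 cells inside and outside the cluster")
  }
  core <- hurdle_core(et[[gene]], in_cluster)
  structure(c(list(gene = gene, cluster = cluster), core),
            class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("Hurdle test: gene %s, cluster %s vs rest\n", x$gene,
              as.character(x$cluster)))
  cat(sprintf("  discrete   p = %.4g\n", x$p_discrete))
  cat(sprintf("  continuous p = %.4g\n", x$p_continuous))
  cat(sprintf("  overall    p = %.4g (df = %d)\n", x$p_overall, x$df))
  cat(sprintf("  avg logFC = %.3f  (n in/out = %d/%d)\n", x$avg_logFC,
              x$n_in, x$n_out))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname hurdle_test
#' @param x A `hurdle_fit` object.
#' @param ... Unused.
#' @method tidy hurdle_fit
#' @export
tidy.hurdle_fit <- function(x, ...) {
  tibble(gene = x$gene, cluster = x$cluster,
         p_continuous = x$p_continuous, p_discrete = x$p_discrete,
         p_overall = x$p_overall, avg_logFC = x$avg_logFC)
}

#' @rdname hurdle_test
#' @method glance hurdle_fit
#' @export
glance.hurdle_fit <- function(x, ...) {
  tibble(statistic = x$chisq_discrete +
           ifelse(is.na(x$chisq_continuous), 0, x$chisq_continuous),
         df = x$df, p.value = x$p_overall,
         n_in = x$n_in, n_out = x$n_out)
}

#' Hurdle tests for all (gene, cluster) pairs
#'
#' @inheritParams hurdle_test
#' @param clusters Cluster labels to test (default: all observed).
#' @param genes Genes to test (default: all gene columns).
#' @return Tibble with one row per (gene, cluster) pair (the row-bound
#'   [tidy()] results).
#' @export
hurdle_test_all <- function(et, clusters = NULL, genes = NULL,
                            cluster_col = "genex_cluster") {
  if (is.null(clusters)) clusters <- sort(unique(et[[cluster_col]]))
  if (is.null(genes)) genes <- genex_genes(et)
  purrr::map_dfr(clusters, function(cl) {
    purrr::map_dfr(genes, function(g) {
      tidy(hurdle_test(et, cl, g, cluster_col = cluster_col))
    })
  })
}

#' Filter hurdle results to marker genes
#'
#' Bonferroni-adjusts the overall p-values over all tests performed and
#' retains records with adjusted p <= `alpha` and |average log fold
#' change| > `lfc_cutoff`.
#'
#' @param results Tibble of hurdle results ([hurdle_test_all()]).
#' @param alpha Significance level after correction (default 0.05).
#' @param lfc_cutoff Absolute average logFC cutoff (default 0.25).
#' @param n_tests Number of tests for the Bonferroni correction; defaults
#'   to `nrow(results)`.
#' @return Tibble of retained marker records with `p_adj` and `is_marker`
#'   columns.
#' @export
marker_filter <- function(results, alpha = 0.05, lfc_cutoff = 0.25,
                          n_tests = nrow(results)) {
  results %>%
    mutate(p_adj = pmin(1, .data$p_overall * n_tests),
           is_marker = .data$p_adj <= alpha &
             abs(.data$avg_logFC) > lfc_cutoff) %>%
    filter(.data$is_marker)
}

#' Per-donor cluster occupancy fractions
#'
#' For each individual, the fraction of that individual's cells located in
#' each cluster (fractions sum to 1 per donor; clusters with no cells from
#' a donor get 0).
#'
#' @param cells Data frame with columns `donor_id`, `cohort` and a cluster
#'   label column.
#' @param cluster_col Cluster label column name.
#' @return Tibble: `donor_id`, `cohort`, `cluster`, `n_cells`, `fraction`.
#' @export
cluster_fractions <- function(cells, cluster_col = "genex_cluster") {
  stopifnot(all(c("donor_id", "cohort", cluster_col) %in% names(cells)))
  cohorts <- distinct(as_tibble(cells), .data$donor_id, .data$cohort)
  as_tibble(cells) %>%
    rename(cluster = all_of(cluster_col)) %>%
    count(.data$donor_id, .data$cluster, name = "n_cells") %>%
    tidyr::complete(.data$donor_id, .data$cluster,
                    fill = list(n_cells = 0L)) %>%
    group_by(.data$donor_id) %>%
    mutate(fraction = .data$n_cells / sum(.data$n_cells)) %>%
    ungroup() %>%
    left_join(cohorts, by = "donor_id") %>%
    select("donor_id", "cohort", "cluster", "n_cells", "fraction")
}

#' Cohort composition test per cluster
#'
#' For each cluster, a two-sided Wilcoxon rank-sum test compares the
#' per-donor occupancy fractions between HD and T1D donors, Bonferroni
#' corrected over the number of clusters. A cluster containing no cells at
#' all yields p = 1.
#'
#' @inheritParams cluster_fractions
#' @return Tibble per cluster: cohort medians, `p_wilcoxon`, `p_adj`.
#' @export
cluster_composition_test <- function(cells, cluster_col = "genex_cluster") {
  fr <- cluster_fractions(cells, cluster_col = cluster_col)
  n_donors <- fr %>% distinct(.data$donor_id, .data$cohort) %>%
    count(.data$cohort)
  if (nrow(n_donors) < 2 || any(n_donors$n < 2)) {
    abort("need at least 2 donors per cohort")
  }
  res <- fr %>%
    group_by(.data$cluster) %>%
    summarise(
      median_hd = stats::median(.data$fraction[.data$cohort == "HD"]),
      median_t1d = stats::median(.data$fraction[.data$cohort == "T1D"]),
      p_wilcoxon = if (sum(.data$n_cells) == 0) 1 else {
        p <- suppressWarnings(wilcox.test(
          .data$fraction[.data$cohort == "HD"],
          .data$fraction[.data$cohort == "T1D"])$p.value)
        # all fractions tied (zero rank variance) is a null result
        if (is.nan(p)) 1 else p
      },
      .groups = "drop"
    )
  res %>% mutate(p_adj = pmin(1, .data$p_wilcoxon * dplyr::n()))
}

#' Cluster cells by expression similarity
#'
#' Scales each gene to zero mean and unit variance, projects the cells on
#' the leading principal components, builds a shared-nearest-neighbour
#' (SNN) graph (Jaccard-weighted overlap of the k-nearest-neighbour sets,
#' pruned below a cutoff) and partitions it with Louvain community
#' detection at the given resolution. Labels are 1-based and ordered by
#' decreasing cluster size.
#'
#' @param et Expression tibble from [preprocess_ct()].
#' @param n_pcs Number of principal components (default 10).
#' @param resolution Louvain resolution (default 1).
#' @param k Neighbours for the SNN graph (default 20).
#' @param prune Jaccard pruning cutoff (default 1/15).
#' @param seed Random seed for the Louvain step.
#' @return `et` with an added integer `genex_cluster` column.
#' @export
cluster_cells <- function(et, n_pcs = 10, resolution = 1, k = 20,
                          prune = 1 / 15, seed = 1L) {
  genes <- genex_genes(et)
  mat <- as.matrix(et[, genes, drop = FALSE])
  n <- nrow(mat)
  if (n < n_pcs + 1) abort("need at least n_pcs + 1 cells")
  if (n <= k) abort("fewer cells than the neighbour parameter k")
  sds <- apply(mat, 2, sd)
  mat <- scale(mat, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  pcs <- prcomp(mat, center = FALSE, scale. = FALSE)$x
  pcs <- pcs[, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE]

  d <- as.matrix(stats::dist(pcs))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  memb <- matrix(0L, n, n)
  for (i in seq_len(n)) memb[i, nn[i, ]] <- 1L
  shared <- memb %*% t(memb)
  jaccard <- shared / (2 * k - shared)
  diag(jaccard) <- 0
  jaccard[jaccard < prune] <- 0

  g <- igraph::graph_from_adjacency_matrix(jaccard, mode = "undirected",
                                           weighted = TRUE)
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  raw <- igraph::membership(comm)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  et$genex_cluster <- as.integer(relabel[as.character(raw)])
  attr(et, "genes") <- genes
  et
}
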