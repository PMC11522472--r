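# Build a minimal expression table directly (bypassing the Ct reader).
make_et <- function(y, cluster, gene = "G1") {
  et <- tibble::tibble(cell_id = sprintf("c%03d", seq_along(y)),
                       genex_cluster = cluster)
  et[[gene]] <- y
  attr(et, "genes") <- gene
  et
}

# Independent hurdle oracle: direct glm/lm maximum-likelihood fits.
oracle_hurdle_p <- function(y, in_cluster) {
  z <- as.integer(y > 0)
  g <- factor(in_cluster)
  m1 <- stats::glm(z ~ g, family = stats::binomial())
  m0 <- stats::glm(z ~ 1, family = stats::binomial())
  d_disc <- m0$deviance - m1$deviance
  ye <- y[y > 0]
  ge <- g[y > 0]
  if (length(unique(ge)) == 2) {
    d_cont <- as.numeric(2 * (stats::logLik(stats::lm(ye ~ ge)) -
                                stats::logLik(stats::lm(ye ~ 1))))
    df <- 2
  } else {
    d_cont <- 0
    df <- 1
  }
  pchisq(d_disc + d_cont, df = df, lower.tail = FALSE)
}

test_that("Ct preprocessing follows min-duplicate, missing-to-32, Et transform", {
  ct <- tibble::tibble(
    cell_id = rep(c("c1", "c2", "c3"), each = 4),
    gene = rep(rep(c("g1", "g2"), each = 2), 3),
    replicate = rep(1:2, 6),
    ct = c(24, 25, NA, NA,      # c1: g1 Et 8, g2 Et 0
           30, NA, 20, 22,      # c2: g1 Et 2, g2 Et 12
           NA, NA, NA, NA)      # c3: all missing -> removed
  )
  expect_message(et <- preprocess_ct(ct), "1 cell")
  expect_equal(nrow(et), 2)
  expect_equal(et$g1[et$cell_id == "c1"], 8)
  expect_equal(et$g2[et$cell_id == "c1"], 0)
  expect_equal(et$g1[et$cell_id == "c2"], 2)
  expect_equal(et$g2[et$cell_id == "c2"], 12)
})

test_that("Ct above 40 is treated as missing with a warning; Et stays in [0, 32]", {
  ct <- tibble::tibble(cell_id = "c1", gene = c("g1", "g2"),
                       replicate = 1, ct = c(45, 10))
  expect_warning(et <- preprocess_ct(ct), "above 40")
  expect_equal(et$g1, 0)
  expect_equal(et$g2, 22)

  set.seed(42)
  big <- tidyr::crossing(cell_id = sprintf("c%02d", 1:20),
                         gene = sprintf("g%02d", 1:10),
                         replicate = 1:2) %>%
    dplyr::mutate(ct = ifelse(runif(dplyr::n()) < 0.3, NA,
                              runif(dplyr::n(), 1, 40)))
  et <- suppressMessages(preprocess_ct(big))
  vals <- as.matrix(et[, genex_genes(et)])
  expect_true(all(vals >= 0 & vals <= 32))
})

test_that("hurdle test is null on identical distributions and saturates on separation", {
  # identical Et distributions in both groups: p = 1, logFC = 0
  y <- rep(c(0, 4, 8, 12), 10)
  cl <- rep(rep(1:2, each = 4), 5)
  fit <- hurdle_test(make_et(y, cl), 1, "G1")
  expect_equal(fit$p_overall, 1)
  expect_equal(fit$avg_logFC, 0)

  y2 <- c(rep(10, 10), rep(0, 10))
  fit2 <- hurdle_test(make_et(y2, rep(1:2, each = 10)), 1, "G1")
  expect_lt(fit2$p_overall, 1e-4)
  expect_equal(fit2$avg_logFC, 10)

  expect_error(hurdle_test(make_et(y2, c(1, rep(2, 19))), 1, "G1"),
               "at least 3")
})

test_that("hurdle statistics match the direct glm/lm likelihood oracle on small instances", {
  set.seed(123)
  for (rep_i in 1:20) {
    n <- sample(8:20, 1)
    cl <- sample(rep(1:2, length.out = n))
    y <- ifelse(runif(n) < 0.6, round(runif(n, 1, 15), 1), 0)
    # need both groups represented with >= 3 cells
    if (min(table(cl)) < 3) next
    fit <- hurdle_test(make_et(y, cl), 1, "G1")
    expect_equal(fit$p_overall, oracle_hurdle_p(y, cl == 1),
                 tolerance = 1e-6)
  }
})

test_that("tidy and glance return one-row summaries of a hurdle fit", {
  fit <- hurdle_test(make_et(c(rep(8, 6), rep(0, 6)), rep(1:2, each = 6)),
                     1, "G1")
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 1)
  expect_named(td, c("gene", "cluster", "p_continuous", "p_discrete",
                     "p_overall", "avg_logFC"))
  gl <- generics::glance(fit)
  expect_equal(gl$p.value, fit$p_overall)
})

test_that("marker filter applies Bonferroni and the logFC cutoff", {
  res <- tibble::tibble(
    gene = c("a", "b", "c"), cluster = 1,
    p_continuous = 1, p_discrete = 1,
    p_overall = c(0.001, 0.001, 0.2),
    avg_logFC = c(0.3, 0.2, 1.0)
  )
  kept <- marker_filter(res, alpha = 0.05, n_tests = 10)
  expect_equal(kept$gene, "a")
  expect_equal(kept$p_adj, 0.01)
  # idempotent in what it retains
  again <- marker_filter(kept, alpha = 0.05, n_tests = 10)
  expect_equal(again$gene, kept$gene)
})

test_that("cluster fractions sum to 1 per donor and the composition test is calibrated", {
  cells <- tidyr::crossing(donor_id = sprintf("d%d", 1:6),
                           genex_cluster = 1:3) %>%
    dplyr::mutate(cohort = ifelse(donor_id %in% c("d1", "d2", "d3"),
                                  "HD", "T1D"))
  fr <- cluster_fractions(cells)
  sums <- tapply(fr$fraction, fr$donor_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # identical fractions in each cohort -> p = 1 everywhere
  res <- cluster_composition_test(cells)
  expect_true(all(res$p_wilcoxon == 1))
})

test_that("composition test matches exact rank-sum enumeration for complete separation", {
  # one donor-level fraction per cohort member, fully separated: the
  # two-sided exact rank-sum p for 3 vs 3 is 2 / choose(6, 3)
  cells <- dplyr::bind_rows(
    purrr::map_dfr(1:3, function(i) tibble::tibble(
      donor_id = paste0("h", i), cohort = "HD",
      genex_cluster = c(rep(1, 8 + i), rep(2, 2 - (i > 2))))),
    purrr::map_dfr(1:3, function(i) tibble::tibble(
      donor_id = paste0("t", i), cohort = "T1D",
      genex_cluster = c(rep(1, 1), rep(2, 8 + i))))
  )
  res <- cluster_composition_test(cells)
  p_exact <- 2 / choose(6, 3)
  expect_equal(res$p_wilcoxon[res$cluster == 1], p_exact)
  expect_equal(res$p_adj[res$cluster == 1], min(1, p_exact * 2))
})

rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- same_a == same_b
  (sum(agree[upper.tri(agree)])) / choose(n, 2)
}

test_that("SNN-Louvain clustering recovers well-separated blobs", {
  set.seed(99)
  n_per <- 100
  genes <- sprintf("g%02d", 1:12)
  centers <- matrix(0, 3, 12)
  centers[1, 1:4] <- 8; centers[2, 5:8] <- 8; centers[3, 9:12] <- 8
  truth <- rep(1:3, each = n_per)
  mat <- centers[truth, ] + matrix(rnorm(3 * n_per * 12), ncol = 12)
  et <- tibble::as_tibble(as.data.frame(mat))
  names(et) <- genes
  et <- dplyr::mutate(et, cell_id = sprintf("c%03d", seq_len(3 * n_per)),
                      .before = 1)
  attr(et, "genes") <- genes
  out <- cluster_cells(et, n_pcs = 10, resolution = 1, seed = 5)
  expect_equal(dplyr::n_distinct(out$genex_cluster), 3)
  expect_gt(rand_index(out$genex_cluster, truth), 0.95)

  # permuting cell order leaves the partition unchanged up to renumbering
  perm <- sample(nrow(et))
  out2 <- cluster_cells(et[perm, ], n_pcs = 10, resolution = 1, seed = 5)
  expect_equal(rand_index(out2$genex_cluster, truth[perm]),
               rand_index(out$genex_cluster, truth))
  expect_equal(rand_index(out$genex_cluster[perm], out2$genex_cluster), 1)
})

test_that("a homogeneous blob stays one cluster at low resolution", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:12)
  et <- tibble::as_tibble(as.data.frame(
    matrix(rnorm(80 * 12), ncol = 12)))
  names(et) <- genes
  et$cell_id <- sprintf("c%03d", 1:80)
  attr(et, "genes") <- genes
  out <- cluster_cells(et, n_pcs = 10, resolution = 0.1, seed = 5)
  expect_equal(dplyr::n_distinct(out$genex_cluster), 1)
  expect_error(cluster_cells(et[1:15, ], n_pcs = 10, k = 20), "neighbour")
})
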