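# Synthetic paired single-cell / bulk TCR repertoire generator with a
# planted-truth manifest. Background clones are globally unique random
# productive CDR3s (so planted sharing is the only sharing); convergence is
# planted through verified synonymous codon substitutions; every planted
# quantity is recorded in the manifest from the generator's own
# bookkeeping, independently of the analysis functions.

# 48-gene single-cell qPCR panel (immune-response genes + SRP14
# housekeeping)
.genex_panel <- c(
  "IL4", "TBX21", "IL17A", "RORA", "CD40", "IL13", "TGFB1", "CCR3",
  "CXCR5", "CCR10", "CD52", "IFNG", "TNF", "GATA3", "IL9", "BCL6",
  "CCL5", "IL17F", "ICOS", "IKZF2", "IL22", "CD4", "REL", "IL18RAP",
  "CTLA4", "IL10", "RGS16", "IL2", "AHR", "MAF", "CCR6", "EGR2",
  "EOMES", "CD8A", "CSF2", "PDCD1", "CCR7", "IL21", "CD3E", "CCR4",
  "TNFRSF18", "RORC", "CCR5", "FOXP3", "NFATC2", "IL7R", "TNFRSF4",
  "SRP14"
)

#' Simulation configuration
#'
#' Defines the cohort conditions the generator emulates: 31 true-naive
#' and 31 central-memory repertoires (17 HD + 14 T1D donors) plus 16 Treg
#' and 16 Tscm repertoires (94 in total), 12 single-cell donors (5 HD, 7
#' T1D) with 10 antigen-specific clonotypes each, power-law clone sizes,
#' a planted publicity spectrum, planted convergence via synonymous
#' variants, planted cohort-exclusive clonotypes, planted clonal
#' expansions, a 48-gene qPCR panel with cluster-structured expression,
#' and ELISPOT/AIM assay tables.
#'
#' @param seed Integer root seed; all stage seeds derive from it.
#' @param n_hd_donors,n_t1d_donors Donors per cohort with TN and CM
#'   repertoires.
#' @param n_treg_tscm_per_cohort Donors per cohort that additionally have
#'   Treg and Tscm repertoires.
#' @param n_sc_hd,n_sc_t1d Single-cell donors per cohort (must have
#'   Treg/Tscm repertoires).
#' @param clones_per_repertoire Background clones per repertoire.
#' @param reads_per_repertoire Total reads per repertoire (clone counts are
#'   multinomial over power-law weights, so every repertoire has exactly
#'   this depth).
#' @param power_exponent Power-law (Pareto) exponent for clone-size
#'   weights (> 1).
#' @param n_clonotypes_per_donor Unique antigen-specific clonotypes per
#'   single-cell donor.
#' @param expansion_sizes Cell counts of the planted expansion groups (one
#'   group per single-cell donor, recycled over donors).
#' @param n_confined_expansions How many expansion groups are confined to a
#'   single gene-expression cluster.
#' @param n_paired_expansions How many expansion groups share the alpha
#'   chain as well as the beta chain.
#' @param n_clusters,markers_per_cluster,cluster_shift,et_sd,dropout,dup_missing
#'   Gene-expression structure: number of true clusters, dedicated marker
#'   genes per cluster, Et shift of a marker gene in its cluster, Gaussian
#'   Et noise, per-(cell, gene) dropout probability, per-replicate missing
#'   probability.
#' @param marker_gate Index-sort/AIM gate cutoff applied to every marker.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 20260101L,
                       n_hd_donors = 17L, n_t1d_donors = 14L,
                       n_treg_tscm_per_cohort = 8L,
                       n_sc_hd = 5L, n_sc_t1d = 7L,
                       clones_per_repertoire = 600L,
                       reads_per_repertoire = 100000L,
                       power_exponent = 2.5,
                       n_clonotypes_per_donor = 10L,
                       expansion_sizes = c(3L, 2L, 2L, 4L, 2L, 3L, 2L, 2L,
                                           3L, 2L),
                       n_confined_expansions = 3L,
                       n_paired_expansions = 4L,
                       n_clusters = 3L,
                       markers_per_cluster = 3L,
                       cluster_shift = 8,
                       et_sd = 1,
                       dropout = 0.2,
                       dup_missing = 0.15,
                       marker_gate = 100) {
  stopifnot(power_exponent > 1, n_sc_hd <= n_treg_tscm_per_cohort,
            n_sc_t1d <= n_treg_tscm_per_cohort,
            n_treg_tscm_per_cohort <= min(n_hd_donors, n_t1d_donors),
            n_confined_expansions <= length(expansion_sizes))
  cfg <- list(
    seed = as.integer(seed),
    n_hd_donors = n_hd_donors, n_t1d_donors = n_t1d_donors,
    n_treg_tscm_per_cohort = n_treg_tscm_per_cohort,
    n_sc_hd = n_sc_hd, n_sc_t1d = n_sc_t1d,
    clones_per_repertoire = clones_per_repertoire,
    reads_per_repertoire = reads_per_repertoire,
    power_exponent = power_exponent,
    n_clonotypes_per_donor = n_clonotypes_per_donor,
    # planted publicity spectrum: per subset, how many donors carry each
    # plant, its convergence (synonymous variants) and per-variant reads
    publicity_plan = tibble(
      plant = c("TN_xpublic", "TN_public", "TN_private", "TN_ultraprivate",
                "CM_xpublic", "CM_public", "CM_ultraprivate",
                "Treg_public", "Treg_ultraprivate", "Tscm_ultraprivate"),
      subset = c("TN", "TN", "TN", "TN", "CM", "CM", "CM", "Treg", "Treg",
                 "Tscm"),
      n_seed = c(24L, 10L, 3L, 1L, 25L, 9L, 1L, 5L, 1L, 1L),
      convergence = c(2L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L),
      count = c(50L, 50L, 50L, 50L, 50L, 50L, 50L, 50L, 50L, 50L)
    ),
    # planted monotone convergence -> frequency relation in TN: clonotype i
    # has i synonymous variants, each at 20 * i reads, in the same 5 donors
    correlation_plan = list(n = 8L, subset = "TN", n_seed = 5L,
                            count_step = 20L),
    # cohort-exclusive clonotypes in CM
    exclusivity_plan = list(n_hd_only = 5L, n_t1d_only = 4L, n_seed = 3L,
                            subset = "CM", count = 60L),
    # clonotypes planted in both Treg and CM of their source donor
    ratio_plan = tibble(count_treg = c(400L, 200L, 100L),
                        count_cm = c(200L, 200L, 400L)),
    expansion_sizes = as.integer(expansion_sizes),
    n_confined_expansions = n_confined_expansions,
    n_paired_expansions = n_paired_expansions,
    n_clusters = n_clusters,
    genes = .genex_panel,
    hk_gene = "SRP14",
    markers_per_cluster = markers_per_cluster,
    cluster_shift = cluster_shift,
    et_sd = et_sd, dropout = dropout, dup_missing = dup_missing,
    marker_gate = marker_gate,
    elispot = list(n_hd = 36L, n_t1d = 40L,
                   type_probs = c(IFNg_only = 0.2, IL10_only = 0.2,
                                  dual = 0.2, negative = 0.4),
                   pos_antigen = 40, pos_diluent = 8,
                   neg_antigen = 12, neg_diluent = 10),
    aim = list(n_hd = 11L, n_t1d = 10L, n_events = 2000L,
               freq = c(no_antigen = 0.001, GAD = 0.01, SEB = 0.1))
  )
  class(cfg) <- "sim_config"
  cfg
}

# --- sequence machinery ----------------------------------------------------

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# n random productive CDR3 nucleotide sequences (length 36-48 nt), framed
# by the conserved C...F anchors. Not guaranteed unique.
random_cdr3_nt <- function(n) {
  codons <- .sense_codons()
  inner <- sample(10:14, n, replace = TRUE)
  maxi <- max(inner)
  mat <- matrix(sample(codons, n * maxi, replace = TRUE), nrow = maxi)
  vapply(seq_len(n), function(i) {
    paste0("TGT", paste(mat[seq_len(inner[i]), i], collapse = ""), "TTT")
  }, character(1))
}

# pool of n globally unique productive CDR3s whose translations avoid
# `exclude_aa`
unique_cdr3_pool <- function(n, exclude_aa = character(0)) {
  pool <- character(0)
  while (length(pool) < n) {
    cand <- unique(random_cdr3_nt(ceiling((n - length(pool)) * 1.1) + 10))
    cand <- setdiff(cand, pool)
    aa <- translate_cdr3(cand)
    cand <- cand[!aa %in% exclude_aa]
    pool <- c(pool, cand)
  }
  pool[seq_len(n)]
}

#' Synonymous nucleotide variants of a CDR3
#'
#' Generates `k` distinct nucleotide sequences (the input first) that all
#' translate to the same amino-acid sequence, by substituting synonymous
#' codons one position at a time. Every returned variant is verified to
#' preserve the translation.
#'
#' @param nt In-frame CDR3 nucleotide sequence.
#' @param k Number of variants required (including the input).
#' @return Character vector of `k` distinct nucleotide sequences.
#' @export
synonymous_variants <- function(nt, k) {
  nt <- toupper(nt)
  if (k < 1) abort("k must be >= 1")
  n_cod <- nchar(nt) / 3
  codons <- substring(nt, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  gc <- Biostrings::GENETIC_CODE
  syn <- split(names(gc), unname(gc))
  variants <- nt
  for (pos in seq_len(n_cod)) {
    if (length(variants) >= k) break
    alts <- setdiff(syn[[unname(gc[codons[pos]])]], codons[pos])
    for (alt in alts) {
      if (length(variants) >= k) break
      mod <- codons
      mod[pos] <- alt
      variants <- c(variants, paste(mod, collapse = ""))
    }
  }
  if (length(variants) < k) {
    abort(sprintf("cannot generate %d synonymous variants of '%s'", k, nt))
  }
  stopifnot(all(translate_cdr3(variants) == translate_cdr3(nt)))
  variants[seq_len(k)]
}

# --- donor and plant tables ------------------------------------------------

build_donors <- function(cfg) {
  hd <- sprintf("HD%02d", seq_len(cfg$n_hd_donors))
  t1d <- sprintf("T1D%02d", seq_len(cfg$n_t1d_donors))
  donors <- tibble(
    donor_id = c(hd, t1d),
    cohort = c(rep("HD", cfg$n_hd_donors), rep("T1D", cfg$n_t1d_donors))
  )
  # Treg/Tscm donors are the first n per cohort; single-cell donors are a
  # subset of those, so every single-cell donor has all four repertoires.
  donors$has_treg_tscm <-
    donors$donor_id %in% c(hd[seq_len(cfg$n_treg_tscm_per_cohort)],
                           t1d[seq_len(cfg$n_treg_tscm_per_cohort)])
  donors$is_sc_donor <-
    donors$donor_id %in% c(hd[seq_len(cfg$n_sc_hd)],
                           t1d[seq_len(cfg$n_sc_t1d)])
  donors
}

# One repertoire per donor x subset: TN and CM for everyone, Treg and Tscm
# for the flagged donors.
build_repertoire_keys <- function(donors) {
  bind_rows(
    tidyr::crossing(donors[, c("donor_id", "cohort")],
                    tibble(subset = c("TN", "CM"))),
    tidyr::crossing(donors[donors$has_treg_tscm, c("donor_id", "cohort")],
                    tibble(subset = c("Treg", "Tscm")))
  ) %>% arrange(match(.data$subset, .subsets), .data$donor_id)
}

# Build the plant catalogue: every planted clonotype with its source
# single-cell donor, target subset, seeded donors, convergence and
# per-variant read count.
build_plants <- function(cfg, donors, rep_keys) {
  sc_donors <- donors$donor_id[donors$is_sc_donor]
  plan <- list()

  pub <- cfg$publicity_plan
  for (i in seq_len(nrow(pub))) {
    plan[[length(plan) + 1]] <- tibble(
      plant_id = paste0("PUB_", pub$plant[i]), role = "publicity",
      subset = pub$subset[i], n_seed = pub$n_seed[i],
      convergence = pub$convergence[i], count = pub$count[i],
      seed_in_source_only = pub$n_seed[i] == 1L
    )
  }
  corr <- cfg$correlation_plan
  for (i in seq_len(corr$n)) {
    plan[[length(plan) + 1]] <- tibble(
      plant_id = sprintf("CORR_%02d", i), role = "correlation",
      subset = corr$subset, n_seed = corr$n_seed,
      convergence = i, count = corr$count_step * i,
      seed_in_source_only = FALSE
    )
  }
  exc <- cfg$exclusivity_plan
  for (i in seq_len(exc$n_hd_only)) {
    plan[[length(plan) + 1]] <- tibble(
      plant_id = sprintf("EXC_HD_%02d", i), role = "exclusivity_hd",
      subset = exc$subset, n_seed = exc$n_seed, convergence = 1L,
      count = exc$count, seed_in_source_only = FALSE
    )
  }
  for (i in seq_len(exc$n_t1d_only)) {
    plan[[length(plan) + 1]] <- tibble(
      plant_id = sprintf("EXC_T1D_%02d", i), role = "exclusivity_t1d",
      subset = exc$subset, n_seed = exc$n_seed, convergence = 1L,
      count = exc$count, seed_in_source_only = FALSE
    )
  }
  for (i in seq_len(nrow(cfg$ratio_plan))) {
    plan[[length(plan) + 1]] <- tibble(
      plant_id = sprintf("RATIO_%02d", i), role = "ratio",
      subset = "ratio", n_seed = 1L, convergence = 1L,
      count = NA_integer_, seed_in_source_only = TRUE
    )
  }
  plants <- bind_rows(plan)

  # assign source donors round-robin over the single-cell donors
  plants$source_donor <- rep(sc_donors, length.out = nrow(plants))
  plants <- left_join(plants,
                      rename(donors[, c("donor_id", "cohort")],
                             source_donor = "donor_id",
                             source_cohort = "cohort"),
                      by = "source_donor")

  # unique base sequences with unique translations
  repeat {
    base <- unique_cdr3_pool(nrow(plants))
    if (n_distinct(translate_cdr3(base)) == nrow(plants)) break
  }
  plants$cdr3_nt <- base
  plants$cdr3_aa <- translate_cdr3(base)

  # choose seeded donors per plant
  correlation_donors <- NULL
  seeds <- vector("list", nrow(plants))
  for (i in seq_len(nrow(plants))) {
    p <- plants[i, ]
    if (p$role == "ratio") {
      seeds[[i]] <- tibble(plant_id = p$plant_id,
                           donor_id = p$source_donor,
                           subset = c("Treg", "CM"),
                           count = c(cfg$ratio_plan$count_treg[
                             as.integer(sub("RATIO_", "", p$plant_id))],
                             cfg$ratio_plan$count_cm[
                               as.integer(sub("RATIO_", "", p$plant_id))]))
      next
    }
    eligible <- rep_keys$donor_id[rep_keys$subset == p$subset]
    if (p$role == "exclusivity_hd") {
      eligible <- intersect(eligible,
                            donors$donor_id[donors$cohort == "HD"])
    } else if (p$role == "exclusivity_t1d") {
      eligible <- intersect(eligible,
                            donors$donor_id[donors$cohort == "T1D"])
    }
    if (p$seed_in_source_only) {
      chosen <- p$source_donor
    } else if (grepl("^exclusivity", p$role)) {
      # single-cohort seeding; the source donor may belong to the other
      # cohort and must not be forced into the seed set
      chosen <- sort(sample(eligible, p$n_seed))
    } else if (p$role == "correlation") {
      # all correlation plants share one donor set so that equal per-variant
      # counts map to exactly proportional mean frequencies
      if (is.null(correlation_donors)) {
        correlation_donors <- sort(sample(eligible, p$n_seed))
      }
      chosen <- correlation_donors
    } else {
      # seed the source donor plus a random draw of others
      others <- setdiff(eligible, p$source_donor)
      chosen <- sort(c(p$source_donor,
                       sample(others, p$n_seed - 1L)))
    }
    seeds[[i]] <- tibble(plant_id = p$plant_id, donor_id = chosen,
                         subset = p$subset, count = p$count)
  }
  seed_tbl <- bind_rows(seeds) %>%
    left_join(donors[, c("donor_id", "cohort")], by = "donor_id") %>%
    left_join(plants[, c("plant_id", "role", "source_donor",
                         "source_cohort", "cdr3_nt", "cdr3_aa",
                         "convergence")],
              by = "plant_id")
  list(plants = plants, seeds = seed_tbl)
}

# --- bulk repertoires ------------------------------------------------------

#' Simulate bulk TCRB repertoires with planted clonotypes
#'
#' Background clones are globally unique random productive CDR3s (no
#' cross-donor background sharing), with read counts multinomial over
#' power-law weights so every repertoire has exactly
#' `reads_per_repertoire` reads. Planted clonotypes are injected into
#' their designated repertoires as `convergence` distinct synonymous
#' nucleotide variants at equal per-variant counts.
#'
#' @param cfg A [sim_config()].
#' @return List with `repertoires` (row-bound clone tibble), `donors`, and
#'   `manifest` (planted truth: plants, per-repertoire seeds with achieved
#'   frequencies, publicity, exclusivity, correlation and tracking-rate
#'   tables).
#' @export
simulate_bulk <- function(cfg) {
  withr::with_seed(cfg$seed + 1L, {
    donors <- build_donors(cfg)
    rep_keys <- build_repertoire_keys(donors)
    built <- build_plants(cfg, donors, rep_keys)
    plants <- built$plants
    seed_tbl <- built$seeds

    # nucleotide variants per plant (variant 1 = the single-cell sequence)
    variant_tbl <- purrr::map_dfr(seq_len(nrow(plants)), function(i) {
      tibble(plant_id = plants$plant_id[i],
             variant = seq_len(plants$convergence[i]),
             cdr3_nt = synonymous_variants(plants$cdr3_nt[i],
                                           plants$convergence[i]),
             cdr3_aa = plants$cdr3_aa[i])
    })

    n_bg <- nrow(rep_keys) * cfg$clones_per_repertoire
    bg_pool <- unique_cdr3_pool(n_bg, exclude_aa = plants$cdr3_aa)
    v_genes <- sprintf("TRBV%d", 1:30)
    j_genes <- c(sprintf("TRBJ1-%d", 1:6), sprintf("TRBJ2-%d", 1:7))

    reps <- vector("list", nrow(rep_keys))
    for (r in seq_len(nrow(rep_keys))) {
      key <- rep_keys[r, ]
      planted <- seed_tbl %>%
        filter(.data$donor_id == key$donor_id,
               .data$subset == key$subset) %>%
        inner_join(variant_tbl, by = "plant_id",
                   relationship = "many-to-many")
      bg_seq <- bg_pool[((r - 1) * cfg$clones_per_repertoire + 1):
                          (r * cfg$clones_per_repertoire)]
      # power-law clone-size weights, multinomial to exact read depth
      w <- runif(length(bg_seq))^(-1 / (cfg$power_exponent - 1))
      reads_bg <- cfg$reads_per_repertoire - sum(planted$count)
      if (reads_bg <= 0) abort("planted reads exceed the repertoire depth")
      counts <- as.vector(stats::rmultinom(1, reads_bg, prob = w))
      keep <- counts > 0
      clones <- tibble(
        cdr3_nt = c(bg_seq[keep], planted$cdr3_nt.y),
        cdr3_aa = c(translate_cdr3(bg_seq[keep]), planted$cdr3_aa.y),
        v_call = sample(v_genes, sum(keep) + nrow(planted), replace = TRUE),
        j_call = sample(j_genes, sum(keep) + nrow(planted), replace = TRUE),
        count = c(counts[keep], planted$count)
      )
      reps[[r]] <- as_repertoire(clones, donor_id = key$donor_id,
                                 cohort = key$cohort, subset = key$subset)
    }
    repertoires <- bind_rows(reps)

    manifest <- build_manifest(cfg, donors, rep_keys, plants, seed_tbl)
    list(repertoires = repertoires, donors = donors, manifest = manifest)
  })
}

# Planted truth, derived from the generator's own seed table (never from
# the analysis functions' matching machinery).
build_manifest <- function(cfg, donors, rep_keys, plants, seed_tbl) {
  total <- cfg$reads_per_repertoire
  seeds <- seed_tbl %>%
    mutate(
      # equal per-variant counts: amino-acid frequency (mean over variants)
      # equals the per-variant frequency; nucleotide frequency is that of
      # variant 1 (the single-cell sequence)
      aa_freq = .data$count / total,
      nt_freq = .data$count / total
    )
  n_searched <- rep_keys %>% count(.data$subset, name = "n_searched")
  pub <- seeds %>%
    group_by(.data$plant_id, .data$cdr3_aa, .data$source_donor,
             .data$source_cohort, .data$subset) %>%
    summarise(n_found = n(),
              convergence = .data$convergence[1],
              mean_aa_freq = mean(.data$aa_freq),
              source_only = n() == 1 &&
                all(.data$donor_id == .data$source_donor[1]),
              .groups = "drop") %>%
    left_join(n_searched, by = "subset") %>%
    mutate(pct = 100 * .data$n_found / .data$n_searched,
           category = classify_publicity(.data$n_found, .data$n_searched,
                                         .data$source_only))
  exclus <- seeds %>%
    filter(.data$subset %in% c("TN", "CM")) %>%
    group_by(.data$subset, .data$plant_id, .data$cdr3_aa) %>%
    summarise(n_hd = sum(.data$cohort == "HD"),
              n_t1d = sum(.data$cohort == "T1D"), .groups = "drop") %>%
    mutate(exclusivity = dplyr::case_when(
      .data$n_hd >= 1 & .data$n_t1d == 0 ~ "hd_only",
      .data$n_t1d >= 1 & .data$n_hd == 0 ~ "t1d_only",
      TRUE ~ NA_character_)) %>%
    filter(!is.na(.data$exclusivity))
  corr <- pub %>%
    filter(grepl("^CORR_", .data$plant_id)) %>%
    select("plant_id", "cdr3_aa", x = "convergence", y = "mean_aa_freq") %>%
    arrange(.data$plant_id)
  ratio <- seeds %>%
    filter(grepl("^RATIO_", .data$plant_id)) %>%
    select("plant_id", "cdr3_nt", "source_donor", "subset", "nt_freq") %>%
    tidyr::pivot_wider(names_from = "subset", values_from = "nt_freq") %>%
    mutate(true_ratio = .data$Treg / .data$CM)
  tracking <- plants %>%
    count(.data$source_donor, name = "n_tracked") %>%
    mutate(n_clonotypes = cfg$n_clonotypes_per_donor,
           rate_pct = 100 * .data$n_tracked / .data$n_clonotypes)
  list(plants = plants, seeds = seeds, publicity = pub,
       exclusivity = exclus, correlation = corr, ratio = ratio,
       tracking = tracking)
}

# --- single cells ----------------------------------------------------------

#' Simulate antigen-specific single cells, their qPCR Ct matrix and
#' index-sort markers
#'
#' Each single-cell donor carries `n_clonotypes_per_donor` unique
#' clonotypes: the planted ones sourced to that donor (present in bulk, so
#' the donor's true tracking rate is their share) plus de novo clonotypes
#' guaranteed absent from every repertoire. Clonal expansions are planted
#' by emitting several cells with an identical beta (and, for paired
#' groups, alpha) nucleotide chain. Ct readings are drawn around
#' per-cluster gene means (duplicate wells, censoring at Ct 32, dropout
#' and per-replicate missingness); index-sort marker intensities are drawn
#' on the known side of the gates.
#'
#' @param cfg A [sim_config()].
#' @param bulk Result of [simulate_bulk()] under the same config.
#' @return List with `cells` (single-cell clonotype tibble), `ct` (long Ct
#'   table), `cell_meta`, `markers` (index-sort intensities), `gates`, and
#'   `manifest` (true cluster/phenotype per cell, expansion groups, gene
#'   means per cluster).
#' @export
simulate_sc <- function(cfg, bulk) {
  withr::with_seed(cfg$seed + 2L, {
    donors <- bulk$donors
    plants <- bulk$manifest$plants
    sc_donors <- donors$donor_id[donors$is_sc_donor]

    # de novo clonotypes: unique, absent from bulk at nt and aa level
    n_denovo <- sum(pmax(0, cfg$n_clonotypes_per_donor -
                           table(factor(plants$source_donor,
                                        levels = sc_donors))))
    exclude_aa <- unique(c(plants$cdr3_aa,
                           unique(bulk$repertoires$cdr3_aa)))
    denovo_pool <- unique_cdr3_pool(n_denovo, exclude_aa = exclude_aa)
    denovo_pool <- setdiff(denovo_pool, bulk$repertoires$cdr3_nt)
    alpha_pool <- unique_cdr3_pool(3L * n_denovo + 3L * nrow(plants) + 200L)
    ai <- 0L
    next_alpha <- function() {
      ai <<- ai + 1L
      alpha_pool[ai]
    }

    v_genes <- sprintf("TRBV%d", 1:30)
    j_genes <- c(sprintf("TRBJ1-%d", 1:6), sprintf("TRBJ2-%d", 1:7))

    cells_list <- list()
    expansion_truth <- list()
    di <- 0L
    pool_at <- 0L
    for (d in sc_donors) {
      di <- di + 1L
      cohort <- donors$cohort[donors$donor_id == d]
      planted_nt <- plants$cdr3_nt[plants$source_donor == d]
      n_new <- cfg$n_clonotypes_per_donor - length(planted_nt)
      denovo_nt <- denovo_pool[pool_at + seq_len(n_new)]
      pool_at <- pool_at + n_new
      clono <- tibble(cdr3b_nt = c(planted_nt, denovo_nt),
                      planted = c(rep(TRUE, length(planted_nt)),
                                  rep(FALSE, n_new)))
      clono$cdr3a_nt <- vapply(seq_len(nrow(clono)),
                               function(i) next_alpha(), character(1))
      clono$v_gene_b <- sample(v_genes, nrow(clono), replace = TRUE)
      clono$j_gene_b <- sample(j_genes, nrow(clono), replace = TRUE)

      # one cell per clonotype, plus extra cells for this donor's planted
      # expansion (on the donor's first de novo clonotype)
      n_cells_per <- rep(1L, nrow(clono))
      exp_idx <- (di - 1L) %% length(cfg$expansion_sizes) + 1L
      if (di <= length(cfg$expansion_sizes)) {
        target <- which(!clono$planted)[1]
        n_cells_per[target] <- cfg$expansion_sizes[exp_idx]
        paired <- di <= cfg$n_paired_expansions
        expansion_truth[[length(expansion_truth) + 1]] <- tibble(
          donor_id = d, cdr3b_nt = clono$cdr3b_nt[target],
          size = cfg$expansion_sizes[exp_idx], paired = paired,
          confined = di <= cfg$n_confined_expansions
        )
      }
      dcells <- clono[rep(seq_len(nrow(clono)), n_cells_per), ]
      # paired expansions share the alpha chain; unpaired expansion cells
      # get their own alpha
      dup <- duplicated(dcells$cdr3b_nt)
      if (any(dup) && di > cfg$n_paired_expansions &&
          di <= length(cfg$expansion_sizes)) {
        dcells$cdr3a_nt[dup] <- vapply(seq_len(sum(dup)),
                                       function(i) next_alpha(),
                                       character(1))
      }
      dcells$cell_id <- sprintf("%s_c%02d", d, seq_len(nrow(dcells)))
      dcells$donor_id <- d
      dcells$cohort <- cohort
      cells_list[[d]] <- dcells
    }
    cells <- bind_rows(cells_list)
    cells$specificity <- "GAD"
    cells$cdr3b_aa <- translate_cdr3(cells$cdr3b_nt)
    cells$cdr3a_aa <- translate_cdr3(cells$cdr3a_nt)
    expansions <- bind_rows(expansion_truth)

    # true gene-expression clusters: expansion cells are assigned to honour
    # the planted single-cluster confinement; all other cells round-robin
    cells$true_cluster <- NA_integer_
    exp_key <- paste(expansions$donor_id, expansions$cdr3b_nt)
    cell_key <- paste(cells$donor_id, cells$cdr3b_nt)
    for (i in seq_len(nrow(expansions))) {
      members <- which(cell_key == exp_key[i])
      if (expansions$confined[i]) {
        cells$true_cluster[members] <- (i %% cfg$n_clusters) + 1L
      } else {
        cells$true_cluster[members] <-
          ((seq_along(members) - 1L) %% cfg$n_clusters) + 1L
      }
    }
    free <- which(is.na(cells$true_cluster))
    cells$true_cluster[free] <- ((seq_along(free) - 1L) %%
                                   cfg$n_clusters) + 1L
    cells$true_phenotype <- sample(.phenotypes, nrow(cells),
                                   replace = TRUE)

    # per-cluster gene means: baseline plus a shift on each cluster's
    # dedicated marker genes; housekeeping gene high everywhere
    genes <- cfg$genes
    base_mean <- stats::setNames(runif(length(genes), 2, 8), genes)
    base_mean[cfg$hk_gene] <- 20
    marker_genes <- setdiff(genes, cfg$hk_gene)[
      seq_len(cfg$n_clusters * cfg$markers_per_cluster)]
    marker_map <- tibble(
      gene = marker_genes,
      cluster = rep(seq_len(cfg$n_clusters), each = cfg$markers_per_cluster)
    )
    mean_mat <- matrix(rep(base_mean, cfg$n_clusters), ncol = cfg$n_clusters,
                       dimnames = list(genes, seq_len(cfg$n_clusters)))
    for (i in seq_len(nrow(marker_map))) {
      mean_mat[marker_map$gene[i], marker_map$cluster[i]] <-
        mean_mat[marker_map$gene[i], marker_map$cluster[i]] +
        cfg$cluster_shift
    }

    n_cells <- nrow(cells)
    ct_rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      mu <- mean_mat[, cells$true_cluster[i]]
      et <- pmin(32, pmax(0, rnorm(length(genes), mu, cfg$et_sd)))
      drop_gene <- runif(length(genes)) < cfg$dropout
      drop_gene[genes == cfg$hk_gene] <- FALSE
      ct_true <- 32 - et
      r1 <- ct_true + rnorm(length(genes), 0, 0.1)
      r2 <- ct_true + rnorm(length(genes), 0, 0.1)
      r1[drop_gene | runif(length(genes)) < cfg$dup_missing |
           ct_true >= 32] <- NA
      r2[drop_gene | runif(length(genes)) < cfg$dup_missing |
           ct_true >= 32] <- NA
      ct_rows[[i]] <- tibble(cell_id = cells$cell_id[i],
                             gene = rep(genes, 2),
                             replicate = rep(1:2, each = length(genes)),
                             ct = pmax(c(r1, r2), 0.1))
    }
    ct <- bind_rows(ct_rows)

    # index-sort marker intensities on the known side of each gate
    g <- cfg$marker_gate
    pos <- function(n) g * runif(n, 1.5, 3)
    neg <- function(n) g * runif(n, 0.2, 0.8)
    ph <- cells$true_phenotype
    markers <- tibble(
      cell_id = cells$cell_id,
      donor_id = cells$donor_id,
      CD45RO = ifelse(ph %in% c("CM", "EM"), pos(n_cells), neg(n_cells)),
      CD27 = ifelse(ph %in% c("TN", "CM", "Tscm"), pos(n_cells),
                    neg(n_cells)),
      CD95 = ifelse(ph == "Tscm", pos(n_cells), neg(n_cells)),
      CD154 = pos(n_cells),
      CD69 = pos(n_cells)
    )
    gates <- list(CD45RO = g, CD27 = g, CD95 = g, CD154 = g, CD69 = g)

    cell_meta <- cells %>%
      select("cell_id", "donor_id", "cohort", "true_cluster",
             "true_phenotype")
    sc_tbl <- cells %>%
      mutate(phenotype = .data$true_phenotype) %>%
      select("cell_id", "donor_id", "cohort", "specificity", "cdr3b_nt",
             "cdr3b_aa", "cdr3a_nt", "cdr3a_aa", "v_gene_b", "j_gene_b",
             "phenotype")
    manifest <- list(cells = cell_meta, expansions = expansions,
                     fraction_single_cluster =
                       sum(expansions$confined) / nrow(expansions),
                     gene_means = mean_mat, marker_map = marker_map)
    list(cells = sc_tbl, ct = ct, cell_meta = cell_meta,
         markers = markers, gates = gates, manifest = manifest)
  })
}

# --- assay tables ----------------------------------------------------------

#' Simulate ELISPOT and AIM assay tables
#'
#' ELISPOT triplicate spot counts are Poisson around per-donor antigen and
#' diluent means determined by the donor's planted response type; AIM
#' tables contain per-event CD154/CD69 intensities with a known gate.
#'
#' @param cfg A [sim_config()].
#' @return List with `elispot_wells`, `elispot_truth`, `aim_events`,
#'   `aim_gates`, `aim_truth`.
#' @export
simulate_assays <- function(cfg) {
  withr::with_seed(cfg$seed + 3L, {
    el <- cfg$elispot
    donors <- tibble(
      donor_id = c(sprintf("EHD%02d", seq_len(el$n_hd)),
                   sprintf("ET1D%02d", seq_len(el$n_t1d))),
      cohort = c(rep("HD", el$n_hd), rep("T1D", el$n_t1d)),
      type = sample(names(el$type_probs), el$n_hd + el$n_t1d,
                    replace = TRUE, prob = el$type_probs)
    )
    one_donor <- function(donor_id, type) {
      purrr::map_dfr(c("IFNg", "IL10"), function(cyt) {
        positive <- switch(type, dual = TRUE,
                           IFNg_only = cyt == "IFNg",
                           IL10_only = cyt == "IL10",
                           negative = FALSE)
        am <- if (positive) el$pos_antigen else el$neg_antigen
        dm <- if (positive) el$pos_diluent else el$neg_diluent
        tibble(donor_id = donor_id, cytokine = cyt,
               condition = rep(c("antigen", "diluent"), each = 3),
               spots = c(rpois(3, am), rpois(3, dm)))
      })
    }
    wells <- purrr::map2_dfr(donors$donor_id, donors$type, one_donor)

    aim <- cfg$aim
    g <- cfg$marker_gate
    aim_donors <- tibble(
      donor_id = c(sprintf("AHD%02d", seq_len(aim$n_hd)),
                   sprintf("AT1D%02d", seq_len(aim$n_t1d))),
      cohort = c(rep("HD", aim$n_hd), rep("T1D", aim$n_t1d))
    )
    events <- tidyr::crossing(aim_donors,
                              tibble(condition = names(aim$freq))) %>%
      purrr::pmap_dfr(function(donor_id, cohort, condition) {
        n <- aim$n_events
        is_aim <- runif(n) < aim$freq[[condition]]
        tibble(donor_id = donor_id, cohort = cohort, condition = condition,
               CD154 = ifelse(is_aim, g * runif(n, 1.5, 3),
                              g * runif(n, 0.2, 0.8)),
               CD69 = ifelse(is_aim, g * runif(n, 1.5, 3),
                             g * runif(n, 0.2, 0.8)),
               true_aim = is_aim)
      })
    list(elispot_wells = wells, elispot_truth = donors,
         aim_events = select(events, -"true_aim"),
         aim_gates = list(CD154 = g, CD69 = g),
         aim_truth = events %>%
           group_by(.data$donor_id, .data$condition) %>%
           summarise(true_frequency = mean(.data$true_aim),
                     .groups = "drop"))
  })
}

#' Simulate a complete paired dataset
#'
#' Runs [simulate_bulk()], [simulate_sc()] and [simulate_assays()] under
#' one configuration and merges their truth manifests.
#'
#' @param cfg A [sim_config()].
#' @return List with `repertoires`, `donors`, `cells`, `ct`, `cell_meta`,
#'   `markers`, `gates`, `assays` and `manifest`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  bulk <- simulate_bulk(cfg)
  sc <- simulate_sc(cfg, bulk)
  assays <- simulate_assays(cfg)
  manifest <- c(bulk$manifest, sc$manifest)
  list(repertoires = bulk$repertoires, donors = bulk$donors,
       cells = sc$cells, ct = sc$ct, cell_meta = sc$cell_meta,
       markers = sc$markers, gates = sc$gates, assays = assays,
       manifest = manifest)
}
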