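#' Track single-cell clonotypes into bulk repertoires
#'
#' Searches each unique antigen-specific clonotype (one per distinct CDR3
#' sequence and source donor; duplicate cells carrying the same clonotype
#' collapse to one query) in every repertoire of the set, producing one hit
#' record per (query, repertoire) pair.
#'
#' At the nucleotide level a query is found when a bulk clone's `cdr3_nt`
#' equals the query beta CDR3 exactly; matching is on the CDR3 alone (V/J
#' calls ignored unless `strict_v = TRUE`), and frequencies of bulk records
#' sharing the query nucleotide sequence are summed.
#'
#' At the amino-acid level the convergent set of a query in a repertoire is
#' the set of distinct bulk nucleotide sequences translating to the query
#' amino-acid CDR3; `convergence` is its size, and the clonotype frequency
#' is the arithmetic mean of the per-nucleotide-sequence frequencies.
#'
#' @param cells Single-cell clonotype tibble with productive beta chains
#'   ([read_sc_clonotypes()]).
#' @param repertoires Row-bound bulk clone tibble
#'   ([read_bulk_repertoire()]).
#' @param level `"nt"` or `"aa"`.
#' @param strict_v If `TRUE`, additionally require V-gene equality between
#'   query and bulk clone.
#' @return Tibble with one row per (query, repertoire): `query_id`,
#'   `query_seq`, `source_donor`, `source_cohort`, `level`, `donor_id`,
#'   `cohort`, `subset`, `found`, `frequency`, `convergence` (identically 1
#'   at any nucleotide-level hit).
#' @export
track_clonotypes <- function(cells, repertoires, level = c("nt", "aa"),
                             strict_v = FALSE) {
  level <- match.arg(level)
  if (nrow(repertoires) == 0) abort("empty repertoire set")
  seq_col <- if (level == "nt") "cdr3b_nt" else "cdr3b_aa"
  qkeys <- c(seq_col, "donor_id", "cohort")
  if (strict_v) qkeys <- c(qkeys, "v_gene_b")
  queries <- as_tibble(cells) %>%
    distinct(across(all_of(qkeys))) %>%
    rename(query_seq = all_of(seq_col), source_donor = "donor_id",
           source_cohort = "cohort") %>%
    mutate(query_id = paste0(.data$source_donor, "|", .data$query_seq))

  rep_keys <- distinct(repertoires, .data$donor_id, .data$cohort,
                       .data$subset)

  # collapse bulk records sharing one nucleotide sequence (and V in strict
  # mode) before matching
  nt_group <- c("donor_id", "cohort", "subset", "cdr3_nt", "cdr3_aa")
  if (strict_v) nt_group <- c(nt_group, "v_call")
  per_nt <- repertoires %>%
    group_by(across(all_of(nt_group))) %>%
    summarise(freq = sum(.data$freq), .groups = "drop")

  if (level == "nt") {
    # per_nt is already unique per (repertoire, cdr3_nt[, v_call]) with
    # frequencies of multi-V/J records summed
    match_tbl <- per_nt %>%
      select(-"cdr3_aa") %>%
      rename(frequency = "freq", query_seq = "cdr3_nt") %>%
      mutate(convergence = 1L)
  } else {
    aa_group <- c("donor_id", "cohort", "subset", "cdr3_aa")
    if (strict_v) aa_group <- c(aa_group, "v_call")
    match_tbl <- per_nt %>%
      group_by(across(all_of(aa_group))) %>%
      summarise(convergence = n_distinct(.data$cdr3_nt),
                frequency = mean(.data$freq), .groups = "drop") %>%
      rename(query_seq = "cdr3_aa")
  }
  join_by <- c("query_seq", "donor_id", "cohort", "subset")
  if (strict_v) {
    match_tbl <- rename(match_tbl, v_gene_b = "v_call")
    join_by <- c(join_by, "v_gene_b")
  }
  grid <- tidyr::crossing(queries, rep_keys)
  hits <- grid %>%
    left_join(match_tbl, by = join_by) %>%
    mutate(
      found = !is.na(.data$frequency),
      frequency = dplyr::coalesce(.data$frequency, 0),
      convergence = dplyr::coalesce(as.integer(.data$convergence), 0L),
      level = level
    ) %>%
    arrange(.data$query_id, match(.data$subset, .subsets), .data$donor_id)
  cols <- c("query_id", "query_seq", "source_donor", "source_cohort",
            if (strict_v) "v_gene_b", "level", "donor_id", "cohort",
            "subset", "found", "frequency", "convergence")
  select(hits, all_of(cols))
}

#' Classify clonotype publicity
#'
#' Maps the share of repertoires where a clonotype is found to one of four
#' categories: extremely public (found in >= 75% of individuals), public
#' (25% to < 75%), ultraprivate (exactly one hit, and that hit in the
#' clonotype's own single-cell source donor) and private otherwise
#' (0% < share < 25%). A single hit in a different donor is private, not
#' ultraprivate. Clonotypes never found return `NA`.
#'
#' @param n_found Number of repertoires where the clonotype was found.
#' @param n_repertoires Number of repertoires searched (>= 1).
#' @param source_donor_hit_only Logical: is the only hit in the source
#'   donor?
#' @return Character vector of categories.
#' @export
classify_publicity <- function(n_found, n_repertoires,
                               source_donor_hit_only) {
  if (any(n_repertoires < 1)) abort("n_repertoires must be >= 1")
  if (any(n_found > n_repertoires)) {
    abort("n_found cannot exceed n_repertoires")
  }
  if (any(n_found < 0)) abort("n_found must be non-negative")
  pct <- 100 * n_found / n_repertoires
  dplyr::case_when(
    n_found == 0 ~ NA_character_,
    pct >= 75 ~ "extremely_public",
    pct >= 25 ~ "public",
    n_found == 1 & source_donor_hit_only ~ "ultraprivate",
    TRUE ~ "private"
  )
}

#' Publicity records per clonotype and subset
#'
#' Aggregates track hits into per-(clonotype, subset) publicity records.
#' The denominator is always the number of repertoires of that subset
#' actually present in the hit table, never a hard-coded cohort size.
#' Clonotypes found in no repertoire of a subset get no record there.
#'
#' @param hits Track-hit tibble from [track_clonotypes()].
#' @return Tibble: `query_id`, `query_seq`, `source_donor`,
#'   `source_cohort`, `subset`, `n_repertoires_searched`, `n_found`, `pct`,
#'   `source_donor_only`, `category`.
#' @export
publicity <- function(hits) {
  hits %>%
    group_by(.data$query_id, .data$query_seq, .data$source_donor,
             .data$source_cohort, .data$subset) %>%
    summarise(
      n_repertoires_searched = n(),
      n_found = sum(.data$found),
      source_donor_only = sum(.data$found) == 1 &&
        all(.data$donor_id[.data$found] == .data$source_donor[1]),
      .groups = "drop"
    ) %>%
    filter(.data$n_found > 0) %>%
    mutate(
      pct = 100 * .data$n_found / .data$n_repertoires_searched,
      category = classify_publicity(.data$n_found,
                                    .data$n_repertoires_searched,
                                    .data$source_donor_only)
    ) %>%
    arrange(match(.data$subset, .subsets), .data$query_id)
}

#' Per-donor tracking rates
#'
#' For each source donor, the percentage of that donor's unique clonotypes
#' found in at least one repertoire of the full set (any subset), with the
#' unweighted mean and sample standard deviation across donors.
#'
#' @param hits Track-hit tibble from [track_clonotypes()] (one level).
#' @return A `tracking_rate` object: list with `per_donor` (tibble:
#'   `source_donor`, `n_clonotypes`, `n_tracked`, `rate_pct`), `mean` and
#'   `sd`.
#' @export
tracking_rate <- function(hits) {
  per_query <- hits %>%
    group_by(.data$query_id, .data$source_donor) %>%
    summarise(tracked = any(.data$found), .groups = "drop")
  per_donor <- per_query %>%
    group_by(.data$source_donor) %>%
    summarise(n_clonotypes = n(), n_tracked = sum(.data$tracked),
              .groups = "drop") %>%
    mutate(rate_pct = 100 * .data$n_tracked / .data$n_clonotypes) %>%
    arrange(.data$source_donor)
  structure(list(per_donor = per_donor,
                 mean = mean(per_donor$rate_pct),
                 sd = sd(per_donor$rate_pct)),
            class = "tracking_rate")
}

#' @export
print.tracking_rate <- function(x, ...) {
  cat(sprintf("Tracking rate over %d donors: %.1f%% +/- %.1f%% (mean +/- sd)\n",
              nrow(x$per_donor), x$mean, x$sd))
  print(x$per_donor, ...)
  invisible(x)
}

#' @rdname tracking_rate
#' @param x A `tracking_rate` object.
#' @param ... Unused.
#' @method tidy tracking_rate
#' @export
tidy.tracking_rate <- function(x, ...) x$per_donor

#' @rdname tracking_rate
#' @method glance tracking_rate
#' @export
glance.tracking_rate <- function(x, ...) {
  tibble(n_donors = nrow(x$per_donor), mean_rate_pct = x$mean,
         sd_rate_pct = x$sd)
}

#' Treg/CM frequency ratio per clonotype in the source donor
#'
#' For each nucleotide-level query found in both the Treg and the CM
#' repertoire of its own source donor, the ratio of its Treg frequency to
#' its CM frequency. Queries absent from either subset yield no row (their
#' count is reported in a message).
#'
#' @param hits Nucleotide-level track-hit tibble.
#' @return Tibble: `query_id`, `source_donor`, `source_cohort`, `f_treg`,
#'   `f_cm`, `ratio`.
#' @export
treg_cm_ratio <- function(hits) {
  own <- hits %>%
    filter(.data$donor_id == .data$source_donor,
           .data$subset %in% c("Treg", "CM")) %>%
    select("query_id", "query_seq", "source_donor", "source_cohort",
           "subset", "frequency") %>%
    tidyr::pivot_wider(names_from = "subset", values_from = "frequency")
  if (!"Treg" %in% names(own)) own$Treg <- NA_real_
  if (!"CM" %in% names(own)) own$CM <- NA_real_
  usable <- !is.na(own$Treg) & !is.na(own$CM) & own$Treg > 0 & own$CM > 0
  if (any(!usable)) {
    inform(sprintf(
      "%d clonotype(s) skipped for the Treg/CM ratio (absent from one subset)",
      sum(!usable)))
  }
  own[usable, , drop = FALSE] %>%
    rename(f_treg = "Treg", f_cm = "CM") %>%
    mutate(ratio = .data$f_treg / .data$f_cm) %>%
    arrange(.data$query_id)
}

#' Convergence-frequency correlation within a subset
#'
#' For each amino-acid clonotype found in a subset, x is the mean
#' convergence and y the mean frequency across the repertoires where it is
#' found; the association is summarised by a two-sided Spearman rank
#' correlation over clonotypes.
#'
#' @param hits Amino-acid-level track-hit tibble.
#' @param subset Repertoire subset (`"TN"`, `"CM"`, `"Treg"`, `"Tscm"`).
#' @param by_cohort If `TRUE`, additionally computed per source cohort.
#' @return Tibble with `subset` (and `source_cohort` when requested),
#'   `n_clonotypes`, `rho`, `p_value`. `rho` is `NA` when all convergence
#'   values coincide.
#' @export
convergence_frequency_correlation <- function(hits, subset,
                                              by_cohort = FALSE) {
  subset <- match.arg(subset, .subsets)
  pts <- hits %>%
    filter(.data$subset == !!subset, .data$found) %>%
    group_by(.data$query_id, .data$source_cohort) %>%
    summarise(x = mean(.data$convergence), y = mean(.data$frequency),
              .groups = "drop")
  one <- function(d) {
    if (nrow(d) < 3) {
      abort("need at least 3 clonotypes with hits in the subset")
    }
    if (n_distinct(d$x) == 1) {
      return(tibble(n_clonotypes = nrow(d), rho = NA_real_,
                    p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(d$x, d$y, method = "spearman",
                                    exact = FALSE))
    tibble(n_clonotypes = nrow(d), rho = unname(ct$estimate),
           p_value = ct$p.value)
  }
  if (by_cohort) {
    pts %>%
      group_by(.data$source_cohort) %>%
      dplyr::group_modify(~ one(.x)) %>%
      ungroup() %>%
      mutate(subset = subset, .before = 1)
  } else {
    mutate(one(pts), subset = subset, .before = 1)
  }
}

#' Cohort-exclusive clonotype sets
#'
#' Within one subset, classifies each amino-acid clonotype found in at
#' least one repertoire as HD-only (found in one or more HD repertoires
#' and in no T1D repertoire), T1D-only (the symmetric case), or shared.
#' Clonotypes found in both cohorts or in neither are excluded from the
#' exclusive sets.
#'
#' @param hits Amino-acid-level track-hit tibble.
#' @param subset Repertoire subset to restrict to.
#' @return Tibble: `query_id`, `query_seq`, `source_donor`, `n_hd`,
#'   `n_t1d`, `exclusivity` in `{hd_only, t1d_only}`.
#' @export
exclusivity_sets <- function(hits, subset) {
  subset <- match.arg(subset, .subsets)
  hits %>%
    filter(.data$subset == !!subset) %>%
    group_by(.data$query_id, .data$query_seq, .data$source_donor) %>%
    summarise(n_hd = sum(.data$found & .data$cohort == "HD"),
              n_t1d = sum(.data$found & .data$cohort == "T1D"),
              .groups = "drop") %>%
    mutate(exclusivity = dplyr::case_when(
      .data$n_hd >= 1 & .data$n_t1d == 0 ~ "hd_only",
      .data$n_t1d >= 1 & .data$n_hd == 0 ~ "t1d_only",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$exclusivity)) %>%
    arrange(.data$exclusivity, .data$query_id)
}

# Fixed 20-letter amino-acid alphabet for positional usage matrices.
.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Sequence features of a clonotype set
#'
#' Summarises a set of unique amino-acid clonotypes: mean CDR3 length,
#' V-gene usage fractions, and (for every CDR3 length represented by at
#' least two clonotypes) a position-by-amino-acid frequency matrix whose
#' columns each sum to 1.
#'
#' @param clonotypes Character vector of unique amino-acid CDR3 sequences.
#' @param v_genes Optional character vector of V genes, parallel to
#'   `clonotypes`.
#' @return List with `mean_length`, `v_usage` (tibble, or `NULL` when no V
#'   genes given) and `positional` (named list of 20 x length matrices).
#' @export
sequence_feature_summary <- function(clonotypes, v_genes = NULL) {
  clonotypes <- unique(clonotypes)
  if (length(clonotypes) == 0) abort("empty clonotype set")
  lens <- nchar(clonotypes)
  v_usage <- NULL
  if (!is.null(v_genes)) {
    v_usage <- tibble(v_gene = v_genes) %>%
      count(.data$v_gene, name = "n") %>%
      mutate(fraction = .data$n / sum(.data$n)) %>%
      arrange(dplyr::desc(.data$fraction), .data$v_gene)
  }
  positional <- list()
  for (L in sort(unique(lens))) {
    seqs <- clonotypes[lens == L]
    if (length(seqs) < 2) next
    m <- matrix(0, nrow = length(.aa_alphabet), ncol = L,
                dimnames = list(.aa_alphabet, seq_len(L)))
    chars <- strsplit(seqs, "")
    for (s in chars) {
      for (j in seq_len(L)) {
        if (s[j] %in% .aa_alphabet) m[s[j], j] <- m[s[j], j] + 1
      }
    }
    positional[[as.character(L)]] <- sweep(m, 2, colSums(m), "/")
  }
  list(mean_length = mean(lens), v_usage = v_usage, positional = positional)
}
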