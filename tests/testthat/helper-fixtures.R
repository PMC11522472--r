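# Shared fixtures and small builders used across the test files.

# A tiny bulk repertoire tibble built in code (no files).
make_repertoire <- function(donor_id = "HD01", cohort = "HD", subset = "CM",
                            cdr3_nt, v_call = NULL, j_call = NULL,
                            count) {
  n <- length(cdr3_nt)
  if (is.null(v_call)) v_call <- rep("TRBV20-1", n)
  if (is.null(j_call)) j_call <- rep("TRBJ2-1", n)
  total <- sum(count)
  tibble::tibble(
    donor_id = donor_id, cohort = cohort, subset = subset,
    cdr3_nt = toupper(cdr3_nt), cdr3_aa = translate_cdr3(cdr3_nt),
    v_call = v_call, j_call = j_call, count = count, freq = count / total
  )
}

# A minimal single-cell table for tracking tests.
make_cells <- function(donor_id, cohort, cdr3b_nt, cell_prefix = "c") {
  n <- length(cdr3b_nt)
  tibble::tibble(
    cell_id = paste0(donor_id, "_", cell_prefix, seq_len(n)),
    donor_id = donor_id, cohort = cohort, specificity = "GAD",
    cdr3b_nt = toupper(cdr3b_nt), cdr3b_aa = translate_cdr3(cdr3b_nt),
    cdr3a_nt = NA_character_, cdr3a_aa = NA_character_,
    v_gene_b = "TRBV20-1", j_gene_b = "TRBJ2-1",
    phenotype = NA_character_
  )
}

# Write an AIRR rearrangement TSV and return its path.
write_airr_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# Reduced-size simulation config for fast tests (same donor structure as
# the default, smaller repertoires).
small_sim_config <- function(seed = 11L) {
  cfg <- sim_config(seed = seed, clones_per_repertoire = 50L,
                    reads_per_repertoire = 20000L)
  cfg
}

# The default study-scale simulation, built once and shared across test
# files (simulation is deterministic for a fixed seed).
shared_sim <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$sim)) {
      cache$sim <- suppressMessages(simulate_dataset(sim_config(seed = 20260101L)))
    }
    cache$sim
  }
})

# Brute-force double-loop tracking oracle: scans every (query, clone)
# pair directly, independent of the join-based implementation.
oracle_track <- function(queries_nt, queries_aa, repertoires, level) {
  rep_keys <- unique(repertoires[, c("donor_id", "cohort", "subset")])
  out <- list()
  for (qi in seq_along(queries_nt)) {
    q <- if (level == "nt") queries_nt[qi] else queries_aa[qi]
    for (ri in seq_len(nrow(rep_keys))) {
      rep_rows <- repertoires[
        repertoires$donor_id == rep_keys$donor_id[ri] &
          repertoires$subset == rep_keys$subset[ri], ]
      if (level == "nt") {
        m <- rep_rows$cdr3_nt == q
        freq <- sum(rep_rows$freq[m])
        conv <- if (any(m)) 1L else 0L
      } else {
        m <- rep_rows$cdr3_aa == q
        nts <- unique(rep_rows$cdr3_nt[m])
        conv <- length(nts)
        freq <- if (conv == 0) 0 else
          mean(vapply(nts, function(s)
            sum(rep_rows$freq[rep_rows$cdr3_nt == s]), numeric(1)))
      }
      out[[length(out) + 1]] <- tibble::tibble(
        query = q, donor_id = rep_keys$donor_id[ri],
        subset = rep_keys$subset[ri], found = conv > 0,
        frequency = freq, convergence = conv
      )
    }
  }
  dplyr::bind_rows(out)
}
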