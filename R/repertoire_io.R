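#' Translate a CDR3 nucleotide sequence
#'
#' Standard-genetic-code translation of an in-frame CDR3, starting at the
#' first position of the given sequence. Stop codons are rendered as `"*"`.
#'
#' @param nt Character vector of DNA sequences (alphabet A, C, G, T;
#'   case-insensitive; length a positive multiple of 3).
#' @return Character vector of amino-acid sequences.
#' @examples
#' translate_cdr3("TGTGCCAGC") # "CAS"
#' @export
translate_cdr3 <- function(nt) {
  if (length(nt) == 0) return(character(0))
  nt <- toupper(as.character(nt))
  bad_frame <- is.na(nt) | nchar(nt) == 0 | nchar(nt) %% 3 != 0
  if (any(bad_frame)) {
    abort(sprintf(
      "out-of-frame CDR3: length not a positive multiple of 3 at position(s) %s",
      paste(which(bad_frame), collapse = ", ")
    ))
  }
  if (any(grepl("[^ACGT]", nt))) {
    abort("non-DNA characters in CDR3 nucleotide sequence")
  }
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     no.init.codon = TRUE))
}

#' Is a CDR3 nucleotide sequence productive?
#'
#' Productive means in frame (length a multiple of 3) and free of stop
#' codons after standard-code translation.
#'
#' @param nt Character vector of DNA sequences.
#' @return Logical vector. Malformed input (empty, `NA`, or non-ACGT
#'   characters) returns `FALSE` with a warning.
#' @export
is_productive <- function(nt) {
  nt <- toupper(as.character(nt))
  out <- rep(FALSE, length(nt))
  malformed <- is.na(nt) | nchar(nt) == 0 | grepl("[^ACGT]", nt)
  if (any(malformed)) {
    warn(sprintf("%d malformed CDR3 sequence(s) treated as non-productive",
                 sum(malformed)))
  }
  candidate <- !malformed & nchar(nt) %% 3 == 0
  if (any(candidate)) {
    aa <- translate_cdr3(nt[candidate])
    out[candidate] <- !grepl("*", aa, fixed = TRUE)
  }
  out
}

#' Read one bulk TCRB repertoire from an AIRR rearrangement TSV
#'
#' Reads a tab-separated AIRR Rearrangement file (columns `junction`,
#' `junction_aa`, `v_call`, `j_call`, `duplicate_count` at minimum) into a
#' tidy clone table. Rows with non-positive `duplicate_count` or an empty
#' `junction` are dropped (with a message); rows sharing the same
#' (`junction`, `v_call`, `j_call`) are merged by summing counts.
#' `junction` is the CDR3 including the conserved anchor residues, stored
#' verbatim (upper-cased, never trimmed).
#'
#' @param path Path to the TSV file.
#' @param donor_id Donor identifier for this repertoire.
#' @param cohort `"HD"` or `"T1D"`.
#' @param subset One of `"TN"`, `"CM"`, `"Treg"`, `"Tscm"`.
#' @return A tibble with columns `donor_id`, `cohort`, `subset`, `cdr3_nt`,
#'   `cdr3_aa`, `v_call`, `j_call`, `count`, `freq` (count / total reads of
#'   the repertoire), sorted by decreasing count then sequence.
#' @export
read_bulk_repertoire <- function(path, donor_id, cohort, subset) {
  cohort <- match.arg(cohort, .cohorts)
  subset <- match.arg(subset, .subsets)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("junction", "junction_aa", "v_call", "j_call",
                "duplicate_count")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("AIRR file '%s' is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  raw$duplicate_count <- suppressWarnings(as.numeric(raw$duplicate_count))
  junction <- toupper(ifelse(is.na(raw$junction), "", raw$junction))
  bad_nt <- junction != "" & grepl("[^ACGT]", junction)
  if (any(bad_nt)) {
    abort(sprintf("non-DNA characters in junction at row(s) %s of '%s'",
                  paste(head(which(bad_nt), 10), collapse = ", "), path))
  }
  keep <- !is.na(raw$duplicate_count) & raw$duplicate_count > 0 &
    junction != ""
  if (any(!keep)) {
    inform(sprintf("%d row(s) dropped from '%s' (empty junction or count <= 0)",
                   sum(!keep), path))
  }
  clones <- tibble(
    cdr3_nt = junction[keep],
    cdr3_aa = toupper(raw$junction_aa[keep]),
    v_call = raw$v_call[keep],
    j_call = raw$j_call[keep],
    count = raw$duplicate_count[keep]
  ) %>%
    group_by(.data$cdr3_nt, .data$v_call, .data$j_call) %>%
    summarise(cdr3_aa = first(.data$cdr3_aa), count = sum(.data$count),
              .groups = "drop")
  as_repertoire(clones, donor_id = donor_id, cohort = cohort, subset = subset)
}

# Normalise a clone table into the canonical repertoire shape:
# frequencies, deterministic row order.
as_repertoire <- function(clones, donor_id, cohort, subset) {
  total <- sum(clones$count)
  clones %>%
    mutate(donor_id = donor_id, cohort = cohort, subset = subset,
           freq = .data$count / total) %>%
    select("donor_id", "cohort", "subset", "cdr3_nt", "cdr3_aa",
           "v_call", "j_call", "count", "freq") %>%
    arrange(dplyr::desc(.data$count), .data$cdr3_nt, .data$v_call,
            .data$j_call)
}

#' Write a bulk repertoire as an AIRR rearrangement TSV
#'
#' Inverse of [read_bulk_repertoire()]: emits `junction`, `junction_aa`,
#' `v_call`, `j_call`, `duplicate_count` in deterministic order
#' (descending count, then sequence).
#'
#' @param repertoire A clone tibble as returned by [read_bulk_repertoire()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bulk_repertoire <- function(repertoire, path) {
  out <- repertoire %>%
    arrange(dplyr::desc(.data$count), .data$cdr3_nt, .data$v_call,
            .data$j_call) %>%
    mutate(junction = .data$cdr3_nt, junction_aa = .data$cdr3_aa,
           duplicate_count = .data$count) %>%
    select("junction", "junction_aa", "v_call", "j_call", "duplicate_count")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Count repertoires per subset in a repertoire set
#'
#' A repertoire set is simply the row-bound clone tables of many
#' repertoires; each repertoire is identified by its (`donor_id`, `subset`)
#' pair (at most one per pair).
#'
#' @param repertoires Tibble of clones across repertoires.
#' @return Tibble with columns `subset` and `n_repertoires`.
#' @export
repertoire_counts <- function(repertoires) {
  repertoires %>%
    distinct(.data$donor_id, .data$subset) %>%
    count(.data$subset, name = "n_repertoires") %>%
    arrange(match(.data$subset, .subsets))
}

#' Read a single-cell clonotype table
#'
#' Reads a TSV of antigen-specific single cells (one row per cell). Cells
#' lacking a productive beta-chain CDR3 are dropped with a message. The
#' amino-acid beta CDR3 is recomputed from the nucleotide sequence so the
#' translation invariant always holds on the returned table.
#'
#' @param path Path to the TSV. Required columns: `cell_id`, `donor_id`,
#'   `cohort`, `specificity`, `cdr3b_nt`. Optional: `cdr3a_nt`, `v_gene_b`,
#'   `j_gene_b`, `phenotype`, `genex_cluster`.
#' @return Tibble of retained cells with recomputed `cdr3b_aa` (and
#'   `cdr3a_aa` where an alpha chain is present and in frame).
#' @export
read_sc_clonotypes <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("cell_id", "donor_id", "cohort", "specificity", "cdr3b_nt")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("single-cell table '%s' is missing column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  bad_cohort <- !raw$cohort %in% .cohorts
  if (any(bad_cohort)) {
    abort(sprintf("invalid cohort value(s): %s",
                  paste(unique(raw$cohort[bad_cohort]), collapse = ", ")))
  }
  bad_spec <- !raw$specificity %in% .specificities
  if (any(bad_spec)) {
    abort(sprintf("invalid specificity value(s): %s",
                  paste(unique(raw$specificity[bad_spec]), collapse = ", ")))
  }
  raw$cdr3b_nt <- toupper(ifelse(is.na(raw$cdr3b_nt), "", raw$cdr3b_nt))
  keep <- suppressWarnings(is_productive(raw$cdr3b_nt))
  if (any(!keep)) {
    inform(sprintf(
      "%d cell(s) dropped from '%s' (missing or non-productive beta CDR3)",
      sum(!keep), path))
  }
  cells <- as_tibble(raw[keep, , drop = FALSE])
  cells$cdr3b_aa <- translate_cdr3(cells$cdr3b_nt)
  if (!"cdr3a_nt" %in% names(cells)) cells$cdr3a_nt <- NA_character_
  cells$cdr3a_nt <- toupper(cells$cdr3a_nt)
  cells$cdr3a_nt[!is.na(cells$cdr3a_nt) & cells$cdr3a_nt == ""] <-
    NA_character_
  has_a <- !is.na(cells$cdr3a_nt) &
    suppressWarnings(is_productive(cells$cdr3a_nt))
  cells$cdr3a_aa <- NA_character_
  if (any(has_a)) cells$cdr3a_aa[has_a] <- translate_cdr3(cells$cdr3a_nt[has_a])
  if ("genex_cluster" %in% names(cells)) {
    cells$genex_cluster <- suppressWarnings(as.integer(cells$genex_cluster))
  }
  cells
}

#' Write a single-cell clonotype table
#'
#' @param cells Tibble of single-cell clonotypes.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sc_clonotypes <- function(cells, path) {
  readr::write_tsv(arrange(cells, .data$donor_id, .data$cell_id), path,
                   progress = FALSE)
  invisible(path)
}
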