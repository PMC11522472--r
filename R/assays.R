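#' ELISPOT stimulation index
#'
#' Scores ELISPOT wells per donor and cytokine as the stimulation index
#' SI = mean(antigen-stimulated spots) / mean(diluent spots). SI >= 3 is a
#' positive response. Wells with zero mean background are scored against a
#' pseudocount of 1 and flagged (`zero_background = TRUE`) rather than
#' returning an infinite SI.
#'
#' @param wells Data frame with one row per well: columns `donor_id`,
#'   `cytokine` (`"IFNg"` or `"IL10"`), `condition` (`"antigen"` or
#'   `"diluent"`) and `spots` (non-negative count). Typically triplicates.
#' @param threshold Positivity threshold on SI (default 3).
#' @return Tibble with one row per donor x cytokine: `mean_antigen`,
#'   `mean_diluent`, `si`, `positive`, `zero_background`.
#' @export
stimulation_index <- function(wells, threshold = 3) {
  stopifnot(all(c("donor_id", "cytokine", "condition", "spots") %in%
                  names(wells)))
  if (any(wells$spots < 0)) abort("negative spot counts are not allowed")
  if (!all(wells$condition %in% c("antigen", "diluent"))) {
    abort("condition must be 'antigen' or 'diluent'")
  }
  as_tibble(wells) %>%
    group_by(.data$donor_id, .data$cytokine) %>%
    summarise(
      mean_antigen = mean(.data$spots[.data$condition == "antigen"]),
      mean_diluent = mean(.data$spots[.data$condition == "diluent"]),
      .groups = "drop"
    ) %>%
    mutate(
      zero_background = .data$mean_diluent == 0,
      si = .data$mean_antigen / ifelse(.data$zero_background, 1,
                                       .data$mean_diluent),
      positive = .data$si >= threshold
    ) %>%
    select("donor_id", "cytokine", "mean_antigen", "mean_diluent", "si",
           "positive", "zero_background")
}

#' Classify a donor's ELISPOT response from IFN-gamma and IL-10 positivity
#'
#' @param si_results Tibble as returned by [stimulation_index()], holding
#'   both cytokines for each donor.
#' @return Tibble with `donor_id` and `response` in
#'   `{IFNg_only, IL10_only, dual, negative}`.
#' @export
classify_elispot_response <- function(si_results) {
  wide <- si_results %>%
    select("donor_id", "cytokine", "positive") %>%
    tidyr::pivot_wider(names_from = "cytokine", values_from = "positive")
  if (!all(c("IFNg", "IL10") %in% names(wide))) {
    abort("both IFNg and IL10 results are required for every donor")
  }
  if (any(is.na(wide$IFNg)) || any(is.na(wide$IL10))) {
    abort("both IFNg and IL10 results are required for every donor")
  }
  wide %>%
    mutate(response = dplyr::case_when(
      .data$IFNg & .data$IL10 ~ "dual",
      .data$IFNg ~ "IFNg_only",
      .data$IL10 ~ "IL10_only",
      TRUE ~ "negative"
    )) %>%
    select("donor_id", "response")
}

#' Post-hoc naive/memory phenotype gating from index-sort markers
#'
#' Assigns each sorted cell one of five CD4+ phenotypes from CD45RO, CD27
#' and CD95 fluorescence against sample-specific gates: CM (CD45RO+ CD27+),
#' EM (CD45RO+ CD27-), NTEM (CD45RO- CD27-), TN (CD45RO- CD27+ CD95-) and
#' Tscm (CD45RO- CD27+ CD95+). A marker is positive when its intensity is
#' strictly above its cutoff; values exactly at the cutoff gate negative.
#'
#' @param markers Data frame with one row per cell: columns `CD45RO`,
#'   `CD27`, `CD95` (numeric intensities); extra columns are carried over.
#' @param gates Named list or one-row data frame of cutoffs for `CD45RO`,
#'   `CD27` and `CD95`.
#' @return Input tibble with an added `phenotype` column.
#' @export
gate_phenotype <- function(markers, gates) {
  need <- c("CD45RO", "CD27", "CD95")
  stopifnot(all(need %in% names(markers)), all(need %in% names(gates)))
  ro <- markers$CD45RO > gates$CD45RO
  c27 <- markers$CD27 > gates$CD27
  c95 <- markers$CD95 > gates$CD95
  phenotype <- dplyr::case_when(
    ro & c27 ~ "CM",
    ro & !c27 ~ "EM",
    !ro & !c27 ~ "NTEM",
    !ro & c27 & c95 ~ "Tscm",
    TRUE ~ "TN" # CD45RO- CD27+ CD95-
  )
  as_tibble(markers) %>% mutate(phenotype = phenotype)
}

#' Per-individual phenotype distribution
#'
#' Normalises phenotype counts within each individual, so each donor
#' contributes a distribution over the five phenotypes summing to 1
#' (phenotypes absent in a donor get fraction 0).
#'
#' @param cells Data frame with columns `donor_id` and `phenotype`.
#' @return Tibble with `donor_id`, `phenotype`, `n_cells`, `fraction`,
#'   complete over all five phenotypes for every donor.
#' @export
phenotype_distribution <- function(cells) {
  stopifnot(all(c("donor_id", "phenotype") %in% names(cells)))
  cells <- as_tibble(cells) %>% filter(!is.na(.data$phenotype))
  if (nrow(cells) == 0) abort("no labelled cells: empty distribution")
  bad <- !cells$phenotype %in% .phenotypes
  if (any(bad)) {
    abort(sprintf("unknown phenotype label(s): %s",
                  paste(unique(cells$phenotype[bad]), collapse = ", ")))
  }
  cells %>%
    count(.data$donor_id, .data$phenotype, name = "n_cells") %>%
    tidyr::complete(.data$donor_id,
                    phenotype = .phenotypes,
                    fill = list(n_cells = 0L)) %>%
    group_by(.data$donor_id) %>%
    mutate(fraction = .data$n_cells / sum(.data$n_cells)) %>%
    ungroup() %>%
    mutate(phenotype = factor(.data$phenotype, levels = .phenotypes)) %>%
    arrange(.data$donor_id, .data$phenotype)
}

#' Activation-induced marker (AIM) frequency
#'
#' Frequency of CD154+ CD69+ cells among CD4+ events, per donor and
#' stimulation condition. No background subtraction is performed; the
#' stimulated and diluent conditions are compared directly downstream.
#'
#' @param events Data frame with one row per CD4+ event: columns
#'   `donor_id`, `condition`, `CD154`, `CD69` (intensities).
#' @param gates Named list with `CD154` and `CD69` cutoffs (positivity is
#'   strictly above the cutoff).
#' @return Tibble per donor x condition: `n_cd4`, `n_aim`, `frequency`.
#' @export
aim_frequency <- function(events, gates) {
  stopifnot(all(c("donor_id", "condition", "CD154", "CD69") %in%
                  names(events)),
            all(c("CD154", "CD69") %in% names(gates)))
  as_tibble(events) %>%
    mutate(aim = .data$CD154 > gates$CD154 & .data$CD69 > gates$CD69) %>%
    group_by(.data$donor_id, .data$condition) %>%
    summarise(n_cd4 = n(), n_aim = sum(.data$aim),
              frequency = mean(.data$aim), .groups = "drop")
}
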