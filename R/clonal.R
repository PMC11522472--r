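#' Detect clonal expansions among single cells
#'
#' Groups cells of the same donor sharing an identical CDR3 nucleotide
#' sequence: at level `"TRB_nt"` identity of the beta chain alone, at level
#' `"TRB_and_TRA_nt"` identity of both beta and alpha chains (cells without
#' an alpha chain cannot join a paired-level group). Groups of at least
#' `min_size` cells are returned. Identical sequences in different donors
#' are publicity, not expansion, and never group together.
#'
#' @param cells Single-cell clonotype tibble ([read_sc_clonotypes()]).
#' @param level `"TRB_nt"` or `"TRB_and_TRA_nt"`.
#' @param min_size Minimum number of cells per group (default 2).
#' @return Tibble with one row per expansion group: `group_id`, `level`,
#'   `donor_id`, `cdr3b_nt` (and `cdr3a_nt` at the paired level), `size`
#'   and a `cell_ids` list-column of member cells.
#' @export
find_expansions <- function(cells, level = c("TRB_nt", "TRB_and_TRA_nt"),
                            min_size = 2) {
  level <- match.arg(level)
  cells <- as_tibble(cells)
  keys <- c("donor_id", "cdr3b_nt")
  if (level == "TRB_and_TRA_nt") {
    cells <- filter(cells, !is.na(.data$cdr3a_nt))
    keys <- c(keys, "cdr3a_nt")
  }
  groups <- cells %>%
    group_by(across(all_of(keys))) %>%
    summarise(size = n(), cell_ids = list(sort(.data$cell_id)),
              .groups = "drop") %>%
    filter(.data$size >= min_size) %>%
    arrange(.data$donor_id, .data$cdr3b_nt)
  groups %>%
    mutate(group_id = sprintf("%s_%03d",
                              ifelse(level == "TRB_nt", "EGB", "EGAB"),
                              row_number()),
           level = level) %>%
    select("group_id", "level", all_of(keys), "size", "cell_ids")
}

#' Cluster span of expansion groups
#'
#' Annotates each expansion group with the set of gene-expression clusters
#' its member cells occupy and whether the group is confined to a single
#' cluster, then summarises the fraction of confined groups. Groups with
#' any unlabelled member are excluded from the summary (with a message).
#'
#' @param groups Expansion-group tibble from [find_expansions()].
#' @param cell_clusters Data frame with `cell_id` and `genex_cluster`.
#' @return List with `groups` (input plus `clusters_spanned` list-column,
#'   `n_clusters`, `single_cluster`) and `fraction_single_cluster` (number
#'   of confined groups / fully labelled groups).
#' @export
expansion_cluster_span <- function(groups, cell_clusters) {
  stopifnot(all(c("cell_id", "genex_cluster") %in% names(cell_clusters)))
  lut <- setNames(cell_clusters$genex_cluster, cell_clusters$cell_id)
  ann <- groups %>%
    mutate(
      clusters_spanned = purrr::map(.data$cell_ids, function(ids) {
        cl <- unname(lut[ids])
        sort(unique(cl[!is.na(cl)]))
      }),
      labelled = purrr::map2_lgl(.data$cell_ids, .data$clusters_spanned,
        function(ids, cl) {
          got <- unname(lut[ids])
          !anyNA(got) && all(ids %in% names(lut))
        }),
      n_clusters = purrr::map_int(.data$clusters_spanned, length),
      single_cluster = ifelse(.data$labelled, .data$n_clusters == 1, NA)
    )
  n_unlab <- sum(!ann$labelled)
  if (n_unlab > 0) {
    inform(sprintf(
      "%d expansion group(s) excluded from the span summary (unlabelled cells)",
      n_unlab))
  }
  fraction <- if (sum(ann$labelled) == 0) NA_real_ else
    sum(ann$single_cluster[ann$labelled]) / sum(ann$labelled)
  list(groups = select(ann, -"labelled"),
       fraction_single_cluster = fraction)
}
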