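#' Run the full analysis pipeline on a simulated dataset
#'
#' Orchestrates simulate -> expression -> clonal -> track-back with one
#' root seed, returning a structured run report. Each stage draws its
#' randomness from a seed derived from the root seed, so re-running with
#' the same configuration reproduces every number, and stages can be
#' re-run independently.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer overriding `cfg$seed`.
#' @param stages Character vector of stages to run after simulation: any
#'   of `"genex"`, `"clonal"`, `"track"`, `"assays"`. Disabled stages are
#'   simply omitted from the report. The clonal cluster-span summary needs
#'   the genex stage.
#' @param out_dir Optional directory: when given, the main result tables
#'   are written there as TSV files.
#' @return A `clonotrack_report` list with the simulated data (`data`),
#'   per-stage result tables, summary statistics and run metadata.
#' @export
run_pipeline <- function(cfg = sim_config(), seed = NULL,
                         stages = c("genex", "clonal", "track", "assays"),
                         out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  data <- simulate_dataset(cfg)
  report <- list(
    parameters = cfg,
    seed = cfg$seed,
    stages = stages,
    input_hash = list(repertoires = rlang::hash(data$repertoires),
                      cells = rlang::hash(data$cells)),
    counts = list(
      n_repertoires = nrow(distinct(data$repertoires, .data$donor_id,
                                    .data$subset)),
      repertoires_per_subset = repertoire_counts(data$repertoires),
      n_cells = nrow(data$cells),
      n_unique_clonotypes = n_distinct(paste(data$cells$donor_id,
                                             data$cells$cdr3b_nt))
    ),
    data = data
  )

  et <- NULL
  if ("genex" %in% stages) {
    et <- preprocess_ct(data$ct, data$cell_meta)
    et <- cluster_cells(et, seed = cfg$seed + 4L)
    hurdle <- hurdle_test_all(et)
    report$genex <- list(
      expression = et,
      n_clusters = n_distinct(et$genex_cluster),
      hurdle = hurdle,
      markers = marker_filter(hurdle),
      composition = cluster_composition_test(et)
    )
  }

  if ("clonal" %in% stages) {
    groups_b <- find_expansions(data$cells, level = "TRB_nt")
    groups_ab <- find_expansions(data$cells, level = "TRB_and_TRA_nt")
    cl_src <- if (!is.null(et)) {
      select(et, "cell_id", "genex_cluster")
    } else {
      data$cell_meta %>% select("cell_id", genex_cluster = "true_cluster")
    }
    span <- expansion_cluster_span(groups_b, cl_src)
    report$clonal <- list(
      expansions_trb = groups_b,
      expansions_trb_tra = groups_ab,
      span = span$groups,
      fraction_single_cluster = span$fraction_single_cluster
    )
  }

  if ("track" %in% stages) {
    hits_nt <- track_clonotypes(data$cells, data$repertoires, level = "nt")
    hits_aa <- track_clonotypes(data$cells, data$repertoires, level = "aa")
    rate_nt <- tracking_rate(hits_nt)
    rate_aa <- tracking_rate(hits_aa)
    pub <- publicity(hits_aa)
    corr <- bind_rows(
      convergence_frequency_correlation(hits_aa, "TN"),
      convergence_frequency_correlation(hits_aa, "CM")
    )
    report$track <- list(
      hits_nt = hits_nt, hits_aa = hits_aa,
      tracking_nt = rate_nt, tracking_aa = rate_aa,
      publicity = pub,
      publicity_counts = pub %>%
        count(.data$subset, .data$source_cohort, .data$category),
      treg_cm_ratios = treg_cm_ratio(hits_nt),
      correlation = corr,
      exclusivity_tn = exclusivity_sets(hits_aa, "TN"),
      exclusivity_cm = exclusivity_sets(hits_aa, "CM")
    )
  }

  if ("assays" %in% stages) {
    si <- stimulation_index(data$assays$elispot_wells)
    report$assays <- list(
      stimulation_index = si,
      elispot_classes = classify_elispot_response(si),
      aim = aim_frequency(data$assays$aim_events, data$assays$aim_gates)
    )
  }

  class(report) <- "clonotrack_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.clonotrack_report <- function(x, ...) {
  cat("clonotrack run report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  repertoires: %d (%s)\n", x$counts$n_repertoires,
              paste(sprintf("%s=%d", x$counts$repertoires_per_subset$subset,
                            x$counts$repertoires_per_subset$n_repertoires),
                    collapse = ", ")))
  cat(sprintf("  single cells: %d (%d unique clonotypes)\n",
              x$counts$n_cells, x$counts$n_unique_clonotypes))
  if (!is.null(x$genex)) {
    cat(sprintf("  expression clusters: %d; marker records: %d\n",
                x$genex$n_clusters, nrow(x$genex$markers)))
  }
  if (!is.null(x$clonal)) {
    cat(sprintf("  expansion groups (TRB): %d; confined to one cluster: %.0f%%\n",
                nrow(x$clonal$expansions_trb),
                100 * x$clonal$fraction_single_cluster))
  }
  if (!is.null(x$track)) {
    cat(sprintf("  nt tracking rate: %.1f%% +/- %.1f%%\n",
                x$track$tracking_nt$mean, x$track$tracking_nt$sd))
    cat(sprintf("  aa tracking rate: %.1f%% +/- %.1f%%\n",
                x$track$tracking_aa$mean, x$track$tracking_aa$sd))
    for (i in seq_len(nrow(x$track$correlation))) {
      cat(sprintf("  convergence-frequency rho (%s): %.3f\n",
                  x$track$correlation$subset[i], x$track$correlation$rho[i]))
    }
    cat(sprintf("  exclusive clonotypes: TN %d HD-only / %d T1D-only; CM %d / %d\n",
                sum(x$track$exclusivity_tn$exclusivity == "hd_only"),
                sum(x$track$exclusivity_tn$exclusivity == "t1d_only"),
                sum(x$track$exclusivity_cm$exclusivity == "hd_only"),
                sum(x$track$exclusivity_cm$exclusivity == "t1d_only")))
  }
  invisible(x)
}

# Persist the main report tables as TSV blocks plus a text summary.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tbl, name) {
    drop <- vapply(tbl, is.list, logical(1))
    readr::write_tsv(tbl[, !drop, drop = FALSE],
                     file.path(out_dir, paste0(name, ".tsv")),
                     progress = FALSE)
  }
  if (!is.null(report$track)) {
    emit(report$track$hits_nt, "hits_nt")
    emit(report$track$hits_aa, "hits_aa")
    emit(report$track$publicity, "publicity")
    emit(report$track$tracking_nt$per_donor, "tracking_nt")
    emit(report$track$treg_cm_ratios, "treg_cm_ratios")
    emit(bind_rows(report$track$exclusivity_tn,
                   report$track$exclusivity_cm), "exclusivity")
    emit(report$track$correlation, "correlation")
  }
  if (!is.null(report$genex)) {
    emit(report$genex$markers, "markers")
    emit(report$genex$composition, "composition")
  }
  if (!is.null(report$clonal)) emit(report$clonal$span, "expansions")
  txt <- file.path(out_dir, "summary.txt")
  sink(txt); print(report); sink()
  invisible(out_dir)
}
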