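# Two small repertoires with synonymous variants, for matching rules.
two_rep_set <- function() {
  # CASSF has two synonymous nucleotide codings in HD01/CM
  dplyr::bind_rows(
    make_repertoire("HD01", "HD", "CM",
                    cdr3_nt = c("TGTGCCAGCAGCTTT",   # CASSF
                                "TGTGCCAGTAGCTTT",   # CASSF (synonymous)
                                "TGTGCCGGCAGCTTT"),  # CAGSF
                    count = c(20, 40, 940)),
    make_repertoire("T1D01", "T1D", "CM",
                    cdr3_nt = c("TGTGCCAGCAGCTTT", "TGTGCCGTCAGCTTT"),
                    count = c(1, 99999))
  )
}

test_that("nucleotide tracking matches exactly and sums multi-V records", {
  reps <- two_rep_set()
  cells <- make_cells("HD01", "HD", "TGTGCCAGCAGCTTT")
  hits <- track_clonotypes(cells, reps, level = "nt")
  expect_equal(nrow(hits), 2) # one per repertoire
  h1 <- hits[hits$donor_id == "HD01", ]
  expect_true(h1$found)
  expect_equal(h1$frequency, 20 / 1000)
  expect_equal(h1$convergence, 1L)
  expect_equal(hits$frequency[hits$donor_id == "T1D01"], 1e-5)

  # same nt sequence under two V calls: frequencies sum
  reps2 <- make_repertoire("HD02", "HD", "TN",
                           cdr3_nt = rep("TGTGCCAGCAGCTTT", 2),
                           v_call = c("TRBV19", "TRBV28"),
                           count = c(2, 3))
  reps2 <- dplyr::bind_rows(reps2,
                            make_repertoire("HD02", "HD", "CM",
                                            cdr3_nt = "TGTGCCGGCAGCTTT",
                                            count = 995))
  reps2$freq[reps2$subset == "TN"] <- c(2, 3) / 1000
  reps2$freq[reps2$subset == "CM"] <- 995 / 1000
  h <- track_clonotypes(cells, reps2, level = "nt")
  expect_equal(h$frequency[h$subset == "TN"], 0.005)
})

test_that("amino-acid tracking averages synonymous variant frequencies", {
  reps <- two_rep_set()
  cells <- make_cells("HD01", "HD", "TGTGCCAGCAGCTTT") # CASSF
  hits <- track_clonotypes(cells, reps, level = "aa")
  h1 <- hits[hits$donor_id == "HD01", ]
  expect_equal(h1$convergence, 2L)
  expect_equal(h1$frequency, mean(c(20, 40) / 1000))
  h2 <- hits[hits$donor_id == "T1D01", ]
  expect_equal(h2$convergence, 1L)
  expect_equal(h2$frequency, 1e-5)
  expect_error(track_clonotypes(cells, reps[0, ], level = "aa"), "empty")
})

test_that("nucleotide hits nest inside amino-acid hits", {
  sim <- shared_sim()
  reps <- sim$repertoires
  cells <- sim$cells[!duplicated(sim$cells$cdr3b_nt), ][1:25, ]
  nt <- track_clonotypes(cells, reps, level = "nt")
  aa <- track_clonotypes(cells, reps, level = "aa")
  aa_of <- setNames(cells$cdr3b_aa, cells$cdr3b_nt)
  key <- paste(nt$source_donor, aa_of[nt$query_seq], nt$donor_id,
               nt$subset)
  akey <- paste(aa$source_donor, aa$query_seq, aa$donor_id, aa$subset)
  # every nt-level hit implies an aa-level hit with convergence >= 1
  nt_found <- key[nt$found]
  matched <- aa[match(nt_found, akey), ]
  expect_false(anyNA(matched$found))
  expect_true(all(matched$found))
  expect_true(all(matched$convergence >= 1))
  expect_true(all(matched$frequency > 0))
})

test_that("tracking equals the brute-force double-loop oracle", {
  sim <- shared_sim()
  # restrict to 6 repertoires for the unit-scale oracle (the acceptance
  # suite runs the larger 20-repertoire version)
  keys <- dplyr::distinct(sim$repertoires, donor_id, subset)[c(1:3, 32:34), ]
  reps <- dplyr::semi_join(sim$repertoires, keys,
                           by = c("donor_id", "subset"))
  cells <- sim$cells[!duplicated(paste(sim$cells$donor_id,
                                       sim$cells$cdr3b_nt)), ][1:10, ]
  for (lvl in c("nt", "aa")) {
    hits <- track_clonotypes(cells, reps, level = lvl)
    orc <- oracle_track(cells$cdr3b_nt, cells$cdr3b_aa, reps, lvl)
    qs <- if (lvl == "nt") cells$cdr3b_nt else cells$cdr3b_aa
    hits$query <- hits$query_seq
    j <- dplyr::inner_join(hits, orc, by = c("query", "donor_id", "subset"))
    expect_equal(nrow(j), nrow(hits))
    expect_equal(j$found.x, j$found.y)
    expect_equal(j$frequency.x, j$frequency.y, tolerance = 1e-12)
    expect_equal(j$convergence.x, j$convergence.y)
  }
})

test_that("scaling all clone counts leaves frequencies and ratios unchanged", {
  reps <- two_rep_set()
  scaled <- dplyr::mutate(reps, count = count * 7)
  scaled <- scaled %>%
    dplyr::group_by(donor_id, subset) %>%
    dplyr::mutate(freq = count / sum(count)) %>%
    dplyr::ungroup()
  cells <- make_cells("HD01", "HD", "TGTGCCAGCAGCTTT")
  h1 <- track_clonotypes(cells, reps, level = "aa")
  h2 <- track_clonotypes(cells, scaled, level = "aa")
  expect_equal(h1$frequency, h2$frequency)
})

test_that("publicity categories respect the stated boundaries", {
  expect_equal(classify_publicity(24, 31, FALSE), "extremely_public")
  expect_equal(classify_publicity(1, 31, TRUE), "ultraprivate")
  expect_equal(classify_publicity(1, 31, FALSE), "private")
  expect_equal(classify_publicity(1, 16, TRUE), "ultraprivate")
  expect_equal(classify_publicity(3, 31, FALSE), "private")
  # boundary checks: >= 25% is public, >= 75% extremely public
  expect_equal(classify_publicity(25, 100, FALSE), "public")
  expect_equal(classify_publicity(24, 100, FALSE), "private")
  expect_equal(classify_publicity(75, 100, FALSE), "extremely_public")
  expect_equal(classify_publicity(74, 100, FALSE), "public")
  expect_true(is.na(classify_publicity(0, 31, FALSE)))
  expect_error(classify_publicity(5, 4, FALSE), "exceed")
  expect_error(classify_publicity(1, 0, FALSE), ">= 1")
  # partition property: every found clonotype maps to exactly one class
  grid <- expand.grid(n_found = 1:31, src = c(TRUE, FALSE))
  cats <- classify_publicity(grid$n_found, 31, grid$src)
  expect_true(all(cats %in% c("extremely_public", "public", "private",
                              "ultraprivate")))
})

test_that("publicity denominators come from the repertoire set", {
  reps <- dplyr::bind_rows(
    make_repertoire("HD01", "HD", "CM", cdr3_nt = "TGTGCCAGCAGCTTT",
                    count = 5),
    make_repertoire("HD02", "HD", "CM", cdr3_nt = "TGTGCCAGTAGCTTT",
                    count = 5),
    make_repertoire("T1D01", "T1D", "CM", cdr3_nt = "TGTGCCGGCAGCTTT",
                    count = 5)
  )
  cells <- make_cells("HD01", "HD", "TGTGCCAGCAGCTTT")
  pub <- publicity(track_clonotypes(cells, reps, level = "aa"))
  expect_equal(pub$n_repertoires_searched, 3)
  # CASSF is coded by two different donors' nt variants -> found in 2 of 3
  expect_equal(pub$n_found, 2)
  expect_equal(pub$pct, 200 / 3)
  expect_equal(pub$category, "public")
})

test_that("tracking rate averages per-donor percentages", {
  reps <- make_repertoire("HD01", "HD", "CM",
                          cdr3_nt = c("TGTGCCAGCAGCTTT", "TGTGCCAAAAGCTTT"),
                          count = c(5, 5))
  cells <- dplyr::bind_rows(
    make_cells("HD01", "HD", c("TGTGCCAGCAGCTTT",       # tracked
                               paste0("TGTGCC", strrep("AGG", 3), "TTT"),
                               paste0("TGTGCC", strrep("CAG", 3), "TTT"),
                               paste0("TGTGCC", strrep("GAG", 3), "TTT"),
                               paste0("TGTGCC", strrep("CCG", 3), "TTT"),
                               paste0("TGTGCC", strrep("TTG", 3), "TTT"),
                               paste0("TGTGCC", strrep("GTG", 3), "TTT"),
                               paste0("TGTGCC", strrep("ATG", 3), "TTT"),
                               paste0("TGTGCC", strrep("CGG", 3), "TTT"),
                               paste0("TGTGCC", strrep("AAG", 3), "TTT"))),
    make_cells("T1D01", "T1D", c("TGTGCCAAAAGCTTT",     # tracked
                                 "TGTGCCAGCAGCTTT",     # tracked
                                 paste0("TGTGCC", strrep("GGA", 3), "TTT"),
                                 paste0("TGTGCC", strrep("TCA", 3), "TTT"),
                                 paste0("TGTGCC", strrep("CTA", 3), "TTT"),
                                 paste0("TGTGCC", strrep("GCA", 3), "TTT"),
                                 paste0("TGTGCC", strrep("ACA", 3), "TTT"),
                                 paste0("TGTGCC", strrep("TGG", 3), "TTT"),
                                 paste0("TGTGCC", strrep("CAA", 3), "TTT"),
                                 paste0("TGTGCC", strrep("GGT", 3), "TTT")))
  )
  rate <- tracking_rate(track_clonotypes(cells, reps, level = "nt"))
  expect_equal(sort(rate$per_donor$rate_pct), c(10, 20))
  expect_equal(rate$mean, 15)
  expect_equal(rate$sd, sd(c(10, 20)))
  gl <- generics::glance(rate)
  expect_equal(gl$mean_rate_pct, 15)
})

test_that("Treg/CM ratios are emitted only when both subsets carry the clonotype", {
  reps <- dplyr::bind_rows(
    make_repertoire("HD01", "HD", "Treg", cdr3_nt = "TGTGCCAGCAGCTTT",
                    count = 2),
    make_repertoire("HD01", "HD", "CM",
                    cdr3_nt = c("TGTGCCAGCAGCTTT", "TGTGCCGGCAGCTTT"),
                    count = c(1, 1))
  )
  reps$freq[reps$subset == "Treg"] <- 2e-4
  reps$freq[reps$subset == "CM"] <- c(1e-4, 1 - 1e-4)
  cells <- make_cells("HD01", "HD",
                      c("TGTGCCAGCAGCTTT", "TGTGCCTCCAGCTTT"))
  expect_message(rt <- treg_cm_ratio(track_clonotypes(cells, reps, "nt")),
                 "skipped")
  expect_equal(nrow(rt), 1)
  expect_equal(rt$ratio, 2)
})

test_that("convergence-frequency correlation matches the rank formula", {
  # planted monotone map -> rho 1; anti-monotone -> rho -1
  mono <- tibble::tibble(
    query_id = sprintf("q%d", 1:8), query_seq = sprintf("s%d", 1:8),
    source_donor = "d", source_cohort = "HD", level = "aa",
    donor_id = "r1", cohort = "HD", subset = "TN", found = TRUE,
    frequency = (1:8) * 1e-4, convergence = 1:8
  )
  expect_equal(convergence_frequency_correlation(mono, "TN")$rho, 1)
  anti <- dplyr::mutate(mono, frequency = rev(frequency))
  expect_equal(convergence_frequency_correlation(anti, "TN")$rho, -1)

  # one exchanged adjacent rank: rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))
  swapped <- mono
  swapped$frequency[4:5] <- swapped$frequency[5:4]
  expect_equal(convergence_frequency_correlation(swapped, "TN")$rho,
               1 - 6 * 2 / (8 * (64 - 1)))

  # all convergence values identical -> rho not available
  flat <- dplyr::mutate(mono, convergence = 2L)
  expect_true(is.na(convergence_frequency_correlation(flat, "TN")$rho))
  expect_error(convergence_frequency_correlation(mono[1:2, ], "TN"),
               "at least 3")
})

test_that("exclusivity sets split by cohort of the carrying repertoires", {
  reps <- dplyr::bind_rows(
    make_repertoire("HD01", "HD", "TN", cdr3_nt = "TGTGCCAGCAGCTTT",
                    count = 1),
    make_repertoire("HD02", "HD", "TN",
                    cdr3_nt = c("TGTGCCAGCAGCTTT", "TGTGCCGGCAGCTTT"),
                    count = c(1, 1)),
    make_repertoire("T1D01", "T1D", "TN",
                    cdr3_nt = c("TGTGCCGGCAGCTTT", "TGTGCCTGGAGCTTT"),
                    count = c(1, 1))
  )
  cells <- make_cells("HD01", "HD",
                      c("TGTGCCAGCAGCTTT",   # HD-only (2 HD, 0 T1D)
                        "TGTGCCGGCAGCTTT",   # both cohorts -> neither
                        "TGTGCCTGGAGCTTT",   # T1D-only
                        "TGTGCCAAAAGCTTT"))  # never found -> no record
  ex <- exclusivity_sets(track_clonotypes(cells, reps, "aa"), "TN")
  expect_equal(nrow(ex), 2)
  expect_equal(ex$exclusivity[ex$query_seq == "CASSF"], "hd_only")
  expect_true(all(sort(ex$exclusivity) == c("hd_only", "t1d_only")))
  # disjointness by construction
  expect_equal(length(intersect(ex$query_seq[ex$exclusivity == "hd_only"],
                                ex$query_seq[ex$exclusivity == "t1d_only"])),
               0)
})

test_that("sequence feature summaries normalise lengths, V usage and positions", {
  fs <- sequence_feature_summary(c("CASSLGETQYF", "CASSLGETQYFABCD"))
  expect_equal(fs$mean_length, 13)
  fs2 <- sequence_feature_summary(
    c("CASSLGETQYF", "CASRLGETQYF", "CASSLGGTQYF"),
    v_genes = rep("TRBV20-1", 3))
  expect_equal(fs2$v_usage$fraction, 1)
  mat <- fs2$positional[["11"]]
  expect_equal(unname(colSums(mat)), rep(1, 11))
  expect_equal(mat["C", 1], 1)
  expect_equal(mat["S", 4], 2 / 3)
  expect_error(sequence_feature_summary(character(0)), "empty")
})
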