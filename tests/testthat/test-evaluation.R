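test_that("match ratio follows 2*Nmatch/(Ndelimited + Nmorph)", {
  # perfect delimitation of 5 species
  sp <- rep(paste("G", paste0("s", 1:5)), each = 2)
  ids <- sprintf("r%02d", 1:10)
  perfect <- tibble::tibble(record_id = ids,
                            motu = rep(1:5, each = 2))
  mr <- match_ratio(perfect, setNames(sp, ids))
  expect_equal(mr$match_ratio, 1)
  expect_equal(mr$n_match, 5L)

  # 3 species in 4 MOTUs, 2 of them exact: 2*2/(4+3) = 4/7
  sp2 <- setNames(rep(paste("G", paste0("s", 1:3)), each = 2),
                  sprintf("r%02d", 1:6))
  part2 <- tibble::tibble(record_id = names(sp2),
                          motu = c(1L, 1L, 2L, 2L, 3L, 4L))
  mr2 <- match_ratio(part2, sp2)
  expect_equal(mr2$n_match, 2L)
  expect_equal(mr2$match_ratio, 4 / 7)

  # everything merged: no exact match
  merged <- tibble::tibble(record_id = names(sp2), motu = 1L)
  expect_equal(match_ratio(merged, sp2)$match_ratio, 0)
})

test_that("match ratio is 1 iff the partition equals the species partition", {
  withr::local_seed(41)
  for (rep in 1:20) {
    n <- sample(6:16, 1)
    ids <- sprintf("r%02d", seq_len(n))
    sp <- setNames(paste("G", paste0("s", sample(1:4, n, replace = TRUE))), ids)
    motu <- sample(1:4, n, replace = TRUE)
    part <- tibble::tibble(record_id = ids, motu = motu)
    mr <- match_ratio(part, sp)
    same <- identical(partition_signature(ids, motu),
                      partition_signature(ids, unname(sp)))
    expect_equal(mr$match_ratio == 1, same)
    expect_gte(mr$match_ratio, 0)
    expect_lte(mr$match_ratio, 1)
  }
})

test_that("species outcomes cover MATCH, SPLIT, MERGE and MIXTURE", {
  ids <- sprintf("r%02d", 1:9)
  sp <- setNames(c("G s1", "G s1",          # MATCH: own motu
                   "G s2", "G s2",          # SPLIT: two pure motus
                   "G s3", "G s4",          # MERGE pair: shared motu
                   "G s5", "G s5", "G s6"), # s5 MIXTURE, s6 MERGE
                 ids)
  motu <- c(1L, 1L, 2L, 3L, 4L, 4L, 5L, 6L, 6L)
  out <- classify_species_outcomes(tibble::tibble(record_id = ids, motu = motu),
                                   sp)
  lookup <- setNames(out$outcome, out$species_name)
  expect_equal(lookup[["G s1"]], "MATCH")
  expect_equal(lookup[["G s2"]], "SPLIT")
  expect_equal(lookup[["G s3"]], "MERGE")
  expect_equal(lookup[["G s4"]], "MERGE")
  expect_equal(lookup[["G s5"]], "MIXTURE")
  expect_equal(lookup[["G s6"]], "MERGE")
  # categories sum to the species count and survive motu relabelling
  expect_equal(nrow(out), 6)
  relab <- sample(10:20)[motu]
  out2 <- classify_species_outcomes(tibble::tibble(record_id = ids,
                                                   motu = relab), sp)
  expect_equal(dplyr::arrange(out2, species_name),
               dplyr::arrange(out, species_name))
})

test_that("overestimation ratio is the relative cluster excess", {
  expect_equal(overestimation_ratio(107, 100), 0.07)
  expect_equal(overestimation_ratio(100, 100), 0)
  expect_lt(overestimation_ratio(90, 100), 0)
  expect_error(overestimation_ratio(5, 0), class = "coigap_config_error")
})

test_that("frequency distribution bins are left-closed right-open", {
  tab <- frequency_distribution(c(0.005, 0.015, 0.015))
  expect_equal(tab$count[tab$bin_lower == 0], 1L)
  expect_equal(tab$count[tab$bin_lower == 0.01], 2L)
  # a value on the edge belongs to the higher bin
  tab2 <- frequency_distribution(c(0.01, 0.019))
  expect_equal(tab2$count, c(0L, 2L))
  # empty input, conservation, frequencies
  expect_equal(nrow(frequency_distribution(numeric())), 0)
  withr::local_seed(42)
  x <- runif(250, 0, 0.2)
  tab3 <- frequency_distribution(x)
  expect_equal(sum(tab3$count), 250L)
  expect_equal(sum(tab3$frequency), 1)
})

test_that("proportion above a cutoff matches direct counting", {
  expect_equal(proportion_above(c(0.01, 0.02), 0.05), 0)
  expect_equal(proportion_above(c(0.1, 0.2), 0.05), 1)
  withr::local_seed(43)
  x <- runif(500, 0, 0.1)
  expect_equal(proportion_above(x, 0.03), sum(x > 0.03) / 500)
})

test_that("mininter subset report matches hand-clustering on a small fixture", {
  # two genera with controlled p-distances (10-site sequences)
  # genus A: s1 {0 diffs}, s2 {0 diffs}; s1-s2 differ at 1 site (0.1)
  # genus B: s3, s4 differ at 4 sites (0.4)
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAA",
            "CAAAAAAAAA", "CAAAAAAAAA",
            "CCCCCCCCCC", "CCCCCCCCCC",
            "GGGGCCCCCC", "GGGGCCCCCC")
  recs <- dplyr::bind_rows(
    records_from_seqs(seqs[1:4], rep(c("A s1", "A s2"), each = 2),
                      genus = "GenA"),
    records_from_seqs(seqs[5:8], rep(c("B s3", "B s4"), each = 2),
                      genus = "GenB"))
  recs$record_id <- sprintf("R%03d", 1:8)
  rep_tab <- mininter_subset_report(recs, cutoffs = c(0, 0.2),
                                    thresholds = c(0.05, 0.15), model = "p")
  # cutoff 0 retains all 4 species
  c0 <- rep_tab[rep_tab$cutoff == 0, ]
  expect_equal(unique(c0$n_species), 4L)
  # t = 0.05: no between-species edge anywhere -> 4 MOTUs
  expect_equal(c0$n_motus[c0$method == "t_0.05"], 4L)
  # t = 0.15: genus A merges (0.1 < 0.15), genus B stays apart -> 3 MOTUs
  expect_equal(c0$n_motus[c0$method == "t_0.15"], 3L)
  # mininter threshold separates everything by construction
  expect_equal(c0$n_motus[c0$method == "mininter"], 4L)
  expect_equal(c0$overestimation[c0$method == "t_0.05"], 0)
  # cutoff 0.2 drops genus A's species (min inter 0.1)
  c2 <- rep_tab[rep_tab$cutoff == 0.2, ]
  expect_equal(unique(c2$n_species), 2L)
  expect_equal(c2$n_motus[c2$method == "t_0.05"], 2L)
  # retained species count is non-increasing in the cutoff
  wide <- rep_tab[rep_tab$method == "mininter", ]
  expect_true(all(diff(wide$n_species) <= 0))
})
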