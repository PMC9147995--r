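name_fixture <- function(names) {
  records_from_seqs(random_alignment(length(names), 30), names)
}

test_that("species-level identification filter removes unnamed records", {
  withr::local_seed(51)
  recs <- name_fixture(c("Apis mellifera", "Apis sp.", "", "Apis",
                         "Apis sp. 5", "Apis sp3", "Bombus terrestris"))
  out <- filter_species_level(recs)
  expect_setequal(out$species_name, c("Apis mellifera", "Bombus terrestris"))
  expect_equal(filter_species_level(out), out)  # idempotent
})

test_that("ambiguous-name filter matches tokens, not substrings", {
  withr::local_seed(52)
  recs <- name_fixture(c("Apis cf. mellifera", "Cfa albipes",
                         "Drosophila spp", "Formica nr clara",
                         "Lasius niger"))
  out <- filter_ambiguous_names(recs)
  expect_setequal(out$species_name, c("Cfa albipes", "Lasius niger"))
  expect_error(filter_ambiguous_names(recs, character()),
               class = "coigap_config_error")
})

test_that("marker filter is exact and case-sensitive", {
  withr::local_seed(53)
  recs <- name_fixture(c("A a", "B b", "C c"))
  recs$marker <- c("COI-5P", "COI-3P", "")
  out <- filter_marker(recs)
  expect_equal(out$species_name, "A a")
})

test_that("minimum-sequence rule keeps species with at least n records", {
  withr::local_seed(54)
  recs <- records_from_seqs(random_alignment(5, 30),
                            c("A a", "A a", "B b", "B b", "B b"))
  out <- filter_min_sequences(recs, 3)
  expect_setequal(unique(out$species_name), "B b")
  expect_equal(nrow(filter_min_sequences(recs, 2)), 5)
})

test_that("subsampling caps species deterministically and order-independently", {
  withr::local_seed(55)
  recs <- records_from_seqs(random_alignment(150, 30), rep("A a", 150))
  out1 <- subsample_species(recs, cap = 100, seed = 9)
  expect_equal(nrow(out1), 100)
  out2 <- subsample_species(recs, cap = 100, seed = 9)
  expect_identical(out1$record_id, out2$record_id)
  # shuffling the rows does not change the chosen set
  shuf <- recs[sample(nrow(recs)), ]
  out3 <- subsample_species(shuf, cap = 100, seed = 9)
  expect_setequal(out3$record_id, out1$record_id)
  # species at or under the cap are untouched
  small <- records_from_seqs(random_alignment(80, 30), rep("B b", 80))
  expect_equal(nrow(subsample_species(small, cap = 100, seed = 9)), 80)
})

test_that("gap handling removes gap-bearing sequences and all-gap columns", {
  clean <- setNames(c("ACGTAC", "ACGTAC", "ACGTAT", "ACTTAC"), paste0("r", 1:4))
  expect_identical(remove_gap_inducers(clean), clean)
  one_gap <- clean
  one_gap["r2"] <- "AC-TAC"
  out <- remove_gap_inducers(one_gap)
  expect_setequal(names(out), c("r1", "r3", "r4"))
  # a column that is gap in every sequence is excised, not fatal
  all_gap <- setNames(c("AC-TAC", "AC-TAC", "AC-TAT"), paste0("r", 1:3))
  out2 <- remove_gap_inducers(all_gap)
  expect_equal(unname(nchar(out2)), rep(5, 3))
  expect_false(any(grepl("-", out2)))
  expect_error(remove_gap_inducers(c("ACGT", "ACG")),
               class = "coigap_data_error")
})

test_that("stop-codon screening uses the minimum-stop reading frame", {
  # clean coding sequences in frame 1 under the invertebrate mito code
  withr::local_seed(56)
  stops <- c("TAA", "TAG")
  codons <- setdiff(as.vector(outer(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"), paste0),
                                    c("A", "C", "G", "T"), paste0)), stops)
  mk <- function(n) paste(sample(codons, n, replace = TRUE), collapse = "")
  seqs <- c(mk(20), mk(20), mk(20))
  expect_true(species_passes_stop_codon_check(seqs))
  # TGA is tryptophan, not a stop, under the invertebrate mitochondrial
  # code (independent check: translation table 5)
  tga <- paste0("ATG", "TGA", mk(10))
  expect_true(species_passes_stop_codon_check(c(tga, mk(12))))
  gc5 <- Biostrings::getGeneticCode("SGC4")
  expect_identical(unname(gc5[["TGA"]]), "W")
  # an internal TAA in the best frame sinks the species
  bad <- paste0(mk(5), "TAA", mk(5))
  counts <- frame_stop_counts(c(bad, mk(11)))
  expect_gte(counts[1], 1)
  # frame totals count every sequence; incomplete final codons ignored
  expect_length(frame_stop_counts(seqs), 3)
})

test_that("undefined-distance filter drops saturated species", {
  # P = 0.5, Q = 0 within one species: log argument hits zero
  sat <- records_from_seqs(c("AGAGAGAGAG", "GAGAGAGAGA", "AGAGAGAGAG"),
                           rep("A a", 3))
  ok <- records_from_seqs(related_alignment(3, 30, 2), rep("B b", 3))
  ok$record_id <- paste0("Q", 1:3)
  both <- dplyr::bind_rows(sat, ok)
  out <- filter_undefined_distances(both)
  expect_setequal(unique(out$species_name), "B b")
  # zero comparable sites is also undefined
  nn <- records_from_seqs(c("NNNNN", "AAAAA", "AAAAA"), rep("C c", 3))
  expect_equal(nrow(filter_undefined_distances(nn)), 0)
})

test_that("quantile rule removes exactly the species above the cutoff", {
  withr::local_seed(57)
  vals <- sort(runif(100, 0, 0.2))
  mi <- tibble::tibble(species_name = sprintf("S %03d", 1:100),
                       max_intra = vals)
  kept <- quantile_retained_species(mi, q = 0.95)
  cutoff <- stats::quantile(vals, 0.95, type = 7, names = FALSE)
  expect_setequal(kept, mi$species_name[mi$max_intra <= cutoff])
  # with 100 distinct values the type-7 cutoff spares the 95th order
  # statistic, so exactly the 5 largest go
  expect_length(kept, 95)
  # all-equal values: nothing is strictly greater
  same <- tibble::tibble(species_name = c("A a", "B b"), max_intra = 0.05)
  expect_length(quantile_retained_species(same), 2)
  single <- tibble::tibble(species_name = "A a", max_intra = 0.4)
  expect_equal(quantile_retained_species(single), "A a")
})

test_that("the cascade removes each engineered defect at its stage", {
  withr::local_seed(58)
  codons <- setdiff(as.vector(outer(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"), paste0),
                                    c("A", "C", "G", "T"), paste0)),
                    c("TAA", "TAG"))
  base <- paste(sample(codons, 20, replace = TRUE), collapse = "")
  perturb <- function(k) {
    repeat {
      ch <- strsplit(base, "")[[1]]
      idx <- sample(60, k)
      ch[idx] <- vapply(ch[idx], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
      out <- paste(ch, collapse = "")
      if (frame_stop_counts(out)[1] == 0) return(out)
    }
  }
  # n identical copies per species: every surviving species then has a
  # zero maximum intraspecific distance, so the quantile stage removes
  # nothing and the survivor set is exactly the defect-free species
  mk_sp <- function(name, n) records_from_seqs(rep(perturb(2), n), rep(name, n))
  good1 <- mk_sp("Apis mellifera", 3)
  good2 <- mk_sp("Apis cerana", 3)
  cf <- mk_sp("Apis cf. florea", 3)
  two_rec <- mk_sp("Apis dorsata", 2)
  wrong_marker <- mk_sp("Apis laboriosa", 3)
  wrong_marker$marker <- "COI-3P"
  gappy <- mk_sp("Apis andreniformis", 4)
  gappy$sequence[1] <- sub("A", "-", gappy$sequence[1])
  stopsp <- mk_sp("Apis koschevnikovi", 3)
  # "TAAATAAATAAA" carries a stop codon in each of the three frames
  stopsp$sequence[1] <- paste0("TAAATAAATAAA",
                               substr(stopsp$sequence[1], 13, 60))
  recs <- dplyr::bind_rows(good1, good2, cf, two_rec, wrong_marker,
                           gappy, stopsp)
  recs$record_id <- sprintf("R%03d", seq_len(nrow(recs)))
  res <- run_filter_cascade(recs, filter_config(quantile_cutoff = 0.99))
  rep_tab <- res$report
  by_stage <- setNames(rep_tab$dropped, rep_tab$stage)
  expect_setequal(recs$species_name[match(by_stage$ambiguous_names,
                                          recs$record_id)],
                  "Apis cf. florea")
  expect_setequal(recs$species_name[match(by_stage$marker, recs$record_id)],
                  "Apis laboriosa")
  expect_setequal(recs$species_name[match(by_stage$min_sequences,
                                          recs$record_id)],
                  "Apis dorsata")
  expect_equal(by_stage$gap_inducers,
               recs$record_id[recs$species_name == "Apis andreniformis"][1])
  expect_setequal(recs$species_name[match(by_stage$stop_codons,
                                          recs$record_id)],
                  "Apis koschevnikovi")
  expect_setequal(unique(res$records$species_name),
                  c("Apis mellifera", "Apis cerana", "Apis andreniformis"))
  # per-stage conservation: dropped ids account for the count difference
  expect_equal(rep_tab$records_in - rep_tab$records_out,
               lengths(rep_tab$dropped))
  expect_equal(rep_tab$records_out[-nrow(rep_tab)], rep_tab$records_in[-1])
})

test_that("the cascade is an identity on clean data and on empty input", {
  withr::local_seed(59)
  # clean species of identical, stop-free coding sequences: no filter
  # has anything to do
  codons <- setdiff(as.vector(outer(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"), paste0),
                                    c("A", "C", "G", "T"), paste0)),
                    c("TAA", "TAG"))
  seqs <- vapply(1:6, function(i)
    paste(sample(codons, 20, replace = TRUE), collapse = ""), character(1))
  recs <- dplyr::bind_rows(lapply(1:6, function(i) {
    records_from_seqs(rep(seqs[i], 3), rep(sprintf("Genus%d species%d", i, i), 3))
  }))
  recs$record_id <- sprintf("R%03d", seq_len(nrow(recs)))
  res <- run_filter_cascade(recs)
  expect_equal(res$records, recs)
  expect_true(all(lengths(res$report$dropped) == 0))
  empty <- recs[0, ]
  res0 <- run_filter_cascade(empty)
  expect_equal(nrow(res0$records), 0)
  expect_equal(nrow(res0$report), 0)
})

test_that("genus preparation removes zero pairs, small genera, lone families", {
  withr::local_seed(60)
  mk <- function(genus, sp, seqs, family = "FamX") {
    r <- records_from_seqs(seqs, paste(genus, sp), genus = genus,
                           family = family)
    r
  }
  s <- random_alignment(1, 40)
  mut <- function(base, k) {
    ch <- strsplit(base, "")[[1]]
    i <- seq_len(k)
    ch[i] <- ifelse(ch[i] == "A", "C", "A")
    paste(ch, collapse = "")
  }
  # GenZ: species z1 and z2 share an identical sequence -> zero pair;
  # z3, z4, z5 distinct -> genus keeps 3 species
  genz <- dplyr::bind_rows(
    mk("GenZ", "z1", c(s, s)), mk("GenZ", "z2", c(s, mut(s, 1))),
    mk("GenZ", "z3", rep(mut(s, 5), 2)), mk("GenZ", "z4", rep(mut(s, 10), 2)),
    mk("GenZ", "z5", rep(mut(s, 15), 2)))
  # GenY (same family): 3 distinct species
  geny <- dplyr::bind_rows(
    mk("GenY", "y1", rep(mut(s, 20), 2)), mk("GenY", "y2", rep(mut(s, 25), 2)),
    mk("GenY", "y3", rep(mut(s, 30), 2)))
  # GenW: only 2 species -> genus dropped
  genw <- dplyr::bind_rows(
    mk("GenW", "w1", rep(mut(s, 3), 2)), mk("GenW", "w2", rep(mut(s, 7), 2)))
  # GenV: fine on its own but alone in family FamV -> family dropped
  genv <- dplyr::bind_rows(
    mk("GenV", "v1", rep(mut(s, 2), 2), family = "FamV"),
    mk("GenV", "v2", rep(mut(s, 6), 2), family = "FamV"),
    mk("GenV", "v3", rep(mut(s, 12), 2), family = "FamV"))
  recs <- dplyr::bind_rows(genz, geny, genw, genv)
  recs$record_id <- sprintf("R%03d", seq_len(nrow(recs)))
  res <- prepare_genus_level(recs)
  kept <- unique(res$records$species_name)
  expect_false(any(c("GenZ z1", "GenZ z2") %in% kept))
  expect_true(all(c("GenZ z3", "GenZ z4", "GenZ z5") %in% kept))
  expect_false(any(grepl("^GenW", kept)))
  expect_false(any(grepl("^GenV", kept)))
  expect_true(all(c("GenY y1", "GenY y2", "GenY y3") %in% kept))
  expect_equal(res$report$stage,
               c("zero_interspecific", "min_species_per_genus",
                 "min_genera_per_family"))
})
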