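# Simulator of BOLD-like insect barcode datasets: per genus, an ancestral
# in-frame coding sequence is evolved to species ancestors and then to
# individuals under a two-rate (kappa) substitution process that rejects
# mutations creating internal stop codons.  Divergence targets are
# expressed as expected pairwise K2P distance and converted to per-site
# mutation probabilities through the K2P expectation, so simulation
# targets live on the same scale as measured distances.

# Expected K2P distance of a sequence in which each site mutates once with
# probability m, the change being a transition with odds kappa : 2.
k2p_expectation <- function(m, kappa) {
  P <- m * kappa / (kappa + 2)
  Q <- 2 * m / (kappa + 2)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# Invert the expectation: per-site mutation probability whose expected
# K2P distance equals `target`.
mutation_prob_for <- function(target, kappa) {
  if (target <= 0) return(0)
  upper <- 0.99 * (kappa + 2) / (2 * kappa + 2)
  if (k2p_expectation(upper, kappa) < target) {
    abort("Divergence target too large for the substitution model.",
          class = "coigap_config_error")
  }
  uniroot(function(m) k2p_expectation(m, kappa) - target,
          lower = 1e-12, upper = upper, tol = 1e-12)$root
}

random_coding_sequence <- function(n_codons, stops) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  allowed <- setdiff(all_codons, stops)
  paste(sample(allowed, n_codons, replace = TRUE), collapse = "")
}

TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")

# One branch of evolution: the number of mutations is binomial in the
# per-site probability; each mutation picks a site and a base (transition
# with odds kappa : 2) and is rejected and redrawn if it would create an
# internal stop codon in frame 1.
mutate_branch <- function(chars, m, kappa, stops) {
  L <- length(chars)
  n_mut <- rbinom(1, L, m)
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_mut)) {
    for (try in 1:1000) {
      site <- sample.int(L, 1)
      cur <- chars[site]
      new <- if (runif(1) < kappa / (kappa + 2)) {
        TS_MAP[[cur]]
      } else {
        sample(setdiff(bases, c(cur, TS_MAP[[cur]])), 1)
      }
      ci <- (site - 1) %/% 3
      codon <- chars[ci * 3 + 1:3]
      codon[site - ci * 3] <- new
      if (!(paste(codon, collapse = "") %in% stops)) {
        chars[site] <- new
        break
      }
    }
  }
  chars
}

pick_count <- function(x, label) {
  if (length(x) == 1) return(as.integer(x))
  if (length(x) == 2) return(sample(seq.int(x[1], x[2]), 1))
  abort(sprintf("`%s` must be a single value or a range of two.", label),
        class = "coigap_config_error")
}

#' Simulate a BOLD-like barcode dataset with known ground truth
#'
#' Generates `n_genera` genera, each from a random ancestral in-frame
#' coding sequence free of internal stop codons.  Species ancestors
#' diverge from the genus ancestor and individuals from their species
#' ancestor under a two-rate substitution process (transition :
#' transversion odds `kappa : 2`) with stop-codon-avoiding rejection
#' sampling, so all output sequences are equal-length, gapless and
#' stop-free.  Branch lengths are set so the expected pairwise
#' intraspecific K2P distance is `intra_divergence` and the expected
#' pairwise distance between congeneric species is `inter_divergence`.
#' Genera are organised two per family and families three per order.
#' Fully deterministic given `seed`.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus: single value or
#'   `c(min, max)` range.
#' @param seqs_per_species Sequences per species: single value or range.
#' @param seq_length Alignment length in bases; must be a codon multiple
#'   (default 600, a COI-5P-like fragment).
#' @param intra_divergence Expected pairwise K2P distance between
#'   conspecific individuals (substitutions/site; default 0.005).
#' @param inter_divergence Expected pairwise K2P distance between
#'   congeneric species (default 0.06); must exceed `intra_divergence`.
#' @param kappa Transition/transversion rate ratio (default 4, a typical
#'   mitochondrial value).
#' @param genetic_code Translation table used for stop-codon avoidance
#'   (default `"SGC4"`, invertebrate mitochondrial).
#' @param seed Integer seed.
#' @return A list with `records` (a record tibble, marker `"COI-5P"`),
#'   `truth` (record-level true genus/species), `species_stats`
#'   (realised `max_intra` per species) and `genus_stats` (realised
#'   `min_inter` and largest congeneric `max_intra` per genus).
#' @export
simulate_barcodes <- function(n_genera = 10, species_per_genus = 4,
                              seqs_per_species = 8, seq_length = 600,
                              intra_divergence = 0.005,
                              inter_divergence = 0.06,
                              kappa = 4, genetic_code = "SGC4", seed = 1) {
  if (seq_length %% 3 != 0) {
    abort("`seq_length` must be a multiple of 3.",
          class = "coigap_config_error")
  }
  if (!(intra_divergence > 0 && inter_divergence > 0 &&
        intra_divergence < 0.5 && inter_divergence < 0.5)) {
    abort("Divergence targets must lie in (0, 0.5).",
          class = "coigap_config_error")
  }
  if (inter_divergence <= intra_divergence) {
    abort("`inter_divergence` must exceed `intra_divergence`.",
          class = "coigap_config_error")
  }
  stops <- genetic_code_stops(genetic_code)
  # expected pairwise intra = 2 * individual branch;
  # expected pairwise inter = 2 * species branch + 2 * individual branch
  m_ind <- mutation_prob_for(intra_divergence / 2, kappa)
  m_sp <- mutation_prob_for((inter_divergence - intra_divergence) / 2, kappa)
  withr::local_seed(as.integer(seed))
  rows <- list()
  counter <- 0L
  for (g in seq_len(n_genera)) {
    genus <- sprintf("Genus%03d", g)
    family <- sprintf("Family%03d", (g - 1L) %/% 2L + 1L)
    ord <- sprintf("Order%02d", ((g - 1L) %/% 2L) %/% 3L + 1L)
    anc <- seq_to_chars(random_coding_sequence(seq_length / 3, stops))
    n_sp <- pick_count(species_per_genus, "species_per_genus")
    for (s in seq_len(n_sp)) {
      sp_name <- sprintf("%s species%02d", genus, s)
      sp_anc <- mutate_branch(anc, m_sp, kappa, stops)
      n_seq <- pick_count(seqs_per_species, "seqs_per_species")
      for (i in seq_len(n_seq)) {
        counter <- counter + 1L
        rows[[counter]] <- tibble(
          record_id = sprintf("SIM%05d", counter),
          order_name = ord, family_name = family,
          genus_name = genus, species_name = sp_name,
          marker = "COI-5P",
          sequence = chars_to_seq(mutate_branch(sp_anc, m_ind, kappa, stops)))
      }
    }
  }
  records <- dplyr::bind_rows(rows)
  truth <- records[, c("record_id", "genus_name", "species_name")]
  species_stats <- per_species_max_intra(records, model = "K2P")
  genus_stats <- records |>
    dplyr::group_by(.data$genus_name) |>
    dplyr::group_modify(function(g, key) {
      d <- distance_matrix(g, model = "K2P")
      mi <- min_interspecific_congeneric(d, g)
      sp_max <- per_species_max_intra(g)
      tibble(n_species = dplyr::n_distinct(g$species_name),
             min_inter = mi$genus_min,
             max_intra = max(sp_max$max_intra))
    }) |>
    dplyr::ungroup()
  list(records = records, truth = truth,
       species_stats = species_stats, genus_stats = genus_stats)
}

#' Inject data defects into a simulated dataset
#'
#' Adds, at the stated rates, the defect classes the quality filters
#' exist to remove: gap-bearing sequences, sequences with a forced
#' internal stop codon, species renamed with a `cf.` qualifier, species
#' truncated below three records, and congeneric species pairs forced to
#' zero interspecific distance (every sequence of the second species
#' replaced by a copy of the first species' first sequence, so the pair —
#' not the species' own intraspecific variation — triggers the rule).
#' Defect targets are drawn from disjoint species so defects do not
#' interact, and the manifest lists every injected defect with the filter
#' stage expected to remove it.
#'
#' @param sim Output of [simulate_barcodes()] (or a record tibble).
#' @param gap_rate Fraction of records receiving alignment gaps.
#' @param stop_codon_rate Fraction of records receiving an internal stop
#'   codon (the whole species is expected to be dropped).
#' @param ambiguous_name_rate Fraction of species renamed with `cf.`.
#' @param undersample_rate Fraction of species truncated to two records.
#' @param zero_pair_rate Fraction of genera given a zero-distance species
#'   pair.
#' @param seed Integer seed.
#' @return A list with `records` (the defect-bearing tibble) and
#'   `manifest`, a tibble with columns `defect`, `record_id`,
#'   `species_name`, `genus_name`, `expected_stage`.
#' @export
inject_defects <- function(sim, gap_rate = 0, stop_codon_rate = 0,
                           ambiguous_name_rate = 0, undersample_rate = 0,
                           zero_pair_rate = 0, seed = 1) {
  records <- if (is.data.frame(sim)) sim else sim$records
  assert_records(records, need = c("record_id", "genus_name", "species_name",
                                   "sequence"))
  withr::local_seed(as.integer(seed))
  species <- sort(unique(records$species_name))
  genera <- sort(unique(records$genus_name))
  n_sp <- length(species)
  n_rec <- nrow(records)
  manifest <- list()
  available_sp <- species

  take_species <- function(n) {
    if (n > length(available_sp)) {
      abort("Defect rates draw more species than are available; lower them.",
            class = "coigap_config_error")
    }
    chosen <- if (n > 0) sample(available_sp, n) else character()
    available_sp <<- setdiff(available_sp, chosen)
    chosen
  }

  # species-level defects first, on disjoint species sets
  amb_sp <- take_species(round(ambiguous_name_rate * n_sp))
  under_sp <- take_species(round(undersample_rate * n_sp))

  n_zero <- round(zero_pair_rate * length(genera))
  zero_pairs <- list()
  if (n_zero > 0) {
    eligible <- genera[vapply(genera, function(g) {
      sum(unique(records$species_name[records$genus_name == g]) %in%
            available_sp) >= 2
    }, logical(1))]
    if (n_zero > length(eligible)) {
      abort("`zero_pair_rate` draws more genera than have two free species.",
            class = "coigap_config_error")
    }
    for (g in sample(eligible, n_zero)) {
      sp_pool <- intersect(unique(records$species_name[records$genus_name == g]),
                           available_sp)
      pair <- sort(sample(sp_pool, 2))
      zero_pairs[[g]] <- pair
      available_sp <- setdiff(available_sp, pair)
    }
  }

  # sequence-level defects on records of still-untouched species, at most
  # one defective record per species so defects never interact
  free_records <- records$record_id[records$species_name %in% available_sp]
  n_gap <- round(gap_rate * n_rec)
  n_stop <- round(stop_codon_rate * n_rec)
  pick_records <- function(n) {
    pool <- records[records$record_id %in% free_records, ]
    chosen <- character()
    for (sp in sample(unique(pool$species_name))) {
      if (length(chosen) >= n) break
      ids <- pool$record_id[pool$species_name == sp]
      chosen <- c(chosen, sample(ids, 1))
    }
    if (length(chosen) < n) {
      abort("Defect rates draw more records than available species allow.",
            class = "coigap_config_error")
    }
    sp_used <- records$species_name[match(chosen, records$record_id)]
    free_records <<- free_records[!(records$species_name[
      match(free_records, records$record_id)] %in% sp_used)]
    available_sp <<- setdiff(available_sp, sp_used)
    chosen
  }
  gap_ids <- pick_records(n_gap)
  stop_ids <- pick_records(n_stop)

  out <- records
  info <- function(ids_or_sp, by = c("record", "species")) {
    by <- match.arg(by)
    if (by == "record") {
      i <- match(ids_or_sp, out$record_id)
      tibble(record_id = ids_or_sp,
             species_name = out$species_name[i],
             genus_name = out$genus_name[i])
    } else {
      i <- match(ids_or_sp, out$species_name)
      tibble(record_id = NA_character_,
             species_name = ids_or_sp,
             genus_name = out$genus_name[i])
    }
  }

  if (length(gap_ids) > 0) {
    for (id in gap_ids) {
      i <- match(id, out$record_id)
      chars <- seq_to_chars(out$sequence[i])
      sites <- sample.int(length(chars), 2)
      chars[sites] <- "-"
      out$sequence[i] <- chars_to_seq(chars)
    }
    manifest$gap <- dplyr::mutate(info(gap_ids, "record"),
                                  defect = "gap",
                                  expected_stage = "gap_inducers")
  }
  if (length(stop_ids) > 0) {
    stops <- genetic_code_stops("SGC4")
    for (id in stop_ids) {
      i <- match(id, out$record_id)
      chars <- seq_to_chars(out$sequence[i])
      n_codons <- length(chars) %/% 3
      ci <- sample.int(n_codons - 2L, 1) + 1L   # internal codon, frame 1
      chars[(ci - 1L) * 3L + 1:3] <- seq_to_chars(stops[1])
      out$sequence[i] <- chars_to_seq(chars)
    }
    manifest$stop <- dplyr::mutate(info(stop_ids, "record"),
                                   defect = "stop_codon",
                                   expected_stage = "stop_codons")
  }
  if (length(amb_sp) > 0) {
    manifest$ambiguous <- dplyr::mutate(info(amb_sp, "species"),
                                        defect = "ambiguous_name",
                                        expected_stage = "ambiguous_names")
    for (sp in amb_sp) {
      i <- out$species_name == sp
      parts <- strsplit(sp, " ")[[1]]
      out$species_name[i] <- paste(parts[1], "cf.",
                                   paste(parts[-1], collapse = " "))
    }
  }
  if (length(under_sp) > 0) {
    manifest$undersample <- dplyr::mutate(info(under_sp, "species"),
                                          defect = "undersampled",
                                          expected_stage = "min_sequences")
    for (sp in under_sp) {
      ids <- out$record_id[out$species_name == sp]
      keep <- sort(ids)[1:2]
      out <- out[!(out$species_name == sp & !(out$record_id %in% keep)), ]
    }
  }
  if (length(zero_pairs) > 0) {
    for (g in names(zero_pairs)) {
      pair <- zero_pairs[[g]]
      donor <- out$sequence[out$species_name == pair[1]][1]
      out$sequence[out$species_name == pair[2]] <- donor
      manifest$zero <- dplyr::bind_rows(
        manifest$zero,
        dplyr::mutate(info(pair, "species"),
                      defect = "zero_distance_pair",
                      expected_stage = "zero_interspecific"))
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  if (nrow(manifest) == 0) {
    manifest <- tibble(record_id = character(), species_name = character(),
                       genus_name = character(), defect = character(),
                       expected_stage = character())
  }
  list(records = out,
       manifest = manifest[, c("defect", "record_id", "species_name",
                               "genus_name", "expected_stage")])
}
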