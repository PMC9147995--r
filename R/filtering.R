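# Quality-filter cascade for barcode records: identification level,
# ambiguous names, marker, minimum sample size, subsampling, alignment
# gaps, internal stop codons, undefined distances, quantile outliers;
# plus the genus-level preparation filters.

#' Filter configuration
#'
#' Bundles every tunable of the quality-filter cascade with the
#' conventional defaults: names containing the qualifier tokens `aff`,
#' `cf`, `nr` or `spp` are excluded; the marker must read `COI-5P`
#' exactly; species need at least 3 sequences; species with more than 100
#' sequences are subsampled to 100; internal stop codons are detected
#' under the invertebrate mitochondrial code; species above the
#' 95th-quantile of maximum intraspecific distance are removed; genera
#' need at least 3 species and families at least 2 genera.
#'
#' @param exclusion_keywords Name tokens marking uncertain identifications.
#' @param required_marker Exact (case-sensitive) marker code to retain.
#' @param min_sequences_per_species Minimum records per species (>= 2).
#' @param subsample_cap Maximum records per species before subsampling.
#' @param subsample_seed Seed for the deterministic per-species subsample.
#' @param genetic_code Translation table name as understood by
#'   [Biostrings::getGeneticCode()]; default `"SGC4"`, the invertebrate
#'   mitochondrial code (TGA encodes tryptophan).
#' @param quantile_cutoff Quantile of the per-species maximum
#'   intraspecific distance above which species are dropped (in (0, 1)).
#' @param quantile_type Quantile algorithm (see [stats::quantile()]);
#'   default 7, linear interpolation between order statistics.
#' @param min_species_per_genus,min_genera_per_family Genus-level
#'   preparation minima.
#' @return A list of class `coigap_filter_config`.
#' @export
filter_config <- function(exclusion_keywords = c("aff", "cf", "nr", "spp"),
                          required_marker = "COI-5P",
                          min_sequences_per_species = 3L,
                          subsample_cap = 100L,
                          subsample_seed = 1L,
                          genetic_code = "SGC4",
                          quantile_cutoff = 0.95,
                          quantile_type = 7L,
                          min_species_per_genus = 3L,
                          min_genera_per_family = 2L) {
  if (min_sequences_per_species < 2) {
    abort("`min_sequences_per_species` must be at least 2.",
          class = "coigap_config_error")
  }
  if (!(quantile_cutoff > 0 && quantile_cutoff < 1)) {
    abort("`quantile_cutoff` must lie in (0, 1).",
          class = "coigap_config_error")
  }
  if (subsample_cap < min_sequences_per_species) {
    abort("`subsample_cap` must be at least `min_sequences_per_species`.",
          class = "coigap_config_error")
  }
  structure(list(exclusion_keywords = tolower(exclusion_keywords),
                 required_marker = required_marker,
                 min_sequences_per_species = as.integer(min_sequences_per_species),
                 subsample_cap = as.integer(subsample_cap),
                 subsample_seed = as.integer(subsample_seed),
                 genetic_code = genetic_code,
                 quantile_cutoff = quantile_cutoff,
                 quantile_type = as.integer(quantile_type),
                 min_species_per_genus = as.integer(min_species_per_genus),
                 min_genera_per_family = as.integer(min_genera_per_family)),
            class = "coigap_filter_config")
}

name_tokens <- function(x) {
  toks <- strsplit(tolower(x), "[ .]+")
  lapply(toks, function(t) t[t != ""])
}

#' Drop records not identified to species level
#'
#' Removes records whose `species_name` is empty, genus-only (a single
#' token), or whose epithet is `sp.` with or without trailing numerals.
#'
#' @param data Record tibble.
#' @return Filtered tibble.
#' @export
filter_species_level <- function(data) {
  assert_records(data, need = c("record_id", "species_name"))
  name <- trimws(data$species_name %||% "")
  name[is.na(name)] <- ""
  toks <- strsplit(name, "\\s+")
  n_tok <- lengths(toks)
  epithet <- tolower(vapply(toks, function(t) if (length(t) >= 2) t[2] else "",
                            character(1)))
  drop <- name == "" | n_tok < 2 | grepl("^sp\\.?[0-9]*$", epithet)
  data[!drop, , drop = FALSE]
}

#' Drop records with qualifier tokens in the species name
#'
#' A record is removed iff any whitespace- or period-delimited token of
#' its species name equals one of the keywords (case-insensitive).
#' Matching is token-based, not substring-based, so legitimate epithets
#' containing e.g. "nr" survive.
#'
#' @param data Record tibble.
#' @param keywords Lowercase qualifier tokens (default
#'   `c("aff", "cf", "nr", "spp")`).
#' @return Filtered tibble.
#' @export
filter_ambiguous_names <- function(data,
                                   keywords = c("aff", "cf", "nr", "spp")) {
  assert_records(data, need = c("record_id", "species_name"))
  if (length(keywords) == 0) {
    abort("`keywords` must be non-empty.", class = "coigap_config_error")
  }
  toks <- name_tokens(data$species_name)
  drop <- vapply(toks, function(t) any(t %in% tolower(keywords)), logical(1))
  data[!drop, , drop = FALSE]
}

#' Keep records with an exact marker code
#'
#' @param data Record tibble.
#' @param required_marker Exact, case-sensitive marker (default
#'   `"COI-5P"`).
#' @return Filtered tibble.
#' @export
filter_marker <- function(data, required_marker = "COI-5P") {
  assert_records(data, need = c("record_id", "marker"))
  keep <- !is.na(data$marker) & data$marker == required_marker
  data[keep, , drop = FALSE]
}

#' Drop species with too few sequences
#'
#' @param data Record tibble.
#' @param n Minimum records per species (default 3).
#' @return Filtered tibble in which every species has at least `n`
#'   records.
#' @export
filter_min_sequences <- function(data, n = 3L) {
  assert_records(data, need = c("record_id", "species_name"))
  counts <- table(data$species_name)
  keep_sp <- names(counts)[counts >= n]
  data[data$species_name %in% keep_sp, , drop = FALSE]
}

#' Subsample over-represented species
#'
#' Species with more than `cap` records are reduced to exactly `cap` by
#' uniform sampling without replacement.  The selection is deterministic
#' given `(seed, species_name, sorted record ids)` — a per-species seed is
#' derived from the global seed and the species name, so results do not
#' depend on row order.
#'
#' @param data Record tibble.
#' @param cap Maximum records per species (default 100).
#' @param seed Global subsampling seed.
#' @return Filtered tibble.
#' @export
subsample_species <- function(data, cap = 100L, seed = 1L) {
  assert_records(data, need = c("record_id", "species_name"))
  if (cap < 1) abort("`cap` must be at least 1.", class = "coigap_config_error")
  counts <- table(data$species_name)
  big <- names(counts)[counts > cap]
  if (length(big) == 0) return(data)
  keep_ids <- unlist(lapply(big, function(sp) {
    ids <- sort(data$record_id[data$species_name == sp])
    withr::with_seed(derive_seed(seed, sp), sample(ids, cap))
  }))
  drop <- data$species_name %in% big & !(data$record_id %in% keep_ids)
  data[!drop, , drop = FALSE]
}

#' Remove gap-inducing sequences from one species alignment
#'
#' Columns consisting solely of gaps are excised first; any sequence still
#' containing a gap character is then removed, so the output alignment
#' contains no `-` at all.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Named character vector of gap-free sequences (possibly shorter
#'   alignment, possibly fewer sequences).
#' @export
remove_gap_inducers <- function(seqs) {
  if (length(unique(nchar(seqs))) > 1) {
    abort("Sequences are not aligned: unequal lengths.",
          class = "coigap_data_error")
  }
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  all_gap <- colSums(chars == "-") == nrow(chars)
  if (any(all_gap)) chars <- chars[, !all_gap, drop = FALSE]
  has_gap <- rowSums(chars == "-") > 0
  kept <- chars[!has_gap, , drop = FALSE]
  out <- apply(kept, 1, paste, collapse = "")
  setNames(as.character(out), names(seqs)[!has_gap])
}

#' Dataset-level gap filter
#'
#' Applies [remove_gap_inducers()] within each species.
#'
#' @param data Record tibble.
#' @return Filtered tibble with gap-free sequences.
#' @export
filter_alignment_gaps <- function(data) {
  assert_records(data)
  if (nrow(data) == 0) return(data)
  pieces <- lapply(split(data, data$species_name), function(g) {
    cleaned <- remove_gap_inducers(setNames(g$sequence, g$record_id))
    g <- g[g$record_id %in% names(cleaned), , drop = FALSE]
    g$sequence <- unname(cleaned[g$record_id])
    g
  })
  out <- dplyr::bind_rows(pieces)
  out[order(match(out$record_id, data$record_id)), , drop = FALSE]
}

.stop_codon_cache <- new.env(parent = emptyenv())

genetic_code_stops <- function(genetic_code = "SGC4") {
  if (is.null(.stop_codon_cache[[genetic_code]])) {
    gc <- Biostrings::getGeneticCode(genetic_code)
    .stop_codon_cache[[genetic_code]] <- names(gc)[gc == "*"]
  }
  .stop_codon_cache[[genetic_code]]
}

#' Stop-codon totals per reading frame
#'
#' Counts internal stop codons in each of the three forward reading
#' frames, summed over all sequences of a species alignment; the final
#' incomplete codon of each frame is ignored.
#'
#' @param seqs Character vector of gap-free, equal-length sequences.
#' @param genetic_code Translation table name (default `"SGC4"`,
#'   invertebrate mitochondrial).
#' @return Integer vector of length 3 (frames 1-3).
#' @export
frame_stop_counts <- function(seqs, genetic_code = "SGC4") {
  stops <- genetic_code_stops(genetic_code)
  L <- unique(nchar(seqs))
  if (length(L) > 1) {
    abort("Sequences are not aligned: unequal lengths.",
          class = "coigap_data_error")
  }
  vapply(1:3, function(f) {
    starts <- seq.int(f, L - 2, by = 3L)
    if (length(starts) == 0) return(0L)
    codons <- unlist(lapply(seqs, function(s) {
      substring(s, starts, starts + 2L)
    }))
    sum(codons %in% stops)
  }, integer(1))
}

#' Stop-codon keep/drop decision for a species
#'
#' The species' reading frame is the forward frame with the fewest total
#' stop codons across all its sequences; the species is dropped iff that
#' minimum is positive (some sequence carries an internal stop in every
#' frame's best reading).
#'
#' @inheritParams frame_stop_counts
#' @return `TRUE` to keep the species, `FALSE` to drop it.
#' @export
species_passes_stop_codon_check <- function(seqs, genetic_code = "SGC4") {
  min(frame_stop_counts(seqs, genetic_code)) == 0L
}

#' Dataset-level stop-codon filter
#'
#' @param data Record tibble with gap-free sequences.
#' @param genetic_code Translation table name.
#' @return Tibble retaining only species passing
#'   [species_passes_stop_codon_check()].
#' @export
filter_stop_codons <- function(data, genetic_code = "SGC4") {
  assert_records(data)
  if (nrow(data) == 0) return(data)
  keep_sp <- names(Filter(isTRUE, lapply(split(data$sequence, data$species_name),
                                         species_passes_stop_codon_check,
                                         genetic_code = genetic_code)))
  data[data$species_name %in% keep_sp, , drop = FALSE]
}

#' Drop species with undefined pairwise distances
#'
#' A species is removed iff any pairwise distance among its records is
#' undefined under the chosen model (no comparable sites, or a
#' non-positive K2P logarithm argument).
#'
#' @param data Record tibble.
#' @param model Distance model (default `"K2P"`).
#' @return Filtered tibble.
#' @export
filter_undefined_distances <- function(data, model = "K2P") {
  assert_records(data)
  if (nrow(data) == 0) return(data)
  ok <- vapply(split(data, data$species_name), function(g) {
    d <- distance_matrix(g, model = model)
    !anyNA(d[lower.tri(d)])
  }, logical(1))
  data[data$species_name %in% names(ok)[ok], , drop = FALSE]
}

#' Retain species at or below a quantile of maximum intraspecific distance
#'
#' The cutoff is the `q`-quantile of the per-species maximum
#' intraspecific distances; species strictly above the cutoff are
#' removed, species exactly at it are retained.
#'
#' @param max_intra Tibble with columns `species_name` and `max_intra`
#'   (one row per species).
#' @param q Quantile (default 0.95).
#' @param type Quantile algorithm (default 7).
#' @return Character vector of retained species names.
#' @export
quantile_retained_species <- function(max_intra, q = 0.95, type = 7L) {
  assert_records(max_intra, need = c("species_name", "max_intra"),
                 arg = "max_intra")
  if (nrow(max_intra) == 0) {
    abort("`max_intra` must be non-empty.", class = "coigap_data_error")
  }
  cutoff <- stats::quantile(max_intra$max_intra, probs = q, type = type,
                            names = FALSE)
  max_intra$species_name[max_intra$max_intra <= cutoff]
}

per_species_max_intra <- function(data, model = "K2P") {
  data |>
    dplyr::group_by(.data$species_name) |>
    dplyr::group_modify(function(g, key) {
      tibble(n_records = nrow(g),
             max_intra = max_intraspecific(distance_matrix(g, model = model)))
    }) |>
    dplyr::ungroup()
}

#' Quantile-outlier filter at dataset level
#'
#' @param data Record tibble (every species needs >= 2 records and fully
#'   defined distances).
#' @param q,type See [quantile_retained_species()].
#' @param model Distance model.
#' @return Filtered tibble.
#' @export
filter_quantile_outliers <- function(data, q = 0.95, type = 7L,
                                     model = "K2P") {
  assert_records(data)
  if (nrow(data) == 0) return(data)
  mi <- per_species_max_intra(data, model = model)
  keep <- quantile_retained_species(mi, q = q, type = type)
  data[data$species_name %in% keep, , drop = FALSE]
}

report_row <- function(stage, before, after) {
  tibble(stage = stage,
         records_in = nrow(before), records_out = nrow(after),
         species_in = dplyr::n_distinct(before$species_name),
         species_out = dplyr::n_distinct(after$species_name),
         dropped = list(setdiff(before$record_id, after$record_id)))
}

#' Run the species-level filter cascade
#'
#' Applies, in order: species-level identification, ambiguous-name
#' keywords, marker, minimum sequences per species, subsampling,
#' alignment-gap removal (with the minimum-sequence rule re-applied,
#' since gap removal can shrink a species below the minimum), stop
#' codons, undefined distances, and the quantile-outlier rule.  Every
#' stage is recorded in the filter report with in/out counts and the
#' identifiers it dropped.
#'
#' @param data Record tibble.
#' @param config A [filter_config()].
#' @param model Distance model used by the distance-based stages.
#' @return A list with `records` (the surviving tibble) and `report` (one
#'   row per stage: `stage`, `records_in`, `records_out`, `species_in`,
#'   `species_out`, `dropped` list-column of record ids).
#' @export
run_filter_cascade <- function(data, config = filter_config(),
                               model = "K2P") {
  assert_records(data, need = c("record_id", "species_name", "marker",
                                "sequence"))
  if (nrow(data) == 0) {
    return(list(records = data,
                report = report_row("empty", data, data)[0, ]))
  }
  stages <- list(
    species_level = function(x) filter_species_level(x),
    ambiguous_names = function(x)
      filter_ambiguous_names(x, config$exclusion_keywords),
    marker = function(x) filter_marker(x, config$required_marker),
    min_sequences = function(x)
      filter_min_sequences(x, config$min_sequences_per_species),
    subsample = function(x)
      subsample_species(x, config$subsample_cap, config$subsample_seed),
    gap_inducers = function(x) filter_alignment_gaps(x),
    min_sequences_recheck = function(x)
      filter_min_sequences(x, config$min_sequences_per_species),
    stop_codons = function(x) filter_stop_codons(x, config$genetic_code),
    undefined_distances = function(x)
      filter_undefined_distances(x, model = model),
    quantile_outliers = function(x)
      filter_quantile_outliers(x, q = config$quantile_cutoff,
                               type = config$quantile_type, model = model))
  report <- list()
  current <- data
  for (stage in names(stages)) {
    nxt <- stages[[stage]](current)
    report[[stage]] <- report_row(stage, current, nxt)
    current <- nxt
    if (nrow(current) == 0) break
  }
  list(records = current, report = dplyr::bind_rows(report))
}

#' Genus-level preparation filters
#'
#' Within each genus, every species whose minimum interspecific distance
#' to some congener is zero is removed (both members of each
#' zero-distance pair); genera left with fewer than
#' `min_species_per_genus` species are then removed, and finally families
#' with fewer than `min_genera_per_family` genera.
#'
#' @param data Record tibble that passed the species-level cascade; needs
#'   `family_name` and `genus_name`.
#' @param config A [filter_config()].
#' @param model Distance model.
#' @return A list with `records` and `report` (as in
#'   [run_filter_cascade()]).
#' @export
prepare_genus_level <- function(data, config = filter_config(),
                                model = "K2P") {
  assert_records(data, need = c("record_id", "family_name", "genus_name",
                                "species_name", "sequence"))
  report <- list()
  # 1. zero interspecific distance within genus
  before <- data
  drop_sp <- character()
  for (g in split(data, data$genus_name)) {
    if (dplyr::n_distinct(g$species_name) < 2) next
    d <- distance_matrix(g, model = model)
    mi <- min_interspecific_congeneric(d, g)
    drop_sp <- c(drop_sp,
                 mi$per_species$species_name[mi$per_species$min_inter == 0])
  }
  current <- data[!(data$species_name %in% drop_sp), , drop = FALSE]
  report$zero_interspecific <- report_row("zero_interspecific", before, current)
  # 2. genera with too few species
  before <- current
  sp_per_genus <- current |>
    dplyr::distinct(.data$genus_name, .data$species_name) |>
    dplyr::count(.data$genus_name)
  keep_gen <- sp_per_genus$genus_name[sp_per_genus$n >=
                                        config$min_species_per_genus]
  current <- current[current$genus_name %in% keep_gen, , drop = FALSE]
  report$min_species_per_genus <- report_row("min_species_per_genus",
                                             before, current)
  # 3. families with a single genus
  before <- current
  gen_per_family <- current |>
    dplyr::distinct(.data$family_name, .data$genus_name) |>
    dplyr::count(.data$family_name)
  keep_fam <- gen_per_family$family_name[gen_per_family$n >=
                                           config$min_genera_per_family]
  current <- current[current$family_name %in% keep_fam, , drop = FALSE]
  report$min_genera_per_family <- report_row("min_genera_per_family",
                                             before, current)
  list(records = current, report = dplyr::bind_rows(report))
}
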