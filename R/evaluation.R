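# Congruence between MOTU partitions and morphological species:
# match ratio, MATCH/SPLIT/MERGE/MIXTURE outcomes, and the summary tables
# (histograms, proportions, cutoff-subset report).

join_partition_species <- function(partition, species) {
  assert_records(partition, need = c("record_id", "motu"), arg = "partition")
  if (is.data.frame(species)) {
    assert_records(species, need = c("record_id", "species_name"),
                   arg = "species")
    sp <- species[, c("record_id", "species_name")]
  } else {
    if (is.null(names(species))) {
      if (length(species) != nrow(partition)) {
        abort("Unnamed `species` must have one label per partition row.",
              class = "coigap_data_error")
      }
      sp <- tibble(record_id = partition$record_id,
                   species_name = as.character(species))
    } else {
      sp <- tibble(record_id = names(species),
                   species_name = as.character(species))
    }
  }
  joined <- dplyr::inner_join(partition, sp, by = "record_id")
  if (nrow(joined) != nrow(partition) ||
      !setequal(sp$record_id, partition$record_id)) {
    abort("`partition` and `species` must cover exactly the same records.",
          class = "coigap_data_error")
  }
  joined
}

#' Match ratio between a MOTU partition and morphological species
#'
#' `Nmatch` counts MOTUs whose member set coincides exactly with the full
#' member set of one species; with `Ndelimited` MOTUs and `Nmorph` species
#' the match ratio is \deqn{2 N_{match} / (N_{delimited} + N_{morph}),}
#' which equals 1 iff the partition reproduces the species partition.
#'
#' @param partition Partition tibble from [threshold_cluster()].
#' @param species Species labels: data frame (`record_id`,
#'   `species_name`), named character vector, or unnamed vector aligned
#'   with the partition rows.
#' @return One-row tibble with `n_morph`, `n_delimited`, `n_match`,
#'   `match_ratio`.
#' @examples
#' part <- tibble::tibble(record_id = c("a", "b", "c"), motu = c(1L, 1L, 2L))
#' match_ratio(part, c(a = "X sp1", b = "X sp1", c = "X sp2"))
#' @export
match_ratio <- function(partition, species) {
  joined <- join_partition_species(partition, species)
  comp <- dplyr::count(joined, .data$motu, .data$species_name)
  sp_sizes <- dplyr::count(joined, .data$species_name, name = "sp_n")
  motu_nsp <- dplyr::count(comp, .data$motu, name = "n_sp")
  exact <- comp |>
    dplyr::inner_join(motu_nsp, by = "motu") |>
    dplyr::inner_join(sp_sizes, by = "species_name") |>
    dplyr::filter(.data$n_sp == 1L, .data$n == .data$sp_n)
  n_morph <- nrow(sp_sizes)
  n_delimited <- nrow(motu_nsp)
  n_match <- nrow(exact)
  tibble(n_morph = n_morph, n_delimited = n_delimited, n_match = n_match,
         match_ratio = 2 * n_match / (n_delimited + n_morph))
}

#' Per-species outcome categories: MATCH, SPLIT, MERGE, MIXTURE
#'
#' For each species occupying the MOTU set `M(S)`: `MATCH` when `M(S)` is a
#' single MOTU containing only that species; `SPLIT` when every MOTU in a
#' multi-MOTU `M(S)` is pure; `MERGE` when the single occupied MOTU also
#' contains other species; `MIXTURE` otherwise (split with sharing).
#'
#' @inheritParams match_ratio
#' @return Tibble with columns `species_name`, `n_motus`, `outcome`.
#' @export
classify_species_outcomes <- function(partition, species) {
  joined <- join_partition_species(partition, species)
  motu_purity <- joined |>
    dplyr::group_by(.data$motu) |>
    dplyr::summarise(pure = dplyr::n_distinct(.data$species_name) == 1L,
                     .groups = "drop")
  joined |>
    dplyr::distinct(.data$species_name, .data$motu) |>
    dplyr::inner_join(motu_purity, by = "motu") |>
    dplyr::group_by(.data$species_name) |>
    dplyr::summarise(n_motus = dplyr::n(),
                     all_pure = all(.data$pure), .groups = "drop") |>
    dplyr::mutate(outcome = dplyr::case_when(
      .data$n_motus == 1L & .data$all_pure ~ "MATCH",
      .data$n_motus >= 2L & .data$all_pure ~ "SPLIT",
      .data$n_motus == 1L & !.data$all_pure ~ "MERGE",
      TRUE ~ "MIXTURE")) |>
    dplyr::select("species_name", "n_motus", "outcome")
}

#' Overestimation ratio of a cluster count
#'
#' `(n_clusters - n_species) / n_species`, the relative excess of MOTUs
#' over morphological species; multiply by 100 for the percentage form
#' used in summary tables.
#'
#' @param n_clusters,n_species Positive counts.
#' @return A fraction (possibly negative).
#' @export
overestimation_ratio <- function(n_clusters, n_species) {
  if (any(n_species <= 0)) {
    abort("`n_species` must be positive.", class = "coigap_config_error")
  }
  (n_clusters - n_species) / n_species
}

#' Frequency distribution with fixed class interval
#'
#' Left-closed, right-open bins `[k*w, (k+1)*w)`; a value exactly on an
#' edge falls in the higher bin.  All bins from zero through the bin
#' containing the maximum are reported, including empty ones.
#'
#' @param values Non-negative numeric vector.
#' @param bin_width Class interval (default 0.01).
#' @return Tibble with `bin_lower`, `bin_upper`, `count`, `frequency`
#'   (relative); counts sum to `length(values)`.
#' @export
frequency_distribution <- function(values, bin_width = 0.01) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(tibble(bin_lower = numeric(), bin_upper = numeric(),
                  count = integer(), frequency = numeric()))
  }
  if (any(values < 0)) {
    abort("`values` must be non-negative.", class = "coigap_data_error")
  }
  k <- pmin(floor(values / bin_width), floor(max(values) / bin_width))
  bins <- 0:max(k)
  counts <- tabulate(k + 1L, nbins = length(bins))
  tibble(bin_lower = bins * bin_width,
         bin_upper = (bins + 1L) * bin_width,
         count = as.integer(counts),
         frequency = counts / length(values))
}

#' Proportion of values above a cutoff
#'
#' @param values Numeric vector.
#' @param cutoff Strict cutoff: counts `values > cutoff`.
#' @return Fraction in `[0, 1]`.
#' @export
proportion_above <- function(values, cutoff) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  mean(values > cutoff)
}

#' Cluster-count report over minimum-interspecific cutoffs
#'
#' Reproduces the shape of the cutoff-subset summary: per-species minimum
#' congeneric distances are computed once on the full genera; for each
#' cutoff `c` the species whose minimum is at least `c` are retained, each
#' genus' retained records are re-clustered at every fixed threshold and
#' at the genus' corrected minimum-interspecific threshold, and species
#' numbers, MOTU counts and overestimation ratios are reported.
#'
#' @param data Record table that already passed genus-level preparation
#'   (see [prepare_genus_level()]); needs `record_id`, `genus_name`,
#'   `species_name`, `sequence`.
#' @param cutoffs Increasing cutoffs on the per-species minimum congeneric
#'   distance (default `seq(0, 0.1, 0.01)`).
#' @param thresholds Fixed clustering thresholds
#'   (default `c(0.01, 0.02, 0.022, 0.03)`).
#' @param model Distance model.
#' @return Long tibble with columns `cutoff`, `n_species`, `method`
#'   (`"t_<threshold>"` or `"mininter"`), `n_motus`, `overestimation`.
#' @export
mininter_subset_report <- function(data, cutoffs = seq(0, 0.1, by = 0.01),
                                   thresholds = c(0.01, 0.02, 0.022, 0.03),
                                   model = "K2P") {
  assert_records(data, need = c("record_id", "genus_name", "species_name",
                                "sequence"))
  genera <- split(data, data$genus_name)
  prep <- lapply(genera, function(g) {
    d <- distance_matrix(g, model = model)
    mi <- min_interspecific_congeneric(d, g)
    list(records = g, d = d, per_species = mi$per_species)
  })
  rows <- list()
  for (cutoff in cutoffs) {
    motus <- setNames(numeric(length(thresholds) + 1),
                      c(paste0("t_", thresholds), "mininter"))
    n_species <- 0L
    for (p in prep) {
      keep_sp <- p$per_species$species_name[p$per_species$min_inter >= cutoff]
      if (length(keep_sp) == 0) next
      keep <- p$records$species_name %in% keep_sp
      ids <- p$records$record_id[keep]
      dsub <- p$d[ids, ids, drop = FALSE]
      n_species <- n_species + length(keep_sp)
      for (t in thresholds) {
        motus[paste0("t_", t)] <- motus[paste0("t_", t)] +
          cluster_count(threshold_cluster(dsub, t))
      }
      g_min <- min(p$per_species$min_inter[p$per_species$species_name %in% keep_sp])
      motus[["mininter"]] <- motus[["mininter"]] +
        cluster_count(threshold_cluster(dsub, mininter_threshold(g_min)))
    }
    over <- if (n_species > 0) {
      overestimation_ratio(as.integer(motus), n_species)
    } else {
      rep(NA_real_, length(motus))
    }
    rows[[length(rows) + 1L]] <- tibble(
      cutoff = cutoff,
      n_species = n_species,
      method = names(motus),
      n_motus = as.integer(motus),
      overestimation = over)
  }
  dplyr::bind_rows(rows)
}
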