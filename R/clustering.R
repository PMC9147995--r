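# Single-linkage threshold clustering: records joined by an edge for every
# pairwise distance below the threshold; MOTUs are the connected components.

#' Single-linkage threshold clustering into MOTUs
#'
#' Two records share a MOTU iff they are connected in the graph that has an
#' edge for every pair at distance strictly below `threshold` (single
#' linkage / connected components).  The strict `<` comparison is the
#' default; it is what makes the conventional `1e-8` correction of the
#' minimum-interspecific threshold (see [mininter_threshold()]) guarantee
#' that the closest heterospecific pair stays separated.  The operator is
#' exposed for sensitivity analysis.
#'
#' @param d Distance matrix ([distance_matrix()]); must contain no
#'   undefined (`NA`) cells.
#' @param threshold Non-negative clustering threshold.
#' @param comparison `"lt"` (strict `<`, default) or `"le"` (`<=`).
#' @return A tibble with columns `record_id` and `motu`.  MOTU ids are
#'   consecutive integers assigned by order of each MOTU's
#'   lexicographically smallest member, so they are deterministic for a
#'   given matrix and threshold.
#' @examples
#' d <- distance_matrix(c(a = "AAAA", b = "AAAT", c = "TTTT"))
#' threshold_cluster(d, 0.3)
#' @export
threshold_cluster <- function(d, threshold, comparison = c("lt", "le")) {
  comparison <- match.arg(comparison)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("`threshold` must be a single non-negative number.",
          class = "coigap_config_error")
  }
  if (anyNA(d)) {
    abort("Distance matrix contains undefined cells; filter them out before clustering.",
          class = "coigap_data_error")
  }
  labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  n <- nrow(d)
  adj <- if (comparison == "lt") d < threshold else d <= threshold
  diag(adj) <- FALSE
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    comp[i] <- cid
    queue <- i
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      if (length(nb) > 0) {
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  # renumber components by their lexicographically smallest member
  smallest <- vapply(split(labels, comp), min, character(1))
  new_id <- rank(smallest)            # smallest members are distinct
  tibble(record_id = labels, motu = as.integer(new_id[as.character(comp)]))
}

#' Number of MOTUs in a partition
#'
#' @param partition A partition tibble from [threshold_cluster()].
#' @return Integer count of distinct MOTU ids.
#' @export
cluster_count <- function(partition) {
  assert_records(partition, need = c("record_id", "motu"), arg = "partition")
  dplyr::n_distinct(partition$motu)
}

#' Per-species clustering at a threshold
#'
#' Clusters each species' records separately (the species-level analysis
#' unit) and reports the number of MOTUs each species splits into.
#'
#' @param data Record table with `record_id`, `species_name`, `sequence`.
#' @param threshold Clustering threshold.
#' @param model Distance model, `"K2P"` or `"p"`.
#' @param comparison Passed to [threshold_cluster()].
#' @return A tibble with columns `species_name`, `n_records`, `n_motus`.
#' @export
cluster_by_species <- function(data, threshold, model = "K2P",
                               comparison = "lt") {
  assert_records(data)
  data |>
    dplyr::group_by(.data$species_name) |>
    dplyr::group_modify(function(g, key) {
      d <- distance_matrix(g, model = model)
      part <- threshold_cluster(d, threshold, comparison = comparison)
      tibble(n_records = nrow(g), n_motus = cluster_count(part))
    }) |>
    dplyr::ungroup()
}

#' Count species split across two or more MOTUs
#'
#' @param species_clusters Output of [cluster_by_species()].
#' @return Integer: number of species whose records occupy at least two
#'   MOTUs.
#' @export
multi_cluster_species <- function(species_clusters) {
  assert_records(species_clusters, need = c("species_name", "n_motus"),
                 arg = "species_clusters")
  sum(species_clusters$n_motus >= 2L)
}
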