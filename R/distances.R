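# Pairwise genetic distances: Kimura two-parameter (K2P) and p-distance,
# both with pairwise deletion of non-ACGT sites.  An undefined distance
# (no comparable sites, or a non-positive logarithm argument in the K2P
# formula) is represented as NA, a first-class state downstream filters act on.

k2p_from_counts <- function(n_sites, n_ts, n_tv) {
  if (n_sites == 0) return(NA_real_)
  P <- n_ts / n_sites
  Q <- n_tv / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

pair_site_counts <- function(seq_a, seq_b) {
  a <- toupper(seq_a)
  b <- toupper(seq_b)
  if (nchar(a) != nchar(b)) {
    abort("Sequences must have equal length (aligned input required).",
          class = "coigap_data_error")
  }
  ca <- match(seq_to_chars(a), c("A", "C", "G", "T"))
  cb <- match(seq_to_chars(b), c("A", "C", "G", "T"))
  ca[is.na(ca)] <- 0L
  cb[is.na(cb)] <- 0L
  ok <- ca > 0L & cb > 0L
  diff <- ok & ca != cb
  s <- ca + cb
  # transitions are A<->G (codes 1+3) and C<->T (codes 2+4)
  ts <- diff & (s == 4L | s == 6L)
  list(n_sites = sum(ok), n_ts = sum(ts), n_tv = sum(diff) - sum(ts))
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P distance with pairwise deletion: sites where either
#' sequence carries a gap, `N` or any ambiguity code are excluded. With
#' `P` the proportion of transitions (A/G, C/T) and `Q` the proportion of
#' transversions among the compared sites, the distance is
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length
#'   (case-insensitive).
#' @return A single non-negative number, or `NA` when the distance is
#'   undefined (no comparable sites, or a logarithm argument \eqn{\le 0}).
#' @examples
#' k2p_distance("ACGTACGT", "ACGTACGT")   # 0
#' k2p_distance("AAAAAAAAAA", "GAAAAAAAAA") # one transition in ten sites
#' @seealso [p_distance()], [distance_matrix()]
#' @export
k2p_distance <- function(seq_a, seq_b) {
  cnt <- pair_site_counts(seq_a, seq_b)
  k2p_from_counts(cnt$n_sites, cnt$n_ts, cnt$n_tv)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatched sites under pairwise deletion of non-ACGT sites.
#'
#' @inheritParams k2p_distance
#' @return Mismatch proportion in `[0, 1]`, or `NA` when no sites are
#'   comparable.
#' @export
p_distance <- function(seq_a, seq_b) {
  cnt <- pair_site_counts(seq_a, seq_b)
  if (cnt$n_sites == 0) return(NA_real_)
  (cnt$n_ts + cnt$n_tv) / cnt$n_sites
}

#' Pairwise distance matrix for a set of aligned sequences
#'
#' Computes all pairwise distances under the chosen model with pairwise
#' deletion.  Undefined distances are `NA`; the diagonal is always 0.
#'
#' @param data A data frame with columns `record_id` and `sequence`, or a
#'   named character vector of sequences.
#' @param model `"K2P"` (default) or `"p"`.
#' @return A symmetric numeric matrix with record identifiers as dimnames
#'   and an attribute `model`.
#' @export
distance_matrix <- function(data, model = c("K2P", "p")) {
  model <- match.arg(model)
  if (is.data.frame(data)) {
    assert_records(data, need = c("record_id", "sequence"))
    ids <- data$record_id
    seqs <- toupper(data$sequence)
  } else {
    ids <- names(data) %||% as.character(seq_along(data))
    seqs <- toupper(as.character(data))
  }
  if (anyDuplicated(ids)) {
    abort("Record identifiers must be unique.", class = "coigap_data_error")
  }
  n <- length(seqs)
  code <- seq_codes_matrix(seqs)
  ok <- (code > 0L) * 1
  n_comp <- ok %*% t(ok)
  ind <- lapply(1:4, function(b) (code == b) * 1)
  n_match <- Reduce(`+`, lapply(ind, function(x) x %*% t(x)))
  ts_half <- ind[[1]] %*% t(ind[[3]]) + ind[[2]] %*% t(ind[[4]])
  n_ts <- ts_half + t(ts_half)
  n_diff <- n_comp - n_match
  d <- matrix(NA_real_, n, n)
  if (model == "p") {
    ok_cell <- n_comp > 0
    d[ok_cell] <- n_diff[ok_cell] / n_comp[ok_cell]
  } else {
    P <- n_ts / n_comp
    Q <- (n_diff - n_ts) / n_comp
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    ok_cell <- n_comp > 0 & !is.na(w1) & w1 > 0 & w2 > 0
    d[ok_cell] <- -0.5 * log(w1[ok_cell]) - 0.25 * log(w2[ok_cell])
  }
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  attr(d, "model") <- model
  d
}

#' All pairwise distance values of a matrix
#'
#' Lower-triangle values of a distance matrix as a plain numeric vector
#' (the input to [local_minima_thresholds()]).
#'
#' @param d A distance matrix from [distance_matrix()].
#' @param drop_na Drop undefined cells? Default `TRUE`.
#' @return Numeric vector of length `n(n-1)/2` (minus dropped cells).
#' @export
pairwise_values <- function(d, drop_na = TRUE) {
  v <- d[lower.tri(d)]
  if (drop_na) v <- v[!is.na(v)]
  v
}

#' Maximum intraspecific distance
#'
#' The largest off-diagonal value of a distance matrix restricted to one
#' species' records.
#'
#' @param d A distance matrix for the records of a single species.
#' @return A single number.
#' @export
max_intraspecific <- function(d) {
  if (nrow(d) < 2) {
    abort("At least two records are required for an intraspecific distance.",
          class = "coigap_data_error")
  }
  v <- d[lower.tri(d)]
  if (anyNA(v)) {
    abort("Distance matrix contains undefined cells; filter first.",
          class = "coigap_data_error")
  }
  max(v)
}

#' Minimum congeneric interspecific distance
#'
#' For one genus, the minimum distance over all heterospecific record pairs,
#' together with each species' own minimum distance to any congener.
#'
#' @param d Distance matrix of all records of one genus.
#' @param species Species labels: either a character vector aligned with the
#'   matrix rows, a named character vector (names = record ids), or a data
#'   frame with columns `record_id` and `species_name`.
#' @return A list with `genus_min` (a number) and `per_species`, a tibble
#'   with columns `species_name` and `min_inter`.
#' @export
min_interspecific_congeneric <- function(d, species) {
  sp <- align_species(d, species)
  if (length(unique(sp)) < 2) {
    abort("At least two species are required for an interspecific distance.",
          class = "coigap_data_error")
  }
  het <- outer(sp, sp, `!=`)
  if (anyNA(d[het])) {
    abort("Undefined distances among heterospecific pairs; filter first.",
          class = "coigap_data_error")
  }
  dd <- d
  dd[!het] <- Inf
  per_record_min <- apply(dd, 1, min)
  per_species <- tibble(species_name = sp, min_record = per_record_min) |>
    dplyr::group_by(.data$species_name) |>
    dplyr::summarise(min_inter = min(.data$min_record), .groups = "drop")
  list(genus_min = min(per_species$min_inter), per_species = per_species)
}

# Resolve a species-label argument to a character vector in matrix row order.
align_species <- function(d, species) {
  labels <- rownames(d)
  if (is.data.frame(species)) {
    assert_records(species, need = c("record_id", "species_name"),
                   arg = "species")
    idx <- match(labels, species$record_id)
    if (anyNA(idx)) {
      abort("`species` does not cover every record in the matrix.",
            class = "coigap_data_error")
    }
    return(as.character(species$species_name[idx]))
  }
  species <- as.character(species)
  if (!is.null(names(species)) && !is.null(labels)) {
    if (all(labels %in% names(species))) {
      return(unname(species[labels]))
    }
  }
  if (length(species) != nrow(d)) {
    abort("`species` must have one label per matrix row.",
          class = "coigap_data_error")
  }
  unname(species)
}
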