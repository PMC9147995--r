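# Flexible threshold selection: kernel-density local minima, grid-search
# minimisation of identification errors, and the minimum congeneric
# interspecific distance with its 1e-8 correction.

#' Evaluation grid of candidate thresholds
#'
#' Thresholds are generated by index (`start + k * step`) so the grid is
#' free of floating-point accumulation drift.
#'
#' @param start,stop,step Grid limits and spacing; defaults 0.001, 0.2,
#'   0.001 (distances, i.e. substitutions per site).
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(start = 0.001, stop = 0.2, step = 0.001) {
  if (!(start > 0 && step > 0 && stop >= start)) {
    abort("Require start > 0, step > 0 and stop >= start.",
          class = "coigap_config_error")
  }
  k <- 0:floor((stop - start) / step + 1e-9)
  start + k * step
}

#' Candidate thresholds from local minima of the distance density
#'
#' Fits a Gaussian kernel density (rule-of-thumb bandwidth, 512 evaluation
#' points spanning the data range extended by three bandwidths) to all
#' pairwise distances and returns the grid points that are strictly lower
#' than both neighbours.  A dip in the density marks the transition between
#' intra- and interspecific distances (the barcoding gap); the method needs
#' no prior species identities.
#'
#' @param distances Numeric vector of pairwise distances (at least two).
#' @param bw Bandwidth specification passed to [stats::density()]
#'   (default `"nrd0"`, Silverman's rule of thumb).
#' @param n_points Number of density evaluation points (default 512).
#' @param cut Range extension in bandwidths (default 3).
#' @return Increasing numeric vector of local-minimum locations (possibly
#'   empty).
#' @seealso [select_local_minimum()]
#' @export
local_minima_thresholds <- function(distances, bw = "nrd0", n_points = 512,
                                    cut = 3) {
  distances <- distances[!is.na(distances)]
  if (length(distances) < 2) {
    abort("At least two distance values are required for a density estimate.",
          class = "coigap_data_error")
  }
  dens <- stats::density(distances, bw = bw, kernel = "gaussian",
                         n = n_points, cut = cut)
  y <- dens$y
  m <- length(y)
  i <- which(y[2:(m - 1)] < y[1:(m - 2)] & y[2:(m - 1)] < y[3:m]) + 1L
  dens$x[i]
}

#' First local minimum as the working threshold
#'
#' @param candidates Output of [local_minima_thresholds()].
#' @return The first (smallest) candidate, or `NA` when there is none —
#'   the method is then not applicable to the genus and is reported as
#'   such rather than falling back to a fixed threshold.
#' @export
select_local_minimum <- function(candidates) {
  if (length(candidates) == 0) NA_real_ else candidates[[1]]
}

# Per-record nearest-neighbour summary backing the identification-error
# counts: for each record, the distance to its nearest neighbour overall,
# to its nearest heterospecific neighbour, and whether its species is a
# singleton in the evaluated set.
nn_summary <- function(d, species) {
  sp <- align_species(d, species)
  if (anyNA(d[lower.tri(d)])) {
    abort("Distance matrix contains undefined cells; filter first.",
          class = "coigap_data_error")
  }
  dd <- d
  diag(dd) <- Inf
  d_all <- apply(dd, 1, min)
  het <- outer(sp, sp, `!=`)
  dh <- dd
  dh[!het] <- Inf
  d_het <- apply(dh, 1, min)
  counts <- table(sp)
  tibble(record_id = rownames(d) %||% as.character(seq_len(nrow(d))),
         species_name = sp,
         d_nearest = d_all,
         d_nearest_hetero = d_het,
         singleton = as.vector(counts[sp] == 1L))
}

errors_at <- function(nn, threshold) {
  m_empty <- nn$d_nearest >= threshold
  tn <- sum(m_empty & nn$singleton)
  fn <- sum(m_empty & !nn$singleton)
  fp <- sum(!m_empty & nn$d_nearest_hetero < threshold)
  tp <- sum(!m_empty & nn$d_nearest_hetero >= threshold)
  tibble(threshold = threshold,
         true_positives = tp, false_positives = fp,
         false_negatives = fn, true_negatives = tn,
         cumulative_error = fp + fn)
}

#' Identification-error counts at one threshold
#'
#' For each record, its neighbourhood `M` is the set of other records at
#' distance strictly below the threshold.  A record is a true negative if
#' `M` is empty and its species is a singleton in the evaluated set; a
#' false negative if `M` is empty otherwise; a true positive if `M` is
#' non-empty and entirely conspecific; and a false positive if `M`
#' contains a heterospecific record.  The four categories are exhaustive
#' and mutually exclusive, so their counts sum to the number of records.
#'
#' @param d Distance matrix with no undefined cells.
#' @param species Species labels (see [min_interspecific_congeneric()]).
#' @param threshold Threshold to evaluate.
#' @return One-row tibble with columns `threshold`, `true_positives`,
#'   `false_positives`, `false_negatives`, `true_negatives`,
#'   `cumulative_error` (false positives + false negatives).
#' @export
identification_errors <- function(d, species, threshold) {
  errors_at(nn_summary(d, species), threshold)
}

#' Optimal threshold by identification-error minimisation
#'
#' Evaluates [identification_errors()] at every grid threshold and selects
#' the threshold minimising the cumulative error (false positives + false
#' negatives).  When several thresholds tie at the minimum, their
#' arithmetic mean is returned.
#'
#' @inheritParams identification_errors
#' @param grid Numeric vector of candidate thresholds
#'   (default [threshold_grid()]).
#' @return An object of class `coigap_threshopt` with elements `optimum`,
#'   `minimum_error`, `tied_thresholds`, `scan` (the full tibble of
#'   per-threshold counts), `n_records` and `n_species`.  Supports
#'   [tidy()], [glance()], [ggplot2::autoplot()] and `print()`.
#' @export
thresh_opt <- function(d, species, grid = threshold_grid()) {
  if (length(grid) < 1) {
    abort("`grid` must contain at least one threshold.",
          class = "coigap_config_error")
  }
  nn <- nn_summary(d, species)
  scan <- dplyr::bind_rows(lapply(grid, function(t) errors_at(nn, t)))
  min_err <- min(scan$cumulative_error)
  tied <- scan$threshold[scan$cumulative_error == min_err]
  structure(
    list(optimum = mean(tied),
         minimum_error = min_err,
         tied_thresholds = tied,
         scan = scan,
         n_records = nrow(nn),
         n_species = dplyr::n_distinct(nn$species_name)),
    class = "coigap_threshopt")
}

#' @export
print.coigap_threshopt <- function(x, ...) {
  cat("Threshold optimisation over", nrow(x$scan), "candidate thresholds\n")
  cat(sprintf("  records: %d  species: %d\n", x$n_records, x$n_species))
  cat(sprintf("  minimum cumulative error: %d (at %d threshold%s)\n",
              x$minimum_error, length(x$tied_thresholds),
              if (length(x$tied_thresholds) == 1) "" else "s"))
  cat(sprintf("  optimal threshold (mean of ties): %.6g\n", x$optimum))
  invisible(x)
}

#' @method tidy coigap_threshopt
#' @export
tidy.coigap_threshopt <- function(x, ...) x$scan

#' @method glance coigap_threshopt
#' @export
glance.coigap_threshopt <- function(x, ...) {
  tibble(optimum = x$optimum,
         minimum_error = x$minimum_error,
         n_tied = length(x$tied_thresholds),
         n_records = x$n_records,
         n_species = x$n_species)
}

#' Minimum-interspecific clustering threshold
#'
#' The per-genus threshold derived from the minimum congeneric
#' interspecific distance, corrected downwards by `1e-8` so that under the
#' strict `<` comparison of [threshold_cluster()] the closest
#' heterospecific pair is guaranteed to fall on or above the threshold and
#' stays separated.
#'
#' @param min_inter Minimum congeneric interspecific distance (must exceed
#'   `1e-8`).
#' @return `min_inter - 1e-8`.
#' @export
mininter_threshold <- function(min_inter) {
  if (!is.numeric(min_inter) || anyNA(min_inter) || any(min_inter <= 1e-8)) {
    abort("`min_inter` must exceed the correction constant 1e-8.",
          class = "coigap_config_error")
  }
  min_inter - 1e-8
}
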