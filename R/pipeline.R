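# End-to-end orchestration: species-level summary (maximum intraspecific
# distances, histograms, per-species clustering), genus-level comparison
# of fixed and flexible thresholds, and a deterministic on-disk run.

#' Pipeline configuration
#'
#' @param filter A [filter_config()].
#' @param model Distance model, `"K2P"` or `"p"`.
#' @param fixed_thresholds Fixed clustering thresholds (default
#'   `c(0.01, 0.02, 0.022, 0.03)`, the empirical COI thresholds).
#' @param grid_start,grid_stop,grid_step Threshold-optimisation grid
#'   (default 0.001 to 0.2 by 0.001).
#' @param proportion_cutoffs Cutoffs for the proportion of species with a
#'   maximum intraspecific distance above them (default 1%, 2%, 3%).
#' @param table_cutoffs Minimum-interspecific cutoffs of the subset
#'   report (default 0 to 0.1 by 0.01).
#' @param bin_width Histogram class interval (default 0.01).
#' @param seed Run seed (subsampling; simulation when used).
#' @param simulation `NULL`, or a named list of arguments to
#'   [simulate_barcodes()] used when [run_pipeline()] is not given
#'   records.
#' @return A list of class `coigap_config`.
#' @export
coigap_config <- function(filter = filter_config(),
                          model = c("K2P", "p"),
                          fixed_thresholds = c(0.01, 0.02, 0.022, 0.03),
                          grid_start = 0.001, grid_stop = 0.2,
                          grid_step = 0.001,
                          proportion_cutoffs = c(0.01, 0.02, 0.03),
                          table_cutoffs = seq(0, 0.1, by = 0.01),
                          bin_width = 0.01,
                          seed = 1L,
                          simulation = NULL) {
  model <- match.arg(model)
  if (any(fixed_thresholds <= 0)) {
    abort("`fixed_thresholds` must be positive.",
          class = "coigap_config_error")
  }
  structure(list(filter = filter, model = model,
                 fixed_thresholds = fixed_thresholds,
                 grid_start = grid_start, grid_stop = grid_stop,
                 grid_step = grid_step,
                 proportion_cutoffs = proportion_cutoffs,
                 table_cutoffs = table_cutoffs,
                 bin_width = bin_width,
                 seed = as.integer(seed),
                 simulation = simulation),
            class = "coigap_config")
}

#' Species-level analysis
#'
#' Computes, from a filtered record table: the per-species maximum
#' intraspecific distance, the per-order frequency distribution of those
#' maxima (class interval `bin_width`), the proportions of species above
#' each cutoff, and per-species single-linkage clustering at each fixed
#' threshold with total MOTU counts and the number of species split into
#' two or more MOTUs.
#'
#' @param data Filtered record tibble.
#' @param config A [coigap_config()].
#' @return A list of tibbles: `species_stats`, `histogram`, `proportions`,
#'   `cluster_summary`.
#' @export
run_species_analysis <- function(data, config = coigap_config()) {
  assert_records(data, need = c("record_id", "order_name", "species_name",
                                "sequence"))
  if (nrow(data) == 0) {
    abort("Species-level analysis needs a non-empty filtered dataset.",
          class = "coigap_data_error")
  }
  orders <- data |>
    dplyr::distinct(.data$species_name, .data$order_name)
  species_stats <- per_species_max_intra(data, model = config$model) |>
    dplyr::left_join(orders, by = "species_name") |>
    dplyr::select("species_name", "order_name", "n_records", "max_intra") |>
    dplyr::arrange(.data$species_name)
  histogram <- species_stats |>
    dplyr::group_by(.data$order_name) |>
    dplyr::group_modify(function(g, key) {
      frequency_distribution(g$max_intra, bin_width = config$bin_width)
    }) |>
    dplyr::ungroup()
  proportions <- tibble(
    cutoff = config$proportion_cutoffs,
    n_species = nrow(species_stats),
    n_above = vapply(config$proportion_cutoffs,
                     function(cc) sum(species_stats$max_intra > cc),
                     integer(1)),
    proportion = vapply(config$proportion_cutoffs,
                        function(cc) proportion_above(species_stats$max_intra, cc),
                        numeric(1)))
  cluster_summary <- dplyr::bind_rows(lapply(
    sort(config$fixed_thresholds), function(t) {
      by_sp <- cluster_by_species(data, t, model = config$model)
      tibble(threshold = t,
             n_species = nrow(by_sp),
             n_clusters = sum(by_sp$n_motus),
             n_multi_cluster_species = multi_cluster_species(by_sp))
    }))
  list(species_stats = species_stats, histogram = histogram,
       proportions = proportions, cluster_summary = cluster_summary)
}

evaluate_genus_method <- function(d, genus_records, threshold, method) {
  if (is.na(threshold)) {
    return(tibble(method = method, threshold = NA_real_, evaluable = FALSE,
                  n_morph = dplyr::n_distinct(genus_records$species_name),
                  n_delimited = NA_integer_, n_match = NA_integer_,
                  match_ratio = NA_real_, MATCH = NA_integer_,
                  SPLIT = NA_integer_, MERGE = NA_integer_,
                  MIXTURE = NA_integer_))
  }
  part <- threshold_cluster(d, threshold)
  mr <- match_ratio(part, genus_records)
  outcomes <- classify_species_outcomes(part, genus_records)
  counts <- table(factor(outcomes$outcome,
                         levels = c("MATCH", "SPLIT", "MERGE", "MIXTURE")))
  tibble(method = method, threshold = threshold, evaluable = TRUE,
         n_morph = mr$n_morph, n_delimited = mr$n_delimited,
         n_match = mr$n_match, match_ratio = mr$match_ratio,
         MATCH = as.integer(counts[["MATCH"]]),
         SPLIT = as.integer(counts[["SPLIT"]]),
         MERGE = as.integer(counts[["MERGE"]]),
         MIXTURE = as.integer(counts[["MIXTURE"]]))
}

#' Genus-level analysis
#'
#' Applies the genus-level preparation filters, then evaluates, per
#' genus, the fixed thresholds alongside the three flexible methods:
#' `localMinima` (first local minimum of the kernel density of all
#' pairwise distances; a genus without one is reported as not evaluable),
#' `mininter` (minimum congeneric interspecific distance minus `1e-8`)
#' and `opt` (grid-search identification-error minimisation).  Each
#' (genus, method) pair is scored against the morphological species with
#' the match ratio and MATCH/SPLIT/MERGE/MIXTURE counts.
#'
#' @param data Record tibble that passed the species-level cascade.
#' @param config A [coigap_config()].
#' @return A list: `genus_evaluation` (one row per genus and method),
#'   `method_summary` (average match ratio and category totals per
#'   method, over evaluable genera), `subset_report`
#'   ([mininter_subset_report()]), `prep_report`, and `records` (the
#'   prepared table).
#' @export
run_genus_analysis <- function(data, config = coigap_config()) {
  prep <- prepare_genus_level(data, config$filter, model = config$model)
  records <- prep$records
  if (nrow(records) == 0) {
    abort("No genera survive the genus-level preparation filters.",
          class = "coigap_data_error")
  }
  grid <- threshold_grid(config$grid_start, config$grid_stop,
                         config$grid_step)
  evals <- lapply(split(records, records$genus_name), function(g) {
    d <- distance_matrix(g, model = config$model)
    rows <- lapply(sort(config$fixed_thresholds), function(t) {
      evaluate_genus_method(d, g, t, sprintf("t_%g", t))
    })
    lm_t <- select_local_minimum(local_minima_thresholds(pairwise_values(d)))
    rows <- c(rows, list(evaluate_genus_method(d, g, lm_t, "localMinima")))
    mi <- min_interspecific_congeneric(d, g)
    rows <- c(rows, list(evaluate_genus_method(
      d, g, mininter_threshold(mi$genus_min), "mininter")))
    opt <- thresh_opt(d, g, grid = grid)
    rows <- c(rows, list(evaluate_genus_method(d, g, opt$optimum, "opt")))
    dplyr::bind_rows(rows)
  })
  genus_evaluation <- dplyr::bind_rows(evals, .id = "genus_name") |>
    dplyr::arrange(.data$genus_name, .data$method)
  method_summary <- genus_evaluation |>
    dplyr::filter(.data$evaluable) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_genera = dplyr::n(),
                     mean_match_ratio = mean(.data$match_ratio),
                     n_morph = sum(.data$n_morph),
                     n_delimited = sum(.data$n_delimited),
                     MATCH = sum(.data$MATCH), SPLIT = sum(.data$SPLIT),
                     MERGE = sum(.data$MERGE), MIXTURE = sum(.data$MIXTURE),
                     .groups = "drop")
  subset_report <- mininter_subset_report(
    records, cutoffs = config$table_cutoffs,
    thresholds = sort(config$fixed_thresholds), model = config$model)
  list(genus_evaluation = genus_evaluation,
       method_summary = method_summary,
       subset_report = subset_report,
       prep_report = prep$report,
       records = records)
}

flatten_report <- function(report) {
  report |>
    dplyr::mutate(dropped = vapply(.data$dropped, paste, character(1),
                                   collapse = ","))
}

#' Run the full pipeline and write its reports
#'
#' Simulates (when `records` is `NULL` and `config$simulation` is set) or
#' takes a record table, runs the filter cascade, the species-level and
#' the genus-level analyses, writes every report as TSV into `out_dir`
#' and a JSON manifest describing the run.  Outputs are byte-identical
#' across runs with the same configuration and seed.
#'
#' @param config A [coigap_config()].
#' @param out_dir Output directory (created if absent).
#' @param records Optional record tibble; when `NULL`, data are simulated
#'   from `config$simulation` and `config$seed`.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config = coigap_config(), out_dir, records = NULL) {
  if (is.null(records)) {
    if (is.null(config$simulation)) {
      abort("Provide `records` or set `config$simulation`.",
            class = "coigap_config_error")
    }
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% config$seed
    records <- do.call(simulate_barcodes, sim_args)$records
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cascade <- run_filter_cascade(records, config$filter, model = config$model)
  if (nrow(cascade$records) == 0) {
    abort("All records were removed by the filter cascade.",
          class = "coigap_data_error")
  }
  species <- run_species_analysis(cascade$records, config)
  genus <- run_genus_analysis(cascade$records, config)
  outputs <- list(
    filtered_records.tsv = cascade$records,
    filter_report.tsv = flatten_report(cascade$report),
    species_stats.tsv = species$species_stats,
    histogram.tsv = species$histogram,
    proportions.tsv = species$proportions,
    cluster_summary.tsv = species$cluster_summary,
    genus_prep_report.tsv = flatten_report(genus$prep_report),
    genus_evaluation.tsv = genus$genus_evaluation,
    method_summary.tsv = genus$method_summary,
    mininter_subset_report.tsv = genus$subset_report)
  for (name in names(outputs)) {
    readr::write_tsv(outputs[[name]], file.path(out_dir, name),
                     progress = FALSE)
  }
  cfg <- unclass(config)
  cfg$filter <- unclass(cfg$filter)
  manifest <- list(
    package = "coigap",
    version = as.character(utils::packageVersion("coigap")),
    seed = config$seed,
    config = cfg,
    config_hash = rlang::hash(cfg),
    stage_counts = setNames(as.list(cascade$report$records_out),
                            cascade$report$stage),
    outputs = lapply(setNames(nm = names(outputs)), function(f) {
      list(rows = nrow(outputs[[f]]),
           md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
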