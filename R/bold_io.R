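# Readers and writers for BOLD-style specimen tables (TSV) and grouped
# FASTA files.  Both produce the record tibble every downstream stage
# consumes: record_id, order_name, family_name, genus_name, species_name,
# marker, sequence (uppercase).

BOLD_DEFAULT_COLUMNS <- c(record_id = "processid",
                          order_name = "order_name",
                          family_name = "family_name",
                          genus_name = "genus_name",
                          species_name = "species_name",
                          marker = "markercode",
                          sequence = "nucleotides")

#' Read a BOLD-style specimen table
#'
#' Reads a tab-separated specimen table (UTF-8, header row required) into
#' the record tibble used throughout the package.  Default column names
#' follow the public BOLD export (`processid`, `order_name`,
#' `family_name`, `genus_name`, `species_name`, `markercode`,
#' `nucleotides`); exports with other headers are mapped via `column_map`.
#' Rows with an empty sequence cell are dropped and counted in the load
#' report (attribute `"load_report"`).
#'
#' @param path Path to the TSV file.
#' @param column_map Named character vector mapping record roles
#'   (`record_id`, `species_name`, ...) to column names in the file;
#'   roles omitted from the map use the BOLD defaults.
#' @return A tibble of records with attribute `load_report`, a one-row
#'   tibble with `rows_in`, `records_out`, `dropped_empty_sequence`.
#' @export
read_bold_tsv <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "coigap_io_error")
  }
  cols <- BOLD_DEFAULT_COLUMNS
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(cols))
    if (length(unknown) > 0) {
      abort(sprintf("Unknown record role(s) in `column_map`: %s.",
                    paste(unknown, collapse = ", ")),
            class = "coigap_config_error")
    }
    cols[names(column_map)] <- column_map
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- cols[!(cols %in% names(raw))]
  # order/family are optional taxonomy context; the core roles must resolve
  core <- c("record_id", "genus_name", "species_name", "marker", "sequence")
  missing_core <- intersect(names(missing), core)
  if (length(missing_core) > 0) {
    abort(sprintf("Cannot resolve required column(s) for role(s) %s (looked for %s).",
                  paste(missing_core, collapse = ", "),
                  paste(cols[missing_core], collapse = ", ")),
          class = "coigap_config_error")
  }
  out <- tibble(record_id = raw[[cols[["record_id"]]]],
                order_name = if (cols[["order_name"]] %in% names(raw))
                  raw[[cols[["order_name"]]]] else NA_character_,
                family_name = if (cols[["family_name"]] %in% names(raw))
                  raw[[cols[["family_name"]]]] else NA_character_,
                genus_name = raw[[cols[["genus_name"]]]],
                species_name = raw[[cols[["species_name"]]]],
                marker = raw[[cols[["marker"]]]],
                sequence = raw[[cols[["sequence"]]]])
  rows_in <- nrow(out)
  empty <- is.na(out$sequence) | trimws(out$sequence) == ""
  out <- out[!empty, , drop = FALSE]
  out$sequence <- toupper(gsub("\\s", "", out$sequence))
  assert_sequences_valid(out$record_id, out$sequence)
  dup <- out$record_id[duplicated(out$record_id)]
  if (length(dup) > 0) {
    abort(c("Duplicate record identifiers in input.",
            setNames(unique(dup)[seq_len(min(5, length(unique(dup))))],
                     rep("x", min(5, length(unique(dup)))))),
          class = "coigap_data_error")
  }
  attr(out, "load_report") <- tibble(rows_in = rows_in,
                                     records_out = nrow(out),
                                     dropped_empty_sequence = sum(empty))
  out
}

#' Read barcode sequences from FASTA
#'
#' Headers must follow the convention
#' `record_id|Genus species|marker` (delimiter configurable).  The genus
#' is taken as the first token of the binomial; order and family are not
#' encoded in FASTA headers and are returned as `NA`.
#'
#' @param path Path to a FASTA file; gaps (`-`) are allowed and treated as
#'   alignment gaps downstream.
#' @param delim Header field delimiter (default `"|"`).
#' @return A record tibble (see [read_bold_tsv()]).
#' @export
read_barcode_fasta <- function(path, delim = "|") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "coigap_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  fields <- strsplit(headers, delim, fixed = TRUE)
  bad <- lengths(fields) != 3
  if (any(bad)) {
    abort(c("FASTA header(s) do not follow 'record_id|Genus species|marker':",
            setNames(headers[bad][seq_len(min(5, sum(bad)))],
                     rep("x", min(5, sum(bad))))),
          class = "coigap_data_error")
  }
  seqs <- toupper(as.character(set))
  ids <- trimws(vapply(fields, `[[`, "", 1))
  species <- trimws(vapply(fields, `[[`, "", 2))
  marker <- trimws(vapply(fields, `[[`, "", 3))
  assert_sequences_valid(ids, seqs)
  if (anyDuplicated(ids)) {
    abort("Duplicate record identifiers in FASTA.", class = "coigap_data_error")
  }
  tibble(record_id = ids,
         order_name = NA_character_,
         family_name = NA_character_,
         genus_name = stringr::word(species, 1),
         species_name = species,
         marker = marker,
         sequence = unname(seqs))
}

sanitize_filename <- function(x) {
  y <- gsub("\\s+", "_", trimws(x))
  y <- gsub("[^A-Za-z0-9_]", "", y)
  y[y == ""] <- "unnamed"
  # resolve collisions deterministically with numeric suffixes
  out <- y
  tab <- table(y)
  for (name in names(tab)[tab > 1]) {
    idx <- which(y == name)
    out[idx] <- paste0(name, "_", seq_along(idx))
  }
  out
}

#' Write records to FASTA, optionally grouped by species or genus
#'
#' Headers follow `record_id|species_name|marker`, the convention
#' [read_barcode_fasta()] parses, so a write/read round trip preserves
#' identifiers, names and sequences.  Group names are turned into
#' deterministic, filesystem-safe file names (spaces to underscores,
#' non-alphanumerics stripped, numeric suffixes on collisions).
#'
#' @param data Record tibble.
#' @param path Output file (grouping `"none"`) or output directory
#'   (grouping `"species"` or `"genus"`).
#' @param group_by `"none"`, `"species"`, or `"genus"`.
#' @return Invisibly, a tibble mapping each group to the file written.
#' @export
write_barcode_fasta <- function(data, path, group_by = c("none", "species",
                                                         "genus")) {
  group_by <- match.arg(group_by)
  assert_records(data, need = c("record_id", "species_name", "marker",
                                "sequence"))
  if (nrow(data) == 0) {
    abort("Refusing to write an empty dataset.", class = "coigap_data_error")
  }
  write_one <- function(records, file) {
    headers <- paste(records$record_id, records$species_name,
                     records$marker, sep = "|")
    set <- Biostrings::BStringSet(setNames(records$sequence, headers))
    Biostrings::writeXStringSet(set, filepath = file, width = 80)
    file
  }
  if (group_by == "none") {
    write_one(data, path)
    return(invisible(tibble(group = NA_character_, file = path)))
  }
  key <- if (group_by == "species") data$species_name else data$genus_name
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  groups <- sort(unique(key))
  files <- file.path(path, paste0(sanitize_filename(groups), ".fasta"))
  for (i in seq_along(groups)) {
    write_one(data[key == groups[i], , drop = FALSE], files[i])
  }
  invisible(tibble(group = groups, file = files))
}
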