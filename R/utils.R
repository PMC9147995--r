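# Shared internals: record-table validation, sequence encoding, seeds.

# Closed nucleotide alphabet: ACGT, IUPAC ambiguity codes, N, alignment gap.
IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

RECORD_COLUMNS <- c("record_id", "order_name", "family_name", "genus_name",
                    "species_name", "marker", "sequence")

assert_records <- function(data, need = c("record_id", "species_name", "sequence"),
                           arg = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame of specimen records.", arg),
          class = "coigap_config_error")
  }
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  arg, paste0("`", missing, "`", collapse = ", ")),
          class = "coigap_config_error")
  }
  invisible(data)
}

assert_sequences_valid <- function(ids, seqs) {
  bad <- !grepl(paste0("^[", paste(IUPAC_CHARS, collapse = ""), "]+$"), seqs)
  if (any(bad)) {
    abort(c("Sequences contain characters outside the IUPAC nucleotide alphabet.",
            setNames(paste0("record ", ids[bad][seq_len(min(5, sum(bad)))]),
                     rep("x", min(5, sum(bad))))),
          class = "coigap_data_error")
  }
  invisible(TRUE)
}

# Integer encoding of an aligned set of sequences: A=1, C=2, G=3, T=4,
# anything else (gap, N, ambiguity) = 0.  Rows are sequences.
seq_codes_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    abort("Sequences are not aligned: unequal lengths.",
          class = "coigap_data_error")
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), c("A", "C", "G", "T")),
              nrow = length(seqs), ncol = lens[1], byrow = TRUE)
  m[is.na(m)] <- 0L
  m
}

seq_to_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

chars_to_seq <- function(chars) paste(chars, collapse = "")

# Deterministic per-unit seed derived from a global seed and a label, so
# subsampling and simulation are independent of row order.
derive_seed <- function(seed, label) {
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  (strtoi(substr(h, 1, 7), base = 16L) %% 2147483546L) + 1L
}

`%||%` <- rlang::`%||%`
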