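# Independent oracles and fixture builders shared across tests.  These
# deliberately re-derive results with different algorithms from the
# package implementation.

# Union-find connected components over a logical adjacency matrix;
# returns a component label per row.
uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j]) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonical partition signature: set of sorted member groups, so two
# partitions can be compared independently of label numbering.
partition_signature <- function(labels, comp) {
  unname(sort(vapply(split(labels, comp),
                     function(g) paste(sort(g), collapse = "+"),
                     character(1))))
}

# Direct per-record identification-error categories by scanning the
# neighbour set (no nearest-neighbour shortcut).
oracle_errors <- function(d, sp, t) {
  n <- nrow(d)
  tp <- fp <- fn <- tn <- 0L
  counts <- table(sp)
  for (i in seq_len(n)) {
    m <- setdiff(which(d[i, ] < t), i)
    if (length(m) == 0) {
      if (counts[[sp[i]]] == 1L) tn <- tn + 1L else fn <- fn + 1L
    } else {
      if (all(sp[m] == sp[i])) tp <- tp + 1L else fp <- fp + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Random symmetric distance matrix with zero diagonal; a fraction of the
# cells are tied to each other to exercise boundary behaviour.
random_dmat <- function(n, max_d = 0.1, tie_prob = 0.2) {
  v <- runif(n * (n - 1) / 2, 0, max_d)
  ties <- runif(length(v)) < tie_prob
  if (any(ties) && sum(!ties) > 0) {
    v[ties] <- sample(v[!ties], sum(ties), replace = TRUE)
  }
  d <- matrix(0, n, n)
  d[lower.tri(d)] <- v
  d <- d + t(d)
  dimnames(d) <- list(sprintf("r%02d", seq_len(n)),
                      sprintf("r%02d", seq_len(n)))
  d
}

# Aligned sequence pair with exact transition/transversion counts over a
# clean A-background; transitions flip A->G, transversions A->C.
pair_with_counts <- function(n_sites, n_ts, n_tv) {
  stopifnot(n_ts + n_tv <= n_sites)
  a <- rep("A", n_sites)
  b <- rep("A", n_sites)
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "C"
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

# Small record tibble straight from sequences, one genus.
records_from_seqs <- function(seqs, species, genus = "Genus001",
                              family = "Family001", order = "Order01",
                              marker = "COI-5P") {
  tibble::tibble(record_id = sprintf("R%03d", seq_along(seqs)),
                 order_name = order, family_name = family,
                 genus_name = genus, species_name = species,
                 marker = marker, sequence = toupper(seqs))
}

# Random gapless ACGT alignment.
random_alignment <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Alignment of n sequences derived from one random ancestor by k random
# substitutions each, so pairwise distances stay far from saturation.
related_alignment <- function(n, len, k = max(1, len %/% 20)) {
  base <- strsplit(random_alignment(1, len), "")[[1]]
  vapply(seq_len(n), function(i) {
    ch <- base
    idx <- sample(len, k)
    ch[idx] <- vapply(ch[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(ch, collapse = "")
  }, character(1))
}
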