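# Shared toy fixtures and independent oracles used across the suite.

# Back-translate a protein with the first codon of each amino acid
# (deterministic), appending a TAA stop.
toy_cds <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  first_codon <- vapply(split(names(gc), gc), `[[`, "", 1L)
  aas <- strsplit(protein, "")[[1]]
  paste0(paste(first_codon[aas], collapse = ""), "TAA")
}

# Parent set + gapless alignment from a character vector of equal-length
# proteins.
toy_family <- function(proteins, ids = sprintf("T%02d", seq_along(proteins))) {
  parents <- parent_set(ids, proteins, vapply(proteins, toy_cds, ""))
  list(parents = parents, aln = msa(stats::setNames(proteins, ids)))
}

# Place junctions at explicit gap-free alignment columns, bypassing
# conservation scoring (used to pin junctions in toy constructions).
junctions_at <- function(aln, columns, min_segment_nt = 1L) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  res_idx <- t(apply(m != "-", 1L, cumsum)) - 1L
  stopifnot(all(colSums(m[, columns, drop = FALSE] == "-") == 0L))
  columns <- sort(as.integer(columns))
  res_pos <- t(res_idx[, columns, drop = FALSE])
  dimnames(res_pos) <- list(NULL, aln$ids)
  structure(list(
    junctions = tibble::tibble(index = seq_along(columns),
                               aln_column = columns,
                               score = rep(NA_real_, length(columns))),
    residue_pos = res_pos,
    nt_pos = 3L * res_pos,
    parent_nt_len = stats::setNames(3L * rowSums(m != "-"), aln$ids),
    min_segment_nt = as.integer(min_segment_nt),
    labels = NULL), class = "junction_set")
}

# --- independent oracles -------------------------------------------------

# Raw per-column conservation by literal pair enumeration.
oracle_column_identity <- function(chars) {
  n <- length(chars)
  pairs <- utils::combn(n, 2L)
  hits <- 0L
  for (k in seq_len(ncol(pairs))) {
    a <- chars[pairs[1L, k]]
    b <- chars[pairs[2L, k]]
    if (a != "-" && b != "-" && a == b) hits <- hits + 1L
  }
  hits / ncol(pairs)
}

# Feasibility of a junction column subset under the per-parent spacing rule.
oracle_feasible_subset <- function(cols, res_idx, parent_nt_len,
                                   min_segment_nt) {
  nt <- 3L * res_idx[, cols, drop = FALSE]
  for (p in seq_len(nrow(nt))) {
    pos <- sort(nt[p, ])
    gaps <- diff(c(0L, pos, parent_nt_len[p]))
    if (any(gaps < min_segment_nt)) return(FALSE)
  }
  TRUE
}

# Exhaustive search: the best feasible junction subset of exactly size k,
# scored by total smoothed conservation.
oracle_best_subset <- function(aln, profile, min_segment_nt, k) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  res_idx <- t(apply(m != "-", 1L, cumsum)) - 1L
  parent_nt_len <- 3L * rowSums(m != "-")
  cand <- which(colSums(m == "-") == 0L)
  if (k == 0L || length(cand) < k) return(NULL)
  subsets <- utils::combn(cand, k)
  best <- NULL
  best_score <- -Inf
  for (s in seq_len(ncol(subsets))) {
    cols <- subsets[, s]
    if (oracle_feasible_subset(cols, res_idx, parent_nt_len, min_segment_nt)) {
      sc <- sum(as.numeric(profile)[cols])
      if (sc > best_score + 1e-12) {
        best_score <- sc
        best <- cols
      }
    }
  }
  list(cols = best, score = best_score)
}

# Largest feasible subset size by exhaustive search (small instances only).
oracle_max_feasible_size <- function(aln, profile, min_segment_nt, k_max) {
  for (k in rev(seq_len(k_max))) {
    res <- oracle_best_subset(aln, profile, min_segment_nt, k)
    if (!is.null(res) && !is.null(res$cols)) return(k)
  }
  0L
}

# Exhaustive global-alignment score by recursive enumeration of all
# alignments (no DP): usable for very short sequences only.
oracle_alignment_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      best <- max(best, rec(i - 1L, j - 1L) +
                    (if (av[i] == bv[j]) match else mismatch))
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(av), length(bv))
}

# Biostrings global alignment with the same scoring scheme: the second
# independent route for longer pairs.
biostrings_alignment_score <- function(a, b, match = 1, mismatch = -1,
                                       gap = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = gap,
                                scoreOnly = TRUE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
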