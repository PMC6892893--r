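#' Specification for anchored PAM extraction
#'
#' Describes where the randomized PAM sits in the amplicon: fixed upstream
#' and downstream anchor sequences flank a `pam_len`-mer (the reporter
#' construct carried an NNNN library 5' of the protospacer). Anchors are
#' matched by Hamming distance only (no indels), tolerating up to
#' `max_anchor_mismatches` per anchor.
#'
#' @param upstream_anchor,downstream_anchor Nucleotide strings flanking the
#'   randomized PAM.
#' @param pam_len PAM length (default 4).
#' @param max_anchor_mismatches Mismatches tolerated per anchor (default 1).
#' @param search_both_strands Also search the reverse complement of each
#'   read (default FALSE; the amplicon is directional).
#' @param min_mean_phred Optional minimum mean Phred (+33) quality per
#'   read; reads below are rejected when qualities are supplied (default
#'   NULL: no quality filtering).
#' @return A `pam_spec` list.
#' @export
pam_spec <- function(upstream_anchor, downstream_anchor, pam_len = 4L,
                     max_anchor_mismatches = 1L, search_both_strands = FALSE,
                     min_mean_phred = NULL) {
  stopifnot(nzchar(upstream_anchor), nzchar(downstream_anchor), pam_len >= 1L)
  structure(list(upstream_anchor = toupper(upstream_anchor),
                 downstream_anchor = toupper(downstream_anchor),
                 pam_len = as.integer(pam_len),
                 max_anchor_mismatches = as.integer(max_anchor_mismatches),
                 search_both_strands = isTRUE(search_both_strands),
                 min_mean_phred = min_mean_phred),
            class = "pam_spec")
}

# Vectorized anchored extraction over a character vector of reads.
# Returns a tibble(pam, status); status "ok" or a rejection category.
extract_pam_impl <- function(reads, spec) {
  n <- length(reads)
  if (n == 0L) return(tibble::tibble(pam = character(), status = character()))
  up <- spec$upstream_anchor
  dn <- spec$downstream_anchor
  lu <- nchar(up)
  ld <- nchar(dn)
  need <- lu + spec$pam_len + ld
  mm <- spec$max_anchor_mismatches
  lens <- nchar(reads)
  maxlen <- max(lens)
  # byte matrix (maxlen x n), short reads padded with 0 bytes (match nothing)
  padded <- paste0(reads, strrep(" ", maxlen - lens))
  m <- matrix(charToRaw(paste(padded, collapse = "")), nrow = maxlen)
  up_raw <- charToRaw(up)
  dn_raw <- charToRaw(dn)
  n_offsets <- maxlen - need + 1L
  pam <- rep(NA_character_, n)
  n_hits <- integer(n)
  if (n_offsets >= 1L) {
    for (s in seq_len(n_offsets)) {
      up_mm <- colSums(m[s:(s + lu - 1L), , drop = FALSE] != up_raw)
      dn_start <- s + lu + spec$pam_len
      dn_mm <- colSums(m[dn_start:(dn_start + ld - 1L), , drop = FALSE] != dn_raw)
      hit <- up_mm <= mm & dn_mm <= mm & (s + need - 1L) <= lens
      if (any(hit)) {
        first <- hit & n_hits == 0L
        pam[first] <- substr(reads[first], s + lu, s + lu + spec$pam_len - 1L)
        n_hits <- n_hits + hit
      }
    }
  }
  status <- rep("ok", n)
  status[lens < need] <- "too-short"
  status[lens >= need & n_hits == 0L] <- "anchor-not-found"
  status[n_hits > 1L] <- "ambiguous-placement"
  has_n <- status == "ok" & grepl("[^ACGT]", pam)
  status[has_n] <- "ambiguous-base"
  pam[status != "ok"] <- NA_character_
  tibble::tibble(pam = pam, status = status)
}

#' Extract the randomized PAM from amplicon reads
#'
#' Finds the anchored PAM in each read: a placement is valid when both
#' anchors match within the allowed mismatches. Reads with no valid
#' placement, more than one valid placement, a non-ACGT base inside the
#' PAM, or insufficient length are rejected with a categorized reason.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `sequence` column (e.g. from [read_fastq()]).
#' @param spec A [pam_spec()].
#' @return Tibble with one row per read: `pam` (NA when rejected) and
#'   `status` (`"ok"`, `"anchor-not-found"`, `"ambiguous-placement"`,
#'   `"ambiguous-base"`, `"too-short"`).
#' @export
extract_pam <- function(reads, spec) {
  stopifnot(inherits(spec, "pam_spec"))
  quals <- NULL
  if (is.data.frame(reads)) {
    quals <- reads$quality
    reads <- reads$sequence
  }
  reads <- toupper(reads)
  res <- extract_pam_impl(reads, spec)
  if (!is.null(spec$min_mean_phred) && !is.null(quals)) {
    mean_q <- vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1L),
                     USE.NAMES = FALSE)
    low <- mean_q < spec$min_mean_phred
    res$status[low] <- "low-quality"
    res$pam[low] <- NA_character_
  }
  if (spec$search_both_strands) {
    retry <- res$status %in% c("anchor-not-found", "too-short")
    if (any(retry)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[retry])))
      res2 <- extract_pam_impl(rc, spec)
      res$pam[retry] <- res2$pam
      res$status[retry] <- res2$status
    }
  }
  res
}

#' All PAMs of a given length, lexicographic
#' @param pam_len PAM length.
#' @return Character vector of `4^pam_len` k-mers.
#' @export
pam_space <- function(pam_len = 4L) {
  bases <- c("A", "C", "G", "T")
  out <- do.call(expand.grid,
                 c(rep(list(bases), pam_len), stringsAsFactors = FALSE))
  # first position varies slowest -> lexicographic order
  sort(do.call(paste0, out))
}

#' Count extracted PAMs over the complete PAM space
#'
#' @inheritParams extract_pam
#' @return A `pam_count_table`: list with `counts` (named integer vector
#'   over all `4^pam_len` PAMs, zeros included), `total_kept`,
#'   `total_rejected`, and `rejected_by` (counts per rejection reason).
#' @export
count_pams <- function(reads, spec) {
  ex <- extract_pam(reads, spec)
  space <- pam_space(spec$pam_len)
  kept <- ex$pam[ex$status == "ok"]
  counts <- table(factor(kept, levels = space))
  counts <- stats::setNames(as.integer(counts), space)
  rejected <- ex$status[ex$status != "ok"]
  structure(list(counts = counts,
                 total_kept = length(kept),
                 total_rejected = length(rejected),
                 rejected_by = table(rejected)),
            class = "pam_count_table")
}

#' @export
print.pam_count_table <- function(x, ...) {
  cat(sprintf("PAM count table: %d PAMs, %d reads kept, %d rejected\n",
              length(x$counts), x$total_kept, x$total_rejected))
  top <- sort(x$counts, decreasing = TRUE)[1:5]
  cat("top PAMs:", paste(names(top), top, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Convert PAM counts to pseudocounted frequencies
#'
#' `freq_i = (count_i + pseudocount) / sum_j (count_j + pseudocount)`.
#' The default pseudocount of 1 keeps every frequency strictly positive so
#' logarithmic enrichment scores stay finite.
#'
#' @param table A `pam_count_table`.
#' @param pseudocount Added to every PAM count (default 1; 0 for
#'   exact-count work).
#' @param role `"X"` for the on-targeting sample, `"Y"` for the
#'   non-targeting control.
#' @return A `pam_frequencies`: list with `freqs` (named numeric, sums
#'   to 1), `role`, `pseudocount`.
#' @export
to_frequencies <- function(table, pseudocount = 1, role = c("X", "Y")) {
  stopifnot(inherits(table, "pam_count_table"))
  role <- match.arg(role)
  adj <- table$counts + pseudocount
  tot <- sum(adj)
  if (tot <= 0) stop("no counts and no pseudocount: frequencies undefined")
  structure(list(freqs = adj / tot, role = role, pseudocount = pseudocount),
            class = "pam_frequencies")
}

#' Per-PAM enrichment scores between targeting and non-targeting samples
#'
#' Compares the PAM frequency under the on-targeting gRNA (`X`) with the
#' non-targeting control (`Y`). Functional PAMs are depleted from the
#' targeting sample (cells carrying them are cut), so they score high.
#'
#' Two score conventions are implemented because the source material
#' describes both: `"log2_ratio"` (default) is the log2 frequency change
#' `E_i = log2(Y_i / X_i)`; `"ratio_of_logs"` is the displayed-equation
#' form `E_i = log2(Y_i) / log2(X_i)`, which is undefined when a frequency
#' is 0 or 1 (flagged, score NA).
#'
#' @param X `pam_frequencies` for the on-targeting sample.
#' @param Y `pam_frequencies` for the non-targeting sample.
#' @param mode `"log2_ratio"` or `"ratio_of_logs"`.
#' @return An `enrichment_table` tibble: `pam`, `X`, `Y`, `score`, `rank`
#'   (dense over the full PAM space; descending score, ties broken
#'   lexicographically, undefined scores ranked last), `flagged`. Attribute
#'   `mode` records the convention.
#' @export
enrichment <- function(X, Y, mode = c("log2_ratio", "ratio_of_logs")) {
  stopifnot(inherits(X, "pam_frequencies"), inherits(Y, "pam_frequencies"))
  mode <- match.arg(mode)
  if (!identical(names(X$freqs), names(Y$freqs))) {
    stop("X and Y cover different PAM spaces")
  }
  x <- X$freqs
  y <- Y$freqs
  if (mode == "log2_ratio") {
    score <- log2(y / x)
    flagged <- !is.finite(score)
  } else {
    score <- log2(y) / log2(x)
    flagged <- x == 0 | x == 1 | y == 0
    score[flagged] <- NA_real_
  }
  pam <- names(x)
  ord <- order(-score, pam, na.last = TRUE)
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  out <- tibble::tibble(pam = pam, X = unname(x), Y = unname(y),
                        score = unname(score), rank = rank,
                        flagged = unname(flagged))
  attr(out, "mode") <- mode
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Position-by-base weight matrix for a sequence logo
#'
#' Summarizes the top-ranked PAMs as per-position base frequencies,
#' weighting each PAM by `max(score, 0)`; every row (position) sums to 1.
#' Export-oriented: feed the matrix to any logo renderer.
#'
#' @param etab An `enrichment_table` from [enrichment()].
#' @param top_k Number of top-ranked PAMs to include (>= 1).
#' @return Numeric matrix, `pam_len` rows (positions) by 4 columns
#'   (A, C, G, T).
#' @export
logo_matrix <- function(etab, top_k) {
  stopifnot(inherits(etab, "enrichment_table"), top_k >= 1L)
  top <- etab[order(etab$rank), ][seq_len(min(top_k, nrow(etab))), ]
  w <- pmax(top$score, 0)
  w[is.na(w)] <- 0
  if (sum(w) == 0) stop("all scores are <= 0 or undefined: nothing to display")
  pam_len <- nchar(top$pam[1L])
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, nrow = pam_len, ncol = 4L,
                dimnames = list(paste0("pos", seq_len(pam_len)), bases))
  chars <- do.call(rbind, strsplit(top$pam, ""))
  for (b in bases) {
    mat[, b] <- colSums((chars == b) * w)
  }
  mat / sum(w)
}
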