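#' Per-column conservation profile of a protein alignment
#'
#' Scores each alignment column by the mean pairwise identity over all row
#' pairs: a pair contributes 1 when both rows carry the same residue
#' (gap-versus-anything, including gap-versus-gap, counts as a mismatch),
#' and the score is the matching fraction of all `choose(n, 2)` pairs. The
#' raw profile is then smoothed with a centered moving average of odd width
#' `window`, truncated at the alignment edges.
#'
#' Crossover-friendly positions are local maxima of this profile: columns
#' where distantly related orthologs still agree, flanked by divergent
#' sequence.
#'
#' @param aln An [msa()] object.
#' @param window Odd positive smoothing width in columns (default 11,
#'   roughly the width of the short conserved motifs shared across
#'   Cas12a-type orthologs).
#' @return A numeric vector of length `n_columns` with scores in `[0, 1]`,
#'   class `conservation_profile`, carrying attributes `window` and `raw`
#'   (the unsmoothed profile).
#' @export
conservation_profile <- function(aln, window = 11L) {
  stopifnot(inherits(aln, "msa"))
  if (length(aln$ids) == 0L || aln$n_columns == 0L) stop("empty alignment")
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  m <- do.call(rbind, strsplit(aln$rows, ""))
  n <- nrow(m)
  if (n < 2L) stop("conservation requires at least two alignment rows")
  npairs <- n * (n - 1L) / 2
  letters_present <- setdiff(unique(as.vector(m)), "-")
  matches <- numeric(ncol(m))
  for (ch in letters_present) {
    cnt <- colSums(m == ch)
    matches <- matches + cnt * (cnt - 1) / 2
  }
  raw <- matches / npairs
  smoothed <- moving_average(raw, window)
  structure(smoothed, window = window, raw = raw,
            class = "conservation_profile")
}

# centered moving average truncated at the edges; direct window sums so
# columns with identical window contents tie exactly (no cumsum drift)
moving_average <- function(x, window) {
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(i - h, 1L)
    hi <- min(i + h, n)
    sum(x[lo:hi]) / (hi - lo + 1L)
  }, numeric(1L))
}

#' Select crossover junctions under conservation and spacing constraints
#'
#' Greedily accepts gap-free alignment columns in descending smoothed
#' conservation score (ties broken toward the smaller column). A candidate
#' is accepted only if, for *every* parent, its projected nucleotide
#' position keeps at least `min_segment_nt` of CDS between it and every
#' previously accepted junction and both sequence ends, so that every
#' exchangeable segment spans at least that many base pairs on every
#' parent. Selection stops at `max_junctions` or when no eligible column
#' remains.
#'
#' @param profile A [conservation_profile()].
#' @param aln The [msa()] the profile was computed from.
#' @param min_segment_nt Minimum segment length in bp on every parent CDS
#'   (default 500).
#' @param max_junctions Maximum number of junctions to select (default 6).
#' @return A `junction_set`: list with `junctions` (tibble: `index`,
#'   `aln_column`, `score`), `residue_pos` and `nt_pos` (junction x parent
#'   matrices; residues 0-based, `nt = 3 * residue`), `parent_nt_len`
#'   (coding length per parent), `min_segment_nt`, and `labels` (NULL until
#'   [label_segments()] is applied). Returns an empty set with a warning
#'   when nothing is eligible.
#' @export
select_junctions <- function(profile, aln, min_segment_nt = 500L,
                             max_junctions = 6L) {
  stopifnot(inherits(profile, "conservation_profile"), inherits(aln, "msa"))
  if (min_segment_nt <= 0L) stop("min_segment_nt must be positive")
  m <- do.call(rbind, strsplit(aln$rows, ""))
  gap_free <- colSums(m == "-") == 0L
  # 0-based residue index per row at each column
  res_idx <- t(apply(m != "-", 1L, cumsum)) - 1L
  parent_res_len <- rowSums(m != "-")
  parent_nt_len <- 3L * parent_res_len
  names(parent_nt_len) <- aln$ids

  candidates <- which(gap_free)
  empty <- function() {
    structure(list(
      junctions = tibble::tibble(index = integer(), aln_column = integer(),
                                 score = numeric()),
      residue_pos = matrix(integer(), nrow = 0L, ncol = length(aln$ids),
                           dimnames = list(NULL, aln$ids)),
      nt_pos = matrix(integer(), nrow = 0L, ncol = length(aln$ids),
                      dimnames = list(NULL, aln$ids)),
      parent_nt_len = parent_nt_len,
      min_segment_nt = as.integer(min_segment_nt), labels = NULL),
      class = "junction_set")
  }
  if (max_junctions < 1L || length(candidates) == 0L) {
    if (length(candidates) == 0L) warning("no gap-free column is eligible")
    return(empty())
  }
  score <- as.numeric(profile)[candidates]
  ord <- order(-score, candidates)
  candidates <- candidates[ord]
  score <- score[ord]

  accepted <- integer()
  for (k in seq_along(candidates)) {
    col <- candidates[k]
    nt <- 3L * res_idx[, col]
    ok <- all(nt >= min_segment_nt) &&
      all(parent_nt_len - nt >= min_segment_nt)
    if (ok && length(accepted) > 0L) {
      for (acol in accepted) {
        if (any(abs(nt - 3L * res_idx[, acol]) < min_segment_nt)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      accepted <- c(accepted, col)
      if (length(accepted) >= max_junctions) break
    }
  }
  if (length(accepted) == 0L) {
    warning("no column satisfies the spacing constraint")
    return(empty())
  }
  accepted <- sort(accepted)
  res_pos <- t(res_idx[, accepted, drop = FALSE])
  dimnames(res_pos) <- list(NULL, aln$ids)
  structure(list(
    junctions = tibble::tibble(index = seq_along(accepted),
                               aln_column = accepted,
                               score = as.numeric(profile)[accepted]),
    residue_pos = res_pos,
    nt_pos = 3L * res_pos,
    parent_nt_len = parent_nt_len,
    min_segment_nt = as.integer(min_segment_nt),
    labels = NULL), class = "junction_set")
}

#' @export
print.junction_set <- function(x, ...) {
  cat(sprintf("Junction set: %d junction(s), min segment %d nt\n",
              nrow(x$junctions), x$min_segment_nt))
  print(x$junctions)
  if (!is.null(x$labels)) cat("segments:", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

#' Attach domain labels to inter-junction segments
#'
#' A set of `k` junctions partitions the protein into `k + 1` segments;
#' labels name those segments (for the six-junction Cas12a design:
#' WED-I&REC1, REC2, WED-II&PI, WED-III, RuvC-I&BH&RuvC-II, Nuc&RuvC-III,
#' plus the leading segment).
#'
#' @param jset A `junction_set`.
#' @param labels Character vector of length `nrow(junctions) + 1`.
#' @return The junction set with `labels` attached.
#' @export
label_segments <- function(jset, labels) {
  stopifnot(inherits(jset, "junction_set"))
  if (length(labels) != nrow(jset$junctions) + 1L) {
    stop("need exactly ", nrow(jset$junctions) + 1L, " segment labels, got ",
         length(labels))
  }
  jset$labels <- as.character(labels)
  jset
}

#' Pairwise percent identity matrix of an alignment
#'
#' Identity between two rows is the fraction of columns where both rows
#' carry the same residue, over columns where at least one row is non-gap
#' (a gap against a residue counts as a mismatch; columns gapped in both
#' rows are ignored).
#'
#' @param aln An [msa()] object.
#' @return Symmetric numeric matrix of percent identities (diagonal 100).
#' @export
pairwise_identity <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  m <- do.call(rbind, strsplit(aln$rows, ""))
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(aln$ids, aln$ids))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both_gap <- m[i, ] == "-" & m[j, ] == "-"
      match <- m[i, ] == m[j, ] & m[i, ] != "-"
      pid <- 100 * sum(match) / sum(!both_gap)
      out[i, j] <- out[j, i] <- pid
    }
  }
  out
}
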