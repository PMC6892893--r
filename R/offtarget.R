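#' Generate the mismatch off-target cassette panel for a guide
#'
#' Builds the nine-cassette panel probing guide tolerance to single
#' mismatches: at each of three positions (by default one per PAM-proximal,
#' middle, and PAM-distal third of the spacer) one substitution, one
#' single-base deletion, and one single-base insertion cassette. Every
#' cassette is at edit distance 1 from the guide.
#'
#' Substitution policy `"transversion"` replaces the base by its complement
#' (always a purine-pyrimidine change, the maximal perturbation of
#' pairing); `"transition"` uses A<->G / C<->T. Insertions place the
#' substituted-policy partner of the position's base immediately 5' of it.
#'
#' @param guide Spacer sequence (>= 6 nt).
#' @param positions Three distinct 1-based guide positions; default
#'   `round(L * c(1, 3, 5) / 6)` for guide length `L` (position 1 is
#'   PAM-proximal for a Cas12a spacer).
#' @param substitution_policy `"transversion"` (default) or `"transition"`.
#' @return Tibble: `cassette_id`, `edit_type` (`substitution`, `deletion`,
#'   `insertion`), `position`, `sequence`.
#' @export
generate_cassettes <- function(guide, positions = NULL,
                               substitution_policy = c("transversion",
                                                       "transition")) {
  substitution_policy <- match.arg(substitution_policy)
  guide <- toupper(guide)
  L <- nchar(guide)
  if (L < 6L) stop("guide must be at least 6 nt")
  if (is.null(positions)) positions <- round(L * c(1, 3, 5) / 6)
  positions <- as.integer(positions)
  if (length(positions) != 3L || anyDuplicated(positions)) {
    stop("positions must be three distinct guide positions")
  }
  if (any(positions < 1L | positions > L)) {
    stop("positions out of range [1, ", L, "]")
  }
  partner <- switch(substitution_policy,
    transversion = c(A = "T", C = "G", G = "C", T = "A"),
    transition   = c(A = "G", C = "T", G = "A", T = "C"))
  rows <- list()
  for (p in positions) {
    base <- substr(guide, p, p)
    if (!base %in% names(partner)) stop("non-ACGT base in guide at ", p)
    sub_seq <- paste0(substr(guide, 1L, p - 1L), partner[[base]],
                      substr(guide, p + 1L, L))
    del_seq <- paste0(substr(guide, 1L, p - 1L), substr(guide, p + 1L, L))
    ins_seq <- paste0(substr(guide, 1L, p - 1L), partner[[base]],
                      substr(guide, p, L))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cassette_id = sprintf(c("sub_p%02d", "del_p%02d", "ins_p%02d"), p),
      edit_type = c("substitution", "deletion", "insertion"),
      position = p,
      sequence = c(sub_seq, del_seq, ins_seq))
  }
  out <- dplyr::bind_rows(rows)
  out[order(match(out$edit_type,
                  c("substitution", "deletion", "insertion")),
            out$position), ]
}

#' Global alignment and mismatch annotation of a site against its target
#'
#' Needleman-Wunsch end-to-end alignment (match +1, mismatch -1, gap -2)
#' with a leftmost-gap tie-break, then reads off the positions that differ:
#' substitutions (both aligned, different base), deletions (target base
#' absent from the site), insertions (site base absent from the target).
#' These are the positions a figure would highlight.
#'
#' @param target Reference (on-target) sequence.
#' @param site_sequence Candidate off-target site; length within 2 of the
#'   target.
#' @return List with `aligned_target`, `aligned_site` (gapped strings),
#'   `score`, and `events`: tibble of `type` (`substitution`, `deletion`,
#'   `insertion`), `target_pos` (1-based position on the target; for
#'   insertions, the target position preceding the inserted base, 0 at the
#'   5' end), `site_pos`.
#' @export
annotate_mismatches <- function(target, site_sequence) {
  target <- toupper(target)
  site <- toupper(site_sequence)
  if (abs(nchar(site) - nchar(target)) > 2L) {
    stop("site and target lengths differ by more than 2")
  }
  al <- nw_align(target, site, match = 1, mismatch = -1, gap = -2)
  ta <- strsplit(al$a, "")[[1]]
  sa <- strsplit(al$b, "")[[1]]
  tpos <- cumsum(ta != "-")
  spos <- cumsum(sa != "-")
  ev <- list()
  for (k in seq_along(ta)) {
    if (ta[k] == "-" && sa[k] != "-") {
      ev[[length(ev) + 1L]] <- tibble::tibble(
        type = "insertion", target_pos = tpos[k], site_pos = spos[k])
    } else if (ta[k] != "-" && sa[k] == "-") {
      ev[[length(ev) + 1L]] <- tibble::tibble(
        type = "deletion", target_pos = tpos[k], site_pos = spos[k])
    } else if (ta[k] != sa[k]) {
      ev[[length(ev) + 1L]] <- tibble::tibble(
        type = "substitution", target_pos = tpos[k], site_pos = spos[k])
    }
  }
  events <- if (length(ev) > 0L) dplyr::bind_rows(ev) else {
    tibble::tibble(type = character(), target_pos = integer(),
                   site_pos = integer())
  }
  list(aligned_target = al$a, aligned_site = al$b, score = al$score,
       events = events)
}

# Needleman-Wunsch, linear gap penalty. Tie-break order in traceback:
# diagonal > gap-in-b (deletion) > gap-in-a (insertion), which floats gaps
# to the leftmost equivalent placement.
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  f <- matrix(0, n + 1L, m + 1L)
  f[, 1L] <- gap * (0:n)
  f[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    s <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      f[i + 1L, j + 1L] <- max(f[i, j] + s[j],
                               f[i, j + 1L] + gap,
                               f[i + 1L, j] + gap)
    }
  }
  # traceback
  ra <- character(0)
  rb <- character(0)
  i <- n
  j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        f[i + 1L, j + 1L] ==
          f[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && f[i + 1L, j + 1L] == f[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = f[n + 1L, m + 1L])
}

#' Summarize on/off-target cleavage from a site read-count table
#'
#' Off-target read counts from an in vitro cleavage assay (e.g. CIRCLE-seq
#' site tables) are a measure of cleavage at each site. Sites with reads at
#' or below `min_reads` are dropped (strictly "higher than" the threshold,
#' default 10), then
#' `percent_off_target = 100 * sum(off) / (on + sum(off))`.
#'
#' @param on_target_reads Read count at the on-target site.
#' @param off_sites Tibble/data frame with columns `site` (sequence) and
#'   `reads`, one row per off-target site; may be empty.
#' @param min_reads Strict read-count filter applied to off-target sites
#'   (default 10).
#' @return An `offtarget_summary` list: `percent_off_target`,
#'   `sites_passing_filter` (filtered tibble), `min_reads`,
#'   `on_target_reads`.
#' @export
offtarget_fraction <- function(on_target_reads, off_sites, min_reads = 10L) {
  stopifnot(on_target_reads >= 0)
  off_sites <- tibble::as_tibble(off_sites)
  if (nrow(off_sites) > 0L) {
    stopifnot(all(c("site", "reads") %in% names(off_sites)),
              all(off_sites$reads >= 0))
    off_sites <- off_sites[off_sites$reads > min_reads, , drop = FALSE]
  } else {
    off_sites <- tibble::tibble(site = character(), reads = numeric())
  }
  total <- on_target_reads + sum(off_sites$reads)
  if (total == 0) stop("all counts filtered out: nothing to summarize")
  structure(list(
    percent_off_target = 100 * sum(off_sites$reads) / total,
    sites_passing_filter = off_sites,
    min_reads = min_reads,
    on_target_reads = on_target_reads), class = "offtarget_summary")
}

#' @export
print.offtarget_summary <- function(x, ...) {
  cat(sprintf("Off-target summary: %.2f%% of reads at %d off-target site(s) (reads > %d)\n",
              x$percent_off_target, nrow(x$sites_passing_filter), x$min_reads))
  invisible(x)
}
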