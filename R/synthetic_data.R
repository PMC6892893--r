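#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# standard-code codon list per amino acid (stops excluded)
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA20]
}

#' Simulate a family of orthologous nuclease proteins with conserved blocks
#'
#' Star-topology generator: every parent copies an ancestral residue with a
#' per-parent probability, otherwise draws uniformly from the 20 amino
#' acids; inside the planted conserved blocks all parents are identical to
#' the ancestor. Per-parent copy probabilities are spaced so the *expected*
#' pairwise identity of the most- and least-related pairs spans
#' `identity_band` — emulating a diverged ortholog family whose pairwise
#' identities range over roughly 34-43%, with short highly conserved
#' blocks marking candidate crossover regions. A CDS is back-generated for
#' every protein with uniformly sampled synonymous codons plus a TAA stop.
#'
#' The family is generated already aligned (no indel evolution), so the
#' returned `msa` is gapless.
#'
#' @param n_parents Number of parents (default 9).
#' @param protein_length Residues per protein (default 1300).
#' @param n_conserved_blocks Planted fully conserved blocks (default 6).
#' @param block_length Width of each block in residues (default 15).
#' @param identity_band Target band (min, max) of expected pairwise
#'   identity as fractions (default `c(0.338, 0.4299)`).
#' @param seed Integer seed; same seed, same family.
#' @return List: `parents` (a [parent_set()]), `aln` (gapless [msa()]),
#'   `block_columns` (list of integer column ranges), `block_centers`
#'   (integer vector).
#' @export
simulate_parent_family <- function(n_parents = 9L, protein_length = 1300L,
                                   n_conserved_blocks = 6L, block_length = 15L,
                                   identity_band = c(0.338, 0.4299),
                                   seed = 1L) {
  stopifnot(n_parents >= 2L, protein_length > 0L, block_length > 0L,
            length(identity_band) == 2L, identity_band[1] > 0,
            identity_band[2] < 1, identity_band[1] <= identity_band[2])
  withr::local_seed(seed)
  L <- as.integer(protein_length)
  nb <- as.integer(n_conserved_blocks)
  bl <- as.integer(block_length)
  # blocks centered at L * i / (nb + 1), i = 1..nb
  centers <- integer(0)
  block_cols <- integer(0)
  blocks <- list()
  if (nb > 0L) {
    centers <- round(L * seq_len(nb) / (nb + 1L))
    starts <- centers - (bl - 1L) %/% 2L
    ends <- starts + bl - 1L
    if (starts[1L] < 1L || ends[nb] > L ||
        (nb > 1L && any(starts[-1L] <= ends[-nb]))) {
      stop("infeasible geometry: conserved blocks do not fit")
    }
    blocks <- Map(function(s, e) s:e, starts, ends)
    block_cols <- unlist(blocks)
  }
  # per-parent ancestor-copy probabilities spaced so expected pairwise
  # identity spans the band; background identity = q_i q_j + (1 - q_i q_j)/20
  f <- length(block_cols) / L
  bg <- (identity_band - f) / (1 - f)
  qq <- (bg - 0.05) / 0.95
  if (any(qq <= 0 | qq >= 1)) stop("identity band infeasible for this geometry")
  u <- sqrt(qq[1])
  v <- sqrt(qq[2])
  if (n_parents > 2L) {
    for (it in 1:100) {
      d <- (v - u) / (n_parents - 1L)
      u <- qq[1] / (u + d)
      v <- qq[2] / (v - d)
    }
  }
  q <- seq(u, v, length.out = n_parents)

  ancestor <- sample(AA20, L, replace = TRUE)
  ancestor[1L] <- "M"
  prot <- matrix("", nrow = n_parents, ncol = L)
  for (i in seq_len(n_parents)) {
    copy <- stats::runif(L) < q[i]
    row <- ifelse(copy, ancestor, sample(AA20, L, replace = TRUE))
    row[block_cols] <- ancestor[block_cols]
    row[1L] <- "M"
    prot[i, ] <- row
  }
  ids <- sprintf("P%02d", seq_len(n_parents))
  proteins <- apply(prot, 1L, paste, collapse = "")
  cba <- codons_by_aa()
  cds <- vapply(seq_len(n_parents), function(i) {
    cods <- character(L)
    for (aa in unique(prot[i, ])) {
      idx <- which(prot[i, ] == aa)
      cods[idx] <- sample(cba[[aa]], length(idx), replace = TRUE)
    }
    paste0(paste(cods, collapse = ""), "TAA")
  }, "")
  parents <- parent_set(ids, proteins, cds,
                        organism = sprintf("synthetic ortholog %d",
                                           seq_len(n_parents)))
  aln <- msa(stats::setNames(proteins, ids))
  list(parents = parents, aln = aln, block_columns = blocks,
       block_centers = centers)
}

#' Simulate a paired PAM-depletion screen
#'
#' Draws the non-targeting sample multinomially over the full PAM space
#' (uniform), and the targeting sample with each functional PAM's weight
#' multiplied by `depletion_factor` before renormalization (cells whose
#' reporter carries a functional PAM are cut and drop out). Reads are
#' built as pad + upstream anchor + PAM + downstream anchor + pad with
#' uniform per-base substitution errors.
#'
#' @param n_reads Reads per sample (default 1e5).
#' @param functional_pams Character vector of functional PAMs (default
#'   TTTV: TTTA, TTTC, TTTG).
#' @param depletion_factor Multiplier in (0, 1] applied to functional PAM
#'   weights in the targeting sample (default 0.01).
#' @param upstream_anchor,downstream_anchor Anchor sequences built into
#'   every read.
#' @param error_rate Per-base substitution error probability (default
#'   0.002).
#' @param pad_max Maximum random pad length on each side (default 5).
#' @param pam_len PAM length (default 4).
#' @param seed Integer seed.
#' @return List: `targeting`, `nontargeting` (tibbles with `id`,
#'   `sequence`, `quality`), `spec` (the matching [pam_spec()]), `truth`
#'   (list with `functional_pams`, `depletion_factor`, and the sampled
#'   per-PAM read counts of each sample before errors).
#' @export
simulate_pam_screen <- function(n_reads = 1e5, functional_pams = NULL,
                                depletion_factor = 0.01,
                                upstream_anchor = "TCCACTGAGC",
                                downstream_anchor = "GTTTCAGAGC",
                                error_rate = 0.002, pad_max = 5L,
                                pam_len = 4L, seed = 1L) {
  stopifnot(n_reads > 0, depletion_factor > 0, depletion_factor <= 1)
  withr::local_seed(seed)
  space <- pam_space(pam_len)
  if (is.null(functional_pams)) {
    functional_pams <- paste0(strrep("T", pam_len - 1L), c("A", "C", "G"))
  }
  stopifnot(all(functional_pams %in% space))
  w_nt <- rep(1, length(space))
  w_t <- w_nt
  w_t[space %in% functional_pams] <- depletion_factor
  draw <- function(w) {
    as.integer(stats::rmultinom(1L, n_reads, w / sum(w)))
  }
  cnt_t <- stats::setNames(draw(w_t), space)
  cnt_nt <- stats::setNames(draw(w_nt), space)
  build <- function(counts, prefix) {
    pams <- rep(names(counts), counts)
    pams <- sample(pams)
    n <- length(pams)
    pad_l <- random_pad(n, pad_max)
    pad_r <- random_pad(n, pad_max)
    seqs <- paste0(pad_l, upstream_anchor, pams, downstream_anchor, pad_r)
    seqs <- inject_errors(seqs, error_rate)
    tibble::tibble(id = sprintf("%s_%07d", prefix, seq_len(n)),
                   sequence = seqs, quality = strrep("I", nchar(seqs)))
  }
  list(targeting = build(cnt_t, "T"),
       nontargeting = build(cnt_nt, "N"),
       spec = pam_spec(upstream_anchor, downstream_anchor, pam_len),
       truth = list(functional_pams = functional_pams,
                    depletion_factor = depletion_factor,
                    counts_targeting = cnt_t,
                    counts_nontargeting = cnt_nt))
}

random_pad <- function(n, pad_max) {
  if (pad_max < 1L) return(rep("", n))
  lens <- sample(0:pad_max, n, replace = TRUE)
  full <- do.call(paste0, as.data.frame(
    matrix(sample(c("A", "C", "G", "T"), n * pad_max, replace = TRUE),
           nrow = n), stringsAsFactors = FALSE))
  substr(full, 1L, lens)
}

# uniform substitution errors over the concatenated reads
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  k <- stats::rbinom(1L, total, error_rate)
  if (k == 0L) return(seqs)
  bytes <- charToRaw(paste(seqs, collapse = ""))
  pos <- sample.int(total, k)
  bytes[pos] <- charToRaw(paste(sample(c("A", "C", "G", "T"), k,
                                       replace = TRUE), collapse = ""))
  whole <- rawToChar(bytes)
  ends <- cumsum(lens)
  substring(whole, ends - lens + 1L, ends)
}

#' Simulate colony counts for killing or color screens
#'
#' Binomial draws at a known true efficiency: for the killing assay, the
#' non-targeting plate yields `n_plated` colonies and the targeting plate
#' `Binomial(n_plated, 1 - true_efficiency)` survivors; for the color
#' screen, edited (white) colonies are `Binomial(n_plated,
#' true_efficiency)`.
#'
#' @param true_efficiency True efficiency in `[0, 1]`.
#' @param n_plated Colonies plated / control colony count (default 200).
#' @param type `"killing"` or `"color"`.
#' @param seed Integer seed.
#' @return For `"killing"`: list `a`, `b`, `true_efficiency`. For
#'   `"color"`: list `edited`, `unedited`, `true_efficiency`.
#' @export
simulate_colony_counts <- function(true_efficiency, n_plated = 200L,
                                   type = c("killing", "color"), seed = 1L) {
  stopifnot(true_efficiency >= 0, true_efficiency <= 1, n_plated > 0)
  type <- match.arg(type)
  withr::local_seed(seed)
  if (type == "killing") {
    list(a = stats::rbinom(1L, n_plated, 1 - true_efficiency),
         b = as.integer(n_plated), true_efficiency = true_efficiency)
  } else {
    edited <- stats::rbinom(1L, n_plated, true_efficiency)
    list(edited = edited, unedited = as.integer(n_plated) - edited,
         true_efficiency = true_efficiency)
  }
}

#' Simulate an on/off-target site read-count table
#'
#' Plants decoy off-target sites at 1-4 substitutions from the guide and
#' allocates a fixed read total across the on-target site (weight 1) and
#' decoys (weight = cleavage propensity at their mismatch count,
#' nonincreasing in mismatches).
#'
#' @param guide Target sequence.
#' @param propensity Numeric vector of relative cleavage propensities for
#'   1-4 mismatches (nonincreasing; default `c(0.05, 0.01, 0.002, 0)`).
#' @param n_total_reads Total reads to allocate (default 1e4).
#' @param n_decoy_sites Number of decoy sites (default 9; mismatch counts
#'   cycle 1, 2, 3, 4, 1, ...).
#' @param seed Integer seed.
#' @return List: `on_target_reads`, `off_sites` (tibble `site`, `reads`,
#'   `n_mismatches`), and `truth` (list with the realized
#'   `percent_off_target` at `min_reads = 0`).
#' @export
simulate_offtarget_table <- function(guide,
                                     propensity = c(0.05, 0.01, 0.002, 0),
                                     n_total_reads = 1e4, n_decoy_sites = 9L,
                                     seed = 1L) {
  guide <- toupper(guide)
  stopifnot(nchar(guide) >= 6L, length(propensity) == 4L,
            all(diff(propensity) <= 0), all(propensity >= 0),
            n_total_reads > 0, n_decoy_sites >= 0L)
  withr::local_seed(seed)
  L <- nchar(guide)
  bases <- c("A", "C", "G", "T")
  mm_counts <- if (n_decoy_sites > 0L) {
    rep(1:4, length.out = n_decoy_sites)
  } else integer(0)
  sites <- vapply(mm_counts, function(m) {
    pos <- sample.int(L, m)
    s <- strsplit(guide, "")[[1L]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    paste(s, collapse = "")
  }, "")
  w <- c(1, propensity[mm_counts])
  alloc <- as.integer(stats::rmultinom(1L, n_total_reads, w / sum(w)))
  off <- tibble::tibble(site = sites, reads = alloc[-1L],
                        n_mismatches = mm_counts)
  truth_pct <- 100 * sum(off$reads) / (alloc[1L] + sum(off$reads))
  list(on_target_reads = alloc[1L], off_sites = off,
       truth = list(percent_off_target = truth_pct))
}
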