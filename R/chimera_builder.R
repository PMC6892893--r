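#' Enumerate single-crossover chimera designs
#'
#' One design per (junction `j`, ordered parent pair `(A, B)` with `A != B`):
#' parent `A` contributes everything before junction `j`, parent `B` the
#' junction residue onward. The crossover sits immediately before the
#' junction residue throughout the package. Count: `J * P * (P - 1)`.
#'
#' @param parents A [parent_set()].
#' @param jset A `junction_set` from [select_junctions()].
#' @return Tibble of designs ordered by (junction, A, B) with columns
#'   `design_id`, `scheme`, `n_crossovers`, and list-columns `junctions`
#'   (junction indices at the crossovers) and `donors` (one donor per
#'   segment). Empty with a warning when there are fewer than 2 parents or
#'   no junctions.
#' @export
enumerate_single_crossover <- function(parents, jset) {
  stopifnot(inherits(parents, "parent_set"), inherits(jset, "junction_set"))
  ids <- sort(parents$id)
  nj <- nrow(jset$junctions)
  if (length(ids) < 2L || nj == 0L) {
    warning("need >= 2 parents and >= 1 junction; returning no designs")
    return(empty_designs("sequential"))
  }
  grid <- expand.grid(b = ids, a = ids, j = seq_len(nj),
                      stringsAsFactors = FALSE)[, c("j", "a", "b")]
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  grid <- grid[order(grid$j, grid$a, grid$b), , drop = FALSE]
  tibble::tibble(
    design_id = sprintf("S%d_%s-%s", grid$j, grid$a, grid$b),
    scheme = "sequential",
    n_crossovers = 1L,
    junctions = lapply(grid$j, identity),
    donors = Map(c, grid$a, grid$b, USE.NAMES = FALSE))
}

#' Enumerate two-crossover (backbone-swap) chimera designs
#'
#' One design per junction pair `i < j`, backbone parent, and donor parent
#' distinct from the backbone: the backbone sequence with its `[i, j)`
#' segment replaced by the donor's. Count: `choose(J, 2) * P * (P - 1)`
#' over all backbones, or `choose(J, 2) * (P - 1)` when `backbone` is
#' fixed.
#'
#' @inheritParams enumerate_single_crossover
#' @param backbone Optional parent id; when supplied only designs on that
#'   backbone are enumerated ("fixed-backbone" policy).
#' @return Tibble of designs ordered by (junction pair, backbone, donor);
#'   same columns as [enumerate_single_crossover()]. Empty with a warning
#'   when there are fewer than 2 parents or fewer than 2 junctions.
#' @export
enumerate_two_crossover <- function(parents, jset, backbone = NULL) {
  stopifnot(inherits(parents, "parent_set"), inherits(jset, "junction_set"))
  ids <- sort(parents$id)
  nj <- nrow(jset$junctions)
  if (length(ids) < 2L || nj < 2L) {
    warning("need >= 2 parents and >= 2 junctions; returning no designs")
    return(empty_designs("backbone-swap"))
  }
  backbones <- ids
  if (!is.null(backbone)) {
    if (!backbone %in% ids) stop("unknown backbone id: ", backbone)
    backbones <- backbone
  }
  pairs <- utils::combn(seq_len(nj), 2L)
  rows <- expand.grid(d = ids, bb = backbones, p = seq_len(ncol(pairs)),
                      stringsAsFactors = FALSE)
  rows <- rows[rows$d != rows$bb, , drop = FALSE]
  i <- pairs[1L, rows$p]
  j <- pairs[2L, rows$p]
  ord <- order(i, j, rows$bb, rows$d)
  rows <- rows[ord, , drop = FALSE]
  i <- i[ord]; j <- j[ord]
  tibble::tibble(
    design_id = sprintf("D%d.%d_%s+%s", i, j, rows$bb, rows$d),
    scheme = "backbone-swap",
    n_crossovers = 2L,
    junctions = Map(c, i, j, USE.NAMES = FALSE),
    donors = Map(c, rows$bb, rows$d, rows$bb, USE.NAMES = FALSE))
}

empty_designs <- function(scheme) {
  tibble::tibble(design_id = character(), scheme = character(),
                 n_crossovers = integer(), junctions = list(),
                 donors = list())
}

#' Realize a chimera design as protein and CDS
#'
#' Concatenates donor CDS slices between projected nucleotide junction
#' coordinates (junction residue belongs to the downstream segment) and
#' translates the result. The terminal stop codon, if the last segment's
#' donor retains one, is carried over.
#'
#' @param design One row of an enumeration tibble (or a list with
#'   `design_id`, `junctions`, `donors`).
#' @param parents A [parent_set()].
#' @param jset The `junction_set` used for enumeration.
#' @return List with `design_id`, `protein_seq`, `cds_seq`.
#' @export
build_sequence <- function(design, parents, jset) {
  stopifnot(inherits(parents, "parent_set"), inherits(jset, "junction_set"))
  if (tibble::is_tibble(design)) {
    stopifnot(nrow(design) == 1L)
    design <- as.list(design)
    design$junctions <- design$junctions[[1L]]
    design$donors <- design$donors[[1L]]
  }
  jx <- design$junctions
  donors <- design$donors
  stopifnot(length(donors) == length(jx) + 1L)
  if (!all(donors %in% parents$id)) {
    stop("unresolvable donor id(s): ",
         paste(setdiff(donors, parents$id), collapse = ", "))
  }
  cds_of <- stats::setNames(parents$cds, parents$id)
  prot_of <- stats::setNames(parents$protein, parents$id)
  pieces <- character(length(donors))
  for (s in seq_along(donors)) {
    donor <- donors[s]
    res_here <- jset$residue_pos[, donor]
    if (anyNA(res_here)) stop("junction projects into a gap for donor ", donor)
    # half-open nt interval of segment s on this donor's coding region
    from <- if (s == 1L) 0L else 3L * res_here[jx[s - 1L]]
    to <- if (s == length(donors)) 3L * nchar(prot_of[[donor]])
          else 3L * res_here[jx[s]]
    if (to < from) stop("junctions out of order for donor ", donor)
    pieces[s] <- substr(cds_of[[donor]], from + 1L, to)
  }
  last_donor <- donors[length(donors)]
  tail_stop <- substr(cds_of[[last_donor]], 3L * nchar(prot_of[[last_donor]]) + 1L,
                      nchar(cds_of[[last_donor]]))
  cds <- paste0(paste(pieces, collapse = ""), tail_stop)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  list(design_id = design$design_id, protein_seq = aa, cds_seq = cds)
}

#' Build every design in an enumeration
#'
#' @param designs Enumeration tibble.
#' @inheritParams build_sequence
#' @return Tibble with `design_id`, `protein_seq`, `cds_seq`.
#' @export
build_sequences <- function(designs, parents, jset) {
  rows <- lapply(seq_len(nrow(designs)), function(k) {
    build_sequence(designs[k, ], parents, jset)
  })
  tibble::tibble(design_id = vapply(rows, `[[`, "", "design_id"),
                 protein_seq = vapply(rows, `[[`, "", "protein_seq"),
                 cds_seq = vapply(rows, `[[`, "", "cds_seq"))
}

#' Split a chimera CDS into Gibson-style assembly fragments
#'
#' Cuts the CDS into the fewest pieces that fit `max_fragment_len` after
#' extension, extends each piece so adjacent pieces share exactly
#' `homology_len` nt, and flanks the construct with the vector arms so the
#' terminal fragments carry vector homology (the library used ~40 bp arms
#' into the expression plasmid). Merging the shared overlaps once
#' reconstructs `vector_left + cds + vector_right` exactly.
#'
#' @param cds_seq Chimera coding sequence.
#' @param vector_left,vector_right Vector sequence flanking the insert.
#' @param homology_len Shared-overlap length in nt (default 40, >= 15).
#' @param max_fragment_len Maximum synthesizable fragment length
#'   (default 3000, gBlock scale).
#' @return Tibble of fragments in assembly order: `fragment_id`, `role`
#'   (`"vector-arm"` or `"insert"`), `sequence`, `left_overlap`,
#'   `right_overlap`. A warning lists overlaps that are not unique within
#'   the construct (assembly ambiguity).
#' @export
design_gblocks <- function(cds_seq, vector_left, vector_right,
                           homology_len = 40L, max_fragment_len = 3000L) {
  homology_len <- as.integer(homology_len)
  if (homology_len < 15L) stop("homology_len must be >= 15")
  if (max_fragment_len <= 2L * homology_len) {
    stop("max_fragment_len must exceed 2 * homology_len")
  }
  L <- nchar(cds_seq)
  if (L < homology_len) stop("CDS shorter than the homology length")
  if (nchar(vector_left) < homology_len || nchar(vector_right) < homology_len) {
    stop("vector arms must be at least homology_len long")
  }
  # smallest piece count whose extended fragments all fit
  n <- max(1L, ceiling(L / (max_fragment_len - 2L * homology_len)))
  bounds <- round(seq(0L, L, length.out = n + 1L))
  construct <- paste0(vector_left, cds_seq, vector_right)
  vl <- nchar(vector_left)
  frag_seq <- character(n)
  left_ov <- character(n)
  right_ov <- character(n)
  for (k in seq_len(n)) {
    # each fragment extends homology_len rightward into its neighbor; the
    # first also extends leftward into the vector so both terminal
    # fragments carry vector homology
    from <- if (k == 1L) vl - homology_len + 1L else vl + bounds[k] + 1L
    to <- vl + bounds[k + 1L] + homology_len
    frag_seq[k] <- substr(construct, from, to)
    left_ov[k] <- substr(construct, from, from + homology_len - 1L)
    right_ov[k] <- substr(construct, to - homology_len + 1L, to)
  }
  frags <- tibble::tibble(
    fragment_id = c("vec_left", sprintf("insert_%02d", seq_len(n)), "vec_right"),
    role = c("vector-arm", rep("insert", n), "vector-arm"),
    sequence = c(vector_left, frag_seq, vector_right),
    left_overlap = c("", left_ov,
                     substr(vector_right, 1L, homology_len)),
    right_overlap = c(substr(vector_left, vl - homology_len + 1L, vl),
                      right_ov, ""))
  overlaps <- frags$right_overlap[-nrow(frags)]
  n_occ <- vapply(overlaps, function(o) {
    length(gregexpr(o, construct, fixed = TRUE)[[1L]])
  }, integer(1L))
  if (any(n_occ > 1L)) {
    warning("non-unique assembly overlap(s) within the construct: ",
            paste(names(n_occ)[n_occ > 1L], collapse = ", "))
  }
  frags
}

#' Collapse designs with identical protein products
#'
#' Distinct segment assignments can realize the same protein when parents
#' agree locally around a junction. Keeps the first design (enumeration
#' order) per distinct protein sequence.
#'
#' @param designs Enumeration tibble.
#' @param sequences Output of [build_sequences()] for the same designs.
#' @return The deduplicated designs tibble, with attribute
#'   `collision_groups`: a list of design-id vectors that shared a protein.
#' @export
deduplicate <- function(designs, sequences) {
  stopifnot(nrow(designs) == nrow(sequences),
            all(designs$design_id == sequences$design_id))
  if (nrow(designs) == 0L) {
    attr(designs, "collision_groups") <- list()
    return(designs)
  }
  keep <- !duplicated(sequences$protein_seq)
  groups <- split(designs$design_id, sequences$protein_seq)
  groups <- unname(groups[vapply(groups, length, 1L) > 1L])
  out <- designs[keep, , drop = FALSE]
  attr(out, "collision_groups") <- groups
  out
}
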