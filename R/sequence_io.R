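#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' conventions the rest of the pipeline relies on: records are returned in
#' file order, sequences are uppercased, and duplicate identifiers are an
#' error (parent ids key every downstream table).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA: first line is not a '>' header in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("empty sequence for id(s): ",
         paste(ids[Biostrings::width(set) == 0L], collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a tibble
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return Tibble with columns `id`, `sequence`, `quality`, one row per read,
#'   in file order. Errors on truncated records or sequence/quality length
#'   mismatches.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(tibble::tibble(id = character(), sequence = character(),
                          quality = character()))
  }
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ record in ", path)
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (!all(startsWith(ids, "@"))) stop("malformed FASTQ header in ", path)
  plus <- lines[seq(3L, length(lines), by = 4L)]
  if (!all(startsWith(plus, "+"))) stop("malformed FASTQ separator in ", path)
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop("sequence/quality length mismatch for read(s): ",
         paste(utils::head(sub("^@", "", ids[bad]), 5L), collapse = ", "))
  }
  tibble::tibble(id = sub("^@", "", sub("\\s.*$", "", ids)),
                 sequence = seqs, quality = quals)
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  out <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Validate a coding sequence against its protein
#'
#' Translates `cds_seq` with the standard genetic code, trims a terminal stop
#' codon if present, and compares against `protein_seq`. The three failure
#' modes the assembly pipeline cares about are reported distinctly: a length
#' that is not a multiple of three, an internal stop codon, and residue-level
#' translation mismatches.
#'
#' @param protein_seq Amino-acid string, no gaps.
#' @param cds_seq Nucleotide string (A/C/G/T).
#' @return List with elements `ok` (logical), `errors` (character vector of
#'   error categories: `"length"`, `"internal_stop"`, `"mismatch"`),
#'   `messages` (human-readable details), and `mismatch_positions`
#'   (1-based residue indices where translation disagrees).
#' @export
validate_cds <- function(protein_seq, cds_seq) {
  stopifnot(nzchar(protein_seq), nzchar(cds_seq))
  errors <- character()
  messages <- character()
  mismatch_positions <- integer()
  if (nchar(cds_seq) %% 3L != 0L) {
    errors <- c(errors, "length")
    messages <- c(messages, sprintf(
      "CDS length %d is not a multiple of 3", nchar(cds_seq)))
  } else {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_seq), no.init.codon = TRUE))
    # tolerate and trim a single terminal stop
    if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
    stops <- which(strsplit(aa, "")[[1]] == "*")
    if (length(stops) > 0L) {
      errors <- c(errors, "internal_stop")
      messages <- c(messages, sprintf(
        "internal stop codon at residue position(s) %s",
        paste(stops, collapse = ", ")))
    } else if (nchar(aa) != nchar(protein_seq)) {
      errors <- c(errors, "mismatch")
      messages <- c(messages, sprintf(
        "translated length %d != protein length %d",
        nchar(aa), nchar(protein_seq)))
    } else {
      pv <- strsplit(protein_seq, "")[[1]]
      av <- strsplit(aa, "")[[1]]
      mismatch_positions <- which(pv != av)
      if (length(mismatch_positions) > 0L) {
        errors <- c(errors, "mismatch")
        messages <- c(messages, sprintf(
          "translation differs at residue(s) %s",
          paste(utils::head(mismatch_positions, 10L), collapse = ", ")))
      }
    }
  }
  list(ok = length(errors) == 0L, errors = errors, messages = messages,
       mismatch_positions = mismatch_positions)
}

#' Construct a set of parental nuclease records
#'
#' Bundles the orthologous parents (protein plus codon-level CDS) that seed a
#' chimera library. Every CDS is validated against its protein on
#' construction.
#'
#' @param id Character vector of short unique labels.
#' @param protein Amino-acid sequences, same length as `id`.
#' @param cds Coding sequences; a retained terminal stop codon is allowed.
#' @param organism Optional free-text organism names.
#' @return A `parent_set` tibble with columns `id`, `organism`, `protein`,
#'   `cds`.
#' @export
parent_set <- function(id, protein, cds, organism = NA_character_) {
  stopifnot(length(id) == length(protein), length(id) == length(cds))
  if (anyDuplicated(id)) stop("duplicate parent ids")
  for (i in seq_along(id)) {
    v <- validate_cds(protein[[i]], cds[[i]])
    if (!v$ok) {
      stop("parent '", id[[i]], "' failed CDS validation: ",
           paste(v$messages, collapse = "; "))
    }
  }
  out <- tibble::tibble(id = as.character(id),
                        organism = rep_len(as.character(organism), length(id)),
                        protein = toupper(as.character(protein)),
                        cds = toupper(as.character(cds)))
  class(out) <- c("parent_set", class(out))
  out
}

#' Construct a protein multiple sequence alignment object
#'
#' The alignment is consumed, not computed: rows come from any standard
#' aligner. Gap characters `-` and `.` are both accepted and normalized
#' to `-`.
#'
#' @param rows Named character vector of gapped amino-acid strings; names are
#'   parent ids.
#' @return An `msa` object: list with `ids`, `rows` (named, gap-normalized),
#'   and `n_columns`.
#' @export
msa <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (anyDuplicated(names(rows))) stop("duplicate row ids in alignment")
  rows <- chartr(".", "-", toupper(rows))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(widths), collapse = ", "))
  }
  structure(list(ids = names(rows), rows = rows,
                 n_columns = unname(widths[1L])),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Protein MSA: %d rows x %d columns\n",
              length(x$ids), x$n_columns))
  cat("rows:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Check that an alignment matches a parent set
#'
#' Every alignment row id must name exactly one parent, and removing gaps
#' from a row must reproduce that parent's protein sequence.
#'
#' @param aln An [msa()] object.
#' @param parents A [parent_set()].
#' @return `TRUE` invisibly, or an error describing the inconsistency.
#' @export
validate_msa <- function(aln, parents) {
  stopifnot(inherits(aln, "msa"), inherits(parents, "parent_set"))
  missing <- setdiff(aln$ids, parents$id)
  if (length(missing) > 0L) {
    stop("alignment rows with no matching parent: ",
         paste(missing, collapse = ", "))
  }
  for (id in aln$ids) {
    degapped <- gsub("-", "", aln$rows[[id]], fixed = TRUE)
    if (degapped != parents$protein[parents$id == id]) {
      stop("degapped alignment row '", id,
           "' does not reproduce the parent protein")
    }
  }
  invisible(TRUE)
}

#' Map an alignment column to an ungapped residue index
#'
#' Alignment columns are 1-based (how alignment viewers number them);
#' residue indices are 0-based, so that the nucleotide projection is simply
#' `3 * residue_index`.
#'
#' @param aln An [msa()] object.
#' @param row_id Alignment row id.
#' @param column Alignment column(s), 1-based.
#' @return Integer vector of 0-based residue indices; `NA` where the row has
#'   a gap at that column.
#' @export
aln_to_seq <- function(aln, row_id, column) {
  stopifnot(inherits(aln, "msa"))
  if (!row_id %in% aln$ids) stop("unknown alignment row id: ", row_id)
  if (any(column < 1L | column > aln$n_columns)) {
    stop("alignment column out of range [1, ", aln$n_columns, "]")
  }
  chars <- strsplit(aln$rows[[row_id]], "")[[1]]
  notgap <- chars != "-"
  # residue index of column c = number of non-gap characters strictly before c
  idx <- cumsum(notgap) - 1L
  out <- ifelse(notgap[column], idx[column], NA_integer_)
  as.integer(out)
}

#' Map an ungapped residue index to its alignment column
#'
#' Inverse of [aln_to_seq()] on non-gap columns.
#'
#' @inheritParams aln_to_seq
#' @param residue_index 0-based residue index (vectorized).
#' @return Integer vector of 1-based alignment columns.
#' @export
seq_to_aln <- function(aln, row_id, residue_index) {
  stopifnot(inherits(aln, "msa"))
  if (!row_id %in% aln$ids) stop("unknown alignment row id: ", row_id)
  chars <- strsplit(aln$rows[[row_id]], "")[[1]]
  cols <- which(chars != "-")
  if (any(residue_index < 0L | residue_index >= length(cols))) {
    stop("residue index out of range [0, ", length(cols) - 1L, "]")
  }
  as.integer(cols[residue_index + 1L])
}

#' Nucleotide interval of a residue on its CDS
#'
#' Residue `i` (0-based) occupies the half-open codon interval
#' `[3 i, 3 i + 3)` on the coding sequence.
#'
#' @param residue_index 0-based residue index (vectorized).
#' @return Tibble with columns `start` and `end` (half-open, 0-based).
#' @export
residue_to_nt <- function(residue_index) {
  stopifnot(all(residue_index >= 0L))
  i <- as.integer(residue_index)
  tibble::tibble(start = 3L * i, end = 3L * i + 3L)
}
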