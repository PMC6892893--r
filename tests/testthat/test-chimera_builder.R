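test_that("enumeration counts follow the combinatorial formulas exhaustively", {
  fam <- simulate_parent_family(n_parents = 9, protein_length = 120,
                                n_conserved_blocks = 0, block_length = 1,
                                seed = 13)
  cols <- round(seq(10, 110, length.out = 6))
  for (P in 2:9) {
    sub <- fam$parents[seq_len(P), ]
    class(sub) <- class(fam$parents)
    sub_aln <- msa(fam$aln$rows[seq_len(P)])
    for (J in 1:6) {
      jset <- junctions_at(sub_aln, cols[seq_len(J)])
      expect_identical(nrow(enumerate_single_crossover(sub, jset)),
                       as.integer(J * P * (P - 1)))
      if (J >= 2) {
        expect_identical(nrow(enumerate_two_crossover(sub, jset)),
                         as.integer(choose(J, 2) * P * (P - 1)))
        expect_identical(
          nrow(enumerate_two_crossover(sub, jset, backbone = sub$id[1])),
          as.integer(choose(J, 2) * (P - 1)))
      }
    }
  }
})

test_that("degenerate enumerations are empty with warnings", {
  fam <- toy_family(c("MKVLWMKVLW", "MKPLWMKVLW"))
  jset <- junctions_at(fam$aln, 5L)
  one <- fam$parents[1, ]
  class(one) <- class(fam$parents)
  expect_warning(d <- enumerate_single_crossover(one, jset), "parents")
  expect_identical(nrow(d), 0L)
  expect_warning(d2 <- enumerate_two_crossover(fam$parents, jset), "junction")
  expect_identical(nrow(d2), 0L)
  expect_error(enumerate_two_crossover(fam$parents,
                                       junctions_at(fam$aln, c(3L, 7L)),
                                       backbone = "nope"), "unknown backbone")
})

test_that("design ids are deterministic and sortable", {
  fam <- toy_family(c("MKVLWMKVLW", "MKPLWMKVLW", "MKQLWMKVLW"))
  jset <- junctions_at(fam$aln, c(3L, 7L))
  d1 <- enumerate_single_crossover(fam$parents, jset)
  expect_identical(d1$design_id[1:2], c("S1_T01-T02", "S1_T01-T03"))
  expect_false(anyDuplicated(d1$design_id) > 0)
  d2 <- enumerate_two_crossover(fam$parents, jset)
  expect_identical(d2$design_id[1], "D1.2_T01+T02")
})

test_that("built chimeras splice donor sequences at projected junctions", {
  fam <- toy_family(c(A = "MAAAW", B = "MCCCW"), ids = c("A", "B"))
  jset <- junctions_at(fam$aln, 3L)  # junction residue index 2
  d <- tibble::tibble(design_id = "S1_A-B", scheme = "sequential",
                      n_crossovers = 1L, junctions = list(1L),
                      donors = list(c("A", "B")))
  built <- build_sequence(d, fam$parents, jset)
  expect_identical(built$protein_seq, "MACCW")
  expect_true(validate_cds(built$protein_seq, built$cds_seq)$ok)
  # identity chimera: all segments from the same donor reproduce the parent
  ident <- tibble::tibble(design_id = "ident", scheme = "sequential",
                          n_crossovers = 1L, junctions = list(1L),
                          donors = list(c("A", "A")))
  built_a <- build_sequence(ident, fam$parents, jset)
  expect_identical(built_a$protein_seq, fam$parents$protein[1])
  expect_identical(built_a$cds_seq, fam$parents$cds[1])
})

test_that("every enumerated design translates cleanly with verbatim segments", {
  fam <- simulate_parent_family(n_parents = 3, protein_length = 90,
                                n_conserved_blocks = 2, block_length = 7,
                                seed = 21)
  prof <- conservation_profile(fam$aln, 5L)
  jset <- select_junctions(prof, fam$aln, min_segment_nt = 60L,
                           max_junctions = 2L)
  expect_identical(nrow(jset$junctions), 2L)
  designs <- dplyr::bind_rows(enumerate_single_crossover(fam$parents, jset),
                              enumerate_two_crossover(fam$parents, jset))
  seqs <- build_sequences(designs, fam$parents, jset)
  prot_of <- stats::setNames(fam$parents$protein, fam$parents$id)
  for (k in seq_len(nrow(designs))) {
    expect_true(validate_cds(seqs$protein_seq[k], seqs$cds_seq[k])$ok)
    # segment fidelity at the protein level
    jx <- designs$junctions[[k]]
    donors <- designs$donors[[k]]
    for (s in seq_along(donors)) {
      donor <- donors[s]
      from <- if (s == 1L) 0L else jset$residue_pos[jx[s - 1L], donor]
      to <- if (s == length(donors)) nchar(prot_of[[donor]])
            else jset$residue_pos[jx[s], donor]
      expect_identical(substr(seqs$protein_seq[k], from + 1L, to),
                       substr(prot_of[[donor]], from + 1L, to))
    }
  }
})

test_that("gblock fragments overlap exactly and reassemble the construct", {
  set.seed(8)
  vl <- random_dna(300)
  vr <- random_dna(300)
  for (L in c(100L, 2950L, 5000L, 9000L)) {
    cds <- random_dna(L)
    frags <- design_gblocks(cds, vl, vr, homology_len = 40L,
                            max_fragment_len = 3000L)
    expect_true(all(nchar(frags$sequence[frags$role == "insert"]) <= 3000L))
    merged <- frags$sequence[1]
    for (k in 2:nrow(frags)) {
      ov <- frags$left_overlap[k]
      expect_identical(nchar(ov), 40L)
      expect_identical(ov, frags$right_overlap[k - 1])
      expect_true(startsWith(frags$sequence[k], ov))
      expect_true(endsWith(frags$sequence[k - 1], ov))
      merged <- paste0(merged, substr(frags$sequence[k], 41L,
                                      nchar(frags$sequence[k])))
    }
    expect_identical(merged, paste0(vl, cds, vr))
  }
})

test_that("gblock preconditions and ambiguity warnings fire", {
  vl <- random_dna(100)
  vr <- random_dna(100)
  expect_error(design_gblocks("ACGTACGT", vl, vr, homology_len = 40L),
               "shorter than")
  expect_error(design_gblocks(random_dna(100), vl, vr, homology_len = 10L),
               ">= 15")
  expect_error(design_gblocks(random_dna(100), vl, vr, homology_len = 40L,
                              max_fragment_len = 60L), "exceed")
  # a repetitive construct makes the junction overlap non-unique
  expect_warning(
    design_gblocks(strrep("ACGT", 2000), strrep("ACGT", 25),
                   strrep("ACGT", 25), 40L, 3000L),
    "non-unique")
})

test_that("deduplicate collapses designs with identical proteins", {
  # B and C agree over the tail segment, so swapping either tail onto A
  # realizes the same protein
  fam <- toy_family(c(A = "MAAAAVVVVW", B = "MCCCCLLLLW", C = "MGGGGLLLLW"),
                    ids = c("A", "B", "C"))
  jset <- junctions_at(fam$aln, 6L)
  designs <- enumerate_single_crossover(fam$parents, jset)
  seqs <- build_sequences(designs, fam$parents, jset)
  dedup <- deduplicate(designs, seqs)
  expect_identical(nrow(dedup), nrow(designs) - 1L)
  groups <- attr(dedup, "collision_groups")
  expect_identical(length(groups), 1L)
  expect_setequal(groups[[1]], c("S1_A-B", "S1_A-C"))
  expect_true("S1_A-B" %in% dedup$design_id)
  expect_false("S1_A-C" %in% dedup$design_id)
  # all-distinct parents: nothing collapses
  fam2 <- toy_family(c(A = "MAAAAAAAAW", B = "MCCCCCCCCW"), ids = c("A", "B"))
  jset2 <- junctions_at(fam2$aln, 6L)
  d2 <- enumerate_single_crossover(fam2$parents, jset2)
  s2 <- build_sequences(d2, fam2$parents, jset2)
  dd2 <- deduplicate(d2, s2)
  expect_identical(nrow(dd2), nrow(d2))
  expect_identical(length(attr(dd2, "collision_groups")), 0L)
  # empty input
  empty <- deduplicate(d2[0, ], s2[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("chimera construction is deterministic", {
  fam <- simulate_parent_family(n_parents = 3, protein_length = 90,
                                n_conserved_blocks = 2, block_length = 7,
                                seed = 21)
  prof <- conservation_profile(fam$aln, 5L)
  jset <- select_junctions(prof, fam$aln, min_segment_nt = 60L,
                           max_junctions = 2L)
  d1 <- enumerate_single_crossover(fam$parents, jset)
  d2 <- enumerate_single_crossover(fam$parents, jset)
  expect_identical(d1, d2)
  expect_identical(build_sequences(d1, fam$parents, jset),
                   build_sequences(d2, fam$parents, jset))
})
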