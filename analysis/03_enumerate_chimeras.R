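#!/usr/bin/env Rscript

# Step 3: enumerate the chimera library over the nine parents and six
# junctions: every single-crossover design (sequential scheme) plus every
# two-crossover design on a fixed backbone (backbone-swap scheme), realize
# a sample as CDS, and emit Gibson-style gBlock fragments with 40-bp
# homology arms for one design.

suppressMessages(library(chimeracas))

fam <- simulate_parent_family(n_parents = 9, protein_length = 1300,
                              n_conserved_blocks = 6, block_length = 15,
                              seed = 1)
prof <- conservation_profile(fam$aln, window = 11L)
jset <- select_junctions(prof, fam$aln, min_segment_nt = 500L,
                         max_junctions = 6L)

d1 <- enumerate_single_crossover(fam$parents, jset)
d2 <- enumerate_two_crossover(fam$parents, jset,
                              backbone = fam$parents$id[1])
designs <- rbind(d1, d2)
cat(sprintf("library: %d single-crossover + %d backbone-swap = %d designs\n",
            nrow(d1), nrow(d2), nrow(designs)))

flat <- designs
flat$junctions <- vapply(designs$junctions, paste, "", collapse = ",")
flat$donors <- vapply(designs$donors, paste, "", collapse = ",")
utils::write.table(flat, "results/designs.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

# realize the single-crossover arm and deduplicate identical proteins
seqs <- build_sequences(d1, fam$parents, jset)
dedup <- deduplicate(d1, seqs)
cat(sprintf("built %d single-crossover chimeras; %d distinct proteins (%d collision group(s))\n",
            nrow(seqs), nrow(dedup),
            length(attr(dedup, "collision_groups"))))
keep <- seqs[seqs$design_id %in% dedup$design_id, ]
write_fasta(setNames(keep$protein_seq, keep$design_id),
            "results/chimeras_protein.fasta")
write_fasta(setNames(keep$cds_seq, keep$design_id),
            "results/chimeras_cds.fasta")

# gBlocks for the first design, flanked by mock vector arms
set.seed(1)
vec_l <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
vec_r <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
frags <- design_gblocks(seqs$cds_seq[1], vec_l, vec_r,
                        homology_len = 40L, max_fragment_len = 3000L)
write_fasta(setNames(frags$sequence, frags$fragment_id),
            "results/gblocks_example.fasta")
cat(sprintf("example %s: %d insert fragment(s), 40-nt overlaps\n",
            seqs$design_id[1], sum(frags$role == "insert")))
cat("wrote results/designs.tsv, chimeras_{protein,cds}.fasta, gblocks_example.fasta\n")
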