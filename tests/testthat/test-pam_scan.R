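spec0 <- pam_spec("ACGTACGTAC", "GGAAGGAAGG", pam_len = 4L,
                  max_anchor_mismatches = 0L)

test_that("anchored extraction finds the PAM and categorizes rejections", {
  read <- paste0("TT", "ACGTACGTAC", "TTTC", "GGAAGGAAGG", "AA")
  res <- extract_pam(read, spec0)
  expect_identical(res$pam, "TTTC")
  expect_identical(res$status, "ok")
  # no anchors anywhere
  res2 <- extract_pam(strrep("C", 40), spec0)
  expect_identical(res2$status, "anchor-not-found")
  expect_true(is.na(res2$pam))
  # N inside the PAM
  resn <- extract_pam(paste0("ACGTACGTAC", "TTNC", "GGAAGGAAGG"), spec0)
  expect_identical(resn$status, "ambiguous-base")
  # too short to hold anchors + PAM
  expect_identical(extract_pam("ACGT", spec0)$status, "too-short")
  # one mismatch in an anchor tolerated when allowed
  spec1 <- pam_spec("ACGTACGTAC", "GGAAGGAAGG", max_anchor_mismatches = 1L)
  readmm <- paste0("TCGTACGTAC", "TTTC", "GGAAGGAAGG")
  expect_identical(extract_pam(readmm, spec0)$status, "anchor-not-found")
  expect_identical(extract_pam(readmm, spec1)$pam, "TTTC")
})

test_that("multiple valid placements are rejected as ambiguous", {
  spec_rep <- pam_spec("AAAA", "CCCC", pam_len = 2L,
                       max_anchor_mismatches = 0L)
  # AAAA at offsets 1 and 2 both followed by a 2-mer and CCCC
  read <- paste0("AAAAA", "G", "CCCCC")
  expect_identical(extract_pam(read, spec_rep)$status, "ambiguous-placement")
})

test_that("count tables cover the full PAM space and conserve reads", {
  reads <- c(paste0("ACGTACGTAC", "TTTC", "GGAAGGAAGG"),
             paste0("ACGTACGTAC", "TTTC", "GGAAGGAAGG"),
             paste0("ACGTACGTAC", "AAAA", "GGAAGGAAGG"),
             strrep("G", 30))
  tab <- count_pams(reads, spec0)
  expect_identical(length(tab$counts), 256L)
  expect_identical(unname(tab$counts[["TTTC"]]), 2L)
  expect_identical(unname(tab$counts[["AAAA"]]), 1L)
  expect_identical(tab$total_kept, 3L)
  expect_identical(tab$total_rejected, 1L)
  expect_identical(sum(tab$counts), tab$total_kept)
  # empty input -> all-zero table
  tab0 <- count_pams(character(0), spec0)
  expect_identical(sum(tab0$counts), 0L)
  expect_identical(length(tab0$counts), 256L)
})

test_that("simulated screens extract cleanly without sequencing error", {
  sim <- simulate_pam_screen(n_reads = 2000, error_rate = 0, seed = 5)
  tab <- count_pams(sim$targeting, sim$spec)
  expect_identical(tab$total_rejected, 0L)
  expect_identical(tab$total_kept, 2000L)
  # generator bookkeeping matches the pipeline count exactly
  expect_identical(tab$counts, sim$truth$counts_targeting)
})

test_that("frequencies are pseudocounted and sum to one", {
  sim <- simulate_pam_screen(n_reads = 1000, error_rate = 0, seed = 6)
  tab <- count_pams(sim$targeting, sim$spec)
  fr <- to_frequencies(tab, pseudocount = 1, role = "X")
  expect_equal(sum(fr$freqs), 1)
  expect_true(all(fr$freqs > 0))
  expect_equal(unname(fr$freqs[["AAAA"]]),
               (tab$counts[["AAAA"]] + 1) / (1000 + 256))
  # uniform counts, no pseudocount -> all 1/256
  tabu <- tab
  tabu$counts[] <- 5L
  fru <- to_frequencies(tabu, pseudocount = 0)
  expect_true(all(abs(fru$freqs - 1 / 256) < 1e-12))
})

test_that("enrichment modes implement both score conventions", {
  sim <- simulate_pam_screen(n_reads = 500, error_rate = 0, seed = 7)
  tab <- count_pams(sim$targeting, sim$spec)
  f <- to_frequencies(tab, role = "X")
  same <- enrichment(f, f, mode = "log2_ratio")
  expect_true(all(abs(same$score) < 1e-12))
  same2 <- enrichment(f, f, mode = "ratio_of_logs")
  expect_true(all(abs(same2$score - 1) < 1e-12))
  # hand case: Y = 1/256, X = 1/1024
  mk <- function(p_special, role) {
    tab2 <- tab
    tab2$counts[] <- 1L
    fr <- to_frequencies(tab2, pseudocount = 0, role = role)
    fr$freqs[] <- (1 - p_special) / 255
    fr$freqs[["TTTC"]] <- p_special
    fr
  }
  X <- mk(1 / 1024, "X")
  Y <- mk(1 / 256, "Y")
  e_ratio <- enrichment(X, Y, mode = "log2_ratio")
  expect_equal(e_ratio$score[e_ratio$pam == "TTTC"], 2)
  e_logs <- enrichment(X, Y, mode = "ratio_of_logs")
  expect_equal(e_logs$score[e_logs$pam == "TTTC"], (-8) / (-10))
  expect_identical(e_ratio$rank[e_ratio$pam == "TTTC"], 1L)
})

test_that("log2_ratio scores are antitone in X and negate under swap", {
  sim <- simulate_pam_screen(n_reads = 5000, seed = 8)
  X <- to_frequencies(count_pams(sim$targeting, sim$spec), role = "X")
  Y <- to_frequencies(count_pams(sim$nontargeting, sim$spec), role = "Y")
  e_xy <- enrichment(X, Y)
  e_yx <- enrichment(Y, X)
  expect_equal(e_xy$score, -e_yx$score)
  # strictly decreasing in X_i for fixed Y_i
  x <- seq(0.001, 0.9, length.out = 20)
  s <- log2(0.5 / x)
  expect_true(all(diff(s) < 0))
})

test_that("planted functional PAMs dominate the enrichment ranking", {
  sim <- simulate_pam_screen(n_reads = 5e4, depletion_factor = 0.01,
                             seed = 9)
  X <- to_frequencies(count_pams(sim$targeting, sim$spec), role = "X")
  Y <- to_frequencies(count_pams(sim$nontargeting, sim$spec), role = "Y")
  e <- enrichment(X, Y)
  top <- e$pam[e$rank <= 3]
  expect_setequal(top, sim$truth$functional_pams)
})

test_that("null screens shrink enrichment toward zero with depth", {
  mean_abs <- function(n_reads) {
    sim <- simulate_pam_screen(n_reads = n_reads, depletion_factor = 1,
                               error_rate = 0, seed = 10)
    X <- to_frequencies(count_pams(sim$targeting, sim$spec), role = "X")
    Y <- to_frequencies(count_pams(sim$nontargeting, sim$spec), role = "Y")
    mean(abs(enrichment(X, Y)$score))
  }
  expect_lt(mean_abs(1e5), mean_abs(1e3))
})

test_that("logo matrix weights positions by positive scores", {
  sim <- simulate_pam_screen(n_reads = 2e4, depletion_factor = 0.01, seed = 11)
  X <- to_frequencies(count_pams(sim$targeting, sim$spec), role = "X")
  Y <- to_frequencies(count_pams(sim$nontargeting, sim$spec), role = "Y")
  e <- enrichment(X, Y)
  lm1 <- logo_matrix(e, top_k = 1)
  winner <- e$pam[e$rank == 1]
  for (p in 1:4) {
    expect_equal(unname(lm1[p, substr(winner, p, p)]), 1)
  }
  expect_true(all(abs(rowSums(logo_matrix(e, 8)) - 1) < 1e-12))
  # equal-scoring PAMs split positions by weight
  e2 <- e[e$pam %in% c("TTTA", "TTTG"), ]
  e2$score <- c(2, 2)
  e2$rank <- c(1L, 2L)
  attr(e2, "mode") <- "log2_ratio"
  class(e2) <- c("enrichment_table", class(e2))
  lm2 <- logo_matrix(e2, 2)
  expect_equal(unname(lm2[4, c("A", "G")]), c(0.5, 0.5))
  # nothing positive to display
  e3 <- e
  e3$score <- -abs(e3$score)
  expect_error(logo_matrix(e3, 5), "nothing to display")
})

test_that("optional mean-Phred filter rejects low-quality reads", {
  spec_q <- pam_spec("ACGTACGTAC", "GGAAGGAAGG", max_anchor_mismatches = 0L,
                     min_mean_phred = 20)
  reads <- tibble::tibble(
    id = c("hi", "lo"),
    sequence = rep(paste0("ACGTACGTAC", "TTTC", "GGAAGGAAGG"), 2),
    quality = c(strrep("I", 24), strrep("#", 24)))  # Q40 vs Q2
  res <- extract_pam(reads, spec_q)
  expect_identical(res$status, c("ok", "low-quality"))
  # qualities ignored when no threshold is set
  res2 <- extract_pam(reads, pam_spec("ACGTACGTAC", "GGAAGGAAGG",
                                      max_anchor_mismatches = 0L))
  expect_identical(res2$status, c("ok", "ok"))
})
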