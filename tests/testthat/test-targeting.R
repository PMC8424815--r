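rc <- function(s) ceRNAnet:::reverse_complement(s)

test_that("a perfect duplex scores zero with an all-match pairing", {
  mir <- "TGAAGCTGCCAGCATGATCTA"  # 21 nt
  out <- score_duplex(mir, rc(mir))
  expect_equal(out$penalty, 0)
  expect_equal(out$pairing, strrep("|", 21))
})

test_that("single defects score by position and pair class", {
  mir <- "TGAAGCTGCCAGCATGATCTA"
  win <- rc(mir)
  # mismatch at miRNA position 1 (outside the 2-13 seed): penalty 1
  w1 <- win
  substr(w1, 21, 21) <- "C"  # pairs miRNA position 1
  out1 <- score_duplex(mir, w1)
  expect_equal(out1$penalty, 1.0)
  expect_equal(substr(out1$pairing, 1, 1), "x")
  # G:U wobble at miRNA position 5 (inside seed): 0.5 * 2 = 1
  expect_equal(substr(mir, 5, 5), "G")
  w2 <- win
  substr(w2, 17, 17) <- "T"  # target base facing miRNA position 5: G:T wobble
  out2 <- score_duplex(mir, w2)
  expect_equal(out2$penalty, 1.0)
  expect_equal(substr(out2$pairing, 5, 5), "o")
  expect_error(score_duplex(mir, "ACGT"), "lengths differ")
})

test_that("score_duplex agrees with the per-position oracle on random windows", {
  set.seed(21)
  for (i in 1:40) {
    mir <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    win <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    expect_equal(score_duplex(mir, win)$penalty,
                 oracle_duplex_penalty(mir, win), info = paste(mir, win))
  }
})

test_that("scoring is invariant under T/U representation", {
  mir <- "UGAAGCUGCCAGCAUGAUCUA"
  mir_t <- chartr("U", "T", mir)
  win <- rc(mir_t)
  win_u <- chartr("T", "U", win)
  expect_equal(score_duplex(mir, win_u)$penalty,
               score_duplex(mir_t, win)$penalty)
})

test_that("an exact complementary target yields one zero-penalty site", {
  mir <- "TGAAGCTGCCAGCATGATCTA"
  sites <- find_mre_sites(mir, rc(mir))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$target_start, 1)
  expect_equal(sites$penalty, 0)
})

test_that("a random target without complementarity has no sites", {
  set.seed(22)
  mir <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
  target <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  expect_identical(oracle_find_sites(mir, target), integer(0))
  expect_equal(nrow(find_mre_sites(mir, target)), 0)
})

test_that("planted sites are recovered at their positions, matching the oracle", {
  set.seed(23)
  mir <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
  target <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  planted <- c(20L, 150L, 300L)
  for (s in planted) substr(target, s, s + 20L) <- rc(mir)
  sites <- find_mre_sites(mir, target)
  expect_true(all(planted %in% sites$target_start))
  expect_equal(sites$target_start, oracle_find_sites(mir, target))
})

test_that("scan equals the exhaustive oracle on degenerate near-site targets", {
  # overlapping candidates: two perfect sites 10 nt apart force the greedy
  # overlap resolution; compare against the step-by-step oracle
  set.seed(24)
  for (i in 1:10) {
    mir <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    target <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    substr(target, 30, 50) <- rc(mir)
    substr(target, 40, 60) <- rc(mir)  # overwrites part of the first
    params <- duplex_params(max_penalty = 8)
    sites <- find_mre_sites(mir, target, params)
    expect_equal(sites$target_start, oracle_find_sites(mir, target, params))
    expect_true(all(sites$penalty <= params$max_penalty))
    if (nrow(sites) > 1)
      expect_true(all(diff(sites$target_start) >= 21))
  }
})

test_that("scanning is strand-explicit", {
  mir <- "TGAAGCTGCCAGCATGATCTA"
  target <- paste0("CCCCCCCCCC", rc(mir), "CCCCCCCCCC")
  expect_equal(nrow(find_mre_sites(mir, target)), 1)
  # the reverse complement of the target carries the miRNA's own sequence,
  # not its complement: no site
  expect_equal(nrow(find_mre_sites(mir, rc(target))), 0)
})

test_that("targets shorter than the miRNA warn and return no sites", {
  expect_warning(out <- find_mre_sites(strrep("A", 21), "ACGT"),
                 "shorter than")
  expect_equal(nrow(out), 0)
})

test_that("count_mres tabulates retained sites per pair, omitting zero pairs", {
  mir <- "TGAAGCTGCCAGCATGATCTA"
  mirnas <- transcript_set("m1", mir, biotype = "miRNA")
  targets <- transcript_set(
    c("t1", "t2"),
    c(paste0(strrep("C", 30), rc(mir), strrep("C", 30)), strrep("AC", 50)))
  out <- count_mres(mirnas, targets)
  expect_equal(nrow(out), 1)
  expect_equal(out$target_id, "t1")
  expect_equal(out$mre_count, 1L)
  empty <- count_mres(mirnas, targets[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("count_mres recovers planted per-pair counts from the generator", {
  p <- simulation_params(n_mirna = 4, n_mrna = 8, n_lncrna = 4,
                         n_planted_triplets = 4, seed = 25)
  seqs <- generate_sequences(p)
  out <- count_mres(seqs$mirnas, seqs$mrnas)
  planted <- seqs$truth$planted_sites
  planted <- planted[grepl("^m_", planted$target_id), ]
  planted_n <- table(paste(planted$mirna_id, planted$target_id))
  for (k in names(planted_n)) {
    parts <- strsplit(k, " ")[[1]]
    row <- out[out$mirna_id == parts[1] & out$target_id == parts[2], ]
    expect_equal(nrow(row), 1)
    expect_gte(row$mre_count, unname(planted_n[k]))
    # exhaustive oracle agreement on the same pair
    seq_t <- seqs$mrnas$seq[seqs$mrnas$id == parts[2]]
    seq_m <- seqs$mirnas$seq[seqs$mirnas$id == parts[1]]
    expect_equal(row$mre_count, length(oracle_find_sites(seq_m, seq_t)))
  }
})
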