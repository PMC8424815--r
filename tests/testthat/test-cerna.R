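test_that("cerna_score spans its extremes and the worked toy case", {
  counts <- c(m1 = 2, m2 = 2, m3 = 1)
  expect_equal(cerna_score(counts, names(counts)), 1.0)
  expect_equal(cerna_score(counts, character(0)), 0.0)
  expect_equal(cerna_score(counts, c("m1", "m3")), 0.6)
  expect_equal(cerna_score(counts, c("m1", "m3"), mode = "species"), 2 / 3)
  expect_error(cerna_score(numeric(0), "m1"), "no MREs")
})

test_that("the toy score arises from actual site enumeration on toy sequences", {
  set.seed(41)
  bases <- c("A", "C", "G", "T")
  mirs <- vapply(1:3, function(i) paste(sample(bases, 21, TRUE), collapse = ""),
                 "")
  rc <- function(s) ceRNAnet:::reverse_complement(s)
  spacer <- function(n) strrep("C", n)
  lnc_seq <- paste0(spacer(25), rc(mirs[1]), spacer(25), rc(mirs[1]),
                    spacer(25), rc(mirs[2]), spacer(25), rc(mirs[2]),
                    spacer(25), rc(mirs[3]), spacer(25))
  mirnas <- transcript_set(c("m1", "m2", "m3"), mirs, biotype = "miRNA")
  lnc <- transcript_set("L1", lnc_seq, biotype = "lncRNA")
  cnt <- count_mres(mirnas, lnc)
  counts <- stats::setNames(cnt$mre_count, cnt$mirna_id)
  expect_equal(counts[c("m1", "m2", "m3")], c(m1 = 2L, m2 = 2L, m3 = 1L))
  expect_equal(cerna_score(counts, c("m1", "m3")), 0.6)
})

test_that("cerna_score is monotone in the shared miRNA set", {
  set.seed(42)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    counts <- stats::setNames(sample(1:4, k, TRUE), sprintf("m%d", 1:k))
    shared <- character(0)
    last <- 0
    for (m in sample(names(counts))) {
      shared <- c(shared, m)
      sc <- cerna_score(counts, shared)
      expect_gte(sc, last)
      expect_gte(sc, 0); expect_lte(sc, 1)
      last <- sc
    }
    expect_equal(last, 1.0)
  }
})

fixture_interactions <- function() {
  mir_lnc <- data.frame(
    mirna_id = c("m1", "m1", "m2"), target_id = c("L1", "L2", "L1"),
    target_kind = "lncRNA", mre_count = c(2L, 1L, 1L),
    pcc = c(-0.95, -0.9, -0.85), pcc_pvalue = 1e-4, stringsAsFactors = FALSE)
  mir_mrna <- data.frame(
    mirna_id = c("m1", "m2", "m2"), target_id = c("M1", "M1", "M2"),
    target_kind = "mRNA", mre_count = c(3L, 1L, 2L),
    pcc = c(-0.92, -0.88, -0.93), pcc_pvalue = 1e-4, stringsAsFactors = FALSE)
  lnc_mrna <- data.frame(
    lncrna_id = c("L1", "L1", "L2"), mrna_id = c("M1", "M2", "M1"),
    pcc = c(0.93, 0.88, 0.91), pcc_pvalue = 1e-4, n = 12,
    stringsAsFactors = FALSE)
  lnc_counts <- data.frame(
    mirna_id = c("m1", "m2", "m1"), target_id = c("L1", "L1", "L2"),
    mre_count = c(2L, 1L, 1L), stringsAsFactors = FALSE)
  list(mir_lnc = mir_lnc, mir_mrna = mir_mrna, lnc_mrna = lnc_mrna,
       lnc_counts = lnc_counts)
}

test_that("a fully supported combination yields exactly one triplet", {
  fx <- fixture_interactions()
  one <- assemble_triplets(fx$mir_lnc[1, ], fx$mir_mrna[1, ],
                           fx$lnc_mrna[1, ], fx$lnc_counts)
  expect_equal(nrow(one), 1)
  expect_equal(one$lncrna_id, "L1")
  expect_equal(one$mirna_id, "m1")
  expect_equal(one$mrna_id, "M1")
  expect_equal(one$cerna_score, 2 / 3)
  # breaking the lncRNA-mRNA leg removes it
  none <- assemble_triplets(fx$mir_lnc[1, ], fx$mir_mrna[1, ],
                            fx$lnc_mrna[0, ], fx$lnc_counts)
  expect_equal(nrow(none), 0)
})

test_that("triplet assembly equals the exhaustive combination oracle", {
  fx <- fixture_interactions()
  for (smin in c(0, 0.4, 0.7, 1)) {
    got <- assemble_triplets(fx$mir_lnc, fx$mir_mrna, fx$lnc_mrna,
                             fx$lnc_counts, score_min = smin)
    keys <- if (nrow(got))
      sort(paste(got$lncrna_id, got$mirna_id, got$mrna_id, sep = "|"))
    else character(0)
    expect_equal(keys, oracle_triplets(fx$mir_lnc, fx$mir_mrna, fx$lnc_mrna,
                                       fx$lnc_counts, score_min = smin),
                 info = paste("score_min", smin))
  }
  # DE restriction drops triplets with an ns member
  de <- c(L1 = "down", L2 = "down", m1 = "up", m2 = "ns",
          M1 = "down", M2 = "down")
  got_de <- assemble_triplets(fx$mir_lnc, fx$mir_mrna, fx$lnc_mrna,
                              fx$lnc_counts, score_min = 0, de_status = de)
  expect_false(any(got_de$mirna_id == "m2"))
  keys_de <- sort(paste(got_de$lncrna_id, got_de$mirna_id, got_de$mrna_id,
                        sep = "|"))
  expect_equal(keys_de, oracle_triplets(fx$mir_lnc, fx$mir_mrna, fx$lnc_mrna,
                                        fx$lnc_counts, score_min = 0,
                                        de_status = de))
})

test_that("assembly is invariant to input row order", {
  fx <- fixture_interactions()
  base <- assemble_triplets(fx$mir_lnc, fx$mir_mrna, fx$lnc_mrna,
                            fx$lnc_counts, score_min = 0)
  set.seed(43)
  shuf <- assemble_triplets(fx$mir_lnc[sample(3), ], fx$mir_mrna[sample(3), ],
                            fx$lnc_mrna[sample(3), ],
                            fx$lnc_counts[sample(3), ], score_min = 0)
  expect_equal(shuf, base)
})

test_that("restrict_to_genes filters by mRNA id and warns on absent keys", {
  fx <- fixture_interactions()
  trips <- assemble_triplets(fx$mir_lnc, fx$mir_mrna, fx$lnc_mrna,
                             fx$lnc_counts, score_min = 0)
  expect_equal(restrict_to_genes(trips, unique(trips$mrna_id)), trips)
  expect_equal(nrow(restrict_to_genes(trips, character(0))), 0)
  expect_warning(out <- restrict_to_genes(trips, c("M1", "ghost")), "ghost")
  expect_true(all(out$mrna_id == "M1"))
})

test_that("a single triplet builds a triangle with uniform degree", {
  one <- data.frame(lncrna_id = "L1", mirna_id = "m1", mrna_id = "M1",
                    cerna_score = 1, lnc_mrna_pcc = 0.9, mir_lnc_pcc = -0.9,
                    mir_mrna_pcc = -0.9, stringsAsFactors = FALSE)
  net <- build_network(one)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$degree == 2))
  expect_equal(net$hubs, c("L1", "M1", "m1"))
})

test_that("a miRNA shared by two disjoint triplets is the unique hub", {
  two <- data.frame(lncrna_id = c("L1", "L2"), mirna_id = "m1",
                    mrna_id = c("M1", "M2"), cerna_score = 1,
                    lnc_mrna_pcc = 0.9, mir_lnc_pcc = -0.9,
                    mir_mrna_pcc = -0.9, stringsAsFactors = FALSE)
  net <- build_network(two)
  expect_equal(unname(net$degree[["m1"]]), 4)
  expect_equal(net$hubs, "m1")
  expect_equal(net$primary_hub, "m1")
})

test_that("degree and hubs equal brute-force incidence counting", {
  set.seed(44)
  trips <- unique(data.frame(
    lncrna_id = sprintf("L%02d", sample(1:8, 25, TRUE)),
    mirna_id = sprintf("m%02d", sample(1:6, 25, TRUE)),
    mrna_id = sprintf("M%02d", sample(1:12, 25, TRUE)),
    stringsAsFactors = FALSE))
  trips$cerna_score <- 1; trips$lnc_mrna_pcc <- 0.9
  trips$mir_lnc_pcc <- -0.9; trips$mir_mrna_pcc <- -0.9
  net <- build_network(trips)
  ora <- oracle_degree(net$edges)
  expect_equal(unname(net$degree[names(ora)]), unname(ora))
  expect_equal(sort(net$hubs), sort(names(ora)[ora == max(ora)]))
  expect_equal(net$primary_hub, sort(net$hubs)[1])
  # handshake: degree sum is twice the edge count
  expect_equal(sum(net$degree), 2 * nrow(net$edges))
})
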