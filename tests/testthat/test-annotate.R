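test_that("short transcripts fail the length filter with reason too_short", {
  ts <- transcript_set("t1", strrep("AC", 75))  # 150 nt
  out <- filter_lncrna_candidates(ts)
  expect_false(out$passed_filters)
  expect_match(out$fail_reasons, "too_short")
})

test_that("length filter is strict: exactly 200 bp fails, 201 bp passes", {
  ts <- transcript_set(c("t200", "t201"),
                       c(strrep("AC", 100), paste0(strrep("AC", 100), "A")))
  out <- filter_lncrna_candidates(ts)
  expect_equal(out$passed_filters, c(FALSE, TRUE))
})

test_that("a long ORF-free sequence passes the coding filter", {
  ts <- transcript_set("t1", strrep("AAC", 167))  # 501 nt, no ATG anywhere
  out <- filter_lncrna_candidates(ts)
  expect_true(out$passed_filters)
  expect_equal(out$orf_nt, 0L)
})

test_that("an engineered long ORF triggers the coding filter", {
  # 351 nt ORF: ATG + 115 non-stop codons + TAA, embedded in AC repeats
  orf <- paste0("ATG", strrep("GCA", 115), "TAA")
  seq <- paste0(strrep("AC", 60), orf, strrep("CA", 65))
  expect_equal(nchar(orf), 351)
  ts <- transcript_set("t1", seq)
  out <- filter_lncrna_candidates(ts)
  expect_false(out$passed_filters)
  expect_match(out$fail_reasons, "coding_orf")
  expect_equal(out$orf_nt, oracle_longest_orf(seq))
})

test_that("longest_orf agrees with the exhaustive start-position oracle", {
  set.seed(31)
  for (i in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    expect_equal(longest_orf(seq), oracle_longest_orf(seq), info = seq)
  }
})

make_class_fixture <- function() {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "+"),
                      start = c(1000L, 20000L), end = c(5000L, 24000L),
                      stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    transcript_id = c("g1.t", "g1.t", "g1.t", "g2.t", "g2.t"),
    chrom = "chr1", strand = "+",
    start = c(1000L, 2000L, 4000L, 20000L, 23000L),
    end = c(1500L, 2500L, 5000L, 21000L, 24000L),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

place <- function(id, start, end, strand = "+") {
  transcript_set(id, strrep("A", 10), chrom = "chr1", strand = strand,
                 exon_start = list(start), exon_end = list(end))
}

test_that("positional classes follow the intergenic/antisense/intronic rules", {
  ann <- make_class_fixture()
  # far from both genes
  expect_equal(classify_positional(place("t", 8000, 8500), ann), "intergenic")
  # exactly covering an exon on the opposite strand
  expect_equal(classify_positional(place("t", 2000, 2500, "-"), ann),
               "antisense")
  # entirely inside intron 2 of same-strand g1 (2501..3999)
  expect_equal(classify_positional(place("t", 2600, 3900), ann), "intronic")
  # overlapping gene span and an exon on the same strand: ambiguous
  expect_equal(classify_positional(place("t", 1400, 1700), ann), "ambiguous")
  # antisense precedence over intronic on double hits
  expect_equal(classify_positional(place("t", 2000, 3900, "-"), ann),
               "antisense")
})

test_that("classification agrees with a brute-force interval oracle", {
  ann <- make_class_fixture()
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2
  oracle_class <- function(s, e, strand) {
    g <- ann$genes
    hit_gene <- which(mapply(function(gs, ge) overlaps(s, e, gs, ge),
                             g$start, g$end))
    if (!length(hit_gene)) return("intergenic")
    anti <- any(mapply(function(es, ee, st) overlaps(s, e, es, ee) &&
                         st != strand,
                       ann$exons$start, ann$exons$end, ann$exons$strand))
    if (anti) return("antisense")
    for (gi in hit_gene) {
      if (g$strand[gi] != strand) next
      ex <- ann$exons[ann$exons$gene_id == g$gene_id[gi], ]
      ex <- ex[order(ex$start), ]
      if (nrow(ex) < 2) next
      for (k in seq_len(nrow(ex) - 1))
        if (s >= ex$end[k] + 1 && e <= ex$start[k + 1] - 1) return("intronic")
    }
    "ambiguous"
  }
  set.seed(17)
  for (i in 1:40) {
    s <- sample(1:25000, 1); e <- s + sample(50:3000, 1)
    strand <- sample(c("+", "-"), 1)
    expect_equal(classify_positional(place("t", s, e, strand), ann),
                 oracle_class(s, e, strand),
                 info = sprintf("%d-%d %s", s, e, strand))
  }
})

test_that("classification is independent of gene order and errors on unplaced", {
  ann <- make_class_fixture()
  ann_rev <- ann
  ann_rev$genes <- ann$genes[2:1, ]
  ann_rev$exons <- ann$exons[nrow(ann$exons):1, ]
  tx <- place("t", 2600, 3900)
  expect_equal(classify_positional(tx, ann), classify_positional(tx, ann_rev))
  expect_error(classify_positional(transcript_set("u", "ACGT"), ann),
               "unplaced transcript")
})

test_that("transcript summaries match a direct recount", {
  one <- transcript_set("a", strrep("A", 500),
                        exon_start = list(1L), exon_end = list(500L))
  s1 <- summarize_transcripts(one)
  expect_equal(s1$fraction_len_201_1900, 1.0)
  expect_equal(s1$fraction_exons_le3, 1.0)
  two <- transcript_set(c("a", "b"), c(strrep("A", 300), strrep("A", 2500)))
  expect_equal(summarize_transcripts(two)$fraction_len_201_1900, 0.5)

  set.seed(9)
  lens <- sample(150:3000, 50, TRUE)
  many <- transcript_set(sprintf("t%02d", 1:50),
                         vapply(lens, function(l) strrep("A", l), ""))
  s <- summarize_transcripts(many)
  expect_equal(sum(s$length_histogram), 50)
  expect_equal(sum(s$exon_count_histogram), 50)
  expect_equal(s$fraction_len_201_1900, mean(lens >= 201 & lens <= 1900))
  expect_error(summarize_transcripts(many[0, ]), "empty")
})
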