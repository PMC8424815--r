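#' Longest ATG-initiated open reading frame
#'
#' Scans the three forward frames of the given strand for the longest open
#' reading frame that starts at an ATG and ends at a stop codon. The returned
#' length counts nucleotides from the A of the ATG through the stop codon
#' inclusive; an ATG run that never reaches a stop codon does not count as an
#' ORF.
#'
#' @param seq DNA sequence string.
#' @return longest ORF length in nt (0 if none).
#' @export
longest_orf <- function(seq) {
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  if (n < 6L) return(0L)
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(seq, starts, starts + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    open_from <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_from) && is_atg[k]) open_from <- k
      if (!is.na(open_from) && is_stop[k]) {
        best <- max(best, (k - open_from + 1L) * 3L)
        open_from <- NA_integer_
      }
    }
  }
  best
}

#' Filter lncRNA candidates by length and coding potential
#'
#' A candidate passes iff its length is strictly greater than `min_length`
#' (non-coding RNAs are defined as larger than 200 bp) and its longest
#' ATG-initiated ORF is shorter than `max_orf_nt`. The ORF rule is a simple,
#' fully specified surrogate for coding-potential classifiers.
#'
#' @param ts a [transcript_set()] of candidates.
#' @param min_length minimum length in bp (strict; default 200).
#' @param max_orf_nt ORF length at or above which a transcript is deemed
#'   coding (default 300 nt, i.e. a 100-codon peptide incl. stop).
#' @return data frame: transcript_id, length, orf_nt, passed_filters,
#'   fail_reasons (comma-joined tokens from `too_short`, `coding_orf`).
#' @export
filter_lncrna_candidates <- function(ts, min_length = 200L, max_orf_nt = 300L) {
  if (nrow(ts) == 0L)
    return(data.frame(transcript_id = character(0), length = integer(0),
                      orf_nt = integer(0), passed_filters = logical(0),
                      fail_reasons = character(0), stringsAsFactors = FALSE))
  len <- nchar(ts$seq)
  orf <- vapply(ts$seq, longest_orf, integer(1), USE.NAMES = FALSE)
  reasons <- mapply(function(l, o) {
    r <- character(0)
    if (l <= min_length) r <- c(r, "too_short")
    if (o >= max_orf_nt) r <- c(r, "coding_orf")
    paste(r, collapse = ",")
  }, len, orf)
  data.frame(transcript_id = ts$id, length = len, orf_nt = orf,
             passed_filters = !nzchar(reasons), fail_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Positional class of a transcript relative to a gene annotation
#'
#' Classes: `intergenic` when the transcript span overlaps no gene span;
#' `antisense` when it overlaps at least one exon of an opposite-strand gene;
#' `intronic` when its span lies entirely inside a single intron of a
#' same-strand gene; otherwise `ambiguous`. When several rules fire the
#' precedence is antisense > intronic > ambiguous.
#'
#' @param ts a [transcript_set()] with chrom/strand/exons set.
#' @param ann a `gene_annotation` from [read_annotation()].
#' @return character vector of classes, one per transcript.
#' @export
classify_positional <- function(ts, ann) {
  if (any(is.na(ts$chrom) | is.na(ts$strand)))
    stop("unplaced transcript: ", ts$id[is.na(ts$chrom) | is.na(ts$strand)][1])
  n_ex <- lengths(ts$exon_start)
  if (any(n_ex == 0L))
    stop("unplaced transcript: ", ts$id[n_ex == 0L][1])
  span_start <- vapply(ts$exon_start, min, numeric(1))
  span_end <- vapply(ts$exon_end, max, numeric(1))
  tgr <- GenomicRanges::GRanges(ts$chrom,
                                IRanges::IRanges(span_start, span_end),
                                strand = ts$strand)
  genes <- ann$genes
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end),
                                strand = genes$strand)
  egr <- GenomicRanges::GRanges(ann$exons$chrom,
                                IRanges::IRanges(ann$exons$start, ann$exons$end),
                                strand = ann$exons$strand)
  out <- rep("ambiguous", nrow(ts))
  hit_gene <- GenomicRanges::findOverlaps(tgr, ggr, ignore.strand = TRUE)
  has_gene <- seq_len(nrow(ts)) %in% S4Vectors::queryHits(hit_gene)
  out[!has_gene] <- "intergenic"
  # antisense: span overlaps an exon of an opposite-strand gene
  hit_ex <- GenomicRanges::findOverlaps(tgr, egr, ignore.strand = TRUE)
  anti <- tapply(
    as.character(GenomicRanges::strand(egr))[S4Vectors::subjectHits(hit_ex)] !=
      ts$strand[S4Vectors::queryHits(hit_ex)],
    S4Vectors::queryHits(hit_ex), any)
  anti_idx <- as.integer(names(anti))[unlist(anti)]
  out[anti_idx] <- "antisense"
  # intronic: entirely inside one intron of a same-strand gene
  for (i in setdiff(which(has_gene), anti_idx)) {
    gi <- S4Vectors::subjectHits(hit_gene)[S4Vectors::queryHits(hit_gene) == i]
    intronic <- FALSE
    for (g in gi) {
      if (genes$strand[g] != ts$strand[i]) next
      ex <- ann$exons[ann$exons$gene_id == genes$gene_id[g], , drop = FALSE]
      if (nrow(ex) < 2L) next
      ex <- ex[order(ex$start), ]
      introns <- cbind(ex$end[-nrow(ex)] + 1L, ex$start[-1] - 1L)
      introns <- introns[introns[, 1] <= introns[, 2], , drop = FALSE]
      if (any(span_start[i] >= introns[, 1] & span_end[i] <= introns[, 2]))
        intronic <- TRUE
    }
    if (intronic) out[i] <- "intronic"
  }
  out
}

#' Length and exon-count summaries of a transcript set
#'
#' Reproduces the standard lncRNA characterisation summaries: a length
#' histogram in 100-bp bins from 201 bp, an exon-count histogram, the
#' fraction of transcripts 201-1900 bp long and the fraction with at most
#' 3 exons.
#'
#' @param ts a non-empty [transcript_set()].
#' @return list with `length_histogram`, `exon_count_histogram`,
#'   `fraction_len_201_1900`, `fraction_exons_le3`.
#' @export
summarize_transcripts <- function(ts) {
  if (nrow(ts) == 0L) stop("empty transcript set")
  len <- nchar(ts$seq)
  brk <- c(0, seq(200, max(2000, max(len) + 100), by = 100), Inf)
  lh <- table(cut(len, breaks = unique(brk), right = TRUE))
  lh <- lh[lh > 0]
  n_ex <- pmax(1L, lengths(ts$exon_start))
  eh <- table(n_ex)
  list(length_histogram = lh,
       exon_count_histogram = eh,
       fraction_len_201_1900 = mean(len >= 201 & len <= 1900),
       fraction_exons_le3 = mean(n_ex <= 3))
}
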