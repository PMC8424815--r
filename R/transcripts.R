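#' Build a transcript set
#'
#' A transcript set is the package's central sequence container: a data frame
#' with one row per transcript and columns `id`, `seq`, `biotype`, `chrom`,
#' `strand`, and list-columns `exon_start` / `exon_end` holding 1-based closed
#' exon intervals. Sequences use the DNA alphabet internally; `U` is converted
#' to `T` on construction.
#'
#' @param id character vector of unique transcript ids.
#' @param seq character vector of sequences over `A,C,G,T,U,N`.
#' @param biotype one of `"mRNA"`, `"lncRNA_candidate"`, `"lncRNA"`, `"miRNA"`
#'   (recycled).
#' @param chrom,strand optional genomic placement (recycled; `NA` = unplaced).
#' @param exon_start,exon_end optional lists of integer vectors, per
#'   transcript, giving sorted non-overlapping exon intervals.
#' @return a `transcript_set` data frame.
#' @export
transcript_set <- function(id, seq, biotype = "mRNA",
                           chrom = NA_character_, strand = NA_character_,
                           exon_start = NULL, exon_end = NULL) {
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id))
    stop("duplicate transcript id: ", id[duplicated(id)][1])
  seq <- toupper(chartr("u", "t", chartr("U", "T", seq)))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("non-alphabet character in sequence of '", id[bad][1], "'")
  if (any(nchar(seq) < 1L)) stop("empty sequence for '", id[nchar(seq) < 1L][1], "'")
  biotype <- rep_len(biotype, length(id))
  stopifnot(all(biotype %in% c("mRNA", "lncRNA_candidate", "lncRNA", "miRNA")))
  mi <- biotype == "miRNA"
  if (any(mi) && any(nchar(seq[mi]) < 18L | nchar(seq[mi]) > 26L))
    stop("miRNA sequence length outside 18-26 nt")
  n <- length(id)
  if (is.null(exon_start)) exon_start <- rep(list(integer(0)), n)
  if (is.null(exon_end)) exon_end <- rep(list(integer(0)), n)
  for (i in seq_len(n)) {
    s <- exon_start[[i]]; e <- exon_end[[i]]
    stopifnot(length(s) == length(e))
    if (length(s) > 1L) {
      if (is.unsorted(s, strictly = TRUE)) stop("exons not sorted for '", id[i], "'")
      if (any(s[-1] <= e[-length(e)])) stop("overlapping exons for '", id[i], "'")
    }
    if (any(e < s)) stop("exon end < start for '", id[i], "'")
  }
  out <- data.frame(id = as.character(id), seq = seq, biotype = biotype,
                    chrom = rep_len(as.character(chrom), n),
                    strand = rep_len(as.character(strand), n),
                    stringsAsFactors = FALSE)
  out$exon_start <- exon_start
  out$exon_end <- exon_end
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' Read transcript sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the transcript id.
#' Sequences are uppercased and `U` is canonicalised to `T`.
#'
#' @param path FASTA file.
#' @param biotype default biotype assigned to all records.
#' @return a [transcript_set()].
#' @export
read_fasta <- function(path, biotype = "mRNA") {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) stop("duplicate transcript id: ", ids[duplicated(ids)][1])
  seqs <- as.character(recs)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence record: ", ids[nchar(seqs) == 0L][1])
  transcript_set(ids, seqs, biotype = biotype)
}

#' Write a transcript set to FASTA
#'
#' @param ts a [transcript_set()].
#' @param path output file.
#' @export
write_fasta <- function(ts, path) {
  x <- Biostrings::DNAStringSet(ts$seq)
  names(x) <- ts$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
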