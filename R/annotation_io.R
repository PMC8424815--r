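#' Read a gene annotation (GTF or GFF3)
#'
#' Parses gene and exon features into a `gene_annotation`: a list with a
#' `genes` data frame (gene_id, chrom, strand, start, end) and an `exons` data
#' frame (gene_id, transcript_id, chrom, strand, start, end). Coordinates are
#' 1-based closed, as in the source formats. Gene spans absent from the file
#' are inferred as the range of the gene's exons.
#'
#' @param path GTF or GFF3 file; the dialect is detected from `ID=`/`Parent=`
#'   versus `gene_id` attributes.
#' @return a `gene_annotation` object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(body)) {
    warning("empty annotation: ", path)
    return(empty_annotation())
  }
  # light pre-validation so errors can name the offending line
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  lineno <- which(body)
  gff3 <- any(vapply(fields, function(f)
    length(f) >= 9 && grepl("(^|;)(ID|Parent)=", f[9]), logical(1)))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 9) stop("line ", lineno[k], ": fewer than 9 columns")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop("line ", lineno[k], ": end < start")
    if (!gff3 && f[3] %in% c("gene", "exon", "transcript") &&
        !grepl("gene_id", f[9], fixed = TRUE))
      stop("line ", lineno[k], ": missing gene_id attribute")
  }
  gr <- rtracklayer::import(path, format = if (gff3) "gff3" else "gtf")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  gid <- if (gff3) gff3_gene_ids(gr) else as.character(md$gene_id)
  tid <- if (gff3) {
    p <- if ("Parent" %in% names(md)) as.character(S4Vectors::unstrsplit(md$Parent, ",")) else NA
    ifelse(typ == "exon" & nzchar(p) & !is.na(p), p, gid)
  } else if ("transcript_id" %in% names(md)) {
    as.character(md$transcript_id)
  } else gid
  df <- data.frame(type = typ, gene_id = gid, transcript_id = tid,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  exons <- df[df$type == "exon", c("gene_id", "transcript_id", "chrom",
                                   "strand", "start", "end")]
  genes <- df[df$type == "gene", c("gene_id", "chrom", "strand", "start", "end")]
  if (nrow(genes) == 0L && nrow(exons) > 0L) {
    sp <- split(exons, exons$gene_id)
    genes <- do.call(rbind, lapply(sp, function(g)
      data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
                 start = min(g$start), end = max(g$end), stringsAsFactors = FALSE)))
  }
  rownames(genes) <- rownames(exons) <- NULL
  bad <- !is.na(match(exons$gene_id, genes$gene_id)) &
    (exons$start < genes$start[match(exons$gene_id, genes$gene_id)] |
       exons$end > genes$end[match(exons$gene_id, genes$gene_id)])
  if (any(bad)) stop("exon interval outside gene span for gene '",
                     exons$gene_id[bad][1], "'")
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

gff3_gene_ids <- function(gr) {
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  par <- if ("Parent" %in% names(md))
    as.character(S4Vectors::unstrsplit(md$Parent, ",")) else rep("", length(gr))
  # walk Parent chains up to the gene feature
  parent_of <- stats::setNames(par, id)
  type_of <- stats::setNames(typ, id)
  resolve <- function(key) {
    seen <- character(0)
    while (!is.na(key) && nzchar(key) && !key %in% seen) {
      if (!is.na(type_of[key]) && identical(unname(type_of[key]), "gene")) return(key)
      seen <- c(seen, key)
      key <- if (key %in% names(parent_of)) unname(parent_of[key]) else NA_character_
    }
    NA_character_
  }
  out <- character(length(gr))
  for (i in seq_along(gr)) {
    out[i] <- if (typ[i] == "gene") id[i]
    else if (nzchar(par[i])) {
      r <- resolve(par[i]); if (is.na(r)) par[i] else r
    } else if (!is.na(id[i])) id[i] else NA_character_
  }
  out
}

empty_annotation <- function() {
  structure(list(
    genes = data.frame(gene_id = character(0), chrom = character(0),
                       strand = character(0), start = integer(0), end = integer(0),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = character(0), transcript_id = character(0),
                       chrom = character(0), strand = character(0),
                       start = integer(0), end = integer(0), stringsAsFactors = FALSE)),
    class = "gene_annotation")
}

#' Write a gene annotation to GTF
#'
#' Inverse of [read_annotation()] for the GTF dialect; used by the synthetic
#' bundle writer.
#'
#' @param ann a `gene_annotation`.
#' @param path output file.
#' @export
write_annotation_gtf <- function(ann, path) {
  fmt <- function(type, chrom, strand, start, end, gid, tid) {
    attr <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    paste(chrom, "ceRNAnet", type, start, end, ".", strand, ".", attr, sep = "\t")
  }
  g <- ann$genes; e <- ann$exons
  lines <- c(
    if (nrow(g)) fmt("gene", g$chrom, g$strand, g$start, g$end, g$gene_id, g$gene_id),
    if (nrow(e)) fmt("exon", e$chrom, e$strand, e$start, e$end, e$gene_id, e$transcript_id))
  writeLines(lines, path)
  invisible(path)
}
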