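#!/usr/bin/env Rscript
# Filter lncRNA candidates (length > 200 bp, longest ORF < 300 nt) and assign
# positional classes (intronic / antisense / intergenic) against the toy gene
# annotation; summarise lengths and exon counts. Run 01_simulate.R first.

suppressMessages(library(ceRNAnet))

lncs <- read_fasta("results/synthetic/lncrna.fasta", biotype = "lncRNA_candidate")
ann <- read_annotation("results/synthetic/annotation.gtf")
plc <- read.delim("results/synthetic/lncrna_placements.tsv")

flt <- filter_lncrna_candidates(lncs)
i <- match(lncs$id, plc$transcript_id)
placed <- transcript_set(lncs$id, lncs$seq, biotype = "lncRNA_candidate",
                         chrom = plc$chrom[i], strand = plc$strand[i],
                         exon_start = as.list(plc$start[i]),
                         exon_end = as.list(plc$end[i]))
cls <- classify_positional(placed, ann)

out <- cbind(flt, positional_class = cls)
dir.create("results", showWarnings = FALSE)
write.table(out, "results/lncrna_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d/%d candidates pass the lncRNA filters\n",
            sum(flt$passed_filters), nrow(flt)))
print(table(cls))
s <- summarize_transcripts(lncs)
cat(sprintf("fraction 201-1900 bp: %.4f; fraction <= 3 exons: %.4f\n",
            s$fraction_len_201_1900, s$fraction_exons_le3))
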