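#!/usr/bin/env Rscript
# Predict miRNA response elements with the complementarity penalty scanner
# (mismatch 1, G:U 0.5, doubled at miRNA positions 2-13, cutoff 4) and
# intersect with signed co-expression: miRNA-target pairs at PCC < -0.7,
# lncRNA-mRNA pairs at PCC > 0.7, both at p < 0.01.

suppressMessages(library(ceRNAnet))

mirnas <- read_fasta("results/synthetic/mirna.fasta", biotype = "miRNA")
mrnas <- read_fasta("results/synthetic/mrna.fasta", biotype = "mRNA")
lncs <- read_fasta("results/synthetic/lncrna.fasta", biotype = "lncRNA_candidate")
keep <- filter_lncrna_candidates(lncs)$passed_filters
lncs <- lncs[keep, ]

cond <- read.delim("results/synthetic/conditions.tsv")
expr <- read_expression_matrix("results/synthetic/expression.tsv",
                               setNames(cond$condition, cond$sample_id),
                               unit = "RPKM")

mre_lnc <- count_mres(mirnas, lncs)
mre_mrna <- count_mres(mirnas, mrnas)
cat(sprintf("MRE pairs: %d miRNA-lncRNA, %d miRNA-mRNA\n",
            nrow(mre_lnc), nrow(mre_mrna)))
write.table(rbind(attr(mre_lnc, "sites"), attr(mre_mrna, "sites")),
            "results/mre_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

int_lnc <- mirna_target_interactions(mre_lnc, expr, "lncRNA")
int_mrna <- mirna_target_interactions(mre_mrna, expr, "mRNA")
lm <- lncrna_mrna_pairs(expr, lncs$id, mrnas$id)
cat(sprintf("co-expression supported: %d miRNA-lncRNA, %d miRNA-mRNA, %d lncRNA-mRNA\n",
            nrow(int_lnc), nrow(int_mrna), nrow(lm)))
write.table(rbind(int_lnc, int_mrna), "results/interactions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(lm, "results/lncrna_mrna_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# expression-trait correlation for the planted trait-linked mRNA
truth <- jsonlite::read_json("results/synthetic/truth.json",
                             simplifyVector = TRUE)
trait <- read.delim("results/synthetic/trait.tsv")
tc <- trait_correlation(expr$values[truth$trait_mrna, trait$sample_id],
                        trait$trait)
cat(sprintf("trait vs %s: r = %.4f (p = %.3g)\n", truth$trait_mrna, tc$r,
            tc$pvalue))
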