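#!/usr/bin/env Rscript
# Call differential expression between control and drought-treated samples
# (Welch t on log2(x + 1), Benjamini-Hochberg; deregulated when padj < 0.05
# and |log2FC| > 1) and compare calls against the planted ground truth.

suppressMessages(library(ceRNAnet))

cond <- read.delim("results/synthetic/conditions.tsv")
cond_map <- setNames(cond$condition, cond$sample_id)
expr <- read_expression_matrix("results/synthetic/expression.tsv", cond_map,
                               unit = "RPKM")
de <- differential_expression(expr)
write.table(de, "results/de_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d features: %d up, %d down, %d ns\n", nrow(de),
            sum(de$status == "up"), sum(de$status == "down"),
            sum(de$status == "ns")))

truth <- jsonlite::read_json("results/synthetic/truth.json",
                             simplifyVector = TRUE)
tab <- table(truth = unlist(truth$true_de)[de$feature_id], called = de$status)
cat("confusion (planted truth vs calls):\n")
print(tab)
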