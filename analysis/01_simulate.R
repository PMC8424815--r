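#!/usr/bin/env Rscript
# Generate the synthetic drought ceRNA study: 20 miRNAs, 200 mRNAs,
# 50 lncRNA candidates, 30 planted lncRNA-miRNA-mRNA triplets, 6 control +
# 6 treated samples. Writes the full fixture bundle (sequences, annotation,
# expression, trait, ground truth) under results/synthetic/.

suppressMessages(library(ceRNAnet))

params <- simulation_params(seed = 20260922)
paths <- synth_bundle(params, "results/synthetic")

truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
cat(sprintf("bundle written to results/synthetic (%d files)\n", length(paths)))
cat(sprintf("planted: %d triplets over %d miRNAs, %d lncRNAs, %d mRNAs\n",
            nrow(truth$planted_triplets),
            length(unique(truth$planted_triplets$mirna_id)),
            length(unique(truth$planted_triplets$lncrna_id)),
            length(unique(truth$planted_triplets$mrna_id))))
cat(sprintf("planted MRE sites: %d\n", nrow(truth$planted_sites)))
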