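#' Pipeline configuration
#'
#' Collects input paths and every stage parameter. Thresholds default to the
#' conventional cutoffs for this analysis: adjusted p < 0.05 and |log2FC| > 1
#' for differential expression, PCC < -0.7 with p < 0.01 for miRNA-target
#' repression, PCC > 0.7 with p < 0.01 for lncRNA-mRNA co-expression.
#'
#' @param mirna_fasta,mrna_fasta,lncrna_fasta sequence inputs.
#' @param expression,conditions expression TSV and sample condition TSV
#'   (columns sample_id, condition).
#' @param annotation optional GTF/GFF3 for positional classification.
#' @param placements optional lncRNA placement TSV (transcript_id, chrom,
#'   strand, start, end).
#' @param key_genes optional plain-text file, one mRNA id per line; when
#'   given, triplets are restricted to these genes.
#' @param trait optional trait TSV (sample_id, trait).
#' @param outdir output directory.
#' @param duplex a [duplex_params()].
#' @param r_max,r_min,p_max correlation thresholds (strict).
#' @param log2fc_min,padj_max,pseudo differential-expression settings.
#' @param score_min,score_mode ceRNA score cutoff and interpretation.
#' @param de_restrict require all triplet members deregulated (default TRUE).
#' @param min_length,max_orf_nt lncRNA candidate filters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_fasta, mrna_fasta, lncrna_fasta,
                            expression, conditions, outdir,
                            annotation = NULL, placements = NULL,
                            key_genes = NULL, trait = NULL,
                            duplex = duplex_params(),
                            r_max = -0.7, r_min = 0.7, p_max = 0.01,
                            log2fc_min = 1.0, padj_max = 0.05, pseudo = 1.0,
                            score_min = 0.5, score_mode = "sites",
                            de_restrict = TRUE,
                            min_length = 200L, max_orf_nt = 300L) {
  stopifnot(r_max < 0, r_min > 0, p_max > 0, p_max <= 1,
            padj_max > 0, padj_max <= 1, score_min >= 0, score_min <= 1)
  structure(list(mirna_fasta = mirna_fasta, mrna_fasta = mrna_fasta,
                 lncrna_fasta = lncrna_fasta, expression = expression,
                 conditions = conditions, annotation = annotation,
                 placements = placements, key_genes = key_genes, trait = trait,
                 outdir = outdir, duplex = duplex,
                 r_max = r_max, r_min = r_min, p_max = p_max,
                 log2fc_min = log2fc_min, padj_max = padj_max, pseudo = pseudo,
                 score_min = score_min, score_mode = score_mode,
                 de_restrict = de_restrict, min_length = min_length,
                 max_orf_nt = max_orf_nt),
            class = "pipeline_config")
}

read_condition_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$condition, tab$sample_id)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full ceRNA inference pipeline
#'
#' Executes annotate -> differential expression -> MRE targeting ->
#' co-expression -> ceRNA network, writing each stage's table, the SIF and
#' GraphML network exports, and a run manifest (parameter echo, input
#' checksums, per-stage feature counts) into `config$outdir`. All stages are
#' deterministic: rerunning on identical inputs reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param verbose print one progress line per stage.
#' @return list with the stage results (`lncrna_classes`, `de`, `mre`,
#'   `interactions`, `triplets`, `network`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  stage <- "input"
  res <- tryCatch({
    for (f in c(config$mirna_fasta, config$mrna_fasta, config$lncrna_fasta,
                config$expression, config$conditions))
      if (!file.exists(f)) stop("missing input file: ", f)
    mirnas <- read_fasta(config$mirna_fasta, biotype = "miRNA")
    mrnas <- read_fasta(config$mrna_fasta, biotype = "mRNA")
    lncs <- read_fasta(config$lncrna_fasta, biotype = "lncRNA_candidate")

    stage <- "annotate"
    flt <- filter_lncrna_candidates(lncs, config$min_length, config$max_orf_nt)
    classes <- rep(NA_character_, nrow(lncs))
    if (!is.null(config$annotation) && !is.null(config$placements)) {
      ann <- read_annotation(config$annotation)
      plc <- utils::read.delim(config$placements, stringsAsFactors = FALSE)
      i <- match(lncs$id, plc$transcript_id)
      placed <- !is.na(i)
      ts <- transcript_set(lncs$id[placed], lncs$seq[placed],
                           biotype = "lncRNA_candidate",
                           chrom = plc$chrom[i[placed]],
                           strand = plc$strand[i[placed]],
                           exon_start = as.list(plc$start[i[placed]]),
                           exon_end = as.list(plc$end[i[placed]]))
      classes[placed] <- classify_positional(ts, ann)
    }
    lnc_table <- cbind(flt, positional_class = classes)
    write_tsv(lnc_table, out("lncrna_classes.tsv"))
    kept_lnc <- lncs[flt$passed_filters, , drop = FALSE]
    say("annotate: %d/%d lncRNA candidates pass filters", nrow(kept_lnc), nrow(lncs))

    stage <- "diffexpr"
    cond <- read_condition_map(config$conditions)
    expr <- read_expression_matrix(config$expression, cond, unit = "RPKM")
    de <- differential_expression(expr, pseudo = config$pseudo,
                                  log2fc_min = config$log2fc_min,
                                  padj_max = config$padj_max)
    write_tsv(de, out("de_table.tsv"))
    say("diffexpr: %d up, %d down of %d features",
        sum(de$status == "up"), sum(de$status == "down"), nrow(de))

    stage <- "targeting"
    mre_lnc <- count_mres(mirnas, kept_lnc, config$duplex)
    mre_mrna <- count_mres(mirnas, mrnas, config$duplex)
    write_tsv(rbind(attr(mre_lnc, "sites"), attr(mre_mrna, "sites")),
              out("mre_sites.tsv"))
    say("targeting: %d miRNA-lncRNA and %d miRNA-mRNA pairs with MREs",
        nrow(mre_lnc), nrow(mre_mrna))

    stage <- "coexpr"
    int_lnc <- mirna_target_interactions(mre_lnc, expr, "lncRNA",
                                         config$r_max, config$p_max)
    int_mrna <- mirna_target_interactions(mre_mrna, expr, "mRNA",
                                          config$r_max, config$p_max)
    write_tsv(rbind(int_lnc, int_mrna), out("interactions.tsv"))
    lm <- lncrna_mrna_pairs(expr, kept_lnc$id, mrnas$id,
                            config$r_min, config$p_max)
    write_tsv(lm, out("lncrna_mrna_pairs.tsv"))
    say("coexpr: %d miRNA-lncRNA, %d miRNA-mRNA, %d lncRNA-mRNA pairs retained",
        nrow(int_lnc), nrow(int_mrna), nrow(lm))

    stage <- "cerna_network"
    de_status <- if (config$de_restrict)
      stats::setNames(de$status, de$feature_id) else NULL
    trip <- assemble_triplets(int_lnc, int_mrna, lm, mre_lnc,
                              score_min = config$score_min,
                              de_status = de_status,
                              score_mode = config$score_mode)
    if (!is.null(config$key_genes)) {
      keys <- readLines(config$key_genes)
      keys <- keys[nzchar(trimws(keys))]
      trip <- suppressWarnings(restrict_to_genes(trip, keys))
    }
    write_tsv(trip, out("triplets.tsv"))
    net <- build_network(trip)
    export_network(net, out("network"))
    write_tsv(data.frame(node = names(net$degree),
                         node_type = net$nodes$node_type,
                         degree = unname(net$degree),
                         is_hub = names(net$degree) %in% net$hubs,
                         stringsAsFactors = FALSE),
              out("degree.tsv"))
    say("network: %d triplets, %d nodes, %d edges; hub %s",
        nrow(trip), nrow(net$nodes), nrow(net$edges), net$primary_hub)

    inputs <- c(config$mirna_fasta, config$mrna_fasta, config$lncrna_fasta,
                config$expression, config$conditions,
                config$annotation, config$placements, config$key_genes)
    par <- unclass(config)[setdiff(names(config), "outdir")]
    par$duplex <- unclass(par$duplex)
    manifest <- list(
      parameters = par,
      input_md5 = as.list(tools::md5sum(inputs)),
      stage_counts = list(
        lncrna_candidates = nrow(lncs), lncrna_pass = nrow(kept_lnc),
        de_up = sum(de$status == "up"), de_down = sum(de$status == "down"),
        mre_pairs_lncrna = nrow(mre_lnc), mre_pairs_mrna = nrow(mre_mrna),
        interactions_lncrna = nrow(int_lnc), interactions_mrna = nrow(int_mrna),
        lncrna_mrna_pairs = nrow(lm), triplets = nrow(trip),
        nodes = nrow(net$nodes), edges = nrow(net$edges)),
      hubs = net$hubs, primary_hub = net$primary_hub)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    list(lncrna_classes = lnc_table, de = de,
         mre = list(lncrna = mre_lnc, mrna = mre_mrna),
         interactions = list(lncrna = int_lnc, mrna = int_mrna,
                             lnc_mrna = lm),
         triplets = trip, network = net, manifest = manifest)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Evaluate reported triplets against planted ground truth
#'
#' Precision is the fraction of reported triplets that were planted. Recall
#' is measured against the *eligible* planted triplets: those whose realised
#' correlations, recomputed from the expression matrix, pass the configured
#' thresholds (miRNA negatively correlated with both members, lncRNA and
#' mRNA positively correlated).
#'
#' @param triplets reported triplet table (lncrna_id, mirna_id, mrna_id).
#' @param truth ground-truth list with `planted_triplets` (e.g. read from the
#'   bundle's truth.json).
#' @param expr `expression_matrix` used by the run.
#' @param r_max,r_min,p_max thresholds as configured for the run.
#' @return list with `precision` (NA when nothing reported), `recall`,
#'   `n_reported`, `n_planted`, `n_eligible`, `n_true_positive`.
#' @export
evaluate_triplets <- function(triplets, truth, expr,
                              r_max = -0.7, r_min = 0.7, p_max = 0.01) {
  key <- function(df) paste(df$lncrna_id, df$mirna_id, df$mrna_id, sep = "\r")
  planted <- as.data.frame(truth$planted_triplets, stringsAsFactors = FALSE)
  miss <- setdiff(unique(unlist(planted[c("lncrna_id", "mirna_id", "mrna_id")])),
                  rownames(expr$values))
  if (length(miss)) stop("planted feature missing from expression matrix: ",
                         miss[1])
  n <- ncol(expr$values)
  pass_neg <- function(a, b) {
    r <- stats::cor(expr$values[a, ], expr$values[b, ])
    r < r_max & cor_pvalue(r, n) < p_max
  }
  pass_pos <- function(a, b) {
    r <- stats::cor(expr$values[a, ], expr$values[b, ])
    r > r_min & cor_pvalue(r, n) < p_max
  }
  eligible <- vapply(seq_len(nrow(planted)), function(i)
    pass_neg(planted$mirna_id[i], planted$lncrna_id[i]) &&
      pass_neg(planted$mirna_id[i], planted$mrna_id[i]) &&
      pass_pos(planted$lncrna_id[i], planted$mrna_id[i]),
    logical(1))
  rep_keys <- key(triplets)
  tp <- length(intersect(rep_keys, key(planted)))
  list(precision = if (length(rep_keys)) tp / length(rep_keys) else NA_real_,
       recall = if (sum(eligible))
         length(intersect(rep_keys, key(planted[eligible, ]))) / sum(eligible)
       else NA_real_,
       n_reported = length(rep_keys), n_planted = nrow(planted),
       n_eligible = sum(eligible), n_true_positive = tp)
}
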