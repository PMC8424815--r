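#' Simulation parameters for the planted-triplet generator
#'
#' Defaults describe the study design the pipeline is built for: a drought
#' experiment with control and treated groups, upregulated miRNAs repressing
#' both a decoy lncRNA and an mRNA target, log-normal expression noise, and
#' near-perfectly complementary plant miRNA sites.
#'
#' @param n_mirna,n_mrna,n_lncrna feature counts (defaults 20/200/50).
#' @param n_planted_triplets planted ceRNA triplets (default 30; at most
#'   `n_mrna`, and the number of distinct miRNAs used is capped by
#'   `min(n_mirna, n_lncrna)`).
#' @param samples_per_condition default 6 per group.
#' @param mirna_len,mrna_len,lncrna_len sequence lengths in nt
#'   (defaults 21/1500/800).
#' @param sites_min,sites_max per-target planted MRE count range (default 1-3).
#' @param beta repression strength: slope of target log2 abundance on the
#'   miRNA's centred log2 abundance (default 1.5).
#' @param sigma log2-scale noise standard deviation (default 0.25).
#' @param mirna_condition_log2fc miRNA upregulation under treatment
#'   (default 2).
#' @param seed RNG seed.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(n_mirna = 20L, n_mrna = 200L, n_lncrna = 50L,
                              n_planted_triplets = 30L,
                              samples_per_condition = 6L,
                              mirna_len = 21L, mrna_len = 1500L,
                              lncrna_len = 800L,
                              sites_min = 1L, sites_max = 3L,
                              beta = 1.5, sigma = 0.25,
                              mirna_condition_log2fc = 2.0, seed = 1L) {
  p <- list(n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
            n_lncrna = as.integer(n_lncrna),
            n_planted_triplets = as.integer(n_planted_triplets),
            samples_per_condition = as.integer(samples_per_condition),
            mirna_len = as.integer(mirna_len), mrna_len = as.integer(mrna_len),
            lncrna_len = as.integer(lncrna_len),
            sites_min = as.integer(sites_min), sites_max = as.integer(sites_max),
            beta = beta, sigma = sigma,
            mirna_condition_log2fc = mirna_condition_log2fc,
            seed = as.integer(seed))
  stopifnot(p$n_mirna > 0, p$n_mrna > 0, p$n_lncrna > 0,
            p$n_planted_triplets >= 0, p$samples_per_condition >= 2,
            p$sites_min >= 1, p$sites_max >= p$sites_min, p$sigma >= 0)
  if (p$n_planted_triplets > p$n_mrna)
    stop("more planted triplets than mRNAs")
  if (p$n_planted_triplets > p$n_mirna * min(p$n_mrna, p$n_lncrna))
    stop("too many planted triplets for the feature counts")
  class(p) <- "simulation_params"
  p
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# triplet layout: one dedicated decoy lncRNA per planted miRNA (the target-
# mimicry pattern); a miRNA reused across triplets keeps its lncRNA and gains
# further mRNAs. Consequently the set of fully supported (L, m, M)
# combinations equals the planted list.
planted_layout <- function(params) {
  n_t <- params$n_planted_triplets
  if (n_t == 0L)
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), stringsAsFactors = FALSE))
  n_u <- min(params$n_mirna, params$n_lncrna, n_t)
  u <- rep_len(seq_len(n_u), n_t)
  data.frame(lncrna_id = sprintf("lnc_%03d", u),
             mirna_id = sprintf("mir_%03d", u),
             mrna_id = sprintf("m_%04d", seq_len(n_t)),
             stringsAsFactors = FALSE)
}

#' Generate synthetic transcript sequences with planted MREs
#'
#' miRNAs and background transcripts are uniform-random; each planted
#' (miRNA, target) pair receives `k` perfect reverse-complement sites
#' (k drawn from `sites_min:sites_max`) at recorded positions separated by
#' more than twice the miRNA length. Fully reproducible from the seed.
#'
#' @param params a [simulation_params()].
#' @return list with `mirnas`, `mrnas`, `lncrnas` ([transcript_set()]s) and
#'   `truth` (planted triplets and sites).
#' @export
generate_sequences <- function(params) {
  set.seed(params$seed)
  trip <- planted_layout(params)
  mirna_ids <- sprintf("mir_%03d", seq_len(params$n_mirna))
  mrna_ids <- sprintf("m_%04d", seq_len(params$n_mrna))
  lnc_ids <- sprintf("lnc_%03d", seq_len(params$n_lncrna))
  mirna_seq <- stats::setNames(
    vapply(mirna_ids, function(i) rand_seq(params$mirna_len), ""), mirna_ids)
  mrna_seq <- stats::setNames(
    vapply(mrna_ids, function(i) rand_seq(params$mrna_len), ""), mrna_ids)
  lnc_seq <- stats::setNames(
    vapply(lnc_ids, function(i) rand_seq(params$lncrna_len), ""), lnc_ids)
  pairs <- unique(rbind(
    data.frame(mirna_id = trip$mirna_id, target_id = trip$lncrna_id,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = trip$mirna_id, target_id = trip$mrna_id,
               stringsAsFactors = FALSE)))
  sites <- list()
  for (k in seq_len(nrow(pairs))) {
    m <- pairs$mirna_id[k]; t <- pairs$target_id[k]
    is_lnc <- t %in% lnc_ids
    tlen <- if (is_lnc) params$lncrna_len else params$mrna_len
    n_sites <- sample(params$sites_min:params$sites_max, 1L)
    block <- tlen %/% n_sites
    if (block < 2L * params$mirna_len + 1L)
      stop("transcript too short for ", n_sites, " sites: ", t)
    offs <- sample.int(block - 2L * params$mirna_len, n_sites, replace = TRUE)
    starts <- (seq_len(n_sites) - 1L) * block + offs
    site_seq <- reverse_complement(mirna_seq[[m]])
    for (s in starts) {
      if (is_lnc) substr(lnc_seq[[t]], s, s + params$mirna_len - 1L) <- site_seq
      else substr(mrna_seq[[t]], s, s + params$mirna_len - 1L) <- site_seq
    }
    sites[[k]] <- data.frame(mirna_id = m, target_id = t, target_start = starts,
                             stringsAsFactors = FALSE)
  }
  truth <- list(planted_triplets = trip,
                planted_sites = if (length(sites)) do.call(rbind, sites) else
                  data.frame(mirna_id = character(0), target_id = character(0),
                             target_start = integer(0), stringsAsFactors = FALSE))
  list(mirnas = transcript_set(mirna_ids, unname(mirna_seq), biotype = "miRNA"),
       mrnas = transcript_set(mrna_ids, unname(mrna_seq), biotype = "mRNA"),
       lncrnas = transcript_set(lnc_ids, unname(lnc_seq),
                                biotype = "lncRNA_candidate"),
       truth = truth)
}

#' Generate synthetic expression with planted repression
#'
#' Planted miRNAs are upregulated under treatment; each planted target's
#' log2 abundance follows `baseline - beta * (centred miRNA log2)` plus
#' noise, which induces negative miRNA-target and positive lncRNA-mRNA
#' correlations. Background features carry noise only. A trait vector is a
#' linear function of the first planted triplet's mRNA abundance plus noise.
#'
#' @param params a [simulation_params()].
#' @param truth the `truth` element returned by [generate_sequences()].
#' @return list with `expr` (an `expression_matrix`, unit RPKM), `trait`
#'   (named numeric vector) and `truth` completed with `true_de` and
#'   `trait_mrna`.
#' @export
generate_expression <- function(params, truth) {
  set.seed(params$seed + 1L)
  n_s <- 2L * params$samples_per_condition
  sample_ids <- sprintf("S%02d", seq_len(n_s))
  condition <- stats::setNames(
    rep(c("control", "treated"), each = params$samples_per_condition), sample_ids)
  treated <- condition == "treated"
  mirna_ids <- sprintf("mir_%03d", seq_len(params$n_mirna))
  mrna_ids <- sprintf("m_%04d", seq_len(params$n_mrna))
  lnc_ids <- sprintf("lnc_%03d", seq_len(params$n_lncrna))
  feats <- c(mirna_ids, mrna_ids, lnc_ids)
  trip <- truth$planted_triplets
  planted_mir <- unique(trip$mirna_id)
  planted_tgt <- unique(c(trip$lncrna_id, trip$mrna_id))
  baseline <- stats::setNames(stats::runif(length(feats), 5, 9), feats)
  log2v <- matrix(NA_real_, length(feats), n_s, dimnames = list(feats, sample_ids))
  # miRNAs first: planted targets are driven by their miRNA's realised values
  for (f in mirna_ids) {
    eff <- if (f %in% planted_mir) params$mirna_condition_log2fc * treated else 0
    log2v[f, ] <- baseline[f] + eff + stats::rnorm(n_s, 0, params$sigma)
  }
  mir_of_target <- c(stats::setNames(trip$mirna_id, trip$lncrna_id),
                     stats::setNames(trip$mirna_id, trip$mrna_id))
  for (f in c(mrna_ids, lnc_ids)) {
    if (f %in% planted_tgt) {
      m <- log2v[mir_of_target[[f]], ]
      log2v[f, ] <- baseline[f] - params$beta * (m - mean(m)) +
        stats::rnorm(n_s, 0, params$sigma)
    } else {
      log2v[f, ] <- baseline[f] + stats::rnorm(n_s, 0, params$sigma)
    }
  }
  values <- 2^log2v
  true_de <- stats::setNames(rep("ns", length(feats)), feats)
  true_de[planted_mir] <- "up"
  true_de[planted_tgt] <- "down"
  trait_mrna <- if (nrow(trip)) trip$mrna_id[1] else NA_character_
  trait <- if (!is.na(trait_mrna)) {
    v <- values[trait_mrna, ]
    0.02 * v + stats::rnorm(n_s, 0, 0.02 * max(stats::sd(v), 1e-12))
  } else stats::setNames(stats::rnorm(n_s), sample_ids)
  truth$true_de <- true_de
  truth$trait_mrna <- trait_mrna
  list(expr = expression_matrix(values, condition, unit = "RPKM"),
       trait = stats::setNames(as.numeric(trait), sample_ids),
       truth = truth)
}

# toy single-chromosome gene models so positional classification is
# exercised: lncRNA j is planted intronic / antisense / intergenic in turn
# relative to gene ((j - 1) mod n_genes) + 1
synthetic_annotation <- function(params) {
  n_g <- params$n_mrna
  g0 <- (seq_len(n_g) - 1L) * 10000L + 1L
  genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(n_g)),
                      chrom = "chr1", strand = "+",
                      start = g0, end = g0 + 3999L, stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(n_g), function(i)
    data.frame(gene_id = genes$gene_id[i], transcript_id = sprintf("m_%04d", i),
               chrom = "chr1", strand = "+",
               start = g0[i] + c(0L, 1500L, 3000L),
               end = g0[i] + c(499L, 2499L, 3999L), stringsAsFactors = FALSE)))
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

synthetic_lncrna_placements <- function(params) {
  j <- seq_len(params$n_lncrna)
  gi <- ((j - 1L) %% params$n_mrna) + 1L
  g0 <- (gi - 1L) * 10000L + 1L
  cls <- c("intronic", "antisense", "intergenic")[((j - 1L) %% 3L) + 1L]
  start <- ifelse(cls == "intronic", g0 + 600L,
                  ifelse(cls == "antisense", g0 + 100L, g0 + 6000L))
  len <- min(params$lncrna_len, 800L)
  data.frame(transcript_id = sprintf("lnc_%03d", j), chrom = "chr1",
             strand = ifelse(cls == "antisense", "-", "+"),
             start = start, end = start + len - 1L,
             planted_class = cls, stringsAsFactors = FALSE)
}

#' Write the full synthetic fixture bundle
#'
#' Writes FASTA files per biotype, a toy GTF annotation, lncRNA genomic
#' placements, the expression matrix, condition labels, the trait vector and
#' the ground truth (JSON) into `outdir`.
#'
#' @param params a [simulation_params()].
#' @param outdir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
synth_bundle <- function(params, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seqs <- generate_sequences(params)
  ge <- generate_expression(params, seqs$truth)
  p <- function(f) file.path(outdir, f)
  write_fasta(seqs$mirnas, p("mirna.fasta"))
  write_fasta(seqs$mrnas, p("mrna.fasta"))
  write_fasta(seqs$lncrnas, p("lncrna.fasta"))
  write_annotation_gtf(synthetic_annotation(params), p("annotation.gtf"))
  plc <- synthetic_lncrna_placements(params)
  utils::write.table(plc, p("lncrna_placements.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression_matrix(ge$expr, p("expression.tsv"))
  utils::write.table(
    data.frame(sample_id = names(ge$expr$condition),
               condition = unname(ge$expr$condition)),
    p("conditions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(ge$trait), trait = unname(ge$trait)),
    p("trait.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth_json <- ge$truth
  truth_json$true_de <- as.list(truth_json$true_de)  # keep feature names
  jsonlite::write_json(truth_json, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(mirna = p("mirna.fasta"), mrna = p("mrna.fasta"),
              lncrna = p("lncrna.fasta"), annotation = p("annotation.gtf"),
              placements = p("lncrna_placements.tsv"),
              expression = p("expression.tsv"), conditions = p("conditions.tsv"),
              trait = p("trait.tsv"), truth = p("truth.json")))
}
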