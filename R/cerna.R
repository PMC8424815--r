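#' ceRNA score of an lncRNA-mRNA pair
#'
#' Fraction of the lncRNA's miRNA response elements attributable to miRNAs
#' shared with the mRNA:
#' `score = (MREs on the lncRNA for shared miRNAs) / (all MREs on the lncRNA)`.
#'
#' Two readings of the numerator are supported. The default, `"sites"`,
#' weights by MRE site counts; `"species"` counts each shared miRNA once and
#' divides by the number of distinct miRNAs with sites on the lncRNA.
#'
#' @param lnc_mre_counts named integer vector: miRNA id -> number of MRE
#'   sites on the lncRNA. Must be non-empty.
#' @param shared_mirnas character vector of miRNA ids shared with the mRNA
#'   (subset of `names(lnc_mre_counts)`, possibly empty).
#' @param mode `"sites"` (default) or `"species"`.
#' @return score in `[0, 1]`.
#' @export
cerna_score <- function(lnc_mre_counts, shared_mirnas, mode = c("sites", "species")) {
  mode <- match.arg(mode)
  if (length(lnc_mre_counts) == 0L) stop("lncRNA has no MREs")
  shared_mirnas <- intersect(shared_mirnas, names(lnc_mre_counts))
  if (mode == "sites")
    sum(lnc_mre_counts[shared_mirnas]) / sum(lnc_mre_counts)
  else
    length(shared_mirnas) / length(lnc_mre_counts)
}

#' Assemble lncRNA-miRNA-mRNA ceRNA triplets
#'
#' A triplet (L, m, M) is emitted iff the miRNA m has a retained interaction
#' with both the lncRNA L and the mRNA M, L and M are positively
#' co-expressed, the ceRNA score of the (L, M) pair is at least `score_min`,
#' and (when DE status is supplied) all three members are deregulated.
#' Output is deduplicated and sorted lexicographically by (L, m, M).
#'
#' @param mir_lnc,mir_mrna interaction tables from
#'   [mirna_target_interactions()] for lncRNA and mRNA targets.
#' @param lnc_mrna pair table from [lncrna_mrna_pairs()].
#' @param lnc_mre_counts MRE count table for lncRNA targets (from
#'   [count_mres()]), used for the ceRNA score denominator.
#' @param score_min minimum ceRNA score (default 0.5).
#' @param de_status optional named character vector feature -> status
#'   (`up`/`down`/`ns`); triplets with any `ns` member are dropped.
#' @param score_mode passed to [cerna_score()].
#' @return data frame: lncrna_id, mirna_id, mrna_id, cerna_score,
#'   lnc_mrna_pcc, mir_lnc_pcc, mir_mrna_pcc.
#' @export
assemble_triplets <- function(mir_lnc, mir_mrna, lnc_mrna, lnc_mre_counts,
                              score_min = 0.5, de_status = NULL,
                              score_mode = "sites") {
  empty <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), cerna_score = numeric(0),
                      lnc_mrna_pcc = numeric(0), mir_lnc_pcc = numeric(0),
                      mir_mrna_pcc = numeric(0), stringsAsFactors = FALSE)
  if (nrow(mir_lnc) == 0L || nrow(mir_mrna) == 0L || nrow(lnc_mrna) == 0L)
    return(empty)
  counts_of <- split(stats::setNames(lnc_mre_counts$mre_count,
                                     lnc_mre_counts$mirna_id),
                     lnc_mre_counts$target_id)
  mir_of_lnc <- split(seq_len(nrow(mir_lnc)), mir_lnc$target_id)
  mir_of_mrna <- split(seq_len(nrow(mir_mrna)), mir_mrna$target_id)
  rows <- list()
  for (k in seq_len(nrow(lnc_mrna))) {
    L <- lnc_mrna$lncrna_id[k]; M <- lnc_mrna$mrna_id[k]
    iL <- mir_of_lnc[[L]]; iM <- mir_of_mrna[[M]]
    if (is.null(iL) || is.null(iM)) next
    shared <- intersect(mir_lnc$mirna_id[iL], mir_mrna$mirna_id[iM])
    if (length(shared) == 0L) next
    sc <- cerna_score(counts_of[[L]], shared, mode = score_mode)
    if (sc < score_min) next
    for (m in shared) {
      if (!is.null(de_status)) {
        st <- de_status[c(L, m, M)]
        if (any(is.na(st)) || any(st == "ns")) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = L, mirna_id = m, mrna_id = M, cerna_score = sc,
        lnc_mrna_pcc = lnc_mrna$pcc[k],
        mir_lnc_pcc = mir_lnc$pcc[iL][match(m, mir_lnc$mirna_id[iL])],
        mir_mrna_pcc = mir_mrna$pcc[iM][match(m, mir_mrna$mirna_id[iM])],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict triplets to a curated key-gene list
#'
#' @param triplets triplet table from [assemble_triplets()].
#' @param key_genes character vector of mRNA ids to keep.
#' @return filtered triplet table; warns on key genes absent from any triplet.
#' @export
restrict_to_genes <- function(triplets, key_genes) {
  absent <- setdiff(key_genes, triplets$mrna_id)
  if (length(absent))
    warning(length(absent), " key gene(s) absent from any triplet, e.g. ",
            absent[1])
  out <- triplets[triplets$mrna_id %in% key_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the tripartite ceRNA network
#'
#' Nodes are the union of triplet members typed lncRNA/miRNA/mRNA; edges are
#' miRNA->lncRNA and miRNA->mRNA "targets" edges and lncRNA-mRNA "competes"
#' edges, deduplicated across triplets. The hub set contains every node of
#' maximal degree; the primary hub is the lexicographically smallest of them.
#'
#' @param triplets triplet table from [assemble_triplets()].
#' @return list of class `cerna_network`: `nodes` (id, node_type), `edges`
#'   (from, to, relation, pcc, cerna_score), `degree` (named integer),
#'   `hubs`, `primary_hub`, and the underlying igraph object in `$graph`.
#' @export
build_network <- function(triplets) {
  n_t <- nrow(triplets)
  nodes <- unique(rbind(
    data.frame(id = triplets$lncrna_id, node_type = rep_len("lncRNA", n_t),
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mirna_id, node_type = rep_len("miRNA", n_t),
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mrna_id, node_type = rep_len("mRNA", n_t),
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  if (anyDuplicated(nodes$id))
    stop("node id used with more than one type: ",
         nodes$id[duplicated(nodes$id)][1])
  edges <- unique(rbind(
    data.frame(from = triplets$mirna_id, to = triplets$lncrna_id,
               relation = rep_len("targets", n_t), pcc = triplets$mir_lnc_pcc,
               cerna_score = rep_len(NA_real_, n_t), stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
               relation = rep_len("targets", n_t), pcc = triplets$mir_mrna_pcc,
               cerna_score = rep_len(NA_real_, n_t), stringsAsFactors = FALSE),
    data.frame(from = triplets$lncrna_id, to = triplets$mrna_id,
               relation = rep_len("competes", n_t), pcc = triplets$lnc_mrna_pcc,
               cerna_score = triplets$cerna_score, stringsAsFactors = FALSE)))
  edges <- edges[!duplicated(edges[, c("from", "to", "relation")]), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  deg <- igraph::degree(g)
  hubs <- if (length(deg)) sort(names(deg)[deg == max(deg)]) else character(0)
  structure(list(nodes = nodes, edges = edges,
                 degree = deg[nodes$id], hubs = hubs,
                 primary_hub = if (length(hubs)) hubs[1] else NA_character_,
                 graph = g),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tt <- table(factor(x$nodes$node_type, c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf("cerna_network: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
              nrow(x$nodes), tt[1], tt[2], tt[3], nrow(x$edges)))
  if (!is.na(x$primary_hub))
    cat(sprintf("hub: %s (degree %d)\n", x$primary_hub,
                x$degree[[x$primary_hub]]))
  invisible(x)
}

#' Export a ceRNA network for Cytoscape
#'
#' Writes `<prefix>.sif` (one line per edge, relation tokens `targets` and
#' `competes`) and `<prefix>.graphml` with node attribute `node_type` and
#' edge attributes `relation`, `pcc` and, on competes edges, `cerna_score`.
#'
#' @param network a `cerna_network`.
#' @param path_prefix output path prefix.
#' @return paths of the two files, invisibly.
#' @export
export_network <- function(network, path_prefix) {
  sif <- paste0(path_prefix, ".sif")
  gml <- paste0(path_prefix, ".graphml")
  e <- network$edges
  writeLines(if (nrow(e)) paste(e$from, e$relation, e$to, sep = "\t")
             else character(0), sif)
  igraph::write_graph(network$graph, gml, format = "graphml")
  invisible(c(sif = sif, graphml = gml))
}
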