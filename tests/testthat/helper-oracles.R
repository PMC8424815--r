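# Independent brute-force oracles used to check the package's optimised
# implementations. These deliberately reimplement each computation in the
# most literal way possible and share no code with R/.

# longest ATG-initiated, stop-terminated ORF by scanning every start position
oracle_longest_orf <- function(seq) {
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  best <- 0L
  for (s in seq_len(max(0L, n - 2L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    pos <- s
    while (pos + 5L <= n) {
      pos <- pos + 3L
      cod <- substr(seq, pos, pos + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, pos + 2L - s + 1L)
        break
      }
    }
  }
  best
}

# per-position duplex penalty, written out literally
oracle_duplex_penalty <- function(mirna, window, params = duplex_params()) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mi <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  wd <- strsplit(chartr("U", "T", toupper(window)), "")[[1]]
  L <- length(mi)
  total <- 0
  for (i in seq_len(L)) {
    tb <- wd[L - i + 1L]
    pen <- if (!is.na(comp[mi[i]]) && comp[mi[i]] == tb) 0
    else if ((mi[i] == "G" && tb == "T") || (mi[i] == "T" && tb == "G"))
      params$gu_penalty
    else params$mismatch_penalty
    if (i %in% params$seed_range) pen <- pen * params$seed_multiplier
    total <- total + pen
  }
  total
}

# exhaustive MRE scan: every window scored via the literal penalty above,
# then the same greedy non-overlap rule applied step by step
oracle_find_sites <- function(mirna, target, params = duplex_params()) {
  L <- nchar(mirna); N <- nchar(target)
  if (N < L) return(integer(0))
  pen <- vapply(seq_len(N - L + 1L), function(s)
    oracle_duplex_penalty(mirna, substr(target, s, s + L - 1L), params),
    numeric(1))
  cand <- which(pen <= params$max_penalty)
  cand <- cand[order(pen[cand], cand)]
  sep <- params$min_site_separation - 1L
  kept <- integer(0)
  for (s in cand) {
    ok <- TRUE
    for (k in kept)
      if (!(s + L - 1L + sep < k || s > k + L - 1L + sep)) ok <- FALSE
    if (ok) kept <- c(kept, s)
  }
  sort(kept)
}

# Pearson r and p from raw sums and the t formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / n
  den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
  r <- num / den
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(r = r, pvalue = p)
}

# hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# exhaustive triplet enumeration applying every predicate to all
# (lncRNA, miRNA, mRNA) combinations
oracle_triplets <- function(mir_lnc, mir_mrna, lnc_mrna, lnc_mre_counts,
                            score_min = 0.5, de_status = NULL,
                            score_mode = "sites") {
  Ls <- unique(lnc_mrna$lncrna_id)
  Ms <- unique(lnc_mrna$mrna_id)
  ms <- unique(c(mir_lnc$mirna_id, mir_mrna$mirna_id))
  out <- list()
  for (L in Ls) for (m in ms) for (M in Ms) {
    if (!any(mir_lnc$mirna_id == m & mir_lnc$target_id == L)) next
    if (!any(mir_mrna$mirna_id == m & mir_mrna$target_id == M)) next
    if (!any(lnc_mrna$lncrna_id == L & lnc_mrna$mrna_id == M)) next
    shared <- intersect(mir_lnc$mirna_id[mir_lnc$target_id == L],
                        mir_mrna$mirna_id[mir_mrna$target_id == M])
    cnt <- lnc_mre_counts[lnc_mre_counts$target_id == L, ]
    sc <- if (score_mode == "sites")
      sum(cnt$mre_count[cnt$mirna_id %in% shared]) / sum(cnt$mre_count)
    else length(intersect(shared, cnt$mirna_id)) / nrow(cnt)
    if (sc < score_min) next
    if (!is.null(de_status) &&
        (any(is.na(de_status[c(L, m, M)])) ||
         any(de_status[c(L, m, M)] == "ns"))) next
    out[[length(out) + 1L]] <- c(L, m, M)
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "|"))
}

# brute-force degree: count incident edges per node from the edge table
oracle_degree <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  vapply(nodes, function(v) sum(edges$from == v) + sum(edges$to == v),
         integer(1))
}

# tiny deterministic interaction fixture shared by coexpr/cerna tests:
# expression profiles with planted sign structure across 12 samples
make_toy_expr <- function(seed = 42) {
  set.seed(seed)
  n <- 12
  cond <- stats::setNames(rep(c("control", "treated"), each = 6),
                          sprintf("S%02d", 1:n))
  drive <- rep(c(0, 2), each = 6) + rnorm(n, 0, 0.2)
  v <- rbind(
    mirX = 2^(6 + drive),
    lncA = 2^(7 - 1.5 * (drive - mean(drive)) + rnorm(n, 0, 0.2)),
    geneB = 2^(6.5 - 1.5 * (drive - mean(drive)) + rnorm(n, 0, 0.2)),
    geneC = 2^(6 + rnorm(n, 0, 0.3)))
  colnames(v) <- names(cond)
  expression_matrix(v, cond, unit = "RPKM")
}
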