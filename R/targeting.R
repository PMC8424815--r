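#' Duplex scoring parameters
#'
#' Parameters of the plant-style complementarity penalty used to call miRNA
#' response elements (MREs). Plant miRNA:target duplexes are near-perfectly
#' complementary, so an ungapped per-position penalty is used: a Watson-Crick
#' pair costs 0, a G:U wobble `gu_penalty`, anything else `mismatch_penalty`;
#' penalties at miRNA positions inside `seed_range` (counted from the miRNA
#' 5' end) are multiplied by `seed_multiplier`. A window is a site when its
#' total penalty is at most `max_penalty`.
#'
#' @param max_penalty site-acceptance cutoff (default 4).
#' @param seed_range integer vector of 1-based miRNA positions forming the
#'   seed/central region (default 2:13).
#' @param mismatch_penalty cost per mismatched position (default 1).
#' @param gu_penalty cost per G:U wobble (default 0.5).
#' @param seed_multiplier penalty multiplier inside the seed (default 2).
#' @param min_site_separation minimum spacing in nt between retained sites;
#'   1 means sites may touch but not overlap.
#' @return list of class `duplex_params`.
#' @export
duplex_params <- function(max_penalty = 4.0, seed_range = 2:13,
                          mismatch_penalty = 1.0, gu_penalty = 0.5,
                          seed_multiplier = 2.0, min_site_separation = 1L) {
  stopifnot(max_penalty >= 0, mismatch_penalty >= 0, gu_penalty >= 0,
            seed_multiplier >= 0, min_site_separation >= 1,
            all(seed_range >= 1))
  structure(list(max_penalty = max_penalty, seed_range = as.integer(seed_range),
                 mismatch_penalty = mismatch_penalty, gu_penalty = gu_penalty,
                 seed_multiplier = seed_multiplier,
                 min_site_separation = as.integer(min_site_separation)),
            class = "duplex_params")
}

# base encoding A=1 C=2 G=3 T=4, anything else (N) = 5
encode_seq <- function(seq) {
  seq <- toupper(chartr("U", "T", seq))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  x <- code[strsplit(seq, "", fixed = TRUE)[[1]]]
  x[is.na(x)] <- 5L
  x
}

# 5x5 penalty class matrix: 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch.
# Row = miRNA base, column = target base (both in mRNA sense).
pair_class_matrix <- function() {
  m <- matrix(2L, 5, 5)
  m[1, 4] <- 0L  # A:U(T)
  m[4, 1] <- 0L  # U(T):A
  m[2, 3] <- 0L  # C:G
  m[3, 2] <- 0L  # G:C
  m[3, 4] <- 1L  # G:U wobble
  m[4, 3] <- 1L  # U:G wobble
  m
}

position_weights <- function(len, params) {
  w <- rep(1, len)
  sr <- params$seed_range[params$seed_range <= len]
  w[sr] <- params$seed_multiplier
  w
}

#' Score one miRNA:target duplex window
#'
#' The miRNA (5' to 3') is aligned against the target window read from its
#' 3' end inward, i.e. miRNA position `i` pairs with window base
#' `L - i + 1`, the antiparallel geometry of a miRNA bound to its site.
#'
#' @param mirna_seq miRNA sequence (length L).
#' @param target_window target subsequence of the same length, mRNA sense.
#' @param params a [duplex_params()].
#' @return list with `penalty` and `pairing` — a string of one symbol per
#'   miRNA position, 5' to 3': `|` Watson-Crick match, `o` G:U wobble,
#'   `x` mismatch.
#' @export
score_duplex <- function(mirna_seq, target_window, params = duplex_params()) {
  mi <- encode_seq(mirna_seq)
  tg <- encode_seq(target_window)
  if (length(mi) != length(tg)) stop("miRNA and window lengths differ")
  L <- length(mi)
  cls <- pair_class_matrix()[cbind(mi, rev(tg))]
  per_pos <- c(0, params$gu_penalty, params$mismatch_penalty)[cls + 1L]
  per_pos <- per_pos * position_weights(L, params)
  list(penalty = sum(per_pos),
       pairing = paste(c("|", "o", "x")[cls + 1L], collapse = ""))
}

#' Find miRNA response elements on a target transcript
#'
#' Slides a window of miRNA length along the target (step 1 nt), keeps
#' windows whose duplex penalty is at most `max_penalty`, and resolves
#' overlapping candidates greedily by ascending penalty (ties broken by
#' smaller start).
#'
#' @param mirna_seq miRNA sequence.
#' @param target_seq target transcript sequence (mRNA sense; only this sense
#'   is scanned).
#' @param params a [duplex_params()].
#' @return data frame: target_start (1-based, 5'-most target base of the
#'   site), penalty, pairing; sorted by target_start. Zero rows when the
#'   target is shorter than the miRNA (with a warning) or no window passes.
#' @export
find_mre_sites <- function(mirna_seq, target_seq, params = duplex_params()) {
  empty <- data.frame(target_start = integer(0), penalty = numeric(0),
                      pairing = character(0), stringsAsFactors = FALSE)
  mi <- encode_seq(mirna_seq)
  tg <- encode_seq(target_seq)
  L <- length(mi); N <- length(tg)
  if (N < L) {
    warning("target shorter than miRNA; no sites")
    return(empty)
  }
  pen <- site_penalties(mi, tg, params)
  cand <- which(pen <= params$max_penalty)
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(pen[cand], cand)]
  sep <- params$min_site_separation - 1L
  kept <- integer(0)
  for (s in cand) {
    if (!length(kept) ||
        all(s + L - 1L + sep < kept | s > kept + L - 1L + sep))
      kept <- c(kept, s)
  }
  kept <- sort(kept)
  pairing <- vapply(kept, function(s)
    score_duplex(mirna_seq, substr(target_seq, s, s + L - 1L), params)$pairing,
    character(1))
  data.frame(target_start = kept, penalty = pen[kept], pairing = pairing,
             stringsAsFactors = FALSE)
}

# penalty of every window start, vectorised over the target
site_penalties <- function(mi, tg, params) {
  L <- length(mi); N <- length(tg)
  n_win <- N - L + 1L
  cls_m <- pair_class_matrix()
  pen_of_class <- c(0, params$gu_penalty, params$mismatch_penalty)
  w <- position_weights(L, params)
  pen <- numeric(n_win)
  for (i in seq_len(L)) {
    idx <- seq_len(n_win) + (L - i)
    pen <- pen + w[i] * pen_of_class[cls_m[mi[i], tg[idx]] + 1L]
  }
  pen
}

#' Count MREs for every miRNA x target pair
#'
#' @param mirnas [transcript_set()] of miRNAs.
#' @param targets [transcript_set()] of candidate targets (mRNA or lncRNA).
#' @param params a [duplex_params()].
#' @return data frame: mirna_id, target_id, mre_count (pairs with zero sites
#'   are omitted), plus a `sites` attribute holding the full per-site table.
#' @export
count_mres <- function(mirnas, targets, params = duplex_params()) {
  rows <- list()
  site_rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(targets))) {
      if (nchar(targets$seq[j]) < nchar(mirnas$seq[i])) next
      s <- find_mre_sites(mirnas$seq[i], targets$seq[j], params)
      if (nrow(s) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mirnas$id[i], target_id = targets$id[j], mre_count = nrow(s),
        stringsAsFactors = FALSE)
      site_rows[[length(site_rows) + 1L]] <- cbind(
        data.frame(mirna_id = mirnas$id[i], target_id = targets$id[j],
                   stringsAsFactors = FALSE), s)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), target_id = character(0),
               mre_count = integer(0), stringsAsFactors = FALSE)
  attr(out, "sites") <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(mirna_id = character(0), target_id = character(0),
               target_start = integer(0), penalty = numeric(0),
               pairing = character(0), stringsAsFactors = FALSE)
  out
}
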