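---
title: "Inferring lncRNA-mediated ceRNA networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-mediated ceRNA networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Under the competing endogenous RNA (ceRNA) hypothesis, a long non-coding RNA
(lncRNA) that carries miRNA response elements (MREs) can sequester a miRNA —
acting as an endogenous target mimic — and thereby de-repress the miRNA's
mRNA targets. In plants under abiotic stress this produces a characteristic
signature: the miRNA is deregulated in one direction, the lncRNA decoy and
the protected mRNA move together in the other, and all three share sequence
complementarity to the same miRNA. `ceRNAnet` infers lncRNA–miRNA–mRNA
triplets showing exactly this signature from three inputs: transcript
sequences, a gene annotation, and a features-by-samples expression matrix
with control/treated condition labels.

The inference chain is:

1. **lncRNA candidate filtering and classification** — keep transcripts
   strictly longer than 200 bp whose longest ATG-initiated open reading
   frame is below 300 nt, and classify each relative to annotated genes as
   intronic, antisense, or intergenic.
2. **Differential expression** — call up/down/ns per feature at
   adjusted *p* < 0.05 and |log2FC| > 1.
3. **MRE prediction** — scan every miRNA against every mRNA and retained
   lncRNA with an ungapped complementarity penalty.
4. **Signed co-expression** — retain miRNA–target pairs with Pearson
   *r* < −0.7 and *p* < 0.01, and lncRNA–mRNA pairs with *r* > 0.7 and
   *p* < 0.01, all strict inequalities, across all samples pooled.
5. **ceRNA scoring and triplet assembly** — a triplet (L, m, M) requires the
   miRNA m to target both L and M with co-expression support, L and M to be
   positively co-expressed, a ceRNA score at or above its cutoff, and (by
   default) all three members deregulated.
6. **Network analysis** — build the tripartite graph, compute degrees,
   report every node of maximal degree as a hub.

## MRE prediction: the penalty model

Plant miRNA:target duplexes are near-perfectly complementary, so the scanner
uses an ungapped per-position penalty rather than a thermodynamic model. The
miRNA (5′→3′) is aligned antiparallel against each target window of its own
length: miRNA position $i$ pairs with window base $L - i + 1$. Each position
contributes

* 0 for a Watson–Crick pair,
* `gu_penalty` (default 0.5) for a G:U wobble,
* `mismatch_penalty` (default 1.0) otherwise,

and positions 2–13 of the miRNA — the seed and central region whose pairing
determines cleavage in plants — have their contribution multiplied by
`seed_multiplier` (default 2). A window is a site when its total penalty is
at most `max_penalty` (default 4.0); overlapping candidate sites are
resolved greedily by ascending penalty, ties by smaller start, which makes
the output deterministic and independent of scan order. These defaults
follow the widely used plant target-prediction rule family (few mismatches,
wobbles half-penalised, central region weighted double). All parameters are
exposed through `duplex_params()`.

Gapped alignments (bulges) are deliberately not modelled: they are rare in
functional plant duplexes and excluding them keeps the scanner exactly
verifiable against an exhaustive window enumeration, which the test suite
exploits.

## The ceRNA score

For an lncRNA–mRNA pair sharing at least one targeting miRNA, the score is
the fraction of the lncRNA's MREs attributable to the shared miRNAs:

$$\mathrm{score}(L, M) \;=\;
\frac{\#\{\text{MREs on } L \text{ for miRNAs shared with } M\}}
     {\#\{\text{all MREs on } L\}} \in [0, 1].$$

The score is 1 when every MRE on the lncRNA belongs to a shared miRNA and 0
when none does, and it is monotone non-decreasing as the shared set grows.
The numerator admits two readings: counting MRE *sites* (the default,
`score_mode = "sites"`) or counting miRNA *species*
(`score_mode = "species"`). Both are defensible; site counting is the
default because the degree of sequestration scales with the number of
binding sites, not just the number of distinct miRNAs. The assembly cutoff
`score_min` defaults to 0.5 — a pair qualifies when at least half of the
lncRNA's MRE burden is shared with the mRNA — and is configurable because
the score can equally be used for ranking only (`score_min = 0`).

## Statistical choices

**Differential expression.** The test is a two-sided Welch *t*-test on
`log2(x + pseudo)` with a pseudo-count of 1, followed by Benjamini–Hochberg
adjustment. The log transform makes the abundance noise approximately
normal and the Welch form drops the equal-variance assumption. The
zero-variance degenerate case (constant groups, as in noise-free
simulations) is resolved analytically: *p* = 0 when the group means differ,
1 when they coincide. The fold-change cutoff is applied two-sided
(|log2FC| > 1) since both up- and down-regulated sets feed the network.

**Correlation.** Pearson *r* with the exact *t* formula
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, two-sided;
$|r| = 1$ maps to *p* = 0. Correlations are computed on the expression
values as given, across all samples with conditions pooled: with typical
designs of 3–6 replicates per condition, pooling is the only way the
*p* < 0.01 threshold is attainable at all. At *n* = 6 samples, *p* < 0.01
already requires $|r| \gtrsim 0.92$ — considerably stricter than the
|r| > 0.7 cutoff, which is why the simulated design defaults to 6 + 6
samples (at *n* = 12, *p* < 0.01 corresponds to $|r| \approx 0.71$, making
the two cutoffs congruent). All thresholds are strict inequalities; a pair
sitting exactly on a cutoff is excluded.

## The synthetic study design

`simulation_params()` defaults encode the study conditions the pipeline
targets: 20 miRNAs (21 nt), 200 mRNAs (1500 nt), 50 lncRNA candidates
(800 nt), 30 planted triplets, 6 control + 6 treated samples, miRNA
treatment effect +2 on the log2 scale, repression slope β = 1.5, and
log2-scale noise σ = 0.25.

**Sequences.** Backgrounds are uniform-random; each planted (miRNA, target)
pair receives 1–3 perfect reverse-complement sites at recorded positions
spaced more than twice the miRNA length apart. Perfect complementarity
makes the exhaustive scanner oracle exact, and a random 21-mer essentially
never passes the penalty cutoff by chance, so sequence false positives are
negligible.

**Triplet layout.** Each decoy lncRNA is dedicated to a single miRNA — the
endogenous-target-mimic pattern, in which a decoy evolves complementarity
to one miRNA family. A miRNA reused across planted triplets keeps its one
lncRNA and gains additional mRNA targets. This matters for evaluation: it
makes the transitive closure of planted pairs coincide with the planted
list, so precision against the planted list is a meaningful quantity. If
decoys were scattered across miRNAs independently, unplanted but fully
supported combinations would arise by construction and no inference method
could score high precision against the planted list.

**Expression.** Log2 abundances: planted miRNAs get
`baseline + 2·1[treated] + N(0, σ)`; each planted target follows
`baseline − β·(its miRNA's centred log2 abundance) + N(0, σ)`, so the
shared repressor induces the negative miRNA–target and positive
lncRNA–mRNA correlations the pipeline screens for; background features are
baseline plus noise. Baselines are uniform on log2 ∈ [5, 9]. Abundances are
exponentiated to a positive scale. With the default β and σ the planted
miRNA–target correlation is ≈ −0.98 in expectation, comfortably past the
−0.7/−0.92-style thresholds; lowering β toward 0.3 or raising σ toward 1.5
degrades it smoothly, which the property tests assert. In the σ → 0 limit
the design matrix is two-valued, so every planted correlation is exactly
±1 — even on the abundance scale, because any two two-valued vectors
aligned on the same sample partition are affinely related.

**Trait.** A linear function of the first planted mRNA's abundance plus 2 %
Gaussian noise, for exercising expression–trait correlation.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: realistic sequence composition and repeat
structure, count-level (negative binomial) noise and library-size effects,
imperfect MREs and bulged duplexes, miRNAs regulating unmodelled targets,
batch effects, and coding-potential signals beyond ORF length. Recovery
rates on this generator are upper bounds on what field data would give.

## Numerical and design notes

* Coordinates are 1-based closed throughout (GTF convention); T is the
  internal alphabet, U converted on read.
* Positional classes use the precedence antisense > intronic > ambiguous on
  multi-gene hits; the rules are: intergenic = no gene-span overlap,
  antisense = overlaps an exon of an opposite-strand gene, intronic = span
  entirely inside one intron of a same-strand gene. The class names are
  standard; the exact rules are this package's own, stated so results are
  reproducible.
* The ORF surrogate for coding potential (longest ATG-initiated,
  stop-terminated ORF ≥ 300 nt ⇒ coding) replaces external classifiers with
  a fully specified, testable rule. Roughly 2–4 % of random 800-nt
  sequences contain such an ORF, so a few true decoys are lost; this is a
  realistic cost of the filter, visible as recall slightly below 1 on the
  synthetic data.
* Triplet DE restriction defaults ON — the network is meant to contain
  deregulated features — and can be switched off via
  `pipeline_config(de_restrict = FALSE)`.
* Hub ties: every node of maximal degree is reported; the lexicographically
  smallest is designated primary for determinism.
* The pipeline is fully deterministic: identical inputs and configuration
  reproduce byte-identical outputs, asserted by checksum in the tests. The
  run manifest records parameters, input MD5 checksums and per-stage
  counts, and deliberately contains no timestamps.

## Problem sizes

The bundled analysis scripts and the test suite run the default design
(270 features × 12 samples, 20 × 250 MRE scans of 780–1480 windows each,
10 000 candidate lncRNA–mRNA pairs) in well under a minute on one core;
oracle-equivalence checks are restricted to fixtures with at most ~10³
candidate combinations so the brute-force references stay exact and fast.

## Limitations

The method inherits the ceRNA hypothesis's own caveats: co-expression plus
shared MREs is correlational evidence, and the sponging stoichiometry
(absolute abundances of miRNA vs decoy) is not modelled. Correlation at
small *n* is noisy; with 3 + 3 designs the *p* < 0.01 threshold dominates
and recall drops. The scanner's ungapped model will miss bulged target
mimics — notably the canonical three-nucleotide bulge of some plant eTMs —
which is the price of exact verifiability; users studying bulged mimics
should lower `seed_multiplier`/raise `max_penalty` or pre-screen with a
thermodynamic tool and feed the pairs in directly.
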