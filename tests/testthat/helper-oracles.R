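# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementations they check.

# Brute-force single-sample enrichment running sum for one sample.
# Walks the ranked gene list explicitly, accumulating the weighted in-set ECDF
# minus the unweighted out-of-set ECDF.
oracle_ssgsea_one <- function(values, genes, set_genes, alpha) {
  stopifnot(length(values) == length(genes))
  ord <- order(-values, genes, method = "radix")
  g <- genes[ord]
  G <- length(g)
  in_set <- g %in% set_genes
  # rank weight: gene at walk position i has expression rank G - i + 1
  total_w <- 0
  for (i in seq_len(G)) if (in_set[i]) total_w <- total_w + (G - i + 1)^alpha
  n_out <- G - sum(in_set)
  es <- 0
  cum_in <- 0
  cum_out <- 0
  for (i in seq_len(G)) {
    if (in_set[i]) {
      cum_in <- cum_in + (G - i + 1)^alpha
    } else {
      cum_out <- cum_out + 1
    }
    es <- es + (cum_in / total_w - cum_out / n_out)
  }
  es
}

# O(n^2) pairwise concordance AUC with 0.5 tie credit.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher p by direct enumeration of all 2x2 tables with the
# observed margins, probability ordering, factorial arithmetic.
oracle_fisher_p <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d; n <- sum(m)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  lprob <- function(x) {
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
      lfactorial(c1 - x) - lfactorial(r2 - c1 + x)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(sapply(support, lprob))
  p_obs <- exp(lprob(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Log-normalized expression of a dense count matrix, duplicated here so the
# exact-permutation oracle is independent of log_normalize_counts().
oracle_lognorm <- function(counts, scale_factor = 1e4) {
  dense <- as.matrix(counts)
  log2(1 + sweep(dense, 2, colSums(dense), "/") * scale_factor)
}

# Small dense cohort fixture: random log-scale matrix with named genes/samples.
random_log_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 5, sd = 2),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, scale = "log")
}
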