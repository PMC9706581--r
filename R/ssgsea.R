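#' Score vectors
#'
#' Per-sample signature scores are carried as named numeric vectors with a
#' `signature` attribute and a `normalization` tag in `{raw, rescaled, zscore}`
#' so that every downstream result records how its inputs were normalized.
#'
#' @param x Named numeric vector (names = sample IDs).
#' @param signature Signature name.
#' @param normalization One of `"raw"`, `"rescaled"`, `"zscore"`.
#' @return A `score_vector`.
#' @export
score_vector <- function(x, signature,
                         normalization = c("raw", "rescaled", "zscore")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(x) || is.null(names(x)) || anyDuplicated(names(x))) {
    stop("scores must be a numeric vector with unique sample names",
         call. = FALSE)
  }
  structure(as.numeric(stats::setNames(x, names(x))),
            names = names(x),
            signature = as.character(signature)[1L],
            normalization = normalization,
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %s [%s], %d samples\n",
              attr(x, "signature"), attr(x, "normalization"), length(x)))
  print(utils::head(stats::setNames(as.numeric(x), names(x)), 6L))
  invisible(x)
}

score_normalization <- function(x) attr(x, "normalization") %||% "raw"

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' For each sample, genes are ranked by expression (descending; ties broken by
#' gene name so the walk is platform-independent) and the enrichment score is
#' the sum, along the ranked list, of the difference between the weighted
#' in-set empirical CDF and the unweighted out-of-set empirical CDF. In-set
#' weights are `rank^alpha`, where rank is the within-sample expression rank
#' (1 = lowest). With `alpha = 0` the statistic depends on ranks only and is
#' therefore invariant to any strictly increasing per-sample transform of the
#' expression values; the same holds for rank-power weights at any `alpha`.
#'
#' Genes of the set absent from the matrix are dropped with a warning stating
#' the coverage fraction; the fraction is also attached as attribute
#' `coverage`. No cross-sample normalization is applied: rescaling is a
#' separate, explicit step ([rescale_scores()]).
#'
#' @param expr An [expression_matrix()] on log scale.
#' @param set A [gene_set()].
#' @param alpha Non-negative rank-weighting exponent; 0.25 by default.
#' @return A `score_vector` (tag `"raw"`), one score per sample.
#' @export
ssgsea_score <- function(expr, set, alpha = 0.25) {
  if (!inherits(expr, "expr_matrix")) {
    stop("'expr' must be an expression_matrix()", call. = FALSE)
  }
  if (expr_scale(expr) != "log") {
    stop("ssGSEA is defined on log-normalized expression; call log_normalize() first",
         call. = FALSE)
  }
  if (!inherits(set, "gene_set")) {
    stop("'set' must be a gene_set()", call. = FALSE)
  }
  stopifnot_scalar_number(alpha, "alpha")
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)

  genes <- rownames(expr)
  present <- set$genes[set$genes %in% genes]
  if (length(present) == 0L) {
    stop(sprintf("no genes of set '%s' are present in the expression matrix",
                 set$name), call. = FALSE)
  }
  coverage <- length(present) / length(set$genes)
  if (coverage < 1) {
    warning(sprintf("gene set '%s': %d/%d genes in matrix (coverage %.2f)",
                    set$name, length(present), length(set$genes), coverage),
            call. = FALSE)
  }
  n_genes <- nrow(expr)
  if (length(present) >= n_genes) {
    stop(sprintf("gene set '%s' covers the whole matrix; out-of-set ECDF undefined",
                 set$name), call. = FALSE)
  }
  in_set <- genes %in% present

  mat <- unclass(expr)
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    # descending expression, ties broken by gene name (stable, deterministic)
    ord <- order(-x, genes, method = "radix")
    hits <- in_set[ord]
    # within-sample rank, 1 = lowest expression; position i holds rank G-i+1
    # up to tie-breaking, which only permutes equal values
    w <- (n_genes - seq_len(n_genes) + 1)^alpha
    w[!hits] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!hits) / (n_genes - length(present))
    sum(p_in - p_out)
  }, numeric(1))

  out <- score_vector(stats::setNames(scores, colnames(mat)),
                      signature = set$name, normalization = "raw")
  attr(out, "coverage") <- coverage
  out
}

#' Score several signatures on one cohort
#'
#' Convenience wrapper running [ssgsea_score()] per set.
#'
#' @inheritParams ssgsea_score
#' @param sets List of [gene_set()] objects (as from [read_gmt()]).
#' @return Named list of `score_vector`s, one per set.
#' @export
score_signatures <- function(expr, sets, alpha = 0.25) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  out <- lapply(sets, ssgsea_score, expr = expr, alpha = alpha)
  names(out) <- vapply(sets, function(s) s$name, character(1))
  out
}

#' Rescale raw enrichment scores onto a positive range
#'
#' ssGSEA scores can be negative, so the log(basal/luminal) ratio needs scores
#' mapped onto a positive interval first. `minmax_eps` maps the cohort's scores
#' affinely onto `[eps, 1]` (default `eps = 0.01`); `none` is the identity.
#' The choice is recorded in the `normalization` tag rather than hidden inside
#' the scoring step.
#'
#' @param scores A `score_vector`.
#' @param method `"minmax_eps"` or `"none"`.
#' @param eps Lower endpoint of the target interval.
#' @return A `score_vector` tagged `"rescaled"`.
#' @export
rescale_scores <- function(scores, method = c("minmax_eps", "none"),
                           eps = 0.01) {
  method <- match.arg(method)
  if (!inherits(scores, "score_vector")) {
    stop("'scores' must be a score_vector", call. = FALSE)
  }
  x <- as.numeric(scores)
  if (method == "none") {
    return(score_vector(stats::setNames(x, names(scores)),
                        signature = attr(scores, "signature"),
                        normalization = "rescaled"))
  }
  rng <- range(x)
  if (length(x) < 2L || rng[1] == rng[2]) {
    stop("minmax_eps rescaling needs >= 2 distinct score values",
         call. = FALSE)
  }
  y <- eps + (x - rng[1]) / (rng[2] - rng[1]) * (1 - eps)
  score_vector(stats::setNames(y, names(scores)),
               signature = attr(scores, "signature"),
               normalization = "rescaled")
}

#' Z-score a score vector
#'
#' Centers and scales with the sample standard deviation (n - 1 denominator),
#' the normalization applied to the cytotoxicity and Macro-C3 scores before
#' fitting the immune-evasion regression lines. Idempotent up to floating
#' point: z-scoring a z-scored vector returns it unchanged.
#'
#' @param scores A `score_vector` (or named numeric vector).
#' @return A `score_vector` tagged `"zscore"` with mean 0 and sd 1.
#' @export
zscore <- function(scores) {
  sig <- attr(scores, "signature") %||% "score"
  x <- as.numeric(scores)
  nm <- names(scores)
  if (length(x) < 2L) {
    stop("z-scoring needs at least 2 samples", call. = FALSE)
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("z-scoring undefined for a constant score vector", call. = FALSE)
  }
  score_vector(stats::setNames((x - mean(x)) / s, nm),
               signature = sig, normalization = "zscore")
}

#' Write scores as a long-format TSV
#'
#' Columns: sample, signature, score, normalization.
#'
#' @param scores A `score_vector` or list of them.
#' @param path Output path.
#' @export
write_scores_tsv <- function(scores, path) {
  if (inherits(scores, "score_vector")) scores <- list(scores)
  rows <- lapply(scores, function(s) {
    data.frame(sample = names(s),
               signature = attr(s, "signature"),
               score = as.numeric(s),
               normalization = score_normalization(s),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
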