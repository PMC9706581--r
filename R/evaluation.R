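#' ROC curve and AUC with Mann-Whitney tie handling
#'
#' The AUC is the concordance probability: the chance a random responder's
#' score exceeds a random non-responder's, with ties credited 0.5 (the
#' Mann-Whitney convention, computed from mean ranks). The stored curve holds
#' the true- and false-positive rates at every distinct score threshold
#' (predict positive when `score >= threshold`), plus the (0,0) endpoint; its
#' trapezoidal integral equals the rank-based AUC identically.
#'
#' @param scores Numeric prediction scores (higher = more responder-like).
#' @param labels Binary 0/1 labels aligned with `scores`.
#' @return An object of class `roc_result`: list with `curve` (data.frame of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  s <- as.numeric(scores)
  y <- as.numeric(labels)
  if (length(s) != length(y)) {
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  }
  if (anyNA(s) || anyNA(y)) stop("inputs contain NA", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("'labels' must be 0/1", call. = FALSE)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  # Mann-Whitney AUC from mean ranks: ties get 0.5 credit automatically
  rk <- rank(s, ties.method = "average")
  auc <- (sum(rk[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s >= t & y == 1), numeric(1)) / n_pos
  fpr <- vapply(thr, function(t) sum(s >= t & y == 0), numeric(1)) / n_neg
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(curve = curve, auc = unname(auc),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d responders, %d non-responders)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Stratify samples into score quartiles
#'
#' Boundaries at the empirical 25/50/75 percentiles; a score tied with a
#' boundary is assigned to the lower quartile, so Q1-vs-Q4 contrasts are
#' reproducible under ties. Q1 holds the lowest scores, Q4 the highest.
#'
#' @param scores Named or unnamed numeric vector, `n >= 4`, not all equal.
#' @return Factor of labels `Q1`..`Q4`, named like `scores`.
#' @export
quartile_stratify <- function(scores) {
  x <- as.numeric(scores)
  if (length(x) < 4L) stop("need at least 4 samples", call. = FALSE)
  if (anyNA(x)) stop("scores contain NA", call. = FALSE)
  if (min(x) == max(x)) {
    stop("all scores identical; quartile strata are degenerate",
         call. = FALSE)
  }
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  lab <- ifelse(x <= qs[1], "Q1",
                ifelse(x <= qs[2], "Q2",
                       ifelse(x <= qs[3], "Q3", "Q4")))
  stats::setNames(factor(lab, levels = c("Q1", "Q2", "Q3", "Q4")),
                  names(scores))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with probability ordering: the two-sided p-value
#' is the sum of probabilities, over all tables with the observed margins, of
#' tables no more probable than the observed one. The odds ratio reported is
#' the sample (unconditional) odds ratio, with the Haldane 0.5 correction
#' applied to all cells when any cell is zero; no conditional-MLE estimate is
#' computed. A table with a zero margin is degenerate and returns p = 1.
#'
#' @param table 2x2 matrix (or length-4 vector, column-major) of non-negative
#'   integer counts.
#' @return List with `p_value` and `odds_ratio`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value  # 2/252
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4L || anyNA(x) || any(x < 0) || any(x != trunc(x))) {
    stop("'table' must be 2x2 non-negative integer counts", call. = FALSE)
  }
  m <- matrix(x, 2L, 2L)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- sum(m)
  if (n == 0 || r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    p <- 1
  } else {
    support <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- stats::dhyper(support, c1, n - c1, r1)
    p_obs <- stats::dhyper(a, c1, n - c1, r1)
    # relative tolerance guards against FP noise in "as extreme" comparison
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  if (any(m == 0)) m <- m + 0.5
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(p_value = p, odds_ratio = unname(or))
}
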