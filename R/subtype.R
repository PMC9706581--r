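#' Basal/luminal subtype axis
#'
#' Scores each sample for the basal and luminal halves of a subtype panel
#' (e.g. BASE47) by ssGSEA, rescales both score vectors onto a positive range
#' (required before taking a ratio of enrichment scores, which can be
#' negative), and returns the per-sample natural-log basal/luminal ratio: the
#' cohort's subtype axis. Positive values are basal-leaning, negative
#' luminal-leaning; exchanging the two gene sets negates the axis exactly.
#'
#' @param expr An [expression_matrix()] on log scale.
#' @param luminal,basal [gene_set()]s for the two panel halves.
#' @param alpha ssGSEA rank-weight exponent, see [ssgsea_score()].
#' @return A data.frame with columns `sample`, `basal`, `luminal` (rescaled
#'   scores in `[0.01, 1]`) and `log_ratio`.
#' @export
subtype_axis <- function(expr, luminal, basal, alpha = 0.25) {
  b <- rescale_scores(ssgsea_score(expr, basal, alpha = alpha))
  l <- rescale_scores(ssgsea_score(expr, luminal, alpha = alpha))
  if (any(as.numeric(b) <= 0) || any(as.numeric(l) <= 0)) {
    stop("internal error: rescaled scores must be positive", call. = FALSE)
  }
  r <- log(as.numeric(b) / as.numeric(l))
  if (any(!is.finite(r))) {
    stop("internal error: non-finite log(basal/luminal) ratio", call. = FALSE)
  }
  data.frame(sample = names(b), basal = as.numeric(b),
             luminal = as.numeric(l), log_ratio = r,
             stringsAsFactors = FALSE)
}

#' Two-group expression clustering into basal and luminal subtypes
#'
#' Reproduces the panel-based two-group split of a cohort: the expression
#' sub-matrix of the panel genes is row z-scored, samples are clustered by
#' average-linkage agglomerative clustering on `1 - Pearson` correlation
#' distance, the tree is cut into `k` groups, and the group with the higher
#' mean basal enrichment score is labeled `"basal"`, the other `"luminal"`.
#'
#' @param expr An [expression_matrix()] on log scale.
#' @param luminal,basal The two halves of the subtype panel; their union is
#'   the clustering feature space, the basal half names the clusters.
#' @param k Number of groups to cut (must be 2 for unambiguous naming).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param alpha ssGSEA exponent used for the naming scores.
#' @return A data.frame with columns `sample`, `label` (`"basal"`/`"luminal"`)
#'   and `method_tag` (`"clinical+clustering"`).
#' @export
cluster_subtypes <- function(expr, luminal, basal, k = 2,
                             linkage = "average", alpha = 0.25) {
  if (k != 2) {
    stop("k must be 2: basal/luminal naming is ambiguous for other k",
         call. = FALSE)
  }
  if (ncol(expr) < k) stop("fewer samples than clusters", call. = FALSE)
  panel <- unique(c(luminal$genes, basal$genes))
  panel <- panel[panel %in% rownames(expr)]
  if (length(panel) < 2L) {
    stop("fewer than 2 panel genes present in the matrix", call. = FALSE)
  }
  sub <- unclass(expr)[panel, , drop = FALSE]
  keep <- apply(sub, 1L, stats::sd) > 0
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) < 2L) {
    stop("fewer than 2 non-constant panel genes; cannot cluster",
         call. = FALSE)
  }
  sub <- t(scale(t(sub)))  # row z-score
  d <- stats::as.dist(1 - stats::cor(sub, method = "pearson"))
  cl <- stats::cutree(stats::hclust(d, method = linkage), k = k)

  bscore <- as.numeric(ssgsea_score(expr, basal, alpha = alpha))
  means <- tapply(bscore, cl, mean)
  basal_cluster <- as.integer(names(means)[which.max(means)])
  label <- ifelse(cl == basal_cluster, "basal", "luminal")
  data.frame(sample = colnames(expr), label = unname(label),
             method_tag = "clinical+clustering", stringsAsFactors = FALSE)
}

#' Three-way subtype assignment using clinical stage
#'
#' Non-muscle-invasive (NMI) samples are labeled `"NMI"` regardless of their
#' expression cluster; muscle-invasive (MI) samples keep their basal/luminal
#' cluster label. This mirrors the stage-defined NMI class used alongside the
#' expression-defined MI subtypes.
#'
#' @param calls A data.frame from [cluster_subtypes()] (columns `sample`,
#'   `label`).
#' @param stage Named character vector, `"NMI"` or `"MI"` per sample; must
#'   cover every sample in `calls`.
#' @return `calls` with `label` replaced by the three-way label.
#' @export
assign_three_way <- function(calls, stage) {
  if (!all(c("sample", "label") %in% names(calls))) {
    stop("'calls' must have columns 'sample' and 'label'", call. = FALSE)
  }
  missing <- setdiff(calls$sample, names(stage))
  if (length(missing)) {
    stop(sprintf("missing stage annotation for sample(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  st <- stage[calls$sample]
  if (!all(st %in% c("NMI", "MI"))) {
    stop("stage annotation values must be 'NMI' or 'MI'", call. = FALSE)
  }
  calls$label <- ifelse(st == "NMI", "NMI", calls$label)
  calls
}
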