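#' Quality-control filter for a single-cell bundle
#'
#' Applies the standard droplet QC rules. Genes expressed (count > 0) in more
#' than `min_cells_per_gene` cells are kept first; cell rules are then
#' evaluated on the gene-filtered matrix. A cell is removed when it violates
#' any of: (i) more than `max_genes` expressed genes, (ii) `min_genes` or
#' fewer expressed genes, (iii) more than `max_mito_frac` of UMIs from
#' mitochondrial genes. Boundary semantics are strict: exactly `min_genes`
#' genes is removed, exactly `max_genes` is kept, mito fraction exactly
#' `max_mito_frac` is kept.
#'
#' The report attributes each removed cell to every rule it violates and, for
#' visibility of the (unstated, order-dependent) convention, also records the
#' counts obtained when the cell rules are evaluated before the gene filter.
#'
#' @param bundle An [single_cell_bundle()].
#' @param min_genes Keep cells with strictly more expressed genes than this.
#' @param max_genes Keep cells with at most this many expressed genes.
#' @param max_mito_frac Keep cells with mitochondrial UMI fraction at or below
#'   this.
#' @param min_cells_per_gene Keep genes expressed in strictly more cells than
#'   this.
#' @return List with `bundle` (filtered) and `report` (list of per-rule
#'   removal counts, removed barcodes per rule, and `cell_first` counts under
#'   the alternative rule order).
#' @export
qc_filter <- function(bundle, min_genes = 200, max_genes = 5000,
                      max_mito_frac = 0.25, min_cells_per_gene = 3) {
  if (!inherits(bundle, "sc_bundle")) {
    stop("'bundle' must be an sc_bundle", call. = FALSE)
  }
  if (!any(bundle$gene_meta$is_mito)) {
    stop("bundle has no mitochondrial gene annotation; cannot apply the mito rule",
         call. = FALSE)
  }
  counts <- bundle$counts

  cell_rules <- function(m, mito_flag) {
    if (ncol(m) == 0L || nrow(m) == 0L) {
      zero <- logical(ncol(m))
      return(list(high_genes = zero, low_genes = zero, high_mito = zero))
    }
    genes_per_cell <- Matrix::colSums(m > 0)
    total <- Matrix::colSums(m)
    mito <- Matrix::colSums(m[mito_flag, , drop = FALSE])
    mito_frac <- ifelse(total > 0, mito / total, 0)
    list(high_genes = genes_per_cell > max_genes,
         low_genes = genes_per_cell <= min_genes,
         high_mito = mito_frac > max_mito_frac)
  }

  # gene filter first, then cell rules on the gene-filtered matrix
  gene_keep <- Matrix::rowSums(counts > 0) > min_cells_per_gene
  filtered <- counts[gene_keep, , drop = FALSE]
  viol <- cell_rules(filtered, bundle$gene_meta$is_mito[gene_keep])
  cell_remove <- viol$high_genes | viol$low_genes | viol$high_mito

  # alternative order, recorded for comparison only
  viol_cf <- cell_rules(counts, bundle$gene_meta$is_mito)

  kept_cells <- colnames(counts)[!cell_remove]
  out_counts <- filtered[, !cell_remove, drop = FALSE]
  out <- single_cell_bundle(
    out_counts,
    bundle$cell_meta[bundle$cell_meta$barcode %in% kept_cells, , drop = FALSE],
    bundle$gene_meta[gene_keep, , drop = FALSE],
    lr_pairs = bundle$lr_pairs,
    planted = bundle$planted
  )
  report <- list(
    genes_removed = sum(!gene_keep),
    cells_removed = sum(cell_remove),
    removed_by_rule = list(
      high_genes = colnames(counts)[viol$high_genes],
      low_genes = colnames(counts)[viol$low_genes],
      high_mito = colnames(counts)[viol$high_mito]
    ),
    rule_counts = vapply(viol, sum, numeric(1)),
    cell_first = list(rule_counts = vapply(viol_cf, sum, numeric(1)))
  )
  list(bundle = out, report = report)
}

#' High-confidence differentially expressed genes between two subtypes
#'
#' A gene passes for a focal subtype only if, in every sample of that subtype,
#' its log2 fold change over the average expression across the other
#' subtype's samples exceeds `threshold`. Operating on per-sample summaries
#' (log2-scale mean expression per sample) makes the call robust to a single
#' dominant sample; candidate genes come from upstream differential testing
#' and are whatever rows the input matrix carries.
#'
#' @param mean_expr Genes x samples matrix of log2-scale mean expression.
#' @param subtype Named character vector mapping every sample (column) to one
#'   of exactly two subtypes.
#' @param threshold Per-sample log2 fold-change bound (default 0.8,
#'   exclusive: a fold change equal to the threshold fails).
#' @return data.frame with one row per gene x focal-subtype direction:
#'   columns `gene`, `subtype`, `min_log2fc` (the weakest per-sample fold
#'   change) and `pass`. The per-sample fold-change matrix for each direction
#'   is attached as attribute `per_sample_log2fc`.
#' @export
high_confidence_degs <- function(mean_expr, subtype, threshold = 0.8) {
  if (!is.matrix(mean_expr) || is.null(colnames(mean_expr)) ||
      is.null(rownames(mean_expr))) {
    stop("'mean_expr' must be a genes x samples matrix with dimnames",
         call. = FALSE)
  }
  missing <- setdiff(colnames(mean_expr), names(subtype))
  if (length(missing)) {
    stop(sprintf("missing subtype for sample(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  st <- subtype[colnames(mean_expr)]
  levels <- unique(st)
  if (length(levels) != 2L) {
    stop("exactly two subtypes are required", call. = FALSE)
  }
  if (any(table(factor(st, levels)) == 0L)) {
    stop("each subtype needs at least one sample", call. = FALSE)
  }

  per_dir <- lapply(levels, function(focal) {
    other <- setdiff(levels, focal)
    focal_cols <- which(st == focal)
    other_mean <- rowMeans(mean_expr[, st == other, drop = FALSE])
    fc <- mean_expr[, focal_cols, drop = FALSE] - other_mean  # log2 scale
    colnames(fc) <- colnames(mean_expr)[focal_cols]
    fc
  })
  names(per_dir) <- levels

  rows <- do.call(rbind, lapply(levels, function(focal) {
    fc <- per_dir[[focal]]
    data.frame(gene = rownames(mean_expr),
               subtype = focal,
               min_log2fc = apply(fc, 1L, min),
               pass = apply(fc, 1L, function(v) all(v > threshold)),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  attr(rows, "per_sample_log2fc") <- per_dir
  attr(rows, "expression_scale") <- "log2 per-sample means"
  rows
}

#' Compartment-relative cluster proportion per sample
#'
#' For each sample, the number of cells in `target_cluster` divided by the
#' number of cells across `compartment_clusters` (which must contain the
#' target), e.g. the proportion of immunosuppressive macrophages within the
#' myeloid compartment, or of exhausted CD8 T cells within the T/NK
#' compartment. Samples contributing fewer than `min_cells` compartment cells
#' are flagged `excluded` (their proportion is still reported).
#'
#' @param bundle An [single_cell_bundle()].
#' @param target_cluster Cluster whose share is measured.
#' @param compartment_clusters Character vector of clusters forming the
#'   compartment.
#' @param min_cells Minimum compartment size per sample (default 100).
#' @return data.frame with columns `sample`, `n_target`, `n_compartment`,
#'   `proportion`, `excluded`.
#' @export
relative_proportion <- function(bundle, target_cluster, compartment_clusters,
                                min_cells = 100) {
  if (!target_cluster %in% compartment_clusters) {
    stop("'target_cluster' must be one of 'compartment_clusters'",
         call. = FALSE)
  }
  meta <- bundle$cell_meta
  unknown <- setdiff(compartment_clusters, meta$cluster)
  if (length(unknown)) {
    stop(sprintf("unknown cluster(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  samples <- sort(unique(meta$sample))
  rows <- lapply(samples, function(s) {
    in_s <- meta$sample == s
    n_comp <- sum(in_s & meta$cluster %in% compartment_clusters)
    n_tgt <- sum(in_s & meta$cluster == target_cluster)
    data.frame(sample = s, n_target = n_tgt, n_compartment = n_comp,
               proportion = if (n_comp > 0) n_tgt / n_comp else NA_real_,
               excluded = n_comp < min_cells,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
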