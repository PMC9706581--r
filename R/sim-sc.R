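#' Construct a single-cell bundle
#'
#' The container for the single-cell rules: a sparse non-negative integer
#' count matrix (genes x cells) plus cell annotations (cluster, sample), gene
#' flags (mitochondrial, ligand, receptor) and an optional ligand-receptor
#' pair panel.
#'
#' @param counts Genes x cells matrix (coerced to `Matrix::dgCMatrix`);
#'   non-negative integers with gene rownames and cell-barcode colnames.
#' @param cell_meta data.frame with columns `barcode`, `cluster`, `sample`
#'   covering every column of `counts`.
#' @param gene_meta data.frame with columns `gene`, `is_mito`, `is_ligand`,
#'   `is_receptor` covering every row of `counts`.
#' @param lr_pairs Optional data.frame with columns `ligand`, `receptor`,
#'   `pair`.
#' @param planted Optional data.frame with columns `barcode`, `rule`
#'   recording deliberately low-quality cells and the QC rule each violates.
#' @return Object of class `sc_bundle`.
#' @export
single_cell_bundle <- function(counts, cell_meta, gene_meta,
                               lr_pairs = NULL, planted = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    stop("counts need gene rownames", call. = FALSE)
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    stop("counts need cell-barcode colnames", call. = FALSE)
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  v <- counts@x
  if (any(v < 0) || any(v != trunc(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  req_cell <- c("barcode", "cluster", "sample")
  if (!all(req_cell %in% names(cell_meta)) ||
      !setequal(cell_meta$barcode, colnames(counts))) {
    stop("cell_meta must have barcode/cluster/sample for every cell",
         call. = FALSE)
  }
  req_gene <- c("gene", "is_mito", "is_ligand", "is_receptor")
  if (!all(req_gene %in% names(gene_meta)) ||
      !setequal(gene_meta$gene, rownames(counts))) {
    stop("gene_meta must have gene/is_mito/is_ligand/is_receptor for every gene",
         call. = FALSE)
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$barcode), ,
                         drop = FALSE]
  gene_meta <- gene_meta[match(rownames(counts), gene_meta$gene), ,
                         drop = FALSE]
  rownames(cell_meta) <- NULL
  rownames(gene_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta, lr_pairs = lr_pairs,
                 planted = planted),
            class = "sc_bundle")
}

#' @export
print.sc_bundle <- function(x, ...) {
  cat(sprintf("<sc_bundle> %d genes x %d cells, %d clusters, %d samples\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cluster)),
              length(unique(x$cell_meta$sample))))
  if (!is.null(x$planted) && nrow(x$planted)) {
    cat(sprintf("  planted low-quality cells: %d\n", nrow(x$planted)))
  }
  invisible(x)
}

#' @export
dim.sc_bundle <- function(x) dim(x$counts)

#' Generate a synthetic clustered single-cell bundle
#'
#' Counts are negative binomial (dispersion 0.5, i.e. `size = 2`) around
#' gene-level means scaled by log-normal per-cell library factors. Each
#' cluster gets `n_marker_genes` marker genes with boosted means. A fraction
#' of genes is designated mitochondrial (symbols prefixed `MT-`) and scaled so
#' healthy cells sit near `mito_frac_target` mitochondrial UMIs. Ligand and
#' receptor genes for `n_lr_pairs` pairs are expressed in a configurable
#' fraction of each cluster's cells (override per gene x cluster via
#' `lr_frac_overrides`). Optionally, low-quality cells violating each QC rule
#' (relative to `qc_reference`) are planted and recorded in `$planted`.
#'
#' @param n_clusters Number of clusters, `>= 2`.
#' @param cells_per_cluster Cells per cluster, `>= 3`.
#' @param n_genes Total genes.
#' @param frac_mito_genes Fraction of genes designated mitochondrial.
#' @param n_lr_pairs Number of ligand-receptor pairs to embed.
#' @param n_samples Number of donor samples cells are assigned to.
#' @param n_marker_genes Markers per cluster.
#' @param mito_frac_target Expected mitochondrial UMI fraction in healthy
#'   cells.
#' @param lr_frac Default fraction of cells per cluster expressing each
#'   ligand/receptor gene.
#' @param lr_frac_overrides Optional data.frame (`gene`, `cluster`, `frac`)
#'   overriding `lr_frac` for specific gene x cluster combinations.
#' @param plant_high_mito,plant_low_genes,plant_high_genes Number of cells to
#'   plant violating, respectively, the mitochondrial-fraction, minimum-genes
#'   and maximum-genes QC rules of `qc_reference`.
#' @param qc_reference List with `min_genes`, `max_genes`, `max_mito_frac`
#'   that planted cells are constructed against (defaults match
#'   [qc_filter()]).
#' @param seed Integer seed.
#' @return An [single_cell_bundle()] of class `sc_bundle`.
#' @export
generate_single_cell_bundle <- function(n_clusters = 3,
                                        cells_per_cluster = 50,
                                        n_genes = 300,
                                        frac_mito_genes = 0.05,
                                        n_lr_pairs = 3,
                                        n_samples = 4,
                                        n_marker_genes = 5,
                                        mito_frac_target = 0.08,
                                        lr_frac = 0.5,
                                        lr_frac_overrides = NULL,
                                        plant_high_mito = 0,
                                        plant_low_genes = 0,
                                        plant_high_genes = 0,
                                        qc_reference = list(
                                          min_genes = 200, max_genes = 5000,
                                          max_mito_frac = 0.25),
                                        seed = 1) {
  if (n_clusters < 2) stop("'n_clusters' must be >= 2", call. = FALSE)
  if (cells_per_cluster < 3) {
    stop("'cells_per_cluster' must be >= 3", call. = FALSE)
  }
  n_mito <- max(1L, round(frac_mito_genes * n_genes))
  n_lr_genes <- 2L * n_lr_pairs
  if (n_genes < n_mito + n_lr_genes + n_clusters * n_marker_genes + 10L) {
    stop("'n_genes' too small for the requested mito/LR/marker genes",
         call. = FALSE)
  }
  if (plant_high_genes > 0 && n_genes <= qc_reference$max_genes) {
    stop("cannot plant high-gene-count cells: n_genes <= qc_reference$max_genes",
         call. = FALSE)
  }

  with_local_seed(seed, {
    clusters <- sprintf("C%d", seq_len(n_clusters))
    mito_genes <- sprintf("MT-%d", seq_len(n_mito))
    lig_genes <- if (n_lr_pairs > 0) sprintf("LIG%d", seq_len(n_lr_pairs)) else character(0)
    rec_genes <- if (n_lr_pairs > 0) sprintf("REC%d", seq_len(n_lr_pairs)) else character(0)
    n_bg <- n_genes - n_mito - n_lr_genes
    bg_genes <- sprintf("G%04d", seq_len(n_bg))
    genes <- c(bg_genes, mito_genes, lig_genes, rec_genes)

    n_cells <- n_clusters * cells_per_cluster
    barcodes <- sprintf("CELL%04d", seq_len(n_cells))
    cell_cluster <- rep(clusters, each = cells_per_cluster)
    cell_sample <- sample(sprintf("P%d", seq_len(n_samples)), n_cells,
                          replace = TRUE)

    # gene-level means; markers boosted in their cluster
    base_mu <- stats::rgamma(n_genes, shape = 2, rate = 2)
    names(base_mu) <- genes
    marker_pool <- bg_genes[seq_len(n_clusters * n_marker_genes)]
    markers <- split(marker_pool, rep(clusters, each = n_marker_genes))
    # scale mitochondrial means toward the target UMI fraction
    non_mito_total <- sum(base_mu[setdiff(genes, mito_genes)])
    base_mu[mito_genes] <- base_mu[mito_genes] /
      sum(base_mu[mito_genes]) *
      non_mito_total * mito_frac_target / (1 - mito_frac_target)

    size_factor <- stats::rlnorm(n_cells, meanlog = 0, sdlog = 0.3)
    counts <- matrix(0, n_genes, n_cells, dimnames = list(genes, barcodes))
    for (j in seq_len(n_cells)) {
      mu <- base_mu
      mu[markers[[cell_cluster[j]]]] <- mu[markers[[cell_cluster[j]]]] * 8
      counts[, j] <- stats::rnbinom(n_genes, mu = mu * size_factor[j],
                                    size = 2)
    }

    # ligand/receptor genes: Bernoulli expression gate per cluster
    lr_gene_all <- c(lig_genes, rec_genes)
    frac_for <- function(gene, cluster) {
      if (!is.null(lr_frac_overrides)) {
        hit <- lr_frac_overrides$gene == gene &
          lr_frac_overrides$cluster == cluster
        if (any(hit)) return(lr_frac_overrides$frac[hit][1L])
      }
      lr_frac
    }
    for (g in lr_gene_all) {
      for (cl in clusters) {
        idx <- which(cell_cluster == cl)
        f <- frac_for(g, cl)
        on <- stats::rbinom(length(idx), 1L, f) == 1L
        counts[g, idx] <- ifelse(on, stats::rpois(length(idx), 3) + 1L, 0L)
      }
    }

    # plant low-quality cells by overwriting the last cells of cluster 1
    planted <- data.frame(barcode = character(0), rule = character(0),
                          stringsAsFactors = FALSE)
    n_plant <- plant_high_mito + plant_low_genes + plant_high_genes
    if (n_plant > 0) {
      if (n_plant > cells_per_cluster - 2L) {
        stop("too many planted cells for cluster size", call. = FALSE)
      }
      plant_idx <- seq_len(n_plant)
      rules <- rep(c("high_mito", "low_genes", "high_genes"),
                   c(plant_high_mito, plant_low_genes, plant_high_genes))
      for (k in seq_along(plant_idx)) {
        j <- plant_idx[k]
        rule <- rules[k]
        if (rule == "high_mito") {
          # push mito fraction above the limit, keep gene count in bounds
          non_mito <- sum(counts[setdiff(genes, mito_genes), j])
          f <- min(0.95, qc_reference$max_mito_frac + 0.1)
          target <- ceiling(non_mito * f / (1 - f))
          per_gene <- floor(target / n_mito)
          counts[mito_genes, j] <- per_gene
          counts[mito_genes[1L], j] <- per_gene + (target - per_gene * n_mito)
        } else if (rule == "low_genes") {
          keep_n <- max(1L, floor(qc_reference$min_genes / 2))
          expressed <- which(counts[, j] > 0)
          if (length(expressed) > keep_n) {
            drop <- setdiff(expressed, expressed[seq_len(keep_n)])
            counts[drop, j] <- 0
          }
        } else { # high_genes
          counts[, j] <- pmax(counts[, j], 1)
        }
        planted <- rbind(planted,
                         data.frame(barcode = barcodes[j], rule = rule,
                                    stringsAsFactors = FALSE))
      }
    }

    gene_meta <- data.frame(
      gene = genes,
      is_mito = genes %in% mito_genes,
      is_ligand = genes %in% lig_genes,
      is_receptor = genes %in% rec_genes,
      stringsAsFactors = FALSE
    )
    cell_meta <- data.frame(barcode = barcodes, cluster = cell_cluster,
                            sample = cell_sample, stringsAsFactors = FALSE)
    lr_pairs <- if (n_lr_pairs > 0) {
      data.frame(ligand = lig_genes, receptor = rec_genes,
                 pair = paste0(lig_genes, "_", rec_genes),
                 stringsAsFactors = FALSE)
    } else {
      NULL
    }
    single_cell_bundle(Matrix::Matrix(counts, sparse = TRUE),
                       cell_meta, gene_meta, lr_pairs = lr_pairs,
                       planted = planted)
  })
}

#' Write / read a single-cell bundle as MTX with sidecars
#'
#' Writes `matrix.mtx`, `features.tsv` (gene, is_mito, is_ligand,
#' is_receptor), `barcodes.tsv` and `cells.tsv` (barcode, cluster, sample)
#' into `dir`; `read_sc_bundle` reads them back.
#'
#' @param bundle An `sc_bundle`.
#' @param dir Directory path.
#' @return `dir` (write) or an `sc_bundle` (read), invisibly for write.
#' @export
write_sc_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(bundle$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(bundle$gene_meta, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(bundle$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(bundle$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$lr_pairs)) {
    utils::write.table(bundle$lr_pairs, file.path(dir, "lr_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_sc_bundle
#' @export
read_sc_bundle <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  gene_meta <- utils::read.delim(file.path(dir, "features.tsv"),
                                 stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  cell_meta <- utils::read.delim(file.path(dir, "cells.tsv"),
                                 stringsAsFactors = FALSE)
  dimnames(counts) <- list(gene_meta$gene, barcodes)
  lr_path <- file.path(dir, "lr_pairs.tsv")
  lr_pairs <- if (file.exists(lr_path)) {
    utils::read.delim(lr_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  single_cell_bundle(counts, cell_meta, gene_meta, lr_pairs = lr_pairs)
}
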