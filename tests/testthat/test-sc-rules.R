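# QC thresholds scaled to the small synthetic bundles used in tests.
test_qc <- list(min_genes = 25, max_genes = 115, max_mito_frac = 0.25)

qc_bundle <- function(plant_high_mito = 0, plant_low_genes = 0,
                      plant_high_genes = 0, seed = 1) {
  generate_single_cell_bundle(
    n_clusters = 2, cells_per_cluster = 30, n_genes = 120, n_lr_pairs = 2,
    plant_high_mito = plant_high_mito, plant_low_genes = plant_low_genes,
    plant_high_genes = plant_high_genes,
    qc_reference = test_qc, seed = seed
  )
}

run_qc <- function(bundle) {
  qc_filter(bundle, min_genes = test_qc$min_genes,
            max_genes = test_qc$max_genes,
            max_mito_frac = test_qc$max_mito_frac)
}

test_that("planted violations are removed with correct per-rule attribution", {
  bundle <- qc_bundle(plant_high_mito = 5, plant_low_genes = 3,
                      plant_high_genes = 2, seed = 11)
  res <- run_qc(bundle)
  planted <- split(bundle$planted$barcode, bundle$planted$rule)

  expect_setequal(res$report$removed_by_rule$high_mito, planted$high_mito)
  expect_setequal(res$report$removed_by_rule$low_genes, planted$low_genes)
  expect_setequal(res$report$removed_by_rule$high_genes, planted$high_genes)
  expect_identical(res$report$cells_removed, 10L + 0L)
  expect_false(any(bundle$planted$barcode %in% colnames(res$bundle$counts)))
  # nothing else was removed
  expect_identical(ncol(res$bundle$counts), ncol(bundle$counts) - 10L)
})

test_that("clean bundles pass through the cell rules untouched", {
  bundle <- qc_bundle(seed = 12)
  res <- run_qc(bundle)
  expect_identical(colnames(res$bundle$counts), colnames(bundle$counts))
  expect_identical(res$report$cells_removed, 0L)
})

test_that("QC boundary semantics are strict on all three cell rules", {
  # hand-built 4-cell matrix around the boundaries: min_genes 2, max_genes 3,
  # mito 0.25; gene rule disabled via min_cells_per_gene = 0
  genes <- c("MT-1", "g1", "g2", "g3")
  m <- Matrix::Matrix(0, 4, 4, dimnames = list(genes, paste0("c", 1:4)),
                      sparse = TRUE)
  m["g1", 1] <- 3; m["g2", 1] <- 1; m["MT-1", 1] <- 1  # 3 genes, mito 1/5
  m["g1", 2] <- 3; m["MT-1", 2] <- 1                   # exactly 2 genes
  m["g1", 3] <- 3; m["g2", 3] <- 3; m["g3", 3] <- 1; m["MT-1", 3] <- 1
  m["g1", 4] <- 3; m["g2", 4] <- 3; m["MT-1", 4] <- 2  # mito 2/8 = 0.25
  bundle <- single_cell_bundle(
    m,
    data.frame(barcode = paste0("c", 1:4), cluster = "C1", sample = "P1"),
    data.frame(gene = genes, is_mito = genes == "MT-1",
               is_ligand = FALSE, is_receptor = FALSE)
  )
  res <- qc_filter(bundle, min_genes = 2, max_genes = 3, max_mito_frac = 0.25,
                   min_cells_per_gene = 0)
  kept <- colnames(res$bundle$counts)
  expect_true("c1" %in% kept)
  expect_false("c2" %in% kept)   # exactly min_genes genes -> removed
  expect_false("c3" %in% kept)   # above max_genes -> removed
  expect_true("c4" %in% kept)    # mito fraction exactly at the limit -> kept
})

test_that("a cell with mito fraction just above the limit is removed by rule iii", {
  genes <- c("MT-1", "g1", "g2")
  m <- Matrix::Matrix(0, 3, 2, dimnames = list(genes, c("bad", "ok")),
                      sparse = TRUE)
  m["g1", "bad"] <- 37; m["g2", "bad"] <- 37; m["MT-1", "bad"] <- 26  # 26%
  m["g1", "ok"] <- 50; m["g2", "ok"] <- 45; m["MT-1", "ok"] <- 5
  bundle <- single_cell_bundle(
    m, data.frame(barcode = c("bad", "ok"), cluster = "C1", sample = "P1"),
    data.frame(gene = genes, is_mito = genes == "MT-1",
               is_ligand = FALSE, is_receptor = FALSE)
  )
  res <- qc_filter(bundle, min_genes = 1, max_genes = 10,
                   max_mito_frac = 0.25, min_cells_per_gene = 0)
  expect_identical(res$report$removed_by_rule$high_mito, "bad")
  expect_identical(colnames(res$bundle$counts), "ok")
})

test_that("the gene filter runs first and its removals are reported", {
  bundle <- qc_bundle(seed = 13)
  # add a gene expressed in exactly 3 cells: must be dropped (> 3 required)
  m <- rbind(bundle$counts,
             RARE = c(rep(1, 3), rep(0, ncol(bundle$counts) - 3)))
  gm <- rbind(bundle$gene_meta,
              data.frame(gene = "RARE", is_mito = FALSE, is_ligand = FALSE,
                         is_receptor = FALSE))
  b2 <- single_cell_bundle(m, bundle$cell_meta, gm)
  res <- qc_filter(b2, min_genes = test_qc$min_genes,
                   max_genes = test_qc$max_genes)
  expect_false("RARE" %in% rownames(res$bundle$counts))
  expect_gte(res$report$genes_removed, 1)
})

test_that("qc_filter is idempotent on generated bundles", {
  for (s in c(14, 15)) {
    bundle <- qc_bundle(plant_high_mito = 2, plant_low_genes = 2, seed = s)
    once <- run_qc(bundle)$bundle
    twice <- run_qc(once)$bundle
    expect_identical(as.matrix(twice$counts), as.matrix(once$counts))
    expect_identical(twice$cell_meta, once$cell_meta)
  }
})

test_that("empty matrices pass through QC with a zero-count report", {
  m <- Matrix::Matrix(0, 2, 0, dimnames = list(c("MT-1", "g1"), NULL),
                      sparse = TRUE)
  colnames(m) <- character(0)
  bundle <- single_cell_bundle(
    m, data.frame(barcode = character(0), cluster = character(0),
                  sample = character(0)),
    data.frame(gene = c("MT-1", "g1"), is_mito = c(TRUE, FALSE),
               is_ligand = FALSE, is_receptor = FALSE)
  )
  res <- qc_filter(bundle)
  expect_identical(ncol(res$bundle$counts), 0L)
  expect_identical(res$report$cells_removed, 0L)
})

test_that("missing mitochondrial annotation is an error", {
  bundle <- qc_bundle(seed = 16)
  bundle$gene_meta$is_mito <- FALSE
  expect_error(qc_filter(bundle), "mitochondrial")
})

test_that("high-confidence DEG rule requires every per-sample log2FC above threshold", {
  # 3 basal samples with per-sample log2FC over the luminal mean of
  # (1.1, 0.9, 0.7) for geneA -> fail; (1.1, 0.9, 0.85) for geneB -> pass
  lum_mean <- 2
  mk <- function(fcs) lum_mean + fcs
  m <- rbind(geneA = c(mk(c(1.1, 0.9, 0.7)), 2, 2),
             geneB = c(mk(c(1.1, 0.9, 0.85)), 2, 2),
             geneC = rep(2, 5))
  colnames(m) <- paste0("s", 1:5)
  subtype <- c(s1 = "basal", s2 = "basal", s3 = "basal",
               s4 = "luminal", s5 = "luminal")
  degs <- high_confidence_degs(m, subtype, threshold = 0.8)
  basal <- degs[degs$subtype == "basal", ]
  expect_false(basal$pass[basal$gene == "geneA"])
  expect_true(basal$pass[basal$gene == "geneB"])
  expect_false(basal$pass[basal$gene == "geneC"])  # log2FC = 0 everywhere
  expect_equal(basal$min_log2fc[basal$gene == "geneA"], 0.7)
  # a fold change exactly at the threshold fails (strict inequality)
  m2 <- rbind(geneD = c(mk(c(0.8, 0.9, 1.0)), 2, 2))
  colnames(m2) <- paste0("s", 1:5)
  d2 <- high_confidence_degs(m2, subtype)
  expect_false(d2$pass[d2$subtype == "basal"])
})

test_that("no gene passes the DEG rule in both directions", {
  set.seed(17)
  m <- matrix(rnorm(30 * 6, 3), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:6)))
  subtype <- setNames(rep(c("basal", "luminal"), each = 3), paste0("s", 1:6))
  degs <- high_confidence_degs(m, subtype)
  both <- tapply(degs$pass, degs$gene, sum)
  expect_true(all(both <= 1))
})

test_that("DEG rule preconditions: two subtypes, full sample coverage", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(high_confidence_degs(m, c(s1 = "a", s2 = "a")),
               "exactly two")
  expect_error(high_confidence_degs(m, c(s1 = "a")), "s2")
})

test_that("relative proportions count cells per sample and flag small compartments", {
  meta <- data.frame(
    barcode = sprintf("c%03d", 1:300),
    cluster = c(rep("Macro-C3", 40), rep("Macro-C1", 160),
                rep("Macro-C3", 20), rep("Macro-C1", 79), "T-cell"),
    sample = c(rep("P1", 200), rep("P2", 99), "P2"),
    stringsAsFactors = FALSE
  )
  m <- Matrix::Matrix(1, 2, 300, sparse = TRUE,
                      dimnames = list(c("MT-1", "g1"), meta$barcode))
  bundle <- single_cell_bundle(
    m, meta,
    data.frame(gene = c("MT-1", "g1"), is_mito = c(TRUE, FALSE),
               is_ligand = FALSE, is_receptor = FALSE)
  )
  prop <- relative_proportion(bundle, "Macro-C3", c("Macro-C3", "Macro-C1"))
  p1 <- prop[prop$sample == "P1", ]
  expect_equal(p1$proportion, 0.20)   # 40 of 200 myeloid cells
  expect_false(p1$excluded)
  p2 <- prop[prop$sample == "P2", ]
  expect_equal(p2$n_compartment, 99L)
  expect_true(p2$excluded)            # fewer than 100 compartment cells

  solo <- relative_proportion(bundle, "Macro-C3", "Macro-C3")
  expect_true(all(solo$proportion == 1.0))
  expect_error(relative_proportion(bundle, "T-cell", c("Macro-C3")),
               "must be one of")
})

test_that("proportions over all compartment clusters sum to one per sample", {
  bundle <- generate_single_cell_bundle(n_clusters = 3, cells_per_cluster = 40,
                                        n_genes = 120, seed = 18)
  clusters <- unique(bundle$cell_meta$cluster)
  props <- lapply(clusters, function(cl) {
    relative_proportion(bundle, cl, clusters, min_cells = 1)
  })
  total <- Reduce(`+`, lapply(props, function(p) p$proportion))
  expect_equal(total, rep(1, length(total)))
})
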