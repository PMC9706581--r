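# Tiny hand-built bundle: explicit counts so gate fractions and strengths are
# exact by construction.
tiny_lr_bundle <- function(counts_lig_c1, counts_rec_c2, n_c1 = 10,
                           n_c2 = 10, filler = 5) {
  genes <- c("LIG1", "REC1", "g1", "MT-1")
  n <- n_c1 + n_c2
  m <- matrix(0, 4, n, dimnames = list(genes, sprintf("c%02d", 1:n)))
  m["g1", ] <- filler
  m["LIG1", seq_len(length(counts_lig_c1))] <- counts_lig_c1
  m["REC1", n_c1 + seq_len(length(counts_rec_c2))] <- counts_rec_c2
  single_cell_bundle(
    Matrix::Matrix(m, sparse = TRUE),
    data.frame(barcode = colnames(m),
               cluster = rep(c("C1", "C2"), c(n_c1, n_c2)),
               sample = "P1", stringsAsFactors = FALSE),
    data.frame(gene = genes, is_mito = genes == "MT-1",
               is_ligand = genes == "LIG1", is_receptor = genes == "REC1",
               stringsAsFactors = FALSE),
    lr_pairs = data.frame(ligand = "LIG1", receptor = "REC1",
                          pair = "LIG1_REC1", stringsAsFactors = FALSE)
  )
}

test_that("the 10% expression gate is enforced on both sides", {
  # ligand in 1/10 sender cells (10%, not strictly more) -> gated
  b <- tiny_lr_bundle(counts_lig_c1 = 4, counts_rec_c2 = rep(4, 8))
  res <- interaction_strength(b, "LIG1", "REC1", "C1", "C2")
  expect_true(res$gated)
  expect_true(is.na(res$strength))
  expect_error(permutation_test(b, "LIG1", "REC1", "C1", "C2"), "gated")

  # ligand in 2/10 (20%) -> passes
  b2 <- tiny_lr_bundle(counts_lig_c1 = c(4, 4), counts_rec_c2 = rep(4, 8))
  res2 <- interaction_strength(b2, "LIG1", "REC1", "C1", "C2")
  expect_false(res2$gated)
  expect_error(interaction_strength(b2, "LIG1", "NOPE", "C1", "C2"),
               "not in the bundle")
  expect_error(interaction_strength(b2, "LIG1", "REC1", "C1", "C9"),
               "unknown or empty")
})

test_that("strength is the arithmetic mean of the two cluster means", {
  b <- tiny_lr_bundle(counts_lig_c1 = rep(3, 10), counts_rec_c2 = rep(7, 10))
  expr <- log_normalize_counts(b)
  want <- (mean(expr["LIG1", 1:10]) + mean(expr["REC1", 11:20])) / 2
  res <- interaction_strength(b, "LIG1", "REC1", "C1", "C2")
  expect_equal(res$strength, want, tolerance = 1e-12)

  # symmetry: reversed pair between swapped clusters has the same strength
  b_sym <- tiny_lr_bundle(counts_lig_c1 = rep(3, 10),
                          counts_rec_c2 = rep(7, 10))
  rev <- interaction_strength(b_sym, "REC1", "LIG1", "C2", "C1")
  expect_equal(rev$strength, res$strength, tolerance = 1e-12)
})

test_that("log normalization is counts-per-scale-factor then log2(1 + x)", {
  b <- tiny_lr_bundle(counts_lig_c1 = rep(2, 10), counts_rec_c2 = rep(2, 10))
  expr <- log_normalize_counts(b, scale_factor = 100)
  lib <- Matrix::colSums(b$counts)
  expect_equal(expr["LIG1", 1], log2(1 + 100 * 2 / lib[1]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("permutation p is seed-reproducible and on the add-one grid", {
  b <- tiny_lr_bundle(counts_lig_c1 = rep(4, 8), counts_rec_c2 = rep(4, 8))
  r1 <- permutation_test(b, "LIG1", "REC1", "C1", "C2", n_perm = 99,
                         seed = 5)
  r2 <- permutation_test(b, "LIG1", "REC1", "C1", "C2", n_perm = 99,
                         seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal((r1$p_value * 100) %% 1, 0, tolerance = 1e-9)
  r3 <- permutation_test(b, "LIG1", "REC1", "C1", "C2", n_perm = 99,
                         seed = 6)
  expect_true(abs(r3$p_value - r1$p_value) < 0.2)  # same test, new draws
})

test_that("exact permutation p matches independent exhaustive enumeration", {
  # 6 cells, 3 per cluster: 20 distinct label assignments
  set.seed(61)
  genes <- c("LIG1", "REC1", "g1", "MT-1")
  m <- matrix(rpois(4 * 6, 4) + 1, 4, 6,
              dimnames = list(genes, paste0("c", 1:6)))
  bundle <- single_cell_bundle(
    Matrix::Matrix(m, sparse = TRUE),
    data.frame(barcode = colnames(m), cluster = rep(c("C1", "C2"), each = 3),
               sample = "P1", stringsAsFactors = FALSE),
    data.frame(gene = genes, is_mito = genes == "MT-1",
               is_ligand = genes == "LIG1", is_receptor = genes == "REC1",
               stringsAsFactors = FALSE)
  )
  res <- permutation_test(bundle, "LIG1", "REC1", "C1", "C2", exact = TRUE)
  expect_identical(res$n_perm, 20L)

  # oracle: choose(6, 3) C1 index sets, dense arithmetic throughout
  expr <- oracle_lognorm(m)
  obs <- (mean(expr["LIG1", 1:3]) + mean(expr["REC1", 4:6])) / 2
  picks <- combn(6, 3, simplify = FALSE)
  stats <- vapply(picks, function(idx) {
    (mean(expr["LIG1", idx]) + mean(expr["REC1", setdiff(1:6, idx)])) / 2
  }, numeric(1))
  p_oracle <- mean(stats >= obs - 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("permutation p is null-calibrated (super-uniform) under label exchange", {
  # expression identical in distribution across clusters -> null is true
  pvals <- vapply(1:60, function(s) {
    b <- generate_single_cell_bundle(n_clusters = 2, cells_per_cluster = 15,
                                     n_genes = 60, n_lr_pairs = 1,
                                     lr_frac = 0.5, seed = 600 + s)
    permutation_test(b, "LIG1", "REC1", "C1", "C2", n_perm = 99,
                     seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  for (alpha in c(0.05, 0.1)) {
    expect_lte(mean(pvals <= alpha), alpha + 3 * sqrt(alpha / 60))
  }
})

test_that("stratified permutations keep per-sample label counts fixed", {
  b <- generate_single_cell_bundle(n_clusters = 2, cells_per_cluster = 20,
                                   n_genes = 60, n_lr_pairs = 1,
                                   n_samples = 2, seed = 62)
  res <- permutation_test(b, "LIG1", "REC1", "C1", "C2", n_perm = 50,
                          seed = 7, stratify_by_sample = TRUE)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("exhaustion screen classifies planted positive pairs and skips constants", {
  n_samp <- 30
  set.seed(63)
  exhausted <- runif(n_samp, 0.05, 0.6)
  names(exhausted) <- sprintf("P%02d", 1:n_samp)
  strengths <- rbind(
    planted = 2 * exhausted + rnorm(n_samp, sd = 0.05),
    neg = 1 - exhausted + rnorm(n_samp, sd = 0.05),
    null1 = rnorm(n_samp),
    flat = rep(1, n_samp)
  )
  colnames(strengths) <- names(exhausted)
  out <- interaction_exhaustion_screen(strengths, exhausted)
  expect_identical(out$class[out$pair == "planted"], "positive")
  expect_identical(out$class[out$pair == "neg"], "negative")
  expect_identical(out$class[out$pair == "flat"], "skipped")
  expect_gt(out$r[out$pair == "planted"], 0.9)

  # exactly proportional strengths give r = 1
  prop <- rbind(exact = 3 * exhausted)
  colnames(prop) <- names(exhausted)
  expect_equal(interaction_exhaustion_screen(prop, exhausted)$r, 1,
               tolerance = 1e-12)
})

test_that("planted positive pairs are recovered with high power across seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(700 + s)
    n <- 30
    y <- runif(n)
    names(y) <- sprintf("P%02d", 1:n)
    planted <- t(sapply(1:5, function(i) {
      0.9 * scale(y)[, 1] + sqrt(1 - 0.81) * rnorm(n)
    }))
    nulls <- matrix(rnorm(20 * n), 20, n)
    strengths <- rbind(planted, nulls)
    rownames(strengths) <- c(sprintf("pos%d", 1:5), sprintf("null%d", 1:20))
    colnames(strengths) <- names(y)
    out <- interaction_exhaustion_screen(strengths, y)
    sum(out$class[1:5] == "positive")
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.9)
})
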