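#' Log-normalize single-cell counts
#'
#' Library-size normalization followed by a log transform:
#' `log2(1 + scale_factor * count / library_size)` per cell. Used for
#' ligand-receptor interaction strengths, which average normalized expression
#' over cluster cells.
#'
#' @param bundle An [single_cell_bundle()].
#' @param scale_factor Counts-per-`scale_factor` normalization target.
#' @return Sparse genes x cells matrix of log-normalized expression.
#' @export
log_normalize_counts <- function(bundle, scale_factor = 1e4) {
  counts <- bundle$counts
  libsize <- Matrix::colSums(counts)
  if (any(libsize == 0)) {
    stop("bundle contains cells with zero total counts; run qc_filter() first",
         call. = FALSE)
  }
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / libsize)
  norm@x <- log2(1 + norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

lr_cluster_cells <- function(bundle, cluster) {
  idx <- which(bundle$cell_meta$cluster == cluster)
  if (!length(idx)) {
    stop(sprintf("unknown or empty cluster '%s'", cluster), call. = FALSE)
  }
  idx
}

# Mean-of-means strength on a plain expression matrix and index vectors.
lr_strength_stat <- function(expr, ligand, receptor, sender_idx,
                             receiver_idx) {
  (mean(expr[ligand, sender_idx]) + mean(expr[receptor, receiver_idx])) / 2
}

#' Ligand-receptor interaction strength between two clusters
#'
#' The strength of a ligand-receptor pair from a sender to a receiver cluster
#' is the arithmetic mean of the ligand's mean log-normalized expression over
#' sender cells and the receptor's over receiver cells (the CellPhoneDB
#' convention). The pair is gated out (strength `NA`, `gated = TRUE`) unless
#' the ligand is expressed (count > 0) in strictly more than `min_frac` of
#' sender cells and the receptor in more than `min_frac` of receiver cells.
#'
#' @param bundle An [single_cell_bundle()].
#' @param ligand,receptor Gene symbols present in the bundle.
#' @param sender,receiver Cluster labels.
#' @param min_frac Expression-fraction gate (default 0.10).
#' @param expr Optional precomputed log-normalized matrix (from
#'   [log_normalize_counts()]) to avoid repeated normalization.
#' @return List with `strength` (NA when gated), `gated`, and the two
#'   expressing fractions.
#' @export
interaction_strength <- function(bundle, ligand, receptor, sender, receiver,
                                 min_frac = 0.10, expr = NULL) {
  genes <- rownames(bundle$counts)
  for (g in c(ligand, receptor)) {
    if (!g %in% genes) {
      stop(sprintf("gene '%s' not in the bundle", g), call. = FALSE)
    }
  }
  s_idx <- lr_cluster_cells(bundle, sender)
  r_idx <- lr_cluster_cells(bundle, receiver)
  frac_lig <- mean(bundle$counts[ligand, s_idx] > 0)
  frac_rec <- mean(bundle$counts[receptor, r_idx] > 0)
  gated <- !(frac_lig > min_frac && frac_rec > min_frac)
  if (gated) {
    return(list(strength = NA_real_, gated = TRUE,
                frac_ligand = frac_lig, frac_receptor = frac_rec))
  }
  expr <- expr %||% log_normalize_counts(bundle)
  list(strength = lr_strength_stat(expr, ligand, receptor, s_idx, r_idx),
       gated = FALSE, frac_ligand = frac_lig, frac_receptor = frac_rec)
}

# All distinct assignments of the multiset of cluster labels to cells,
# as a list of label vectors. Used for exact permutation tests on tiny
# bundles; errors out beyond `limit` assignments.
enumerate_label_assignments <- function(labels, limit = 1e5) {
  tab <- c(table(labels))
  n_assign <- exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
  if (n_assign > limit) {
    stop(sprintf("exact enumeration infeasible: %.0f distinct assignments",
                 n_assign), call. = FALSE)
  }
  recurse <- function(free_idx, remaining) {
    lev <- names(remaining)[remaining > 0]
    if (length(lev) == 1L) {
      return(list(stats::setNames(list(free_idx), lev)))
    }
    first <- lev[1L]
    picks <- utils::combn(free_idx, remaining[[first]], simplify = FALSE)
    rem <- remaining
    rem[[first]] <- 0L
    out <- list()
    for (p in picks) {
      for (s in recurse(setdiff(free_idx, p), rem)) {
        s[[first]] <- p
        out <- c(out, list(s))
      }
    }
    out
  }
  assignments <- recurse(seq_along(labels), tab)
  lapply(assignments, function(a) {
    v <- character(length(labels))
    for (lev in names(a)) v[a[[lev]]] <- lev
    v
  })
}

#' Permutation test for a ligand-receptor interaction
#'
#' Empirical significance of an interaction strength: cluster labels of all
#' cells are permuted jointly `n_perm` times (default 1000) and the strength
#' recomputed; `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)` (the
#' add-one Monte-Carlo convention, so p is never 0 and is a multiple of
#' `1/(n_perm + 1)`). With `exact = TRUE` all distinct label assignments are
#' enumerated instead and `p` is the exact fraction of assignments with
#' strength at or above the observed one (the observed assignment is in the
#' enumeration). A `stratify_by_sample` option permutes labels within each
#' sample.
#'
#' @inheritParams interaction_strength
#' @param n_perm Number of permutations (`>= 1`).
#' @param seed Integer seed.
#' @param exact Enumerate all distinct assignments instead of sampling.
#' @param stratify_by_sample Permute within samples rather than across all
#'   cells.
#' @return List of class `lr_result`: `ligand`, `receptor`, `sender`,
#'   `receiver`, `strength`, `p_value`, `n_perm`, `gated`.
#' @export
permutation_test <- function(bundle, ligand, receptor, sender, receiver,
                             n_perm = 1000, seed = 1, min_frac = 0.10,
                             exact = FALSE, stratify_by_sample = FALSE) {
  if (!exact && n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  obs <- interaction_strength(bundle, ligand, receptor, sender, receiver,
                              min_frac = min_frac)
  if (obs$gated) {
    stop("interaction is gated (expression fraction below the gate); no test",
         call. = FALSE)
  }
  expr <- log_normalize_counts(bundle)
  labels <- bundle$cell_meta$cluster
  stat_for <- function(lab) {
    lr_strength_stat(expr, ligand, receptor,
                     which(lab == sender), which(lab == receiver))
  }

  if (exact) {
    assignments <- enumerate_label_assignments(labels)
    stats_all <- vapply(assignments, stat_for, numeric(1))
    p <- mean(stats_all >= obs$strength - 1e-12)
    n_used <- length(assignments)
  } else {
    perm_stats <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        lab <- if (stratify_by_sample) {
          out <- labels
          for (s in unique(bundle$cell_meta$sample)) {
            idx <- which(bundle$cell_meta$sample == s)
            out[idx] <- labels[sample(idx)]
          }
          out
        } else {
          sample(labels)
        }
        stat_for(lab)
      }, numeric(1))
    })
    p <- (1 + sum(perm_stats >= obs$strength - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(ligand = ligand, receptor = receptor, sender = sender,
                 receiver = receiver, strength = obs$strength,
                 p_value = p, n_perm = n_used, gated = FALSE),
            class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("<lr_result> %s -> %s: %s_%s strength %.3f, p = %.4g (%d perms)\n",
              x$sender, x$receiver, x$ligand, x$receptor,
              x$strength, x$p_value, x$n_perm))
  invisible(x)
}

#' Interaction-vs-exhaustion correlation screen
#'
#' Correlates, across samples, per-sample interaction strengths of a panel of
#' ligand-receptor pairs with the per-sample fraction of exhausted CD8 T
#' cells, classifying each pair as a positive, negative or non-significant
#' correlate of exhaustion (two-sided Pearson test at `alpha`). Pairs with a
#' constant strength vector are skipped with a flag.
#'
#' @param strengths Pairs x samples numeric matrix of per-sample interaction
#'   strengths (rownames = pair names).
#' @param exhausted_frac Named numeric vector of per-sample exhausted-cell
#'   fractions covering the columns of `strengths`.
#' @param alpha Significance level for the sign classification.
#' @return data.frame with columns `pair`, `r`, `p_value`, `class`
#'   (`positive` / `negative` / `ns` / `skipped`).
#' @export
interaction_exhaustion_screen <- function(strengths, exhausted_frac,
                                          alpha = 0.05) {
  if (!is.matrix(strengths) || is.null(rownames(strengths))) {
    stop("'strengths' must be a pairs x samples matrix with pair rownames",
         call. = FALSE)
  }
  missing <- setdiff(colnames(strengths), names(exhausted_frac))
  if (length(missing)) {
    stop(sprintf("missing exhausted fraction for sample(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  y <- exhausted_frac[colnames(strengths)]
  if (ncol(strengths) < 3L) {
    stop("need >= 3 samples for the correlation screen", call. = FALSE)
  }
  rows <- lapply(rownames(strengths), function(pair) {
    x <- strengths[pair, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(pair = pair, r = NA_real_, p_value = NA_real_,
                        class = "skipped", stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    cls <- if (ct$p.value < alpha) {
      if (ct$estimate > 0) "positive" else "negative"
    } else {
      "ns"
    }
    data.frame(pair = pair, r = unname(ct$estimate), p_value = ct$p.value,
               class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
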