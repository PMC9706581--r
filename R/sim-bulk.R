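#' Synthetic signature sets
#'
#' Generates disjoint stand-in gene sets with deterministic symbols for the
#' four signatures the pipeline scores: the luminal and basal halves of the
#' subtype panel, the immunosuppressive-macrophage (Macro-C3) signature and
#' the T-cell cytotoxicity signature. Real signatures are loaded from GMT with
#' [read_gmt()] instead; these exist so that every downstream stage is
#' testable without external gene lists. Default sizes mirror a 47-gene
#' luminal/basal panel (24 + 23).
#'
#' @param n_luminal,n_basal,n_macro,n_cytotox Set sizes, each `>= 2`.
#' @param seed Integer seed (kept for interface uniformity; the symbols are
#'   deterministic functions of the sizes).
#' @return Named list of four [gene_set()]s: `BASE47-luminal`, `BASE47-basal`,
#'   `Macro-C3`, `cytotoxicity`.
#' @export
generate_signature_sets <- function(n_luminal = 24, n_basal = 23,
                                    n_macro = 10, n_cytotox = 8, seed = 1) {
  sizes <- c(n_luminal = n_luminal, n_basal = n_basal,
             n_macro = n_macro, n_cytotox = n_cytotox)
  for (nm in names(sizes)) {
    if (!is.numeric(sizes[[nm]]) || sizes[[nm]] < 2) {
      stop(sprintf("'%s' must be >= 2", nm), call. = FALSE)
    }
  }
  mk <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  list(
    "BASE47-luminal" = gene_set("BASE47-luminal", mk("LUM", n_luminal),
                                "synthetic luminal half of the subtype panel"),
    "BASE47-basal" = gene_set("BASE47-basal", mk("BAS", n_basal),
                              "synthetic basal half of the subtype panel"),
    "Macro-C3" = gene_set("Macro-C3", mk("MAC", n_macro),
                          "synthetic immunosuppressive macrophage signature"),
    "cytotoxicity" = gene_set("cytotoxicity", mk("CTX", n_cytotox),
                              "synthetic T-cell cytotoxicity signature")
  )
}

#' Configuration for the synthetic bulk cohort generator
#'
#' Encodes the statistical structure the downstream analysis assumes: a latent
#' basal differentiation axis along which basal-signature genes rise and
#' luminal-signature genes fall, with the Macro-C3 and cytotoxicity signature
#' genes also rising (immunosuppressive macrophage infiltration and T-cell
#' cytotoxicity both increase with the basal program), and an ICI response
#' probability tied to the macrophage score only below a latent evasion
#' threshold.
#'
#' The latent axis is uniform with unit half-width centered on
#' `threshold_a_true` (so `[-1, 1]` for the default threshold 0). Centering
#' the cohort on its threshold is what makes the threshold identifiable by the
#' regression-intersection model: with both responses z-scored, each fitted
#' line passes through the axis mean, so the intersection estimates the center
#' of the sampled axis.
#'
#' Below the threshold, responder probability is
#' `plogis(qlogis(p_base) + response_link_strength * z)` where `z` is the
#' standardized latent macrophage score; at/above it, the same expression is
#' evaluated at the cohort-minimum `z` — a constant low baseline, decoupled
#' from each sample's own score (the evasion regime). With
#' `response_link_strength = 0` the probability is `p_base` everywhere and
#' labels are independent of all scores.
#'
#' @param n_samples Cohort size, `>= 8`.
#' @param n_genes Total genes; must cover all signature genes plus at least 50
#'   background genes.
#' @param threshold_a_true Latent evasion threshold on the axis scale.
#' @param slope_cytotox,slope_macro Log2-expression change of the cytotoxicity
#'   and Macro-C3 signature genes per unit of latent axis.
#' @param slope_basal,slope_luminal Same for the subtype panel halves
#'   (`slope_luminal` should be negative).
#' @param response_link_strength Logistic slope (per SD of latent macrophage
#'   score) linking score to response below the threshold; `>= 0`.
#' @param p_base Baseline responder probability (at average macrophage score).
#' @param noise_sd SD of gene-level Gaussian noise on the log2 scale, `> 0`.
#' @param signatures Signature sets to embed; defaults to
#'   [generate_signature_sets()].
#' @param seed Integer seed; mandatory, never taken from global state.
#' @return A validated list of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_samples = 400, n_genes = 500,
                            threshold_a_true = 0,
                            slope_cytotox = 1.5, slope_macro = 1.5,
                            slope_basal = 2, slope_luminal = -2,
                            response_link_strength = 2, p_base = 0.3,
                            noise_sd = 0.3,
                            signatures = generate_signature_sets(),
                            seed = 1) {
  stopifnot_scalar_number(n_samples, "n_samples")
  stopifnot_scalar_number(n_genes, "n_genes")
  stopifnot_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  stopifnot_scalar_number(response_link_strength, "response_link_strength")
  stopifnot_scalar_number(threshold_a_true, "threshold_a_true")
  if (n_samples < 8) stop("'n_samples' must be >= 8", call. = FALSE)
  if (response_link_strength < 0) {
    stop("'response_link_strength' must be >= 0", call. = FALSE)
  }
  if (p_base <= 0 || p_base >= 1) {
    stop("'p_base' must be in (0, 1)", call. = FALSE)
  }
  sig_genes <- unlist(lapply(signatures, function(s) s$genes))
  if (anyDuplicated(sig_genes)) {
    stop("signature sets overlap; they must be disjoint", call. = FALSE)
  }
  if (n_genes < length(sig_genes) + 50) {
    stop(sprintf("'n_genes' must be >= %d (all signature genes + 50 background)",
                 length(sig_genes) + 50), call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         threshold_a_true = threshold_a_true,
         slope_cytotox = slope_cytotox, slope_macro = slope_macro,
         slope_basal = slope_basal, slope_luminal = slope_luminal,
         response_link_strength = response_link_strength, p_base = p_base,
         noise_sd = noise_sd, signatures = signatures,
         seed = as.integer(seed)),
    class = "bulk_sim_config"
  )
}

#' Generate a synthetic bulk expression cohort
#'
#' Expression is generated on the log2 scale as gene baseline + latent-axis
#' effect + Gaussian noise, exponentiated, and column-rescaled to TPM (each
#' sample sums to 1e6). Rank-based scoring downstream only needs this
#' monotone structure. The returned truth table carries the latent axis, the
#' noiseless latent signature values, the standardized latent macrophage
#' score, each sample's responder probability and drawn 0/1 label, plus the
#' generating threshold and seed.
#'
#' @param config A [bulk_sim_config()].
#' @return Object of class `sim_cohort`: list with `expression`
#'   (an [expression_matrix()], TPM scale), `truth` (data.frame), `signatures`
#'   and `config`.
#' @export
generate_bulk_cohort <- function(config) {
  if (!inherits(config, "bulk_sim_config")) {
    stop("'config' must be a bulk_sim_config()", call. = FALSE)
  }
  with_local_seed(config$seed, {
    n <- config$n_samples
    sig <- config$signatures
    sig_genes <- unlist(lapply(sig, function(s) s$genes), use.names = FALSE)
    n_bg <- config$n_genes - length(sig_genes)
    genes <- c(sig_genes, sprintf("BG%04d", seq_len(n_bg)))
    samples <- sprintf("S%03d", seq_len(n))

    # per-gene latent-axis effect on the log2 scale
    beta <- stats::setNames(numeric(config$n_genes), genes)
    beta[sig[["BASE47-basal"]]$genes] <- config$slope_basal
    beta[sig[["BASE47-luminal"]]$genes] <- config$slope_luminal
    beta[sig[["Macro-C3"]]$genes] <- config$slope_macro
    beta[sig[["cytotoxicity"]]$genes] <- config$slope_cytotox

    t_axis <- stats::runif(n, config$threshold_a_true - 1,
                           config$threshold_a_true + 1)
    baseline <- stats::rnorm(config$n_genes, mean = 5, sd = 1.5)
    centered <- t_axis - config$threshold_a_true
    log2_expr <- outer(baseline, rep(1, n)) + outer(beta, centered) +
      matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
             config$n_genes, n)
    tpm <- 2^log2_expr
    tpm <- sweep(tpm, 2L, colSums(tpm), "/") * 1e6
    dimnames(tpm) <- list(genes, samples)

    m_true <- config$slope_macro * t_axis
    c_true <- config$slope_cytotox * t_axis
    sd_m <- stats::sd(m_true)
    macro_z <- if (is.finite(sd_m) && sd_m > 0) {
      (m_true - mean(m_true)) / sd_m
    } else {
      rep(0, n)
    }
    eta0 <- stats::qlogis(config$p_base)
    link <- config$response_link_strength
    below <- t_axis < config$threshold_a_true
    p <- ifelse(below,
                stats::plogis(eta0 + link * macro_z),
                stats::plogis(eta0 + link * min(macro_z)))
    responder <- stats::rbinom(n, 1L, p)

    truth <- data.frame(
      sample = samples, latent_axis = t_axis,
      cytotox_true = c_true, macro_true = m_true, macro_z = macro_z,
      p_response = p, responder = responder,
      threshold_a_true = config$threshold_a_true, seed = config$seed,
      stringsAsFactors = FALSE
    )
    structure(
      list(expression = expression_matrix(tpm, scale = "tpm"),
           truth = truth, signatures = sig, config = config),
      class = "sim_cohort"
    )
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d genes x %d samples (seed %d)\n",
              nrow(x$expression), ncol(x$expression), x$config$seed))
  cat(sprintf("  latent threshold %.3f; %d/%d responders\n",
              x$config$threshold_a_true, sum(x$truth$responder),
              nrow(x$truth)))
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' Writes `expression.tsv` (genes x samples TPM), `truth.tsv` and
#' `signatures.gmt`.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "sim_cohort")) {
    stop("'cohort' must be a sim_cohort", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  invisible(dir)
}
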