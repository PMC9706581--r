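#' Fit the immune-evasion regression-intersection model
#'
#' The core model of the package. Two ordinary-least-squares lines are fitted
#' against the log(basal/luminal) subtype axis: `L_C` with the z-scored
#' T-cell cytotoxicity score as response, and `L_M` with the z-scored
#' Macro-C3 (immunosuppressive macrophage) score as response. Their
#' intersection `(a, b)` defines the cohort's immune-evasion threshold: below
#' `a`, cytotoxicity dominates the macrophage signal and the Macro-C3 score
#' tracks ICI response; at or above `a`, the macrophage signal dominates and
#' the score is read as immune-evasion capacity instead.
#'
#' A consequence of z-scoring both responses on the same samples is that each
#' OLS line passes through `(mean(log_ratio), 0)`, so for z-scored inputs the
#' intersection abscissa equals the cohort mean log-ratio exactly; the fitter
#' itself is generic and accepts any numeric responses.
#'
#' @param log_ratio Numeric vector, the per-sample log(basal/luminal) score
#'   (see [subtype_axis()]); the independent variable for both lines.
#' @param cytotox Numeric response for line `L_C` (z-scored cytotoxicity in
#'   the published pipeline; see [zscore()]).
#' @param macro Numeric response for line `L_M` (z-scored Macro-C3 score).
#' @param robust If `TRUE`, fit both lines by iterated reweighted least
#'   squares with Huber weights instead of OLS.
#' @return An object of class `evasion_fit` with components `lines` (2 x 2
#'   matrix of intercepts and slopes for `L_C`, `L_M`), `a`, `b` (the
#'   intersection), `n`, `data` (the three input vectors), `robust`, `call`.
#' @examples
#' x <- c(-1, 0, 1, 2)
#' fit <- fit_evasion_model(x, cytotox = 2 * x + 1, macro = -x + 4)
#' fit$a  # 1
#' fit$b  # 3
#' @export
fit_evasion_model <- function(log_ratio, cytotox, macro, robust = FALSE) {
  x <- as.numeric(log_ratio)
  zc <- as.numeric(cytotox)
  zm <- as.numeric(macro)
  n <- length(x)
  if (length(zc) != n || length(zm) != n) {
    stop("log_ratio, cytotox and macro must have equal length", call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 samples to fit the model", call. = FALSE)
  if (anyNA(x) || anyNA(zc) || anyNA(zm)) {
    stop("inputs contain NA", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("log(basal/luminal) is constant; lines are not identifiable",
         call. = FALSE)
  }
  fit1 <- if (robust) rlm_huber(x, zc) else stats::lm.fit(cbind(1, x), zc)$coefficients
  fit2 <- if (robust) rlm_huber(x, zm) else stats::lm.fit(cbind(1, x), zm)$coefficients
  lines <- rbind(L_C = fit1, L_M = fit2)
  colnames(lines) <- c("intercept", "slope")

  dslope <- lines["L_C", "slope"] - lines["L_M", "slope"]
  if (abs(dslope) < 1e-12) {
    stop("fitted lines are parallel; intersection threshold undefined",
         call. = FALSE)
  }
  a <- (lines["L_M", "intercept"] - lines["L_C", "intercept"]) / dslope
  b <- lines["L_C", "slope"] * a + lines["L_C", "intercept"]

  structure(
    list(lines = lines, a = unname(a), b = unname(b), n = n,
         data = list(log_ratio = x, cytotox = zc, macro = zm,
                     sample = names(log_ratio)),
         robust = robust, call = match.call()),
    class = "evasion_fit"
  )
}

# Huber IRLS line fit; k = 1.345 (95% Gaussian efficiency).
rlm_huber <- function(x, y, k = 1.345, maxit = 50L, tol = 1e-10) {
  beta <- stats::lm.fit(cbind(1, x), y)$coefficients
  for (i in seq_len(maxit)) {
    r <- y - beta[1] - beta[2] * x
    s <- stats::mad(r)
    if (s == 0) break
    w <- pmin(1, k * s / abs(r))
    w[!is.finite(w)] <- 1
    newb <- stats::lm.wfit(cbind(1, x), y, w)$coefficients
    if (max(abs(newb - beta)) < tol) {
      beta <- newb
      break
    }
    beta <- newb
  }
  beta
}

#' @export
print.evasion_fit <- function(x, digits = 4, ...) {
  cat("Immune-evasion regression-intersection model\n")
  cat(sprintf("  n = %d samples%s\n", x$n,
              if (x$robust) " (Huber robust fit)" else ""))
  cat(sprintf("  L_C (cytotoxicity): Z = %.*f %+.*f * log(basal/luminal)\n",
              digits, x$lines["L_C", "intercept"],
              digits, x$lines["L_C", "slope"]))
  cat(sprintf("  L_M (Macro-C3):     Z = %.*f %+.*f * log(basal/luminal)\n",
              digits, x$lines["L_M", "intercept"],
              digits, x$lines["L_M", "slope"]))
  cat(sprintf("  intersection (a, b) = (%.*f, %.*f)\n",
              digits, x$a, digits, x$b))
  cat(sprintf("  evasion threshold a = %.*f on the log(basal/luminal) axis\n",
              digits, x$a))
  invisible(x)
}

#' @export
coef.evasion_fit <- function(object, ...) {
  c(intercept_C = unname(object$lines["L_C", "intercept"]),
    slope_C = unname(object$lines["L_C", "slope"]),
    intercept_M = unname(object$lines["L_M", "intercept"]),
    slope_M = unname(object$lines["L_M", "slope"]),
    a = object$a, b = object$b)
}

#' @export
summary.evasion_fit <- function(object, ...) {
  res <- residuals(object)
  below <- object$data$log_ratio < object$a
  out <- list(
    fit = object,
    rmse = sqrt(colMeans(res^2)),
    n_below = sum(below),
    n_above = sum(!below)
  )
  class(out) <- "summary.evasion_fit"
  out
}

#' @export
print.summary.evasion_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual RMSE: L_C %.4f, L_M %.4f\n",
              x$rmse["cytotox"], x$rmse["macro"]))
  cat(sprintf("  samples below threshold: %d; at/above: %d\n",
              x$n_below, x$n_above))
  invisible(x)
}

#' @export
residuals.evasion_fit <- function(object, ...) {
  x <- object$data$log_ratio
  cbind(
    cytotox = object$data$cytotox -
      (object$lines["L_C", "intercept"] + object$lines["L_C", "slope"] * x),
    macro = object$data$macro -
      (object$lines["L_M", "intercept"] + object$lines["L_M", "slope"] * x)
  )
}

#' Piecewise ICI response score from a fitted evasion model
#'
#' `predict()` on an `evasion_fit` applies the piecewise scoring rule via
#' [ici_response_score()]: samples with log-ratio strictly below the threshold
#' keep their Macro-C3 score; samples at or above it receive the cohort-minimum
#' Macro-C3 score (their macrophage signal is read as evasion, not response
#' propensity).
#'
#' @param object An `evasion_fit`.
#' @param macro Macro-C3 score vector to score (defaults to the training
#'   macro response, which in the published pipeline is its z-score).
#' @param log_ratio Log(basal/luminal) vector aligned with `macro`.
#' @param threshold Threshold to use; defaults to the fitted `a`. Supplying a
#'   published cohort threshold (e.g. 0.294) overrides the fitted one.
#' @param ... Unused.
#' @return See [ici_response_score()].
#' @export
predict.evasion_fit <- function(object, macro = NULL, log_ratio = NULL,
                                threshold = object$a, ...) {
  macro <- macro %||% stats::setNames(object$data$macro, object$data$sample)
  log_ratio <- log_ratio %||%
    stats::setNames(object$data$log_ratio, object$data$sample)
  ici_response_score(macro, log_ratio, threshold)
}

#' @export
plot.evasion_fit <- function(x, ...) {
  d <- x$data
  rng <- range(c(d$cytotox, d$macro))
  graphics::plot(d$log_ratio, d$cytotox, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = "log(basal/luminal)", ylab = "z-score",
                 ylim = rng, ...)
  graphics::points(d$log_ratio, d$macro, pch = 17,
                   col = grDevices::adjustcolor("firebrick", 0.6))
  graphics::abline(x$lines["L_C", "intercept"], x$lines["L_C", "slope"],
                   col = "steelblue", lwd = 2)
  graphics::abline(x$lines["L_M", "intercept"], x$lines["L_M", "slope"],
                   col = "firebrick", lwd = 2)
  graphics::abline(v = x$a, lty = 2)
  graphics::points(x$a, x$b, pch = 4, cex = 1.5, lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("Z(cytotoxicity), L_C", "Z(Macro-C3), L_M",
                              sprintf("threshold a = %.3f", x$a)),
                   col = c("steelblue", "firebrick", "black"),
                   pch = c(16, 17, NA), lty = c(1, 1, 2))
  invisible(x)
}

#' Piecewise ICI response score
#'
#' @param macro Named numeric (or `score_vector`) of Macro-C3 scores.
#' @param log_ratio Named numeric of log(basal/luminal) scores over the same
#'   samples (any order; aligned by name when both are named).
#' @param threshold The log-ratio threshold `a`.
#' @return A data.frame with columns `sample`, `score`, `rule` where `rule` is
#'   `"below: macro_score"` or `"above: cohort_min"`. Every at/above-threshold
#'   sample's score equals `min(macro)` over the whole cohort exactly.
#' @export
ici_response_score <- function(macro, log_ratio, threshold) {
  m <- as.numeric(macro)
  r <- as.numeric(log_ratio)
  nm <- names(macro)
  if (!is.null(nm) && !is.null(names(log_ratio))) {
    if (!setequal(nm, names(log_ratio))) {
      stop("'macro' and 'log_ratio' cover different sample sets",
           call. = FALSE)
    }
    r <- as.numeric(log_ratio)[match(nm, names(log_ratio))]
  } else if (length(m) != length(r)) {
    stop("'macro' and 'log_ratio' must align on the same samples",
         call. = FALSE)
  }
  if (length(m) == 0L) stop("empty cohort", call. = FALSE)
  stopifnot_scalar_number(threshold, "threshold")
  below <- r < threshold
  floor_score <- min(m)
  data.frame(
    sample = nm %||% paste0("S", seq_along(m)),
    score = ifelse(below, m, floor_score),
    rule = ifelse(below, "below: macro_score", "above: cohort_min"),
    stringsAsFactors = FALSE
  )
}

#' Responder fraction over a grid of log-ratio cutoffs
#'
#' Evaluates, at `n_points` evenly spaced cutoffs spanning the observed
#' log-ratio range, the cumulative fraction of responders among samples with
#' log-ratio at or below the cutoff. At the final (maximal) cutoff the
#' fraction equals the cohort's overall responder rate, which makes the curve
#' self-checking. A sliding-window variant (`window = "sliding"`, fraction
#' `window_frac` of the axis range per window) is available for local rates.
#'
#' @param log_ratio Numeric per-sample log(basal/luminal).
#' @param responder Binary 0/1 response labels aligned with `log_ratio`.
#' @param n_points Number of cutoffs (256 by default).
#' @param window `"cumulative"` (default) or `"sliding"`.
#' @param window_frac Half-width of the sliding window as a fraction of the
#'   axis range (only for `window = "sliding"`).
#' @return A data.frame with columns `cutoff`, `fraction` (NA where no sample
#'   falls in the window), `n` (denominator).
#' @export
responder_fraction_curve <- function(log_ratio, responder, n_points = 256,
                                     window = c("cumulative", "sliding"),
                                     window_frac = 0.2) {
  window <- match.arg(window)
  r <- as.numeric(log_ratio)
  y <- as.numeric(responder)
  if (length(r) != length(y) || length(r) < 1L) {
    stop("'log_ratio' and 'responder' must be non-empty and aligned",
         call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("'responder' labels must be 0/1", call. = FALSE)
  }
  if (n_points < 2L) stop("'n_points' must be >= 2", call. = FALSE)
  cutoffs <- seq(min(r), max(r), length.out = n_points)
  if (window == "cumulative") {
    stats_at <- function(x) {
      sel <- r <= x
      c(sum(y[sel]), sum(sel))
    }
  } else {
    half <- window_frac * diff(range(r)) / 2
    stats_at <- function(x) {
      sel <- abs(r - x) <= half
      c(sum(y[sel]), sum(sel))
    }
  }
  m <- vapply(cutoffs, stats_at, numeric(2))
  n <- m[2, ]
  data.frame(cutoff = cutoffs,
             fraction = ifelse(n > 0, m[1, ] / n, NA_real_),
             n = as.integer(n))
}
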