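#' Odds ratio per standard deviation of a score, with Wald p-value
#'
#' Univariate logistic regression of the binary outcome on the score
#' standardized by its own sample standard deviation (maximum likelihood via
#' iteratively reweighted least squares). The exponentiated slope is the
#' odds ratio for a one-SD increase of the score; the p-value is the
#' two-sided Wald test of the slope.
#'
#' Fits with quasi-separation or failed convergence are returned with
#' `flagged = TRUE` so a simulation driver can drop and count them.
#'
#' @param y Binary outcome vector (both classes present, length >= 50).
#' @param grs Score vector, non-constant, same length as `y`.
#' @return A list: `or` (odds ratio per SD), `log_or`, `se`, `p_value`,
#'   `flagged`.
#' @export
fit_or_per_sd <- function(y, grs) {
  n <- length(y)
  if (length(grs) != n) stop("y and grs must have equal length")
  if (n < 50L) stop("need at least 50 observations for a stable fit")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  s <- stats::sd(grs)
  if (s == 0) stop("degenerate score: constant over the sample")
  z <- (grs - mean(grs)) / s
  X <- cbind(1, z)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  b <- unname(fit$coefficients[2L])
  wt <- fit$weights
  V <- tryCatch(solve(crossprod(X * sqrt(wt))), error = function(e) NULL)
  flagged <- !isTRUE(fit$converged) || is.null(V) ||
    any(fit$fitted.values < 1e-8) || any(fit$fitted.values > 1 - 1e-8) ||
    abs(b) > 10
  se <- if (is.null(V)) NA_real_ else sqrt(V[2L, 2L])
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(b / se))
  list(or = exp(b), log_or = b, se = unname(se), p_value = unname(p),
       flagged = flagged)
}

#' Rank (Mann-Whitney) estimator of the AUC
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one-half — computed from midranks, which is
#' the convention needed for integer-valued allele-count scores.
#'
#' @param y Binary outcome vector (both classes present).
#' @param grs Score vector of equal length.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(y, grs) {
  if (length(grs) != length(y)) stop("y and grs must have equal length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(grs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Closed-form AUC of a standardized score from its log odds ratio
#'
#' Binormal relation for a single predictor with equal within-class
#' variances: `AUC = pnorm(log_or_per_sd / sqrt(2))`, where `log_or_per_sd`
#' is the logistic slope of the SD-standardized score.
#'
#' @param log_or_per_sd Log odds ratio per SD (finite).
#' @return AUC in (0, 1).
#' @export
closed_form_auc <- function(log_or_per_sd) {
  stopifnot(all(is.finite(log_or_per_sd)))
  stats::pnorm(log_or_per_sd / sqrt(2))
}

#' Pearson correlation between the gold-standard and an alternate GRS
#'
#' @param gold,alt Non-constant numeric vectors of equal length.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_corr <- function(gold, alt) {
  if (length(gold) != length(alt)) stop("vectors must have equal length")
  if (stats::var(gold) == 0 || stats::var(alt) == 0)
    stop("degenerate score vector: constant over the sample")
  stats::cor(gold, alt)
}

#' Scenario-level summaries of per-iteration results
#'
#' Aggregates a long table of per-iteration metrics into one row per
#' scenario cell: the 5th/25th/50th/75th/95th percentiles of the OR per SD,
#' statistical power (share of iterations with p < `alpha`), the median AUC,
#' and percentiles of the correlation with the gold standard. Flagged
#' (non-converged / separated) iterations are excluded from the metric
#' aggregation and counted in `n_flagged`.
#'
#' @param results Data frame of per-iteration rows as produced by
#'   [run_study()] (`$iterations`): at least `scheme`, `or_input`,
#'   `proportion`, `strategy`, `or_per_sd`, `p_value`, `auc`,
#'   `corr_with_gold`, `flagged`.
#' @param strata Optional extra grouping columns (e.g.
#'   `"extremes_available"`).
#' @param alpha Significance level for the power computation (default 0.05).
#' @return Data frame with one row per scenario (x stratum) cell.
#' @export
summarize_results <- function(results, strata = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  keys <- c("scheme", "or_input", "proportion", "strategy", strata)
  keys <- keys[keys %in% names(results)]
  # paste (not interaction) so NA keys -- e.g. the gold rows' proportion --
  # form their own cell instead of being dropped
  key <- do.call(paste, c(lapply(keys, function(k) results[[k]]), sep = "\r"))
  parts <- split(results, key)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  rows <- lapply(parts, function(d) {
    hd <- d[1L, keys, drop = FALSE]
    ok <- d[!d$flagged, , drop = FALSE]
    if (nrow(ok) == 0L) {
      warning("scenario cell with no usable iterations omitted")
      return(NULL)
    }
    oq <- stats::quantile(ok$or_per_sd, qs, names = FALSE)
    cq <- stats::quantile(ok$corr_with_gold, qs, names = FALSE, na.rm = TRUE)
    cbind(hd,
          data.frame(n_iter = nrow(ok), n_flagged = sum(d$flagged),
                     or_p5 = oq[1], or_p25 = oq[2], or_median = oq[3],
                     or_p75 = oq[4], or_p95 = oq[5],
                     power = mean(ok$p_value < alpha),
                     median_auc = stats::median(ok$auc),
                     corr_p5 = cq[1], corr_p25 = cq[2], corr_median = cq[3],
                     corr_p75 = cq[4], corr_p95 = cq[5]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$scheme, out$or_input, out$proportion,
            match(out$strategy, c("gold", grs_strategies))), , drop = FALSE]
}

#' Bin the mean MAF of masked SNPs for stratified summaries
#'
#' @param results Per-iteration data frame with a `mean_maf_missing` column.
#' @param breaks Bin edges on the MAF scale.
#' @return `results` with an added factor column `maf_bin`.
#' @export
add_maf_bins <- function(results, breaks = seq(0.05, 0.5, by = 0.05)) {
  stopifnot("mean_maf_missing" %in% names(results))
  results$maf_bin <- cut(results$mean_maf_missing, breaks = breaks,
                         include.lowest = TRUE)
  results
}
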