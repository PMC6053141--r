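#' Linear predictor of the logistic causal model
#'
#' `eta_j = mu + sum_i beta_i X_ij` over the causal SNPs. With a common
#' scheme (all betas equal) this reduces to `mu + beta * rowSums(X)`, the
#' unweighted count form of the model.
#'
#' @param X Genotype matrix (individuals x causal SNPs), allele counts.
#' @param scheme A `"grs_weights"` with calibrated `mu`.
#' @return Numeric vector of logits, one per row of `X`.
#' @export
linear_predictor <- function(X, scheme) {
  stopifnot(inherits(scheme, "grs_weights"))
  X <- as.matrix(X)
  if (ncol(X) != length(scheme$betas))
    stop("X must have one column per SNP in the weight scheme")
  if (is.na(scheme$mu))
    stop("scheme has no calibrated intercept; run calibrate_mu() first")
  drop(scheme$mu + X %*% scheme$betas)
}

#' Disease risk from a logit
#'
#' Inverse-logit transform `exp(eta) / (1 + exp(eta))`.
#'
#' @param eta Numeric vector of logits.
#' @return Risks strictly inside (0, 1).
#' @export
risk <- function(eta) {
  stopifnot(all(is.finite(eta)))
  stats::plogis(eta)
}

#' Calibrate the model intercept to a target disease prevalence
#'
#' Chooses `mu` so that the expected prevalence `E[expit(mu + sum beta_i X_i)]`
#' over the panel's MAF spectrum equals `target_prev`. A Monte Carlo
#' calibration sample of `n_cal` genotype rows is drawn once (in chunks, each
#' chunk with a fresh MAF vector so the calibration integrates over the MAF
#' distribution, as a fresh panel is generated per simulated dataset);
#' bisection on `mu` against this fixed sample is then deterministic and
#' monotone. The achieved sample prevalence must land within `tol` of the
#' target, else an error is raised.
#'
#' @param scheme A `"grs_weights"` (its `mu` is ignored).
#' @param maf Optional fixed MAF vector (one per SNP); if `NULL`, each chunk
#'   draws MAFs uniformly from `maf_range`.
#' @param maf_range MAF spectrum when `maf` is `NULL`.
#' @param n_cal Calibration-sample size (default 200000 rows).
#' @param chunk_size Rows sharing one MAF vector (default 400, the target
#'   sample size).
#' @param target_prev Target marginal frequency of the outcome (default 0.5).
#' @param tol Acceptable absolute deviation of the achieved prevalence.
#' @return The calibrated intercept `mu` (numeric scalar).
#' @export
calibrate_mu <- function(scheme, maf = NULL, maf_range = c(0.05, 0.5),
                         n_cal = 200000L, chunk_size = 400L,
                         target_prev = 0.5, tol = 0.005) {
  stopifnot(inherits(scheme, "grs_weights"),
            target_prev > 0, target_prev < 1, tol > 0)
  m <- length(scheme$betas)
  if (!is.null(maf)) stopifnot(length(maf) == m, all(maf > 0), all(maf < 1))
  n_chunks <- ceiling(n_cal / chunk_size)
  eta0 <- numeric(n_chunks * chunk_size)
  for (k in seq_len(n_chunks)) {
    p <- if (is.null(maf)) stats::runif(m, maf_range[1], maf_range[2]) else maf
    X <- matrix(stats::rbinom(chunk_size * m, 2L, rep(p, each = chunk_size)),
                chunk_size, m)
    eta0[(k - 1L) * chunk_size + seq_len(chunk_size)] <- X %*% scheme$betas
  }
  f <- function(mu) mean(stats::plogis(mu + eta0))
  lo <- -40; hi <- 40
  if (f(lo) > target_prev || f(hi) < target_prev)
    stop("calibration failed: target prevalence not bracketed")
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target_prev) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  mu <- (lo + hi) / 2
  if (abs(f(mu) - target_prev) > tol)
    stop("calibration did not converge to the target prevalence")
  mu
}

#' Draw Bernoulli phenotypes from per-individual risks
#'
#' @param risks Vector of probabilities strictly inside (0, 1) (a degenerate
#'   all-0/all-1 risk vector is allowed at the boundaries for testing).
#' @return An object of class `"grs_phenotypes"`: `risks`, binary
#'   `outcomes`, and the realized `prevalence`.
#' @export
draw_phenotypes <- function(risks) {
  stopifnot(all(risks >= 0), all(risks <= 1))
  y <- stats::rbinom(length(risks), 1L, risks)
  structure(list(risks = risks, outcomes = y, prevalence = mean(y)),
            class = "grs_phenotypes")
}

#' @export
print.grs_phenotypes <- function(x, ...) {
  cat(sprintf("Simulated binary phenotype: n = %d, prevalence = %.3f\n",
              length(x$outcomes), x$prevalence))
  invisible(x)
}
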