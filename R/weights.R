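#' Construct a per-SNP weight scheme
#'
#' Low-level constructor used by [make_common_weights()],
#' [make_tada_like_weights()] and [unit_weights()]. Weights are per-allele
#' odds ratios; the log ORs are the betas of the logistic causal model. The
#' intercept `mu` is unset (`NA`) until calibrated with [calibrate_mu()].
#'
#' @param ors Vector of per-allele odds ratios (> 0).
#' @param kind One of `"common"`, `"tada_like"`, `"unit"`.
#' @param extreme_ids SNP ids of the large-weight outliers (`tada_like` only).
#' @param ids SNP identifiers; default `snp01 ... snpNN`.
#' @param mu Intercept on the logit scale (optional).
#' @return An object of class `"grs_weights"`.
#' @export
weight_scheme <- function(ors, kind, extreme_ids = character(),
                          ids = sprintf("snp%02d", seq_along(ors)),
                          mu = NA_real_) {
  stopifnot(all(ors > 0), length(ids) == length(ors),
            kind %in% c("common", "tada_like", "unit"),
            all(extreme_ids %in% ids))
  structure(list(ids = ids, ors = as.numeric(ors), betas = log(ors),
                 mu = mu, kind = kind, extreme_ids = extreme_ids),
            class = "grs_weights")
}

#' @export
print.grs_weights <- function(x, ...) {
  cat(sprintf("GRS weight scheme '%s': %d SNPs, OR median %.3f [%.3f, %.3f]\n",
              x$kind, length(x$ors), stats::median(x$ors), min(x$ors),
              max(x$ors)))
  if (length(x$extreme_ids))
    cat("  extreme-weight SNPs:", paste(x$extreme_ids, collapse = ", "), "\n")
  cat(sprintf("  intercept mu: %s\n",
              if (is.na(x$mu)) "not calibrated" else sprintf("%.4f", x$mu)))
  invisible(x)
}

#' Equal-weight ("common") scheme for an unweighted GRS design
#'
#' All 50 SNPs carry the same per-allele odds ratio, so the causal model
#' reduces to intercept + beta * (risk-allele count). The design range of the
#' per-allele OR is 1.05 to 1.10.
#'
#' @param or_value Per-allele odds ratio in \[1.05, 1.10\].
#' @param n_snps Number of SNPs (default 50).
#' @return A `"grs_weights"` object of kind `"common"`.
#' @export
make_common_weights <- function(or_value, n_snps = 50L) {
  stopifnot(length(or_value) == 1L)
  if (or_value < 1.05 || or_value > 1.10)
    stop("per-allele OR must lie in the design range [1.05, 1.10]")
  weight_scheme(rep(or_value, n_snps), kind = "common")
}

#' Unit weights: the risk-allele-counting GRS
#'
#' All betas equal 1, so the score is the plain count of risk alleles. Used
#' as the score-side weights of the unweighted GRS (odds-ratio-per-SD and
#' correlation metrics are invariant to the common scale factor).
#'
#' @param n_snps Number of SNPs (default 50).
#' @return A `"grs_weights"` object of kind `"unit"`.
#' @export
unit_weights <- function(n_snps = 50L) {
  weight_scheme(rep(exp(1), n_snps), kind = "unit")
}

# interquartile range 0.04 for a symmetric triangular distribution:
# quartiles sit at +/- w (1 - 1/sqrt(2)) around the centre
tada_tri_halfwidth <- function(iqr = 0.04) iqr / (2 * (1 - 1 / sqrt(2)))

#' Heavy-tailed ("Tada-like") weight scheme
#'
#' Emulates a published 50-SNP coronary-heart-disease score from its printed
#' summary statistics: three fixed extreme per-allele ORs (1.51, 1.45, 1.29)
#' placed at random SNP positions, plus 47 ORs drawn from a symmetric
#' triangular distribution centred at 1.07 with interquartile range 0.04, so
#' that each extreme OR lies more than 1.5 IQR above the set's third
#' quartile. The exact published OR vector is not reproduced, only its
#' summary statistics.
#'
#' @param n_snps Number of SNPs (default 50).
#' @param extremes The three extreme per-allele ORs.
#' @param center,iqr Centre and interquartile range of the non-extreme ORs.
#' @return A `"grs_weights"` object of kind `"tada_like"` with
#'   `extreme_ids` recording the positions of the extreme weights.
#' @export
make_tada_like_weights <- function(n_snps = 50L,
                                   extremes = c(1.51, 1.45, 1.29),
                                   center = 1.07, iqr = 0.04) {
  stopifnot(n_snps > length(extremes))
  w <- tada_tri_halfwidth(iqr)
  n_common <- n_snps - length(extremes)
  common <- center + w * (stats::runif(n_common) + stats::runif(n_common) - 1)
  ids <- sprintf("snp%02d", seq_len(n_snps))
  pos <- sample.int(n_snps, length(extremes))
  ors <- numeric(n_snps)
  ors[pos] <- extremes
  ors[-pos] <- common
  weight_scheme(ors, kind = "tada_like", extreme_ids = ids[pos], ids = ids)
}

#' Write a weight scheme to CSV
#'
#' Flat table (snp id, OR, beta, extreme flag) so published weights can be
#' substituted for the emulated ones.
#'
#' @param scheme A `"grs_weights"`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_weights_csv <- function(scheme, file) {
  stopifnot(inherits(scheme, "grs_weights"))
  utils::write.csv(data.frame(id = scheme$ids, or = scheme$ors,
                              beta = scheme$betas,
                              extreme = scheme$ids %in% scheme$extreme_ids,
                              stringsAsFactors = FALSE),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read a weight scheme from CSV
#'
#' @param file Path to a CSV written by [write_weights_csv()] (columns
#'   `id`, `or`, optional `extreme`).
#' @param kind Scheme kind to record; default `"tada_like"` if any extreme
#'   flag is set, else `"common"`.
#' @param mu Optional calibrated intercept.
#' @return A `"grs_weights"` object.
#' @export
read_weights_csv <- function(file, kind = NULL, mu = NA_real_) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "or") %in% names(d)))
  ex <- if ("extreme" %in% names(d)) d$id[as.logical(d$extreme)] else character()
  if (is.null(kind)) kind <- if (length(ex)) "tada_like" else "common"
  weight_scheme(d$or, kind = kind, extreme_ids = ex, ids = d$id, mu = mu)
}
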