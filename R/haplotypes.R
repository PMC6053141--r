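#' Two-locus haplotype frequencies with a prescribed allele correlation
#'
#' Constructs the four haplotype frequencies of a biallelic SNP pair so that
#' the haplotype-level Pearson correlation between the two loci equals `r`
#' exactly. Writing `D = r * sqrt(p(1-p) q(1-q))` for the usual linkage
#' disequilibrium coefficient, the frequencies are `h11 = pq + D`,
#' `h10 = p(1-q) - D`, `h01 = (1-p)q - D`, `h00 = (1-p)(1-q) + D`.
#'
#' Not every (p, q, r) triple is feasible: the requested `D` may push a
#' haplotype frequency outside \[0, 1\] (e.g. a high positive `r` between loci
#' with very different allele frequencies). In that case an error is raised
#' rather than silently truncating.
#'
#' @param p Allele-1 frequency at the first (index) locus, in (0, 1).
#' @param q Allele-1 frequency at the second (proxy) locus, in (0, 1).
#' @param r Signed haplotype-level correlation, in \[-1, 1\].
#'
#' @return A named numeric vector of class `"hap_freqs"` with components
#'   `h11`, `h10`, `h01`, `h00` (first digit = allele at the index locus),
#'   summing to 1 with marginals `p` and `q`.
#'
#' @examples
#' make_ld_haplotype_freqs(0.3, 0.3, 1)   # perfect co-inheritance
#' make_ld_haplotype_freqs(0.3, 0.3, 0)   # independence: product form
#' @export
make_ld_haplotype_freqs <- function(p, q, r) {
  stopifnot(length(p) == 1L, length(q) == 1L, length(r) == 1L,
            is.finite(p), is.finite(q), is.finite(r))
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1)
    stop("allele frequencies must lie strictly inside (0, 1)")
  if (abs(r) > 1) stop("'r' must lie in [-1, 1]")
  D <- r * sqrt(p * (1 - p) * q * (1 - q))
  h <- c(h11 = p * q + D,
         h10 = p * (1 - q) - D,
         h01 = (1 - p) * q - D,
         h00 = (1 - p) * (1 - q) + D)
  tol <- 1e-12
  if (any(h < -tol) || any(h > 1 + tol))
    stop(sprintf(
      "infeasible LD configuration: p=%.4g, q=%.4g, r=%.4g gives haplotype frequency outside [0,1]",
      p, q, r))
  h <- pmin(pmax(h, 0), 1)
  structure(h, p = p, q = q, r = r, class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat(sprintf("Two-locus haplotype frequencies (p=%.3f, q=%.3f, r=%.3f)\n",
              attr(x, "p"), attr(x, "q"), attr(x, "r")))
  print(round(unclass(x), 6))
  invisible(x)
}

# Draw proxy-locus haplotype alleles conditionally on the index-locus alleles.
# P(b=1 | a=1) = h11/p, P(b=1 | a=0) = h01/(1-p). Shared machinery between
# sample_genotype_pair() and build_panel(), where several proxies must be
# generated against the same index haplotypes.
sample_alleles_given_index <- function(index_alleles, freqs) {
  p <- attr(freqs, "p")
  p0 <- if (p < 1) freqs[["h01"]] / (1 - p) else 0
  p1 <- if (p > 0) freqs[["h11"]] / p else 0
  pr <- p0 + index_alleles * (p1 - p0)
  stats::rbinom(length(index_alleles), 1L, pr)
}

#' Sample genotype allele counts for a SNP pair under random mating
#'
#' Each individual receives two haplotypes drawn independently from `freqs`,
#' so both loci are in Hardy-Weinberg equilibrium by construction and the
#' genotype-count correlation equals the haplotype-level correlation.
#'
#' @param freqs A `"hap_freqs"` object from [make_ld_haplotype_freqs()].
#' @param n Number of individuals (>= 1).
#'
#' @return An integer matrix `n x 2` of allele counts in \{0, 1, 2\} with
#'   columns `index` and `proxy`.
#' @export
sample_genotype_pair <- function(freqs, n) {
  stopifnot(inherits(freqs, "hap_freqs"), length(n) == 1L, n >= 1)
  p <- attr(freqs, "p")
  a <- stats::rbinom(2L * n, 1L, p)
  b <- sample_alleles_given_index(a, freqs)
  odd <- seq(1L, 2L * n, by = 2L)
  cbind(index = a[odd] + a[odd + 1L],
        proxy = b[odd] + b[odd + 1L])
}

#' Squared Pearson correlation between two allele-count columns
#'
#' The standard r-squared measure of linkage disequilibrium between two SNPs
#' coded as 0/1/2 allele counts; invariant to flipping the counted allele.
#'
#' @param a,b Numeric vectors of equal length >= 2, neither constant.
#' @return Squared Pearson correlation in \[0, 1\].
#' @export
estimate_r2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("columns must have equal length >= 2")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("degenerate column: allele counts are constant")
  stats::cor(a, b)^2
}

#' Chi-square goodness-of-fit test for Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts (0/1/2) to the HWE expectations
#' `n p^2, 2 n p (1-p), n (1-p)^2` at the estimated allele frequency;
#' 1 degree of freedom.
#'
#' @param column Allele-count vector in \{0, 1, 2\}, length >= 30.
#' @return A list with `statistic`, `p_value` and `df`.
#' @export
hwe_chisq <- function(column) {
  if (length(column) < 30L)
    stop("need at least 30 genotypes for the HWE test")
  n <- length(column)
  obs <- tabulate(column + 1L, nbins = 3L)
  phat <- (obs[2L] + 2L * obs[3L]) / (2L * n)
  if (phat == 0 || phat == 1)
    stop("degenerate column: allele frequency is 0 or 1")
  expc <- n * c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
  stat <- sum((obs - expc)^2 / expc)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L)
}
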