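# Independent oracles used across the test files. These deliberately use
# brute force / enumeration rather than the package's own code paths.

# All-pairs AUC: average over every (case, control) pair of
# 1[case > control] + 0.5 * 1[tie].
oracle_auc_pairs <- function(y, score) {
  cases <- score[y == 1]
  controls <- score[y == 0]
  s <- 0
  for (a in cases) for (b in controls)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cases) * length(controls))
}

# Univariate logistic MLE by dense grid search over (intercept, slope),
# refined over three zoom levels. Returns the slope.
oracle_logistic_slope <- function(y, x, span = 5, steps = 81) {
  loglik <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  ctr <- c(0, 0); width <- span
  for (lvl in 1:4) {
    as <- seq(ctr[1] - width, ctr[1] + width, length.out = steps)
    bs <- seq(ctr[2] - width, ctr[2] + width, length.out = steps)
    ll <- outer(as, bs, Vectorize(loglik))
    ij <- arrayInd(which.max(ll), dim(ll))
    ctr <- c(as[ij[1]], bs[ij[2]])
    width <- width / 10
  }
  ctr[2]
}

# Genotype-count correlation implied by two-locus haplotype frequencies
# under random mating, by enumeration of the 16 ordered haplotype pairs.
oracle_genotype_corr <- function(freqs) {
  h <- unclass(freqs)
  al <- c(h11 = 1, h10 = 1, h01 = 0, h00 = 0)  # allele at locus a
  bl <- c(h11 = 1, h10 = 0, h01 = 1, h00 = 0)  # allele at locus b
  Ea <- 0; Eb <- 0; Eab <- 0; Ea2 <- 0; Eb2 <- 0
  for (i in names(h)) for (j in names(h)) {
    pr <- h[[i]] * h[[j]]
    a <- al[[i]] + al[[j]]; b <- bl[[i]] + bl[[j]]
    Ea <- Ea + pr * a; Eb <- Eb + pr * b
    Eab <- Eab + pr * a * b
    Ea2 <- Ea2 + pr * a^2; Eb2 <- Eb2 + pr * b^2
  }
  (Eab - Ea * Eb) / sqrt((Ea2 - Ea^2) * (Eb2 - Eb^2))
}

# Exact expected prevalence for a single-SNP scheme with X ~ Binomial(2, p).
oracle_prevalence_1snp <- function(mu, beta, p) {
  sum(stats::dbinom(0:2, 2, p) * stats::plogis(mu + beta * (0:2)))
}
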