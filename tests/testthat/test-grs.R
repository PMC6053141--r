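# small panel shared by this file's tests
make_test_panel <- function(seed = 71, n_target = 120, n_ref = 99) {
  set.seed(seed)
  build_panel(panel_config(n_target = n_target, n_ref = n_ref))
}

test_that("missingness masks have the exact design counts", {
  ids <- sprintf("snp%02d", 1:50)
  set.seed(81)
  expect_length(draw_missing_mask(0.2, ids)$missing_ids, 10L)
  expect_length(draw_missing_mask(0.3, ids)$missing_ids, 15L)
  expect_length(draw_missing_mask(0.5, ids)$missing_ids, 25L)
  expect_length(draw_missing_mask(0.7, ids)$missing_ids, 35L)
  expect_error(draw_missing_mask(0.4, ids), "one of")
  m1 <- draw_missing_mask(0.5, ids); m2 <- draw_missing_mask(0.5, ids)
  expect_false(setequal(m1$missing_ids, m2$missing_ids))
})

test_that("proxy orientation flips negatively correlated proxies", {
  x <- c(0, 1, 2, 0, 1, 2, 2)
  expect_equal(align_proxy(x, x), "as_is")
  expect_equal(align_proxy(x, 2 - x), "flipped")
  expect_error(align_proxy(x, rep(1, 7)), "degenerate")

  # simulated pair with negative haplotype correlation: flipped column
  # correlates positively with the index
  set.seed(83)
  g <- sample_genotype_pair(make_ld_haplotype_freqs(0.5, 0.5, -0.9), 500)
  expect_equal(align_proxy(g[, 1], g[, 2]), "flipped")
  expect_gt(cor(g[, 1], 2 - g[, 2]), 0.8)
})

test_that("GRS strategies match the weighted-sum definitions on a toy panel", {
  # two SNPs, beta = (0.1, 0.2); SNP2 masked with an as-is proxy count of 1
  # for the single individual: omission 0.2, proxy 0.4, gold 0.6
  tgt <- matrix(c(2L, 2L, 1L), 1, 3,
                dimnames = list(NULL, c("snp01", "snp02", "snp02_ex")))
  ref <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L), 3, 3,
                dimnames = list(NULL, c("snp01", "snp02", "snp02_ex")))
  specs <- data.frame(
    id = c("snp01", "snp02", "snp02_ex"),
    role = c("causal", "causal", "proxy"),
    index_of = c(NA, NA, "snp02"), maf = c(0.3, 0.3, 0.3),
    target_r = c(NA, NA, 0.9747), tier = c(NA, NA, "excellent"),
    block = c(1L, 1L, 1L), realized_ref_r2 = c(NA, NA, 1),
    stringsAsFactors = FALSE)
  panel <- structure(list(target = tgt, ref = ref, specs = specs,
                          config = NULL), class = "grs_panel")
  scheme <- weight_scheme(exp(c(0.1, 0.2)), kind = "common",
                          ids = c("snp01", "snp02"))
  a1 <- make_proxy_assignment(panel)
  expect_equal(a1$orientation, "as_is")
  # reuse the single proxy column for all three tiers of this toy panel
  assignment <- rbind(a1, within(a1, tier <- "very_good"),
                      within(a1, tier <- "good"))
  mask <- structure(list(missing_ids = "snp02", proportion = 0.5),
                    class = "grs_mask")
  X <- panel$target[, c("snp01", "snp02"), drop = FALSE]
  gold <- drop(X %*% c(0.1, 0.2))
  expect_equal(gold, 0.6)
  expect_equal(compute_grs(panel, scheme, mask, assignment, "omission"), 0.2)
  s <- grs_set(panel, scheme, mask, assignment)
  expect_equal(s$gold, 0.6)
  expect_equal(s$proxy_excellent, 0.4)
  # a masked SNP without any proxy row is an error
  expect_error(
    grs_set(panel, scheme,
            structure(list(missing_ids = "snp01", proportion = 0.5),
                      class = "grs_mask"), assignment),
    "missing proxy assignment")
})

test_that("an empty mask makes all strategies collapse onto the gold standard", {
  panel <- make_test_panel(85)
  scheme <- unit_weights()
  mask <- structure(list(missing_ids = character(), proportion = 0.2),
                    class = "grs_mask")
  s <- grs_set(panel, scheme, mask)
  for (nm in c("omission", "proxy_excellent", "proxy_very_good", "proxy_good"))
    expect_identical(s[[nm]], s$gold)
})

test_that("unweighted scores count risk alleles and omission never exceeds gold", {
  panel <- make_test_panel(87)
  assignment <- make_proxy_assignment(panel)
  set.seed(88)
  mask <- draw_missing_mask(0.5, causal_ids(panel))
  s <- grs_set(panel, unit_weights(), mask, assignment)
  X <- panel$target[, causal_ids(panel)]
  expect_equal(s$gold, unname(rowSums(X)))
  avail <- setdiff(causal_ids(panel), mask$missing_ids)
  expect_equal(s$omission, unname(rowSums(X[, avail])))
  # nonnegative weights: omission <= gold, equality iff masked alleles are 0
  expect_true(all(s$omission <= s$gold))
  zero_masked <- rowSums(X[, mask$missing_ids]) == 0
  expect_equal(s$omission == s$gold, zero_masked, ignore_attr = TRUE)
})

test_that("a perfectly correlated, correctly oriented proxy reproduces the gold GRS", {
  panel <- make_test_panel(89)
  cid <- causal_ids(panel)
  # overwrite the excellent proxies with exact copies of their index SNPs
  for (id in cid) {
    panel$target[, paste0(id, "_ex")] <- panel$target[, id]
    panel$ref[, paste0(id, "_ex")] <- panel$ref[, id]
  }
  panel$specs$realized_ref_r2[panel$specs$tier %in% "excellent"] <- 1
  assignment <- make_proxy_assignment(panel)
  set.seed(90)
  mask <- draw_missing_mask(0.7, cid)
  s <- grs_set(panel, unit_weights(), mask, assignment)
  expect_equal(s$proxy_excellent, s$gold)
})

test_that("gold-omission correlation stays high at 20% missing", {
  panel <- make_test_panel(91, n_target = 404)
  assignment <- make_proxy_assignment(panel)
  set.seed(92)
  for (i in 1:20) {
    mask <- draw_missing_mask(0.2, causal_ids(panel))
    s <- grs_set(panel, unit_weights(), mask, assignment)
    for (nm in c("omission", "proxy_excellent", "proxy_very_good",
                 "proxy_good"))
      expect_gt(pearson_corr(s$gold, s[[nm]]), 0.8)
  }
})

test_that("extreme-weight availability follows the hypergeometric law", {
  set.seed(93)
  w <- make_tada_like_weights()
  mask0 <- structure(list(missing_ids = character(), proportion = 0.2),
                     class = "grs_mask")
  expect_equal(count_extremes_available(mask0, w), 3L)
  mask_all <- structure(list(missing_ids = w$extreme_ids, proportion = 0.2),
                        class = "grs_mask")
  expect_equal(count_extremes_available(mask_all, w), 0L)
  expect_error(count_extremes_available(mask0, make_common_weights(1.05)),
               "tada_like")

  # 70% masks: availability count ~ Hypergeometric(50, 3, 15 kept)
  counts <- replicate(4000, {
    m <- draw_missing_mask(0.7, w$ids)
    count_extremes_available(m, w)
  })
  expected <- dhyper(0:3, 3, 47, 15) * 4000
  chi <- sum((tabulate(counts + 1L, 4) - expected)^2 / expected)
  expect_gt(pchisq(chi, df = 3, lower.tail = FALSE), 0.001)
})

test_that("GRS vectors export to CSV", {
  panel <- make_test_panel(95, n_target = 50)
  set.seed(96)
  mask <- draw_missing_mask(0.2, causal_ids(panel))
  s <- grs_set(panel, unit_weights(), mask, make_proxy_assignment(panel))
  f <- file.path(tempdir(), "grs_test.csv")
  write_grs_csv(s, f)
  d <- utils::read.csv(f)
  expect_equal(d$gold, s$gold)
  expect_equal(d$proxy_good, s$proxy_good)
  unlink(f)
})
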