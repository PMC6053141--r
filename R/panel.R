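#' Configuration for a synthetic genotype panel
#'
#' Describes the panel the generator emulates: a target sample and an
#' independent reference panel, `n_blocks` LD blocks each carrying
#' `snps_per_block` mutually independent causal SNPs, and (optionally) three
#' proxy SNPs per causal SNP whose reference-panel r-squared with the causal
#' SNP falls in one of three quality tiers:
#' excellent `[0.9, 1]`, very good `[0.8, 0.9)`, good `[0.6, 0.8)`.
#'
#' @param n_target Target-sample size (default 404).
#' @param n_ref Reference-panel size (default 99, a CEU-like panel).
#' @param n_blocks Number of LD blocks (default 10).
#' @param snps_per_block Causal SNPs per block (default 5).
#' @param maf_range Range of the uniform minor-allele-frequency spectrum;
#'   default `c(0.05, 0.5)`, respecting the MAF >= 5% filter.
#' @param tier_r2 Named vector of intended r-squared per proxy tier
#'   (defaults to the tier-bin midpoints 0.95, 0.85, 0.70).
#' @param with_proxies If `FALSE`, generate causal SNPs only (used for
#'   gold-standard-only runs).
#' @param max_tries Rejection-sampling cap per proxy before giving up.
#'
#' @return A list of class `"panel_config"`.
#' @export
panel_config <- function(n_target = 404L, n_ref = 99L,
                         n_blocks = 10L, snps_per_block = 5L,
                         maf_range = c(0.05, 0.5),
                         tier_r2 = c(excellent = 0.95, very_good = 0.85,
                                     good = 0.70),
                         with_proxies = TRUE, max_tries = 200L) {
  stopifnot(n_target >= 2, n_ref >= 2, n_blocks >= 1, snps_per_block >= 1,
            length(maf_range) == 2L, maf_range[1] >= 0.05,
            maf_range[2] <= 0.5, maf_range[1] < maf_range[2],
            max_tries >= 1)
  tiers <- c("excellent", "very_good", "good")
  stopifnot(identical(names(tier_r2), tiers))
  bins <- tier_bins()
  for (t in tiers)
    if (tier_r2[[t]] < bins[[t]][1] || tier_r2[[t]] >= bins[[t]][2])
      stop("tier_r2[", t, "] outside its tier bin")
  structure(list(n_target = as.integer(n_target), n_ref = as.integer(n_ref),
                 n_blocks = as.integer(n_blocks),
                 snps_per_block = as.integer(snps_per_block),
                 maf_range = maf_range, tier_r2 = tier_r2,
                 with_proxies = isTRUE(with_proxies),
                 max_tries = as.integer(max_tries)),
            class = "panel_config")
}

# r-squared acceptance bins per proxy-quality tier (upper bound of
# "excellent" is closed at 1).
tier_bins <- function() {
  list(excellent = c(0.90, 1 + 1e-9),
       very_good = c(0.80, 0.90),
       good      = c(0.60, 0.80))
}

tier_suffix <- c(excellent = "ex", very_good = "vg", good = "gd")

#' Generate a synthetic genotype panel with tiered proxy SNPs
#'
#' Causal SNPs are generated independently of each other (each with MAF drawn
#' uniformly from `maf_range`) as two Bernoulli haplotypes per individual,
#' i.e. in Hardy-Weinberg equilibrium. Each proxy SNP shares its causal SNP's
#' allele frequency and is drawn haplotype-wise conditional on the causal
#' haplotypes at correlation `sqrt(tier_r2)`; a proxy is redrawn until its
#' realized reference-panel genotype r-squared falls inside its tier's bin
#' (rejection sampling on the reference panel only, since that is the panel a
#' practitioner would use to choose the proxy).
#'
#' @param config A [panel_config()].
#' @return An object of class `"grs_panel"`: integer allele-count matrices
#'   `target` (`n_target x m`) and `ref` (`n_ref x m`), and a `specs` data
#'   frame with one row per SNP (id, role, index_of, maf, target_r, tier,
#'   block, realized_ref_r2).
#' @export
build_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  n_t <- config$n_target; n_r <- config$n_ref; n <- n_t + n_r
  n_causal <- config$n_blocks * config$snps_per_block
  tiers <- names(config$tier_r2)
  per <- if (config$with_proxies) 1L + length(tiers) else 1L
  m <- n_causal * per
  tgt <- matrix(0L, n_t, m)
  ref <- matrix(0L, n_r, m)
  sp_id <- character(m); sp_role <- character(m)
  sp_index_of <- rep(NA_character_, m); sp_maf <- rep(NA_real_, m)
  sp_target_r <- rep(NA_real_, m); sp_tier <- rep(NA_character_, m)
  sp_block <- integer(m); sp_r2 <- rep(NA_real_, m)
  bins <- tier_bins()
  odd <- seq(1L, 2L * n, by = 2L)
  it <- seq_len(n_t); ir <- n_t + seq_len(n_r)
  not_const <- function(x) any(x != x[1L])
  col <- 0L
  for (s in seq_len(n_causal)) {
    block <- (s - 1L) %/% config$snps_per_block + 1L
    id <- sprintf("snp%02d", s)
    # A candidate causal SNP is kept only if all three proxy tiers can be
    # realized against its reference-panel column; otherwise the SNP is
    # redrawn with a fresh MAF. This mirrors restricting the SNP pool to
    # SNPs for which excellent, very good and good proxies are available
    # in the reference panel.
    accepted <- FALSE
    for (attempt in seq_len(config$max_tries)) {
      # redraw if monomorphic in either sample: proxy r2 and orientation
      # are undefined on a constant reference column
      repeat {
        maf <- stats::runif(1L, config$maf_range[1], config$maf_range[2])
        hap <- stats::rbinom(2L * n, 1L, maf)
        counts <- hap[odd] + hap[odd + 1L]
        if (not_const(counts[it]) && not_const(counts[ir])) break
      }
      if (!config$with_proxies) { accepted <- TRUE; break }
      causal_ref <- counts[ir]
      prox <- list()
      for (t in tiers) {
        r_target <- sqrt(config$tier_r2[[t]])
        freqs <- make_ld_haplotype_freqs(maf, maf, r_target)
        bin <- bins[[t]]
        for (try in seq_len(config$max_tries)) {
          phap <- sample_alleles_given_index(hap, freqs)
          pcounts <- phap[odd] + phap[odd + 1L]
          if (!not_const(pcounts[ir]) || !not_const(pcounts[it])) next
          r2 <- stats::cor(causal_ref, pcounts[ir])^2
          if (r2 >= bin[1] && r2 < bin[2]) {
            prox[[t]] <- list(counts = pcounts, r2 = r2, r = r_target)
            break
          }
        }
        if (is.null(prox[[t]])) break
      }
      if (length(prox) == length(tiers)) { accepted <- TRUE; break }
    }
    if (!accepted)
      stop(sprintf(
        "failed to realize all proxy tiers for %s after %d candidate SNPs of %d rejection rounds each",
        id, config$max_tries, config$max_tries))
    col <- col + 1L
    tgt[, col] <- counts[it]; ref[, col] <- counts[ir]
    sp_id[col] <- id; sp_role[col] <- "causal"
    sp_maf[col] <- maf; sp_block[col] <- block
    if (!config$with_proxies) next
    for (t in tiers) {
      col <- col + 1L
      tgt[, col] <- prox[[t]]$counts[it]; ref[, col] <- prox[[t]]$counts[ir]
      sp_id[col] <- paste0(id, "_", tier_suffix[[t]])
      sp_role[col] <- "proxy"; sp_index_of[col] <- id; sp_maf[col] <- maf
      sp_target_r[col] <- prox[[t]]$r; sp_tier[col] <- t
      sp_block[col] <- block; sp_r2[col] <- prox[[t]]$r2
    }
  }
  specs <- data.frame(id = sp_id, role = sp_role, index_of = sp_index_of,
                      maf = sp_maf, target_r = sp_target_r, tier = sp_tier,
                      block = sp_block, realized_ref_r2 = sp_r2,
                      stringsAsFactors = FALSE)
  colnames(tgt) <- sp_id; colnames(ref) <- sp_id
  structure(list(target = tgt, ref = ref, specs = specs, config = config),
            class = "grs_panel")
}

#' @export
print.grs_panel <- function(x, ...) {
  nc <- sum(x$specs$role == "causal")
  cat(sprintf("Synthetic genotype panel: %d target / %d reference individuals\n",
              nrow(x$target), nrow(x$ref)))
  cat(sprintf("  %d causal SNPs in %d blocks, %d proxy SNPs\n",
              nc, x$config$n_blocks, sum(x$specs$role == "proxy")))
  if (any(x$specs$role == "proxy")) {
    rr <- x$specs$realized_ref_r2[x$specs$role == "proxy"]
    cat(sprintf("  reference-panel proxy r2: %.3f-%.3f\n", min(rr), max(rr)))
  }
  invisible(x)
}

#' Causal SNP identifiers of a panel
#' @param panel A `"grs_panel"`.
#' @return Character vector of causal SNP ids in panel order.
#' @export
causal_ids <- function(panel) {
  stopifnot(inherits(panel, "grs_panel"))
  panel$specs$id[panel$specs$role == "causal"]
}

#' Export a panel as allele-count CSV tables
#'
#' Writes `<prefix>_target.csv` and `<prefix>_ref.csv` (individuals x SNPs)
#' plus `<prefix>_snps.csv` with the per-SNP specification side table.
#'
#' @param panel A `"grs_panel"`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_panel_csv <- function(panel, prefix) {
  stopifnot(inherits(panel, "grs_panel"))
  paths <- paste0(prefix, c("_target.csv", "_ref.csv", "_snps.csv"))
  utils::write.csv(panel$target, paths[1], row.names = FALSE)
  utils::write.csv(panel$ref, paths[2], row.names = FALSE)
  utils::write.csv(panel$specs, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Export a panel to a minimal VCF (GT field only)
#'
#' One pseudo-contig per LD block, positions by within-block order; target
#' samples are named `t<i>` and reference samples `r<i>`. Genotypes are
#' unphased (0/0, 0/1, 1/1) with the counted (risk) allele as ALT.
#'
#' @param panel A `"grs_panel"`.
#' @param file Output path (plain-text `.vcf`).
#' @return Invisibly, `file`.
#' @export
write_panel_vcf <- function(panel, file) {
  stopifnot(inherits(panel, "grs_panel"))
  sp <- panel$specs
  samples <- c(paste0("t", seq_len(nrow(panel$target))),
               paste0("r", seq_len(nrow(panel$ref))))
  counts <- rbind(panel$target, panel$ref)
  gt <- matrix(c("0/0", "0/1", "1/1")[counts + 1L], nrow(counts), ncol(counts))
  pos <- stats::ave(seq_len(nrow(sp)), sp$block, FUN = seq_along)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=grsmiss",
           sprintf("##contig=<ID=block%d>", sort(unique(sp$block))),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sp)), function(i) {
    paste(c(paste0("block", sp$block[i]), pos[i], sp$id[i], "A", "G", ".",
            "PASS", ".", "GT", gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), file)
  invisible(file)
}
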