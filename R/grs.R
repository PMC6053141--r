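#' Draw a SNP-level missingness mask
#'
#' Marks a fixed fraction of the causal SNPs as unavailable in the target
#' sample: exactly `round(proportion * n)` SNPs, drawn uniformly without
#' replacement. The study design uses proportions 20%, 30%, 50% and 70%.
#'
#' @param proportion One of 0.2, 0.3, 0.5, 0.7.
#' @param snp_ids Causal SNP identifiers to draw from.
#' @return An object of class `"grs_mask"`: `missing_ids`, `proportion`.
#' @export
draw_missing_mask <- function(proportion, snp_ids) {
  if (!proportion %in% c(0.2, 0.3, 0.5, 0.7))
    stop("proportion must be one of 0.2, 0.3, 0.5, 0.7")
  k <- round(proportion * length(snp_ids))
  structure(list(missing_ids = sample(snp_ids, k), proportion = proportion),
            class = "grs_mask")
}

#' Decide the risk-allele orientation of a proxy SNP
#'
#' A proxy's counted allele may tag the non-risk allele of the SNP it
#' replaces. The orientation is decided on the reference panel only (the
#' target-sample index SNP is unavailable by assumption): if the Pearson
#' correlation between the index and proxy allele counts is negative, the
#' proxy enters the GRS as `2 - count`.
#'
#' @param index_col_ref,proxy_col_ref Reference-panel allele-count columns.
#' @return `"as_is"` or `"flipped"`.
#' @export
align_proxy <- function(index_col_ref, proxy_col_ref) {
  if (stats::var(index_col_ref) == 0 || stats::var(proxy_col_ref) == 0)
    stop("degenerate column: allele counts are constant")
  if (stats::cor(index_col_ref, proxy_col_ref) < 0) "flipped" else "as_is"
}

#' Proxy assignment table for a panel
#'
#' One row per (causal SNP, tier): the proxy id, its realized reference-panel
#' r-squared, and its risk-allele orientation from [align_proxy()].
#'
#' @param panel A `"grs_panel"` built with proxies.
#' @return A data frame of class `"proxy_assignment"` with columns
#'   `snp_id`, `proxy_id`, `tier`, `ref_r2`, `orientation`.
#' @export
make_proxy_assignment <- function(panel) {
  stopifnot(inherits(panel, "grs_panel"))
  sp <- panel$specs
  pr <- sp[sp$role == "proxy", , drop = FALSE]
  if (nrow(pr) == 0L) stop("panel was built without proxies")
  orientation <- vapply(seq_len(nrow(pr)), function(i) {
    align_proxy(panel$ref[, pr$index_of[i]], panel$ref[, pr$id[i]])
  }, character(1))
  out <- data.frame(snp_id = pr$index_of, proxy_id = pr$id, tier = pr$tier,
                    ref_r2 = pr$realized_ref_r2, orientation = orientation,
                    stringsAsFactors = FALSE)
  class(out) <- c("proxy_assignment", "data.frame")
  out
}

grs_strategies <- c("omission", "proxy_excellent", "proxy_very_good",
                    "proxy_good")

#' All five GRS of one iteration
#'
#' Computes, per individual in the target sample, the gold-standard score
#' (all causal SNPs), the omission score (available SNPs only) and the three
#' proxy-tier scores (available SNPs plus oriented proxy counts for the
#' missing SNPs), sharing one weighted-sum code path.
#'
#' @param panel A `"grs_panel"`.
#' @param scheme A `"grs_weights"` whose betas weight the score (use
#'   [unit_weights()] for the risk-allele-counting unweighted GRS).
#' @param mask A `"grs_mask"` (may contain zero missing SNPs).
#' @param assignment A `"proxy_assignment"`; may be `NULL` if the mask is
#'   empty.
#' @return An object of class `"grs_set"`: list of score vectors `gold`,
#'   `omission`, `proxy_excellent`, `proxy_very_good`, `proxy_good`.
#' @export
grs_set <- function(panel, scheme, mask, assignment = NULL) {
  stopifnot(inherits(panel, "grs_panel"), inherits(scheme, "grs_weights"),
            inherits(mask, "grs_mask"))
  cid <- causal_ids(panel)
  stopifnot(length(cid) == length(scheme$betas))
  w <- scheme$betas
  names(w) <- cid
  X <- panel$target[, cid, drop = FALSE]
  gold <- drop(X %*% w)
  miss <- mask$missing_ids
  if (!all(miss %in% cid)) stop("mask contains non-causal SNP ids")
  if (length(miss) == 0L) {
    out <- list(gold = gold, omission = gold,
                proxy_excellent = gold, proxy_very_good = gold,
                proxy_good = gold)
    return(structure(out, class = "grs_set"))
  }
  omission <- gold - drop(X[, miss, drop = FALSE] %*% w[miss])
  if (is.null(assignment))
    stop("missing proxy assignment for a non-empty mask")
  out <- list(gold = gold, omission = omission)
  for (t in names(tier_suffix)) {
    a <- assignment[assignment$tier == t & assignment$snp_id %in% miss, ,
                    drop = FALSE]
    if (!setequal(a$snp_id, miss))
      stop("missing proxy assignment for a masked SNP in tier ", t)
    a <- a[match(miss, a$snp_id), , drop = FALSE]
    P <- panel$target[, a$proxy_id, drop = FALSE]
    flip <- a$orientation == "flipped"
    if (any(flip)) P[, flip] <- 2L - P[, flip]
    out[[paste0("proxy_", t)]] <- omission + drop(P %*% w[miss])
  }
  structure(out, class = "grs_set")
}

#' One GRS under a given missingness strategy
#'
#' Strategy `"gold"` uses all causal SNPs; `"omission"` drops the masked
#' SNPs; the `"proxy_*"` strategies replace each masked SNP with its
#' oriented proxy of the given quality tier.
#'
#' @inheritParams grs_set
#' @param strategy One of `"gold"`, `"omission"`, `"proxy_excellent"`,
#'   `"proxy_very_good"`, `"proxy_good"`.
#' @return Numeric score vector, one value per target individual.
#' @export
compute_grs <- function(panel, scheme, mask, assignment = NULL,
                        strategy = c("gold", "omission", "proxy_excellent",
                                     "proxy_very_good", "proxy_good")) {
  strategy <- match.arg(strategy)
  grs_set(panel, scheme, mask, assignment)[[strategy]]
}

#' Number of extreme-weight SNPs left available by a mask
#'
#' @param mask A `"grs_mask"`.
#' @param scheme A `"grs_weights"` of kind `"tada_like"`.
#' @return Integer in 0..3.
#' @export
count_extremes_available <- function(mask, scheme) {
  stopifnot(inherits(mask, "grs_mask"), inherits(scheme, "grs_weights"))
  if (scheme$kind != "tada_like")
    stop("extreme-weight stratification requires a tada_like scheme")
  sum(!scheme$extreme_ids %in% mask$missing_ids)
}

#' Export one iteration's GRS vectors to CSV
#'
#' @param set A `"grs_set"`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_grs_csv <- function(set, file) {
  stopifnot(inherits(set, "grs_set"))
  d <- data.frame(person = seq_along(set$gold), gold = set$gold,
                  omission = set$omission,
                  proxy_excellent = set$proxy_excellent,
                  proxy_very_good = set$proxy_very_good,
                  proxy_good = set$proxy_good)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
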