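#' Configuration of a simulation study
#'
#' One study runs a single weight design over a grid of missing-SNP
#' proportions and replacement strategies; each iteration generates a fresh
#' genotype panel, phenotype set, and missingness mask.
#'
#' @param scheme `"common"` (equal per-allele ORs, unweighted GRS) or
#'   `"tada_like"` (heavy-tailed emulated weights, weighted GRS).
#' @param or_value Per-allele OR of the common scheme (ignored for
#'   `tada_like`).
#' @param proportions Missing-SNP proportions, subset of
#'   `c(0.2, 0.3, 0.5, 0.7)`; may be empty for gold-standard-only runs.
#' @param strategies Replacement strategies to evaluate, subset of
#'   `c("omission", "proxy_excellent", "proxy_very_good", "proxy_good")`.
#' @param n_iterations Number of Monte Carlo iterations (default 10000, the
#'   full study size; use `quick = TRUE` for a 500-iteration run).
#' @param seed Base seed; every source of randomness in the study derives
#'   from it, and any single iteration is reproducible in isolation.
#' @param n_target,n_ref Target-sample and reference-panel sizes.
#' @param target_prev Calibration target for the disease prevalence.
#' @param cal_n,cal_tol Calibration-sample size and tolerance for
#'   [calibrate_mu()].
#' @param maf_range MAF spectrum of the generated panels.
#' @param quick If `TRUE`, overrides `n_iterations` to 500.
#' @return A list of class `"grs_sim_config"`.
#' @export
sim_config <- function(scheme = c("common", "tada_like"), or_value = 1.05,
                       proportions = c(0.2, 0.3, 0.5, 0.7),
                       strategies = grs_strategies,
                       n_iterations = 10000L, seed = 1L,
                       n_target = 404L, n_ref = 99L, target_prev = 0.5,
                       cal_n = 200000L, cal_tol = 0.005,
                       maf_range = c(0.05, 0.5), quick = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(all(proportions %in% c(0.2, 0.3, 0.5, 0.7)),
            all(strategies %in% grs_strategies),
            n_iterations >= 1, seed == as.integer(seed))
  if (scheme == "common" && (or_value < 1.05 || or_value > 1.10))
    stop("or_value must lie in [1.05, 1.10]")
  if (isTRUE(quick)) n_iterations <- 500L
  structure(list(scheme = scheme, or_value = or_value,
                 proportions = proportions, strategies = strategies,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), n_target = as.integer(n_target),
                 n_ref = as.integer(n_ref), target_prev = target_prev,
                 cal_n = as.integer(cal_n), cal_tol = cal_tol,
                 maf_range = maf_range),
            class = "grs_sim_config")
}

# Derived seed for (base seed, iteration); iteration 0 is reserved for the
# weight-scheme draw and intercept calibration. Kept below 2^31 - 1.
iteration_seed <- function(base, iteration) {
  as.integer(((base %% 100000) * 20011 + iteration * 7 + 1) %% 2147483647)
}

# Build (and, for tada_like, draw) the scheme, then calibrate its intercept.
# Uses the iteration-0 seed so the scheme is part of the study's seed
# contract.
prepare_scheme <- function(config) {
  set.seed(iteration_seed(config$seed, 0L))
  scheme <- switch(config$scheme,
                   common = make_common_weights(config$or_value),
                   tada_like = make_tada_like_weights())
  scheme$mu <- calibrate_mu(scheme, maf_range = config$maf_range,
                            n_cal = config$cal_n,
                            target_prev = config$target_prev,
                            tol = config$cal_tol)
  scheme
}

#' Run one simulation iteration
#'
#' Generates one genotype panel and phenotype set, then for each configured
#' missing proportion draws a fresh mask and evaluates the gold-standard,
#' omission and proxy-tier GRS. All randomness derives from
#' `(config$seed, iteration)`, so a single iteration can be replayed in
#' isolation.
#'
#' @param config A [sim_config()].
#' @param scheme The calibrated `"grs_weights"` from the study (see
#'   [run_study()]); its `mu` must be set.
#' @param iteration Iteration index (1-based).
#' @return Data frame of per-strategy metric rows (one `gold` row plus one
#'   row per proportion x strategy).
#' @export
run_iteration <- function(config, scheme, iteration) {
  stopifnot(inherits(config, "grs_sim_config"), !is.na(scheme$mu))
  set.seed(iteration_seed(config$seed, iteration))
  with_proxies <- length(config$strategies) > 0 && length(config$proportions) > 0
  panel <- build_panel(panel_config(
    n_target = config$n_target, n_ref = config$n_ref,
    maf_range = config$maf_range, with_proxies = with_proxies))
  cid <- causal_ids(panel)
  Xc <- panel$target[, cid, drop = FALSE]
  ph <- draw_phenotypes(risk(linear_predictor(Xc, scheme)))
  y <- ph$outcomes
  # score-side weights: pure allele counting for the common (unweighted)
  # design, the causal betas for the weighted design
  score_scheme <- if (config$scheme == "common") unit_weights() else scheme
  assignment <- if (with_proxies) make_proxy_assignment(panel) else NULL
  maf <- panel$specs$maf[match(cid, panel$specs$id)]
  names(maf) <- cid

  n_rows <- 1L + length(config$proportions) * length(config$strategies)
  rows <- vector("list", n_rows)
  gold <- drop(Xc %*% score_scheme$betas)
  fit <- fit_or_per_sd(y, gold)
  rows[[1L]] <- list(iteration = iteration, proportion = NA_real_,
                     strategy = "gold", or_per_sd = fit$or,
                     p_value = fit$p_value, auc = auc_rank(y, gold),
                     corr_with_gold = 1, mean_maf_missing = NA_real_,
                     extremes_available = NA_integer_, flagged = fit$flagged)
  k <- 1L
  for (prop in config$proportions) {
    mask <- draw_missing_mask(prop, cid)
    set <- grs_set(panel, score_scheme, mask, assignment)
    ext <- if (config$scheme == "tada_like")
      count_extremes_available(mask, scheme) else NA_integer_
    mmaf <- mean(maf[mask$missing_ids])
    for (strat in config$strategies) {
      g <- set[[strat]]
      fit <- fit_or_per_sd(y, g)
      k <- k + 1L
      rows[[k]] <- list(iteration = iteration, proportion = prop,
                        strategy = strat, or_per_sd = fit$or,
                        p_value = fit$p_value, auc = auc_rank(y, g),
                        corr_with_gold = pearson_corr(gold, g),
                        mean_maf_missing = mmaf, extremes_available = ext,
                        flagged = fit$flagged)
    }
  }
  out <- do.call(rbind, lapply(rows[seq_len(k)], as.data.frame))
  out$prevalence <- ph$prevalence
  out$scheme <- config$scheme
  out$or_input <- if (config$scheme == "common") config$or_value else NA_real_
  out
}

#' Run a full simulation study
#'
#' Draws and calibrates the weight scheme, runs all iterations over the
#' scenario grid, and aggregates scenario summaries. Re-running with the
#' same configuration reproduces the results exactly.
#'
#' @param config A [sim_config()].
#' @param progress Print a progress line every `progress` iterations
#'   (0 = silent).
#' @return An object of class `"grs_study"`: the `config`, the calibrated
#'   `scheme`, the per-iteration long table `iterations`, the scenario
#'   `summary` table, and the count of flagged fits.
#' @export
run_study <- function(config = sim_config(), progress = 0L) {
  stopifnot(inherits(config, "grs_sim_config"))
  scheme <- prepare_scheme(config)
  chunks <- vector("list", config$n_iterations)
  for (i in seq_len(config$n_iterations)) {
    chunks[[i]] <- run_iteration(config, scheme, i)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("iteration %d / %d", i, config$n_iterations))
  }
  iterations <- do.call(rbind, chunks)
  rownames(iterations) <- NULL
  structure(list(config = config, scheme = scheme, iterations = iterations,
                 summary = summarize_results(iterations),
                 n_flagged = sum(iterations$flagged)),
            class = "grs_study")
}

#' @export
print.grs_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("GRS missingness simulation study ('%s' scheme%s)\n",
              cfg$scheme,
              if (cfg$scheme == "common")
                sprintf(", per-allele OR %.2f", cfg$or_value) else ""))
  cat(sprintf("  %d iterations, n_target = %d, seed = %d, mu = %.4f\n",
              cfg$n_iterations, cfg$n_target, cfg$seed, x$scheme$mu))
  cat(sprintf("  mean prevalence %.3f; %d flagged fits\n",
              mean(x$iterations$prevalence[x$iterations$strategy == "gold"]),
              x$n_flagged))
  gold <- x$summary[x$summary$strategy == "gold", , drop = FALSE]
  if (nrow(gold))
    cat(sprintf("  gold standard: median OR per SD %.3f, median AUC %.3f\n",
                gold$or_median[1], gold$median_auc[1]))
  invisible(x)
}

#' @export
summary.grs_study <- function(object, ...) {
  object$summary
}

#' Box plots of the gold-vs-alternate GRS correlations
#'
#' One box per missing proportion x strategy, mirroring the study's
#' correlation figure.
#'
#' @param x A `"grs_study"`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.grs_study <- function(x, ...) {
  d <- x$iterations[x$iterations$strategy != "gold", , drop = FALSE]
  if (nrow(d) == 0L) stop("study has no alternate-strategy iterations")
  grp <- interaction(d$strategy, d$proportion, sep = "\n")
  graphics::boxplot(d$corr_with_gold ~ grp,
                    ylab = "correlation with gold-standard GRS",
                    xlab = "", las = 2, ...)
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Emits `iterations.csv` (long per-iteration table), `summary.csv`
#' (scenario summaries), `weights.csv` (the calibrated scheme) and
#' `manifest.json` (configuration, seed, versions, flagged-fit tally).
#'
#' @param study A `"grs_study"`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "grs_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$iterations, file.path(dir, "iterations.csv"),
                   row.names = FALSE)
  utils::write.csv(study$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  write_weights_csv(study$scheme, file.path(dir, "weights.csv"))
  manifest <- list(config = unclass(study$config),
                   mu = study$scheme$mu,
                   n_flagged = study$n_flagged,
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("grsmiss")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
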