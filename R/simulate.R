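#' Configuration for the synthetic case-control genotype generator
#'
#' The generator emulates a candidate-gene resequencing sample: a few hundred
#' individuals typed at a mixture of common variants and rare variants
#' (MAF < 0.01), with a binary phenotype driven by a logistic liability on a
#' known causal subset. Defaults mirror the mini-exome shape the package is
#' calibrated against: 209 cases and 488 controls, 133 common plus 400 rare
#' variants, MAFs drawn uniformly from \[0.05, 0.45\] (common) and
#' \[0.0007, 0.01\] (rare).
#'
#' @param n_cases,n_controls Numbers of cases and controls to sample.
#' @param n_common,n_rare Numbers of common and rare variants.
#' @param maf_common_range,maf_rare_range MAF intervals (within (0, 0.5))
#'   from which per-variant MAFs are drawn uniformly.
#' @param causal_common,causal_rare Causal variants in each block: either a
#'   count (a random subset is drawn) or explicit positions within the block.
#' @param effect_common,effect_rare Per-causal-variant log-odds ratios,
#'   recycled to the number of causal variants in the block. Negative values
#'   give protective variants. Defaults: log(1.5) for common and log(10) for
#'   rare causal variants.
#' @param baseline_prevalence Disease probability for an individual carrying
#'   no causal minor alleles (the logistic intercept is its logit).
#' @param seed Optional integer seed; identical configurations with the same
#'   seed yield identical datasets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 209, n_controls = 488,
                       n_common = 133, n_rare = 400,
                       maf_common_range = c(0.05, 0.45),
                       maf_rare_range = c(0.0007, 0.01),
                       causal_common = 0, causal_rare = 0,
                       effect_common = log(1.5), effect_rare = log(10),
                       baseline_prevalence = 0.3, seed = NULL) {
  chk_range <- function(r, nm) {
    if (length(r) != 2 || any(r <= 0) || any(r >= 0.5) || r[1] > r[2]) {
      abort_invalid(sprintf("`%s` must be an increasing interval within (0, 0.5).", nm))
    }
  }
  chk_range(maf_common_range, "maf_common_range")
  chk_range(maf_rare_range, "maf_rare_range")
  if (n_cases < 1 || n_controls < 1 || n_common < 0 || n_rare < 0 ||
      n_common + n_rare < 1) {
    abort_invalid("Sample and variant counts must be positive.")
  }
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    abort_invalid("`baseline_prevalence` must lie in (0, 1).")
  }
  chk_causal <- function(x, n, nm) {
    if (length(x) == 1L && x >= 0 && x <= n) return(invisible())
    if (all(x >= 1) && all(x <= n) && !anyDuplicated(x)) return(invisible())
    abort_invalid(sprintf("`%s` must be a count or distinct positions within 1..%d.", nm, n))
  }
  chk_causal(causal_common, n_common, "causal_common")
  chk_causal(causal_rare, n_rare, "causal_rare")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_common = as.integer(n_common), n_rare = as.integer(n_rare),
    maf_common_range = maf_common_range, maf_rare_range = maf_rare_range,
    causal_common = causal_common, causal_rare = causal_rare,
    effect_common = effect_common, effect_rare = effect_rare,
    baseline_prevalence = baseline_prevalence,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

# Draw the generative truth: per-variant MAFs, causal subsets, effect
# vector. Uses the current RNG state.
draw_truth <- function(config) {
  w <- function(n, prefix) {
    if (n == 0L) return(character(0))
    paste0(prefix, formatC(seq_len(n), width = nchar(n), flag = "0"))
  }
  ids <- c(w(config$n_common, "cv"), w(config$n_rare, "rv"))
  maf <- c(stats::runif(config$n_common, config$maf_common_range[1],
                        config$maf_common_range[2]),
           stats::runif(config$n_rare, config$maf_rare_range[1],
                        config$maf_rare_range[2]))
  causal_c <- if (length(config$causal_common) == 1L)
    sort(sample.int(config$n_common, as.integer(config$causal_common)))
  else sort(as.integer(config$causal_common))
  causal_r <- if (length(config$causal_rare) == 1L)
    sort(sample.int(config$n_rare, as.integer(config$causal_rare)))
  else sort(as.integer(config$causal_rare))
  beta <- numeric(config$n_common + config$n_rare)
  beta[causal_c] <- rep_len(config$effect_common, length(causal_c))
  beta[config$n_common + causal_r] <- rep_len(config$effect_rare,
                                              length(causal_r))
  list(
    variant_ids = ids, maf = maf, beta = beta,
    beta0 = stats::qlogis(config$baseline_prevalence),
    causal_common = ids[causal_c],
    causal_rare = ids[config$n_common + causal_r],
    baseline_prevalence = config$baseline_prevalence
  )
}

# Sample genotypes + phenotype for one replicate of a fixed truth:
# Hardy-Weinberg genotypes (Binomial(2, MAF)), logistic disease liability,
# rejection sampling until the requested case/control counts are filled.
draw_dataset <- function(truth, config) {
  n_need <- c(case = config$n_cases, control = config$n_controls)
  v <- length(truth$maf)
  causal <- which(truth$beta != 0)
  bc <- truth$beta[causal]
  keep_case <- vector("list", 0)
  keep_ctrl <- vector("list", 0)
  got <- c(case = 0L, control = 0L)
  drawn <- 0L
  p_min <- min(config$baseline_prevalence, 1 - config$baseline_prevalence)
  max_draws <- ceiling(50 * sum(n_need) / p_min)
  batch <- max(500L, 2L * sum(n_need))
  while (any(got < n_need)) {
    if (drawn >= max_draws) {
      abort_timeout(c(
        sprintf("Could not collect %d cases and %d controls within %d draws.",
                n_need[1], n_need[2], max_draws),
        i = "Adjust `baseline_prevalence` or the requested class counts."))
    }
    G <- vapply(truth$maf, function(p) stats::rbinom(batch, 2L, p),
                integer(batch))
    eta <- truth$beta0 +
      if (length(causal)) drop(G[, causal, drop = FALSE] %*% bc) else 0
    y <- stats::rbinom(batch, 1L, stats::plogis(eta))
    drawn <- drawn + batch
    if (got["case"] < n_need["case"]) {
      take <- which(y == 1L)[seq_len(min(sum(y == 1L), n_need["case"] - got["case"]))]
      if (length(take)) {
        keep_case[[length(keep_case) + 1L]] <- G[take, , drop = FALSE]
        got["case"] <- got["case"] + length(take)
      }
    }
    if (got["control"] < n_need["control"]) {
      take <- which(y == 0L)[seq_len(min(sum(y == 0L), n_need["control"] - got["control"]))]
      if (length(take)) {
        keep_ctrl[[length(keep_ctrl) + 1L]] <- G[take, , drop = FALSE]
        got["control"] <- got["control"] + length(take)
      }
    }
  }
  G <- rbind(do.call(rbind, keep_case), do.call(rbind, keep_ctrl))
  colnames(G) <- truth$variant_ids
  status <- rep(c(1L, 0L), times = n_need)
  genotype_data(G, status = status,
                sample_id = paste0("S", formatC(seq_len(nrow(G)),
                                                width = nchar(nrow(G)),
                                                flag = "0")))
}

#' Simulate a case-control genotype dataset
#'
#' Draws per-variant MAFs uniformly from the configured ranges, genotypes
#' under Hardy-Weinberg equilibrium (minor-allele counts ~ Binomial(2, MAF)),
#' and disease status from a logistic liability
#' \eqn{logit P(case) = \beta_0 + \sum_j \beta_j g_j} over the causal
#' variants, then rejection-samples individuals until the requested case and
#' control counts are reached. The generative truth (MAFs, causal variants,
#' effects) is attached as the `"truth"` attribute and retrievable with
#' [sim_truth()].
#'
#' @param config A [sim_config()].
#' @return A genotype tibble (see [genotype_data()]) with common variants
#'   (`cv...`) followed by rare variants (`rv...`).
#' @examples
#' d <- simulate_dataset(sim_config(n_cases = 30, n_controls = 30,
#'                                  n_common = 5, n_rare = 10, seed = 1))
#' dim(d)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  truth <- draw_truth(config)
  out <- draw_dataset(truth, config)
  attr(out, "truth") <- truth
  out
}

#' @rdname simulate_dataset
#' @param data A dataset produced by [simulate_dataset()].
#' @export
sim_truth <- function(data) attr(data, "truth")

#' Common-variant depletion sweep comparing CROC and FROC
#'
#' For each repeat, a generative truth is drawn and two independent
#' replicates are sampled from it; models are fitted on the first replicate
#' and their held-out AUC is measured on the second (evaluating on an
#' independent replicate keeps rare variants present in both datasets). At
#' each requested common-variant count a random subset of that size of the
#' common variants is retained (all rare variants always stay in), and both
#' [fit_croc()] and [fit_froc()] are fitted with a shared per-repeat seed, so
#' method comparisons are paired.
#'
#' @param config A [sim_config()] describing the generative truth.
#' @param common_counts Integer vector of common-variant counts to retain,
#'   each within `[0, config$n_common]`.
#' @param repeats Number of independent truth/replicate-pair draws.
#' @param seed Integer seed for the whole sweep.
#' @param folds,maf_threshold,pseudocount,max_model_size Passed to the
#'   fitting functions.
#' @return A tibble with one row per (common count, method): `common_count`,
#'   `method`, `mean_auc`, `sd_auc`, `se_auc`, `ci_lo`, `ci_hi` (2.5% and
#'   97.5% percentiles across repeats), `n_repeats`. The per-repeat held-out
#'   AUCs are attached as the `"replicates"` attribute for paired analyses.
#' @export
run_depletion_sweep <- function(config, common_counts, repeats = 20,
                                seed = 1, folds = 10, maf_threshold = 0.01,
                                pseudocount = 0.5, max_model_size = 20) {
  stopifnot(inherits(config, "sim_config"))
  common_counts <- as.integer(common_counts)
  if (any(common_counts < 0L) || any(common_counts > config$n_common)) {
    abort_invalid(sprintf("`common_counts` must lie in [0, %d].",
                          config$n_common))
  }
  withr::local_seed(as.integer(seed))
  rows <- vector("list", 0)
  for (r in seq_len(repeats)) {
    truth <- draw_truth(config)
    train <- draw_dataset(truth, config)
    test <- draw_dataset(truth, config)
    drop_order <- sample.int(config$n_common)
    fit_seed <- sample.int(2^31 - 1, 1)
    common_ids <- truth$variant_ids[seq_len(config$n_common)]
    rare_ids <- setdiff(truth$variant_ids, common_ids)
    for (cnt in common_counts) {
      keep <- sort(drop_order[seq_len(cnt)])
      cols <- c("sample_id", "status", common_ids[keep], rare_ids)
      dtr <- train[cols]
      dte <- test[cols]
      for (method in c("croc", "froc")) {
        fit <- if (method == "croc") {
          fit_croc(dtr, folds = folds, seed = fit_seed,
                   maf_threshold = maf_threshold, pseudocount = pseudocount,
                   max_model_size = max_model_size)
        } else {
          fit_froc(dtr, folds = folds, seed = fit_seed,
                   pseudocount = pseudocount,
                   max_model_size = max_model_size)
        }
        sc <- predict(fit, dte)$score
        rows[[length(rows) + 1L]] <- tibble::tibble(
          repeat_id = r, common_count = cnt, method = method,
          auc = auc_num(sc, dte$status))
      }
    }
  }
  reps <- dplyr::bind_rows(rows)
  out <- reps |>
    dplyr::group_by(.data$common_count, .data$method) |>
    dplyr::summarise(
      mean_auc = mean(.data$auc),
      sd_auc = stats::sd(.data$auc),
      se_auc = stats::sd(.data$auc) / sqrt(dplyr::n()),
      ci_lo = unname(stats::quantile(.data$auc, 0.025)),
      ci_hi = unname(stats::quantile(.data$auc, 0.975)),
      n_repeats = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "replicates") <- reps
  out
}

#' Plot a depletion sweep
#'
#' Mean held-out AUC against the number of common variants retained, by
#' method, with percentile confidence ribbons.
#'
#' @param sweep Output of [run_depletion_sweep()].
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$common_count,
                                      y = .data$mean_auc,
                                      colour = .data$method,
                                      fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "Common variants retained", y = "Held-out AUC",
                  colour = "Method", fill = "Method") +
    ggplot2::theme_minimal()
}
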