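#' Likelihood-ratio table for a set of predictor loci
#'
#' Cross-tabulates the multilocus genotypes observed at `loci` and estimates,
#' for each genotype group, its frequency among cases and among controls and
#' the likelihood ratio of the two. The LR of a genotype group is the optimal
#' risk score for ROC construction: ranking individuals by it maximizes the
#' ROC curve at every operating point.
#'
#' With a pseudocount \eqn{c} and \eqn{M} observed groups, the LR of a group
#' with \eqn{a} case and \eqn{b} control carriers out of \eqn{N_D} cases and
#' \eqn{N_{\bar D}} controls is
#' \deqn{LR = \frac{(a + c) / (N_D + cM)}{(b + c) / (N_{\bar D} + cM)}.}
#' The default Haldane-style pseudocount of 0.5 keeps every LR finite without
#' changing the rank order of groups. With `pseudocount = 0`, raw frequency
#' ratios are used and clamped into `[1/lr_cap, lr_cap]` so that groups absent
#' from one class get a large-but-finite score.
#'
#' @param data A genotype tibble (see [genotype_data()]).
#' @param loci Variant IDs (character) or positions (integer, over variant
#'   columns) of the predictor loci.
#' @param pseudocount Non-negative smoothing count added per group and class.
#' @param lr_cap Finite cap applied to raw ratios when `pseudocount = 0`.
#' @param unseen_lr Score assigned at prediction time to genotype tuples that
#'   were not observed when the table was built (default 1, i.e. neutral
#'   evidence).
#'
#' @return A tibble of class `lr_table`, one row per observed multilocus
#'   genotype: `genotype` (codes joined by `"|"` in `loci` order), `n_case`,
#'   `n_control`, `case_freq`, `control_freq` (raw, unsmoothed frequencies),
#'   and `lr`. The selected loci and smoothing settings are carried as
#'   attributes.
#' @examples
#' d <- genotype_data(matrix(c(0, 0, 1, 2), nrow = 4), status = c(1, 1, 0, 0))
#' lr_table(d, loci = "V1", pseudocount = 0)
#' @export
lr_table <- function(data, loci, pseudocount = 0.5, lr_cap = 1e6,
                     unseen_lr = 1) {
  p <- gd_parts(data)
  if (pseudocount < 0) abort_invalid("`pseudocount` must be non-negative.")
  idx <- resolve_loci(loci, p$variants)
  key <- genotype_key(p$G, idx)
  new_lr_table(key, p$y, loci = p$variants[idx], pseudocount = pseudocount,
               lr_cap = lr_cap, unseen_lr = unseen_lr)
}

# Internal constructor shared by lr_table() and the CV refits.
new_lr_table <- function(key, y, loci, pseudocount, lr_cap, unseen_lr) {
  n_case <- sum(y == 1L)
  n_control <- sum(y == 0L)
  if (n_case == 0L || n_control == 0L) {
    abort_degenerate("LR estimation needs at least one case and one control.")
  }
  groups <- sort(unique(key))
  gi <- match(key, groups)
  cc <- tabulate(gi[y == 1L], length(groups))
  dd <- tabulate(gi[y == 0L], length(groups))
  lr <- lr_values(cc, dd, n_case, n_control, pseudocount, lr_cap)
  out <- tibble::tibble(
    genotype = groups,
    n_case = cc,
    n_control = dd,
    case_freq = cc / !!n_case,
    control_freq = dd / !!n_control,
    lr = lr
  )
  out <- out[order(-out$lr, out$genotype), ]
  structure(out,
            class = c("lr_table", class(tibble::tibble()))) |>
    set_lr_attrs(loci = loci, pseudocount = pseudocount, lr_cap = lr_cap,
                 unseen_lr = unseen_lr, n_case = n_case, n_control = n_control)
}

set_lr_attrs <- function(x, loci, pseudocount, lr_cap, unseen_lr,
                         n_case, n_control) {
  attr(x, "loci") <- loci
  attr(x, "pseudocount") <- pseudocount
  attr(x, "lr_cap") <- lr_cap
  attr(x, "unseen_lr") <- unseen_lr
  attr(x, "n_case") <- n_case
  attr(x, "n_control") <- n_control
  x
}

# Smoothed likelihood ratios from per-group case/control counts.
lr_values <- function(cc, dd, n_case, n_control, pseudocount, lr_cap) {
  m <- length(cc)
  if (pseudocount > 0) {
    (cc + pseudocount) / (n_case + pseudocount * m) /
      ((dd + pseudocount) / (n_control + pseudocount * m))
  } else {
    r <- (cc / n_case) / (dd / n_control)
    pmin(lr_cap, pmax(1 / lr_cap, r))
  }
}

# Multilocus genotype key: codes joined with "|" in locus order. NA prints as
# "NA", giving missing calls their own level under the "category" policy.
genotype_key <- function(G, idx) {
  if (length(idx) == 1L) return(as.character(G[, idx]))
  do.call(paste, c(lapply(idx, function(j) G[, j]), sep = "|"))
}

#' Score individuals with a fitted LR table
#'
#' Each individual is assigned the likelihood ratio of the multilocus genotype
#' group they carry at the table's loci. Genotype tuples never observed when
#' the table was estimated receive the table's `unseen_lr` (default 1,
#' neutral evidence).
#'
#' @param data A genotype tibble containing all of the table's loci.
#' @param table An [lr_table()].
#' @return A tibble with columns `sample_id` and `score`.
#' @export
lr_scores <- function(data, table) {
  stopifnot(inherits(table, "lr_table"))
  p <- gd_parts(data)
  loci <- attr(table, "loci")
  idx <- resolve_loci(loci, p$variants, what = "table loci")
  key <- genotype_key(p$G, idx)
  hit <- match(key, table$genotype)
  score <- table$lr[hit]
  score[is.na(hit)] <- attr(table, "unseen_lr")
  tibble::tibble(sample_id = p$ids, score = score)
}

#' ROC curve and AUC for a vector of risk scores
#'
#' Computes the empirical ROC curve obtained by sweeping a threshold over the
#' distinct score values, and the area under it as the Mann-Whitney
#' two-sample statistic
#' \deqn{AUC = \frac{1}{N_D N_{\bar D}} \sum_{i \in cases} \sum_{j \in controls}
#'       \psi(s_i, s_j),}
#' with kernel \eqn{\psi = 1} if the case outscores the control, \eqn{1/2} on
#' ties and 0 otherwise. The trapezoidal area under the returned curve equals
#' this statistic exactly.
#'
#' @param scores Numeric risk scores, one per individual.
#' @param status Case/control status (1/0, logical, or "case"/"control").
#' @return An object of class `roc_result`: a list with elements `auc`,
#'   `curve` (tibble of `threshold`, `fpr`, `tpr`, ordered by decreasing
#'   threshold, starting at (0,0) and ending at (1,1)), `n_case`,
#'   `n_control`.
#' @examples
#' roc_auc(c(2, .5, 1, .5), c(1, 1, 0, 0))$auc  # 0.625
#' @export
roc_auc <- function(scores, status) {
  y <- coerce_status(status)
  if (length(scores) != length(y)) {
    abort_invalid("`scores` and `status` must have the same length.")
  }
  if (anyNA(scores)) abort_invalid("`scores` must not contain NA.")
  n_case <- sum(y == 1L)
  n_control <- sum(y == 0L)
  if (n_case == 0L || n_control == 0L) {
    abort_degenerate("ROC needs at least one case and one control.")
  }
  lev <- sort(unique(scores))                     # ascending score levels
  gi <- match(scores, lev)
  cc <- tabulate(gi[y == 1L], length(lev))
  dd <- tabulate(gi[y == 0L], length(lev))
  auc <- auc_from_ordered_groups(cc, dd)
  # threshold sweep from the largest score down: classify positive if
  # score >= threshold
  cc_d <- rev(cc); dd_d <- rev(dd)
  tpr <- cumsum(cc_d) / n_case
  fpr <- cumsum(dd_d) / n_control
  curve <- tibble::tibble(
    threshold = c(Inf, rev(lev)),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  structure(list(auc = auc, curve = curve, n_case = n_case,
                 n_control = n_control),
            class = "roc_result")
}

# Mann-Whitney AUC from per-score-level case/control counts, levels in
# ascending score order (ties already aggregated). For each level: cases
# there beat all controls at lower levels and tie controls at the same level.
auc_from_ordered_groups <- function(cc, dd) {
  n_case <- sum(cc)
  n_control <- sum(dd)
  d_below <- cumsum(dd) - dd
  sum(cc * d_below + 0.5 * cc * dd) / (n_case * n_control)
}

# AUC from group counts and arbitrary (possibly tied) group scores.
auc_from_groups <- function(cc, dd, score) {
  o <- order(score)
  s <- score[o]
  f <- cumsum(!duplicated(s))   # run id over equal scores, ascending
  cc2 <- as.vector(rowsum(cc[o], f))
  dd2 <- as.vector(rowsum(dd[o], f))
  auc_from_ordered_groups(cc2, dd2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d cases, %d controls, %d thresholds)\n",
              x$auc, x$n_case, x$n_control, nrow(x$curve) - 1L))
  invisible(x)
}

#' @rdname roc_auc
#' @param object,x An `roc_result`.
#' @param ... Unused.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("LR-ordered ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
plot.roc_result <- function(x, ...) print(autoplot.roc_result(x, ...))
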