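#' Partition variants into common and rare by minor allele frequency
#'
#' Rare means MAF strictly below `threshold` (a variant whose MAF equals the
#' threshold exactly is common). MAF is estimated on the pooled sample.
#'
#' @param data A genotype tibble (see [genotype_data()]).
#' @param threshold MAF threshold in (0, 0.5]; default 0.01.
#' @return A list with integer vectors `common` and `rare` (positions over
#'   the variant columns, named by variant ID).
#' @export
split_by_maf <- function(data, threshold = 0.01) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 0.5) {
    abort_invalid("`threshold` must lie in (0, 0.5].")
  }
  info <- variant_info(data, maf_threshold = threshold)
  common <- which(!info$rare)
  rare <- which(info$rare)
  names(common) <- info$variant_id[common]
  names(rare) <- info$variant_id[rare]
  list(common = common, rare = rare)
}

#' Collapse a group of rare variants into a carrier indicator
#'
#' The pseudo-common variant of a group is the CAST-style burden indicator:
#' 1 for individuals carrying at least one minor allele at at least one
#' variant in the group, 0 otherwise. Missing calls count as non-carrier.
#'
#' @param data A genotype tibble.
#' @param group Non-empty set of variant IDs or positions.
#' @return An integer vector of 0/1 carrier indicators, one per individual.
#' @export
collapse_indicator <- function(data, group) {
  p <- gd_parts(data)
  idx <- resolve_loci(group, p$variants, what = "group")
  as.integer(rowSums(p$G[, idx, drop = FALSE] >= 1L, na.rm = TRUE) > 0L)
}

# Burden coding (minor-allele count summed over the group); optional
# alternative to the indicator.
collapse_burden <- function(data, group) {
  p <- gd_parts(data)
  idx <- resolve_loci(group, p$variants, what = "group")
  as.integer(rowSums(p$G[, idx, drop = FALSE], na.rm = TRUE))
}

# Closed-form Mann-Whitney AUC of a binary carrier indicator from carrier
# counts: AUC = 0.5 + 0.5 * (P(carrier | case) - P(carrier | control)).
indicator_auc <- function(a, b, n_case, n_control) {
  0.5 + 0.5 * (a / n_case - b / n_control)
}

#' Grow one pseudo-common variant by stepwise collapsing
#'
#' Seeds a group with the available rare variant whose single-variant carrier
#' indicator has the highest AUC (ties to the lowest variant index), then
#' repeatedly absorbs the rare variant that most increases the AUC of the
#' updated collapsed indicator. Growth stops when no addition improves the
#' AUC by more than `epsilon`.
#'
#' @param data A genotype tibble.
#' @param available_rares Non-empty set of rare-variant IDs or positions to
#'   draw from.
#' @param epsilon Minimum AUC improvement to keep absorbing (default 0).
#' @param coding `"indicator"` (default, carrier union) or `"burden"`
#'   (summed minor-allele counts) for the collapsed score.
#' @return A list with `group` (variant IDs in absorption order) and
#'   `auc_path` (AUC after each absorption; strictly increasing after the
#'   seed).
#' @export
grow_pseudo_variant <- function(data, available_rares, epsilon = 0,
                                coding = c("indicator", "burden")) {
  coding <- match.arg(coding)
  p <- gd_parts(data)
  check_two_classes(p$y)
  idx <- resolve_loci(available_rares, p$variants, what = "available_rares")
  idx <- sort(idx)
  res <- if (coding == "indicator") {
    grow_group_indicator(p$G, p$y, idx, epsilon)
  } else {
    grow_group_burden(p$G, p$y, idx, epsilon)
  }
  list(group = p$variants[res$group], auc_path = res$auc_path)
}

# Greedy carrier-union growth over columns `idx` of G (ascending index, so
# which.max ties resolve to the lowest variant index). Candidate updates are
# computed as crossproducts of the carrier matrix with the not-yet-covered
# case/control masks, which keeps each step a single BLAS call.
grow_group_indicator <- function(G, y, idx, epsilon) {
  Cm <- G[, idx, drop = FALSE] >= 1L
  Cm[is.na(Cm)] <- FALSE
  storage.mode(Cm) <- "double"
  ycase <- y == 1L
  n_case <- sum(ycase)
  n_control <- sum(!ycase)
  a <- as.vector(crossprod(Cm, as.double(ycase)))
  b <- as.vector(crossprod(Cm, as.double(!ycase)))
  auc <- indicator_auc(a, b, n_case, n_control)
  j <- which.max(auc)
  group <- j
  path <- auc[j]
  z <- Cm[, j] > 0
  in_group <- rep(FALSE, length(idx))
  in_group[j] <- TRUE
  while (!all(in_group)) {
    a2 <- sum(z & ycase) + as.vector(crossprod(Cm, as.double(!z & ycase)))
    b2 <- sum(z & !ycase) + as.vector(crossprod(Cm, as.double(!z & !ycase)))
    auc2 <- indicator_auc(a2, b2, n_case, n_control)
    auc2[in_group] <- -Inf
    jj <- which.max(auc2)
    if (!(auc2[jj] > path[length(path)] + epsilon)) break
    group <- c(group, jj)
    path <- c(path, auc2[jj])
    z <- z | Cm[, jj] > 0
    in_group[jj] <- TRUE
  }
  list(group = idx[group], auc_path = path)
}

grow_group_burden <- function(G, y, idx, epsilon) {
  B <- G[, idx, drop = FALSE]
  B[is.na(B)] <- 0L
  single <- vapply(seq_along(idx), function(j) auc_num(B[, j], y), numeric(1))
  j <- which.max(single)
  group <- j
  path <- single[j]
  s <- B[, j]
  remaining <- setdiff(seq_along(idx), j)
  while (length(remaining) > 0L) {
    auc2 <- vapply(remaining, function(jj) auc_num(s + B[, jj], y), numeric(1))
    jj <- which.max(auc2)
    if (!(auc2[jj] > path[length(path)] + epsilon)) break
    group <- c(group, remaining[jj])
    path <- c(path, auc2[jj])
    s <- s + B[, remaining[jj]]
    remaining <- remaining[-jj]
  }
  list(group = idx[group], auc_path = path)
}

#' Multistage collapsing: partition all rare variants into pseudo-common ones
#'
#' Repeatedly runs [grow_pseudo_variant()] on the rare variants not yet
#' collapsed, finishing one pseudo-common variant per stage, until no rare
#' variants remain. Every rare variant ends up in exactly one group; groups
#' whose indicator is uninformative are still emitted (the downstream forward
#' selection is what discards useless pseudo-variants). Because growth is
#' AUC-guided, case-enriched (risk) and control-enriched (protective) rare
#' variants end up in different groups, which is how the multistage procedure
#' accommodates bidirectional effects.
#'
#' @param data A genotype tibble.
#' @param rare_indices Rare-variant IDs or positions; `NULL` (default) takes
#'   every variant with MAF below `maf_threshold`. May be empty, giving an
#'   empty plan.
#' @param maf_threshold MAF threshold used when `rare_indices` is `NULL`,
#'   and recorded in the plan.
#' @param epsilon,coding Passed to [grow_pseudo_variant()].
#' @return A tibble of class `collapsing_plan`, one row per pseudo-common
#'   variant: `pseudo_id`, `variants` (list of variant IDs), `size`, `auc`
#'   (training AUC of the finished indicator) and `auc_path` (list,
#'   per-absorption AUC sequence).
#' @export
build_collapsing_plan <- function(data, rare_indices = NULL,
                                  maf_threshold = 0.01, epsilon = 0,
                                  coding = c("indicator", "burden")) {
  coding <- match.arg(coding)
  p <- gd_parts(data)
  check_two_classes(p$y)
  idx <- if (is.null(rare_indices)) {
    unname(split_by_maf(data, maf_threshold)$rare)
  } else if (length(rare_indices) == 0L) {
    integer(0)
  } else {
    resolve_loci(rare_indices, p$variants, what = "rare_indices")
  }
  groups <- list()
  paths <- list()
  remaining <- sort(idx)
  while (length(remaining) > 0L) {
    res <- if (coding == "indicator") {
      grow_group_indicator(p$G, p$y, remaining, epsilon)
    } else {
      grow_group_burden(p$G, p$y, remaining, epsilon)
    }
    groups[[length(groups) + 1L]] <- res$group
    paths[[length(paths) + 1L]] <- res$auc_path
    remaining <- setdiff(remaining, res$group)
  }
  plan <- tibble::tibble(
    pseudo_id = if (length(groups)) paste0("PCV", seq_along(groups)) else character(0),
    variants = lapply(groups, function(g) p$variants[g]),
    size = lengths(groups),
    auc = vapply(paths, function(x) x[length(x)], numeric(1)),
    auc_path = paths
  )
  structure(plan, class = c("collapsing_plan", class(tibble::tibble())),
            maf_threshold = maf_threshold, coding = coding)
}

#' Materialize a collapsing plan as pseudo-common variant columns
#'
#' Replaces the plan's rare-variant columns with one pseudo-common column per
#' group (named by the plan's `pseudo_id`), leaving all other variants in
#' place. Used internally by [fit_croc()] and [predict.croc_fit()]; exported
#' so the two-path equivalence (collapse-then-score vs score-pre-collapsed)
#' can be checked directly.
#'
#' @param data A genotype tibble containing every variant the plan mentions.
#' @param plan A `collapsing_plan`.
#' @return A genotype tibble with the common variants followed by the
#'   pseudo-common columns.
#' @export
apply_collapsing <- function(data, plan) {
  stopifnot(inherits(plan, "collapsing_plan"))
  p <- gd_parts(data)
  coding <- attr(plan, "coding")
  if (nrow(plan) == 0L) return(tibble::as_tibble(data))
  rare_ids <- unlist(plan$variants, use.names = FALSE)
  resolve_loci(rare_ids, p$variants, what = "plan variants")
  keep <- setdiff(p$variants, rare_ids)
  pseudo <- lapply(plan$variants, function(g) {
    sub <- p$G[, match(g, p$variants), drop = FALSE]
    if (coding == "burden") {
      as.integer(rowSums(sub, na.rm = TRUE))
    } else {
      as.integer(rowSums(sub >= 1L, na.rm = TRUE) > 0L)
    }
  })
  names(pseudo) <- plan$pseudo_id
  dplyr::bind_cols(
    data[c("sample_id", "status", keep)],
    tibble::as_tibble(pseudo)
  )
}

#' Fit a collapsing-ROC (CROC) risk prediction model
#'
#' The CROC approach extends [fit_froc()] to data containing rare variants,
#' which forward selection almost never picks individually because of their
#' low frequency. Variants are first split at `maf_threshold`; the rare ones
#' are collapsed by the multistage procedure of [build_collapsing_plan()]
#' into pseudo-common carrier indicators; forward selection with
#' cross-validated model-size choice then runs over the common variants plus
#' the pseudo-common ones. On data with no rare variants the procedure
#' reduces exactly to FROC (same seed, same model).
#'
#' @inheritParams fit_froc
#' @param maf_threshold Variants with pooled-sample MAF strictly below this
#'   are collapsed (default 0.01).
#' @param coding Collapsed-variant coding: `"indicator"` (carrier union,
#'   default) or `"burden"` (summed minor-allele counts).
#' @param collapse_cv `"fixed"` (default) builds the collapsing plan once on
#'   the full training data and keeps it fixed inside cross-validation;
#'   `"per-fold"` rebuilds the plan (and re-runs selection, implying nested
#'   CV) inside each fold.
#' @return A `croc_fit` whose `collapsing_plan` records the rare-variant
#'   groups, so [predict.croc_fit()] can be applied to raw genotype data.
#' @export
fit_croc <- function(data, folds = 10, seed, maf_threshold = 0.01,
                     pseudocount = 0.5, epsilon = 0, max_model_size = 20,
                     cv_mode = c("fixed-path", "nested"),
                     collapse_cv = c("fixed", "per-fold"),
                     coding = c("indicator", "burden"), unseen_lr = 1,
                     lr_cap = 1e6) {
  cv_mode <- match.arg(cv_mode)
  collapse_cv <- match.arg(collapse_cv)
  coding <- match.arg(coding)
  data <- validate_genotype_data(data)
  plan <- build_collapsing_plan(data, maf_threshold = maf_threshold,
                                epsilon = epsilon, coding = coding)
  aug <- apply_collapsing(data, plan)
  if (collapse_cv == "per-fold") {
    cv_mode <- "nested"
    prepare <- function(tr, te) {
      plan_f <- build_collapsing_plan(tr, maf_threshold = maf_threshold,
                                      epsilon = epsilon, coding = coding)
      tr_aug <- apply_collapsing(tr, plan_f)
      list(train = tr_aug, test = apply_collapsing(te, plan_f),
           candidates = variant_cols(tr_aug))
    }
    fit <- fit_engine(aug, candidates = NULL, folds, seed, pseudocount,
                      epsilon, max_model_size, cv_mode, unseen_lr, lr_cap,
                      method = "croc", nested_prepare = prepare,
                      raw_data = data)
  } else {
    fit <- fit_engine(aug, candidates = NULL, folds, seed, pseudocount,
                      epsilon, max_model_size, cv_mode, unseen_lr, lr_cap,
                      method = "croc")
  }
  fit$collapsing_plan <- plan
  fit$config$maf_threshold <- maf_threshold
  fit$config$coding <- coding
  fit$config$collapse_cv <- collapse_cv
  fit
}
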