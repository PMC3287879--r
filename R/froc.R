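#' One step of greedy forward locus selection
#'
#' Evaluates every candidate locus as an addition to the current predictor
#' set: each candidate is scored by the training AUC of the LR table built on
#' `c(current_loci, candidate)`, and the candidate with the largest AUC wins.
#' Ties are broken in favour of the lowest variant (column) index.
#'
#' @param data A genotype tibble (see [genotype_data()]).
#' @param current_loci Loci already in the model (IDs or positions); may be
#'   `NULL` for the first step.
#' @param candidates Candidate loci to consider (IDs or positions); must be
#'   non-empty and disjoint from `current_loci`.
#' @param pseudocount,lr_cap Smoothing settings, as in [lr_table()].
#' @return A one-row tibble with columns `locus` (variant ID) and
#'   `train_auc`.
#' @export
forward_step <- function(data, current_loci = NULL, candidates = NULL,
                         pseudocount = 0.5, lr_cap = 1e6) {
  p <- gd_parts(data)
  check_two_classes(p$y)
  cur <- if (length(current_loci)) resolve_loci(current_loci, p$variants) else integer(0)
  cand <- if (is.null(candidates)) {
    setdiff(seq_along(p$variants), cur)
  } else {
    resolve_loci(candidates, p$variants, what = "candidates")
  }
  if (length(cand) == 0L) abort_invalid("`candidates` must be non-empty.")
  if (length(intersect(cand, cur))) {
    abort_invalid("`candidates` must be disjoint from `current_loci`.")
  }
  st <- group_state(p$G, cur)
  res <- step_eval(p$G, p$y == 1L, st$g, st$M, sort(cand), pseudocount, lr_cap)
  tibble::tibble(locus = p$variants[res$j], train_auc = res$auc)
}

# Internal fast kernels ---------------------------------------------------

# Genotype level 1..4 (0,1,2 minor alleles; 4 = missing call).
geno_level <- function(x) {
  l <- x + 1L
  l[is.na(l)] <- 4L
  l
}

# Integer group ids (1..M) for the multilocus genotypes at `idx`.
group_state <- function(G, idx) {
  n <- nrow(G)
  g <- rep(1L, n)
  M <- 1L
  for (j in idx) {
    comb <- (g - 1L) * 4L + geno_level(G[, j])
    u <- sort(unique(comb))
    g <- match(comb, u)
    M <- length(u)
  }
  list(g = g, M = M)
}

# Best single addition: max training AUC, ties to the lowest column index
# (cand_idx must be ascending; strict > keeps the first maximum).
step_eval <- function(G, ycase, g, M, cand_idx, pseudocount, lr_cap) {
  n_case <- sum(ycase)
  n_control <- length(ycase) - n_case
  base <- (g - 1L) * 4L
  nb <- M * 4L
  best_j <- NA_integer_
  best_auc <- -Inf
  for (j in cand_idx) {
    comb <- base + geno_level(G[, j])
    cc <- tabulate(comb[ycase], nb)
    dd <- tabulate(comb[!ycase], nb)
    keep <- (cc + dd) > 0L
    cck <- cc[keep]
    ddk <- dd[keep]
    lr <- lr_values(cck, ddk, n_case, n_control, pseudocount, lr_cap)
    a <- auc_from_groups(cck, ddk, lr)
    if (a > best_auc) {
      best_auc <- a
      best_j <- j
    }
  }
  list(j = best_j, auc = best_auc)
}

# Greedy forward path until the best addition no longer improves the training
# AUC by more than epsilon (null model AUC = 0.5), the size cap is hit, or
# candidates run out.
build_path <- function(G, y, cand_idx, pseudocount, epsilon, max_model_size,
                       lr_cap) {
  ycase <- y == 1L
  g <- rep(1L, nrow(G))
  M <- 1L
  prev <- 0.5
  path <- integer(0)
  aucs <- numeric(0)
  avail <- sort(cand_idx)
  warned <- FALSE
  while (length(avail) > 0L && length(path) < max_model_size) {
    st <- step_eval(G, ycase, g, M, avail, pseudocount, lr_cap)
    if (!(st$auc > prev + epsilon)) break
    path <- c(path, st$j)
    aucs <- c(aucs, st$auc)
    prev <- st$auc
    comb <- (g - 1L) * 4L + geno_level(G[, st$j])
    u <- sort(unique(comb))
    g <- match(comb, u)
    M <- length(u)
    if (!warned && M > 4096L) {
      rlang::warn(sprintf(
        "Forward path reached %d observed genotype groups; LR estimates will be sparse.", M))
      warned <- TRUE
    }
    avail <- avail[avail != st$j]
  }
  list(path = path, train_auc = aucs)
}

# Internal numeric AUC (no curve construction).
auc_num <- function(scores, y) {
  lev <- sort(unique(scores))
  gi <- match(scores, lev)
  cc <- tabulate(gi[y == 1L], length(lev))
  dd <- tabulate(gi[y == 0L], length(lev))
  auc_from_ordered_groups(cc, dd)
}

# Stratified fold assignment: cases and controls shuffled separately and
# dealt round-robin, so each fold's case:control ratio is within one
# individual of the overall ratio. Uses the current RNG state.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in c(1L, 0L)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Held-out AUC of each path prefix with the path fixed: per fold, the LR
# table is re-estimated on the fold-training rows at the prefix loci and the
# fold-test rows are scored with it.
cv_fixed_path <- function(G, y, path, fold, k, pseudocount, lr_cap, unseen_lr) {
  vapply(seq_along(path), function(s) {
    key <- genotype_key(G, path[seq_len(s)])
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      ktr <- key[tr]
      ytr <- y[tr]
      groups <- sort(unique(ktr))
      gi <- match(ktr, groups)
      cc <- tabulate(gi[ytr == 1L], length(groups))
      dd <- tabulate(gi[ytr == 0L], length(groups))
      lr <- lr_values(cc, dd, sum(ytr == 1L), sum(ytr == 0L), pseudocount,
                      lr_cap)
      hit <- match(key[!tr], groups)
      sc <- lr[hit]
      sc[is.na(hit)] <- unseen_lr
      auc_num(sc, y[!tr])
    }, numeric(1)))
  }, numeric(1))
}

# Nested CV: each fold re-runs its own preparation (e.g. collapsing) and
# forward selection on the fold-training rows, then its path prefixes are
# scored on the fold-test rows. `prepare(train_raw, test_raw)` returns
# list(train, test, candidates). Returns the mean held-out AUC per model
# size 1..n_sizes (folds whose path is shorter contribute their longest
# prefix).
cv_nested <- function(raw, fold, k, n_sizes, prepare, pseudocount, epsilon,
                      max_model_size, lr_cap, unseen_lr) {
  aucs <- matrix(NA_real_, nrow = k, ncol = n_sizes)
  for (f in seq_len(k)) {
    tr <- fold != f
    pr <- prepare(raw[tr, , drop = FALSE], raw[!tr, , drop = FALSE])
    ptr <- gd_parts(pr$train)
    pte <- gd_parts(pr$test)
    cand <- resolve_loci(pr$candidates, ptr$variants, what = "candidates")
    bp <- build_path(ptr$G, ptr$y, cand, pseudocount, epsilon,
                     max_model_size, lr_cap)
    if (length(bp$path) == 0L) {
      aucs[f, ] <- 0.5
      next
    }
    for (s in seq_len(n_sizes)) {
      use <- bp$path[seq_len(min(s, length(bp$path)))]
      key_tr <- genotype_key(ptr$G, use)
      groups <- sort(unique(key_tr))
      gi <- match(key_tr, groups)
      cc <- tabulate(gi[ptr$y == 1L], length(groups))
      dd <- tabulate(gi[ptr$y == 0L], length(groups))
      lr <- lr_values(cc, dd, sum(ptr$y == 1L), sum(ptr$y == 0L),
                      pseudocount, lr_cap)
      te_idx <- match(ptr$variants[use], pte$variants)
      key_te <- genotype_key(pte$G, te_idx)
      hit <- match(key_te, groups)
      sc <- lr[hit]
      sc[is.na(hit)] <- unseen_lr
      aucs[f, s] <- auc_num(sc, pte$y)
    }
  }
  colMeans(aucs)
}

# Shared fitting engine behind fit_froc() and fit_croc().
fit_engine <- function(data, candidates, folds, seed, pseudocount, epsilon,
                       max_model_size, cv_mode, unseen_lr, lr_cap, method,
                       nested_prepare = NULL, raw_data = NULL) {
  p <- gd_parts(data)
  cand <- if (is.null(candidates)) {
    seq_along(p$variants)
  } else {
    resolve_loci(candidates, p$variants, what = "candidates")
  }
  if (length(cand) == 0L) abort_invalid("`candidates` must be non-empty.")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_invalid("`seed` is required (a single integer).")
  }
  n_case <- sum(p$y == 1L)
  n_control <- sum(p$y == 0L)
  if (n_case == 0L || n_control == 0L) {
    abort_degenerate("Fitting needs at least one case and one control.")
  }
  if (folds < 2L) abort_invalid("`folds` must be at least 2.")
  if (folds > min(n_case, n_control)) {
    abort_invalid(sprintf(
      "`folds` (%d) cannot exceed the smaller class count (%d cases, %d controls).",
      folds, n_case, n_control))
  }
  withr::local_seed(as.integer(seed))

  bp <- build_path(p$G, p$y, cand, pseudocount, epsilon, max_model_size,
                   lr_cap)
  fold <- stratified_folds(p$y, folds)
  if (length(bp$path) == 0L) {
    cv <- numeric(0)
    chosen <- 0L
    table <- NULL
  } else {
    cv <- if (cv_mode == "nested") {
      cv_nested(if (is.null(raw_data)) data else raw_data, fold, folds,
                length(bp$path),
                if (is.null(nested_prepare)) {
                  function(tr, te) list(train = tr, test = te,
                                        candidates = p$variants[cand])
                } else nested_prepare,
                pseudocount, epsilon, max_model_size, lr_cap, unseen_lr)
    } else {
      cv_fixed_path(p$G, p$y, bp$path, fold, folds, pseudocount, lr_cap,
                    unseen_lr)
    }
    chosen <- which.max(cv)   # first maximum = smallest size on ties
    key <- genotype_key(p$G, bp$path[seq_len(chosen)])
    table <- new_lr_table(key, p$y, loci = p$variants[bp$path[seq_len(chosen)]],
                          pseudocount = pseudocount, lr_cap = lr_cap,
                          unseen_lr = unseen_lr)
  }
  trace <- tibble::tibble(
    step = seq_along(bp$path),
    locus = p$variants[bp$path],
    train_auc = bp$train_auc,
    cv_auc = if (length(bp$path)) cv else numeric(0)
  )
  structure(list(
    loci = if (chosen > 0L) p$variants[bp$path[seq_len(chosen)]] else character(0),
    lr_table = table,
    trace = trace,
    chosen_size = chosen,
    collapsing_plan = NULL,
    config = list(method = method, folds = as.integer(folds),
                  seed = as.integer(seed), pseudocount = pseudocount,
                  epsilon = epsilon, max_model_size = as.integer(max_model_size),
                  cv_mode = cv_mode, unseen_lr = unseen_lr, lr_cap = lr_cap),
    n_case = n_case, n_control = n_control
  ), class = "croc_fit")
}

#' Fit a forward-ROC (FROC) risk prediction model
#'
#' Greedy forward selection over the candidate loci: at each step the locus
#' whose addition maximizes the training AUC of the likelihood-ratio-ordered
#' ROC curve joins the model, until no addition improves the AUC by more than
#' `epsilon` (or `max_model_size` is reached). Model size is then chosen by
#' stratified k-fold cross-validation: for each prefix of the forward path the
#' LR table is re-estimated on the fold-training data and the held-out fold is
#' scored; the size with the best mean held-out AUC wins, ties going to the
#' smaller (more parsimonious) model. The final LR table is re-estimated on
#' the full data at the chosen loci.
#'
#' @param data A genotype tibble (see [genotype_data()]).
#' @param candidates Candidate loci (variant IDs or positions); default all
#'   variants.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed governing fold assignment; required, and recorded
#'   in the fitted model so fits are exactly reproducible.
#' @param pseudocount,lr_cap,unseen_lr Smoothing settings, see [lr_table()].
#' @param epsilon Minimum training-AUC improvement to keep adding loci
#'   (default 0: stop when the AUC no longer increases).
#' @param max_model_size Cap on the number of selected loci (default 20),
#'   bounding the growth of the genotype-group cross-tabulation.
#' @param cv_mode `"fixed-path"` (default) re-estimates LR tables along the
#'   full-data forward path inside each fold; `"nested"` re-runs forward
#'   selection inside each fold.
#' @return An object of class `croc_fit` with elements `loci`, `lr_table`,
#'   `trace` (tibble of `step`, `locus`, `train_auc`, `cv_auc`),
#'   `chosen_size`, `collapsing_plan` (`NULL` for FROC) and `config`.
#' @seealso [fit_croc()] for the variant that collapses rare variants first,
#'   [predict.croc_fit()], [generics::tidy()], [generics::glance()].
#' @export
fit_froc <- function(data, candidates = NULL, folds = 10, seed,
                     pseudocount = 0.5, epsilon = 0, max_model_size = 20,
                     cv_mode = c("fixed-path", "nested"), unseen_lr = 1,
                     lr_cap = 1e6) {
  cv_mode <- match.arg(cv_mode)
  fit_engine(data, candidates, folds, seed, pseudocount, epsilon,
             max_model_size, cv_mode, unseen_lr, lr_cap, method = "froc")
}

#' Predict likelihood-ratio risk scores for new individuals
#'
#' Applies the model's collapsing plan (if any) to materialize pseudo-common
#' variant columns from the raw genotypes, then assigns each individual the
#' LR of their multilocus genotype group. Genotype tuples unseen at training
#' receive the model's neutral `unseen_lr` (default 1).
#'
#' @param object A `croc_fit` from [fit_froc()] or [fit_croc()].
#' @param newdata A genotype tibble containing every model locus (for CROC
#'   models, every rare variant referenced by the collapsing plan).
#' @param ... Unused.
#' @return A tibble with columns `sample_id` and `score`.
#' @export
predict.croc_fit <- function(object, newdata, ...) {
  data <- newdata
  if (!is.null(object$collapsing_plan) && nrow(object$collapsing_plan) > 0L) {
    data <- apply_collapsing(data, object$collapsing_plan)
  }
  if (is.null(object$lr_table)) {
    p <- gd_parts(data)
    return(tibble::tibble(sample_id = p$ids,
                          score = rep(object$config$unseen_lr, length(p$ids))))
  }
  lr_scores(data, object$lr_table)
}

#' @export
print.croc_fit <- function(x, ...) {
  cat(sprintf("<%s model> %d selected loci (path length %d)\n",
              toupper(x$config$method), length(x$loci), nrow(x$trace)))
  if (length(x$loci)) {
    cat("  loci:", paste(x$loci, collapse = ", "), "\n")
    cat(sprintf("  training AUC %.4f | mean CV AUC %.4f (%d-fold)\n",
                x$trace$train_auc[x$chosen_size],
                x$trace$cv_auc[x$chosen_size], x$config$folds))
  } else {
    cat("  (no locus improved on the null model)\n")
  }
  if (!is.null(x$collapsing_plan)) {
    cat(sprintf("  collapsing plan: %d pseudo-common variants from %d rare variants\n",
                nrow(x$collapsing_plan),
                sum(lengths(x$collapsing_plan$variants))))
  }
  invisible(x)
}

#' Tidy the forward-selection trace of a fitted model
#'
#' @param x A `croc_fit`.
#' @param ... Unused.
#' @return One row per forward-selection step: `step`, `locus`, `train_auc`,
#'   `cv_auc`, and `selected` (whether the step is within the chosen model
#'   size).
#' @method tidy croc_fit
#' @export
tidy.croc_fit <- function(x, ...) {
  dplyr::mutate(x$trace, selected = .data$step <= x$chosen_size)
}

#' One-row summary of a fitted risk model
#'
#' @param x A `croc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_loci`, `n_groups`, `train_auc`,
#'   `cv_auc`, `folds`, `seed`.
#' @method glance croc_fit
#' @export
glance.croc_fit <- function(x, ...) {
  tibble::tibble(
    method = x$config$method,
    n_loci = length(x$loci),
    n_groups = if (is.null(x$lr_table)) 0L else nrow(x$lr_table),
    train_auc = if (x$chosen_size > 0L) x$trace$train_auc[x$chosen_size] else 0.5,
    cv_auc = if (x$chosen_size > 0L) x$trace$cv_auc[x$chosen_size] else 0.5,
    folds = x$config$folds,
    seed = x$config$seed
  )
}

#' Plot the forward-selection trace
#'
#' Training and cross-validated AUC against model size, with the chosen size
#' marked. The widening gap between the two curves is the overfitting the
#' cross-validation guards against.
#'
#' @param object A `croc_fit`.
#' @param ... Unused.
#' @method autoplot croc_fit
#' @export
autoplot.croc_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("train_auc", "cv_auc"),
                            names_to = "which", values_to = "auc")
  tr$which <- dplyr::recode(tr$which, train_auc = "training",
                            cv_auc = "cross-validated")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$auc,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_vline(xintercept = object$chosen_size, linetype = "dotted") +
    ggplot2::labs(x = "Model size (number of loci)", y = "AUC",
                  colour = NULL,
                  title = sprintf("%s forward-selection trace",
                                  toupper(object$config$method))) +
    ggplot2::theme_minimal()
}

#' @export
plot.croc_fit <- function(x, ...) print(autoplot.croc_fit(x, ...))
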