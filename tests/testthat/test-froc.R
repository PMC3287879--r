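# Greedy forward selection and cross-validated model-size choice.

test_that("forward_step picks a perfectly separating locus with AUC 1", {
  set.seed(1)
  y <- rep(c(1, 0), each = 10)
  d <- make_data(status = y,
                 noise1 = rbinom(20, 2, 0.3),
                 noise2 = rbinom(20, 2, 0.3),
                 sep = y * 2)
  st <- forward_step(d)
  expect_equal(st$locus, "sep")
  expect_equal(st$train_auc, 1.0)
})

test_that("forward_step breaks ties toward the lowest variant index", {
  set.seed(2)
  x <- rbinom(30, 2, 0.4)
  d <- make_data(status = rep(c(1, 0), 15), a = x, b = x)
  expect_equal(forward_step(d)$locus, "a")
  # same columns offered in the other order still give the first position
  expect_equal(forward_step(d, candidates = c("b", "a"))$locus, "a")
})

test_that("forward_step agrees with exhaustive single-addition evaluation", {
  for (seed in 1:8) {
    d <- rand_data(n = 40, v = 5, seed = seed)
    # tilt the phenotype so there is something to find
    aucs <- vapply(variant_cols(d), function(v) bf_train_auc(d, v), numeric(1))
    st <- forward_step(d)
    expect_equal(st$train_auc, max(aucs), tolerance = 1e-12)
    expect_equal(st$locus, variant_cols(d)[which.max(aucs)])
    # second step given the first locus
    first <- st$locus
    rest <- setdiff(variant_cols(d), first)
    aucs2 <- vapply(rest, function(v) bf_train_auc(d, c(first, v)), numeric(1))
    st2 <- forward_step(d, current_loci = first, candidates = rest)
    expect_equal(st2$train_auc, max(aucs2), tolerance = 1e-12)
  }
})

test_that("forward_step validates its inputs", {
  d <- rand_data(20, 3, seed = 3)
  expect_error(forward_step(d, candidates = character(0)),
               class = "crocr_invalid_argument")
  expect_error(forward_step(d, current_loci = "V1", candidates = c("V1", "V2")),
               class = "crocr_invalid_argument")
})

test_that("training AUC is strictly increasing along the forward path", {
  for (seed in 1:15) {
    d <- rand_data(n = 50, v = 8, seed = 100 + seed)
    fit <- fit_froc(d, folds = 5, seed = seed)
    if (nrow(fit$trace) > 1) {
      expect_true(all(diff(fit$trace$train_auc) > 0))
    }
    expect_true(all(fit$trace$train_auc >= 0.5))
    expect_lte(fit$chosen_size, nrow(fit$trace))
    expect_false(anyDuplicated(fit$trace$locus) > 0)
  }
})

test_that("stratified folds keep the case:control ratio within one individual", {
  set.seed(4)
  y <- rep(c(1L, 0L), times = c(37, 85))[sample(122)]
  k <- 10
  fold <- crocr:::stratified_folds(y, k)
  for (f in seq_len(k)) {
    expect_lte(abs(sum(y[fold == f] == 1L) - 37 / k), 1)
    expect_lte(abs(sum(y[fold == f] == 0L) - 85 / k), 1)
  }
})

test_that("refitting with the same data and seed gives an identical model", {
  d <- rand_data(n = 60, v = 6, seed = 5)
  f1 <- fit_froc(d, folds = 5, seed = 99)
  f2 <- fit_froc(d, folds = 5, seed = 99)
  expect_identical(f1, f2)
  expect_identical(write_model(f1), write_model(f2))
  # a different seed may change fold assignment, hence CV values
  f3 <- fit_froc(d, folds = 5, seed = 100)
  expect_identical(f1$trace$train_auc, f3$trace$train_auc)
})

test_that("a single strongly associated locus is recovered as a one-locus model", {
  # one causal common variant (MAF 0.3, allelic log-odds 1.8, baseline
  # prevalence 0.2: population single-locus AUC about 0.75) among nine noise
  # candidates
  cfg <- sim_config(n_cases = 100, n_controls = 100, n_common = 10,
                    n_rare = 0, maf_common_range = c(0.3, 0.3),
                    causal_common = 1, effect_common = 1.8,
                    baseline_prevalence = 0.2)
  set.seed(6)
  first <- kept <- 0L
  for (r in 1:100) {
    truth <- crocr:::draw_truth(cfg)
    d <- crocr:::draw_dataset(truth, cfg)
    fit <- fit_froc(d, folds = 10, seed = r)
    first <- first + as.integer(fit$trace$locus[1] == truth$causal_common)
    kept <- kept + as.integer(truth$causal_common %in% fit$loci)
  }
  expect_gte(first, 90)   # the causal locus dominates the first step
  expect_gte(kept, 90)    # and survives the cross-validated size choice
})

test_that("held-out AUC of the selected model is centred at 0.5 under the null", {
  cfg <- sim_config(n_cases = 50, n_controls = 50, n_common = 6, n_rare = 0)
  set.seed(7)
  heldout <- cv_nested_means <- numeric(0)
  for (r in 1:200) {
    truth <- crocr:::draw_truth(cfg)
    dtr <- crocr:::draw_dataset(truth, cfg)
    dte <- crocr:::draw_dataset(truth, cfg)
    fit <- fit_froc(dtr, folds = 5, seed = r)
    sc <- predict(fit, dte)
    heldout <- c(heldout, roc_auc(sc$score, dte$status)$auc)
  }
  se <- sd(heldout) / sqrt(length(heldout))
  expect_lt(abs(mean(heldout) - 0.5), 3 * se + 1e-8)
})

test_that("nested cross-validation is unbiased under the null", {
  # with per-fold re-selection, the fold-held-out AUC of every model size is
  # an honest estimate, so its mean over null repeats sits at 0.5
  cfg <- sim_config(n_cases = 40, n_controls = 40, n_common = 6, n_rare = 0)
  set.seed(8)
  cv1 <- numeric(0)
  for (r in 1:80) {
    d <- simulate_dataset(cfg)
    fit <- fit_froc(d, folds = 4, seed = r, cv_mode = "nested")
    if (nrow(fit$trace) >= 1) cv1 <- c(cv1, fit$trace$cv_auc[1])
  }
  se <- sd(cv1) / sqrt(length(cv1))
  expect_lt(abs(mean(cv1) - 0.5), 3 * se + 0.01)
})

test_that("predict is idempotent on training data and closed over seen tuples", {
  d <- rand_data(n = 80, v = 5, seed = 9)
  fit <- fit_froc(d, folds = 5, seed = 1)
  s1 <- predict(fit, d)
  s2 <- predict(fit, d)
  expect_identical(s1, s2)
  expect_true(all(s1$score %in% fit$lr_table$lr))
  expect_identical(s1$score, lr_scores(d, fit$lr_table)$score)
})

test_that("fit_froc rejects impossible fold counts and degenerate data", {
  d <- rand_data(20, 3, seed = 10)
  expect_error(fit_froc(d, folds = 40, seed = 1),
               class = "crocr_invalid_argument")
  expect_error(fit_froc(d, folds = 1, seed = 1),
               class = "crocr_invalid_argument")
  expect_error(fit_froc(d, folds = 5, seed = NULL),
               class = "crocr_invalid_argument")
})

test_that("tidy, glance and autoplot expose the selection trace", {
  d <- rand_data(n = 60, v = 5, seed = 11)
  fit <- fit_froc(d, folds = 5, seed = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("step", "locus", "train_auc", "cv_auc", "selected"))
  expect_equal(sum(td$selected), fit$chosen_size)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_loci, length(fit$loci))
  expect_s3_class(autoplot(fit), "ggplot")
})
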