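# Multistage collapsing of rare variants and the combined CROC fit.

test_that("split_by_maf partitions at a strict threshold", {
  # 1000 individuals with exact allele counts: MAFs 0.2, 0.005, 0.0005, 0.01
  n <- 1000
  mk <- function(ones) c(rep(1L, ones), rep(0L, n - ones))
  d <- make_data(status = rep(c(1, 0), n / 2),
                 a = mk(400), b = mk(10), c = mk(1), d = mk(20))
  sp <- split_by_maf(d, 0.01)
  expect_equal(unname(sp$common), c(1, 4))   # MAF exactly 0.01 is common
  expect_equal(unname(sp$rare), c(2, 3))
  # boundary: everything below 0.5 is rare at threshold 0.5
  expect_length(split_by_maf(d, 0.5)$rare, 4)
  expect_error(split_by_maf(d, 0), class = "crocr_invalid_argument")
})

test_that("collapse_indicator is the carrier union of the group", {
  d <- make_data(status = rep(c(1, 0), 3),
                 r1 = c(1, 0, 0, 0, 0, 0),
                 r2 = c(0, 0, 1, 0, 0, 0),
                 r3 = c(0, 0, 0, 0, 2, 0),
                 r4 = c(0, 0, 0, 0, 0, 0))
  pc <- collapse_indicator(d, c("r1", "r2", "r3"))
  expect_equal(pc, c(1L, 0L, 1L, 0L, 1L, 0L))
  expect_equal(sum(pc), 3)                       # one carrier per variant
  expect_equal(collapse_indicator(d, "r4"), rep(0L, 6))
  expect_error(collapse_indicator(d, integer(0)),
               class = "crocr_invalid_argument")
})

test_that("pseudo-variant growth absorbs complementary case-only carriers", {
  # two rare risk variants carried by distinct cases: the union separates
  # four cases instead of two, so both are absorbed and the collapsed AUC
  # beats each single-variant AUC
  status <- rep(c(1, 0), each = 10)
  r1 <- ifelse(seq_len(20) %in% 1:2, 1, 0)
  r2 <- ifelse(seq_len(20) %in% 3:4, 1, 0)
  d <- make_data(status = status, r1 = r1, r2 = r2)
  g <- grow_pseudo_variant(d, c("r1", "r2"))
  expect_setequal(g$group, c("r1", "r2"))
  single <- c(bf_auc(r1, status), bf_auc(r2, status))
  expect_equal(g$auc_path[length(g$auc_path)],
               bf_auc(as.numeric(r1 | r2), status))
  expect_gt(g$auc_path[length(g$auc_path)], max(single))
  expect_true(all(diff(g$auc_path) > 0))
})

test_that("a single available rare gives a singleton group", {
  d <- make_data(status = rep(c(1, 0), 10), r1 = rbinom(20, 1, 0.1))
  g <- grow_pseudo_variant(d, "r1")
  expect_equal(g$group, "r1")
  expect_length(g$auc_path, 1)
})

test_that("null single-carrier rares: growth stops early and generalizes to 0.5", {
  cfg <- sim_config(n_cases = 20, n_controls = 20, n_common = 0, n_rare = 12,
                    maf_rare_range = c(0.009, 0.01))
  set.seed(20)
  sizes <- integer(0)
  test_auc <- numeric(0)
  for (r in 1:100) {
    truth <- crocr:::draw_truth(cfg)
    dtr <- crocr:::draw_dataset(truth, cfg)
    dte <- crocr:::draw_dataset(truth, cfg)
    g <- grow_pseudo_variant(dtr, variant_cols(dtr))
    sizes <- c(sizes, length(g$group))
    ind <- collapse_indicator(dte, g$group)
    if (length(unique(ind)) > 1) {
      test_auc <- c(test_auc, roc_auc(ind, dte$status)$auc)
    }
  }
  expect_lt(mean(sizes), 12)   # growth stops before exhausting the rares
  se <- sd(test_auc) / sqrt(length(test_auc))
  expect_lt(abs(mean(test_auc) - 0.5), 3 * se + 1e-8)
})

test_that("greedy growth matches an independent brute-force greedy oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 30
    g <- matrix(rbinom(n * 6, 1, 0.08), n, 6)
    d <- genotype_data(g, status = rep(c(1, 0), n / 2))
    mine <- grow_pseudo_variant(d, variant_cols(d))
    oracle <- bf_greedy_group(d, variant_cols(d))
    expect_identical(mine$group, oracle$group)
    expect_equal(mine$auc_path[length(mine$auc_path)], oracle$auc,
                 tolerance = 1e-12)
  }
})

test_that("risk and protective rare variants end up in different groups", {
  # 3 case-enriched and 3 control-enriched rares; merging across directions
  # always lowers the indicator AUC, so the first group is purely risk
  status <- rep(c(1, 0), each = 12)
  carrier <- function(ids) ifelse(seq_len(24) %in% ids, 1, 0)
  d <- make_data(status = status,
                 risk1 = carrier(1:2), risk2 = carrier(3:4),
                 risk3 = carrier(5:6),
                 prot1 = carrier(13:14), prot2 = carrier(15:16),
                 prot3 = carrier(17:18))
  plan <- build_collapsing_plan(d, rare_indices = variant_cols(d))
  expect_setequal(plan$variants[[1]], c("risk1", "risk2", "risk3"))
  for (grp in plan$variants) {
    kinds <- unique(substr(grp, 1, 4))
    expect_length(kinds, 1)   # no group mixes risk and protective variants
  }
  # exhaustive check at this size: no carrier-union subset of the six rares
  # has a higher indicator AUC than the greedy first group
  ids <- variant_cols(d)
  best <- 0
  for (k in 1:6) {
    for (sub in combn(ids, k, simplify = FALSE)) {
      ind <- as.numeric(rowSums(as.data.frame(d[sub]) >= 1) > 0)
      best <- max(best, bf_auc(ind, status))
    }
  }
  expect_equal(plan$auc[1], best, tolerance = 1e-12)
})

test_that("collapsing plans partition the rare set", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 50
    g <- cbind(matrix(rbinom(n * 3, 2, 0.3), n, 3),
               matrix(rbinom(n * 9, 1, 0.04), n, 9))
    d <- genotype_data(g, status = rep(c(1, 0), n / 2))
    rares <- paste0("V", 4:12)
    plan <- build_collapsing_plan(d, rare_indices = rares)
    got <- unlist(plan$variants)
    expect_setequal(got, rares)
    expect_equal(length(got), length(rares))   # disjoint: no duplicates
    expect_true(all(plan$size >= 1))
    # within-group AUC path strictly increases after the seed
    for (pth in plan$auc_path) {
      if (length(pth) > 1) expect_true(all(diff(pth) > 0))
    }
  }
})

test_that("an empty rare set gives an empty plan", {
  d <- rand_data(20, 3, seed = 30)
  plan <- build_collapsing_plan(d, rare_indices = integer(0))
  expect_equal(nrow(plan), 0)
  expect_identical(apply_collapsing(d, plan), tibble::as_tibble(d))
})

test_that("pseudo-variant carrier frequency dominates its constituents", {
  set.seed(31)
  n <- 80
  g <- matrix(rbinom(n * 10, 1, 0.05), n, 10)
  d <- genotype_data(g, status = rep(c(1, 0), n / 2))
  plan <- build_collapsing_plan(d, rare_indices = variant_cols(d))
  for (i in seq_len(nrow(plan))) {
    pc <- collapse_indicator(d, plan$variants[[i]])
    for (v in plan$variants[[i]]) {
      expect_gte(mean(pc), mean(d[[v]] >= 1))
    }
  }
})

test_that("CROC equals FROC when the data has no rare variants", {
  cfg <- sim_config(n_cases = 40, n_controls = 60, n_common = 12, n_rare = 0,
                    seed = 32)
  d <- simulate_dataset(cfg)
  ff <- fit_froc(d, folds = 5, seed = 5)
  fc <- fit_croc(d, folds = 5, seed = 5)
  expect_equal(nrow(fc$collapsing_plan), 0)
  expect_identical(fc$loci, ff$loci)
  expect_identical(fc$trace, ff$trace)
  expect_identical(write_model(fc), write_model(ff))
})

test_that("scoring raw data through the plan equals scoring pre-collapsed data", {
  cfg <- sim_config(n_cases = 60, n_controls = 60, n_common = 8, n_rare = 30,
                    causal_rare = 6, effect_rare = log(10),
                    baseline_prevalence = 0.2, seed = 33)
  dtr <- simulate_dataset(cfg)
  dte <- simulate_dataset(sim_config(n_cases = 60, n_controls = 60,
                                     n_common = 8, n_rare = 30, seed = 34))
  fit <- fit_croc(dtr, folds = 5, seed = 6)
  via_model <- predict(fit, dte)
  pre <- apply_collapsing(dte, fit$collapsing_plan)
  direct <- lr_scores(pre, fit$lr_table)
  expect_identical(via_model$score, direct$score)
})

test_that("burden coding is available and changes only the pseudo-variant values", {
  set.seed(35)
  n <- 40
  g <- matrix(rbinom(n * 6, 1, 0.08), n, 6)
  d <- genotype_data(g, status = rep(c(1, 0), n / 2))
  plan <- build_collapsing_plan(d, rare_indices = variant_cols(d),
                                coding = "burden")
  aug <- apply_collapsing(d, plan)
  pc <- aug[[plan$pseudo_id[1]]]
  expect_true(all(pc == rowSums(as.data.frame(d[plan$variants[[1]]]))))
})
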