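# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by the most literal route available
# (pairwise double loops, exhaustive enumeration, hand counting) so they stay
# independent of the package's vectorized kernels.

# Mann-Whitney AUC as the literal sum over all case-control pairs:
# psi = 1 if case > control, 0.5 on ties, 0 otherwise.
bf_auc <- function(scores, y) {
  cs <- scores[y == 1]
  ds <- scores[y == 0]
  psi <- outer(cs, ds, ">") + 0.5 * outer(cs, ds, "==")
  sum(psi) / (length(cs) * length(ds))
}

# AUC of an explicit group ordering: groups with case counts cc / control
# counts dd are ranked by `ord` (ascending score); literal sum over group
# pairs.
ordered_group_auc <- function(cc, dd, ord) {
  cc <- cc[ord]
  dd <- dd[ord]
  m <- length(cc)
  total <- 0
  for (i in seq_len(m)) {
    if (i > 1) total <- total + cc[i] * sum(dd[seq_len(i - 1)])
    total <- total + 0.5 * cc[i] * dd[i]
  }
  total / (sum(cc) * sum(dd))
}

# Hand-computed training AUC of an LR model at `loci`: tabulate genotype
# tuples with paste/table, form smoothed frequency-ratio LRs, score each
# individual, brute-force AUC.
bf_train_auc <- function(data, loci, pseudocount = 0.5) {
  g <- as.data.frame(data[loci])
  key <- do.call(paste, c(g, sep = "/"))
  y <- data$status
  groups <- unique(key)
  m <- length(groups)
  lr <- vapply(groups, function(k) {
    a <- sum(key == k & y == 1)
    b <- sum(key == k & y == 0)
    ((a + pseudocount) / (sum(y == 1) + pseudocount * m)) /
      ((b + pseudocount) / (sum(y == 0) + pseudocount * m))
  }, numeric(1))
  bf_auc(lr[match(key, groups)], y)
}

# Independent greedy collapsing: grow one carrier-union group from `rares`
# (variant IDs), maximizing bf_auc of the indicator at each step, ties to the
# variant earliest in `rares`.
bf_greedy_group <- function(data, rares) {
  y <- data$status
  carrier <- function(ids) {
    as.integer(rowSums(as.data.frame(data[ids]) >= 1) > 0)
  }
  aucs <- vapply(rares, function(v) bf_auc(carrier(v), y), numeric(1))
  group <- rares[which.max(aucs)]
  best <- max(aucs)
  rest <- setdiff(rares, group)
  repeat {
    if (length(rest) == 0) break
    cand <- vapply(rest, function(v) bf_auc(carrier(c(group, v)), y),
                   numeric(1))
    if (max(cand) <= best) break
    pick <- rest[which.max(cand)]
    group <- c(group, pick)
    best <- max(cand)
    rest <- setdiff(rest, pick)
  }
  list(group = group, auc = best)
}

# All permutations of 1..n (n small).
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Population AUC of a single biallelic locus under the logistic model,
# by direct enumeration of the three genotype groups.
expected_locus_auc <- function(maf, beta0, beta) {
  q <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  pcase <- stats::plogis(beta0 + beta * (0:2))
  cdist <- q * pcase / sum(q * pcase)
  ddist <- q * (1 - pcase) / sum(q * (1 - pcase))
  ord <- order(cdist / ddist)
  ordered_group_auc(cdist, ddist, ord)
}

# Random genotype dataset with no phenotype association.
rand_data <- function(n = 40, v = 5, seed = NULL, p = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rbinom(n * v, 2, p), n, v)
  genotype_data(g, status = rep(c(1, 0), length.out = n))
}

# Dataset built from explicit genotype columns (one vector per variant).
make_data <- function(status, ...) {
  cols <- list(...)
  genotype_data(do.call(cbind, cols), status = status,
                variant_ids = names(cols))
}
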