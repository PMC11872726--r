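make_usage <- function(values, genes = "g1") {
  matrix(values, ncol = length(genes),
         dimnames = list(sprintf("S%02d", seq_len(length(values) /
                                                    length(genes))), genes))
}

test_that("Mann-Whitney usage tests apply Bonferroni and report effect sizes", {
  meta <- tibble::tibble(subject_id = sprintf("S%02d", 1:10),
                         group = rep(c("A", "B"), each = 5))
  u <- make_usage(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  res <- mannwhitney_usage(u, meta, list(c("A", "B")))
  expect_equal(res$p_raw, 1)  # identical samples carry no evidence

  u2 <- make_usage(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  res2 <- mannwhitney_usage(u2, meta, list(c("A", "B")), m_tests = 2)
  expect_equal(res2$p_adjusted, min(1, 2 * res2$p_raw))
  expect_equal(res2$effect_size,
               cohens_d(u2[1:5, 1], u2[6:10, 1]))
  # Bonferroni caps at 1
  res3 <- mannwhitney_usage(u, meta, list(c("A", "B")), m_tests = 50)
  expect_equal(res3$p_adjusted, 1)
  expect_error(mannwhitney_usage(u2, meta[-(1:4), ], list(c("A", "B"))),
               ">= 2 subjects")
})

test_that("Mann-Whitney p-values are invariant under monotone transforms", {
  set.seed(61)
  x <- rnorm(12)
  y <- rnorm(15, 0.5)
  meta <- tibble::tibble(subject_id = sprintf("S%02d", 1:27),
                         group = rep(c("A", "B"), c(12, 15)))
  p1 <- mannwhitney_usage(make_usage(c(x, y)), meta, list(c("A", "B")))$p_raw
  p2 <- mannwhitney_usage(make_usage(exp(c(x, y))), meta,
                          list(c("A", "B")))$p_raw
  expect_equal(p1, p2)
})

test_that("Kruskal-Wallis omnibus plus Dunn's z and Holm-Sidak q-values", {
  set.seed(62)
  values <- c(rnorm(10), rnorm(10), rnorm(10, 3))
  groups <- rep(c("a", "b", "c"), each = 10)
  res <- kruskal_dunn(values, groups)
  expect_equal(res$omnibus$statistic,
               unname(stats::kruskal.test(values, factor(groups))$statistic))
  expect_equal(nrow(res$pairwise), 3L)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw - 1e-12))
  # the shifted group separates from both others
  shifted <- grepl("c", res$pairwise$comparison)
  expect_true(all(res$pairwise$p_adjusted[shifted] < 0.01))
  expect_error(kruskal_dunn(values[1:20], groups[1:20]), "3 groups")
})

test_that("Dunn's z reduces to the exact pooled-rank formula without ties", {
  set.seed(63)
  values <- sample(1:30)  # no ties
  groups <- rep(c("a", "b", "c"), each = 10)
  res <- kruskal_dunn(values, groups)
  r <- rank(values)
  z_ab <- (mean(r[groups == "a"]) - mean(r[groups == "b"])) /
    sqrt(30 * 31 / 12 * (1 / 10 + 1 / 10))
  expect_equal(res$pairwise$z[res$pairwise$comparison == "a vs b"], z_ab)
})

test_that("Holm-Sidak is the step-down Sidak transform with monotone repair", {
  q <- holm_sidak(c(0.01, 0.2, 0.8))
  expect_equal(q[1], 1 - (1 - 0.01)^3, tolerance = 1e-12)
  expect_equal(q[2], 1 - (1 - 0.2)^2, tolerance = 1e-12)
  expect_equal(q[3], 1 - (1 - 0.8)^1, tolerance = 1e-12)
  expect_equal(holm_sidak(c(0.01, 0.2, 0.35))[3],
               1 - (1 - 0.2)^2, tolerance = 1e-12)  # cummax repair kicks in
  expect_true(all(diff(sort(q)) >= 0))
  expect_true(all(holm_sidak(c(0.9, 0.99, 0.5)) <= 1))
  # order is preserved relative to the input
  p <- c(0.5, 0.001, 0.2)
  expect_equal(order(holm_sidak(p))[1], 2L)
})

test_that("Cohen's d uses the pooled n-1 standard deviation", {
  set.seed(64)
  a <- rnorm(20, 1, 1)
  b <- rnorm(25, 0, 1)
  sp <- sqrt((19 * var(a) + 24 * var(b)) / 43)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_equal(cohens_d(a, a), 0)
  expect_error(cohens_d(a, 1), ">= 2")
  expect_error(cohens_d(rep(1, 5), rep(1, 6)), "zero pooled")
})

test_that("standardized-shift recovery at the study's group sizes", {
  # location shift of 0.70 pooled SDs on normal samples, n = 25 vs 21
  set.seed(65)
  est <- replicate(500, cohens_d(rnorm(25, 0.70), rnorm(21)))
  expect_lt(abs(mean(est) - 0.70), 0.05)
})

test_that("median usage correlation is R-squared of per-gene group medians", {
  set.seed(66)
  n_genes <- 12
  base <- runif(n_genes, 0.01, 0.2)
  usage <- t(replicate(20, base + rnorm(n_genes, 0, 0.002)))
  colnames(usage) <- sprintf("g%02d", seq_len(n_genes))
  rownames(usage) <- sprintf("S%02d", 1:20)
  meta <- tibble::tibble(subject_id = rownames(usage),
                         group = rep(c("A", "B"), each = 10))
  r2 <- median_usage_correlation(usage, meta, "A", "B")
  ma <- apply(usage[1:10, ], 2, median)
  mb <- apply(usage[11:20, ], 2, median)
  expect_equal(r2, cor(ma, mb)^2)
  expect_gt(r2, 0.95)
  # identical groups give exactly 1
  usage2 <- rbind(usage[1:10, ], usage[1:10, ])
  rownames(usage2) <- rownames(usage)
  expect_equal(median_usage_correlation(usage2, meta, "A", "B"), 1)
  flat <- usage
  flat[11:20, ] <- 0.05
  expect_error(median_usage_correlation(flat, meta, "A", "B"),
               "zero variance")
})

test_that("median correlation of independent usage vectors is near zero", {
  set.seed(67)
  small <- replicate(40, {
    u <- matrix(runif(20 * 50), 20, 50,
                dimnames = list(sprintf("S%02d", 1:20),
                                sprintf("g%02d", 1:50)))
    meta <- tibble::tibble(subject_id = rownames(u),
                           group = rep(c("A", "B"), each = 10))
    median_usage_correlation(u, meta, "A", "B") < 0.2
  })
  expect_gte(mean(small), 0.95)
})

test_that("PCA standardizes, fixes signs and matches an eigendecomposition", {
  set.seed(68)
  x <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("f", 1:6)))
  res <- pca_features(x)
  expect_equal(sum(res$explained_variance), 1)
  ev <- eigen(cor(x))$values
  expect_equal(res$explained_variance, ev / sum(ev), tolerance = 1e-10)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (k in seq_len(ncol(res$loadings))) {
    expect_gt(res$loadings[which.max(abs(res$loadings[, k])), k], 0)
  }
  # two perfectly correlated features -> one component carries everything
  y <- cbind(a = rnorm(15), b = 0)
  y[, "b"] <- 2 * y[, "a"]
  res2 <- pca_features(y)
  expect_equal(res2$explained_variance[1], 1)
  # constant features are dropped with a warning
  z <- cbind(x, const = 1)
  expect_warning(res3 <- pca_features(z), "const")
  expect_equal(ncol(res3$loadings), 6L)
  # full-rank scores back-project to the standardized data
  zs <- scale(x)
  expect_equal(res$scores %*% t(res$loadings), zs, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("stratified split preserves label proportions and partitions", {
  set.seed(69)
  subj <- sprintf("S%02d", 1:20)
  labs <- rep(c("case", "ctrl"), each = 10)
  sp <- stratified_split(subj, labs, 0.6)
  expect_equal(length(sp$train), 12L)
  expect_equal(sum(labs[match(sp$train, subj)] == "case"), 6L)
  expect_setequal(c(sp$train, sp$test), subj)
  expect_equal(length(intersect(sp$train, sp$test)), 0L)
  # every size combination keeps per-label train counts within one subject
  # of the exact fraction
  for (na in seq(4, 50, by = 3)) {
    for (nb in seq(4, 50, by = 3)) {
      s <- sprintf("X%03d", seq_len(na + nb))
      l <- rep(c("a", "b"), c(na, nb))
      sp <- stratified_split(s, l, 0.6)
      n_tr <- table(l[match(sp$train, s)])
      expect_lte(abs(n_tr[["a"]] - 0.6 * na), 1)
      expect_lte(abs(n_tr[["b"]] - 0.6 * nb), 1)
      expect_setequal(c(sp$train, sp$test), s)
    }
  }
  expect_error(stratified_split(subj[1:11], rep(c("a", "b"), c(10, 1))),
               ">= 2")
})

test_that("logistic fit matches an independent IRLS oracle", {
  set.seed(70)
  X <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(30, 1, plogis(0.3 + X %*% c(0.8, -0.5, 0.2)))
  fit <- fit_logistic(X, y)
  expect_false(fit$separation)
  expect_equal(unname(fit$coefficients), unname(oracle_irls(X, y)),
               tolerance = 1e-6)
  expect_error(fit_logistic(cbind(X, k = 1), y), "constant")
  expect_error(fit_logistic(X[1:3, ], y[1:3]), "more training subjects")
})

test_that("separable data trigger the flagged ridge fallback", {
  x <- matrix(c(-(10:1), 1:10), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c(0, 1), each = 10)
  expect_message(fit <- fit_logistic(x, y), "separation")
  expect_true(fit$separation)
  expect_gt(fit$ridge_used, 0)
  expect_gt(fit$coefficients[["f"]], 0)  # direction recovered
  scores <- plogis(cbind(1, x) %*% fit$coefficients)
  expect_equal(roc_auc(drop(scores), y)$auc, 1)
})

test_that("null-feature logistic fits give chance-level training AUC", {
  set.seed(71)
  X <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, 0.5)
  fit <- fit_logistic(X, y)
  auc <- roc_auc(drop(plogis(cbind(1, X) %*% fit$coefficients)), y)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.65)
})

test_that("AUC is the tie-aware pairwise comparison probability", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(1, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  set.seed(72)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    scores <- sample(1:10, n, replace = TRUE)  # ties guaranteed
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  # invariance under strictly increasing transforms
  sc <- rnorm(30)
  lb <- rbinom(30, 1, 0.5) == 1
  expect_equal(roc_auc(sc, lb)$auc, roc_auc(exp(sc), lb)$auc)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("the ROC curve starts at (0,0), ends at (1,1) and matches pROC", {
  set.seed(73)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.5) == 1
  res <- roc_auc(scores, labels)
  expect_equal(unlist(res$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(res$curve[nrow(res$curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  ref <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
  expect_equal(res$auc, as.numeric(pROC::auc(ref)))
})

test_that("the classifier experiment is deterministic and honest about splits", {
  set.seed(74)
  base <- base_gene_frequencies("v")
  subjects <- sprintf("S%02d", 1:40)
  usage_v <- t(replicate(40, sample_subject_usage(base, 150)))
  rownames(usage_v) <- subjects
  usage_d <- t(replicate(40, sample_subject_usage(base_gene_frequencies("d"),
                                                  150)))
  usage_j <- t(replicate(40, sample_subject_usage(base_gene_frequencies("j"),
                                                  150)))
  rownames(usage_d) <- rownames(usage_j) <- subjects
  meta <- tibble::tibble(subject_id = subjects,
                         group = rep(c("ME_mm", "HC"), each = 20))
  rep1 <- run_classifier_experiment(list(v = usage_v, d = usage_d,
                                         j = usage_j),
                                    meta, "ME_mm", "HC", seed = 5L)
  rep2 <- run_classifier_experiment(list(v = usage_v, d = usage_d,
                                         j = usage_j),
                                    meta, "ME_mm", "HC", seed = 5L)
  expect_identical(rep1$train_ids, rep2$train_ids)
  expect_identical(rep1$auc_test, rep2$auc_test)
  expect_equal(length(intersect(rep1$train_ids, rep1$test_ids)), 0L)
  expect_setequal(c(rep1$train_ids, rep1$test_ids), subjects)
  expect_equal(length(rep1$features), 6L)
})

test_that("classifier AUC reflects planted multi-gene signal and its absence", {
  set.seed(75)
  feats <- classifier_features()
  null_auc <- numeric(60)
  sig_auc <- numeric(60)
  for (i in 1:60) {
    x <- matrix(abs(rnorm(60 * 6, 0.05, 0.01)), 60, 6,
                dimnames = list(sprintf("S%02d", 1:60), feats))
    meta <- tibble::tibble(subject_id = rownames(x),
                           group = rep(c("ME_mm", "HC"), each = 30))
    null_auc[i] <- suppressMessages(
      run_classifier_experiment(list(v = x), meta, "ME_mm",
                                "HC", seed = i))$auc_test
    x2 <- x
    x2[1:30, ] <- x2[1:30, ] + 2 * 0.01  # 2 SD shift on every feature
    sig_auc[i] <- suppressMessages(
      run_classifier_experiment(list(v = x2), meta, "ME_mm",
                                "HC", seed = i))$auc_test
  }
  expect_gte(mean(null_auc >= 0.3 & null_auc <= 0.7), 0.75)
  expect_gte(mean(sig_auc > 0.9), 0.9)
  expect_gt(mean(sig_auc), mean(null_auc))
})
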