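#' Mann-Whitney U tests of gene usage between groups
#'
#' Two-sided Mann-Whitney U tests comparing per-subject usage of each gene
#' between group pairs, with Bonferroni correction. The exact null
#' distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. The Bonferroni family size defaults to the
#' number of (gene, comparison) tests in the call and can be overridden —
#' e.g. `m_tests = 2` for the targeted two-comparisons-per-gene
#' replication design.
#'
#' @param usage Gene-usage matrix from [gene_usage_matrix()].
#' @param metadata Tibble with `subject_id`, `group`.
#' @param comparisons List of length-2 character vectors of group labels.
#' @param genes Genes to test (default: all columns).
#' @param m_tests Bonferroni family size; `NULL` means the number of tests
#'   performed in this call.
#' @return Tibble: gene, comparison, statistic (U), p_raw, p_adjusted,
#'   method, effect_size (Cohen's d, first group minus second).
#' @export
mannwhitney_usage <- function(usage, metadata, comparisons,
                              genes = colnames(usage), m_tests = NULL) {
  rows <- list()
  for (cmp in comparisons) {
    ids_a <- intersect(metadata$subject_id[metadata$group == cmp[1]],
                       rownames(usage))
    ids_b <- intersect(metadata$subject_id[metadata$group == cmp[2]],
                       rownames(usage))
    if (length(ids_a) < 2 || length(ids_b) < 2) {
      stop("comparison ", cmp[1], " vs ", cmp[2],
           ": both groups need >= 2 subjects", call. = FALSE)
    }
    for (g in genes) {
      x <- usage[ids_a, g]
      y <- usage[ids_b, g]
      res <- .mann_whitney(x, y)
      d <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, comparison = paste(cmp[1], "vs", cmp[2]),
        statistic = res$statistic, p_raw = res$p)
      rows[[length(rows)]]$effect_size <- d
    }
  }
  out <- dplyr::bind_rows(rows)
  m <- if (is.null(m_tests)) nrow(out) else m_tests
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out$method <- sprintf("bonferroni (m = %d)", as.integer(m))
  out[, c("gene", "comparison", "statistic", "p_raw", "p_adjusted",
          "method", "effect_size")]
}

.mann_whitney <- function(x, y) {
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' The omnibus Kruskal-Wallis H test (tie-corrected) across three or more
#' groups, followed by Dunn's z tests on the pooled ranks for every group
#' pair, reported with raw p-values and Holm-Sidak step-down adjusted
#' q-values.
#'
#' @param values Numeric vector of per-subject measurements.
#' @param groups Group label for each value (>= 3 distinct groups, each
#'   with >= 2 values).
#' @return List with `omnibus` (tibble: statistic, df, p) and `pairwise`
#'   (tibble: comparison, z, p_raw, p_adjusted).
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.character(groups)
  labs <- unique(groups)
  if (length(labs) < 3) {
    stop("kruskal_dunn needs >= 3 groups; use mannwhitney_usage for two",
         call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("every group needs >= 2 values", call. = FALSE)
  }
  kw <- stats::kruskal.test(values, factor(groups))
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- table(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  var_base <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  z <- vapply(pairs, function(pr) {
    (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(var_base * (1 / ni[[pr[1]]] + 1 / ni[[pr[2]]]))
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  list(
    omnibus = tibble::tibble(statistic = unname(kw$statistic),
                             df = unname(kw$parameter),
                             p = kw$p.value),
    pairwise = tibble::tibble(
      comparison = vapply(pairs, paste, character(1), collapse = " vs "),
      z = z, p_raw = p, p_adjusted = holm_sidak(p)))
}

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Orders the m raw p-values ascending, applies the Sidak transform
#' `1 - (1 - p_(i))^(m - i + 1)` and enforces step-down monotonicity via a
#' running maximum; results are returned in the input order, capped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted q-values, same order as `p`.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  q <- pmin(1, cummax(q))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Cohen's d standardized mean difference
#'
#' `(mean(a) - mean(b)) / s_pooled`, with the pooled standard deviation
#' `sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric samples of >= 2 values each.
#' @return Signed effect size.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) {
    stop("cohens_d: both samples need >= 2 values", call. = FALSE)
  }
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("cohens_d: zero pooled standard deviation", call. = FALSE)
  (mean(a) - mean(b)) / sp
}

#' Between-group correlation of median gene usage
#'
#' Computes each gene's median usage within two groups and returns the
#' squared Pearson correlation of the two median vectors — the statistic
#' used to show that overall V-gene usage profiles are conserved across
#' disease groups.
#'
#' @param usage Gene-usage matrix from [gene_usage_matrix()].
#' @param metadata Tibble with `subject_id`, `group`.
#' @param group_a,group_b Group labels.
#' @return R-squared (scalar).
#' @export
median_usage_correlation <- function(usage, metadata, group_a, group_b) {
  if (ncol(usage) < 3) {
    stop("median_usage_correlation needs >= 3 shared genes", call. = FALSE)
  }
  ids_a <- intersect(metadata$subject_id[metadata$group == group_a],
                     rownames(usage))
  ids_b <- intersect(metadata$subject_id[metadata$group == group_b],
                     rownames(usage))
  med_a <- apply(usage[ids_a, , drop = FALSE], 2, stats::median)
  med_b <- apply(usage[ids_b, , drop = FALSE], 2, stats::median)
  if (stats::sd(med_a) == 0 || stats::sd(med_b) == 0) {
    stop("median usage vector has zero variance", call. = FALSE)
  }
  stats::cor(med_a, med_b)^2
}

#' Principal component analysis of standardized features
#'
#' Features are standardized (zero mean, unit variance) before the
#' decomposition; constant features are dropped with a warning. Component
#' signs follow a deterministic convention: the largest-magnitude loading
#' of each component is made positive.
#'
#' @param x Numeric matrix or data frame, subjects x features.
#' @return List with `scores`, `loadings`, `explained_variance` (fractions
#'   summing to 1), and `dropped` (names of constant features).
#' @export
pca_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("pca_features needs >= 2 subjects and >= 2 features", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2), dropped = dropped)
}

#' Stratified train/test split of subjects
#'
#' Splits subjects into a training and a test set with each label
#' represented in (as close as possible to) the same proportions as the
#' full cohort. Per label, the training allocation is
#' round-half-to-even(label count x `train_frac`), then repaired one
#' subject at a time (largest fractional remainder first) so the total
#' training size matches round(total x `train_frac`); every label keeps at
#' least one subject on each side.
#'
#' @param subjects Character vector of subject ids.
#' @param labels Label per subject.
#' @param train_frac Training fraction (default 0.6).
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
stratified_split <- function(subjects, labels, train_frac = 0.6) {
  labels <- as.character(labels)
  cnt <- table(labels)
  if (any(cnt < 2)) {
    stop("every label needs >= 2 subjects to split", call. = FALSE)
  }
  raw <- cnt * train_frac
  n_tr <- round(raw)  # round half to even
  n_tr <- pmin(pmax(n_tr, 1), cnt - 1)
  target <- round(length(subjects) * train_frac)
  resid <- raw - n_tr
  while (sum(n_tr) != target) {
    if (sum(n_tr) < target) {
      cand <- which(n_tr < cnt - 1)
      if (!length(cand)) break
      i <- cand[which.max(resid[cand])]
      n_tr[i] <- n_tr[i] + 1
    } else {
      cand <- which(n_tr > 1)
      if (!length(cand)) break
      i <- cand[which.min(resid[cand])]
      n_tr[i] <- n_tr[i] - 1
    }
    resid <- raw - n_tr
  }
  train <- character(0)
  for (lab in names(cnt)) {
    ids <- sample(subjects[labels == lab])
    train <- c(train, ids[seq_len(n_tr[[lab]])])
  }
  list(train = train, test = setdiff(subjects, train))
}

#' Maximum-likelihood logistic regression with separation fallback
#'
#' Fits an unregularized binomial GLM (intercept included). When the data
#' are perfectly or quasi-perfectly separable — fitted probabilities pinned
#' at 0/1 or a non-converged fit — the fit is flagged and refitted with a
#' small ridge penalty on the slopes via penalized iteratively reweighted
#' least squares, and a message is logged.
#'
#' @param x Numeric feature matrix (no constant columns).
#' @param y Logical or 0/1 response.
#' @param ridge Ridge penalty used on fallback (default 1e-4).
#' @return List with `coefficients` (named, intercept first), `converged`,
#'   `separation`, `ridge_used`.
#' @export
fit_logistic <- function(x, y, ridge = 1e-4) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) <= ncol(x)) {
    stop("fit_logistic: need more training subjects than features",
         call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("fit_logistic: constant feature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                   family = stats::binomial()))
  mu <- fit$fitted.values
  separation <- !fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8)
  if (!separation) {
    return(list(coefficients = stats::setNames(fit$coefficients,
                                               c("(Intercept)",
                                                 colnames(x))),
                converged = fit$converged, separation = FALSE,
                ridge_used = 0))
  }
  message("fit_logistic: separation detected; refitting with ridge = ",
          ridge)
  beta <- .irls_ridge(cbind(1, x), y, ridge)
  list(coefficients = stats::setNames(beta,
                                      c("(Intercept)", colnames(x))),
       converged = TRUE, separation = TRUE, ridge_used = ridge)
}

# penalized IRLS; the intercept is not penalized
.irls_ridge <- function(X, y, lambda, max_iter = 200, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    new_beta <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new_beta - beta)) < tol) {
      beta <- drop(new_beta)
      break
    }
    beta <- drop(new_beta)
  }
  beta
}

#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney U statistic of the scores: the
#' probability that a random case outranks a random control, counting ties
#' as one half. The curve lists (FPR, TPR) at every distinct score
#' threshold, anchored at (0,0) and (1,1).
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Logical (or 0/1) case indicator; both classes required.
#' @return List with `auc` and `curve` (tibble: threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n0, numeric(1))
  curve <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                          tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1) {
    curve <- rbind(curve, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(auc = auc, curve = curve)
}
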