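#' Default gene-usage classifier features
#'
#' The six V, D and J gene-usage features previously reported to separate
#' ME/CFS cases from healthy controls: IGHV3-30, IGHV3-30-3, IGHV3-49,
#' IGHV1-3, IGHD1-26 and IGHJ6 usage.
#'
#' @return Character vector of six gene names.
#' @export
classifier_features <- function() {
  c("IGHV3-30", "IGHV3-30-3", "IGHV3-49", "IGHV1-3", "IGHD1-26", "IGHJ6")
}

#' Assemble a per-subject feature matrix from usage matrices
#'
#' Looks each feature gene up across the supplied segment usage matrices;
#' a gene absent from every matrix becomes a zero column (flagged
#' downstream as constant).
#'
#' @param usage_list Named list of gene-usage matrices (e.g.
#'   `list(v = ..., d = ..., j = ...)`) sharing row (subject) names.
#' @param features Gene names (default [classifier_features()]).
#' @return Numeric matrix, subjects x features.
#' @export
assemble_features <- function(usage_list, features = classifier_features()) {
  subjects <- rownames(usage_list[[1]])
  out <- matrix(0, nrow = length(subjects), ncol = length(features),
                dimnames = list(subjects, features))
  for (f in features) {
    for (u in usage_list) {
      if (f %in% colnames(u)) {
        out[, f] <- u[subjects, f]
        break
      }
    }
  }
  out
}

#' Case/control classification experiment on gene-usage features
#'
#' Reproduces the repertoire-feature classification protocol: assemble the
#' six gene-usage features, split case and control subjects 60/40 with
#' stratification by group, fit a multivariate logistic regression on the
#' training set (features enter unscaled; usage proportions are already
#' commensurate), and evaluate ROC curves and AUCs on both sets.
#'
#' @param usage_list Named list of segment usage matrices
#'   (`list(v = , d = , j = )`).
#' @param metadata Tibble with `subject_id`, `group`.
#' @param case_group,control_group Group labels.
#' @param features Feature genes (default [classifier_features()]).
#' @param train_frac Training fraction (default 0.6).
#' @param seed Integer seed controlling the split (`NULL` = current RNG
#'   state).
#' @return A `classifier_report` list: features, coefficients, train_ids,
#'   test_ids, auc_train, auc_test, roc_train, roc_test, separation,
#'   case_group, control_group, seed.
#' @export
run_classifier_experiment <- function(usage_list, metadata, case_group,
                                      control_group,
                                      features = classifier_features(),
                                      train_frac = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- metadata$group %in% c(case_group, control_group)
  meta <- metadata[keep, ]
  meta <- meta[meta$subject_id %in% rownames(usage_list[[1]]), ]
  x_all <- assemble_features(usage_list, features)[meta$subject_id, ,
                                                   drop = FALSE]
  # constant features carry no information and break the GLM; drop here
  sds <- apply(x_all, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x_all)[sds == 0], collapse = ", "),
            call. = FALSE)
    x_all <- x_all[, sds > 0, drop = FALSE]
  }
  y_all <- meta$group == case_group
  split <- stratified_split(meta$subject_id, meta$group, train_frac)
  tr <- meta$subject_id %in% split$train
  fit <- fit_logistic(x_all[tr, , drop = FALSE], y_all[tr])
  score <- function(idx) {
    stats::plogis(drop(cbind(1, x_all[idx, , drop = FALSE]) %*%
                         fit$coefficients))
  }
  roc_tr <- roc_auc(score(tr), y_all[tr])
  roc_te <- roc_auc(score(!tr), y_all[!tr])
  structure(list(
    features = colnames(x_all),
    coefficients = fit$coefficients,
    train_ids = sort(split$train), test_ids = sort(split$test),
    auc_train = roc_tr$auc, auc_test = roc_te$auc,
    roc_train = roc_tr$curve, roc_test = roc_te$curve,
    separation = fit$separation, ridge_used = fit$ridge_used,
    case_group = case_group, control_group = control_group,
    seed = seed), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Gene-usage logistic classifier:", x$case_group, "vs",
      x$control_group, "\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  train: %d subjects, AUC = %.3f\n",
              length(x$train_ids), x$auc_train))
  cat(sprintf("  test:  %d subjects, AUC = %.3f\n",
              length(x$test_ids), x$auc_test))
  if (x$separation) cat("  note: separation detected; ridge =",
                        x$ridge_used, "\n")
  invisible(x)
}
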