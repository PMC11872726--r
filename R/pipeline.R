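#' Run the full repertoire analysis pipeline
#'
#' End-to-end analysis of a cohort, either simulated from a
#' [simulation_config()] or loaded from AIRR files: quality filtering
#' (productive records, 1,500-UMI depth threshold, aberrant-repertoire
#' diagnostic), rarefied Gini/Shannon diversity, cross-subject clonotype
#' clustering, gene-usage matrices and repertoire features, between-group
#' usage tests with Bonferroni correction, Kruskal-Wallis + Dunn tests of
#' diversity and isotype composition, median-usage correlations, and the
#' six-feature case/control classifier. All stage outputs are written
#' under `out_dir` as plain-text tables and the assembled results are
#' returned.
#'
#' The run is deterministic given `seed` (which also seeds the simulator
#' when `config` is used).
#'
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param config [simulation_config()] describing a simulated cohort;
#'   ignored when `airr_path` is given.
#' @param airr_path,metadata_path Optional paths to an existing AIRR TSV
#'   and metadata TSV.
#' @param seed Integer seed for the whole run.
#' @param min_umis Depth threshold (default 1500).
#' @param diversity_subsample,diversity_iterations Rarefaction parameters
#'   (defaults 1000 and 1000).
#' @param clonotype_threshold Clonotype distance cut (default 0.15).
#' @param comparisons Group comparisons for usage testing (default: each
#'   non-HC group vs HC).
#' @param case_group,control_group Classifier groups (defaults "ME_mm" and
#'   "HC").
#' @return List with elements `qc`, `aberrant`, `diversity`, `clonotypes`,
#'   `usage` (list v/d/j), `features`, `isotypes`, `usage_tests`,
#'   `diversity_tests`, `isotype_tests`, `usage_correlations`,
#'   `classifier`, plus `records`, `metadata` and (for simulated cohorts)
#'   `ledger`.
#' @export
run_repertoire_pipeline <- function(out_dir = NULL,
                                    config = simulation_config(),
                                    airr_path = NULL, metadata_path = NULL,
                                    seed = 1L, min_umis = 1500L,
                                    diversity_subsample = 1000L,
                                    diversity_iterations = 1000L,
                                    clonotype_threshold = 0.15,
                                    comparisons = NULL,
                                    case_group = "ME_mm",
                                    control_group = "HC") {
  set.seed(seed)
  ledger <- NULL
  if (!is.null(airr_path)) {
    records <- read_airr(airr_path)
    metadata <- read_metadata(metadata_path)
  } else {
    config$seed <- as.integer(seed)
    sim <- simulate_cohort(config)
    records <- sim$records
    metadata <- sim$metadata
    ledger <- sim$ledger
  }

  prod <- filter_productive(records)
  qc <- apply_depth_threshold(prod, metadata, min_umis = min_umis)
  kept <- qc$records
  kept_meta <- metadata[metadata$subject_id %in% unique(kept$subject_id), ]
  aberrant <- flag_aberrant_repertoires(kept)

  diversity <- diversity_profile(kept, kept_meta,
                                 subsample_size = diversity_subsample,
                                 iterations = diversity_iterations)
  comp_bins <- dplyr::bind_rows(lapply(kept_meta$subject_id, function(sid) {
    b <- composition_bins(kept[kept$subject_id == sid, ])
    tibble::tibble(subject_id = sid, bin = names(b), proportion = unname(b))
  }))

  clustered <- cluster_clonotypes(kept, threshold = clonotype_threshold)
  ctab <- clonotype_table(clustered)

  usage <- list(v = gene_usage_matrix(kept, kept_meta, "v"),
                d = gene_usage_matrix(kept, kept_meta, "d"),
                j = gene_usage_matrix(kept, kept_meta, "j"))
  feats <- repertoire_features(kept, kept_meta)
  isotypes <- isotype_table(kept, kept_meta)

  grp_labels <- unique(kept_meta$group)
  if (is.null(comparisons)) {
    comparisons <- lapply(setdiff(grp_labels, control_group),
                          function(g) c(g, control_group))
  }
  usage_tests <- mannwhitney_usage(usage$v, kept_meta, comparisons)
  diversity_tests <- if (length(grp_labels) >= 3) {
    list(shannon = kruskal_dunn(diversity$shannon, diversity$group),
         gini = kruskal_dunn(diversity$gini, diversity$group))
  } else NULL
  isotype_tests <- if (length(grp_labels) >= 3) {
    kruskal_dunn(isotypes$IgM, isotypes$group)
  } else NULL
  usage_correlations <- dplyr::bind_rows(lapply(
    setdiff(grp_labels, control_group), function(g) {
      tibble::tibble(comparison = paste(g, "vs", control_group),
                     r_squared = median_usage_correlation(
                       usage$v, kept_meta, g, control_group))
    }))

  classifier <- run_classifier_experiment(usage, kept_meta, case_group,
                                          control_group, seed = seed)

  results <- list(records = records, metadata = metadata, ledger = ledger,
                  qc = qc$qc, aberrant = aberrant, diversity = diversity,
                  composition = comp_bins, clonotypes = ctab,
                  clustered_records = clustered, usage = usage,
                  features = feats, isotypes = isotypes,
                  usage_tests = usage_tests,
                  diversity_tests = diversity_tests,
                  isotype_tests = isotype_tests,
                  usage_correlations = usage_correlations,
                  classifier = classifier, seed = seed)
  if (!is.null(out_dir)) .write_pipeline_outputs(results, out_dir)
  invisible(results)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, name), progress = FALSE)
  }
  write_airr(res$records, file.path(out_dir, "cohort.tsv"))
  write_metadata(res$metadata, file.path(out_dir, "metadata.tsv"))
  w(res$qc, "qc_report.csv")
  w(res$aberrant, "aberrant_repertoires.csv")
  w(res$diversity, "diversity.csv")
  w(res$composition, "composition_bins.csv")
  w(res$clonotypes, "clonotypes.csv")
  for (seg in names(res$usage)) {
    u <- tibble::as_tibble(res$usage[[seg]], rownames = "subject_id")
    w(u, sprintf("usage_%s.csv", seg))
  }
  w(res$features$subject_summary, "features_summary.csv")
  w(res$isotypes, "isotype_proportions.csv")
  w(res$usage_tests, "usage_tests.csv")
  w(res$usage_correlations, "usage_correlations.csv")
  cls <- res$classifier
  w(tibble::tibble(term = names(cls$coefficients),
                   estimate = unname(cls$coefficients)),
    "classifier_coefficients.csv")
  w(tibble::tibble(set = c("train", "test"),
                   auc = c(cls$auc_train, cls$auc_test),
                   n_subjects = c(length(cls$train_ids),
                                  length(cls$test_ids))),
    "classifier_auc.csv")
  w(dplyr::bind_rows(
    dplyr::mutate(cls$roc_train, set = "train"),
    dplyr::mutate(cls$roc_test, set = "test")), "roc_points.csv")
  invisible(out_dir)
}
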