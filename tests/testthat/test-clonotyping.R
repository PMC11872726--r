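test_that("candidate partition separates V, J and CDR3 length and pools subjects", {
  rec <- dplyr::bind_rows(
    make_records(1, sequence_id = "a", subject_id = "S1",
                 v_call = "IGHV3-30*01", j_call = "IGHJ6*01",
                 junction_aa = "CARDYGMDVWATW"),
    make_records(1, sequence_id = "b", subject_id = "S2",
                 v_call = "IGHV3-30*02", j_call = "IGHJ6*02",
                 junction_aa = "CARDYGMDVWATW"),
    make_records(1, sequence_id = "c", subject_id = "S1",
                 v_call = "IGHV3-30*01", j_call = "IGHJ6*01",
                 junction_aa = "CARDYGMDVWATSW"))
  parts <- partition_candidates(rec)
  expect_equal(length(parts), 2L)
  # same key across subjects lands in one group (cross-subject clustering)
  expect_true(any(vapply(parts, length, integer(1)) == 2))
  expect_equal(unname(sort(unlist(parts))), 1:3)
  expect_equal(length(partition_candidates(make_records(0))), 0L)
})

test_that("normalized Hamming distance counts substitutions per residue", {
  expect_equal(normalized_hamming("CARDYW", "CARDYW"), 0)
  expect_equal(normalized_hamming("CARDYGMDVW", "CARDYGMDVF"), 0.10)
  expect_equal(normalized_hamming("CARDYW", "CARDFW"), 1 / 6)
  expect_gt(normalized_hamming("CARDYW", "CARDFW"), 0.15)
  expect_error(normalized_hamming("CARW", "CARDW"), "equal length")
})

test_that("single linkage chains near-identical CDR3s into one clonotype", {
  base <- "CARDYGMDVWAT"  # 12 aa
  a <- base
  b <- sub("Y", "F", base)            # d(a,b) = 1/12
  c <- sub("T$", "S", sub("Y", "F", base))  # d(b,c) = 1/12, d(a,c) = 2/12
  expect_equal(normalized_hamming(a, c), 2 / 12)
  rec <- make_records(3, junction_aa = c(a, b, c))
  cl <- cluster_clonotypes(rec, threshold = 0.15)
  expect_equal(length(unique(cl$clonotype_id)), 1L)
  # a tighter cut separates the chain ends
  cl2 <- cluster_clonotypes(rec, threshold = 0.05)
  expect_gt(length(unique(cl2$clonotype_id)), 1L)
  expect_error(cluster_clonotypes(rec, threshold = 0), "threshold")
  expect_error(cluster_clonotypes(rec, threshold = 1.2), "threshold")
})

test_that("clustering equals connected components of the threshold graph", {
  set.seed(41)
  for (trial in 1:20) {
    len <- sample(8:12, 1)
    junc <- random_junctions(sample(10:60, 1), len)
    rec <- make_records(length(junc), junction_aa = junc)
    cl <- cluster_clonotypes(rec, threshold = 0.15)
    uj <- unique(junc)
    memb <- oracle_components(uj, 0.15)
    expect_true(same_partition(
      partition_sets(rec$sequence_id, cl$clonotype_id),
      partition_sets(rec$sequence_id, memb[match(junc, uj)])))
  }
})

test_that("the clonotype partition is stable under row permutation", {
  set.seed(42)
  junc <- random_junctions(40, 9)
  rec <- make_records(40, junction_aa = junc,
                      v_call = sample(c("IGHV3-30*01", "IGHV1-2*01"), 40,
                                      replace = TRUE))
  cl1 <- cluster_clonotypes(rec, threshold = 0.15)
  perm <- sample(nrow(rec))
  cl2 <- cluster_clonotypes(rec[perm, ], threshold = 0.15)
  m1 <- stats::setNames(cl1$clonotype_id, cl1$sequence_id)
  m2 <- stats::setNames(cl2$clonotype_id, cl2$sequence_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("raising the threshold only merges clonotypes", {
  set.seed(43)
  junc <- random_junctions(60, 8)
  rec <- make_records(60, junction_aa = junc)
  lo <- cluster_clonotypes(rec, threshold = 0.10)$clonotype_id
  hi <- cluster_clonotypes(rec, threshold = 0.30)$clonotype_id
  # every low-threshold clonotype maps into exactly one high-threshold one
  expect_true(all(tapply(hi, lo, function(x) length(unique(x))) == 1))
})

test_that("high-usage subject selection applies the mean + k*SD rule strictly", {
  usage <- matrix(c(0.02, 0.02, 0.02, 0.030, 0.025),
                  ncol = 1, dimnames = list(paste0("S", 1:5), "IGHV3-30"))
  meta <- tibble::tibble(subject_id = paste0("S", 1:5),
                         group = c("HC", "HC", "HC", "ME", "ME"))
  # zero reference variance: anything above the mean is selected
  expect_equal(select_high_usage_subjects(usage, meta, "IGHV3-30",
                                          "ME", "HC"), c("S4", "S5"))
  usage2 <- usage
  usage2[1:3, 1] <- c(0.015, 0.020, 0.025)  # mean 0.02, sd 0.005
  expect_equal(select_high_usage_subjects(usage2, meta, "IGHV3-30",
                                          "ME", "HC"), "S4")
  usage3 <- usage2
  usage3["S4", 1] <- 0.025  # exactly mean + sd: strict > excludes it
  expect_equal(length(select_high_usage_subjects(usage3, meta, "IGHV3-30",
                                                 "ME", "HC")), 0L)
  expect_error(select_high_usage_subjects(usage, meta, "IGHV9-99",
                                          "ME", "HC"), "absent")
})

test_that("selection on a simulated cohort matches recomputation from the usage matrix", {
  sim <- simulate_cohort(simulation_config(
    group_sizes = c(HC = 10L, ME_mm = 10L), umi_range = c(600L, 900L),
    seed = 17L))
  prod <- filter_productive(sim$records)
  u <- gene_usage_matrix(prod, sim$metadata, "v")
  sel <- select_high_usage_subjects(u, sim$metadata, "IGHV3-30",
                                    "ME_mm", "HC")
  hc <- sim$metadata$subject_id[sim$metadata$group == "HC"]
  cases <- sim$metadata$subject_id[sim$metadata$group == "ME_mm"]
  cutoff <- mean(u[hc, "IGHV3-30"]) + stats::sd(u[hc, "IGHV3-30"])
  expect_setequal(sel, cases[u[cases, "IGHV3-30"] > cutoff])
})

test_that("matched subsampling conserves exact UMI totals and is seeded", {
  sim <- simulate_cohort(simulation_config(
    group_sizes = c(HC = 4L, ME_mm = 4L), umi_range = c(500L, 700L),
    seed = 19L))
  prod <- filter_productive(sim$records)
  set.seed(1)
  sub <- subsample_matched(prod, sim$metadata, n_subjects = 3L,
                           total_umis = 800L)
  umis <- tapply(sub$duplicate_count,
                 sim$metadata$group[match(sub$subject_id,
                                          sim$metadata$subject_id)], sum)
  expect_true(all(umis == 800L))
  set.seed(1)
  sub2 <- subsample_matched(prod, sim$metadata, n_subjects = 3L,
                            total_umis = 800L)
  expect_identical(sub, sub2)
  expect_error(subsample_matched(prod, sim$metadata, n_subjects = 9L,
                                 total_umis = 800L), "subjects")
  expect_error(subsample_matched(prod, sim$metadata, n_subjects = 3L,
                                 total_umis = 10L^7), "UMIs")
})

test_that("a group holding exactly the target UMIs is returned unchanged", {
  rec <- make_records(4, subject_id = "S1", duplicate_count = 25L)
  meta <- tibble::tibble(subject_id = "S1", group = "HC")
  out <- subsample_matched(rec, meta, n_subjects = 1L, total_umis = 100L)
  expect_identical(out, rec)
})

test_that("network edges are cliques below the cap and stars above it", {
  junc <- "CARDYGMDVW"
  rec3 <- make_records(3, junction_aa = junc)
  g3 <- build_network(cluster_clonotypes(rec3))
  expect_equal(igraph::vcount(g3), 3L)
  expect_equal(igraph::ecount(g3), 3L)  # 3 choose 2

  singles <- make_records(100, junction_aa = "CARDYGMDVW",
                          v_call = sprintf("IGHV%d-99*01", 1:100))
  gs <- build_network(cluster_clonotypes(singles))
  expect_equal(igraph::vcount(gs), 100L)
  expect_equal(igraph::ecount(gs), 0L)

  big <- make_records(60, junction_aa = junc,
                      duplicate_count = c(50L, rep(1L, 59)))
  gb <- build_network(cluster_clonotypes(big), edge_cap = 50L)
  expect_equal(igraph::ecount(gb), 59L)
  expect_true(all(igraph::E(gb)$star))
  expect_match(igraph::graph_attr(gb, "capped_clonotypes"), "CT")
  # the hub is the most abundant member
  deg <- igraph::degree(gb)
  expect_equal(names(which.max(deg)), "R001")
})

test_that("clonotype table reports sizes, spans and consensus CDR3", {
  rec <- dplyr::bind_rows(
    make_records(2, sequence_id = c("x1", "x2"),
                 subject_id = c("S1", "S2"),
                 junction_aa = "CARDYGMDVW", duplicate_count = c(5L, 2L)),
    make_records(1, sequence_id = "x3", subject_id = "S1",
                 junction_aa = "CARDYGMDVF", duplicate_count = 3L))
  cl <- cluster_clonotypes(rec, threshold = 0.15)
  tab <- clonotype_table(cl)
  expect_equal(nrow(tab), 1L)  # 1 substitution / 10 aa merges all
  expect_equal(tab$size, 10L)
  expect_equal(tab$n_subjects, 2L)
  expect_equal(tab$consensus_cdr3, "CARDYGMDVW")
  expect_error(clonotype_table(rec), "clonotype_id")
})
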