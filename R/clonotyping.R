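#' Partition records into clonotype candidate groups
#'
#' Clonotype clustering only ever compares sequences sharing the same
#' gene-level V call, J call and CDR3 amino-acid length, so records are
#' first partitioned by that key. The partition is disjoint and exhaustive
#' and pools records from all subjects, allowing shared clonotypes between
#' individuals to be found.
#'
#' @param records Productive rearrangement records with non-empty
#'   `junction_aa`.
#' @return Named list of record-index vectors, keyed by
#'   `"v_gene|j_gene|cdr3_length"`, keys sorted.
#' @export
partition_candidates <- function(records) {
  if (!nrow(records)) return(stats::setNames(list(), character(0)))
  key <- paste(strip_allele(records$v_call), strip_allele(records$j_call),
               nchar(records$junction_aa), sep = "|")
  idx <- split(seq_len(nrow(records)), key)
  idx[order(names(idx))]
}

#' Normalized substitution distance between two equal-length CDR3s
#'
#' The per-residue substitution distance used for clonotype clustering:
#' number of differing positions divided by the CDR3 length. Lengths are a
#' partition key, so insertions/deletions never arise and unequal lengths
#' are an error.
#'
#' @param a,b Equal-length amino-acid strings (vectorized elementwise).
#' @return Numeric distance(s) in `[0, 1]`.
#' @examples
#' normalized_hamming("CARDYGMDVW", "CARDYGMDVF")  # 0.10
#' @export
normalized_hamming <- function(a, b) {
  if (any(nchar(a) != nchar(b))) {
    stop("normalized_hamming: sequences must have equal length", call. = FALSE)
  }
  if (any(nchar(a) == 0)) {
    stop("normalized_hamming: empty sequence", call. = FALSE)
  }
  mapply(function(x, y) {
    sum(charToRaw(x) != charToRaw(y)) / nchar(x)
  }, a, b, USE.NAMES = FALSE)
}

# pairwise normalized Hamming distances among equal-length strings,
# as a dense matrix
.hamming_matrix <- function(strings) {
  n <- length(strings)
  L <- nchar(strings[1])
  chars <- matrix(unlist(strsplit(strings, "", fixed = TRUE)),
                  nrow = n, byrow = TRUE)
  d <- matrix(0L, n, n)
  for (j in seq_len(L)) {
    d <- d + outer(chars[, j], chars[, j], "!=")
  }
  d / L
}

#' Cluster records into clonotypes
#'
#' Within each (V gene, J gene, CDR3 length) partition group, unique CDR3
#' amino-acid sequences are clustered by single-linkage agglomeration on
#' the normalized substitution distance, cut at `threshold` (default 0.15
#' substitutions per residue). A single-linkage cut is exactly the set of
#' connected components of the graph joining pairs at distance <=
#' threshold, the standard clonotype semantics; chains of near-identical
#' CDR3s therefore merge even when their endpoints exceed the threshold.
#'
#' Clonotype ids are deterministic: groups are processed in sorted key
#' order and clusters within a group are numbered by their smallest member
#' `sequence_id`, so permuting the input rows never changes the partition
#' or the ids.
#'
#' @param records Productive rearrangement records.
#' @param threshold Maximum normalized substitution distance within a
#'   linked pair, in (0, 1].
#' @return `records` with a `clonotype_id` column added.
#' @export
cluster_clonotypes <- function(records, threshold = 0.15) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("configuration error: threshold must lie in (0, 1]", call. = FALSE)
  }
  records$clonotype_id <- NA_character_
  if (!nrow(records)) return(records)
  parts <- partition_candidates(records)
  ct <- 0L
  assignment <- integer(nrow(records))
  for (key in names(parts)) {
    idx <- parts[[key]]
    junc <- records$junction_aa[idx]
    uj <- unique(junc)
    if (length(uj) == 1L) {
      cl <- rep.int(1L, length(uj))
    } else {
      d <- .hamming_matrix(uj)
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      cl <- stats::cutree(hc, h = threshold)
    }
    memb <- cl[match(junc, uj)]
    # renumber clusters by smallest member sequence_id for determinism
    first_id <- tapply(records$sequence_id[idx], memb, min)
    rank <- match(names(first_id)[order(first_id)], names(first_id))
    remap <- integer(length(first_id))
    remap[as.integer(names(first_id))[order(first_id)]] <-
      seq_along(first_id)
    assignment[idx] <- ct + remap[memb]
    ct <- ct + length(first_id)
  }
  records$clonotype_id <- sprintf("CT%06d", assignment)
  records
}

#' Summarise clonotypes
#'
#' @param records Records carrying a `clonotype_id` column (from
#'   [cluster_clonotypes()]).
#' @return Tibble: clonotype_id, v_gene, j_gene, cdr3_length, size (UMIs),
#'   n_records, n_subjects, consensus_cdr3 (the most abundant member CDR3,
#'   lexicographic tie-break).
#' @export
clonotype_table <- function(records) {
  if (!"clonotype_id" %in% names(records)) {
    stop("records lack a clonotype_id column; run cluster_clonotypes()",
         call. = FALSE)
  }
  df <- tibble::tibble(clonotype_id = records$clonotype_id,
                       v_gene = strip_allele(records$v_call),
                       j_gene = strip_allele(records$j_call),
                       junction_aa = records$junction_aa,
                       subject_id = records$subject_id,
                       duplicate_count = records$duplicate_count)
  # consensus CDR3 = most abundant member junction, lexicographic tie-break
  ab <- dplyr::summarise(
    dplyr::group_by(df, .data$clonotype_id, .data$junction_aa),
    umis = sum(.data$duplicate_count), .groups = "drop")
  ab <- ab[order(ab$clonotype_id, -ab$umis, ab$junction_aa), ]
  cons <- ab[!duplicated(ab$clonotype_id), c("clonotype_id", "junction_aa")]
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$clonotype_id),
    v_gene = .data$v_gene[1],
    j_gene = .data$j_gene[1],
    cdr3_length = nchar(.data$junction_aa[1]),
    size = sum(.data$duplicate_count),
    n_records = dplyr::n(),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    .groups = "drop")
  out$consensus_cdr3 <- cons$junction_aa[match(out$clonotype_id,
                                               cons$clonotype_id)]
  out
}

#' Select case subjects with elevated usage of one gene
#'
#' Returns the case-group subjects whose usage of `gene` exceeds the
#' reference-group mean by more than `k` reference-group standard
#' deviations (sample SD, n-1 denominator; strict inequality). This is the
#' rule used to pick high-IGHV3-30 patients for the subset network
#' analysis.
#'
#' @param usage Gene-usage matrix (subjects x genes) from
#'   [gene_usage_matrix()].
#' @param metadata Tibble with `subject_id`, `group`.
#' @param gene Gene name (column of `usage`).
#' @param case_group,reference_group Group labels.
#' @param k Number of reference SDs above the reference mean (default 1).
#' @return Character vector of selected case subject ids.
#' @export
select_high_usage_subjects <- function(usage, metadata, gene, case_group,
                                       reference_group, k = 1) {
  if (!gene %in% colnames(usage)) {
    stop("gene '", gene, "' absent from the usage matrix", call. = FALSE)
  }
  ref_ids <- metadata$subject_id[metadata$group == reference_group]
  ref_ids <- intersect(ref_ids, rownames(usage))
  if (length(ref_ids) < 2) {
    stop("reference group needs >= 2 subjects with usage data", call. = FALSE)
  }
  case_ids <- intersect(metadata$subject_id[metadata$group == case_group],
                        rownames(usage))
  cutoff <- mean(usage[ref_ids, gene]) + k * stats::sd(usage[ref_ids, gene])
  case_ids[usage[case_ids, gene] > cutoff]
}

#' Depth-matched group subsets for network comparison
#'
#' For each group: keep `n_subjects` subjects (given explicitly or drawn at
#' random), then draw exactly `total_umis` UMIs without replacement from
#' the group's pooled records. Returned records carry resampled
#' `duplicate_count` values summing to `total_umis` per group; records
#' drawing zero UMIs are dropped.
#'
#' @param records Cohort rearrangement tibble (productive).
#' @param metadata Tibble with `subject_id`, `group`.
#' @param subjects Optional named list, group -> subject id vector; groups
#'   absent from the list have subjects drawn at random.
#' @param groups Groups to retain (default: all in `metadata`).
#' @param n_subjects Subjects kept per group (default 10).
#' @param total_umis UMIs drawn per group (default 5000).
#' @return Records restricted to the matched subsets.
#' @export
subsample_matched <- function(records, metadata, subjects = NULL,
                              groups = unique(metadata$group),
                              n_subjects = 10L, total_umis = 5000L) {
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    pool_subj <- metadata$subject_id[metadata$group == g]
    pool_subj <- intersect(pool_subj, unique(records$subject_id))
    chosen <- if (!is.null(subjects) && !is.null(subjects[[g]])) {
      subjects[[g]]
    } else {
      if (length(pool_subj) < n_subjects) {
        stop("group '", g, "' has ", length(pool_subj),
             " subjects; ", n_subjects, " required", call. = FALSE)
      }
      sample(pool_subj, n_subjects)
    }
    sub <- records[records$subject_id %in% chosen, , drop = FALSE]
    n_umis <- sum(sub$duplicate_count)
    if (n_umis < total_umis) {
      stop("group '", g, "' has ", n_umis, " UMIs after subsetting; ",
           total_umis, " required", call. = FALSE)
    }
    if (n_umis == total_umis) {
      out[[gi]] <- sub
    } else {
      expanded <- rep.int(seq_len(nrow(sub)), sub$duplicate_count)
      draw <- expanded[sample.int(n_umis, total_umis)]
      counts <- tabulate(draw, nbins = nrow(sub))
      keep <- counts > 0
      sub <- sub[keep, , drop = FALSE]
      sub$duplicate_count <- counts[keep]
      out[[gi]] <- sub
    }
  }
  dplyr::bind_rows(out)
}

#' Build a clonotype network
#'
#' One node per record; nodes of the same clonotype are connected — as a
#' clique when the clonotype has at most `edge_cap` members, otherwise as a
#' star centred on the most abundant member (highest `duplicate_count`,
#' smallest `sequence_id` on ties), flagged via the `star` edge attribute
#' and the graph attribute `capped_clonotypes`. Node attributes carry the
#' subject, constant-region call and mutation frequency used to colour
#' network renderings.
#'
#' @param records Records with a `clonotype_id` column.
#' @param edge_cap Maximum clonotype size rendered as a clique (default 50).
#' @return An `igraph` graph.
#' @export
build_network <- function(records, edge_cap = 50L) {
  if (!"clonotype_id" %in% names(records)) {
    stop("records lack a clonotype_id column; run cluster_clonotypes()",
         call. = FALSE)
  }
  mf <- mutation_frequency(records$sequence, records$germline_alignment)
  nodes <- data.frame(name = records$sequence_id,
                      subject = records$subject_id,
                      isotype = records$c_call,
                      clonotype = records$clonotype_id,
                      duplicate_count = records$duplicate_count,
                      mutation_frequency = mf,
                      stringsAsFactors = FALSE)
  split_rows <- split(seq_len(nrow(records)), records$clonotype_id)
  edges <- vector("list", length(split_rows))
  star_flag <- vector("list", length(split_rows))
  capped <- character(0)
  for (k in seq_along(split_rows)) {
    i <- split_rows[[k]]
    m <- length(i)
    if (m < 2) next
    ids <- records$sequence_id[i]
    if (m <= edge_cap) {
      pairs <- utils::combn(ids, 2)
      edges[[k]] <- pairs
      star_flag[[k]] <- rep(FALSE, ncol(pairs))
    } else {
      ord <- order(-records$duplicate_count[i], ids)
      hub <- ids[ord[1]]
      leaves <- setdiff(ids, hub)
      edges[[k]] <- rbind(rep(hub, length(leaves)), leaves)
      star_flag[[k]] <- rep(TRUE, length(leaves))
      capped <- c(capped, names(split_rows)[k])
    }
  }
  em <- do.call(cbind, edges[!vapply(edges, is.null, logical(1))])
  g <- igraph::graph_from_data_frame(
    d = if (is.null(em)) {
      data.frame(from = character(0), to = character(0),
                 star = logical(0))
    } else {
      data.frame(from = em[1, ], to = em[2, ],
                 star = unlist(star_flag), stringsAsFactors = FALSE)
    },
    directed = FALSE, vertices = nodes)
  g <- igraph::set_graph_attr(g, "capped_clonotypes",
                              paste(capped, collapse = ","))
  g
}

#' Export a clonotype network for external rendering
#'
#' Writes the graph as GraphML plus a plain-text edge list (TSV), the
#' formats consumed by Gephi-class network renderers.
#'
#' @param graph An `igraph` graph from [build_network()].
#' @param path_prefix Output path prefix; `<prefix>.graphml` and
#'   `<prefix>_edges.tsv` are written.
#' @return Invisibly, the GraphML path.
#' @export
export_network <- function(graph, path_prefix) {
  graphml <- paste0(path_prefix, ".graphml")
  igraph::write_graph(graph, graphml, format = "graphml")
  el <- igraph::as_data_frame(graph, what = "edges")
  readr::write_tsv(el, paste0(path_prefix, "_edges.tsv"), progress = FALSE)
  invisible(graphml)
}

#' High-usage subset network comparison
#'
#' Replicates the targeted subset analysis around elevated IGHV3-30 usage:
#' case-group subjects whose usage of `gene` exceeds the reference mean by
#' more than `k` reference SDs are selected, an equal number of reference
#' subjects is drawn at random, both subsets are restricted to records
#' using `gene` and depth-matched by drawing `total_umis` UMIs per group,
#' clonotypes are clustered across the pooled subsets, and per-group
#' networks plus per-subject summaries (clonotype-level Shannon entropy at
#' the matched depth, IgM proportion, mean mutation frequency) are
#' returned with Mann-Whitney comparisons between the groups.
#'
#' @param records Productive, QC-passing cohort records.
#' @param metadata Tibble with `subject_id`, `group`.
#' @param usage V-gene usage matrix from [gene_usage_matrix()].
#' @param gene Gene defining the subset (default "IGHV3-30").
#' @param case_group,reference_group Group labels.
#' @param k Reference-SD multiplier for the selection rule (default 1).
#' @param n_subjects Subjects per group (default 10); the case side uses
#'   the selected subjects (however many there are), the reference side
#'   draws this many at random.
#' @param total_umis UMIs drawn per group (default 5000).
#' @param subsample_size,iterations Rarefaction parameters for the
#'   clonotype-level diversity summaries.
#' @param threshold Clonotype distance cut (default 0.15).
#' @param edge_cap Clique cap for network construction (default 50).
#' @return List with `case_subjects`, `reference_subjects`, `records`
#'   (matched subset with clonotype ids), `networks` (igraph per group),
#'   `subject_summary` and `tests`.
#' @export
subset_network_analysis <- function(records, metadata, usage,
                                    gene = "IGHV3-30",
                                    case_group = "ME_mm",
                                    reference_group = "HC", k = 1,
                                    n_subjects = 10L, total_umis = 5000L,
                                    subsample_size = 1000L,
                                    iterations = 100L,
                                    threshold = 0.15, edge_cap = 50L) {
  high <- select_high_usage_subjects(usage, metadata, gene, case_group,
                                     reference_group, k)
  if (length(high) < 2) {
    stop("fewer than 2 high-usage case subjects selected", call. = FALSE)
  }
  gene_records <- records[strip_allele(records$v_call) == gene, ,
                          drop = FALSE]
  matched <- subsample_matched(
    gene_records, metadata,
    subjects = stats::setNames(list(high), case_group),
    groups = c(case_group, reference_group),
    n_subjects = n_subjects, total_umis = total_umis)
  ref_subjects <- unique(matched$subject_id[
    matched$subject_id %in% metadata$subject_id[
      metadata$group == reference_group]])
  clustered <- cluster_clonotypes(matched, threshold = threshold)
  networks <- list()
  for (g in c(case_group, reference_group)) {
    ids <- metadata$subject_id[metadata$group == g]
    networks[[g]] <- build_network(
      clustered[clustered$subject_id %in% ids, , drop = FALSE],
      edge_cap = edge_cap)
  }
  meta_sub <- metadata[metadata$subject_id %in% unique(clustered$subject_id), ]
  rows <- lapply(meta_sub$subject_id, function(sid) {
    rec <- clustered[clustered$subject_id == sid, , drop = FALSE]
    n_umis <- sum(rec$duplicate_count)
    div <- resampled_diversity(rec, unit = "clonotype",
                               subsample_size = min(subsample_size, n_umis),
                               iterations = iterations)
    tibble::tibble(
      subject_id = sid,
      group = meta_sub$group[match(sid, meta_sub$subject_id)],
      umis = n_umis,
      shannon = div$shannon,
      igm_fraction = isotype_proportions(rec)[["IgM"]],
      mean_mutation_frequency = stats::weighted.mean(
        mutation_frequency(rec$sequence, rec$germline_alignment),
        rec$duplicate_count))
  })
  summ <- dplyr::bind_rows(rows)
  test_one <- function(col) {
    x <- summ[[col]][summ$group == case_group]
    y <- summ[[col]][summ$group == reference_group]
    res <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
    tibble::tibble(feature = col, statistic = unname(res$statistic),
                   p = res$p.value)
  }
  tests <- dplyr::bind_rows(lapply(
    c("shannon", "igm_fraction", "mean_mutation_frequency"), test_one))
  list(case_subjects = high, reference_subjects = ref_subjects,
       records = clustered, networks = networks,
       subject_summary = summ, tests = tests)
}
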