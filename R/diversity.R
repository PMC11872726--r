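#' Gini index of a species abundance vector
#'
#' Clonality measure of a repertoire's clone-size distribution:
#' \deqn{G = \frac{\sum_{i=1}^{S} (2i - S - 1)\, P_{(i)}}{S \sum_i P_i}}
#' with proportions \eqn{P_{(i)}} sorted ascending and \eqn{S} the number of
#' species with non-zero count. G is 0 for a perfectly even repertoire and
#' approaches 1 ((S-1)/S) when a single clone dominates; it is invariant to
#' rescaling the counts and to species order.
#'
#' @param counts Non-negative numeric abundance vector (zero-count species
#'   are dropped).
#' @return Gini index in `[0, (S-1)/S]`.
#' @examples
#' gini_index(c(1, 1, 1, 1))  # 0
#' gini_index(c(3, 1))        # 0.25
#' @export
gini_index <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) {
    stop("gini_index: abundance vector has no positive counts", call. = FALSE)
  }
  s <- length(counts)
  p <- sort(counts / sum(counts))
  sum((2 * seq_len(s) - s - 1) * p) / s
}

#' Shannon entropy of a species abundance vector
#'
#' Diversity measure in nats: \eqn{H = -\sum_i P_i \ln P_i}, with
#' \eqn{0 \ln 0 = 0}. H is 0 for a single species and maximal at
#' \eqn{\ln S} for an even repertoire of S species.
#'
#' @inheritParams gini_index
#' @return Shannon entropy (nats), in `[0, ln S]`.
#' @examples
#' shannon_entropy(c(1, 1, 1, 1))  # log(4)
#' @export
shannon_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) {
    stop("shannon_entropy: abundance vector has no positive counts",
         call. = FALSE)
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Rarefied clonality and diversity of one repertoire
#'
#' Implements the fixed-depth resampling protocol that makes diversity
#' comparable across sequencing depths: each iteration draws
#' `subsample_size` UMIs without replacement (records expanded by
#' `duplicate_count`), tallies species abundances — unique CDR3 amino-acid
#' sequences, or clonotype ids when `unit = "clonotype"` — and computes the
#' Gini index and Shannon entropy; the across-iteration means are returned.
#'
#' @param records Rearrangement records of a single subject (productive,
#'   depth-passing).
#' @param unit `"cdr3"` (species = unique `junction_aa`) or `"clonotype"`
#'   (species = `clonotype_id`, which must be a column of `records`).
#' @param subsample_size UMIs drawn per iteration (default 1000).
#' @param iterations Number of resampling iterations (default 1000).
#' @return List with `gini`, `shannon`, `subsample_size`, `iterations`,
#'   `unit`.
#' @export
resampled_diversity <- function(records, unit = c("cdr3", "clonotype"),
                                subsample_size = 1000L, iterations = 1000L) {
  unit <- match.arg(unit)
  col <- if (unit == "cdr3") "junction_aa" else "clonotype_id"
  if (!col %in% names(records)) {
    stop("records lack the '", col, "' column", call. = FALSE)
  }
  species <- records[[col]]
  ids <- match(species, unique(species))
  pool <- rep.int(ids, records$duplicate_count)
  n <- length(pool)
  if (n < subsample_size) {
    stop("insufficient depth: repertoire has ", n, " UMIs but ",
         subsample_size, " are required; it should have been excluded by ",
         "the depth threshold", call. = FALSE)
  }
  nbins <- max(ids)
  g <- numeric(iterations)
  h <- numeric(iterations)
  if (n == subsample_size) {
    counts <- tabulate(pool, nbins = nbins)
    g[] <- gini_index(counts)
    h[] <- shannon_entropy(counts)
  } else {
    for (it in seq_len(iterations)) {
      draw <- pool[sample.int(n, subsample_size)]
      counts <- tabulate(draw, nbins = nbins)
      g[it] <- gini_index(counts)
      h[it] <- shannon_entropy(counts)
    }
  }
  list(gini = mean(g), shannon = mean(h),
       subsample_size = as.integer(subsample_size),
       iterations = as.integer(iterations), unit = unit)
}

#' Rarefied diversity for every subject in a cohort
#'
#' @param records Cohort rearrangement tibble (productive, QC-passing).
#' @param metadata Tibble with `subject_id`, `group`.
#' @inheritParams resampled_diversity
#' @return Tibble: subject_id, group, shannon, gini, unit, subsample,
#'   iterations.
#' @export
diversity_profile <- function(records, metadata, unit = "cdr3",
                              subsample_size = 1000L, iterations = 1000L) {
  subjects <- intersect(metadata$subject_id, unique(records$subject_id))
  rows <- lapply(subjects, function(sid) {
    res <- resampled_diversity(records[records$subject_id == sid, ],
                               unit = unit, subsample_size = subsample_size,
                               iterations = iterations)
    tibble::tibble(subject_id = sid,
                   group = metadata$group[match(sid, metadata$subject_id)],
                   shannon = res$shannon, gini = res$gini, unit = unit,
                   subsample = res$subsample_size,
                   iterations = res$iterations)
  })
  dplyr::bind_rows(rows)
}

#' Repertoire composition by clone-abundance rank
#'
#' Ranks unique CDR3s by UMI-weighted abundance (ties broken
#' lexicographically by CDR3 string for determinism) and returns the
#' proportion of the repertoire occupied by the top 1, 2-10, 11-100, and
#' 101+ most abundant CDR3s.
#'
#' @param records Rearrangement records of one subject (productive).
#' @return Named numeric vector of four bin proportions summing to 1:
#'   `top_1`, `top_2_10`, `top_11_100`, `top_101_plus`.
#' @export
composition_bins <- function(records) {
  if (!nrow(records)) {
    stop("composition_bins: empty repertoire", call. = FALSE)
  }
  ab <- tapply(records$duplicate_count, records$junction_aa, sum)
  ab <- ab[order(-ab, names(ab))]
  total <- sum(ab)
  r <- seq_along(ab)
  bin <- cut(r, c(0, 1, 10, 100, Inf),
             labels = c("top_1", "top_2_10", "top_11_100", "top_101_plus"))
  out <- tapply(as.numeric(ab), bin, sum, default = 0) / total
  stats::setNames(as.numeric(out),
                  c("top_1", "top_2_10", "top_11_100", "top_101_plus"))
}
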