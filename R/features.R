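#' UMI-weighted germline gene-usage matrix
#'
#' For each subject, the fraction of the repertoire (weighted by
#' `duplicate_count`) assigned to each gene-level V, D or J call. Rows sum
#' to 1; genes never seen in a subject are 0; columns cover every gene
#' observed in the cohort, sorted.
#'
#' @param records Cohort rearrangement tibble (productive, QC-passing,
#'   as produced upstream).
#' @param metadata Tibble with `subject_id`, `group`; every listed subject
#'   must have at least one record.
#' @param segment `"v"`, `"d"` or `"j"`.
#' @return Numeric matrix (subjects x genes) with attribute `segment`.
#' @export
gene_usage_matrix <- function(records, metadata, segment = c("v", "d", "j")) {
  segment <- match.arg(segment)
  call_col <- paste0(segment, "_call")
  subjects <- metadata$subject_id
  missing <- setdiff(subjects, unique(records$subject_id))
  if (length(missing)) {
    stop("empty repertoire for subject(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gene <- strip_allele(records[[call_col]])
  tab <- tapply(records$duplicate_count,
                list(factor(records$subject_id, levels = subjects), gene),
                sum, default = 0)
  mat <- as.matrix(tab)
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  mat <- mat / rowSums(mat)
  attr(mat, "segment") <- segment
  mat
}

#' Combined usage of a set of genes
#'
#' Per-subject sum of the listed genes' usage proportions; genes absent
#' from the matrix contribute 0. Used e.g. for pooled IGHV3-30 +
#' IGHV3-30-3 usage, which behave as one closely related gene family.
#'
#' @param usage Gene-usage matrix from [gene_usage_matrix()].
#' @param genes Character vector of gene names (non-empty).
#' @return Named numeric vector, one value per subject.
#' @export
combine_genes <- function(usage, genes) {
  if (!length(genes)) {
    stop("combine_genes: empty gene list", call. = FALSE)
  }
  present <- intersect(genes, colnames(usage))
  if (!length(present)) {
    return(stats::setNames(rep(0, nrow(usage)), rownames(usage)))
  }
  rowSums(usage[, present, drop = FALSE])
}

#' Somatic mutation count of aligned sequences
#'
#' Counts aligned positions where the observed sequence and its germline
#' alignment both carry an unambiguous nucleotide (A/C/G/T, case
#' insensitive) and differ. Gap and ambiguity positions are skipped, so
#' only substitution mismatches are counted. Vectorized over records.
#'
#' @param sequence,germline Character vectors of equal-length aligned
#'   nucleotide strings (pairwise).
#' @return Integer vector of mutation counts.
#' @export
mutation_count <- function(sequence, germline) {
  .compare_aligned(sequence, germline)$mismatches
}

#' Somatic mutation frequency of aligned sequences
#'
#' Mutation count divided by the number of compared positions (those where
#' both strands carry an unambiguous nucleotide), i.e. mutations per
#' sequenced nucleotide.
#'
#' @inheritParams mutation_count
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
mutation_frequency <- function(sequence, germline) {
  cmp <- .compare_aligned(sequence, germline)
  if (any(cmp$compared == 0)) {
    stop("mutation_frequency: no comparable (unambiguous, non-gap) ",
         "positions in record ", which(cmp$compared == 0)[1], call. = FALSE)
  }
  cmp$mismatches / cmp$compared
}

.compare_aligned <- function(sequence, germline) {
  if (length(sequence) != length(germline)) {
    stop("sequence and germline vectors differ in length", call. = FALSE)
  }
  n <- length(sequence)
  la <- nchar(sequence, type = "bytes")
  lb <- nchar(germline, type = "bytes")
  bad <- which(la != lb)
  if (length(bad)) {
    stop("alignment error in record ", bad[1],
         ": sequence and germline_alignment lengths differ", call. = FALSE)
  }
  # byte-class lookup tables: uppercased code for unambiguous nucleotides,
  # 0 otherwise
  up_tab <- integer(256)
  for (b in c("A", "C", "G", "T")) {
    code <- utf8ToInt(b)
    up_tab[code + 1L] <- code
    up_tab[code + 33L] <- code  # lower-case variant
  }
  mism <- integer(n)
  comp <- integer(n)
  chunk <- max(1L, floor(2e7 / max(la[1], 1)))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    a <- up_tab[as.integer(charToRaw(paste(sequence[idx], collapse = ""))) + 1L]
    b <- up_tab[as.integer(charToRaw(paste(germline[idx], collapse = ""))) + 1L]
    valid <- a > 0L & b > 0L
    diffv <- valid & a != b
    ends <- cumsum(la[idx])
    starts <- ends - la[idx]
    cv <- c(0L, cumsum(valid))
    cd <- c(0L, cumsum(diffv))
    comp[idx] <- cv[ends + 1L] - cv[starts + 1L]
    mism[idx] <- cd[ends + 1L] - cd[starts + 1L]
  }
  list(mismatches = mism, compared = comp)
}

#' Count N-glycosylation sequons in a peptide
#'
#' Scans an amino-acid string for the N-linked glycosylation motif
#' N-X-S/T where X is any amino acid except proline. Overlapping motifs
#' are all counted; the unknown residue `X` and stop `*` never match any
#' motif position. Vectorized.
#'
#' @param aa_sequence Character vector of amino-acid strings.
#' @return Integer vector of sequon counts (0 for strings shorter than 3).
#' @examples
#' count_nglyc_sites(c("NGS", "NPS", "NNST"))  # 1, 0, 2
#' @export
count_nglyc_sites <- function(aa_sequence) {
  vapply(aa_sequence, function(s) {
    if (is.na(s) || nchar(s) < 3) return(0L)
    m <- gregexpr("N(?=[^PX*][ST])", s, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Translate nucleotide sequences in the V-region reading frame
#'
#' Standard-code translation starting at position 1 (the frame guaranteed
#' by the simulator's V-region alignment); any trailing incomplete codon is
#' dropped; ambiguity-containing codons translate to `X`; stop codons
#' translate to `*`.
#'
#' @param sequence Character vector of nucleotide strings.
#' @return Character vector of amino-acid strings.
#' @examples
#' translate_in_frame("AATGGTAGT")  # "NGS"
#' @export
translate_in_frame <- function(sequence) {
  keep <- nchar(sequence) - nchar(sequence) %% 3L
  trimmed <- substr(sequence, 1L, keep)
  out <- character(length(sequence))
  nonempty <- keep >= 3L
  if (any(nonempty)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(trimmed[nonempty]),
                                if.fuzzy.codon = "X")
    out[nonempty] <- as.character(aa)
  }
  out
}

#' UMI-weighted isotype composition of a repertoire
#'
#' Maps constant-region calls by prefix (`IGHM` to IgM, `IGHG*` to IgG,
#' anything else to "other") and returns UMI-weighted fractions summing
#' to 1. The assay behind this analysis sequences IgM and IgG only, so
#' "other" is reported but excluded from IgM:IgG comparisons.
#'
#' @param records Rearrangement records of one subject.
#' @return Named numeric vector `c(IgM, IgG, other)`.
#' @export
isotype_proportions <- function(records) {
  cc <- records$c_call
  ok <- !is.na(cc) & nzchar(cc)
  if (!any(ok)) {
    stop("isotype_proportions: all c_call values missing", call. = FALSE)
  }
  cc <- cc[ok]
  w <- records$duplicate_count[ok]
  iso <- ifelse(startsWith(cc, "IGHM"), "IgM",
                ifelse(startsWith(cc, "IGHG"), "IgG", "other"))
  tot <- sum(w)
  c(IgM = sum(w[iso == "IgM"]) / tot,
    IgG = sum(w[iso == "IgG"]) / tot,
    other = sum(w[iso == "other"]) / tot)
}

#' Per-record and per-subject repertoire features
#'
#' Computes, for every record, the somatic mutation count and frequency,
#' the N-glycosylation sequon count over the full translated variable
#' region and over the CDR3 junction alone, and the isotype — then
#' summarises per subject x isotype. Records whose translation contains an
#' internal stop (possible when hypermutation creates one) are flagged and
#' excluded from sequon counting with a warning.
#'
#' @param records Cohort rearrangement tibble (productive).
#' @param metadata Tibble with `subject_id`, `group`.
#' @return List with `record_features` (sequence_id, subject_id, isotype,
#'   mutation_count, mutation_frequency, nglyc_sites, nglyc_sites_junction,
#'   internal_stop) and `subject_summary` (subject_id, group, isotype, n
#'   records, UMIs, mean mutation frequency, mean sequon counts).
#' @export
repertoire_features <- function(records, metadata) {
  cmp <- .compare_aligned(records$sequence, records$germline_alignment)
  if (any(cmp$compared == 0)) {
    stop("record ", which(cmp$compared == 0)[1],
         " has no comparable aligned positions", call. = FALSE)
  }
  mc <- cmp$mismatches
  mf <- cmp$mismatches / cmp$compared
  aa <- translate_in_frame(records$sequence)
  has_stop <- grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE)
  if (any(has_stop)) {
    warning(sum(has_stop), " productive record(s) translate with an ",
            "internal stop; excluded from sequon counting", call. = FALSE)
  }
  ng <- ifelse(has_stop, NA_integer_, count_nglyc_sites(aa))
  ngj <- count_nglyc_sites(records$junction_aa)
  iso <- ifelse(startsWith(records$c_call, "IGHM"), "IgM",
                ifelse(startsWith(records$c_call, "IGHG"), "IgG", "other"))
  rec <- tibble::tibble(
    sequence_id = records$sequence_id, subject_id = records$subject_id,
    isotype = iso, duplicate_count = records$duplicate_count,
    mutation_count = mc, mutation_frequency = mf,
    nglyc_sites = ng, nglyc_sites_junction = ngj,
    internal_stop = has_stop)
  grp <- interaction(rec$subject_id, rec$isotype, drop = TRUE)
  summ <- lapply(split(rec, grp), function(df) {
    tibble::tibble(
      subject_id = df$subject_id[1],
      group = metadata$group[match(df$subject_id[1], metadata$subject_id)],
      isotype = df$isotype[1],
      n_records = nrow(df),
      umis = sum(df$duplicate_count),
      mean_mutation_frequency = stats::weighted.mean(df$mutation_frequency,
                                                     df$duplicate_count),
      mean_nglyc_sites = stats::weighted.mean(df$nglyc_sites,
                                              df$duplicate_count,
                                              na.rm = TRUE),
      mean_nglyc_sites_junction = stats::weighted.mean(
        df$nglyc_sites_junction, df$duplicate_count))
  })
  list(record_features = rec, subject_summary = dplyr::bind_rows(summ))
}

#' Per-subject isotype composition table
#'
#' @param records Cohort rearrangement tibble (productive).
#' @param metadata Tibble with `subject_id`, `group`.
#' @return Tibble: subject_id, group, IgM, IgG, other.
#' @export
isotype_table <- function(records, metadata) {
  subjects <- intersect(metadata$subject_id, unique(records$subject_id))
  rows <- lapply(subjects, function(sid) {
    p <- isotype_proportions(records[records$subject_id == sid, ])
    tibble::tibble(subject_id = sid,
                   group = metadata$group[match(sid, metadata$subject_id)],
                   IgM = p[["IgM"]], IgG = p[["IgG"]], other = p[["other"]])
  })
  dplyr::bind_rows(rows)
}
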