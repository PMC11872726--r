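#' @importFrom dplyr %>%
NULL

.airr_required_cols <- c("sequence_id", "sequence", "productive", "v_call",
                         "d_call", "j_call", "c_call", "junction_aa",
                         "germline_alignment", "duplicate_count",
                         "subject_id")

#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated MiAIRR-style rearrangement file (one row per
#' UMI-consensus transcript). Column order and row order are preserved;
#' `productive` accepts the AIRR `T`/`F` convention as well as
#' `TRUE`/`FALSE` (case-insensitive); a missing `duplicate_count` value
#' defaults to 1.
#'
#' @param path Path to a tab-separated rearrangement file.
#' @return Tibble of rearrangement records.
#' @seealso [write_airr()]
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(.airr_required_cols, names(raw))
  if (length(missing)) {
    stop("AIRR schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prod <- .parse_airr_logical(raw$productive)
  if (anyNA(prod)) {
    bad <- which(is.na(prod))[1]
    stop("parse error in column 'productive', row ", bad,
         ": cannot interpret '", raw$productive[bad], "' as a logical",
         call. = FALSE)
  }
  dup <- raw$duplicate_count
  dup[is.na(dup) | dup == ""] <- "1"
  dupi <- suppressWarnings(as.integer(dup))
  if (anyNA(dupi) || any(dupi < 1)) {
    bad <- which(is.na(dupi) | dupi < 1)[1]
    stop("parse error in column 'duplicate_count', row ", bad,
         ": must be a positive integer", call. = FALSE)
  }
  out <- raw
  out$productive <- prod
  out$duplicate_count <- dupi
  out
}

.parse_airr_logical <- function(x) {
  up <- toupper(trimws(x))
  res <- rep(NA, length(x))
  res[up %in% c("T", "TRUE")] <- TRUE
  res[up %in% c("F", "FALSE")] <- FALSE
  res
}

#' Write an AIRR rearrangement table
#'
#' Writes records as a tab-separated file using the AIRR `T`/`F` encoding
#' for the `productive` column. [read_airr()] of the written file returns
#' field-identical records.
#'
#' @param records Tibble of rearrangement records.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_airr <- function(records, path) {
  missing <- setdiff(.airr_required_cols, names(records))
  if (length(missing)) {
    stop("cannot write AIRR table: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- records
  out$productive <- ifelse(out$productive, "T", "F")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Keep productive records only
#'
#' Non-productive rearrangements (out-of-frame or stop-containing) carry no
#' expressed receptor and are excluded from every analysis. Order is
#' preserved.
#'
#' @param records Tibble of rearrangement records with a logical
#'   `productive` column.
#' @return The productive subset of `records`.
#' @export
filter_productive <- function(records) {
  records[records$productive %in% TRUE, , drop = FALSE]
}

#' Apply the per-sample sequencing-depth threshold
#'
#' A repertoire is excluded when its productive UMI total (sum of
#' `duplicate_count` over productive records) is *less than* `min_umis`;
#' a repertoire with exactly `min_umis` productive UMIs is kept. Every
#' subject in `metadata` receives a QC status, including subjects with no
#' records at all (excluded, zero depth).
#'
#' @param records Cohort rearrangement tibble.
#' @param metadata Tibble with `subject_id` and `group`.
#' @param min_umis Minimum productive UMI count (default 1500).
#' @return List with `records` (records of included subjects only) and
#'   `qc` (tibble: subject_id, group, productive_umis, qc_status,
#'   qc_reason).
#' @export
apply_depth_threshold <- function(records, metadata, min_umis = 1500L) {
  if (min_umis < 1) {
    stop("configuration error: min_umis must be >= 1", call. = FALSE)
  }
  prod <- filter_productive(records)
  depth <- if (nrow(prod)) {
    stats::aggregate(duplicate_count ~ subject_id,
                     data = prod[, c("subject_id", "duplicate_count")],
                     FUN = sum)
  } else {
    data.frame(subject_id = character(0), duplicate_count = integer(0))
  }
  qc <- metadata
  qc$productive_umis <- depth$duplicate_count[
    match(qc$subject_id, depth$subject_id)]
  qc$productive_umis[is.na(qc$productive_umis)] <- 0L
  qc$qc_status <- ifelse(qc$productive_umis >= min_umis,
                         "included", "excluded")
  qc$qc_reason <- ifelse(qc$qc_status == "included", "",
                         sprintf("productive UMI count %d < %d",
                                 qc$productive_umis, as.integer(min_umis)))
  keep <- qc$subject_id[qc$qc_status == "included"]
  list(records = records[records$subject_id %in% keep, , drop = FALSE],
       qc = tibble::as_tibble(qc))
}

#' Strip the allele suffix from a V/D/J call
#'
#' Reduces gene+allele calls to gene-level names: the text before the first
#' `*` of the first comma-separated call, with surrounding whitespace
#' removed. Duplicate-gene suffixes (e.g. the `-3` of `IGHV3-30-3`) are part
#' of the gene name and are retained; in multi-call assignments the first
#' listed call wins.
#'
#' @param call Character vector of gene+allele call strings.
#' @return Character vector of gene names.
#' @examples
#' strip_allele(c("IGHV3-30*04", "IGHV3-30-3*03", "IGHV4-34*01,IGHV4-34*02"))
#' @export
strip_allele <- function(call) {
  if (any(is.na(call) | !nzchar(call))) {
    stop("strip_allele: empty call string", call. = FALSE)
  }
  first <- sub(",.*$", "", call)
  trimws(sub("\\*.*$", "", first))
}

#' Flag repertoires dominated by a single V gene
#'
#' Diagnostic for aberrant repertoires: reports, per subject, the V gene
#' with the highest UMI-weighted usage and whether it exceeds
#' `max_fraction`. This mirrors a manual exclusion decision (one study
#' sample carried 96% IGHV4-34 usage); flagged repertoires are reported,
#' never dropped automatically.
#'
#' @param records Cohort rearrangement tibble (productive records are used).
#' @param max_fraction Dominance threshold (default 0.9).
#' @return Tibble: subject_id, top_gene, top_fraction, flagged.
#' @export
flag_aberrant_repertoires <- function(records, max_fraction = 0.9) {
  prod <- filter_productive(records)
  if (!nrow(prod)) {
    return(tibble::tibble(subject_id = character(0), top_gene = character(0),
                          top_fraction = numeric(0), flagged = logical(0)))
  }
  prod$gene <- strip_allele(prod$v_call)
  agg <- stats::aggregate(duplicate_count ~ subject_id + gene, data = prod,
                          FUN = sum)
  split_rows <- split(agg, agg$subject_id)
  out <- lapply(split_rows, function(df) {
    tot <- sum(df$duplicate_count)
    i <- which.max(df$duplicate_count)
    tibble::tibble(subject_id = df$subject_id[1], top_gene = df$gene[i],
                   top_fraction = df$duplicate_count[i] / tot)
  })
  res <- dplyr::bind_rows(out)
  res$flagged <- res$top_fraction > max_fraction
  res
}

#' Read / write the cohort metadata table
#'
#' @param path Path to a tab-separated file with columns `subject_id` and
#'   `group`.
#' @return Tibble with `subject_id` and `group`.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  missing <- setdiff(c("subject_id", "group"), names(meta))
  if (length(missing)) {
    stop("metadata schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta
}

#' @rdname read_metadata
#' @param metadata Tibble with `subject_id` and `group`.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}
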