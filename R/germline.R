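#' Toy germline gene panel
#'
#' A self-contained reference panel of synthetic IGHV/IGHD/IGHJ germline
#' sequences used by the cohort simulator. Gene *names* follow human IGH
#' nomenclature (so gene-level analyses behave like real data), but the
#' sequences themselves are synthetic: every analysis in this package
#' depends only on gene names and on mismatch counts against the aligned
#' germline, never on biological sequence content.
#'
#' Sequences are built from sense codons only (no stop codons in frame 1)
#' so that V+D+J concatenations translate cleanly; lengths are multiples
#' of three. The panel is deterministic: repeated calls return identical
#' sequences regardless of the caller's RNG state.
#'
#' @return A tibble with columns `gene`, `segment` ("V", "D" or "J") and
#'   `sequence` (unambiguous upper-case nucleotides).
#' @examples
#' ref <- germline_reference()
#' table(ref$segment)
#' @export
germline_reference <- function() {
  if (!is.null(.immrep_cache$germline)) {
    return(.immrep_cache$germline)
  }
  genes <- c(names(.base_freqs$v), names(.base_freqs$d), names(.base_freqs$j))
  segment <- rep(c("V", "D", "J"),
                 c(length(.base_freqs$v), length(.base_freqs$d),
                   length(.base_freqs$j)))
  n_codons <- rep(c(98L, 6L, 16L),
                  c(length(.base_freqs$v), length(.base_freqs$d),
                    length(.base_freqs$j)))
  seqs <- .with_local_seed(873221L, {
    vapply(n_codons, function(k) {
      paste(sample(.sense_codons, k, replace = TRUE), collapse = "")
    }, character(1))
  })
  out <- tibble::tibble(gene = genes, segment = segment, sequence = seqs)
  .immrep_cache$germline <- out
  out
}

#' Population-level germline gene usage frequencies
#'
#' Baseline probabilities over the toy gene panel, used as the centre of the
#' Dirichlet between-subject usage model. IGHV3-23 carries the highest V-gene
#' probability, matching its dominance in human peripheral repertoires.
#'
#' @param segment One of `"v"`, `"d"`, `"j"`.
#' @return Named numeric probability vector summing to 1.
#' @export
base_gene_frequencies <- function(segment = c("v", "d", "j")) {
  segment <- match.arg(segment)
  .base_freqs[[segment]]
}

# package-local mutable cache (germline panel, memoised lookups)
.immrep_cache <- new.env(parent = emptyenv())

# the 61 sense codons of the standard genetic code
.sense_codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# standard genetic code as a named vector (codon -> single-letter aa)
.codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
  aa <- vapply(codons, function(cd) {
    # minimal standard-code lookup built from Biostrings at load would pull
    # a heavy dependency into a constant; spelled out instead.
    switch(cd,
      TTT = , TTC = "F", TTA = , TTG = , CTT = , CTC = , CTA = , CTG = "L",
      ATT = , ATC = , ATA = "I", ATG = "M",
      GTT = , GTC = , GTA = , GTG = "V",
      TCT = , TCC = , TCA = , TCG = , AGT = , AGC = "S",
      CCT = , CCC = , CCA = , CCG = "P",
      ACT = , ACC = , ACA = , ACG = "T",
      GCT = , GCC = , GCA = , GCG = "A",
      TAT = , TAC = "Y", TAA = , TAG = , TGA = "*",
      CAT = , CAC = "H", CAA = , CAG = "Q",
      AAT = , AAC = "N", AAA = , AAG = "K",
      GAT = , GAC = "D", GAA = , GAG = "E",
      TGT = , TGC = "C", TGG = "W",
      CGT = , CGC = , CGA = , CGG = , AGA = , AGG = "R",
      GGT = , GGC = , GGA = , GGG = "G")
  }, character(1))
  stats::setNames(aa, codons)
})

.aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y")

.base_freqs <- list(
  v = c("IGHV1-2" = 0.04, "IGHV1-3" = 0.03, "IGHV1-18" = 0.04,
        "IGHV1-69" = 0.05, "IGHV2-5" = 0.02, "IGHV3-7" = 0.05,
        "IGHV3-9" = 0.04, "IGHV3-15" = 0.04, "IGHV3-21" = 0.05,
        "IGHV3-23" = 0.12, "IGHV3-30" = 0.05, "IGHV3-30-3" = 0.02,
        "IGHV3-33" = 0.05, "IGHV3-48" = 0.05, "IGHV3-49" = 0.02,
        "IGHV3-53" = 0.04, "IGHV4-34" = 0.06, "IGHV4-39" = 0.06,
        "IGHV4-59" = 0.07, "IGHV5-51" = 0.06, "IGHV6-1" = 0.04),
  d = c("IGHD1-26" = 0.18, "IGHD2-2" = 0.14, "IGHD3-10" = 0.25,
        "IGHD3-22" = 0.16, "IGHD4-17" = 0.12, "IGHD6-19" = 0.15),
  j = c("IGHJ1" = 0.02, "IGHJ2" = 0.03, "IGHJ3" = 0.08,
        "IGHJ4" = 0.45, "IGHJ5" = 0.14, "IGHJ6" = 0.28)
)

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
.with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
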