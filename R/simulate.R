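#' Configuration for the synthetic cohort simulator
#'
#' Builds a validated configuration object describing a simulated BCR
#' heavy-chain sequencing cohort: group composition, per-subject UMI depth,
#' gene-usage variability, clone-size law, a planted case/control usage
#' effect, isotype composition, and isotype-conditional somatic
#' hypermutation.
#'
#' Defaults describe a four-group cohort (21 healthy controls, 25
#' mild/moderate ME/CFS, 36 severe ME/CFS, 28 MS controls) with a planted
#' standardized shift of 0.70 in IGHV3-30 usage for the mild/moderate group
#' relative to the population baseline — the study conditions the analysis
#' stack is calibrated against.
#'
#' @param group_sizes Named integer vector, group label -> number of subjects.
#' @param umi_range Length-2 integer vector; per-subject total UMI depth is
#'   drawn uniformly from this range.
#' @param n_shallow Number of subjects (drawn at random across the cohort)
#'   whose depth is instead drawn from `shallow_range`, planting samples that
#'   fail the 1,500-UMI quality threshold.
#' @param shallow_range Length-2 integer vector of shallow depths; its upper
#'   end must stay below 1,500 so planted-shallow subjects always fail QC.
#' @param dirichlet_concentration Positive scalar; between-subject gene usage
#'   is Dirichlet(concentration * base frequencies). Larger values mean less
#'   between-subject variability.
#' @param clone_size_law List with `law` ("zipf" or "constant") and its
#'   parameters (`exponent`, `max_size` for zipf; `size` for constant).
#' @param effect_size Standardized shift (Cohen's d units) planted on
#'   `effect_gene` usage in `effect_group` subjects.
#' @param effect_gene,effect_group Gene and group receiving the planted shift.
#' @param igm_fraction_by_group Named numeric vector of mean IgM transcript
#'   proportions per group; per-subject fractions are Beta-distributed around
#'   these means.
#' @param igm_concentration Beta concentration (a+b) for per-subject IgM
#'   fractions.
#' @param shm_model List with `igm = list(zero_prob, lambda)` (zero-inflated
#'   Poisson mutation counts, modelling naive-dominated IgM) and
#'   `igg = list(mu, size)` (negative binomial, overdispersed with positive
#'   mean, modelling antigen-experienced IgG).
#' @param nglyc_rate Per-mutation probability that a somatic mutation is
#'   directed to create an N-glycosylation sequon (N-X-S/T, X != P).
#' @param nonproductive_rate Probability that a record is emitted as
#'   non-productive.
#' @param cdr3_length_range Inclusive junction amino-acid length range
#'   (including the invariant leading C and trailing W).
#' @param member_substitution_prob Probability that a clone member beyond the
#'   founder carries one CDR3 amino-acid substitution, giving clonotype
#'   clustering within-clone structure to recover.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A `simulation_config` list.
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(group_sizes = c(HC = 21L, ME_mm = 25L,
                                              ME_sa = 36L, MS = 28L),
                              umi_range = c(2500L, 4000L),
                              n_shallow = 0L,
                              shallow_range = c(200L, 1400L),
                              dirichlet_concentration = 200,
                              clone_size_law = list(law = "zipf",
                                                    exponent = 2.5,
                                                    max_size = 100L),
                              effect_size = 0.70,
                              effect_gene = "IGHV3-30",
                              effect_group = "ME_mm",
                              igm_fraction_by_group = c(HC = 0.55,
                                                        ME_mm = 0.65,
                                                        ME_sa = 0.55,
                                                        MS = 0.55),
                              igm_concentration = 40,
                              shm_model = list(
                                igm = list(zero_prob = 0.5, lambda = 3),
                                igg = list(mu = 15, size = 3)),
                              nglyc_rate = 0.05,
                              nonproductive_rate = 0.02,
                              cdr3_length_range = c(8L, 24L),
                              member_substitution_prob = 0.1,
                              seed = 1L) {
  cfg <- list(group_sizes = group_sizes, umi_range = as.integer(umi_range),
              n_shallow = as.integer(n_shallow),
              shallow_range = as.integer(shallow_range),
              dirichlet_concentration = dirichlet_concentration,
              clone_size_law = clone_size_law, effect_size = effect_size,
              effect_gene = effect_gene, effect_group = effect_group,
              igm_fraction_by_group = igm_fraction_by_group,
              igm_concentration = igm_concentration, shm_model = shm_model,
              nglyc_rate = nglyc_rate,
              nonproductive_rate = nonproductive_rate,
              cdr3_length_range = as.integer(cdr3_length_range),
              member_substitution_prob = member_substitution_prob,
              seed = as.integer(seed))
  .validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

.validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid simulation configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  gs <- cfg$group_sizes
  if (is.null(names(gs)) || any(!nzchar(names(gs)))) {
    fail("group_sizes", "must be a named vector of subject counts")
  }
  if (any(gs < 2)) fail("group_sizes", "must have >= 2 subjects per group")
  if (length(cfg$umi_range) != 2 || any(cfg$umi_range < 1) ||
      cfg$umi_range[1] > cfg$umi_range[2]) {
    fail("umi_range", "must be an increasing positive pair")
  }
  if (cfg$n_shallow < 0 || cfg$n_shallow > sum(gs)) {
    fail("n_shallow", "must be between 0 and the cohort size")
  }
  if (length(cfg$shallow_range) != 2 || any(cfg$shallow_range < 1) ||
      cfg$shallow_range[1] > cfg$shallow_range[2]) {
    fail("shallow_range", "must be an increasing positive pair")
  }
  if (!is.numeric(cfg$dirichlet_concentration) ||
      cfg$dirichlet_concentration <= 0) {
    fail("dirichlet_concentration", "must be a positive scalar")
  }
  if (!is.finite(cfg$effect_size)) fail("effect_size", "must be finite")
  if (!cfg$effect_group %in% names(gs)) {
    fail("effect_group", "must name a group in group_sizes")
  }
  igm <- cfg$igm_fraction_by_group
  if (!all(names(gs) %in% names(igm))) {
    fail("igm_fraction_by_group", "must cover every group")
  }
  for (field in c("igm_fraction_by_group", "nglyc_rate",
                  "nonproductive_rate", "member_substitution_prob")) {
    val <- cfg[[field]]
    if (any(val < 0 | val > 1)) fail(field, "must lie in [0, 1]")
  }
  if (cfg$cdr3_length_range[1] < 3 ||
      cfg$cdr3_length_range[1] > cfg$cdr3_length_range[2]) {
    fail("cdr3_length_range", "must be an increasing pair with minimum >= 3")
  }
  law <- cfg$clone_size_law
  if (is.null(law$law)) fail("clone_size_law", "must name a 'law'")
  invisible(TRUE)
}

#' Draw one subject's germline gene-usage vector
#'
#' Samples a subject-level usage probability vector from a Dirichlet
#' distribution centred on the population base frequencies, optionally
#' applying a planted additive shift to one gene (the mechanism behind the
#' simulator's case/control effect). After shifting, the remaining genes are
#' rescaled so the vector stays on the simplex; the shifted gene's mean is
#' raised by exactly `shift$delta` (or `shift$d * shift$sd`).
#'
#' @param base_freqs Named probability vector summing to 1.
#' @param concentration Positive Dirichlet concentration scalar.
#' @param shift Optional list: `gene` plus either `delta` (absolute usage
#'   shift) or `d` and `sd` (standardized shift times usage SD).
#' @return Named probability vector over the same genes.
#' @export
sample_subject_usage <- function(base_freqs, concentration, shift = NULL) {
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      concentration <= 0) {
    stop("concentration must be a positive scalar", call. = FALSE)
  }
  if (abs(sum(base_freqs) - 1) > 1e-8) {
    stop("base_freqs must sum to 1", call. = FALSE)
  }
  g <- stats::rgamma(length(base_freqs), shape = concentration * base_freqs,
                     rate = 1)
  # zero-probability genes can draw exactly 0; the simplex only needs sum > 0
  if (sum(g) == 0) g[] <- base_freqs
  p <- g / sum(g)
  names(p) <- names(base_freqs)
  if (!is.null(shift)) {
    gene <- shift$gene
    if (!gene %in% names(p)) {
      stop("shift gene '", gene, "' not in base_freqs", call. = FALSE)
    }
    delta <- if (!is.null(shift$delta)) shift$delta else shift$d * shift$sd
    target <- min(max(p[[gene]] + delta, 0), 0.99)
    others <- setdiff(names(p), gene)
    denom <- sum(p[others])
    if (denom > 0) p[others] <- p[others] * (1 - target) / denom
    p[[gene]] <- target
  }
  p / sum(p)
}

#' Draw clone sizes from a heavy-tailed law
#'
#' Clone sizes (UMIs per clone) are drawn from a configurable law. The
#' default cohort uses a truncated discrete power law ("zipf"), which yields
#' mostly singleton clones with occasional large expansions — the source of
#' the skew summarised by the top-1 / 2-10 / 11-100 / 101+ composition bins.
#'
#' Exactly one of `n_clones` and `total` must be given. With `total`, sizes
#' are drawn until their sum reaches the target and the final clone is
#' trimmed so the sizes sum to `total` exactly.
#'
#' @param n_clones Number of clones to draw.
#' @param law List with element `law` ("zipf" or "constant") and parameters:
#'   `exponent` and `max_size` for zipf, `size` for constant.
#' @param total Target total UMI count.
#' @return Integer vector of positive clone sizes.
#' @export
sample_clone_sizes <- function(n_clones = NULL, law, total = NULL) {
  if (is.null(n_clones) == is.null(total)) {
    stop("give exactly one of n_clones or total", call. = FALSE)
  }
  draw <- switch(law$law,
    constant = {
      size <- if (is.null(law$size)) 1L else as.integer(law$size)
      function(n) rep.int(size, n)
    },
    zipf = {
      kmax <- if (is.null(law$max_size)) 10000L else as.integer(law$max_size)
      expo <- law$exponent
      if (is.null(expo) || expo <= 1) {
        stop("zipf law requires exponent > 1", call. = FALSE)
      }
      prob <- seq_len(kmax)^(-expo)
      function(n) sample.int(kmax, n, replace = TRUE, prob = prob)
    },
    stop("unknown clone size law '", law$law, "'", call. = FALSE)
  )
  if (!is.null(n_clones)) {
    if (n_clones < 1) stop("n_clones must be >= 1", call. = FALSE)
    return(as.integer(draw(n_clones)))
  }
  if (total < 1) stop("total must be >= 1", call. = FALSE)
  sizes <- integer(0)
  while (sum(sizes) < total) {
    sizes <- c(sizes, as.integer(draw(max(16L, ceiling(total / 4)))))
  }
  cum <- cumsum(sizes)
  k <- which(cum >= total)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - total)
  if (sizes[k] == 0L) sizes <- sizes[-k]
  sizes
}

#' Introduce point mutations into a germline sequence
#'
#' Applies exactly `n_mutations` nucleotide substitutions at distinct
#' positions drawn uniformly without replacement; every substituted base
#' differs from the original, so the downstream mismatch count against the
#' germline recovers `n_mutations` exactly. Lengths are preserved (no
#' indels), matching a substitution-only somatic hypermutation model.
#'
#' @param germline_nt Single nucleotide string (A/C/G/T).
#' @param n_mutations Number of substitutions, 0 <= n <= nchar(germline_nt).
#' @return List with `sequence` (mutated string) and `positions` (sorted
#'   integer positions of the substitutions).
#' @export
mutate_sequence <- function(germline_nt, n_mutations) {
  n <- nchar(germline_nt)
  if (n_mutations < 0 || n_mutations > n) {
    stop("n_mutations must be between 0 and the germline length", call. = FALSE)
  }
  if (n_mutations == 0) {
    return(list(sequence = germline_nt, positions = integer(0)))
  }
  ch <- strsplit(germline_nt, "", fixed = TRUE)[[1]]
  pos <- sort(sample.int(n, n_mutations))
  bases <- c("A", "C", "G", "T")
  old_idx <- match(ch[pos], bases)
  new_idx <- (old_idx + sample.int(3L, n_mutations, replace = TRUE) - 1L) %% 4L + 1L
  ch[pos] <- bases[new_idx]
  list(sequence = paste(ch, collapse = ""), positions = pos)
}

# ---- internal simulator machinery -----------------------------------------

# translate a nucleotide char vector (length divisible by 3) with the
# package codon table; used only on the generator side of round trips
.translate_chars <- function(ch) {
  n <- length(ch)
  codons <- paste0(ch[seq(1, n, 3)], ch[seq(2, n, 3)], ch[seq(3, n, 3)])
  unname(.codon_table[codons])
}

# generator-side sequon scan on an amino-acid char vector; deliberately a
# different route from the exported regex-based count_nglyc_sites()
.scan_sequons <- function(aa) {
  n <- length(aa)
  if (n < 3) return(0L)
  i <- which(aa[seq_len(n - 2)] == "N")
  if (!length(i)) return(0L)
  sum(!aa[i + 1] %in% c("P", "X", "*") & aa[i + 2] %in% c("S", "T"))
}

# positions where a single substitution turns a codon into AAT/AAC completing
# a new sequon N-X-S/T (X != P) against the unmutated germline frame
.sequon_candidates <- function(ch) {
  aa <- .translate_chars(ch)
  k <- length(aa)
  if (k < 3) return(data.frame(pos = integer(0), base = character(0)))
  ok <- which(aa[seq_len(k - 2)] != "N" &
                !aa[pmin(seq_len(k - 2) + 1, k)] %in% c("P", "*") &
                aa[pmin(seq_len(k - 2) + 2, k)] %in% c("S", "T"))
  pos <- integer(0); base <- character(0)
  for (i in ok) {
    cod <- ch[(3 * i - 2):(3 * i)]
    for (target in list(c("A", "A", "T"), c("A", "A", "C"))) {
      diff <- which(cod != target)
      if (length(diff) == 1) {
        pos <- c(pos, 3 * (i - 1) + diff)
        base <- c(base, target[diff])
      }
    }
  }
  keep <- !duplicated(pos)
  data.frame(pos = pos[keep], base = base[keep],
             stringsAsFactors = FALSE)
}

# random amino-acid inner strings of the given lengths, via one bulk draw
.random_aa_strings <- function(lengths) {
  total <- sum(lengths)
  if (total == 0) return(rep("", length(lengths)))
  big <- paste(sample(.aa_alphabet, total, replace = TRUE), collapse = "")
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1
  substring(big, starts, ends)
}

#' Simulate an annotated BCR heavy-chain cohort
#'
#' Generates one repertoire per subject as AIRR-style rearrangement records
#' with V/D/J and constant-region calls, junction amino-acid sequences,
#' mutated nucleotide sequences aligned to their germline, productive flags
#' and UMI weights, together with a ground-truth ledger that reconciles
#' exactly with the emitted records (record, UMI, isotype and mutation
#' totals; true usage vectors; clone sizes; planted effect sizes).
#'
#' The generative model, per subject: a Dirichlet draw around population
#' gene frequencies gives the usage vector (with the configured additive
#' shift on the effect gene for effect-group subjects); clone sizes follow
#' the configured heavy-tailed law and are trimmed to the subject's UMI
#' depth; each clone gets a V/D/J assignment, an allele, and a CDR3 of the
#' form `C...W`; clone members may carry one CDR3 substitution; each record
#' draws an isotype (IgM/IgG) from the subject's IgM fraction and a mutation
#' count from the isotype's SHM law, applied as substitutions to the clone
#' germline, a configurable fraction of which are directed to create
#' N-glycosylation sequons.
#'
#' @param config A [simulation_config()] object.
#' @param reference Germline panel tibble, as from [germline_reference()].
#' @return List with `records` (one tibble of AIRR records for the whole
#'   cohort), `metadata` (subject_id, group), and `ledger` (list of truth
#'   tables: `subjects`, `usage`, `clone_sizes`, `records`, `effects`).
#' @examples
#' cfg <- simulation_config(group_sizes = c(HC = 3L, ME_mm = 3L),
#'                          umi_range = c(300L, 400L), seed = 7L)
#' sim <- simulate_cohort(cfg)
#' dplyr::count(sim$metadata, group)
#' @export
simulate_cohort <- function(config, reference = germline_reference()) {
  if (!inherits(config, "simulation_config")) .validate_config(config)
  set.seed(config$seed)

  groups <- rep(names(config$group_sizes), config$group_sizes)
  n_subj <- length(groups)
  subject_id <- sprintf("S%03d", seq_len(n_subj))
  shallow <- rep(FALSE, n_subj)
  if (config$n_shallow > 0) {
    shallow[sample.int(n_subj, config$n_shallow)] <- TRUE
  }

  base_v <- .base_freqs$v
  base_d <- .base_freqs$d
  base_j <- .base_freqs$j
  conc <- config$dirichlet_concentration

  # calibrate the planted shift so the realized standardized difference in
  # observed usage equals effect_size: delta = d * sd(observed usage). The
  # observed-usage variance has a between-subject (Dirichlet) component and
  # a within-subject clone-sampling component: genes are assigned per clone
  # and weighted by clone size, so the sampling variance is
  # p(1-p) * E[sum(w^2)/(sum w)^2] at the nominal depth, estimated here by
  # a short deterministic draw from the clone-size law
  # usage is measured on productive records only, so the nominal depth is
  # scaled by the expected productive fraction: baseline artefact rate
  # times the chance that no somatic mutation creates an internal stop
  # (probability-generating functions of the per-isotype mutation laws at
  # the exact per-substitution stop probability of the codon table)
  p0 <- base_v[[config$effect_gene]]
  q <- .stop_substitution_prob() * (1 - config$nglyc_rate)
  shm0 <- config$shm_model
  p_ok_igm <- shm0$igm$zero_prob +
    (1 - shm0$igm$zero_prob) * exp(-shm0$igm$lambda * q)
  p_ok_igg <- (1 + q * shm0$igg$mu / shm0$igg$size)^(-shm0$igg$size)
  igm_w <- sum(config$igm_fraction_by_group[names(config$group_sizes)] *
                 config$group_sizes) / sum(config$group_sizes)
  p_prod <- (1 - config$nonproductive_rate) *
    (igm_w * p_ok_igm + (1 - igm_w) * p_ok_igg)
  m_nom <- as.integer(round(mean(config$umi_range)))
  kappa_key <- paste(c("kappa", unlist(config$clone_size_law), m_nom,
                       round(p_prod, 4)), collapse = "_")
  kappa <- .immrep_cache[[kappa_key]]
  if (is.null(kappa)) {
    kappa <- .with_local_seed(190777L, {
      keep_rate <- (1 - config$nonproductive_rate) *
        c(p_ok_igg, p_ok_igm)
      mean(replicate(2000, {
        w <- sample_clone_sizes(law = config$clone_size_law, total = m_nom)
        iso <- 1L + (stats::runif(length(w)) < igm_w)
        w <- w[stats::runif(length(w)) < keep_rate[iso]]
        if (!length(w)) return(0)
        sum(w^2) / sum(w)^2
      }))
    })
    .immrep_cache[[kappa_key]] <- kappa
  }
  sd_tot <- sqrt(p0 * (1 - p0) * (1 / (conc + 1) + kappa))
  delta <- config$effect_size * sd_tot

  v_names <- names(base_v)
  d_names <- names(base_d)
  j_names <- names(base_j)
  nv <- length(base_v)
  nd <- length(base_d)
  nj <- length(base_j)
  # combo tables over all nv*nd*nj germlines, indexed by the integer id
  # ((vi-1)*nd + di-1)*nj + ji; cached across calls for the default panel
  tab <- .germline_tables(reference, v_names, d_names, j_names)
  L <- tab$len
  K <- L %/% 3L

  rec_list <- vector("list", n_subj)
  truth_list <- vector("list", n_subj)
  clone_list <- vector("list", n_subj)
  usage_list <- vector("list", n_subj)
  subj_rows <- vector("list", n_subj)
  len_lo <- config$cdr3_length_range[1]
  len_hi <- config$cdr3_length_range[2]
  len_vals <- len_lo:len_hi
  # triangular length weights peaked near 15 aa, the human CDR3 mode
  len_w <- pmax(1, 8 - abs(len_vals - 15L))
  bases4 <- c("A", "C", "G", "T")

  for (s in seq_len(n_subj)) {
    grp <- groups[s]
    depth <- if (shallow[s]) {
      .sample_range(config$shallow_range)
    } else {
      .sample_range(config$umi_range)
    }
    shift <- NULL
    if (grp == config$effect_group && config$effect_size != 0) {
      shift <- list(gene = config$effect_gene, delta = delta)
    }
    usage_v <- sample_subject_usage(base_v, conc, shift)
    usage_d <- sample_subject_usage(base_d, conc)
    usage_j <- sample_subject_usage(base_j, conc)

    sizes <- sample_clone_sizes(law = config$clone_size_law, total = depth)
    nc <- length(sizes)
    v_idx <- sample.int(nv, nc, replace = TRUE, prob = usage_v)
    d_idx <- sample.int(nd, nc, replace = TRUE, prob = usage_d)
    j_idx <- sample.int(nj, nc, replace = TRUE, prob = usage_j)
    v_gene <- v_names[v_idx]
    d_gene <- d_names[d_idx]
    j_gene <- j_names[j_idx]
    allele <- sprintf("*0%d", sample.int(4L, nc, replace = TRUE))

    jlen <- sample(len_vals, nc, replace = TRUE, prob = len_w)
    junction <- paste0("C", .random_aa_strings(jlen - 2L), "W")

    # clone members: founder record plus variant members carrying one CDR3
    # amino-acid substitution each
    n_var <- stats::rbinom(nc, sizes - 1L, config$member_substitution_prob)
    founder_umis <- sizes - n_var
    clone_idx <- c(seq_len(nc)[founder_umis > 0],
                   rep.int(seq_len(nc), n_var))
    dup <- c(founder_umis[founder_umis > 0],
             rep.int(1L, sum(n_var)))
    is_variant <- c(rep(FALSE, sum(founder_umis > 0)),
                    rep(TRUE, sum(n_var)))
    junc <- junction[clone_idx]
    if (any(is_variant)) {
      vi <- which(is_variant)
      inner_len <- jlen[clone_idx[vi]] - 2L
      pos <- 1L + ceiling(stats::runif(length(vi)) * inner_len)
      old <- substr(junc[vi], pos, pos)
      new <- .aa_alphabet[(match(old, .aa_alphabet) +
                             sample.int(19L, length(vi), replace = TRUE)
                           - 1L) %% 20L + 1L]
      substr(junc[vi], pos, pos) <- new
    }
    nrec <- length(clone_idx)
    ord <- order(clone_idx)
    clone_idx <- clone_idx[ord]; dup <- dup[ord]; junc <- junc[ord]

    igm_mean <- config$igm_fraction_by_group[[grp]]
    kconc <- config$igm_concentration
    igm_frac <- stats::rbeta(1, igm_mean * kconc, (1 - igm_mean) * kconc)
    is_igm <- stats::runif(nrec) < igm_frac
    c_call <- ifelse(is_igm, "IGHM",
                     sprintf("IGHG%d", sample.int(4L, nrec, replace = TRUE)))
    shm <- config$shm_model
    n_mut <- integer(nrec)
    n_mut[is_igm] <- ifelse(
      stats::runif(sum(is_igm)) < shm$igm$zero_prob, 0L,
      stats::rpois(sum(is_igm), shm$igm$lambda))
    n_mut[!is_igm] <- stats::rnbinom(sum(!is_igm), mu = shm$igg$mu,
                                     size = shm$igg$size)

    # the panel has constant gene lengths, so every germline is L
    # nucleotides and the whole subject can be mutated and translated as
    # one byte vector / character matrix
    cid <- (v_idx - 1L) * nd * nj + (d_idx - 1L) * nj + j_idx
    gid <- cid[clone_idx]
    n_mut <- as.integer(pmin(n_mut, L))
    n_targeted <- stats::rbinom(nrec, n_mut, config$nglyc_rate)

    A <- tab$aa_mat[gid, , drop = FALSE]
    # all records concatenated as one raw byte vector (record r occupies
    # bytes (r-1)*L + 1 ... r*L), so substitutions are plain index writes
    big <- as.vector(tab$raw_mat[, gid])
    raw_bases <- charToRaw("ACGT")
    # distinct substitution positions per record; sequon-directed ones first
    # (their replacement base is fixed by the candidate table, the rest get
    # a random base differing from the germline one)
    # records with sequon-directed mutations keep a per-record draw (the
    # candidate pool differs per germline); all other records draw their
    # distinct positions in one batch with rejection of within-record
    # duplicates
    has_tgt <- n_targeted > 0L
    pos_list <- vector("list", nrec)
    base_list <- vector("list", nrec)
    for (r in which(n_mut > 0L & has_tgt)) {
      cand <- tab$cand[[gid[r]]]
      n_cand <- length(cand$pos)
      nt_tgt <- min(n_targeted[r], n_cand)
      if (nt_tgt == 0L) {
        has_tgt[r] <- FALSE
        next
      }
      sel <- sample.int(n_cand, nt_tgt)
      tpos <- cand$pos[sel]
      rest_pool <- seq_len(L)[-tpos]
      rest <- rest_pool[sample.int(length(rest_pool), n_mut[r] - nt_tgt)]
      pos_list[[r]] <- c(tpos, rest)
      base_list[[r]] <- c(cand$base[sel],
                          rep(NA_character_, length(rest)))
    }
    idx_t <- which(lengths(pos_list) > 0L)
    idx_u <- which(n_mut > 0L & !has_tgt)
    ri_u <- rep.int(idx_u, n_mut[idx_u])
    pos_u <- sample.int(L, length(ri_u), replace = TRUE)
    if (length(pos_u)) {
      repeat {
        clash <- duplicated(ri_u * 512L + pos_u)
        if (!any(clash)) break
        pos_u[clash] <- sample.int(L, sum(clash), replace = TRUE)
      }
    }
    all_ri <- c(rep.int(idx_t, n_mut[idx_t]), ri_u)
    all_ci <- c(unlist(pos_list[idx_t]), pos_u)
    all_base <- c(unlist(base_list[idx_t]),
                  rep(NA_character_, length(pos_u)))
    if (length(all_ci)) {
      gp <- (all_ri - 1L) * L + all_ci
      na_b <- is.na(all_base)
      new_raw <- raw_bases[match(all_base, bases4)]
      oi <- match(big[gp[na_b]], raw_bases)
      new_raw[na_b] <- raw_bases[(oi +
                                    sample.int(3L, sum(na_b), replace = TRUE)
                                  - 1L) %% 4L + 1L]
      big[gp] <- new_raw
    }
    big_str <- rawToChar(big)
    off <- (seq_len(nrec) - 1L) * L
    seq_nt <- substring(big_str, off + 1L, off + L)
    internal_stop <- logical(nrec)
    if (length(all_ci)) {
      # retranslate exactly the codons containing a substitution
      cod <- (all_ci - 1L) %/% 3L
      keep <- !duplicated(all_ri * 128L + cod)
      rr <- all_ri[keep]
      cc <- cod[keep]
      new_aa <- .codon_table[substring(big_str, (rr - 1L) * L + 3L * cc + 1L,
                                       (rr - 1L) * L + 3L * cc + 3L)]
      A[cbind(rr, cc + 1L)] <- new_aa
      # the germline has no stop codons, so internal stops can only arise
      # at a mutated codon
      stopped <- new_aa == "*" & cc + 1L < K
      internal_stop[rr[stopped]] <- TRUE
    }
    # sequon scan (N-X-S/T, X not P/X/*), vectorized over records
    isN <- A[, 1:(K - 2), drop = FALSE] == "N"
    mid <- A[, 2:(K - 1), drop = FALSE]
    thr <- A[, 3:K, drop = FALSE]
    hit <- isN & (mid != "P" & mid != "X" & mid != "*") &
      (thr == "S" | thr == "T")
    n_sequons <- as.integer(rowSums(hit))
    germ_nt <- tab$nt[gid]

    # stop-containing transcripts cannot encode a receptor: they are
    # emitted as non-productive, alongside the configured baseline rate of
    # frameshift-like artefacts
    productive <- stats::runif(nrec) >= config$nonproductive_rate &
      !internal_stop
    sid <- subject_id[s]
    seq_ids <- sprintf("%s_%05d", sid, seq_len(nrec))
    rec_list[[s]] <- .fast_df(
      sequence_id = seq_ids,
      subject_id = sid,
      sequence = seq_nt,
      germline_alignment = germ_nt,
      v_call = paste0(v_gene[clone_idx], allele[clone_idx]),
      d_call = paste0(d_gene[clone_idx], allele[clone_idx]),
      j_call = paste0(j_gene[clone_idx], allele[clone_idx]),
      c_call = c_call,
      junction_aa = junc,
      productive = productive,
      duplicate_count = as.integer(dup))
    truth_list[[s]] <- .fast_df(
      sequence_id = seq_ids, subject_id = sid,
      clone_id = sprintf("%s_C%04d", sid, clone_idx),
      n_mutations = n_mut, n_sequons = n_sequons,
      isotype = ifelse(is_igm, "IgM", "IgG"))
    clone_list[[s]] <- .fast_df(
      subject_id = sid, clone_id = sprintf("%s_C%04d", sid, seq_len(nc)),
      size = as.integer(sizes), v_gene = v_gene, d_gene = d_gene,
      j_gene = j_gene)
    usage_list[[s]] <- .fast_df(
      subject_id = sid,
      segment = rep(c("v", "d", "j"),
                    c(length(usage_v), length(usage_d), length(usage_j))),
      gene = c(names(usage_v), names(usage_d), names(usage_j)),
      true_usage = c(usage_v, usage_d, usage_j))
    subj_rows[[s]] <- .fast_df(
      subject_id = sid, group = grp, shallow = shallow[s],
      depth = as.integer(depth), n_records = nrec,
      n_productive = sum(productive),
      productive_umis = sum(dup[productive]),
      igm_umis = sum(dup[is_igm]), igg_umis = sum(dup[!is_igm]),
      total_mutations = sum(n_mut),
      igm_fraction_true = igm_frac)
  }

  records <- dplyr::bind_rows(rec_list)
  metadata <- tibble::tibble(subject_id = subject_id, group = groups)
  ledger <- list(
    subjects = dplyr::bind_rows(subj_rows),
    usage = dplyr::bind_rows(usage_list),
    clone_sizes = dplyr::bind_rows(clone_list),
    records = dplyr::bind_rows(truth_list),
    effects = list(effect_gene = config$effect_gene,
                   effect_group = config$effect_group,
                   effect_size = config$effect_size,
                   delta = delta))
  list(records = records, metadata = metadata, ledger = ledger)
}

# uniform integer draw from an inclusive range (safe when lo == hi)
.sample_range <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

# minimal-overhead data.frame constructor for hot loops; atomic columns,
# length-1 inputs recycled
.fast_df <- function(...) {
  x <- list(...)
  n <- max(lengths(x))
  short <- lengths(x) == 1L & n > 1L
  x[short] <- lapply(x[short], rep.int, n)
  structure(x, class = "data.frame", row.names = .set_row_names(n))
}

# Precompute germline tables for every V/D/J combo of the panel: nucleotide
# string, raw bytes (column per combo), translated amino acids (row per
# combo), and single-substitution sequon candidates. Cached for the default
# panel.
.germline_tables <- function(reference, v_names, d_names, j_names) {
  is_default <- identical(reference, germline_reference())
  if (is_default && !is.null(.immrep_cache$germ_tab)) {
    return(.immrep_cache$germ_tab)
  }
  ref_seq <- stats::setNames(reference$sequence, reference$gene)
  nd <- length(d_names)
  nj <- length(j_names)
  n_combo <- length(v_names) * nd * nj
  vi <- rep(seq_along(v_names), each = nd * nj)
  di <- rep(rep(seq_along(d_names), each = nj), times = length(v_names))
  ji <- rep(seq_along(j_names), times = length(v_names) * nd)
  nt <- paste0(ref_seq[v_names[vi]], ref_seq[d_names[di]],
               ref_seq[j_names[ji]])
  L <- nchar(nt[1])
  if (any(nchar(nt) != L)) {
    stop("germline reference genes must have constant per-segment lengths",
         call. = FALSE)
  }
  raw_mat <- matrix(unlist(lapply(nt, charToRaw)), nrow = L)
  aa_list <- vector("list", n_combo)
  cand <- vector("list", n_combo)
  for (i in seq_len(n_combo)) {
    ch <- strsplit(nt[i], "", fixed = TRUE)[[1]]
    aa_list[[i]] <- .translate_chars(ch)
    cc <- .sequon_candidates(ch)
    cand[[i]] <- list(pos = cc$pos, base = cc$base)
  }
  aa_mat <- do.call(rbind, aa_list)
  out <- list(nt = nt, raw_mat = raw_mat, aa_mat = aa_mat, cand = cand,
              len = L)
  if (is_default) .immrep_cache$germ_tab <- out
  out
}

# exact probability that one random substitution (uniform position, uniform
# non-identical base) in a uniform sense codon yields a stop codon
.stop_substitution_prob <- function() {
  hit <- .immrep_cache$q_stop
  if (!is.null(hit)) return(hit)
  bases <- c("A", "C", "G", "T")
  n_stop <- 0L
  for (cod in .sense_codons) {
    ch <- strsplit(cod, "")[[1]]
    for (p in 1:3) {
      for (b in setdiff(bases, ch[p])) {
        mut <- ch
        mut[p] <- b
        if (.codon_table[[paste(mut, collapse = "")]] == "*") {
          n_stop <- n_stop + 1L
        }
      }
    }
  }
  q <- n_stop / (length(.sense_codons) * 9)
  .immrep_cache$q_stop <- q
  q
}
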