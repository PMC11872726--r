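# programmatic fixtures: no data files, everything built in code

# minimal rearrangement record tibble with sensible defaults
make_records <- function(n = 1, sequence_id = sprintf("R%03d", seq_len(n)),
                         subject_id = "S001",
                         sequence = strrep("ACGT", 75),
                         germline_alignment = sequence,
                         v_call = "IGHV3-23*01", d_call = "IGHD3-10*01",
                         j_call = "IGHJ4*01", c_call = "IGHM",
                         junction_aa = "CARDYW", productive = TRUE,
                         duplicate_count = 1L) {
  tibble::tibble(sequence_id = sequence_id, subject_id = subject_id,
                 sequence = sequence, germline_alignment = germline_alignment,
                 v_call = v_call, d_call = d_call, j_call = j_call,
                 c_call = c_call, junction_aa = junction_aa,
                 productive = productive,
                 duplicate_count = as.integer(duplicate_count))
}

# small two-group simulated cohort for integration-style tests
tiny_cohort <- function(seed = 1L, ...) {
  simulate_cohort(simulation_config(
    group_sizes = c(HC = 4L, ME_mm = 4L),
    umi_range = c(400L, 600L), seed = seed, ...))
}

# random junction set with coarse alphabet so near-threshold distances occur
random_junctions <- function(n, len, alphabet = c("A", "R", "N", "D")) {
  vapply(seq_len(n), function(i) {
    paste(c("C", sample(alphabet, len - 2, replace = TRUE), "W"),
          collapse = "")
  }, character(1))
}
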