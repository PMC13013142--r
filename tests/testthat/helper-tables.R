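# Build a call table from a list of per-sequence duration vectors.
# `individuals` assigns each sequence to an individual (recycled).
make_table <- function(durations, individuals = "ind1", context = "test") {
  n <- lengths(durations)
  k <- length(durations)
  ind <- rep_len(individuals, k)
  call_table(data.frame(
    context = context,
    individual_id = rep.int(ind, n),
    sequence_id = rep.int(sprintf("s%03d", seq_len(k)), n),
    position = sequence(n),
    duration_s = unlist(durations, use.names = FALSE),
    stringsAsFactors = FALSE
  ))
}

# A quick mid-sized synthetic table for fit-level tests.
quick_synth <- function(seed = 1, n_seq = 200L, ...) {
  simulate_call_table(
    preset_config("trained_crow", sequences_per_individual = n_seq, ...),
    seed = seed)
}

# Location of the deposited benchmark dataset (not shipped with the
# package; see README for how to obtain and convert it).
deposited_path <- function(file) {
  dir <- Sys.getenv("MENZERATH_DEPOSITED_DATA",
                    testthat::test_path("deposited"))
  file.path(dir, file)
}

expect_deposited <- function(path) {
  if (!file.exists(path)) {
    fail(sprintf(
      "deposited benchmark dataset not available at '%s'; download it (DOI 10.6084/m9.figshare.31370020), convert to the canonical call-table CSV, and place it there (or set MENZERATH_DEPOSITED_DATA)",
      path))
    FALSE
  } else {
    TRUE
  }
}
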