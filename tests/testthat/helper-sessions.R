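# Small deterministic fixtures shared across test files. Everything is
# generated in code; nothing is read from disk.

# A label timeline with the standard run layout (lead-in rest, then one
# block per condition with rest separators), without generating any volume.
make_block_labels <- function(n_runs = 3L, conditions = c("A", "B"),
                              block_trs = 4L, rest_trs = 2L, seed = 1L) {
  set.seed(seed)
  run_len <- rest_trs + length(conditions) * (block_trs + rest_trs)
  cond <- character(run_len * n_runs)
  cond[] <- "REST"
  run <- rep(seq_len(n_runs), each = run_len)
  for (r in seq_len(n_runs)) {
    pos <- (r - 1L) * run_len + rest_trs
    for (cc in sample(conditions)) {
      cond[pos + seq_len(block_trs)] <- cc
      pos <- pos + block_trs + rest_trs
    }
  }
  label_timeline(tibble::tibble(run = run, condition = cond))
}

# A tiny session with injected condition patterns in one spherical region,
# suitable for classifier and connectivity tests.
tiny_session <- function(volume = c(10L, 10L, 10L), n_runs = 4L,
                         conditions = c("A", "B", "C", "D"),
                         block_trs = 4L, rest_trs = 2L,
                         base_snr = 4, noise_sd = 1, rng_seed = 7L,
                         region_center = c(5L, 5L, 5L), radius = 3,
                         base_mean = 0, delay = 0L) {
  spec <- synthetic_spec(
    volume_shape = volume, n_runs = n_runs, conditions = conditions,
    block_trs = block_trs, rest_trs = rest_trs,
    regions = list(region_spec("r1", region_center, radius,
                               base_snr = base_snr,
                               base_mean_amplitude = base_mean)),
    noise_sd = noise_sd, hemodynamic_delay_trs = delay,
    rng_seed = rng_seed)
  generate_subject(spec, 1L)
}

# Deterministic bold_dataset from an explicit voxels-x-TRs matrix.
dataset_from_matrix <- function(V, shape, run_of_tr, mask = NULL, ...) {
  bold_dataset(array(V, dim = c(shape, ncol(V))), run_of_tr, mask = mask, ...)
}
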