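# small deterministic fixtures built in code

tiny_grid <- function(n = 4L) log_diameter_grid(n, 20, 240)

# dataset with explicit values: days x replicates, percentages given per row
manual_dataset <- function(days, values_by_row, replicates = NULL, grid = NULL) {
  if (is.null(grid)) grid <- log_diameter_grid(ncol(values_by_row), 20, 240)
  if (is.null(replicates)) replicates <- rep(1L, length(days))
  cellsize_dataset(days, replicates, values_by_row, grid)
}

# lognormal-ish observation fixture: `k` period-bins of `m` positive values
obs_fixture <- function(seed, k = 3L, m = 4L) {
  set.seed(seed)
  lapply(seq_len(k), function(b) exp(rnorm(m, log(c(2, 4, 8, 1, 6)[b]), 0.2)))
}

quick_sim <- function(seed = 1, n_bins = 6L, ...) {
  sample_dataset(generator_config(grid = log_diameter_grid(n_bins), seed = seed, ...))
}
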