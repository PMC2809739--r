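#' Biopsy-day schedule of the longitudinal Zucker rat study
#'
#' The irregular schedule on which micro-biopsies were taken: days
#' 0, 2, 6, 9, 13, 23, 33, 57, 69, 86, 98, 134, 141, 150, 156, 162.
#' Data for animal 1 end at day 150 (14 time points); animal 2 has two
#' additional time points (days 156 and 162).
#'
#' @param animal 1 or 2.
#' @return Integer vector of biopsy days.
#' @examples
#' setdiff(biopsy_schedule(2), biopsy_schedule(1))  # 156 162
#' @export
biopsy_schedule <- function(animal = 2) {
  full <- c(0L, 2L, 6L, 9L, 13L, 23L, 33L, 57L, 69L, 86L, 98L, 134L, 141L, 150L, 156L, 162L)
  if (animal == 1) full[full <= 150L] else full
}

#' Configuration for the synthetic-data generator
#'
#' Describes the statistical structure the periodicity analysis assumes:
#' a bimodal diameter distribution (a small-cell and a large-cell lognormal
#' mode) whose small-mode weight varies periodically in time, sampled on an
#' irregular biopsy schedule with a fixed particle count per measurement and
#' replicate-level multiplicative noise.
#'
#' In `"piecewise_constant"` mode the small-mode weight is constant within
#' each of `n_period_bins_true` equal segments of the period and depends on
#' the day only through `floor(day / (true_period / n_period_bins_true)) %%
#' n_period_bins_true` -- exactly the exchangeability-within-period-bin
#' assumption of the inference model, so period recovery is a well-posed
#' test. The per-segment weights alternate between `base + amplitude` and
#' `base - amplitude` (with an odd segment count the alternation is
#' genuinely periodic at `true_period`, not at twice the segment length);
#' see the methods vignette for why slowly varying within-period patterns
#' are unsuitable for recovery experiments on sparse schedules. In `"smooth"` mode the weight follows a sinusoid in the day, a
#' stress test closer to real biology.
#'
#' @param grid Diameter grid, default the 80-bin 20--240 um grid.
#' @param schedule Biopsy days, default [biopsy_schedule()].
#' @param true_period Period of the modulation in days.
#' @param mode `"piecewise_constant"` or `"smooth"`.
#' @param n_period_bins_true Number of constant segments per period
#'   (piecewise mode).
#' @param small_mode,large_mode Length-2 vectors `(meanlog, sdlog)` of the
#'   small- and large-cell lognormal diameter components (diameters in um).
#' @param w_small_base,w_small_amplitude Baseline and modulation amplitude
#'   of the small-mode mixture weight; `base +/- amplitude` must stay in
#'   `[0, 1]`.
#' @param particles_per_measurement Particles counted per measurement.
#' @param replicates_per_day Replicate measurements per biopsy day.
#' @param replicate_overrides Optional named integer vector (names = days)
#'   overriding the replicate count on specific days.
#' @param measurement_noise_cv Coefficient of variation of the independent
#'   multiplicative lognormal per-bin noise applied after counting.
#' @param seed Master seed; all randomness derives from it.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(grid = log_diameter_grid(),
                             schedule = biopsy_schedule(),
                             true_period = 56,
                             mode = c("piecewise_constant", "smooth"),
                             n_period_bins_true = 7L,
                             small_mode = c(meanlog = log(35), sdlog = 0.25),
                             large_mode = c(meanlog = log(110), sdlog = 0.35),
                             w_small_base = 0.5,
                             w_small_amplitude = 0.2,
                             particles_per_measurement = 6000L,
                             replicates_per_day = 4L,
                             replicate_overrides = NULL,
                             measurement_noise_cv = 0.05,
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "diameter_grid"))
  if (true_period <= 0) stop("`true_period` must be positive", call. = FALSE)
  if (particles_per_measurement < 1) stop("need at least one particle", call. = FALSE)
  if (w_small_base - w_small_amplitude < 0 || w_small_base + w_small_amplitude > 1)
    stop("w_small_base +/- w_small_amplitude must stay within [0, 1]", call. = FALSE)
  if (measurement_noise_cv < 0) stop("`measurement_noise_cv` must be >= 0", call. = FALSE)
  structure(
    list(grid = grid, schedule = as.integer(schedule), true_period = true_period,
         mode = mode, n_period_bins_true = as.integer(n_period_bins_true),
         small_mode = small_mode, large_mode = large_mode,
         w_small_base = w_small_base, w_small_amplitude = w_small_amplitude,
         particles_per_measurement = as.integer(particles_per_measurement),
         replicates_per_day = as.integer(replicates_per_day),
         replicate_overrides = replicate_overrides,
         measurement_noise_cv = measurement_noise_cv,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# small-mode weight on a given day
w_small_at <- function(day, config) {
  with(config, {
    if (mode == "piecewise_constant") {
      seg <- true_period / n_period_bins_true
      j <- floor(day / seg) %% n_period_bins_true
      w_small_base + w_small_amplitude * (1 - 2 * (j %% 2))
    } else {
      w_small_base + w_small_amplitude * sin(2 * pi * day / true_period)
    }
  })
}

#' Noise-free cell-size distribution on a given day
#'
#' Mixture of the two lognormal diameter components with the day-dependent
#' small-mode weight, integrated over each grid bin and renormalised over
#' the measurable range.
#'
#' @param day Day (numeric).
#' @param config A [generator_config()].
#' @return Probability vector over the grid bins (sums to 1).
#' @export
true_distribution <- function(day, config) {
  stopifnot(inherits(config, "generator_config"))
  w <- w_small_at(day, config)
  if (w < 0 || w > 1) stop("small-mode weight escaped [0, 1]", call. = FALSE)
  e <- config$grid$edges
  ps <- diff(stats::plnorm(e, config$small_mode[[1]], config$small_mode[[2]]))
  pl <- diff(stats::plnorm(e, config$large_mode[[1]], config$large_mode[[2]]))
  p <- w * ps + (1 - w) * pl
  p / sum(p)
}

#' Sample a synthetic longitudinal dataset
#'
#' For each scheduled day and replicate, draws
#' `particles_per_measurement` particles from the day's true distribution
#' (multinomial over bins), applies independent multiplicative lognormal
#' per-bin noise with the configured coefficient of variation, and
#' renormalises to percentages. Fully deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with elements `dataset` (a [cellsize_dataset()]) and
#'   `truth` (list: `days`, matrix `p` of true per-day bin probabilities,
#'   `w_small` per day, `true_period`, `mode`).
#' @export
sample_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  nb <- config$grid$n_bins
  cv <- config$measurement_noise_cv
  sdlog <- sqrt(log1p(cv^2))
  days <- config$schedule
  p_true <- vapply(days, true_distribution, numeric(nb), config = config)

  day_col <- integer(0); rep_col <- integer(0); rows <- list()
  for (i in seq_along(days)) {
    nrep <- config$replicates_per_day
    ov <- config$replicate_overrides
    if (!is.null(ov) && as.character(days[i]) %in% names(ov))
      nrep <- as.integer(ov[[as.character(days[i])]])
    for (r in seq_len(nrep)) {
      counts <- as.numeric(stats::rmultinom(1, config$particles_per_measurement, p_true[, i]))
      if (cv > 0)
        counts <- counts * stats::rlnorm(nb, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      rows[[length(rows) + 1L]] <- normalize_to_percent(counts)
      day_col <- c(day_col, days[i]); rep_col <- c(rep_col, r)
    }
  }
  dataset <- cellsize_dataset(day_col, rep_col, do.call(rbind, rows),
                              config$grid, animal_id = "synthetic")
  truth <- list(days = days, p = t(p_true),
                w_small = vapply(days, w_small_at, numeric(1), config = config),
                true_period = config$true_period, mode = config$mode)
  list(dataset = dataset, truth = truth)
}
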