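#' Map biopsy days to period-bins
#'
#' A discrete periodic model divides a period of `n_bins * bin_width` days
#' into `n_bins` period-bins of `bin_width` days. The repeating bin pattern
#' is laid over the calendar with day 0 sitting `phase` days into the first
#' period-bin, and each biopsy day takes the bin number directly above it:
#' `floor((day + phase) / bin_width) %% n_bins`.
#'
#' @param days Sorted integer vector of biopsy days.
#' @param n_bins Number of period-bins.
#' @param bin_width Period-bin duration in days.
#' @param phase Integer in `[0, bin_width - 1]`.
#' @return Integer vector of period-bin indices (0-based), one per day.
#' @examples
#' assign_bins(biopsy_schedule(2), 7, 8, 7)
#' @export
assign_bins <- function(days, n_bins, bin_width, phase) {
  if (is.unsorted(days)) stop("`days` must be sorted ascending", call. = FALSE)
  if (phase < 0 || phase >= bin_width)
    stop("`phase` must lie in [0, bin_width - 1]", call. = FALSE)
  as.integer(((days + phase) %/% bin_width) %% n_bins)
}

#' Is a period-bin assignment testable?
#'
#' A model tests periodicity only if every period-bin receives biopsy days
#' that are not all contiguous in the day sequence: each bin index must
#' occur at least twice and its occurrence positions must not form one
#' single contiguous run. Otherwise apparent within-bin constancy could be
#' mere continuity of the underlying time course.
#'
#' @param assignment Integer vector of 0-based period-bin indices.
#' @param n_bins Number of period-bins of the model.
#' @return `TRUE` if every bin passes, else `FALSE`.
#' @examples
#' is_testable(c(0,0,0,0,1,1,2,3,0,2,2,3), 4)  # FALSE: bin 1 one run
#' is_testable(c(0,0,0,0,1,1,2,0,1,2,2,1), 3)  # TRUE
#' @export
is_testable <- function(assignment, n_bins) {
  for (b in seq_len(n_bins) - 1L) {
    pos <- which(assignment == b)
    if (length(pos) < 2L) return(FALSE)
    if (pos[length(pos)] - pos[1L] + 1L == length(pos)) return(FALSE)  # single run
  }
  TRUE
}

#' Model-space configuration
#'
#' Enumeration ranges and period bounds for [enumerate_models()]. The
#' defaults enumerate 2--10 period-bins of width 5--50 days and keep models
#' with periods in 30--100 days: shorter periods cannot be resolved by the
#' coarsest inter-biopsy gaps, longer ones are not repeated often enough
#' within the time course.
#'
#' @param n_bins_range,bin_width_range Inclusive integer ranges.
#' @param period_min,period_max Inclusive period bounds in days.
#' @return An object of class `"model_space_config"`.
#' @export
model_space_config <- function(n_bins_range = c(2L, 10L),
                               bin_width_range = c(5L, 50L),
                               period_min = 30, period_max = 100) {
  if (period_min >= period_max) stop("period_min must be < period_max", call. = FALSE)
  structure(list(n_bins_range = as.integer(n_bins_range),
                 bin_width_range = as.integer(bin_width_range),
                 period_min = period_min, period_max = period_max),
            class = "model_space_config")
}

new_periodic_model <- function(n_bins, assignment, combos, days) {
  periods <- n_bins * combos[, 1L]
  rep_combo <- combos[which.min(abs(periods - stats::median(periods))), ]
  structure(
    list(n_bins = as.integer(n_bins),
         bin_width = as.integer(rep_combo[[1L]]),
         phase = as.integer(rep_combo[[2L]]),
         assignment = as.integer(assignment),
         combos = combos,                     # generating (bin_width, phase) pairs
         period_min = min(periods), period_max = max(periods),
         period = (min(periods) + max(periods)) / 2,
         ambiguity = max(periods) - min(periods),
         days = as.integer(days),
         periodic = TRUE),
    class = "periodic_model"
  )
}

#' @export
print.periodic_model <- function(x, ...) {
  if (!x$periodic) {
    cat("<periodic_model> null model (no period): 1 bin\n")
  } else {
    cat(sprintf("<periodic_model> %d bins x %d d (phase %d), period %.1f d%s\n",
                x$n_bins, x$bin_width, x$phase, x$period,
                if (x$ambiguity > 0) sprintf(" (ambiguity %g d)", x$ambiguity) else ""))
    cat("  assignment:", paste(x$assignment, collapse = " "), "\n")
  }
  invisible(x)
}

#' The no-period model
#'
#' A single period-bin covering all days: all measurements are modelled as
#' draws from one common per-cell-size-bin lognormal. Its evidence is the
#' reference that periodic models must beat.
#'
#' @param days Sorted biopsy days.
#' @return A `"periodic_model"` with `n_bins = 1` and `periodic = FALSE`.
#' @export
null_model <- function(days) {
  if (length(days) < 1L) stop("`days` must be non-empty", call. = FALSE)
  structure(
    list(n_bins = 1L, bin_width = NA_integer_, phase = NA_integer_,
         assignment = integer(length(days)), combos = NULL,
         period_min = NA_real_, period_max = NA_real_, period = NA_real_,
         ambiguity = 0, days = as.integer(days), periodic = FALSE),
    class = "periodic_model"
  )
}

#' Enumerate, deduplicate and prune discrete periodic models
#'
#' Iterates over all `(n_bins, bin_width, phase)` combinations in the
#' configured ranges, computes each combination's day-to-bin assignment,
#' and merges combinations that are indistinguishable on the data, i.e.
#' share `(n_bins, assignment)`: such combinations imply the same grouping
#' of measurements and hence the same likelihood. Each merged model records
#' all generating `(bin_width, phase)` pairs; the spread of their periods
#' is the model's period ambiguity, and the representative period is the
#' midpoint of the generating-period range. Models are then pruned: the
#' assignment must be testable ([is_testable()]) and at least one
#' generating period must lie within `[period_min, period_max]`.
#'
#' @param days Sorted biopsy days (>= 2).
#' @param config A [model_space_config()].
#' @return List of `"periodic_model"` objects, sorted by representative
#'   period, then `n_bins`, then assignment; attributes `n_pre_pruning`
#'   (deduplicated model count before pruning) and `n_post_pruning`.
#' @export
enumerate_models <- function(days, config = model_space_config()) {
  if (length(days) < 2L) stop("need at least two biopsy days", call. = FALSE)
  days <- as.integer(days)
  reg <- new.env(parent = emptyenv())
  for (nb in seq(config$n_bins_range[1], config$n_bins_range[2])) {
    for (w in seq(config$bin_width_range[1], config$bin_width_range[2])) {
      # all phases at once: one column per phase
      a <- (outer(days, 0:(w - 1L), `+`) %/% w) %% nb
      keys <- paste0(nb, "|", apply(a, 2L, paste, collapse = ","))
      for (ph in seq_len(w)) {
        k <- keys[ph]
        hit <- reg[[k]]
        if (is.null(hit)) {
          reg[[k]] <- list(n_bins = nb, assignment = a[, ph],
                           combos = list(c(w, ph - 1L)))
        } else {
          hit$combos[[length(hit$combos) + 1L]] <- c(w, ph - 1L)
          reg[[k]] <- hit
        }
      }
    }
  }
  entries <- as.list(reg)
  n_pre <- length(entries)
  models <- list()
  for (e in entries) {
    if (!is_testable(e$assignment, e$n_bins)) next
    combos <- do.call(rbind, e$combos)
    colnames(combos) <- c("bin_width", "phase")
    periods <- e$n_bins * combos[, 1L]
    if (!any(periods >= config$period_min & periods <= config$period_max)) next
    models[[length(models) + 1L]] <- new_periodic_model(e$n_bins, e$assignment, combos, days)
  }
  ord <- order(vapply(models, `[[`, numeric(1), "period"),
               vapply(models, `[[`, integer(1), "n_bins"),
               vapply(models, function(m) paste(sprintf("%02d", m$assignment), collapse = ""),
                      character(1)))
  models <- models[ord]
  attr(models, "n_pre_pruning") <- n_pre
  attr(models, "n_post_pruning") <- length(models)
  attr(models, "config") <- config
  models
}

#' Period-ambiguity statistics of a model set
#'
#' @param models List of `"periodic_model"` objects (from
#'   [enumerate_models()]).
#' @return List with `mean` and `max` period ambiguity in days.
#' @export
ambiguity_stats <- function(models) {
  if (length(models) == 0L) stop("empty model list", call. = FALSE)
  amb <- vapply(models, `[[`, numeric(1), "ambiguity")
  list(mean = mean(amb), max = max(amb))
}

#' Export a model set as a data frame
#'
#' @param x List of models from [enumerate_models()].
#' @param ... Unused.
#' @return Data frame with one row per model (columns: `n_bins`,
#'   `bin_width`, `phase`, `period_min`, `period_max`,
#'   `representative_period`, `ambiguity`, `assignment` dash-joined).
#' @export
models_as_data_frame <- function(x, ...) {
  data.frame(
    n_bins = vapply(x, `[[`, integer(1), "n_bins"),
    bin_width = vapply(x, `[[`, integer(1), "bin_width"),
    phase = vapply(x, `[[`, integer(1), "phase"),
    period_min = vapply(x, `[[`, numeric(1), "period_min"),
    period_max = vapply(x, `[[`, numeric(1), "period_max"),
    representative_period = vapply(x, `[[`, numeric(1), "period"),
    ambiguity = vapply(x, `[[`, numeric(1), "ambiguity"),
    assignment = vapply(x, function(m) paste(m$assignment, collapse = "-"), character(1))
  )
}
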