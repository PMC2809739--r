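rat1_days <- biopsy_schedule(1)
rat2_days <- biopsy_schedule(2)

test_that("day-to-bin assignment follows the closed-form rule", {
  expect_identical(assign_bins(rat2_days, 7, 8, 7),
                   c(0L, 1L, 1L, 2L, 2L, 3L, 5L, 1L, 2L, 4L, 6L, 3L, 4L, 5L, 6L, 0L))
  expect_identical(assign_bins(rat1_days, 5, 11, 4),
                   c(0L, 0L, 0L, 1L, 1L, 2L, 3L, 0L, 1L, 3L, 4L, 2L, 3L, 4L))
  expect_identical(assign_bins(rat2_days, 1, 10, 0), rep(0L, 16L))
  expect_error(assign_bins(rat2_days, 7, 8, 8), "phase")
})

test_that("assignment is invariant under shifting days and phase by one bin width", {
  for (w in c(5L, 8L, 13L)) {
    a0 <- assign_bins(rat2_days, 4, w, 2)
    a1 <- assign_bins(rat2_days + w, 4, w, 2)
    expect_identical(a1, (a0 + 1L) %% 4L)  # cyclic relabelling only
  }
})

test_that("testability requires non-contiguous occurrences of every bin", {
  expect_false(is_testable(c(0, 0, 0, 0, 1, 1, 2, 3, 0, 2, 2, 3), 4))
  expect_true(is_testable(c(0, 0, 0, 0, 1, 1, 2, 0, 1, 2, 2, 1), 3))
  expect_false(is_testable(c(0, 0, 1), 3))           # bin 2 never assigned
  expect_false(is_testable(c(0, 1, 1, 1, 0, 0), 2))  # bin 1 one single run
})

test_that("enumeration deduplicates, prunes and orders deterministically", {
  models <- enumerate_models(rat1_days)
  # frozen regression values under the documented rule (enumerate 2-10 bins
  # x 5-50 d x all phases; dedup on (n_bins, assignment); keep testable
  # models with a generating period in [30, 100])
  expect_identical(attr(models, "n_pre_pruning"), 2366L)
  expect_identical(length(models), 393L)

  for (m in models) {
    expect_true(is_testable(m$assignment, m$n_bins))
    periods <- m$n_bins * m$combos[, "bin_width"]
    expect_true(any(periods >= 30 & periods <= 100))
    expect_equal(m$period, (min(periods) + max(periods)) / 2)
    expect_equal(m$ambiguity, max(periods) - min(periods))
  }
  pv <- vapply(models, `[[`, numeric(1), "period")
  expect_true(!is.unsorted(pv))

  # deduplication is a partition of the raw combinations
  n_combos <- sum(vapply(enumerate_models(rat2_days),
                         function(m) nrow(m$combos), integer(1)))
  expect_lte(n_combos, 9 * sum(5:50))
})

test_that("enumeration agrees with a brute-force oracle on a small range", {
  cfg <- model_space_config(n_bins_range = c(2L, 3L),
                            bin_width_range = c(5L, 10L),
                            period_min = 10, period_max = 30)
  days <- c(0L, 3L, 7L, 12L, 18L, 25L, 31L)
  models <- enumerate_models(days, cfg)

  # independent exhaustive enumeration
  reg <- list()
  for (nb in 2:3) for (w in 5:10) for (ph in 0:(w - 1)) {
    a <- ((days + ph) %/% w) %% nb
    key <- paste(nb, paste(a, collapse = ","))
    reg[[key]] <- c(reg[[key]], nb * w)
  }
  keep <- Filter(function(periods) any(periods >= 10 & periods <= 30), reg)
  keep <- keep[vapply(names(keep), function(k) {
    parts <- strsplit(k, " ")[[1]]
    a <- as.integer(strsplit(parts[2], ",")[[1]])
    is_testable(a, as.integer(parts[1]))
  }, logical(1))]
  expect_identical(length(models), length(keep))
  got <- sort(vapply(models, function(m)
    paste(m$n_bins, paste(m$assignment, collapse = ",")), character(1)))
  expect_identical(got, sort(names(keep)))
})

test_that("ambiguity statistics summarise the generating-period spreads", {
  fake <- lapply(c(1, 3), function(a) {
    m <- null_model(0:3); m$ambiguity <- a; m
  })
  s <- ambiguity_stats(fake)
  expect_equal(s$mean, 2)
  expect_equal(s$max, 3)
  expect_error(ambiguity_stats(list()), "empty")

  singleton <- enumerate_models(rat2_days)
  one <- Filter(function(m) nrow(m$combos) == 1L, singleton)
  expect_true(all(vapply(one, `[[`, numeric(1), "ambiguity") == 0))
})

test_that("the no-period model assigns every day to one bin", {
  nm <- null_model(rat2_days)
  expect_identical(nm$assignment, rep(0L, 16L))
  expect_false(nm$periodic)
  expect_identical(null_model(0L)$assignment, 0L)
})

test_that("days confined to a short window admit no testable model", {
  expect_error(enumerate_models(c(0L, 3L, 6L, 9L)), NA)
  short <- tryCatch(enumerate_models(c(0L, 2L, 5L, 8L, 10L)),
                    error = function(e) list())
  # all models on a 10-day window fail the period range / testability prune
  expect_identical(length(short), 0L)
})
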