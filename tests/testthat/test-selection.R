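fake_evidence <- function(model, logz, excluded = 6L) {
  structure(list(model = model, per_bin_logZ = logz, total_logZ = logz,
                 excluded_bin = excluded, engine = "pt", diagnostics = list()),
            class = "evidence_result")
}

fake_model <- function(period, n_bins = 2L, assignment = c(0L, 1L, 0L, 1L)) {
  structure(list(n_bins = n_bins, bin_width = as.integer(period / n_bins),
                 phase = 0L, assignment = assignment, combos = NULL,
                 period_min = period, period_max = period, period = period,
                 ambiguity = 0, days = c(0L, 10L, 20L, 30L), periodic = TRUE),
            class = "periodic_model")
}

test_that("ranking sorts by evidence with deterministic tie-breaks", {
  ms <- list(fake_model(40), fake_model(60), fake_model(80))
  r <- rank_models(Map(fake_evidence, ms, c(7, 10, 3)))
  expect_identical(r$entries$period, c(60, 40, 80))
  expect_equal(loglik_gap(r, 1, 3), 7)
  expect_equal(loglik_gap(r, 1, 1), 0)
  expect_gte(loglik_gap(r, 1, 2), 0)
  expect_error(loglik_gap(r, 1, 9), "out of range")

  one <- rank_models(list(fake_evidence(fake_model(50), 1)))
  expect_identical(nrow(one$entries), 1L)

  # equal evidence: smaller period first
  tie <- rank_models(Map(fake_evidence, list(fake_model(70), fake_model(35)), c(2, 2)))
  expect_identical(tie$entries$period, c(35, 70))

  expect_error(
    rank_models(list(fake_evidence(fake_model(40), 1, excluded = 1L),
                     fake_evidence(fake_model(50), 1, excluded = 2L))),
    "not comparable")
})

test_that("the period posterior is a normalised vote over 5-day intervals", {
  one <- rank_models(list(fake_evidence(fake_model(56), 0)))
  pp <- period_posterior(one)
  expect_equal(sum(pp$probability), 1, tolerance = 1e-9)
  expect_equal(pp$probability[pp$lo == 55], 1)

  two <- rank_models(Map(fake_evidence,
                         list(fake_model(40), fake_model(70)), c(5, 5)))
  pp2 <- period_posterior(two)
  expect_equal(pp2$probability[pp2$lo %in% c(40, 70)], c(0.5, 0.5))
  expect_identical(pp2$lo, seq(30, 95, by = 5))
  expect_identical(pp2$hi, seq(35, 100, by = 5))
})

test_that("period-bin profiles average the assigned measurements", {
  sim <- quick_sim(41)
  d <- sim$dataset
  models <- enumerate_models(d$days)
  best <- Filter(function(m) m$n_bins == 7L && m$bin_width == 8L && m$phase == 7L,
                 models)[[1]]
  prof <- period_bin_profiles(d, best)
  expect_identical(dim(prof), c(7L, 6L))
  expect_true(all(abs(rowSums(prof) - 100) < 1e-9))
  sel <- d$day %in% c(2L, 6L, 57L)   # period-bin 1 of the printed sequence
  expect_equal(unname(prof[2, ]), unname(colMeans(d$values[sel, ])))

  nullprof <- period_bin_profiles(d, null_model(d$days))
  expect_equal(unname(nullprof[1, ]), unname(mean_distribution(d)))
})

test_that("the fitted object exposes the best model and a coherent posterior", {
  sim <- quick_sim(42, n_bins = 5L)
  fit <- fit_periodicity(sim$dataset, pt = pt_config(preset = "reduced", seed = 2),
                         engine = "quadrature")
  expect_s3_class(fit, "period_fit")
  expect_equal(sum(fit$posterior$probability), 1, tolerance = 1e-9)
  expect_identical(unname(coef(fit)["period"]),
                   fit$ranking$entries$period[1])
  expect_lt(fit$null_logZ, fit$ranking$entries$total_logZ[1])
  expect_output(print(fit), "best model")
  s <- summary(fit)
  expect_output(print(s), "Period posterior")
})

test_that("pipeline runs are reproducible file for file", {
  sim <- quick_sim(43, n_bins = 4L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  pt <- pt_config(preset = "reduced", seed = 9)
  run_pipeline(sim$dataset, d1, pt = pt)
  run_pipeline(sim$dataset, d2, pt = pt)
  for (f in c("ranking.csv", "period_posterior.csv", "best_model_profiles.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "run_log.txt")))
})
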