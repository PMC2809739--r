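test_that("the lognormal log-density keeps its full normalising constant", {
  expect_equal(lognormal_loglik(1, 0, 1), -0.5 * log(2 * pi))
  expect_equal(lognormal_loglik(exp(1), 1, 1), -1 - 0.5 * log(2 * pi))
  set.seed(8)
  y <- exp(rnorm(20, 0.5, 0.4))
  expect_equal(lognormal_loglik(y, 0.5, 0.3),
               stats::dlnorm(y, 0.5, 0.3, log = TRUE))
  expect_error(lognormal_loglik(-1, 0, 1), "positive")
  expect_error(lognormal_loglik(1, 0, 0), "positive")
})

test_that("observations are grouped by period-bin with the zero floor applied", {
  sim <- quick_sim(31)
  d <- sim$dataset
  models <- enumerate_models(d$days)
  best <- Filter(function(m) m$n_bins == 7L && m$bin_width == 8L && m$phase == 7L,
                 models)[[1]]
  obs <- prepare_observations(d, best, 2L)
  expect_length(obs, 7L)
  group_days <- lapply(0:6, function(b) sum(best$assignment == b))
  expect_identical(vapply(obs, length, integer(1)),
                   vapply(group_days, function(k) 4L * k, integer(1)))
  # the day groups implied by the reference assignment sequence
  groups <- lapply(0:6, function(b) d$days[best$assignment == b])
  expect_identical(groups,
                   list(c(0L, 162L), c(2L, 6L, 57L), c(9L, 13L, 69L),
                        c(23L, 134L), c(86L, 141L), c(33L, 150L), c(98L, 156L)))

  nullobs <- prepare_observations(d, null_model(d$days), 1L)
  expect_length(nullobs, 1L)
  expect_length(nullobs[[1]], nrow(d$values))

  z <- manual_dataset(c(0L, 5L), rbind(c(0, 100), c(50, 50)),
                      grid = log_diameter_grid(2))
  floored <- prepare_observations(z, null_model(z$days), 1L)[[1]]
  expect_equal(min(floored), 100 * 0.5 / 6000)
  expect_equal(100 * 0.5 / 6000, 0.008333, tolerance = 1e-4)
})

test_that("quadrature evidence converges and matches a naive Monte Carlo oracle", {
  pr <- prior_spec()
  expect_identical(binwise_evidence_quadrature(list(numeric(0)), pr)[1], 0)

  set.seed(2)
  y <- exp(rnorm(5, log(3), 0.3))
  q <- binwise_evidence_quadrature(list(y), pr)[1]
  q_tight <- adipowaves:::group_logz_quadrature(y, pr, tol = 1e-6)
  expect_equal(q, q_tight, tolerance = 1e-3)

  # naive Monte Carlo over prior draws
  set.seed(77)
  N <- 2e5
  mu <- runif(N, pr$mu_low, pr$mu_high)
  sg <- pr$sigma_low * exp(runif(N) * log(pr$sigma_high / pr$sigma_low))
  n <- length(y); A <- sum(log(y)); B <- sum(log(y)^2)
  ll <- -A - n * log(sg) - 0.5 * n * log(2 * pi) -
    (B - 2 * mu * A + n * mu^2) / (2 * sg^2)
  w <- exp(ll - max(ll))
  mc <- log(mean(w)) + max(ll)
  se_log <- sd(w) / sqrt(N) / mean(w)
  expect_lt(abs(q - mc), 3 * se_log)
})

test_that("parallel-tempering evidence is deterministic given the seed", {
  obs <- obs_fixture(1)
  pt <- pt_config(preset = "reduced", seed = 42)
  a <- binwise_evidence_pt(obs, pt = pt)
  b <- binwise_evidence_pt(obs, pt = pt)
  expect_identical(a[1], b[1])
  expect_identical(attr(a, "per_bin"), attr(b, "per_bin"))
  c2 <- binwise_evidence_pt(obs, pt = pt_config(preset = "reduced", seed = 43))
  expect_false(identical(a[1], c2[1]))
})

test_that("a single-rung ladder degenerates with a warning", {
  obs <- obs_fixture(2, k = 1L)
  expect_warning(
    binwise_evidence_pt(obs, pt = pt_config(beta_ladder = 1, n_equilibration = 200L,
                                            n_samples = 100L, seed = 1)),
    "biased")
})

test_that("grouping cannot change a fixed-parameter likelihood", {
  sim <- quick_sim(32)
  d <- sim$dataset
  model <- enumerate_models(d$days)[[50]]
  mu <- 1.2; sigma <- 0.4
  obs_split <- prepare_observations(d, model, 3L)
  obs_null <- prepare_observations(d, null_model(d$days), 3L)
  ll_split <- sum(vapply(obs_split, function(y) sum(lognormal_loglik(y, mu, sigma)),
                         numeric(1)))
  expect_equal(ll_split, sum(lognormal_loglik(obs_null[[1]], mu, sigma)))
})

test_that("duplicating the data moves the evidence as the oracle predicts", {
  pr <- prior_spec()
  set.seed(9)
  y <- exp(rnorm(4, log(2), 0.25))
  q1 <- adipowaves:::group_logz_quadrature(y, pr)
  q2 <- adipowaves:::group_logz_quadrature(c(y, y), pr)
  pt <- pt_config(seed = 7)
  p1 <- binwise_evidence_pt(list(y), pr, pt)[1]
  p2 <- binwise_evidence_pt(list(c(y, y)), pr, pt)[1]
  expect_identical(sign(q2 - q1), sign(p2 - p1))
  expect_equal(p2 - p1, q2 - q1, tolerance = 0.2)
})

test_that("model evidence sums per-cell-size-bin terms and honours the excluded bin", {
  sim <- quick_sim(33, n_bins = 3L)
  d <- sim$dataset
  model <- enumerate_models(d$days)[[10]]
  pt <- pt_config(preset = "reduced", seed = 5)
  ev <- model_evidence(d, model, pt = pt)
  expect_length(ev$per_bin_logZ, 2L)      # 3-bin grid, last excluded
  expect_equal(ev$total_logZ, sum(ev$per_bin_logZ))

  ev0 <- model_evidence(d, model, pt = pt, excluded_bin = 1L)
  expect_false(isTRUE(all.equal(ev$total_logZ, ev0$total_logZ)))

  two <- quick_sim(34, n_bins = 2L)$dataset
  ev2 <- model_evidence(two, enumerate_models(two$days)[[10]], pt = pt)
  expect_length(ev2$per_bin_logZ, 1L)
})

test_that("the batched fit path reproduces per-model evidence calls exactly", {
  sim <- quick_sim(35, n_bins = 4L)
  d <- sim$dataset
  models <- enumerate_models(d$days)[c(3L, 77L)]
  pt <- pt_config(preset = "reduced", seed = 11)
  batch <- adipowaves:::evidence_all_models(d, models, prior_spec(), pt, "pt")
  for (i in seq_along(models)) {
    single <- model_evidence(d, models[[i]], pt = pt)
    expect_equal(batch$evidences[[i]]$total_logZ, single$total_logZ)
    expect_equal(batch$evidences[[i]]$per_bin_logZ, single$per_bin_logZ)
  }
  null_single <- model_evidence(d, null_model(d$days), pt = pt)
  expect_equal(batch$null_evidence$total_logZ, null_single$total_logZ)
})
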