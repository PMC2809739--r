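#' Parameters of the adipocyte recruitment oscillator
#'
#' A schematic three-compartment model of adipose tissue growth. Adipocytes
#' are small, medium or large (`N_s`, `N_m`, `N_l`); medium cells provide
#' the lipid uptake capacity `U = u * N_m`. When the flux of lipid needing
#' storage `L` exceeds `U`, PPAR signalling `P` rises (Heaviside switch,
#' with the maximal rate of increase of `P` numerically equal to its decay
#' rate `delta`); `P` drives recruitment of new small adipocytes, which
#' mature into the medium compartment and finally, at a rate proportional
#' to the lipid flux, fill up and join the large compartment:
#'
#' \deqn{dP/dt = \delta\,\theta(L - U) - \delta P}
#' \deqn{dN_s/dt = r P - g N_s}
#' \deqn{dN_m/dt = g N_s - k L N_m}
#' \deqn{dN_l/dt = k L N_m}
#'
#' with \eqn{\theta(0) = 1}. The alternation of hypertrophy (filling) and
#' hyperplasia (recruitment) makes this a relaxation oscillator. The
#' default parameters are pinned to produce sustained oscillations with a
#' period in the tens of days; they are a demonstration operating point of
#' this realisation, not fitted values.
#'
#' @param L Lipid flux needing storage (g/day).
#' @param delta PPAR decay rate (1/day).
#' @param r Recruitment rate (cell-number units/day per unit P).
#' @param g Small-to-medium maturation rate (1/day).
#' @param u Uptake capacity per medium cell (g/day per cell-number unit).
#' @param k Medium-to-large transition rate constant (1/(g day)); the
#'   transition rate is `k * L`.
#' @param heaviside_epsilon Smoothing width of the switch (0 = exact
#'   discontinuous Heaviside with event localisation).
#' @return An object of class `"adipo_params"`.
#' @export
adipo_params <- function(L = 1, delta = 0.25, r = 40, g = 0.12,
                         u = 0.02, k = 0.06, heaviside_epsilon = 0) {
  p <- list(L = L, delta = delta, r = r, g = g, u = u, k = k,
            heaviside_epsilon = heaviside_epsilon)
  if (any(unlist(p[1:6]) < 0)) stop("all rates must be non-negative", call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  structure(p, class = "adipo_params")
}

# switch function: exact Heaviside with theta(0) = 1, or logistic smoothing
theta_switch <- function(x, eps) {
  if (eps == 0) as.numeric(x >= 0) else stats::plogis(x / eps)
}

#' Right-hand side of the recruitment oscillator
#'
#' @param state Numeric vector `c(P, N_s, N_m, N_l)`, all non-negative.
#' @param params An [adipo_params()].
#' @return Named vector of time derivatives.
#' @export
adipo_derivatives <- function(state, params) {
  if (any(state < 0)) stop("state must be non-negative", call. = FALSE)
  P <- state[[1]]; N_s <- state[[2]]; N_m <- state[[3]]
  U <- params$u * N_m
  th <- theta_switch(params$L - U, params$heaviside_epsilon)
  c(P = params$delta * (th - P),
    N_s = params$r * P - params$g * N_s,
    N_m = params$g * N_s - params$k * params$L * N_m,
    N_l = params$k * params$L * N_m)
}

rhs_raw <- function(state, params) {
  P <- state[1L]; N_s <- state[2L]; N_m <- state[3L]
  U <- params$u * N_m
  th <- theta_switch(params$L - U, params$heaviside_epsilon)
  c(params$delta * (th - P),
    params$r * P - params$g * N_s,
    params$g * N_s - params$k * params$L * N_m,
    params$k * params$L * N_m)
}

rk4_step <- function(state, h, params) {
  k1 <- rhs_raw(state, params)
  k2 <- rhs_raw(state + h / 2 * k1, params)
  k3 <- rhs_raw(state + h / 2 * k2, params)
  k4 <- rhs_raw(state + h * k3, params)
  state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate the recruitment oscillator
#'
#' Fixed-step 4th-order Runge--Kutta integration. With
#' `heaviside_epsilon = 0` the right-hand side is discontinuous where
#' `L = U`; sign changes of `L - U` within a step are localised by
#' bisection (to 1e-8 on the switching function) and the step is split
#' there, so the integrator never averages across the switch. Fully
#' deterministic.
#'
#' @param params An [adipo_params()].
#' @param initial_state `c(P, N_s, N_m, N_l)` at time 0.
#' @param t_end Final time (days).
#' @param dt Output/integration step (days).
#' @return An object of class `"adipo_trajectory"`: data frame with
#'   columns `time`, `P`, `N_s`, `N_m`, `N_l`; `params` kept as attribute.
#' @export
simulate_adipo <- function(params, initial_state = c(P = 0, N_s = 0, N_m = 0, N_l = 0),
                           t_end = 400, dt = 0.02) {
  stopifnot(inherits(params, "adipo_params"))
  if (dt <= 0 || t_end <= 0) stop("`dt` and `t_end` must be positive", call. = FALSE)
  n_steps <- ceiling(t_end / dt)
  out <- matrix(NA_real_, n_steps + 1L, 4L)
  state <- as.numeric(initial_state)
  if (any(state < 0)) stop("initial state must be non-negative", call. = FALSE)
  out[1L, ] <- state
  gfun <- function(s) params$L - params$u * s[3L]
  exact <- params$heaviside_epsilon == 0
  for (i in seq_len(n_steps)) {
    remaining <- dt
    repeat {
      cand <- rk4_step(state, remaining, params)
      if (exact && sign_theta(gfun(cand)) != sign_theta(gfun(state)) && remaining > 1e-10) {
        # bisect the sub-step length to land on the switching surface
        lo <- 0; hi <- remaining
        for (it in 1:60) {
          mid <- (lo + hi) / 2
          gm <- gfun(rk4_step(state, mid, params))
          if (abs(gm) < 1e-8) break
          if (sign_theta(gm) == sign_theta(gfun(state))) lo <- mid else hi <- mid
        }
        state <- rk4_step(state, mid, params)
        remaining <- remaining - mid
        next
      }
      state <- cand
      break
    }
    if (any(state < -1e-9))
      stop("state became negative; decrease `dt`", call. = FALSE)
    state[state < 0] <- 0
    out[i + 1L, ] <- state
  }
  df <- data.frame(time = seq(0, by = dt, length.out = n_steps + 1L),
                   P = out[, 1L], N_s = out[, 2L], N_m = out[, 3L], N_l = out[, 4L])
  structure(df, class = c("adipo_trajectory", "data.frame"), params = params)
}

# theta(0) = 1: zero belongs with the positive branch
sign_theta <- function(x) if (x >= 0) 1L else -1L

#' @export
plot.adipo_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$P, type = "l", xlab = "time (d)", ylab = "PPAR level P")
  graphics::matplot(x$time, cbind(x$N_s, x$N_m, x$N_l), type = "l", lty = 1,
                    xlab = "time (d)", ylab = "compartment size")
  graphics::legend("topleft", c("N_s", "N_m", "N_l"), col = 1:3, lty = 1, bty = "n")
  invisible(x)
}

#' Estimate the oscillation period of a trajectory
#'
#' Discards the first quarter of the trajectory as transient, finds local
#' maxima above the post-transient median separated by at least one day,
#' and returns the mean inter-peak interval.
#'
#' @param trajectory An [simulate_adipo()] result.
#' @param variable One of `"P"`, `"N_s"`, `"N_m"`.
#' @return Period in days.
#' @export
estimate_period <- function(trajectory, variable = c("N_s", "P", "N_m")) {
  variable <- match.arg(variable)
  t <- trajectory$time
  keep <- t >= max(t) / 4
  tt <- t[keep]; x <- trajectory[[variable]][keep]
  med <- stats::median(x)
  n <- length(x)
  is_pk <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE) & x > med
  pk <- tt[is_pk]
  if (length(pk) > 1L) {  # enforce >= 1 day separation
    keep_pk <- c(TRUE, diff(pk) >= 1)
    while (!all(keep_pk)) {
      pk <- pk[keep_pk]
      keep_pk <- c(TRUE, diff(pk) >= 1)
    }
  }
  if (length(pk) < 3L)
    stop("fewer than three peaks: no period detectable", call. = FALSE)
  mean(diff(pk))
}

#' Oscillation period as a function of lipid flux
#'
#' Simulates the oscillator across a sweep of lipid-flux values and
#' estimates the recruitment period for each; fluxes for which no
#' oscillation is detected yield `NA` rather than an error.
#'
#' @param params Baseline [adipo_params()].
#' @param L_values Numeric vector of lipid-flux values.
#' @param t_end,dt Passed to [simulate_adipo()].
#' @return Data frame with columns `L` and `period` (days; `NA` where
#'   non-oscillatory).
#' @export
period_vs_flux <- function(params, L_values, t_end = 400, dt = 0.02) {
  period <- vapply(L_values, function(Lv) {
    p <- params; p$L <- Lv
    tryCatch(estimate_period(simulate_adipo(p, t_end = t_end, dt = dt)),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(L = L_values, period = period)
}
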