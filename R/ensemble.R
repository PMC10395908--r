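# Stochastic validation of the stationary solver: exact (Gillespie)
# simulation of a finite ensemble of motors pulling a rigid common filament
# against a constant external load, with instantaneous mechanical
# re-equilibration after every reaction event.

#' Filament shift balancing bound heads against a constant load
#'
#' Solves `sum_m U'(x_m + delta) = F_load` for the filament shift `delta`.
#' The total elastic force is non-decreasing in `delta` because the
#' potential is convex, so the root is unique.
#'
#' @param strains elongations of the currently bound heads (units of `d`).
#' @param pot an [elastic_potential].
#' @param F_load total external load on the ensemble (`kBT/d` units;
#'   positive loads oppose the working direction).
#' @return the shift `delta` (residual force balance below 1e-10).
#' @export
mechanical_equilibrate <- function(strains, pot, F_load) {
  if (length(strains) == 0)
    stop(structure(class = c("motorlimits_no_bound_error", "error", "condition"),
                   list(message = "no bound motors: force balance undefined",
                        call = sys.call(-1))))
  f <- function(delta) sum(potential_force(pot, strains + delta)) - F_load
  lo <- -1; hi <- 1
  it <- 0
  while (f(lo) > 0 && it < 200) { lo <- lo * 2; it <- it + 1 }
  it <- 0
  while (f(hi) < 0 && it < 200) { hi <- hi * 2; it <- it + 1 }
  uniroot(f, c(lo, hi), tol = 1e-13)$root
}

#' Gillespie simulation of a motor ensemble under constant load
#'
#' Exact stochastic simulation of `n_motors` motors sharing a rigid
#' filament. Event propensities use the strain-dependent rates at the
#' current strains; detached motors attach with total propensity equal to
#' the bare attachment rate, with the attachment strain drawn from the
#' Boltzmann density of the elastic element; after every event the filament
#' position re-equilibrates against the load (so `X(t)` is piecewise
#' constant). If all motors detach under load, the position is frozen until
#' the next attachment and the episode is counted.
#'
#' @param cycle a [motor_cycle]. Use a moderate hydrolysis rate (`k_hyd`)
#'   when building cycles for simulation; it sets the detached dwell (duty
#'   ratio) and hence the event rate, but not the efficiency.
#' @param pot an [elastic_potential].
#' @param n_motors ensemble size (>= 1).
#' @param F_load total external load (`kBT/d`).
#' @param t_end simulated time (rate units).
#' @param seed mandatory integer seed (identical seeds give identical
#'   traces).
#' @param burn_in fraction of `t_end` discarded by [trace_summary].
#' @param thin record every `thin`-th event.
#' @param max_events hard cap on the number of events (trace flagged as
#'   truncated if reached).
#' @return an `ensemble_trace`: data frame `events` (time, X, n_ATP, bound)
#'   plus the resolved configuration and event counters.
#' @export
simulate_ensemble <- function(cycle, pot, n_motors, F_load, t_end, seed,
                              burn_in = 0.2, thin = 1L, max_events = 5e6) {
  stopifnot(inherits(cycle, "motor_cycle"), inherits(pot, "elastic_potential"))
  if (n_motors < 1) stop_invalid("N_m >= 1", "need at least one motor")
  if (t_end <= 0) stop_invalid("t_end > 0", "simulation time must be positive")
  if (missing(seed) || is.null(seed))
    stop_invalid("seed", "a seed is mandatory for reproducibility")
  set.seed(seed)

  pot_spec <- list(
    kind = match(pot$kind, c("harmonic", "two_regime", "piecewise")) - 1L,
    kappa = pot$kappa, x_a = pot$x_a %||% 0,
    breakpoints = pot$breakpoints %||% numeric(0),
    curvatures = pot$curvatures %||% numeric(0),
    slope_knots = pot$slope_knots %||% numeric(0),
    energy_knots = pot$energy_knots %||% numeric(0))

  # tabulated inverse-CDF of the Boltzmann attachment strain (non-harmonic)
  if (pot$kind == "harmonic") {
    att_x <- att_cdf <- numeric(0)
  } else {
    lim <- function(dir) {
      x <- dir
      while (potential_energy(pot, x) < 40) x <- x * 2
      x
    }
    xs <- seq(lim(-1), lim(1), length.out = 8192)
    dens <- boltzmann_density(pot, xs)
    cdf <- cumsum(dens)
    cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
    keep <- c(TRUE, diff(cdf) > 0)
    att_x <- xs[keep]; att_cdf <- cdf[keep]
  }

  raw <- gillespie_run(cycle$n_bound, cycle$G, cycle$d, cycle$alpha,
                       cycle$k0, cycle$dG_ATP, pot_spec,
                       as.integer(n_motors), F_load, t_end,
                       att_x, att_cdf, as.integer(thin),
                       as.integer(max_events))
  events <- data.frame(time = raw$time, X = raw$X, n_ATP = raw$n_ATP,
                       bound = raw$bound)
  structure(list(events = events, n_events = raw$n_events,
                 all_detached_episodes = raw$all_detached_episodes,
                 truncated = raw$truncated, t_final = raw$t_final,
                 config = list(cycle = cycle, potential = pot,
                               n_motors = n_motors, F_load = F_load,
                               t_end = t_end, seed = seed,
                               burn_in = burn_in, thin = thin)),
            class = "ensemble_trace")
}

#' @export
print.ensemble_trace <- function(x, ...) {
  cat(sprintf("<ensemble_trace> N_m = %d, F_load = %g, t = %g, %g events (%d recorded)\n",
              x$config$n_motors, x$config$F_load, x$t_final, x$n_events,
              nrow(x$events)))
  if (x$truncated) cat("  [truncated at max_events]\n")
  invisible(x)
}

#' Summary statistics of an ensemble trace
#'
#' Computes, over the post-burn-in window: the sliding velocity (negative
#' least-squares slope of `X(t)`, so positive in the working direction), the
#' ATPase rate per motor, and the efficiency
#' `F_load * (-dX) / (n_ATP * |dG_ATP|)`. Standard errors come from a block
#' bootstrap over equal-time blocks.
#'
#' @param trace an `ensemble_trace`.
#' @param burn_in fraction of the simulated time discarded (defaults to the
#'   value stored in the trace).
#' @param n_blocks number of time blocks.
#' @param n_boot bootstrap resamples.
#' @return list with `velocity`, `r_ATPase`, `efficiency`, their standard
#'   errors, and window bookkeeping.
#' @export
trace_summary <- function(trace, burn_in = NULL, n_blocks = 20, n_boot = 200) {
  stopifnot(inherits(trace, "ensemble_trace"))
  burn_in <- burn_in %||% trace$config$burn_in
  ev <- trace$events
  t0 <- burn_in * trace$config$t_end
  w <- ev[ev$time >= t0, ]
  if (nrow(w) < 100)
    stop("fewer than 100 events after burn-in; extend t_end")
  g <- -trace$config$cycle$dG_ATP
  nm <- trace$config$n_motors
  f <- trace$config$F_load

  span <- diff(range(w$time))
  velocity <- -unname(coef(lm(X ~ time, data = w))[2])
  dX <- w$X[nrow(w)] - w$X[1]
  dATP <- w$n_ATP[nrow(w)] - w$n_ATP[1]
  r_atpase <- dATP / (span * nm)
  eff <- if (dATP > 0 && g > 0) f * (-dX) / (dATP * g) else 0

  # block bootstrap on equal-time blocks: per-block displacement and ATP
  # increments are resampled and recombined into velocity / efficiency
  edges <- seq(w$time[1], w$time[nrow(w)], length.out = n_blocks + 1)
  idx <- findInterval(w$time, edges, rightmost.closed = TRUE)
  bl <- lapply(seq_len(n_blocks), function(b) {
    rows <- which(idx == b)
    if (length(rows) < 2) return(NULL)
    list(dX = w$X[rows[length(rows)]] - w$X[rows[1]],
         dATP = w$n_ATP[rows[length(rows)]] - w$n_ATP[rows[1]],
         dt = w$time[rows[length(rows)]] - w$time[rows[1]])
  })
  bl <- Filter(Negate(is.null), bl)
  if (length(bl) >= 4) {
    boots <- replicate(n_boot, {
      pick <- sample(length(bl), replace = TRUE)
      sdX <- sum(vapply(bl[pick], `[[`, numeric(1), "dX"))
      sATP <- sum(vapply(bl[pick], `[[`, numeric(1), "dATP"))
      sdt <- sum(vapply(bl[pick], `[[`, numeric(1), "dt"))
      c(v = -sdX / sdt,
        eta = if (sATP > 0 && g > 0) f * (-sdX) / (sATP * g) else 0)
    })
    se_v <- stats::sd(boots["v", ])
    se_eta <- stats::sd(boots["eta", ])
  } else {
    se_v <- NA_real_; se_eta <- NA_real_
  }
  list(velocity = velocity, r_ATPase = r_atpase, efficiency = eff,
       se_velocity = se_v, se_efficiency = se_eta,
       n_events_window = nrow(w), window = range(w$time),
       work = f * (-dX), n_ATP = dATP)
}
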