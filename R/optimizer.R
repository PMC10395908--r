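# Constrained efficiency optimization: scenarios, multi-start drivers,
# continuation scans, and functional optimization of the elastic potential.

#' Define an optimization scenario
#'
#' A scenario fixes the physically constrained quantities (number of bound
#' states, free energy of ATP hydrolysis, stiffness cap, rate caps) and
#' declares which remaining parameters are free, mirroring the three study
#' designs:
#'
#' * `"free_velocity"`: the sliding velocity is itself an optimization
#'   parameter; efficiency is evaluated at the peak of the eta-v relation.
#' * `"fixed_force_stable"`: as above, but the operating point must lie
#'   outside the hysteresis of the force-velocity relation, so that the
#'   operating force maps to a unique velocity (stability under constant
#'   load).
#' * `"fixed_velocity"`: efficiency is maximized at a prescribed velocity
#'   with caps on the ATP-induced detachment rate and on ADP binding
#'   (expressed as the ratio `k_ADP_binding*[ADP] / (k_ATP_binding*[ATP])`).
#'
#' Free parameters (per the scenario) are: velocity, the free energies of
#' bound states 2..N_B, the load-distribution coefficients of the
#' bound-bound transitions, the bare rates (in log space), the intermediate
#' lever positions, and the stiffness up to its cap. Fixed by convention:
#' `G_1 = 0`, `G_{N_B+1} = dG_ATP`, `alpha_attach = 1`, `alpha_detach = 0`,
#' `d_1 = 1`, `d_{N_B} = 0`, and in free-velocity scenarios the detachment
#' rate equals the rate unit.
#'
#' @param name scenario name (see above).
#' @param n_bound number of bound states.
#' @param dG_ATP free energy of ATP hydrolysis in `kBT` (non-positive).
#' @param half_kappa_cap upper bound on the dimensionless stiffness
#'   `K d^2 / (2 kBT)`.
#' @param detach_rate_cap cap on the ATP-induced detachment rate in rate
#'   units (the unit itself, so 1 by default).
#' @param adp_ratio_cap cap on `k_ADP_binding*[ADP]` relative to the rate
#'   unit (`Inf` disables the cap; the physiological estimate is ~1/100).
#'   Only used by fixed-velocity scenarios, where it indirectly bounds the
#'   bare rate of the ADP-release transition through detailed balance.
#' @param v_target prescribed dimensionless velocity (fixed-velocity only).
#' @param potential_mode `"harmonic"`, `"two_regime"` or `"piecewise"`.
#' @param n_segments number of segments for piecewise potentials.
#' @param segment_window strain window covered by the segments.
#' @param k_hyd hydrolysis rate between the detached pools.
#' @return object of class `motor_scenario`.
#' @export
motor_scenario <- function(name = c("free_velocity", "fixed_force_stable",
                                    "fixed_velocity"),
                           n_bound, dG_ATP = -25, half_kappa_cap = 40,
                           detach_rate_cap = 1, adp_ratio_cap = Inf,
                           v_target = NULL,
                           potential_mode = c("harmonic", "two_regime",
                                              "piecewise"),
                           n_segments = 16, segment_window = c(-1.5, 1.5),
                           k_hyd = 1e5) {
  name <- match.arg(name)
  potential_mode <- match.arg(potential_mode)
  if (n_bound < 2) stop_invalid("n_bound", "need at least two bound states")
  if (half_kappa_cap <= 0 || detach_rate_cap <= 0 || adp_ratio_cap <= 0)
    stop_invalid("caps > 0", "all caps must be positive")
  if (dG_ATP > 0) stop_invalid("dG_ATP <= 0", "dG_ATP must be non-positive")
  if (name == "fixed_velocity") {
    if (is.null(v_target) || v_target <= 0)
      stop_invalid("v_target > 0",
                   "fixed-velocity scenarios need a positive target velocity")
  } else if (!is.null(v_target)) {
    stop_invalid("v_target", "v_target only applies to fixed-velocity scenarios")
  }
  structure(list(name = name, n_bound = as.integer(n_bound), dG_ATP = dG_ATP,
                 half_kappa_cap = half_kappa_cap,
                 detach_rate_cap = detach_rate_cap,
                 adp_ratio_cap = adp_ratio_cap, v_target = v_target,
                 potential_mode = potential_mode,
                 n_segments = as.integer(n_segments),
                 segment_window = segment_window, k_hyd = k_hyd),
            class = "motor_scenario")
}

#' @export
print.motor_scenario <- function(x, ...) {
  cat(sprintf("<motor_scenario> %s, N_B = %d, -dG_ATP = %g, kappa/2 <= %g, potential: %s\n",
              x$name, x$n_bound, -x$dG_ATP, x$half_kappa_cap, x$potential_mode))
  if (!is.null(x$v_target)) cat(sprintf("  v_target = %g\n", x$v_target))
  invisible(x)
}

# Parameter table for a scenario: names, box bounds, and the sub-box from
# which multi-starts are drawn. Rates are optimized in log space; lever
# positions via ordered fractions; alpha and stiffness via plain boxes.
par_spec <- function(scn) {
  nb <- scn$n_bound
  rows <- list()
  add <- function(name, lower, upper, s_lo = lower, s_hi = upper)
    rows[[length(rows) + 1]] <<- data.frame(name = name, lower = lower,
                                            upper = upper, s_lo = s_lo,
                                            s_hi = s_hi)
  if (scn$name != "fixed_velocity")
    add("log_v", log(1e-6), log(10), log(5e-4), log(1))
  for (i in 2:nb)          # published indexing convention: bound-state free energies
    add(paste0("G", i), scn$dG_ATP - 10, 10, scn$dG_ATP, 0)
  for (i in 1:(nb - 1))    # bound-bound load distribution coefficients
    add(paste0("alpha", i), 0, 1, 0, 1)
  if (scn$name == "fixed_velocity") {
    for (i in 0:(nb - 2))
      add(paste0("log_k", i), log(1e-4), log(1e9), log(0.1), log(1e8))
    cap_q <- if (is.finite(scn$adp_ratio_cap)) log(scn$adp_ratio_cap) else log(1e9)
    add("log_kADP", log(1e-9), cap_q, cap_q - 12, cap_q)
    add("log_kdet", log(1e-4), log(scn$detach_rate_cap),
        log(scn$detach_rate_cap) - 6, log(scn$detach_rate_cap))
  } else {
    for (i in 0:(nb - 1))
      add(paste0("log_k", i), log(1e-4), log(1e9), log(0.1), log(1e8))
  }
  if (nb > 2)
    for (i in 2:(nb - 1))  # ordered fractions: d_i = s_i * d_{i-1}
      add(paste0("s", i), 0, 1, 0.05, 0.95)
  if (scn$potential_mode == "piecewise") {
    for (j in seq_len(scn$n_segments))
      add(paste0("curv", j), 0, 2 * scn$half_kappa_cap,
          0.1 * scn$half_kappa_cap, 2 * scn$half_kappa_cap)
  } else {
    # stiffness is optimized in log space: optimal values span decades
    # (from the soft near-equilibrium regime to caps in the hundreds)
    add("log_half_kappa", log(max(1e-3, 1e-4 * scn$half_kappa_cap)),
        log(scn$half_kappa_cap), log(scn$half_kappa_cap / 100),
        log(scn$half_kappa_cap))
    if (scn$potential_mode == "two_regime") add("x_a", -3, 0, -1, -0.05)
  }
  do.call(rbind, rows)
}

# Assemble (cycle, potential, velocity) from a parameter vector.
build_model <- function(scn, th, spec = par_spec(scn)) {
  p <- setNames(as.numeric(th), spec$name)
  nb <- scn$n_bound
  ns <- nb + 2L
  G <- numeric(ns)
  G[ns] <- scn$dG_ATP
  for (i in 2:nb) G[i + 1L] <- p[[paste0("G", i)]]
  alpha <- c(1, vapply(1:(nb - 1), function(i) p[[paste0("alpha", i)]],
                       numeric(1)), 0, 0)
  d <- numeric(ns)
  d[1] <- d[2] <- 1
  if (nb > 2) for (i in 2:(nb - 1)) d[i + 1L] <- d[i] * p[[paste0("s", i)]]
  k0 <- numeric(ns)
  if (scn$name == "fixed_velocity") {
    for (i in 0:(nb - 2)) k0[i + 1L] <- exp(p[[paste0("log_k", i)]])
    # ADP binding cap acts on the reverse of the ADP-release transition;
    # detailed balance then bounds its bare forward rate
    k0[nb] <- exp(p[["log_kADP"]] - (G[nb + 1L] - G[nb]))
    k0[nb + 1L] <- exp(p[["log_kdet"]])
    v <- scn$v_target
  } else {
    for (i in 0:(nb - 1)) k0[i + 1L] <- exp(p[[paste0("log_k", i)]])
    k0[nb + 1L] <- scn$detach_rate_cap
    v <- exp(p[["log_v"]])
  }
  k0[ns] <- scn$k_hyd
  cycle <- motor_cycle(nb, G = G, d = d, alpha = alpha, k0 = k0,
                       dG_ATP = scn$dG_ATP)
  pot <- switch(scn$potential_mode,
    harmonic = elastic_potential("harmonic",
                                 kappa = 2 * exp(p[["log_half_kappa"]])),
    two_regime = elastic_potential("two_regime",
                                   kappa = 2 * exp(p[["log_half_kappa"]]),
                                   x_a = min(p[["x_a"]], 0)),
    piecewise = {
      M <- scn$n_segments
      bp <- seq(scn$segment_window[1], scn$segment_window[2],
                length.out = M + 1)
      cv <- vapply(seq_len(M), function(j) p[[paste0("curv", j)]], numeric(1))
      elastic_potential("piecewise", kappa = 2 * scn$half_kappa_cap,
                        breakpoints = bp, curvatures = cv)
    })
  list(cycle = cycle, pot = pot, v = v)
}

# Efficiency objective (to minimize). Any validation/solver failure maps to
# a large value; the optimizer simply avoids those regions.
scenario_objective <- function(scn, spec = par_spec(scn)) {
  force(scn); force(spec)
  function(th) {
    if (any(th < spec$lower - 1e-9) || any(th > spec$upper + 1e-9))
      return(2 + sum(pmax(0, spec$lower - th)) + sum(pmax(0, th - spec$upper)))
    out <- tryCatch({
      m <- build_model(scn, th, spec)
      f <- solve_stationary(m$cycle, m$pot, m$v, detail = FALSE)
      # reject numerically untrustworthy corners: a cycle flux at the
      # cancellation floor or a poorly conserved flux makes eta meaningless
      if (!is.finite(f$eta) || f$eta > 0.999 ||
          f$residuals["flux"] > 1e-5 || f$r_ATPase < 1e-9) 2 else -f$eta
    }, error = function(e) 2)
    out
  }
}

# Latin-hypercube multi-start driver with bounded quasi-Newton refinement
# and simplex polish of the best candidates.
multistart_optimize <- function(scn, fn, starts, seed, init = NULL,
                                spec = par_spec(scn),
                                maxit_qn = 150, maxit_polish = 800,
                                n_polish = 3) {
  set.seed(seed)
  p <- nrow(spec)
  U <- lhs::randomLHS(max(starts, 1L), p)
  TH <- t(apply(U, 1, function(u) spec$s_lo + u * (spec$s_hi - spec$s_lo)))
  if (p == 1) TH <- matrix(TH, ncol = 1)
  if (!is.null(init)) {
    init <- if (is.list(init) && !is.data.frame(init)) do.call(rbind, init)
            else matrix(init, ncol = p, byrow = FALSE)
    init <- matrix(pmin(pmax(t(init), spec$lower), spec$upper), ncol = p,
                   byrow = TRUE)
    TH <- rbind(init, TH)
  }
  runs <- vector("list", nrow(TH))
  for (i in seq_len(nrow(TH))) {
    o <- tryCatch(
      optim(TH[i, ], fn, method = "L-BFGS-B", lower = spec$lower,
            upper = spec$upper,
            control = list(maxit = maxit_qn, factr = 1e8,
                           ndeps = rep(1e-5, p))),
      error = function(e) list(par = TH[i, ], value = fn(TH[i, ]),
                               convergence = 99L))
    runs[[i]] <- o
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  for (i in utils::head(order(vals), n_polish)) {
    o <- optim(runs[[i]]$par, fn, method = "Nelder-Mead",
               control = list(maxit = maxit_polish, reltol = 1e-9))
    if (o$value < runs[[i]]$value) runs[[i]] <- o
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  if (min(vals) >= 2)
    stop("no optimization start converged to a valid model; ",
         "check scenario caps and bounds")
  best <- runs[[which.min(vals)]]
  diag <- data.frame(start = seq_along(runs), value = vals,
                     convergence = vapply(runs, function(r)
                       as.integer(r$convergence %||% 0L), integer(1)))
  list(theta = best$par, value = best$value, diagnostics = diag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Package the optimizer state into a reported optimum, re-evaluated through
# the stationary solver (the report must reproduce eta when re-run).
make_optimum <- function(scn, theta, diagnostics, spec = par_spec(scn),
                         extra = list()) {
  m <- build_model(scn, theta, spec)
  f <- solve_stationary(m$cycle, m$pot, m$v)
  nb <- scn$n_bound
  # K_D^ADP/[ADP] = exp(G_ADPstate - G_rigor): the penultimate bound state
  # (1-based index nb) releases ADP into the rigor state (index nb + 1)
  kd <- exp(m$cycle$G[nb] - m$cycle$G[nb + 1L])
  out <- c(list(
    eta_max = f$eta, v_star = m$v,
    cycle = m$cycle, potential = m$pot, field = f,
    theta = setNames(as.numeric(theta), spec$name),
    K_D_ADP = kd,
    scenario = scn, diagnostics = diagnostics), extra)
  class(out) <- "motor_optimum"
  out
}

#' @export
print.motor_optimum <- function(x, ...) {
  cat(sprintf("<motor_optimum> %s: eta_max = %.4f at v = %.4g\n",
              x$scenario$name, x$eta_max, x$v_star))
  cat("  theta:\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Maximize efficiency with free velocity
#'
#' Maximizes the peak efficiency of the eta-v relation over all free model
#' parameters (velocity, free energies, rate ratios, load-distribution
#' coefficients, lever positions and stiffness up to its cap) by seeded
#' Latin-hypercube multi-start: bounded quasi-Newton refinement of every
#' start followed by simplex polish of the best candidates.
#'
#' @param scenario a [motor_scenario] with name `"free_velocity"`.
#' @param starts number of multi-starts.
#' @param seed integer seed (fixed seed implies identical trajectories and
#'   an identical reported optimum).
#' @param init optional matrix/list of additional start vectors (e.g. from a
#'   continuation neighbour).
#' @return a `motor_optimum` with the best parameters, `eta_max`, `v_star`,
#'   the ADP dissociation constant implied by the last bound transition, and
#'   per-start diagnostics.
#' @export
maximize_free_velocity <- function(scenario, starts = 20, seed = 1,
                                   init = NULL) {
  stopifnot(inherits(scenario, "motor_scenario"))
  if (scenario$name != "free_velocity")
    stop("scenario must have name 'free_velocity'")
  spec <- par_spec(scenario)
  fn <- scenario_objective(scenario, spec)
  res <- multistart_optimize(scenario, fn, starts, seed, init, spec)
  make_optimum(scenario, res$theta, res$diagnostics, spec)
}

# Penalized objective for the fixed-force stability constraint: the force at
# the operating point must lie strictly below the force anywhere on the
# slower branch, F(v*) <= min_{v < v*} F(v) - delta, so that the operating
# force maps to a unique velocity under constant load.
stability_violation <- function(scn, th, spec, n_vgrid = 25, delta = 1e-4) {
  m <- build_model(scn, th, spec)
  vstar <- m$v
  # log-spaced points cover the near-stall region (the slow branch often
  # attains its minimum force as v -> 0), linear points the rest
  n_lo <- max(4L, n_vgrid %/% 4L)
  vg <- c(exp(seq(log(1e-4), log(0.15 * vstar), length.out = n_lo)),
          seq(0.2 * vstar, vstar, length.out = n_vgrid - n_lo))
  Fs <- vapply(vg, function(v)
    tryCatch(solve_stationary(m$cycle, m$pot, v, detail = FALSE)$F,
             error = function(e) NA_real_),
    numeric(1))
  if (any(!is.finite(Fs))) return(list(viol = Inf, eta = -2))
  fstar <- Fs[n_vgrid]
  eta <- solve_stationary(m$cycle, m$pot, vstar, detail = FALSE)$eta
  list(viol = fstar - (min(Fs[-n_vgrid]) - delta), eta = eta)
}

#' Maximize efficiency constrained to stable fixed-force operation
#'
#' As [maximize_free_velocity], but the operating point is required to lie
#' outside the hysteresis of the force-velocity relation: on a velocity grid
#' below the operating point, the operating force must be strictly smaller
#' than the force anywhere on the slower branch. The nonlinear constraint is
#' enforced by sequential quadratic-penalty passes (increasing penalty
#' weight, warm-started), each solved with the bounded multi-start
#' quasi-Newton driver.
#'
#' @inheritParams maximize_free_velocity
#' @param scenario a [motor_scenario] with name `"fixed_force_stable"`.
#' @param n_vgrid number of velocity points used to trace the slower branch.
#' @param delta force margin defining strict stability.
#' @param mu penalty weights of the successive passes.
#' @return a `motor_optimum`; element `constraint` reports the final
#'   violation (<= 0 means feasible) and whether the constraint is active.
#' @export
maximize_fixed_force_stable <- function(scenario, starts = 4, seed = 1,
                                        init = NULL, n_vgrid = 16,
                                        delta = 1e-4, mu = c(200, 2e4)) {
  stopifnot(inherits(scenario, "motor_scenario"))
  if (scenario$name != "fixed_force_stable")
    stop("scenario must have name 'fixed_force_stable'")
  spec <- par_spec(scenario)
  pen_fn <- function(w) {
    function(th) {
      if (any(th < spec$lower - 1e-9) || any(th > spec$upper + 1e-9))
        return(2 + sum(pmax(0, spec$lower - th)) + sum(pmax(0, th - spec$upper)))
      out <- tryCatch({
        sv <- stability_violation(scenario, th, spec, n_vgrid, delta)
        if (!is.finite(sv$eta) || sv$eta < -1) 2
        else -sv$eta + w * max(0, sv$viol)^2
      }, error = function(e) 2)
      out
    }
  }
  res <- multistart_optimize(scenario, pen_fn(mu[1]), starts, seed, init,
                             spec, maxit_qn = 40, maxit_polish = 200,
                             n_polish = 2)
  for (w in mu[-1]) {
    res2 <- multistart_optimize(scenario, pen_fn(w), starts = 0, seed = seed,
                                init = rbind(res$theta), spec = spec,
                                maxit_qn = 40, maxit_polish = 200,
                                n_polish = 1)
    res <- res2
  }
  sv <- stability_violation(scenario, res$theta, spec, n_vgrid, delta)
  make_optimum(scenario, res$theta, res$diagnostics, spec,
               extra = list(constraint = list(
                 violation = sv$viol, feasible = sv$viol <= 1e-3,
                 active = sv$viol > -0.05)))
}

#' Maximize efficiency at a prescribed velocity
#'
#' Fixed-velocity scenario: the sliding velocity is given and the caps on
#' the ATP-induced detachment rate and on ADP binding restrict the kinetics.
#' The ADP-binding cap constrains the reverse rate of the ADP-release
#' transition, which through detailed balance bounds its bare forward rate
#' given the free-energy difference of the transition.
#'
#' @inheritParams maximize_free_velocity
#' @param scenario a [motor_scenario] with name `"fixed_velocity"`.
#' @param v_target optional override of the scenario's target velocity.
#' @return a `motor_optimum`.
#' @export
maximize_at_velocity <- function(scenario, v_target = NULL, starts = 12,
                                 seed = 1, init = NULL) {
  stopifnot(inherits(scenario, "motor_scenario"))
  if (scenario$name != "fixed_velocity")
    stop("scenario must have name 'fixed_velocity'")
  if (!is.null(v_target)) scenario$v_target <- v_target
  spec <- par_spec(scenario)
  fn <- scenario_objective(scenario, spec)
  res <- multistart_optimize(scenario, fn, starts, seed, init, spec)
  make_optimum(scenario, res$theta, res$diagnostics, spec)
}

#' Functional optimization of the elastic potential shape
#'
#' Allows an arbitrary convex potential with curvature between 0 and the
#' stiffness cap by optimizing per-segment curvatures of a piecewise form
#' jointly with the kinetic parameters at a prescribed velocity. A harmonic
#' potential at the cap is always included among the starts (it is a
#' feasible point, so the anharmonic optimum can never fall below the
#' harmonic one beyond solver tolerance). The optimal shape is afterwards
#' summarized by the best-fitting two-regime potential and its transition
#' point `x_a`.
#'
#' @inheritParams maximize_at_velocity
#' @param scenario a [motor_scenario] with name `"fixed_velocity"`; its
#'   `potential_mode` is forced to `"piecewise"`.
#' @return a `motor_optimum` with extra elements `x_a_fit` (transition point
#'   of the fitted two-regime form) and `two_regime_fit`.
#' @export
optimize_potential_shape <- function(scenario, v_target = NULL, starts = 10,
                                     seed = 1, init = NULL) {
  stopifnot(inherits(scenario, "motor_scenario"))
  if (scenario$name != "fixed_velocity")
    stop("potential-shape optimization uses a fixed_velocity scenario")
  scenario$potential_mode <- "piecewise"
  if (!is.null(v_target)) scenario$v_target <- v_target
  spec <- par_spec(scenario)
  fn <- scenario_objective(scenario, spec)
  # harmonic-at-cap starts: all curvatures at the cap, kinetics from LHS
  set.seed(seed + 1L)
  hstart <- spec$s_lo + runif(nrow(spec)) * (spec$s_hi - spec$s_lo)
  hstart[grepl("^curv", spec$name)] <- 2 * scenario$half_kappa_cap
  res <- multistart_optimize(scenario, fn, starts, seed,
                             init = rbind(hstart, if (!is.null(init)) init),
                             spec = spec)
  opt <- make_optimum(scenario, res$theta, res$diagnostics, spec)
  fit <- fit_two_regime(opt$potential, kappa_cap = 2 * scenario$half_kappa_cap,
                        window = scenario$segment_window)
  opt$x_a_fit <- fit$x_a
  opt$two_regime_fit <- fit
  opt
}

# Least-squares fit of a two-regime potential (stiff above x_a, compliant
# below) to an arbitrary potential, matching U'(x) on a grid.
fit_two_regime <- function(pot, kappa_cap, window = c(-1.5, 1.5)) {
  xs <- seq(window[1], window[2], length.out = 601)
  target <- potential_force(pot, xs)
  sse <- function(par) {
    k <- par[1]; xa <- par[2]
    if (k <= 0 || k > kappa_cap * 1.001 || xa > 0 || xa < window[1]) return(1e10)
    sum((k * pmax(xs, xa) - target)^2)
  }
  o <- optim(c(kappa_cap, -0.2), sse, method = "Nelder-Mead",
             control = list(maxit = 2000, reltol = 1e-12))
  list(kappa = o$par[1], x_a = o$par[2], sse = o$value,
       rmse = sqrt(o$value / length(xs)))
}

#' Continuation scan of an optimization scenario
#'
#' Re-optimizes along an ordered sequence of values of one scenario
#' parameter, initializing each point from its already-solved neighbour,
#' once in ascending and once in descending order, plus fresh multi-starts;
#' the best of the three is reported per point.
#'
#' @param scenario base [motor_scenario].
#' @param scan_param one of `"half_kappa_cap"`, `"dG_ATP"`, `"v_target"`.
#' @param values ordered scan values.
#' @param starts fresh multi-starts per point.
#' @param seed integer seed.
#' @return data frame with one row per scan value (`value`, `eta_max`,
#'   `v_star`, `K_D_ADP`, `ok`); the full optima are attached as the
#'   `"optima"` attribute. Per-point failures are recorded and the scan
#'   continues.
#' @export
continuation_scan <- function(scenario, scan_param = c("half_kappa_cap",
                                                       "dG_ATP", "v_target"),
                              values, starts = 6, seed = 1) {
  scan_param <- match.arg(scan_param)
  if (is.unsorted(values) && is.unsorted(rev(values)))
    stop("scan values must be ordered")
  run_one <- function(scn, init, seed)
    tryCatch({
      switch(scn$name,
        free_velocity = maximize_free_velocity(scn, starts, seed, init),
        fixed_force_stable = maximize_fixed_force_stable(scn, starts, seed, init),
        fixed_velocity = maximize_at_velocity(scn, starts = starts,
                                              seed = seed, init = init))
    }, error = function(e) NULL)
  sweep <- function(vals, seed0) {
    out <- vector("list", length(vals))
    prev <- NULL
    for (i in seq_along(vals)) {
      scn <- scenario
      scn[[scan_param]] <- vals[i]
      if (scan_param == "half_kappa_cap" && !is.null(prev)) {
        ik <- which(par_spec(scn)$name == "log_half_kappa")
        if (length(ik)) prev[ik] <- min(prev[ik], log(vals[i]))
      }
      o <- run_one(scn, if (!is.null(prev)) rbind(prev), seed0 + i)
      if (!is.null(o)) prev <- unname(o$theta)
      out[[i]] <- o
    }
    out
  }
  asc <- sweep(values, seed)
  desc <- rev(sweep(rev(values), seed + 1000L))
  opt <- lapply(seq_along(values), function(i) {
    cands <- Filter(Negate(is.null), list(asc[[i]], desc[[i]]))
    if (!length(cands)) return(NULL)
    cands[[which.max(vapply(cands, `[[`, numeric(1), "eta_max"))]]
  })
  df <- do.call(rbind, lapply(seq_along(values), function(i) {
    o <- opt[[i]]
    data.frame(value = values[i],
               eta_max = if (is.null(o)) NA_real_ else o$eta_max,
               v_star = if (is.null(o)) NA_real_ else o$v_star,
               K_D_ADP = if (is.null(o)) NA_real_ else o$K_D_ADP,
               ok = !is.null(o))
  }))
  attr(df, "optima") <- opt
  df
}

#' Optimal ADP affinity as a function of velocity
#'
#' Runs the fixed-velocity optimization over a grid of target velocities
#' (with continuation) and reports the ADP dissociation constant implied by
#' the free-energy difference of the ADP-release transition,
#' `K_D^ADP = [ADP] exp(-(G_rigor - G_ADPstate)/kBT)`, in units of `[ADP]`.
#' The mid-range log-log slope of `K_D(v)` is attached (fast myosins from
#' different muscle types empirically follow a roughly quadratic law).
#'
#' @param scenario a fixed-velocity [motor_scenario].
#' @param v_values ordered target velocities.
#' @param starts,seed as in [continuation_scan].
#' @return data frame with `v`, `K_D_ADP`, `dG_release` (G_rigor minus
#'   G_ADPstate, in kBT; positive = uphill release), `eta_max`, `ok`;
#'   attributes `loglog_slope` (fitted on interior points) and `optima`.
#' @export
optimal_kd_adp <- function(scenario, v_values, starts = 4, seed = 1) {
  stopifnot(scenario$name == "fixed_velocity")
  df <- continuation_scan(scenario, "v_target", v_values, starts, seed)
  opt <- attr(df, "optima")
  out <- data.frame(v = df$value, K_D_ADP = df$K_D_ADP,
                    dG_release = vapply(opt, function(o) {
                      if (is.null(o)) return(NA_real_)
                      nb <- o$cycle$n_bound
                      o$cycle$G[nb + 1L] - o$cycle$G[nb]
                    }, numeric(1)),
                    eta_max = df$eta_max, ok = df$ok)
  ok <- out$ok & is.finite(out$K_D_ADP) & out$K_D_ADP > 0
  idx <- which(ok)
  if (length(idx) >= 4) idx <- idx[-c(1, length(idx))]  # interior points
  slope <- if (length(idx) >= 2)
    unname(coef(lm(log(out$K_D_ADP[idx]) ~ log(out$v[idx])))[2]) else NA_real_
  attr(out, "loglog_slope") <- slope
  attr(out, "optima") <- opt
  out
}
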