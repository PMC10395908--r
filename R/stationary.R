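# Stationary master-equation solver: bound-state strain densities of a
# motor ensemble sliding at constant velocity, plus all thermodynamic
# observables (ATPase flux, force, entropy production, efficiency).

#' Strain grid for the stationary solver
#'
#' @param x_min,x_max strain bounds (units of the stroke `d`); must satisfy
#'   `x_min < 0 < 1 < x_max`.
#' @param dx step size (> 0). Non-adaptive stepping; convergence is checked
#'   by halving.
#' @param refine integer refinement factor applied to `dx` (for convergence
#'   studies).
#' @param decay_tol integration stops early once the bound densities have
#'   decayed below this fraction of their running maximum (after all lever
#'   positions and thermal tails are covered).
#' @return object of class `solve_grid`.
#' @export
solve_grid <- function(x_min, x_max, dx, refine = 1L, decay_tol = 1e-14) {
  if (!(x_min < 0 && x_max > 1))
    stop_invalid("x_min < 0 < 1 < x_max", "grid must cover the full working stroke")
  if (dx <= 0) stop_invalid("dx > 0", "step size must be positive")
  structure(list(x_min = x_min, x_max = x_max, dx = dx / max(1L, refine),
                 decay_tol = decay_tol),
            class = "solve_grid")
}

# Default grid: step resolves the sharpest thermal length by a factor 50,
# the upper bound sits where the Boltzmann weight has decayed to exp(-40),
# and the lower bound allows for the advected tail of bound heads (extended
# conservatively; integration stops early once the densities have decayed).
auto_grid <- function(cycle, pot, v, refine = 1L) {
  kmax <- switch(pot$kind,
                 harmonic = pot$kappa,
                 two_regime = pot$kappa,
                 piecewise = max(pot$curvatures, pot$kappa / 50))
  dx <- min(sqrt(1 / kmax) / 50, 1 / 400) / max(1L, refine)
  # strain beyond which exp(-U) < exp(-40)
  ulim <- function(dir) {
    f <- function(z) potential_energy(pot, dir * z) - 40
    uniroot(f, c(0, 1e6), tol = 1e-10)$root
  }
  x_max <- max(cycle$d) + ulim(1)
  kmin <- min(cycle$k0[2:(cycle$n_bound + 1L)])
  ext <- min(80, max(2, 30 * max(v, 1e-6) / kmin))
  x_min <- min(cycle$d) - ulim(-1) - ext
  solve_grid(x_min, x_max, dx)
}

# Composite Simpson weights on a uniform grid of n points with spacing h.
simpson_weights <- function(n, h) {
  if (n < 2) return(rep(0, n))
  if (n == 2) return(c(h / 2, h / 2))
  m <- if (n %% 2 == 1) n else n - 1
  w <- numeric(n)
  w[seq_len(m)] <- rep(c(2, 4), length.out = m)
  w[1] <- 1; w[m] <- 1
  w <- w * h / 3
  if (n %% 2 == 0) {
    w[n - 1] <- w[n - 1] + h / 2
    w[n] <- h / 2
  }
  w
}

# Effective pool-level rates of the hydrolysis transition. The detached
# strain partition functions are identical in the two pools (shared
# potential), so pool-level detailed balance gives the reverse rate from
# the free-energy difference alone (zero under the closure convention).
hydrolysis_rates <- function(cycle) {
  ns <- cycle$n_states
  Wf <- cycle$k0[ns]
  Wr <- Wf * exp(cycle$G[1] + cycle$dG_ATP - cycle$G[ns])
  c(forward = Wf, reverse = Wr)
}

#' Solve the stationary master equations at fixed sliding velocity
#'
#' Computes the stationary strain densities `P_i(x)` of the bound states and
#' the occupancies of the two thermally equilibrated detached pools for a
#' motor cycle sliding at dimensionless velocity `v >= 0`, together with all
#' observables: per-transition probability flux densities, the conserved
#' cycle flux (ATPase rate per motor), the mean force per motor, the
#' per-transition entropy-production map and the thermodynamic efficiency
#' `eta = v F / (r_ATPase * (-dG_ATP))`.
#'
#' The bound densities obey `-v dP_i/dx = j_{i-1}(x) - j_i(x)` with
#' `P_i(x -> +Inf) = 0`; they are integrated downward in `x` with a
#' non-adaptive 3-step backward differentiation formula. Linearity in the
#' pool occupancies is exploited: two basis problems (unit occupancy in each
#' detached pool) are integrated simultaneously and closed by the detached
#' pool stationarity condition plus normalization (a 2x2 linear solve). For
#' `v = 0` the advection term vanishes and the densities decouple into local
#' linear systems solved pointwise. Negative velocities (lengthening) are
#' rejected.
#'
#' @param cycle a [motor_cycle].
#' @param pot an [elastic_potential].
#' @param v dimensionless sliding velocity (units of `k_ATP * d`), `>= 0`.
#' @param grid a [solve_grid], or `NULL` for an automatic grid.
#' @param detail if `FALSE`, skip the entropy-production map, chemical
#'   potentials and energy-balance bookkeeping (used in optimization inner
#'   loops, where only flux, force and efficiency are needed).
#' @return An object of class `stationary_field` with elements `x`, `P`
#'   (bound densities, columns = bound states), `P_pool` (detached pool
#'   occupancies), `j` (flux densities per strain-resolved transition),
#'   `sdot` (entropy-production densities), `mu` (chemical potentials),
#'   `flux_by_transition`, `dissipation_by_transition`, `r_ATPase`, `F`,
#'   `eta`, `T_Sdot_total` and `residuals` (flux conservation, energy
#'   balance, boundary mass).
#' @export
solve_stationary <- function(cycle, pot, v, grid = NULL, detail = TRUE) {
  stopifnot(inherits(cycle, "motor_cycle"), inherits(pot, "elastic_potential"))
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("v must be a single finite number")
  if (v < 0)
    stop_invalid("v >= 0", "lengthening (v < 0) is outside the model's scope")
  if (is.null(grid)) grid <- auto_grid(cycle, pot, v)

  nb <- cycle$n_bound
  ns <- cycle$n_states
  h <- grid$dx
  x_desc <- seq(grid$x_max, grid$x_min, by = -h)
  nx <- length(x_desc)

  kf <- matrix(0, nx, nb + 1L)
  kr <- matrix(0, nx, nb + 1L)
  for (t in seq_len(nb + 1L)) {
    kf[, t] <- forward_rate(cycle, pot, t, x_desc)
    kr[, t] <- reverse_rate(cycle, pot, t, x_desc)
  }
  rho0 <- boltzmann_density(pot, x_desc - cycle$d[1])
  rhod <- boltzmann_density(pot, x_desc - cycle$d[ns])

  if (v > 0) {
    # early stopping allowed only once all lever positions + thermal tails
    # are covered
    x_cover <- min(cycle$d) - 6 / sqrt(max(potential_curvature(pot, 0), pot$kappa / 10))
    n_min <- min(nx - 1L, ceiling((grid$x_max - x_cover) / h) + 3L)
    sol <- bdf_integrate(nb, kf, kr, rho0, rhod, v, h, n_min,
                         grid$decay_tol %||% 1e-14)
    n_used <- sol$n_used
    Pa <- sol$Pa[seq_len(n_used), , drop = FALSE]
    Pb <- sol$Pb[seq_len(n_used), , drop = FALSE]
    if (!sol$truncated) {
      # reached the hard floor: verify that the remaining mass is negligible
      tail_frac <- (sum(abs(Pa[n_used, ])) + sum(abs(Pb[n_used, ]))) /
        max(sol$max_sum, 1e-300)
      if (tail_frac > 1e-8)
        stop(structure(class = c("motorlimits_grid_error", "error", "condition"),
                       list(message = paste0(
                         "bound probability has not decayed at the lower grid ",
                         "boundary (residual fraction ", signif(tail_frac, 3),
                         "); enlarge the domain (smaller x_min)"), call = sys.call(-1))))
    }
  } else {
    # v = 0: pointwise algebraic stationarity (advection term vanishes)
    n_used <- nx
    Pa <- matrix(0, nx, nb)
    Pb <- matrix(0, nx, nb)
    for (n in seq_len(nx)) {
      A <- matrix(0, nb, nb)
      Ba <- numeric(nb); Bb <- numeric(nb)
      for (m in seq_len(nb)) {
        A[m, m] <- kr[n, m] + kf[n, m + 1L]
        if (m > 1) A[m, m - 1L] <- -kf[n, m]
        if (m < nb) A[m, m + 1L] <- -kr[n, m + 1L]
      }
      Ba[1] <- kf[n, 1] * rho0[n]
      Bb[nb] <- kr[n, nb + 1L] * rhod[n]
      sol0 <- tryCatch(solve(A, cbind(Ba, Bb)), error = function(e) NULL)
      if (is.null(sol0)) stop("singular local system in v = 0 solve")
      Pa[n, ] <- sol0[, 1]
      Pb[n, ] <- sol0[, 2]
    }
  }

  x_desc <- x_desc[seq_len(n_used)]
  kf <- kf[seq_len(n_used), , drop = FALSE]
  kr <- kr[seq_len(n_used), , drop = FALSE]
  rho0 <- rho0[seq_len(n_used)]
  rhod <- rhod[seq_len(n_used)]

  # flip to ascending x for quadrature and outputs
  ord <- rev(seq_len(n_used))
  x <- x_desc[ord]
  Pa <- Pa[ord, , drop = FALSE]
  Pb <- Pb[ord, , drop = FALSE]
  kf <- kf[ord, , drop = FALSE]
  kr <- kr[ord, , drop = FALSE]
  rho0 <- rho0[ord]
  rhod <- rhod[ord]

  w <- simpson_weights(n_used, h)
  W <- hydrolysis_rates(cycle)

  # pool closure: stationarity of the pre-attachment pool + normalization
  S0 <- sum(w * kf[, 1] * rho0)
  Ia <- sum(w * kr[, 1] * Pa[, 1])
  Ib <- sum(w * kr[, 1] * Pb[, 1])
  J1a <- S0 - Ia
  J1b <- -Ib
  Ma <- sum(w * rowSums(Pa))
  Mb <- sum(w * rowSums(Pb))
  A2 <- rbind(c(-W["reverse"] - J1a, W["forward"] - J1b),
              c(1 + Ma, 1 + Mb))
  cc <- tryCatch(solve(A2, c(0, 1)), error = function(e) NULL)
  if (is.null(cc) || any(!is.finite(cc)))
    stop("pool closure system is singular; model parameters may be degenerate")
  c_a <- cc[1]; c_b <- cc[2]
  if (c_a < -1e-10 || c_b < -1e-10)
    stop("pool closure produced negative occupancies; refine the grid")
  c_a <- max(c_a, 0); c_b <- max(c_b, 0)

  P <- c_a * Pa + c_b * Pb
  P[P < 0] <- 0   # clip sub-roundoff undershoots from the implicit stepping

  # state densities along the cycle: pool 1, bound 1..nb, pool ns
  dens <- cbind(c_a * rho0, P, c_b * rhod)
  jmat <- matrix(0, n_used, nb + 1L)
  for (t in seq_len(nb + 1L))
    jmat[, t] <- kf[, t] * dens[, t] - kr[, t] * dens[, t + 1L]
  J <- as.numeric(crossprod(w, jmat))
  J_hyd <- unname(W["forward"] * c_b - W["reverse"] * c_a)
  flux <- c(J, hydrolysis = J_hyd)
  names(flux)[seq_len(nb + 1L)] <- paste0("t", seq_len(nb + 1L))
  r <- mean(flux)
  flux_resid <- (max(flux) - min(flux)) / max(abs(r), 1e-300)

  Fm <- 0
  for (m in seq_len(nb))
    Fm <- Fm + sum(w * P[, m] * potential_force(pot, x - cycle$d[m + 1L]))
  g <- -cycle$dG_ATP
  denom <- r * g
  eta <- if (denom > 0) v * Fm / denom else 0

  if (detail) {
    # entropy production density per transition, evaluated in log space:
    # sdot = (a - b)(log a - log b) >= 0 with a, b the directed one-way
    # fluxes. Only a bound density at exact zero (upstream of the
    # truncation) lacks a finite logarithm; it is replaced by the smallest
    # representable log so that its one-way flux vanishes. Analytic pool
    # log-densities are kept at full (possibly astronomically negative)
    # value: their magnitude carries the real entropy cost of detaching a
    # deeply strained head, and routing it through exp(-U) would silently
    # drop that contribution once U exceeds ~700 kBT.
    lfloor <- -745
    ldens <- cbind(log(max(c_a, 1e-300)) -
                     potential_energy(pot, x - cycle$d[1]) - pot$logZ,
                   log(P),
                   log(max(c_b, 1e-300)) -
                     potential_energy(pot, x - cycle$d[ns]) - pot$logZ)
    ldens[!is.finite(ldens)] <- lfloor
    sdot <- matrix(0, n_used, nb + 1L)
    for (t in seq_len(nb + 1L)) {
      ex <- rate_exponents(cycle, pot, t, x)
      la <- ex$lf + ldens[, t]
      lb <- ex$lr + ldens[, t + 1L]
      sdot[, t] <- (exp(pmin(la, 700)) - exp(pmin(lb, 700))) * (la - lb)
    }
    D <- as.numeric(crossprod(w, sdot))
    D_hyd <- if (W["forward"] * c_b > 0 && W["reverse"] * c_a > 0)
      unname((W["forward"] * c_b - W["reverse"] * c_a) *
             log((W["forward"] * c_b) / (W["reverse"] * c_a))) else 0
    diss <- c(D, hydrolysis = D_hyd)
    names(diss)[seq_len(nb + 1L)] <- paste0("t", seq_len(nb + 1L))
    TS <- sum(diss)
    balance_resid <- abs(TS - (r * g - v * Fm)) / max(abs(r * g), 1e-300)

    # chemical potentials (kBT): bound strain-resolved, pools uniform
    mu <- matrix(-Inf, n_used, ns)
    mu[, 1] <- cycle$G[1] + log(max(c_a, 1e-300)) - pot$logZ
    mu[, ns] <- cycle$G[ns] + log(max(c_b, 1e-300)) - pot$logZ
    for (m in seq_len(nb)) {
      pos <- P[, m] > 0
      mu[pos, m + 1L] <- cycle$G[m + 1L] +
        potential_energy(pot, x[pos] - cycle$d[m + 1L]) + log(P[pos, m])
    }
  } else {
    sdot <- mu <- NULL
    diss <- NULL
    TS <- NA_real_
    balance_resid <- NA_real_
  }

  norm_resid <- abs(c_a + c_b + sum(w * rowSums(P)) - 1)

  structure(list(
    x = x, P = P, P_pool = c(pre = c_a, post = c_b),
    j = jmat, sdot = sdot, mu = mu,
    v = v, r_ATPase = r, F = Fm, eta = eta,
    flux_by_transition = flux,
    dissipation_by_transition = diss,
    T_Sdot_total = TS,
    residuals = c(flux = flux_resid, balance = balance_resid,
                  normalization = norm_resid),
    grid = grid, cycle = cycle, potential = pot,
    quad_weights = w),
    class = "stationary_field")
}

#' @export
print.stationary_field <- function(x, ...) {
  cat(sprintf("<stationary_field> v = %.4g, r_ATPase = %.4g, F = %.4g, eta = %.4g\n",
              x$v, x$r_ATPase, x$F, x$eta))
  cat(sprintf("  pools: pre = %.4g, post = %.4g | residuals: flux %.2e, balance %.2e\n",
              x$P_pool[1], x$P_pool[2], x$residuals["flux"], x$residuals["balance"]))
  invisible(x)
}

#' Entropy-production map of a stationary solution
#'
#' Per-transition, per-strain dissipation densities
#' `j_i(x) (mu_i(x) - mu_{i+1}(x))` (in `kBT` per unit time) and the
#' per-transition integrated losses. The map is pointwise non-negative by
#' construction (each local term has the form `(a - b) log(a/b)`), and the
#' integrated losses sum to the total dissipation
#' `T Sdot = -v F + r_ATPase (-dG_ATP)`.
#'
#' @param field a solved [stationary_field].
#' @return list with `density` (matrix, columns = strain-resolved
#'   transitions), `by_transition` (integrated losses, including the pool
#'   hydrolysis step), `total`, and the energy-balance residual.
#' @export
dissipation_map <- function(field) {
  stopifnot(inherits(field, "stationary_field"))
  list(x = field$x,
       density = field$sdot,
       by_transition = field$dissipation_by_transition,
       total = field$T_Sdot_total,
       balance_residual = unname(field$residuals["balance"]))
}

#' Force-velocity-efficiency relation
#'
#' Solves the stationary problem over a velocity grid and reports the mean
#' force per motor, efficiency and ATPase rate, flagging anomalous regions
#' where the force rises with velocity (the signature of a multivalued,
#' hysteretic force-velocity relation).
#'
#' @param cycle a [motor_cycle].
#' @param pot an [elastic_potential].
#' @param v_grid sorted non-negative velocities.
#' @param grid optional [solve_grid] shared by all points.
#' @return object of class `fv_curve`: data frame with columns `v`, `F`,
#'   `eta`, `r_ATPase`, `anomalous` (logical, `dF/dv > 0` on the following
#'   interval), `ok`; failed points carry `NA` (never silently filled).
#' @export
fv_curve <- function(cycle, pot, v_grid, grid = NULL) {
  if (is.unsorted(v_grid) || any(v_grid < 0))
    stop("v_grid must be sorted and non-negative")
  res <- lapply(v_grid, function(v) {
    tryCatch({
      f <- solve_stationary(cycle, pot, v, grid)
      data.frame(v = v, F = f$F, eta = f$eta, r_ATPase = f$r_ATPase, ok = TRUE)
    }, error = function(e)
      data.frame(v = v, F = NA_real_, eta = NA_real_, r_ATPase = NA_real_,
                 ok = FALSE))
  })
  out <- do.call(rbind, res)
  dF <- c(diff(out$F) / diff(out$v), NA)
  out$anomalous <- !is.na(dF) & dF > 0
  class(out) <- c("fv_curve", "data.frame")
  out
}

#' Detect hysteresis in a force-velocity curve
#'
#' A force-velocity relation with an anomalous (positive-slope) region is
#' multivalued in force: the same load can be carried at several velocities,
#' and the intermediate branch is unstable under fixed load. Returns the
#' hull of forces attained at more than one velocity, bounded by the fold
#' forces (the local extrema of `F(v)`).
#'
#' @param curve an [fv_curve].
#' @return list with `multivalued` (logical), `interval` (force range,
#'   `NULL` if monotone) and `fold_forces` (forces at the local extrema).
#' @export
detect_hysteresis <- function(curve) {
  stopifnot(inherits(curve, "fv_curve"))
  ok <- curve$ok & is.finite(curve$F)
  Fv <- curve$F[ok]; vv <- curve$v[ok]
  n <- length(Fv)
  if (n < 3) stop("curve too short for hysteresis detection")
  s <- diff(Fv)
  if (all(s <= 0) || all(s >= 0))
    return(list(multivalued = FALSE, interval = NULL, fold_forces = numeric(0)))
  if (n < 50)
    stop(structure(class = c("motorlimits_grid_error", "error", "condition"),
                   list(message = paste0(
                     "force-velocity curve is non-monotone but has fewer than ",
                     "50 points; refine the velocity grid"), call = sys.call(-1))))
  ext <- which(s[-1] * s[-(n - 1)] < 0) + 1L   # interior local extrema
  folds <- Fv[ext]
  list(multivalued = length(folds) > 0,
       interval = if (length(folds)) range(folds) else NULL,
       fold_forces = folds)
}

#' Locate the peak of the efficiency-velocity relation
#'
#' Scalar maximization of `eta(v)` over a bracket by golden-section /
#' parabolic refinement. If the maximum sits at a bracket end a boundary
#' flag is raised.
#'
#' @param cycle a [motor_cycle].
#' @param pot an [elastic_potential].
#' @param v_bracket length-2 numeric bracket (non-negative).
#' @param grid optional [solve_grid].
#' @param tol velocity tolerance of the scalar search.
#' @return list with `v_star`, `eta_star`, `boundary` (TRUE if the optimum
#'   landed on a bracket end).
#' @export
efficiency_peak <- function(cycle, pot, v_bracket, grid = NULL, tol = 1e-4) {
  stopifnot(length(v_bracket) == 2, all(v_bracket >= 0))
  f <- function(v) -solve_stationary(cycle, pot, v, grid)$eta
  opt <- optimize(f, interval = sort(v_bracket), tol = tol)
  span <- diff(range(v_bracket))
  boundary <- min(abs(opt$minimum - v_bracket)) < 2 * max(tol, 1e-3 * span)
  if (boundary) {
    ends <- vapply(v_bracket, f, numeric(1))
    if (min(ends) < opt$objective) {
      opt$minimum <- v_bracket[which.min(ends)]
      opt$objective <- min(ends)
    }
    warning("efficiency peak lies at the bracket boundary")
  }
  list(v_star = opt$minimum, eta_star = -opt$objective, boundary = boundary)
}
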