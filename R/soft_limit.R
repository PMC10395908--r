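# Closed-form analytics in the soft-spring limit K d^2 << |dG_ATP|: with a
# compliant elastic element the strain energies lose their influence on the
# transition rates, the cycle becomes effectively irreversible and the
# velocity, force and efficiency admit closed forms. These serve as the
# independent analytic oracle for the numerical stationary solver.

#' Soft-spring limit model
#'
#' A motor cycle in the regime where the elastic energy over a working
#' stroke is small against the free energy of hydrolysis, so all transition
#' rates are strain-independent and effectively irreversible. The optimal
#' kinetic structure in this limit has a fast first bound-bound transition
#' carrying the full working stroke and equal rates for the remaining bound
#' transitions.
#'
#' @param n_bound number of bound states.
#' @param k_rates strain-independent forward rates of the bound transitions
#'   `k_1 ... k_NB` (exit rates of bound states 1..N_B), in rate units.
#' @param t_off mean detached dwell per cycle (sets the duty ratio; the
#'   efficiency does not depend on it).
#' @param kappa dimensionless stiffness `K d^2/kBT` (soft: `kappa/2 << g`).
#' @param g dimensionless free energy of hydrolysis `-dG_ATP/kBT`.
#' @return object of class `soft_limit_model` with `t_on = sum(1/k)` and
#'   `t_cycle = t_on + t_off`.
#' @export
soft_limit_model <- function(n_bound, k_rates, t_off = 0, kappa, g) {
  if (n_bound < 2) stop_invalid("n_bound", "need at least two bound states")
  if (length(k_rates) != n_bound)
    stop_invalid("length(k_rates)", "need one exit rate per bound state")
  if (any(k_rates <= 0)) stop_invalid("k > 0", "rates must be positive")
  if (t_off < 0) stop_invalid("t_off >= 0", "detached dwell cannot be negative")
  if (kappa <= 0 || g <= 0) stop_invalid("kappa, g > 0", "need positive kappa and g")
  t_on <- sum(1 / k_rates)
  m <- structure(list(n_bound = as.integer(n_bound), k_rates = k_rates,
                      t_on = t_on, t_cycle = t_on + t_off,
                      kappa = kappa, g = g),
                 class = "soft_limit_model")
  if (kappa / 2 > 0.1 * g)
    warning("kappa/2 exceeds 0.1*g; the soft-spring limit is dubious here")
  m
}

# TRUE when the rate structure matches the optimal soft-limit layout:
# fast first transition, remaining rates equal.
soft_structure_optimal <- function(model) {
  k <- model$k_rates
  rest <- k[-1]
  k[1] >= 50 * max(rest) &&
    (length(rest) < 2 || diff(range(rest)) <= 1e-8 * max(rest))
}

#' Maximal unloaded velocity in the soft-spring limit
#'
#' For the optimal structure (fast first transition carrying the full
#' stroke, equal remaining rates) the unloaded velocity is
#' `v_max = 2 d (1 - 1/N_B) / t_on`. For other rate sets the same formula is
#' returned together with a flag marking that the structure is not the
#' optimal one.
#'
#' @param model a [soft_limit_model].
#' @return `v_max` (dimensionless); attribute `optimal_structure`.
#' @export
soft_velocity_max <- function(model) {
  v <- 2 * (1 - 1 / model$n_bound) / model$t_on
  attr(v, "optimal_structure") <- soft_structure_optimal(model)
  v
}

#' Efficiency at the optimal operating point in the soft-spring limit
#'
#' `eta = (kappa / (2 g)) (1 - 1/N_B)`; the work per ATP is
#' `kappa/2 * (1 - 1/N_B)` in `kBT`. The ceiling `kappa/(2g)` is reached
#' only as the number of bound states grows without bound.
#'
#' @param model a [soft_limit_model].
#' @return list with `eta` and `work_per_ATP` (kBT).
#' @export
soft_efficiency <- function(model) {
  if (model$kappa / 2 > 0.1 * model$g)
    warning("kappa/2 > 0.1*g: soft-limit prediction is unreliable")
  fac <- 1 - 1 / model$n_bound
  list(eta = model$kappa / (2 * model$g) * fac,
       work_per_ATP = model$kappa / 2 * fac)
}

#' Optimal operating point in the soft-spring limit
#'
#' The stall force per motor is `kappa * t_on / t_cycle` (in `kBT/d`, with
#' the stroke `d = 1`); maximum power and efficiency are reached at half the
#' stall force and half the maximal velocity.
#'
#' @param model a [soft_limit_model].
#' @return list with `F_stall`, `F_opt`, `v_opt`, and the exact fractions
#'   `F_opt_frac = v_opt_frac = 1/2`.
#' @export
soft_operating_point <- function(model) {
  vmax <- as.numeric(soft_velocity_max(model))
  F_stall <- model$kappa * model$t_on / model$t_cycle
  list(F_stall = F_stall, F_opt = F_stall / 2, v_opt = vmax / 2,
       v_max = vmax, F_opt_frac = 0.5, v_opt_frac = 0.5)
}

#' Force, power and efficiency along the soft-limit force-velocity line
#'
#' In the soft-spring limit the force-velocity relation is linear between
#' the stall force at `v = 0` and zero at `v_max`; the efficiency
#' `eta(v) = v F(v) t_cycle / g` peaks exactly at `v_max / 2`.
#'
#' @param model a [soft_limit_model].
#' @param v vector of dimensionless velocities.
#' @return data frame with `v`, `F`, `power`, `eta`.
#' @export
soft_fv_curve <- function(model, v) {
  vmax <- as.numeric(soft_velocity_max(model))
  op <- soft_operating_point(model)
  Fv <- op$F_stall * (1 - v / vmax)
  data.frame(v = v, F = Fv, power = v * Fv, eta = v * Fv * model$t_cycle / model$g)
}

#' Distribution of the time from attachment to detachment
#'
#' With strain-independent irreversible sequential rates after a fast first
#' transition, the bound time is a sum of independent exponential stages
#' (hypoexponential). A cascade of similar rates narrows the distribution:
#' for `n` equal stages the coefficient of variation is `1/sqrt(n)`, making
#' detachment timing more deterministic and reducing the elastic energy
#' wasted by heads detaching at the wrong position.
#'
#' @param model a [soft_limit_model]; stages are the rates `k_2 ... k_NB`
#'   following the fast first transition.
#' @return list with `pdf` (vectorized density function of the detachment
#'   time), `mean`, `cv`, `rates`.
#' @export
detachment_time_density <- function(model) {
  rates <- model$k_rates[-1]
  n <- length(rates)
  mean_t <- sum(1 / rates)
  cv <- sqrt(sum(1 / rates^2)) / mean_t
  pdf <- function(t) hypoexp_pdf(t, rates)
  list(pdf = pdf, mean = mean_t, cv = cv, rates = rates)
}

# Hypoexponential density: time through a linear chain of exponential
# stages. Computed by integrating the stage occupancies with the (lower
# triangular) generator, which is exact and robust for repeated rates:
# closed-form partial fractions break down when rates coincide.
hypoexp_pdf <- function(t, rates) {
  n <- length(rates)
  if (n == 1) return(stats::dexp(t, rates))
  out <- numeric(length(t))
  pos <- t >= 0
  if (!any(pos)) return(out)
  # occupancy p_j(t) solves p' = Q^T p, p(0) = e_1; density = k_n p_n(t).
  # Solve by series in the uniformized chain: exact eigen decomposition when
  # rates are distinct, else small imaginary-free perturbation-free path via
  # repeated convolution on a fine grid is avoided -- use the recursive
  # integral formulation with scaled stages.
  if (length(unique(signif(rates, 12))) == n) {
    # distinct rates: classical partial-fraction form
    w <- vapply(seq_len(n), function(i) {
      prod(rates[-i] / (rates[-i] - rates[i]))
    }, numeric(1))
    for (i in seq_len(n))
      out[pos] <- out[pos] + w[i] * rates[i] * exp(-rates[i] * t[pos])
  } else {
    # repeated rates (partial fractions degenerate): matrix exponential of
    # the sequential generator
    Q <- matrix(0, n, n)
    diag(Q) <- -rates
    for (j in seq_len(n - 1)) Q[j, j + 1] <- rates[j]
    out[pos] <- vapply(t[pos], function(tt) {
      E <- as.matrix(Matrix::expm(Matrix::Matrix(Q * tt)))
      rates[n] * E[1, n]
    }, numeric(1))
  }
  pmax(out, 0)
}
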