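#' @useDynLib motorlimits, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize runif setNames lm coef uniroot approx rnorm
#' @importFrom utils modifyList head tail
NULL

# Structured validation error naming the violated invariant.
stop_invalid <- function(invariant, msg) {
  cnd <- structure(
    class = c("motorlimits_validation_error", "error", "condition"),
    list(message = sprintf("%s [invariant: %s]", msg, invariant),
         call = sys.call(-1), invariant = invariant)
  )
  stop(cnd)
}

#' Define a mechano-chemical motor cycle
#'
#' Builds a validated kinetic scheme for a non-processive motor of the myosin
#' family. The cycle has `n_bound` bound states plus two detached states: a
#' pre-attachment state carrying the hydrolysis products (ADP and Pi) and a
#' post-detachment state carrying freshly bound ATP. States are stored
#' 1-based: state 1 is the detached pre-attachment state, states
#' `2 ... n_bound + 1` are bound, and state `n_bound + 2` is the detached
#' post-ATP state. Transition `t` connects state `t` to state `t + 1`
#' (cyclically); transition 1 is actin attachment, transition `n_bound + 1`
#' is ATP-induced detachment and the final transition is ATP hydrolysis,
#' which connects the two thermally equilibrated detached pools.
#'
#' All energies are in units of the thermal energy `kBT`, all distances in
#' units of the working stroke `d`, and all rates in units of the maximal
#' ATP-induced detachment rate `k_ATP` (the product of the second-order ATP
#' binding constant and the ATP concentration).
#'
#' Reverse bare rates are never supplied: they are always derived via
#' `k_rev0 = k0 * exp(G[t+1] - G[t])`, which makes generalized detailed
#' balance unbreakable by construction.
#'
#' @param n_bound integer, number of bound states (>= 2).
#' @param G numeric vector of state free energies, length `n_bound + 2`,
#'   in `kBT`. `G[1] = 0` by convention and `G[n_bound + 2] = dG_ATP`, so
#'   the full free-energy drop of hydrolysis is distributed over the
#'   attachment--detachment leg and the hydrolysis step between the detached
#'   pools is iso-energetic.
#' @param d numeric vector of unstrained lever positions, length
#'   `n_bound + 2`, in units of `d`. The first bound state has `d = 1` and
#'   the last bound (rigor) state `d = 0`; intermediate values must be
#'   non-increasing within `[0, 1]`. The detached lever positions are tied
#'   to their bound neighbours (`d[1] = d[2]`, `d[ns] = d[ns - 1]`): the
#'   recovery stroke completes while detached, so attachment and detachment
#'   themselves involve no change of elastic energy and the strain
#'   dependence of attachment enters purely through the Boltzmann-weighted
#'   reach of the detached head.
#' @param alpha numeric vector of load-distribution coefficients, one per
#'   transition (length `n_bound + 2`). The attachment transition must have
#'   `alpha = 1` (strain acts on attachment only), the detachment transition
#'   `alpha = 0` (strain-independent detachment). The entry for the
#'   hydrolysis transition is ignored (that transition is handled at the
#'   level of equilibrated pools).
#' @param k0 numeric vector of bare forward rates, one per transition.
#'   Either length `n_bound + 2` (last entry = hydrolysis rate) or length
#'   `n_bound + 1`, in which case the hydrolysis rate defaults to `k_hyd`.
#' @param dG_ATP free energy of ATP hydrolysis in `kBT` (non-positive;
#'   physiologically about -25).
#' @param k_hyd hydrolysis rate between the detached pools, used when `k0`
#'   has length `n_bound + 1`. It sets the duty ratio but provably does not
#'   affect the efficiency; the large default keeps the detached dwell
#'   short. Use a moderate value for realistic stochastic traces.
#'
#' @return An object of class `motor_cycle`.
#' @export
motor_cycle <- function(n_bound, G, d, alpha, k0, dG_ATP, k_hyd = 1e5) {
  if (!is.numeric(n_bound) || length(n_bound) != 1L || n_bound < 2 ||
      n_bound != round(n_bound))
    stop_invalid("n_bound", "n_bound must be an integer >= 2")
  nb <- as.integer(n_bound)
  ns <- nb + 2L

  if (length(G) != ns)
    stop_invalid("length(G)", sprintf("G must have length %d", ns))
  if (length(d) != ns)
    stop_invalid("length(d)", sprintf("d must have length %d", ns))
  if (length(alpha) != ns)
    stop_invalid("length(alpha)", sprintf("alpha must have length %d", ns))
  if (length(k0) == ns - 1L) k0 <- c(k0, k_hyd)
  if (length(k0) != ns)
    stop_invalid("length(k0)",
                 sprintf("k0 must have length %d or %d", ns - 1L, ns))
  if (!is.numeric(dG_ATP) || length(dG_ATP) != 1L || dG_ATP > 0)
    stop_invalid("dG_ATP", "dG_ATP must be a single non-positive number")

  if (abs(G[1]) > 1e-12)
    stop_invalid("G[1] = 0", "free energy of the detached ADP.Pi state must be 0")
  if (abs(G[ns] - dG_ATP) > 1e-9)
    stop_invalid("G[NS] = dG_ATP",
                 "free energy of the detached ATP state must equal dG_ATP (cyclic closure)")

  if (abs(d[2] - 1) > 1e-12)
    stop_invalid("d[first bound] = 1", "first bound state must carry the full stroke d = 1")
  if (abs(d[nb + 1L]) > 1e-12)
    stop_invalid("d[rigor] = 0", "last bound (rigor) state must have d = 0")
  if (abs(d[1] - d[2]) > 1e-12)
    stop_invalid("d[detached.pre] = d[first bound]",
                 "pre-attachment detached lever position must equal the first bound state")
  if (abs(d[ns] - d[nb + 1L]) > 1e-12)
    stop_invalid("d[detached.post] = d[rigor]",
                 "post-detachment lever position must equal the rigor state")
  db <- d[2:(nb + 1L)]
  if (any(db < -1e-12 | db > 1 + 1e-12) || any(diff(db) > 1e-12))
    stop_invalid("d ordering", "bound lever positions must be non-increasing within [0, 1]")

  if (any(alpha < -1e-12 | alpha > 1 + 1e-12))
    stop_invalid("alpha in [0,1]", "all load-distribution coefficients must lie in [0, 1]")
  if (abs(alpha[1] - 1) > 1e-12)
    stop_invalid("alpha[attachment] = 1",
                 "attachment transition must have alpha = 1 (strain acts on attachment only)")
  if (abs(alpha[nb + 1L]) > 1e-12)
    stop_invalid("alpha[detachment] = 0",
                 "detachment transition must have alpha = 0 (strain-independent detachment)")

  if (any(!is.finite(k0)) || any(k0 <= 0))
    stop_invalid("k0 > 0", "all bare rates must be finite and strictly positive")

  structure(
    list(n_bound = nb, n_states = ns,
         G = as.numeric(G), d = as.numeric(d),
         alpha = as.numeric(alpha), k0 = as.numeric(k0),
         dG_ATP = as.numeric(dG_ATP)),
    class = "motor_cycle")
}

#' @export
print.motor_cycle <- function(x, ...) {
  cat(sprintf("<motor_cycle> %d bound + 2 detached states, -dG_ATP/kBT = %g\n",
              x$n_bound, -x$dG_ATP))
  st <- data.frame(
    state = c("D.ADP.Pi", paste0("B", seq_len(x$n_bound)), "D.ATP"),
    G = x$G, d = x$d, alpha = x$alpha, k0 = x$k0)
  print(st, row.names = FALSE, digits = 4)
  invisible(x)
}

# Indices of the special transitions (1-based, transition t: state t -> t+1).
attach_transition <- function(cycle) 1L
detach_transition <- function(cycle) cycle$n_bound + 1L
hydrolysis_transition <- function(cycle) cycle$n_states

# Free-energy change of transition t (state t -> t+1), including the
# hydrolysis offset on the cyclic wrap-around.
transition_dG <- function(cycle, t) {
  ns <- cycle$n_states
  Gnext <- c(cycle$G[-1], cycle$G[1] + cycle$dG_ATP)
  Gnext[t] - cycle$G[t]
}

# Log-rates (unclamped exponents) of a strain-resolved transition; used
# where products with exponentially small densities must be evaluated in
# log space (entropy production of deeply strained heads).
rate_exponents <- function(cycle, pot, t, x) {
  dU <- potential_energy(pot, x - cycle$d[t + 1L]) -
        potential_energy(pot, x - cycle$d[t])
  list(lf = log(cycle$k0[t]) - cycle$alpha[t] * dU,
       lr = log(cycle$k0[t]) + transition_dG(cycle, t) +
            (1 - cycle$alpha[t]) * dU)
}

#' Strain-dependent transition rates
#'
#' Forward and reverse rates of transition `t` (state `t` to `t + 1`) at
#' strain-coordinate `x`. The elastic energy difference
#' `dU = U(x - d[t+1]) - U(x - d[t])` is split between the two directions by
#' the load-distribution coefficient: the forward rate carries
#' `exp(-alpha * dU)` and the reverse rate `exp((1 - alpha) * dU)`, so the
#' ratio always satisfies generalized detailed balance
#' `k_fwd / k_rev = exp(-(G[t+1] + U[t+1] - G[t] - U[t]))` for any alpha.
#' The hydrolysis transition connects two Boltzmann-equilibrated detached
#' pools whose configurational partition functions are identical (the
#' potential is the same in all states), so its effective pool-level rates
#' are independent of `x`.
#'
#' @param cycle a [motor_cycle].
#' @param pot an [elastic_potential].
#' @param t transition index (1 to `n_states`).
#' @param x numeric vector of strain coordinates (units of the stroke `d`).
#' @return numeric vector of rates (units of the ATP-detachment rate).
#' @export
forward_rate <- function(cycle, pot, t, x) {
  ns <- cycle$n_states
  if (t < 1 || t > ns) stop("transition index out of range")
  if (t == ns) return(rep(cycle$k0[ns], length(x)))
  dU <- potential_energy(pot, x - cycle$d[t + 1L]) -
        potential_energy(pot, x - cycle$d[t])
  exp(pmin(log(cycle$k0[t]) - cycle$alpha[t] * dU, 700))
}

#' @rdname forward_rate
#' @export
reverse_rate <- function(cycle, pot, t, x) {
  ns <- cycle$n_states
  if (t < 1 || t > ns) stop("transition index out of range")
  lk0r <- log(cycle$k0[t]) + transition_dG(cycle, t)
  if (t == ns) return(rep(exp(lk0r), length(x)))
  dU <- potential_energy(pot, x - cycle$d[t + 1L]) -
        potential_energy(pot, x - cycle$d[t])
  exp(pmin(lk0r + (1 - cycle$alpha[t]) * dU, 700))
}
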