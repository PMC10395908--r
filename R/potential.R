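#' Elastic potential of the motor's compliant element
#'
#' The elastic element connecting a motor head to its filament stores energy
#' `U(x)` when stretched by `x` (in units of the working stroke `d`; energies
#' in `kBT`). Three shapes are supported:
#'
#' * `"harmonic"`: `U(x) = kappa * x^2 / 2`, with dimensionless stiffness
#'   `kappa = K d^2 / kBT` (conventionally quoted as `kappa / 2`, the elastic
#'   energy at a full working-stroke displacement).
#' * `"two_regime"`: stiff (`U'' = kappa`) for `x >= x_a`, perfectly
#'   compliant (`U'' = 0`, constant pushing force `kappa * x_a`) for
#'   `x < x_a`, with `x_a <= 0`. This is the buckling-type asymmetric
#'   element: stiff when pulling, soft beyond a threshold pushing force.
#' * `"piecewise"`: convex piecewise-quadratic with per-segment curvature
#'   values in `[0, kappa]` between ordered breakpoints; the outermost
#'   segments extend to infinity. Used for functional (free-shape)
#'   optimization of the potential under the curvature cap.
#'
#' All shapes are convex and C1 with minimum `U(0) = 0`, `U'(0) = 0`.
#'
#' @param kind one of `"harmonic"`, `"two_regime"`, `"piecewise"`.
#' @param kappa dimensionless stiffness `K d^2 / kBT` (for `"piecewise"` this
#'   is the curvature cap).
#' @param x_a transition point of the two-regime potential (must be <= 0).
#' @param breakpoints ordered breakpoints for `"piecewise"` (length M + 1,
#'   must straddle 0).
#' @param curvatures per-segment curvatures for `"piecewise"` (length M,
#'   each in `[0, kappa]`).
#' @return An object of class `elastic_potential`.
#' @export
elastic_potential <- function(kind = c("harmonic", "two_regime", "piecewise"),
                              kappa, x_a = NULL, breakpoints = NULL,
                              curvatures = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0 || !is.finite(kappa))
    stop_invalid("kappa > 0", "stiffness kappa must be a positive finite number")
  pot <- list(kind = kind, kappa = kappa)

  if (kind == "two_regime") {
    if (is.null(x_a) || !is.numeric(x_a) || length(x_a) != 1L || x_a > 0)
      stop_invalid("x_a <= 0",
                   "two-regime potential needs a transition point x_a <= 0 (minimum stays at 0)")
    pot$x_a <- x_a
  }
  if (kind == "piecewise") {
    if (is.null(breakpoints) || is.null(curvatures) ||
        length(breakpoints) != length(curvatures) + 1L)
      stop_invalid("segments", "need length(breakpoints) == length(curvatures) + 1")
    if (any(diff(breakpoints) <= 0))
      stop_invalid("segments ordered", "breakpoints must be strictly increasing")
    if (min(breakpoints) > 0 || max(breakpoints) < 0)
      stop_invalid("segments straddle 0", "breakpoints must straddle the minimum at 0")
    if (any(curvatures < -1e-12) || any(curvatures > kappa + 1e-9))
      stop_invalid("0 <= U'' <= kappa",
                   "segment curvatures must lie in [0, kappa] (convexity + stiffness cap)")
    pot$breakpoints <- as.numeric(breakpoints)
    pot$curvatures <- pmin(pmax(as.numeric(curvatures), 0), kappa)
    # precompute U' and U at the knots by integrating the curvature from 0
    pot <- pw_precompute(pot)
    # a normalizable Boltzmann weight needs the tails of U to grow
    if (pot$curvatures[1] == 0 && pot$slope_knots[1] >= -1e-10)
      stop_invalid("normalizable left tail",
                   "flat left tail: exp(-U) not integrable; detached density undefined")
    M <- length(pot$curvatures)
    if (pot$curvatures[M] == 0 && pot$slope_knots[M + 1] <= 1e-10)
      stop_invalid("normalizable right tail",
                   "flat right tail: exp(-U) not integrable; detached density undefined")
  }
  class(pot) <- "elastic_potential"
  pot$logZ <- log(boltzmann_norm(pot))
  pot
}

# knot slopes/energies for the piecewise form, anchored at U(0) = U'(0) = 0
pw_precompute <- function(pot) {
  b <- pot$breakpoints; cv <- pot$curvatures
  M <- length(cv)
  slope <- numeric(M + 1)
  en <- numeric(M + 1)
  # slope at knot j relative to 0: integral of curvature from 0 to b[j]
  i0 <- findInterval(0, b, all.inside = TRUE)  # segment containing 0
  slope[i0] <- -cv[i0] * (0 - b[i0])
  if (i0 > 1) for (j in (i0 - 1):1) slope[j] <- slope[j + 1] - cv[j] * (b[j + 1] - b[j])
  slope[i0 + 1] <- slope[i0] + cv[i0] * (b[i0 + 1] - b[i0])
  if (i0 + 1 <= M) for (j in (i0 + 1):M) slope[j + 1] <- slope[j] + cv[j] * (b[j + 1] - b[j])
  # energy at knots: quadratic segments, anchored so U(0) = 0
  seg_en <- function(j, xa, xb) slope[j] * (xb - xa) + 0.5 * cv[j] * (xb - xa)^2
  en[i0] <- -seg_en(i0, b[i0], 0)
  if (i0 > 1) for (j in (i0 - 1):1) en[j] <- en[j + 1] - seg_en(j, b[j], b[j + 1])
  en[i0 + 1] <- en[i0] + seg_en(i0, b[i0], b[i0 + 1])
  if (i0 + 1 <= M) for (j in (i0 + 1):M) en[j + 1] <- en[j] + seg_en(j, b[j], b[j + 1])
  pot$slope_knots <- slope
  pot$energy_knots <- en
  pot
}

#' Elastic energy, restoring force and curvature
#'
#' `potential_energy` returns `U(x)` in `kBT`; `potential_force` its exact
#' derivative `U'(x)` in `kBT / d`; `potential_curvature` the local second
#' derivative. All are vectorized total functions.
#'
#' @param pot an [elastic_potential].
#' @param x numeric vector of elongations (units of `d`).
#' @export
potential_energy <- function(pot, x) {
  switch(pot$kind,
    harmonic = 0.5 * pot$kappa * x^2,
    two_regime = {
      k <- pot$kappa; xa <- pot$x_a
      ifelse(x >= xa, 0.5 * k * x^2, 0.5 * k * xa^2 + k * xa * (x - xa))
    },
    piecewise = {
      b <- pot$breakpoints
      j <- pmin(pmax(findInterval(x, b), 1L), length(pot$curvatures))
      dxl <- x - b[j]
      pot$energy_knots[j] + pot$slope_knots[j] * dxl + 0.5 * pot$curvatures[j] * dxl^2
    })
}

#' @rdname potential_energy
#' @export
potential_force <- function(pot, x) {
  switch(pot$kind,
    harmonic = pot$kappa * x,
    two_regime = pot$kappa * pmax(x, pot$x_a),
    piecewise = {
      b <- pot$breakpoints
      j <- pmin(pmax(findInterval(x, b), 1L), length(pot$curvatures))
      pot$slope_knots[j] + pot$curvatures[j] * (x - b[j])
    })
}

#' @rdname potential_energy
#' @export
potential_curvature <- function(pot, x) {
  switch(pot$kind,
    harmonic = rep(pot$kappa, length(x)),
    two_regime = ifelse(x >= pot$x_a, pot$kappa, 0),
    piecewise = {
      j <- pmin(pmax(findInterval(x, pot$breakpoints), 1L), length(pot$curvatures))
      pot$curvatures[j]
    })
}

# Configurational partition function Z = integral exp(-U(x)) dx. Identical
# for every state because the potential is shared and only shifted by d_i.
boltzmann_norm <- function(pot) {
  if (pot$kind == "harmonic") return(sqrt(2 * pi / pot$kappa))
  # numeric: expand symmetric-ish window until U > 40 on both sides
  lim <- function(dir) {
    x <- dir
    while (potential_energy(pot, x) < 40) {
      x <- x * 2
      if (abs(x) > 1e6)
        stop_invalid("normalizable", "exp(-U) tail does not decay; cannot normalize")
    }
    x
  }
  xlo <- lim(-1); xhi <- lim(1)
  xs <- seq(xlo, xhi, length.out = 20001)
  simpson_uniform(exp(-potential_energy(pot, xs)), xs[2] - xs[1])
}

#' Thermal (Boltzmann) density of a detached head's elastic coordinate
#'
#' Detached heads equilibrate their strain much faster than the chemical
#' kinetics, so their strain density is `exp(-U(x)) / Z`.
#'
#' @inheritParams potential_energy
#' @export
boltzmann_density <- function(pot, x) {
  exp(-potential_energy(pot, x) - pot$logZ)
}

#' @export
print.elastic_potential <- function(x, ...) {
  cat(sprintf("<elastic_potential> kind = %s, kappa = %g (kappa/2 = %g)\n",
              x$kind, x$kappa, x$kappa / 2))
  if (x$kind == "two_regime") cat(sprintf("  transition point x_a = %g\n", x$x_a))
  if (x$kind == "piecewise")
    cat(sprintf("  %d segments on [%g, %g]\n", length(x$curvatures),
                min(x$breakpoints), max(x$breakpoints)))
  invisible(x)
}

# Composite Simpson on a uniform grid (falls back to a trapezoid correction
# for the last interval when the number of points is even).
simpson_uniform <- function(y, h) {
  n <- length(y)
  if (n < 2) return(0)
  if (n == 2) return(h * (y[1] + y[2]) / 2)
  m <- if (n %% 2 == 1) n else n - 1
  i <- seq_len(m)
  w <- rep(c(2, 4), length.out = m)
  w[1] <- 1; w[m] <- 1
  s <- sum(w * y[i]) * h / 3
  if (n %% 2 == 0) s <- s + h * (y[n - 1] + y[n]) / 2
  s
}
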