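#' Equilibrium variant abundance spectrum of the Moran process
#'
#' In a constant population of `N` cells undergoing Moran turnover with `mu`
#' new unique mutations per daughter per division, the expected number of
#' variants shared by exactly `k` cells approaches the stationary value
#' `V*(k) = mu * N / k` for `k = 1, ..., N - 1` (the `k = N` class is
#' absorbing and excluded).
#'
#' @param N Population size (cells), at least 2.
#' @param mu Mutation rate per daughter per division.
#' @return A data frame with columns `k` (abundance, `1..N-1`) and `V`
#'   (expected variant count).
#' @examples
#' moran_equilibrium(10, 1)  # V = 10, 5, 10/3, ...
#' @export
moran_equilibrium <- function(N, mu) {
  stopifnot(N >= 2, mu >= 0)
  k <- seq_len(N - 1)
  data.frame(k = k, V = mu * N / k)
}

#' Brute-force master-equation dynamics of the Moran abundance spectrum
#'
#' Integrates the `N - 1` coupled rate equations for the expected number of
#' variants `V_k(t)` at abundance `k` in a Moran process of size `N`:
#' `dV_k/dt = rho * (C_{k-1} + C_{k+1} - 2 C_k)` with
#' `C_k = k/N * (1 - k/N) * V_k` the mean per-event flux out of abundance
#' `k`, the `k = 1` influx term `C_0` replaced by the fixed mutation rate
#' `mu`, and the absorbing `k = N` class dropped.  This is the small-`N`
#' oracle against which the closed-form equilibrium and the continuum solver
#' are validated.
#'
#' @param N Population size; intended for small systems (`N <= 200`).
#' @param mu Mutation rate per daughter per division.
#' @param rho Moran event rate (/cell/year); sets the time scale only.
#' @param t_end Integration time (years).
#' @return A data frame with columns `k`, `V` (expected counts at `t_end`)
#'   and `C` (the flux terms `C_k`).
#' @export
moran_master_iteration <- function(N, mu, rho = 1, t_end = 1000) {
  stopifnot(N >= 2, N <= 200, mu >= 0, rho > 0, t_end > 0)
  k <- seq_len(N - 1)
  pk <- k / N * (1 - k / N)
  deriv <- function(t, V, parms) {
    C <- pk * V
    influx <- c(mu, C[-(N - 1)])          # C_{k-1}, with C_0 -> mu
    outflux_up <- c(C[-1], 0)             # C_{k+1}, with C_N = 0
    list(rho * (influx + outflux_up - 2 * C))
  }
  out <- deSolve::ode(y = rep(0, N - 1), times = c(0, t_end), func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  V <- as.numeric(out[nrow(out), -1])
  data.frame(k = k, V = V, C = pk * V)
}

#' Expected abundance spectrum of a pure-birth population, by recursion
#'
#' In a strictly growing population that starts from one unmutated cell and
#' adds one cell per division event, the expected number of variants at
#' abundance `k` after `t` events obeys
#' `V_k(t+1) = (1 - k/(t+1)) V_k(t) + (k-1)/(t+1) V_{k-1}(t)` with
#' `V_1(t+1) = (1 - 1/(t+1)) V_1(t) + 2 mu` (each division adds two daughters
#' carrying on average `mu` new unique variants each).  The process is viewed
#' in event time, so after `t` events the population has `t + 1` cells.
#'
#' @param t_events Number of division events, at least 1.
#' @param mu Mutation rate per daughter per division.
#' @return A data frame with columns `k` (`1..t_events`) and `V`.
#' @examples
#' pure_birth_recursion(3, 1)  # V = 4, 4/3, 2/3
#' @export
pure_birth_recursion <- function(t_events, mu) {
  stopifnot(t_events >= 1, mu >= 0)
  V <- numeric(t_events)
  V[1] <- 2 * mu                       # after the first division
  if (t_events > 1) {
    for (t in seq_len(t_events - 1)) { # step from t to t + 1 events
      k <- seq_len(t + 1)
      Vprev <- c(V[seq_len(t)], 0)
      Vlow <- c(0, V[seq_len(t)])
      V[k] <- (1 - k / (t + 1)) * Vprev + (k - 1) / (t + 1) * Vlow
      V[1] <- V[1] + 2 * mu
    }
  }
  data.frame(k = seq_len(t_events), V = V)
}

#' Closed-form pure-birth abundance spectrum
#'
#' Closed form of the recursion in [pure_birth_recursion]:
#' `V_k(t) = 2 mu (t + 1) / (k (k + 1))`, exact for all `1 <= k <= t`.
#'
#' @param k Abundance (cells sharing the variant); vectorized.
#' @param t_events Number of division events.
#' @param mu Mutation rate per daughter per division.
#' @return Expected variant count(s).
#' @export
pure_birth_closed <- function(k, t_events, mu) {
  stopifnot(all(k >= 1), all(k <= t_events), mu >= 0)
  2 * mu * (t_events + 1) / (k * (k + 1))
}

#' Reference frequency-spectrum shapes for growing and constant populations
#'
#' Continuum reference shapes of the variant allele frequency spectrum used
#' for regression fitting: a growing (exponentially expanding) population has
#' density `2 mu / (f + f^2)`, while a constant-size population has the
#' scale-free shape `mu / f` (the caller fixes the scale, e.g. to `mu * N`
#' in abundance space, where it coincides with [moran_equilibrium]).
#'
#' @param kind `"growing"` or `"constant"`.
#' @param mu Mutation rate per daughter per division.
#' @param f Frequencies, strictly inside `(0, 1)`; vectorized.
#' @return Density values at `f`.
#' @export
frequency_spectrum <- function(kind = c("growing", "constant"), mu, f) {
  kind <- match.arg(kind)
  if (any(f <= 0 | f >= 1)) stop("'f' must lie strictly inside (0, 1)")
  switch(kind,
    growing = 2 * mu / (f + f^2),
    constant = mu / f)
}
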