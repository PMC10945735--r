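#' Variable-step abundance grid for the VAF solver
#'
#' Builds the non-uniform spatial grid on which the expected-VAF equation is
#' discretized.  Steps grow linearly with index, `dk_i = 1 + (i - 1) alpha`,
#' so resolution is finest (unit spacing) near the variant influx point
#' `kappa = 1` and coarsest near `kappa = N`; `alpha` is fixed by requiring
#' the steps to span `[1, N]` exactly, `alpha = 2 (N - n) / ((n-1) (n-2))`.
#'
#' @param N Domain endpoint (maximum abundance, cells), `N > n`.
#' @param n Number of grid points, at least 4.
#' @return An object of class `size_grid`: list with `kappa` (node
#'   positions, `kappa[1] = 1`, `kappa[n] = N`), `steps` (the `n - 1`
#'   spacings), `alpha` and `n`.
#' @export
build_grid <- function(N, n) {
  if (n < 4) stop("'n' must be at least 4")
  if (N <= n) stop("'N' must exceed 'n' (unit spacing is the finest allowed)")
  i <- seq_len(n - 1)
  alpha <- 2 * (N - n) / ((n - 1) * (n - 2))
  steps <- 1 + (i - 1) * alpha
  kappa <- c(1, 1 + cumsum(steps))
  kappa[n] <- N   # guard against rounding drift
  structure(list(kappa = kappa, steps = steps, alpha = alpha, n = n, N = N),
            class = "size_grid")
}

# Instantaneous per-cell growth rate d log N / dt of the mean trajectory,
# consistent with population_size().
growth_rate_at <- function(params, t) {
  switch(params$growth_kind,
    "exponential-capped" = if (t < params$tM) params$gamma else 0,
    "logistic" = {
      Nt <- population_size(params, t)
      params$g_logis * (1 - Nt / params$NM)
    },
    "linear-adult" = if (t < params$tM) params$gamma
                     else params$linear_slope /
                          (1 + params$linear_slope * (t - params$tM)))
}

#' Drift, diffusion and influx coefficients of the expected-VAF equation
#'
#' The expected VAF spectrum `V(kappa, t)` (variants per unit abundance
#' `kappa = f N`) obeys
#' `dV/dt = -d/dkappa[A V] + d^2/dkappa^2[B V] + C delta(kappa - 1)` with
#' `A = gamma kappa`, `B = kappa (1 - kappa/N) rho + gamma kappa / 2` and
#' `C = 2 mu N (rho + gamma + phi/2)`.  Growth advects variants to larger
#' abundance, Moran turnover diffuses them, and every division injects new
#' variants at `kappa = 1`; asymmetric divisions leave a single daughter in
#' the pool and therefore supply mutations at half weight.  Rates are the
#' phase-dependent effective rates at age `t` (growth from the configured
#' growth curve, homeostasis once `N(t) > NH`).
#'
#' @param params A [model_params] object.
#' @param kappa Abundance coordinate(s), `0 <= kappa`; values beyond `N(t)`
#'   get zero coefficients.
#' @param t Age (years).
#' @return List with vectors `A`, `B` and scalar `C`.
#' @export
pde_coefficients <- function(params, kappa, t) {
  stopifnot(inherits(params, "model_params"), all(kappa >= 0), t >= 0)
  Nt <- population_size(params, t)
  g <- growth_rate_at(params, t)
  homeo <- Nt > params$NH
  rho <- if (homeo) params$rho else 0
  phi <- if (homeo) params$phi else 0
  A <- g * kappa
  B <- kappa * pmax(0, 1 - kappa / Nt) * rho + g * kappa / 2
  off <- kappa > Nt
  A[off] <- 0
  B[off] <- 0
  list(A = A, B = B, C = 2 * params$mu * Nt * (rho + g + phi / 2))
}

#' Numerically evolve the expected VAF spectrum
#'
#' Integrates the expected-VAF equation (see [pde_coefficients()]) from an
#' empty spectrum at `t = 0` to the observation age by the method of lines:
#' flux-conservative central finite differences on the variable-step grid of
#' [build_grid()], a ghost node at `kappa = 0` and the `kappa = N` node held
#' at zero (absorbing extinction and fixation boundaries), the delta influx
#' approximated as a step of height `2 / (dk_1 + dk_2)` at the `kappa = 1`
#' node, and stiff adaptive implicit time integration (banded-Jacobian
#' `lsoda`).  Integration is split at the phase switch times so the solver
#' never steps across a rate discontinuity.
#'
#' @param params A [model_params] object.
#' @param t_obs Observation age (years), positive; may be a vector of
#'   increasing times, in which case a solution is returned for each.
#' @param n Number of grid points (default 400).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param V0 Optional initial spectrum on the grid nodes (default: zero).
#' @param influx Logical; set `FALSE` to disable the mutation influx term
#'   (used for stationarity checks).
#' @param t_start Time at which `V0` is imposed (default 0; setting it at or
#'   beyond `tM` starts the integration inside the mature phase).
#' @return For scalar `t_obs` an object of class `vaf_solution`: list with
#'   `kappa`, `value` (variants per unit abundance), `t_obs`, `N_obs`,
#'   `grid` and `params`.  For vector `t_obs`, a list of such objects.
#' @export
evolve_expected_vaf <- function(params, t_obs, n = 400, rtol = 1e-6,
                                atol = 1e-10, V0 = NULL, influx = TRUE,
                                t_start = 0) {
  stopifnot(inherits(params, "model_params"), all(t_obs > t_start),
            !is.unsorted(t_obs), t_start >= 0)
  t_max <- max(t_obs)
  Ndom <- ceiling(max(population_size(params, t_max), params$NM))
  grid <- build_grid(Ndom, n)
  kap <- grid$kappa
  d <- c(1, grid$steps)          # edge spacings incl. ghost edge [0, 1]
  h <- diff(c(0, kap, Ndom)) / 2 # half-spacings
  vol <- h[-length(h)] + h[-1]   # control volumes; vol[1] = (1 + dk_1)/2
  vol <- vol[seq_len(n)]
  src_height <- 2 / (grid$steps[1] + grid$steps[2])

  rhs <- function(t, V, parms) {
    V[n] <- 0
    co <- pde_coefficients(params, kap, t)
    AV <- c(0, co$A * V)                       # ghost node kappa = 0
    BV <- c(0, co$B * V)
    # fluxes at the n edges left of each node (edge e between nodes e-1, e)
    Fadv <- (AV[-(n + 1)] + AV[-1]) / 2
    Fadv[1] <- 0                               # no advection across kappa=0
    Fdif <- diff(BV) / d
    Fl <- Fadv - Fdif
    dV <- (Fl - c(Fl[-1], 0)) / vol            # no flux through kappa = N
    if (influx) dV[1] <- dV[1] + co$C * src_height
    dV[n] <- 0
    list(dV)
  }

  splits <- sort(unique(c(params$tH, params$tM, t_obs)))
  splits <- splits[splits > t_start & splits <= t_max]
  times <- c(t_start, splits)
  V <- if (is.null(V0)) rep(0, n) else as.numeric(V0)
  stopifnot(length(V) == n)
  out <- vector("list", length(t_obs))
  for (s in seq_len(length(times) - 1)) {
    sol <- deSolve::ode(y = V, times = times[s:(s + 1)], func = rhs,
                        parms = NULL, method = "lsoda",
                        jactype = "bandint", bandup = 1, banddown = 1,
                        rtol = rtol, atol = atol, maxsteps = 200000)
    if (attr(sol, "istate")[1] < 0)
      stop("VAF solver failed to converge at t = ", times[s + 1],
           " (rtol = ", rtol, ", atol = ", atol, ")")
    V <- as.numeric(sol[nrow(sol), -1])
    ti <- times[s + 1]
    if (ti %in% t_obs) {
      idx <- which(t_obs == ti)
      out[[idx]] <- structure(list(
        kappa = kap, value = V, t_obs = ti,
        N_obs = population_size(params, ti), grid = grid, params = params),
        class = "vaf_solution")
    }
  }
  if (length(t_obs) == 1L) out[[1]] else out
}

#' @export
print.vaf_solution <- function(x, ...) {
  cat(sprintf("Expected VAF spectrum at t = %g y (N = %g, %d grid points)\n",
              x$t_obs, x$N_obs, length(x$kappa)))
  cat(sprintf("  V(1) = %.4g, total variants = %.4g\n",
              x$value[1], sum(x$value * c(diff(x$kappa), 0))))
  invisible(x)
}

#' Evaluate an expected-VAF solution at integer abundances
#'
#' Interpolates the continuum solution `V(kappa)` onto integer abundances
#' `k = 1, ..., kmax`, giving the expected number of variants per abundance
#' class (the counterpart of a discrete spectrum's `V_k`).  Interpolation is
#' linear in `log kappa` / `log V` where the solution is positive, with
#' linear fallback elsewhere.
#'
#' @param sol A `vaf_solution`.
#' @param kmax Largest abundance to report (default: the population size at
#'   observation).
#' @return Numeric vector of length `kmax`, the expected counts `V_k`.
#' @export
expected_spectrum <- function(sol, kmax = floor(sol$N_obs)) {
  stopifnot(inherits(sol, "vaf_solution"), kmax >= 1)
  k <- seq_len(kmax)
  pos <- sol$value > 0
  if (sum(pos) >= 2) {
    f <- approx(log(sol$kappa[pos]), log(sol$value[pos]), xout = log(k),
                rule = 2)
    v <- exp(f$y)
    # fall back to linear interpolation where the solution is not positive
    lin <- approx(sol$kappa, sol$value, xout = k, rule = 2)$y
    v[!is.finite(v)] <- lin[!is.finite(v)]
    neg <- approx(sol$kappa, as.numeric(!pos), xout = k, rule = 2)$y > 0
    v[neg] <- lin[neg]
  } else {
    v <- approx(sol$kappa, sol$value, xout = k, rule = 2)$y
  }
  pmax(v, 0)
}

#' Expected VAF spectra along a sequence of observation times
#'
#' Convenience wrapper returning the expected spectrum at each requested
#' age, used to follow the wave-like equilibration of the spectrum from the
#' growing-population shape towards the constant-population shape after
#' maturity.
#'
#' @param params A [model_params] object.
#' @param t_list Increasing observation ages (years), all beyond maturity.
#' @param ... Passed to [evolve_expected_vaf()].
#' @return A list of `vaf_solution` objects, one per time.
#' @export
transition_profile <- function(params, t_list, ...) {
  stopifnot(all(diff(t_list) > 0))
  sols <- evolve_expected_vaf(params, t_list, ...)
  if (inherits(sols, "vaf_solution")) sols <- list(sols)
  sols
}
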