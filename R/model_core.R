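#' Demographic and mutational parameters of the three-phase stem cell model
#'
#' Constructs the parameter set of the stem cell model: a population grows
#' exponentially from one founder cell at rate `gamma = log(NM)/tM` until it
#' reaches its mature size `NM` at age `tM`; once the population exceeds `NH`
#' cells, homeostatic turnover starts alongside growth (the mixed phase);
#' after `tM` the population is constant and only homeostatic events occur.
#' Homeostatic turnover consists of Moran events (a symmetric division paired
#' with a removal) at rate `rho` per cell and asymmetric divisions at rate
#' `phi` per cell.  The user supplies the total homeostatic division rate
#' `lam = rho + phi` and the asymmetric fraction `p = phi/lam`, from which
#' `rho` and `phi` are derived; this is the parameterization in which the
#' population-size inference operates.  Every daughter cell retained in the
#' stem cell pool acquires `Poisson(mu)` new mutations at birth (infinite
#' sites: all mutations are unique).
#'
#' @param NM Mature population size (cells), at least 2.
#' @param tM Age at maturity (years).
#' @param NH Population size at the onset of homeostatic divisions (cells),
#'   between 1 and `NM`.
#' @param lam Total homeostatic division rate `rho + phi` (/cell/year).
#' @param p Fraction of homeostatic divisions that are asymmetric,
#'   `p = phi/lam`, in `[0, 1]`.
#' @param mu Mutation rate (mutations per daughter cell per division).
#' @param growth_kind One of `"exponential-capped"` (exponential growth
#'   truncated at `NM`), `"logistic"` (logistic growth from one cell, maturity
#'   taken where the population reaches `0.99 * NM`), or `"linear-adult"`
#'   (exponential to `NM` at `tM`, then slow linear growth
#'   `NM * (1 + linear_slope * (t - tM))`).
#' @param linear_slope Relative growth slope of the adult population for
#'   `growth_kind = "linear-adult"` (/year).  Ignored otherwise.
#'
#' @return An object of class `model_params`: a list with the supplied fields
#'   plus the derived rates `gamma`, `rho`, `phi` and the mixed-phase onset
#'   time `tH` (the age at which the population reaches `NH`).
#'
#' @examples
#' par <- model_params(NM = 1e4, tM = 5, NH = 50, lam = 5, p = 0.4, mu = 1.2)
#' par$gamma            # log(1e4)/5
#' c(par$rho, par$phi)  # 3, 2
#' @export
model_params <- function(NM, tM, NH = 1, lam = 0, p = 0, mu = 1,
                         growth_kind = c("exponential-capped", "logistic",
                                         "linear-adult"),
                         linear_slope = 0.005) {
  growth_kind <- match.arg(growth_kind)
  if (!is.numeric(NM) || length(NM) != 1L || NM < 2)
    stop("'NM' must be a single number >= 2")
  if (!is.numeric(tM) || length(tM) != 1L || tM <= 0)
    stop("'tM' must be a single positive number")
  if (NH < 1 || NH > NM)
    stop("'NH' must satisfy 1 <= NH <= NM")
  if (lam < 0) stop("'lam' must be non-negative")
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  if (mu < 0) stop("'mu' must be non-negative")
  if (linear_slope < 0) stop("'linear_slope' must be non-negative")

  gamma <- log(NM) / tM
  # Logistic growth from a single cell: N(t) = NM / (1 + (NM - 1) exp(-g t)).
  # Maturity is the age where N reaches 0.99 * NM, forced to equal tM by
  # choice of the logistic rate g.
  if (growth_kind == "logistic") {
    g_logis <- log((NM - 1) * 0.99 / max(1 - 0.99, 1e-12)) / tM
  } else {
    g_logis <- NA_real_
  }
  tH <- growth_onset_time(NH, NM, tM, gamma, growth_kind, g_logis)

  structure(list(
    NM = NM, tM = tM, NH = NH,
    lam = lam, p = p, mu = mu,
    gamma = gamma, rho = (1 - p) * lam, phi = p * lam,
    growth_kind = growth_kind, linear_slope = linear_slope,
    g_logis = g_logis, tH = tH
  ), class = "model_params")
}

# Age at which the mean population trajectory first reaches NH.
growth_onset_time <- function(NH, NM, tM, gamma, growth_kind, g_logis) {
  if (NH <= 1) return(0)
  switch(growth_kind,
    "exponential-capped" = ,
    "linear-adult" = min(log(NH) / gamma, tM),
    "logistic" = {
      if (NH >= 0.99 * NM) return(tM)
      # invert N(t) = NM / (1 + (NM - 1) exp(-g t))
      log((NM - 1) / (NM / NH - 1)) / g_logis
    })
}

#' @export
print.model_params <- function(x, ...) {
  cat("Three-phase stem cell model parameters\n")
  cat(sprintf("  NM = %g cells, tM = %g y, NH = %g cells (%s growth)\n",
              x$NM, x$tM, x$NH, x$growth_kind))
  cat(sprintf("  gamma = %.4g /y, lam = %g /y (rho = %g, phi = %g, p = %g)\n",
              x$gamma, x$lam, x$rho, x$phi, x$p))
  cat(sprintf("  mu = %g mutations/daughter/division\n", x$mu))
  invisible(x)
}

#' Per-cell event rates in force at a given age and population size
#'
#' The growth, Moran and asymmetric division rates are piecewise constant:
#' growth divisions run at rate `gamma` while `t < tM`, homeostatic events
#' (Moran at `rho`, asymmetric at `phi`) run once the population exceeds
#' `NH`.  Early phase (`t < tM`, `N <= NH`) therefore has rates
#' `(gamma, 0, 0)`, the mixed phase (`t < tM`, `N > NH`) has
#' `(gamma, rho, phi)` and the mature phase (`t >= tM`) has `(0, rho, phi)`.
#'
#' @param params A [model_params] object.
#' @param t Age (years), non-negative.
#' @param N Current population size (cells), at least 1.
#' @return A named list with elements `gamma`, `rho`, `phi` (per-cell rates
#'   per year in force at `(t, N)`).
#' @export
rates_at <- function(params, t, N) {
  stopifnot(inherits(params, "model_params"), t >= 0, N >= 1)
  growing <- t < params$tM
  homeo <- N > params$NH
  list(gamma = if (growing) params$gamma else 0,
       rho   = if (homeo) params$rho else 0,
       phi   = if (homeo) params$phi else 0)
}

#' Mean population size trajectory
#'
#' Deterministic population size `N(t)` for the configured growth model:
#' `exponential-capped` gives `min(exp(gamma t), NM)`; `logistic` gives
#' growth from a single cell saturating at `NM`, scaled so that `0.99 * NM`
#' is reached at `tM`; `linear-adult` follows the capped exponential and then
#' grows linearly as `NM * (1 + linear_slope * (t - tM))` during adulthood.
#'
#' @param params A [model_params] object.
#' @param t Age (years), non-negative; may be a vector.
#' @return Population size(s) in cells.
#' @export
population_size <- function(params, t) {
  stopifnot(inherits(params, "model_params"), all(t >= 0))
  switch(params$growth_kind,
    "exponential-capped" = pmin(exp(params$gamma * t), params$NM),
    "logistic" = params$NM / (1 + (params$NM - 1) * exp(-params$g_logis * t)),
    "linear-adult" = ifelse(t < params$tM,
      pmin(exp(params$gamma * t), params$NM),
      params$NM * (1 + params$linear_slope * (t - params$tM))))
}
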