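#' Summary moments of a mutational burden sample
#'
#' Mean, unbiased variance, dispersion ratio `theta = Var(m)/E(m)` and
#' standard error of the mean of a set of per-cell mutation counts.  Under
#' division-linked Poisson mutation the burden is a compound Poisson sum
#' over a cell's past divisions, so `E(m) = E(y) E(u)` and
#' `Var(m) = E(y) Var(u) + E(u)^2 Var(y)` with `y` the divisions per lineage
#' and `u` the mutations per division; the moments reported here are the
#' sample-side inputs to those identities.
#'
#' @param b A [burden_sample] or a numeric vector of burdens (at least 2
#'   cells).
#' @return List with `mean`, `var`, `theta`, `se_mean` and `S`.
#' @export
burden_moments <- function(b) {
  if (!inherits(b, "burden_sample")) b <- burden_sample(b)
  if (b$S < 2) stop("need at least 2 cells for a variance")
  list(mean = b$mean, var = b$var, theta = b$theta, se_mean = b$se_mean,
       S = b$S)
}

#' Expected divisions per lineage from the mean burden
#'
#' With Poisson(`mu`) mutations per daughter per division, the mean burden
#' satisfies `E(m) = mu * E(y)`, so the average number of divisions in a
#' cell's past is estimated as `E(y) = E(m) / mu`.
#'
#' @param mean_burden Sample mean burden (mutations/cell).
#' @param mu Mutation rate per daughter per division, positive.
#' @return Estimated divisions per lineage.
#' @export
estimate_divisions <- function(mean_burden, mu) {
  if (mu <= 0) stop("'mu' must be positive")
  stopifnot(mean_burden >= 0)
  mean_burden / mu
}

#' Per-division mutation rate from burden over-dispersion
#'
#' Moment estimator `mu = (Var(m)/E(m) - 1) * E(y)/Var(y)`: under
#' division-linked Poisson mutation the excess of the burden dispersion
#' ratio over one, `theta - 1`, equals `mu` times the dispersion
#' `Var(y)/E(y)` of the divisions per lineage, so dividing by the assumed
#' division dispersion recovers `mu`.  `dispersion = 1` corresponds to
#' Poisson-distributed
#' divisions per lineage (exponential waiting times).  A negative estimate
#' signals under-dispersed burdens and is returned with a warning rather
#' than clamped.
#'
#' @param mean_burden Sample mean burden, positive.
#' @param var_burden Sample burden variance.
#' @param dispersion Assumed `Var(y)/E(y)` of divisions per lineage
#'   (default 1, the Poisson model).
#' @return Estimated mutation rate per daughter per division.
#' @export
estimate_mu <- function(mean_burden, var_burden, dispersion = 1) {
  if (mean_burden <= 0) stop("'mean_burden' must be positive")
  if (dispersion <= 0) stop("'dispersion' must be positive")
  mu_hat <- (var_burden / mean_burden - 1) / dispersion
  if (mu_hat < 0)
    warning("burden sample is under-dispersed (Var(m) < E(m)); ",
            "mutation rate estimate is negative")
  mu_hat
}

#' Compound Poisson burden distribution
#'
#' Probability mass function of the mutational burden when a cell's past
#' holds `Poisson(Ey)` divisions, each contributing `Poisson(mu)` mutations:
#' `P(m) = sum_d dpois(d, Ey) dpois(m, d mu)`, with mean `Ey * mu` and
#' variance `Ey * mu * (1 + mu)`.  This is the between-population null for
#' the single-cell burden distribution; within one population, shared
#' ancestry narrows the realized distribution relative to it.
#'
#' @param Ey Expected divisions per lineage, positive.
#' @param mu Mutation rate per daughter per division, positive.
#' @param m_range Integer burdens at which to evaluate the pmf (default: a
#'   range covering all but `1e-10` of the mass).
#' @return Data frame with columns `m` and `prob`.
#' @export
compound_poisson_pmf <- function(Ey, mu, m_range = NULL) {
  stopifnot(Ey > 0, mu > 0)
  if (is.null(m_range)) {
    mean_m <- Ey * mu
    sd_m <- sqrt(Ey * mu * (1 + mu))
    m_range <- max(0, floor(mean_m - 12 * sd_m)):ceiling(mean_m + 12 * sd_m)
  }
  d <- stats::qpois(1e-15, Ey):stats::qpois(1e-15, Ey, lower.tail = FALSE)
  wd <- dpois(d, Ey)
  prob <- vapply(m_range,
                 function(m) sum(wd * dpois(m, d * mu)),
                 numeric(1))
  data.frame(m = m_range, prob = prob)
}

#' Expected divisions per lineage under the demographic model
#'
#' Integrates the per-lineage division accrual over the three demographic
#' phases: growth divisions add `2 gamma (1 - 1/(N + 1))` divisions per
#' lineage per year, Moran events add `2 rho (1 - 1/(2N))` (the factor two
#' because both daughters stay in the pool; the `1/N` correction covers
#' self-replacement), and asymmetric divisions add `phi` (a single surviving
#' daughter).  Uses numerical quadrature with the integral split at the
#' homeostasis onset `tH` and maturity `tM`.
#'
#' @param params A [model_params] object.
#' @param t Age (years), positive.
#' @return Expected number of divisions per lineage `y(t)`.
#' @export
expected_divisions <- function(params, t) {
  stopifnot(inherits(params, "model_params"), t > 0)
  integrand <- function(tau) {
    Nt <- population_size(params, tau)
    g <- vapply(tau, function(x) growth_rate_at(params, x), numeric(1))
    homeo <- as.numeric(Nt > params$NH)
    2 * g * (1 - 1 / (Nt + 1)) +
      homeo * (2 * params$rho * (1 - 1 / (2 * Nt)) + params$phi)
  }
  cuts <- sort(unique(pmin(c(params$tH, params$tM, t), t)))
  cuts <- c(0, cuts[cuts > 0])
  total <- 0
  for (s in seq_len(length(cuts) - 1)) {
    total <- total + integrate(integrand, cuts[s], cuts[s + 1],
                               rel.tol = 1e-10,
                               subdivisions = 500L)$value
  }
  total
}

#' Homeostatic division rate solving the division integral
#'
#' Finds the total homeostatic division rate `lam` such that the expected
#' divisions per lineage [expected_divisions()] at age `t` equals the
#' observed value `R = E(m)/mu`, holding the demographic geometry
#' `(NM, NH, tM)` and the asymmetric fraction `p` fixed.  Solved by
#' bracketed one-dimensional root finding (`y(t)` is monotone in `lam`).
#'
#' @param R Observed divisions per lineage (`E(m)/mu`), positive.
#' @param NM,NH,tM,p Demographic parameters, as in [model_params()].
#' @param t Age (years), beyond `tM`.
#' @param growth_kind Growth curve, as in [model_params()].
#' @param tol Absolute root tolerance on `lam`.
#' @return Estimated `lam` (/cell/year).
#' @export
solve_lambda <- function(R, NM, NH, tM, p, t,
                         growth_kind = "exponential-capped", tol = 1e-10) {
  stopifnot(R > 0, t > tM)
  y_of <- function(lam)
    expected_divisions(model_params(NM = NM, tM = tM, NH = NH, lam = lam,
                                    p = p, mu = 1,
                                    growth_kind = growth_kind), t)
  y0 <- y_of(0)
  if (R < y0)
    stop(sprintf(
      "no root: R = %.4g is below the growth-phase division count %.4g",
      R, y0))
  hi <- 1
  while (y_of(hi) < R) hi <- hi * 2
  uniroot(function(l) y_of(l) - R, c(0, hi), tol = tol)$root
}

#' Sweep of the division-rate inference over unidentified parameters
#'
#' The burden distribution pins down the divisions per lineage `R` but not
#' the demographic geometry, so `lam` is re-solved on a grid of plausible
#' `(tM, NH, NM, p)` combinations; the spread of the resulting `lam` values
#' is the parameter-uncertainty interval, reported separately from the
#' statistical standard error on `R`.
#'
#' @param R Observed divisions per lineage.
#' @param t Age (years).
#' @param tM,NH,NM,p Numeric grids of the swept parameters.
#' @param R_se Optional standard error on `R`; when given, `lam` is also
#'   solved at `R +- R_se` at the central geometry.
#' @return List with `grid` (data frame of swept combinations and `lam`),
#'   `central` (median `lam`), `range` (min/max) and, when `R_se` is given,
#'   `se_range`.
#' @export
sweep_lambda <- function(R, t,
                         tM = c(0.2, 2.5, 5, 7.5, 10),
                         NH = c(1, 50, 250, 1000),
                         NM = c(2e4, 1e5, 5e5),
                         p = seq(0, 1, by = 0.25),
                         R_se = NULL) {
  grid <- expand.grid(tM = tM, NH = NH, NM = NM, p = p,
                      KEEP.OUT.ATTRS = FALSE)
  grid$lam <- mapply(function(tMi, NHi, NMi, pi)
    solve_lambda(R, NM = NMi, NH = NHi, tM = tMi, p = pi, t = t),
    grid$tM, grid$NH, grid$NM, grid$p)
  out <- list(grid = grid, central = median(grid$lam),
              range = range(grid$lam))
  if (!is.null(R_se)) {
    mid <- lapply(list(R - R_se, R + R_se), function(Ri)
      solve_lambda(Ri, NM = median(NM), NH = median(NH), tM = median(tM),
                   p = 0.5, t = t))
    out$se_range <- sort(unlist(mid))
  }
  out
}
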