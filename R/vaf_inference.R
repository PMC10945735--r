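#' Mutation rate by linear regression against a reference spectrum shape
#'
#' Least-squares estimator of the per-division mutation rate from a VAF
#' spectrum: if the data spectrum `V_d` has the shape of a unit-rate
#' reference `V_r` (so `E(V_d) = mu * V_r`), then
#' `mu = Cov(V_d, V_r) / Var(V_r)`.  The estimator is exactly
#' scale-equivariant in the data and insensitive to additive offsets.
#'
#' @param V_data Observed variant counts on a fixed frequency support.
#' @param V_ref Reference expected counts on the same support, computed at
#'   unit mutation rate; must not be constant.
#' @return Estimated mutation rate (mutations/daughter/division).
#' @seealso [reference_spectrum()] for the growing- and constant-population
#'   reference shapes.
#' @export
regress_mu <- function(V_data, V_ref) {
  stopifnot(length(V_data) == length(V_ref), length(V_ref) >= 3)
  if (var(V_ref) == 0) stop("degenerate reference spectrum (zero variance)")
  sum((V_data - mean(V_data)) * (V_ref - mean(V_ref))) /
    sum((V_ref - mean(V_ref))^2)
}

#' Sample-level reference spectrum shapes at unit mutation rate
#'
#' Expected sampled VAF spectra for the two limiting demographies, evaluated
#' at `mu = 1` for use as regression references: the growing population uses
#' the pure-birth spectrum `V_j = 2 N / (j (j + 1))` and the constant
#' population the Moran equilibrium supplied with two mutated daughters per
#' division, `V_j = 2 N / j`.  Both are pushed through the hypergeometric
#' sampling transform at sample size `S`, so the reference lives on the
#' data's own support of sample frequencies; this removes any binning or
#' normalization arbitrariness.
#'
#' @param kind `"growing"` or `"constant"`.
#' @param N Population size (cells).
#' @param S Sample size (cells), `S <= N`; `S = N` returns the population
#'   spectrum itself.
#' @param i Sample abundance classes to report (default `1..S`).
#' @return Numeric vector of expected counts at sample abundances `i`.
#' @export
reference_spectrum <- function(kind = c("growing", "constant"), N, S = N,
                               i = seq_len(S)) {
  kind <- match.arg(kind)
  j <- seq_len(N)
  V <- switch(kind, growing = 2 * N / (j * (j + 1)), constant = 2 * N / j)
  V[N] <- 0                       # fixed class carries no information
  if (S == N) return(V[i])
  expected_sampled_vaf(V, S)$count[i]
}

#' Average VAF spectrum of a donor age group
#'
#' Per-bin mean of several donors' VAF spectra on a common frequency
#' binning, as used to compare age brackets of a bulk-sequenced cohort
#' against the growing- and constant-population reference shapes.
#'
#' @param spectra A list of numeric vectors (counts per bin, identical
#'   length) or data frames with columns `f` and `count` on an identical
#'   `f` grid.
#' @return A list with `count` (mean spectrum), `f` (the common grid, if
#'   supplied) and `n_donors`.
#' @export
average_age_group <- function(spectra) {
  if (length(spectra) < 1) stop("need at least one donor spectrum")
  f <- NULL
  mats <- lapply(spectra, function(s) {
    if (is.data.frame(s)) {
      if (!all(c("f", "count") %in% names(s)))
        stop("data-frame spectra need columns 'f' and 'count'")
      if (is.null(f)) f <<- s$f
      else if (!isTRUE(all.equal(f, s$f)))
        stop("donor spectra are not on a common frequency grid")
      s$count
    } else as.numeric(s)
  })
  len <- unique(lengths(mats))
  if (length(len) != 1) stop("donor spectra differ in length")
  list(count = Reduce(`+`, mats) / length(mats), f = f,
       n_donors = length(mats))
}

# Expected number of variants at sample abundance 1 for a population
# spectrum given as counts indexed by j = 1..N.
sampled_singleton_expectation <- function(V, S) {
  N <- length(V)
  j <- seq_len(N)
  nz <- which(V > 0)
  sum(V[nz] * dhyper(1, m = j[nz], n = N - j[nz], k = S))
}

#' Lowest-frequency prediction error at one parameter-space point
#'
#' Computes `delta_vf`, the difference between the model-predicted and the
#' observed number of variants at the lowest sample frequency `1/S`.  The
#' prediction evolves the expected VAF spectrum to the observation age for
#' the candidate `(NM, p)` (with the remaining parameters fixed), applies
#' the hypergeometric sampling transform, and reads off the
#' sample-singleton class.  The lowest-frequency class is used because its
#' across-replicate variance is the smallest of all sampled classes.
#'
#' @param NM,p Candidate mature population size and asymmetric fraction.
#' @param fixed Named list of the fixed quantities: `tM`, `NH`, `mu`, `lam`,
#'   `t_obs`, `S`, and optionally `n` (grid points, default 400).
#' @param data_lowest_count Observed variant count at sample frequency
#'   `1/S`, non-negative.
#' @return `predicted - observed` (a signed count).
#' @export
delta_vf <- function(NM, p, fixed, data_lowest_count) {
  stopifnot(data_lowest_count >= 0,
            all(c("tM", "NH", "mu", "lam", "t_obs", "S") %in% names(fixed)))
  n <- if (is.null(fixed$n)) 400 else fixed$n
  params <- model_params(NM = NM, tM = fixed$tM, NH = fixed$NH,
                         lam = fixed$lam, p = p, mu = fixed$mu)
  sol <- evolve_expected_vaf(params, fixed$t_obs, n = n)
  Vk <- expected_spectrum(sol)
  sampled_singleton_expectation(Vk, fixed$S) - data_lowest_count
}

#' Lattice of lowest-frequency prediction errors over (NM, p)
#'
#' Evaluates [delta_vf()] on a rectangular lattice of candidate mature
#' population sizes and asymmetric fractions.  The zero crossing of the
#' resulting error surface is the curve of `(NM, p)` combinations consistent
#' with the observed data (see [zero_contour()]).
#'
#' @param data_lowest_count Observed variant count at sample frequency `1/S`.
#' @param NM_range Vector of lattice population sizes (at least 2 distinct).
#' @param p_range Vector of lattice asymmetric fractions (at least 1).
#' @param fixed Fixed parameters, as in [delta_vf()].
#' @param verbose Print progress per lattice point.
#' @return An object of class `fit_lattice`: list with `NM_axis`, `p_axis`,
#'   `delta` (matrix `length(NM_axis)` x `length(p_axis)`), `fixed` and
#'   `observed`.
#' @export
lattice_fit <- function(data_lowest_count, NM_range, p_range, fixed,
                        verbose = FALSE) {
  NM_range <- sort(unique(NM_range))
  p_range <- sort(unique(p_range))
  if (length(NM_range) < 2) stop("'NM_range' must contain at least 2 values")
  delta <- matrix(NA_real_, length(NM_range), length(p_range),
                  dimnames = list(NULL, NULL))
  for (jp in seq_along(p_range)) {
    for (im in seq_along(NM_range)) {
      delta[im, jp] <- delta_vf(NM_range[im], p_range[jp], fixed,
                                data_lowest_count)
      if (verbose)
        message(sprintf("NM = %g, p = %g: delta = %.3f",
                        NM_range[im], p_range[jp], delta[im, jp]))
    }
  }
  structure(list(NM_axis = NM_range, p_axis = p_range, delta = delta,
                 fixed = fixed, observed = data_lowest_count),
            class = "fit_lattice")
}

#' @export
print.fit_lattice <- function(x, ...) {
  cat(sprintf(
    "Lowest-frequency fit lattice: %d NM x %d p points, observed count %.4g\n",
    length(x$NM_axis), length(x$p_axis), x$observed))
  invisible(x)
}

#' Zero-error contour of a fit lattice and the maximal population size
#'
#' For each asymmetric fraction on the lattice, interpolates the error
#' `delta_vf` along the population-size axis (spline in `log NM`) and
#' locates its zero crossing, giving the consistency curve `NM(p)`.  The
#' predicted singleton count grows with `NM`, so the crossing is unique
#' when present; rows without a sign change are reported as `NA`.
#' `max_population()` reads off the curve at `p = 0`, the largest
#' population size able to produce the observed data (exclusively symmetric
#' divisions).
#'
#' @param lattice A `fit_lattice`.
#' @return Data frame with columns `p` and `NM` (the interpolated zero
#'   crossing, `NA` where `delta_vf` does not change sign).
#' @export
zero_contour <- function(lattice) {
  stopifnot(inherits(lattice, "fit_lattice"))
  lx <- log(lattice$NM_axis)
  NM_at <- vapply(seq_along(lattice$p_axis), function(jp) {
    dcol <- lattice$delta[, jp]
    if (all(dcol > 0) || all(dcol < 0)) return(NA_real_)
    sf <- splinefun(lx, dcol, method = "monoH.FC")
    cross <- which(diff(sign(dcol)) != 0)[1]
    exp(uniroot(sf, lx[c(cross, cross + 1)])$root)
  }, numeric(1))
  if (all(is.na(NM_at)))
    warning("delta_vf does not change sign anywhere on the lattice; ",
            "no zero-error contour exists")
  data.frame(p = lattice$p_axis, NM = NM_at)
}

#' @rdname zero_contour
#' @param contour A contour data frame from [zero_contour()].
#' @return `max_population()`: the contour population size at `p = 0`
#'   (interpolated if `p = 0` is not a lattice point).
#' @export
max_population <- function(contour) {
  stopifnot(is.data.frame(contour), all(c("p", "NM") %in% names(contour)))
  ok <- !is.na(contour$NM)
  if (!any(ok)) return(NA_real_)
  if (any(contour$p[ok] == 0)) return(contour$NM[ok & contour$p == 0][1])
  if (sum(ok) == 1) return(contour$NM[ok])
  # linear extrapolation in (p, log NM) from the two smallest available p
  pp <- contour$p[ok][order(contour$p[ok])][1:2]
  ll <- log(contour$NM[ok][order(contour$p[ok])][1:2])
  exp(ll[1] - pp[1] * diff(ll) / diff(pp))
}
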