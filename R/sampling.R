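#' Expected VAF spectrum of a uniform cell sample
#'
#' Transforms a whole-population abundance spectrum into the expected
#' spectrum seen in a uniform sample of `S` cells drawn without replacement:
#' `Vtilde(i) = sum_j V(j) * P_hyper(i; j, N - j, S)` for sample abundances
#' `i = 1, ..., S`.  The undetected class `i = 0` is computed internally for
#' normalization but not reported.  Terms are evaluated with the stable
#' hypergeometric density, so population sizes up to about `1e6` are
#' practical.
#'
#' @param V A `vaf_spectrum`, or a numeric vector of expected counts indexed
#'   by population abundance `j = 1..N`.
#' @param S Sample size (cells), `1 <= S <= N`.
#' @param N Population size; required when `V` is a bare vector shorter than
#'   `N` (missing classes are taken as zero), defaults to `length(V)`.
#' @return An object of class `sampled_spectrum`: list with `count`
#'   (expected counts at sample abundance `1..S`), `S`, `parent_N` and
#'   `undetected` (the expected number of population variants absent from
#'   the sample).
#' @examples
#' # one variant shared by 2 of 4 cells, sample 2: detected singleton 2/3,
#' # doubleton 1/6 (enumeration over the 6 equally likely subsets)
#' expected_sampled_vaf(c(0, 1, 0, 0), S = 2)
#' @export
expected_sampled_vaf <- function(V, S, N = NULL) {
  if (inherits(V, "vaf_spectrum")) {
    N <- V$size
    V <- V$count
  } else {
    if (is.null(N)) N <- length(V)
    stopifnot(length(V) <= N)
    if (length(V) < N) V <- c(V, rep(0, N - length(V)))
  }
  if (S < 1 || S > N) stop("'S' must satisfy 1 <= S <= N")
  S <- as.integer(S)
  j <- seq_len(N)
  nz <- which(V > 0)
  counts <- numeric(S + 1)             # i = 0..S
  for (i in 0:S) {
    w <- dhyper(i, m = j[nz], n = N - j[nz], k = S)
    counts[i + 1] <- sum(V[nz] * w)
  }
  structure(list(count = counts[-1], S = S, parent_N = N,
                 undetected = counts[1]),
            class = "sampled_spectrum")
}

#' @export
print.sampled_spectrum <- function(x, ...) {
  cat(sprintf(
    "Sampled VAF spectrum: S = %d of N = %d; %.4g variants detected (%.4g undetected)\n",
    x$S, x$parent_N, sum(x$count), x$undetected))
  invisible(x)
}

#' @export
as.data.frame.sampled_spectrum <- function(x, ...) {
  data.frame(i = seq_len(x$S), f = seq_len(x$S) / x$S, count = x$count)
}

#' Realized sample VAF spectrum from a genealogy
#'
#' Draws one uniform sample of `S` cells from a simulated genealogy and
#' returns the realized sample spectrum.  Its expectation over repeated
#' draws equals [expected_sampled_vaf()] applied to the population spectrum.
#'
#' @param g A `genealogy`.
#' @param S Sample size.
#' @param seed Optional integer seed.
#' @return A `sampled_spectrum` with realized (integer) counts.
#' @export
stochastic_sample_spectrum <- function(g, S, seed = NULL) {
  sub <- subsample_genealogy(g, S, seed)
  structure(list(count = sub$spectrum$count, S = S, parent_N = g$N,
                 undetected = NA_real_),
            class = "sampled_spectrum")
}

#' Binomial read-depth noise on sampled variant frequencies
#'
#' Emulates bulk sequencing of a cell sample: each variant's observed
#' frequency is drawn as `Binomial(depth, f) / depth` around its true sample
#' frequency `f`.  Used by the synthetic bulk-cohort generator; no
#' site-specific error model is applied.
#'
#' @param f True variant frequencies in `[0, 1]`.
#' @param depth Read depth (draws per variant), at least 1.
#' @param seed Optional integer seed.
#' @return Data frame with columns `f_true` and `f_obs`.
#' @export
read_depth_noise <- function(f, depth, seed = NULL) {
  stopifnot(all(f >= 0), all(f <= 1), depth >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(f_true = f, f_obs = rbinom(length(f), depth, f) / depth)
}
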