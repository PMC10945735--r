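#' Stochastic simulation of the three-phase stem cell model
#'
#' Runs an exact Gillespie simulation of the stem cell model at single-cell
#' resolution, starting from one unmutated founder cell.  Growth divisions
#' occur at per-cell rate `gamma` until the population reaches `NM` cells
#' (with `gamma = log(NM)/tM` the mean time to maturity is `tM`); Moran
#' events (a symmetric division paired with a uniform removal, the divider
#' itself included among removal candidates) at rate `rho` and asymmetric
#' divisions at rate `phi` occur once the population exceeds `NH`.  Every
#' surviving daughter draws `Poisson(mu)` new unique mutations.  The
#' genealogy is stored on branches (parent links plus per-branch mutation
#' counts); burdens and abundance spectra are recovered by tree traversal.
#'
#' @param params A [model_params] object.  Only `growth_kind =
#'   "exponential-capped"` population dynamics are simulated.
#' @param t_end Final age (years), positive.
#' @param seed Integer seed; if non-`NULL` the R random number generator is
#'   seeded, making the run fully reproducible.
#' @param max_events Hard cap on the number of Gillespie events; the run
#'   stops with a warning if it is hit.
#' @return An object of class `genealogy`: a list with integer vectors
#'   `parent` and `nmut` (one entry per branch node; parents precede
#'   children; `parent = 0` marks the founder), `alive` (node ids of living
#'   cells), `t` (final time), `N` (number of living cells), `n_events`, and
#'   the generating `params`.
#' @seealso [cell_burdens()], [vaf_spectrum()], [subsample_genealogy()]
#' @export
simulate_population <- function(params, t_end, seed = NULL,
                                max_events = 1e8) {
  stopifnot(inherits(params, "model_params"))
  if (t_end <= 0) stop("'t_end' must be positive")
  if (!is.null(seed)) set.seed(seed)
  raw <- .sim_genealogy_cpp(as.integer(params$NM), params$NH, params$gamma,
                            params$rho, params$phi, params$mu, t_end,
                            max_events)
  if (raw$capped)
    warning("event cap reached at t = ", signif(raw$t, 4),
            "; genealogy is truncated")
  structure(list(parent = raw$parent, nmut = raw$nmut, alive = raw$alive,
                 t = raw$t, N = length(raw$alive),
                 n_events = raw$n_events, params = params, seed = seed),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("Genealogy: %d living cells at t = %.3g y (%d branch nodes, %g events)\n",
              x$N, x$t, length(x$parent), x$n_events))
  invisible(x)
}

#' Single-cell mutational burden sample
#'
#' Wraps a vector of per-cell mutation counts together with its summary
#' moments: the sample mean, the unbiased variance, the dispersion ratio
#' `theta = var/mean` (the sample-size-robust observable separating
#' division-linked from purely Poisson mutation accumulation) and the
#' standard error of the mean.
#'
#' @param burdens Non-negative integer mutation counts, one per cell.
#' @return An object of class `burden_sample` with fields `burdens`, `S`,
#'   `mean`, `var`, `theta`, `se_mean`.
#' @export
burden_sample <- function(burdens) {
  if (length(burdens) < 1) stop("need at least one cell")
  if (any(burdens < 0) || any(burdens != round(burdens)))
    stop("burdens must be non-negative integers")
  S <- length(burdens)
  m <- mean(burdens)
  v <- if (S >= 2) var(burdens) else NA_real_
  structure(list(burdens = as.integer(round(burdens)), S = S, mean = m,
                 var = v, theta = if (isTRUE(m > 0)) v / m else NA_real_,
                 se_mean = if (S >= 2) sqrt(v / S) else NA_real_),
            class = "burden_sample")
}

#' @export
print.burden_sample <- function(x, ...) {
  cat(sprintf("Burden sample: S = %d cells, mean = %.2f, var = %.2f, theta = %.2f\n",
              x$S, x$mean, x$var, x$theta))
  invisible(x)
}

#' Mutational burdens of the living cells of a genealogy
#'
#' The burden of a cell is the sum of the branch mutation counts along its
#' path to the founder.
#'
#' @param g A `genealogy` from [simulate_population()].
#' @param cells Node ids of the cells to report (default: all living cells).
#' @return A [burden_sample].
#' @export
cell_burdens <- function(g, cells = g$alive) {
  stopifnot(inherits(g, "genealogy"))
  b <- .node_burdens_cpp(g$parent, g$nmut)
  burden_sample(b[cells])
}

#' Divisions per lineage in a genealogy
#'
#' Number of divisions in each living cell's past (its depth in the branch
#' tree), the quantity whose expectation the division integral
#' [expected_divisions()] predicts.
#'
#' @inheritParams cell_burdens
#' @return Integer vector of division counts, one per cell.
#' @export
lineage_divisions <- function(g, cells = g$alive) {
  stopifnot(inherits(g, "genealogy"))
  d <- .node_burdens_cpp(g$parent, rep(1L, length(g$parent)))
  d[cells] - 1L
}

#' Variant abundance (VAF) spectrum of a genealogy
#'
#' Counts, for each abundance `k`, the number of variants carried by exactly
#' `k` of the given cells.  Variants carried by all cells (`k = size`) are
#' kept in the spectrum but flagged via the `fixed` field; variants carried
#' by none are dropped.
#'
#' @param g A `genealogy`.
#' @param cells Node ids of the cells observed (default: all living cells,
#'   giving the whole-population spectrum).
#' @return An object of class `vaf_spectrum`: list with `count` (numeric
#'   vector indexed by abundance `k = 1..size`), `size`, `scope`
#'   (`"population"` or `"sample"`) and `fixed` (the `k = size` count).
#' @export
vaf_spectrum <- function(g, cells = g$alive) {
  stopifnot(inherits(g, "genealogy"))
  cnt <- .descendant_counts_cpp(g$parent, as.integer(cells))
  size <- length(cells)
  sel <- cnt > 0L & g$nmut > 0L
  counts <- numeric(size)
  if (any(sel)) {
    agg <- rowsum(as.numeric(g$nmut[sel]), group = cnt[sel])
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  new_vaf_spectrum(counts, size,
                   scope = if (size == g$N) "population" else "sample")
}

new_vaf_spectrum <- function(counts, size, scope = "population") {
  stopifnot(length(counts) == size, all(counts >= 0))
  structure(list(count = as.numeric(counts), size = size, scope = scope,
                 fixed = counts[size]),
            class = "vaf_spectrum")
}

#' @export
print.vaf_spectrum <- function(x, ...) {
  cat(sprintf("VAF spectrum (%s, size %d): %.6g variants (%.6g fixed)\n",
              x$scope, x$size, sum(x$count), x$fixed))
  invisible(x)
}

#' @export
as.data.frame.vaf_spectrum <- function(x, ...) {
  data.frame(k = seq_len(x$size), f = seq_len(x$size) / x$size,
             count = x$count)
}

#' Uniform subsample of cells from a genealogy
#'
#' Draws `S` distinct living cells uniformly without replacement and returns
#' their burden sample and the sample VAF spectrum (variant occupancy counted
#' among the sampled cells only; undetected variants are dropped).
#'
#' @param g A `genealogy`.
#' @param S Number of cells to sample, `1 <= S <= N`.
#' @param seed Optional integer seed.
#' @return A list with `cells` (sampled node ids), `burdens` (a
#'   [burden_sample]) and `spectrum` (a `vaf_spectrum` with scope
#'   `"sample"`).
#' @export
subsample_genealogy <- function(g, S, seed = NULL) {
  stopifnot(inherits(g, "genealogy"))
  if (S < 1 || S > g$N) stop("'S' must satisfy 1 <= S <= N")
  if (!is.null(seed)) set.seed(seed)
  cells <- sample(g$alive, S, replace = FALSE)
  sp <- vaf_spectrum(g, cells)
  sp$scope <- if (S == g$N) "population" else "sample"
  list(cells = cells, burdens = cell_burdens(g, cells), spectrum = sp)
}

#' Binary cell-by-variant matrix for a set of cells
#'
#' Expands the branch representation into an explicit 0/1 matrix of variant
#' occupancy for the given cells.  Columns are the variants present in at
#' least one of the cells, ordered by their global identifier (branch
#' creation order); row order follows `cells`.
#'
#' @param g A `genealogy`.
#' @param cells Node ids (default: all living cells).
#' @return Integer 0/1 matrix of dimension `length(cells)` x n_variants.
#' @export
cell_variant_matrix <- function(g, cells = g$alive) {
  stopifnot(inherits(g, "genealogy"))
  var_end <- cumsum(g$nmut)
  path_variants <- function(node) {
    ids <- integer(0)
    while (node > 0L) {
      n <- g$nmut[node]
      if (n > 0L) ids <- c(ids, (var_end[node] - n + 1L):var_end[node])
      node <- g$parent[node]
    }
    ids
  }
  per_cell <- lapply(cells, path_variants)
  all_ids <- sort(unique(unlist(per_cell)))
  mat <- matrix(0L, nrow = length(cells), ncol = length(all_ids))
  for (i in seq_along(per_cell))
    mat[i, match(per_cell[[i]], all_ids)] <- 1L
  colnames(mat) <- if (length(all_ids)) paste0("v", all_ids) else character(0)
  rownames(mat) <- paste0("cell", seq_along(cells))
  mat
}

#' Burden-only simulation of mutation acquisition in a constant population
#'
#' Individual-based simulation tracking only per-cell mutation counts (no
#' variant identities) in a population of fixed size `N` starting from zero
#' mutations.  Division events occur at total rate `N * lam`; a fraction `p`
#' are asymmetric (the divider gains `Poisson(mu)` mutations), the rest are
#' symmetric replacements (the replaced slot inherits the divider's burden
#' plus `Poisson(mu)` new mutations, and the divider also gains
#' `Poisson(mu)`).  Used to study within- and between-replicate fluctuations
#' of the burden distribution and its dispersion ratio.
#'
#' @param N Population size (cells).
#' @param p Asymmetric fraction of divisions, in `[0, 1]`.
#' @param mu Mutation rate per daughter per division.
#' @param lam Total division rate (/cell/year).
#' @param t_end Simulated time (years).
#' @param reps Number of independent replicates.
#' @param seed Optional integer seed.
#' @param max_events Per-replicate event cap.
#' @return An `N x reps` integer matrix of final burdens.
#' @export
simulate_burdens <- function(N, p, mu, lam, t_end, reps = 1, seed = NULL,
                             max_events = 1e8) {
  stopifnot(N >= 1, p >= 0, p <= 1, mu >= 0, lam >= 0, t_end > 0, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  .sim_burden_only_cpp(as.integer(N), p, mu, lam, t_end, as.integer(reps),
                       max_events)
}

#' Probability that the burden dispersion ratio falls in an interval
#'
#' Fraction of independent burden-only replicates whose dispersion ratio
#' `theta = Var(m)/E(m)` lies strictly inside `interval`.  Replicates with
#' zero mean burden (undefined `theta`) count as outside.
#'
#' @inheritParams simulate_burdens
#' @param interval Numeric length-2 open interval for `theta`; the default
#'   `(3, 5)` is the experimentally observed range in adult blood.
#' @return A single probability in `[0, 1]`.
#' @export
dispersion_probability <- function(N, p, mu, lam, t_end, interval = c(3, 5),
                                   reps = 100, seed = NULL) {
  stopifnot(length(interval) == 2, reps >= 1)
  m <- simulate_burdens(N, p, mu, lam, t_end, reps, seed)
  theta <- apply(m, 2, function(x) {
    mm <- mean(x)
    if (mm <= 0) NA_real_ else var(x) / mm
  })
  mean(!is.na(theta) & theta > interval[1] & theta < interval[2])
}
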