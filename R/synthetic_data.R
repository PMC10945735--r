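#' Synthetic single-cell sequencing dataset
#'
#' Generates a study-like single-cell dataset: a population is simulated to
#' the donor age under the three-phase model, `S` cells are sampled
#' uniformly, and the per-cell burden list, the binary cell-by-variant
#' matrix and the sample VAF spectrum are written as TSV with a JSON
#' manifest recording the generating truth.  The defaults emulate a
#' bone-marrow aspirate design: 89 cells from a 59-year-old donor.
#'
#' @param params A [model_params] object (the generating truth).
#' @param S Number of cells sampled, `S <= NM`.
#' @param age Donor age (years).
#' @param seed Integer seed (all randomness in the dataset derives from it).
#' @param dir Output directory (created if missing); `NULL` returns the
#'   in-memory dataset without writing files.
#' @return An object of class `synthetic_dataset`: list with `kind`,
#'   `genealogy`, `sample` (output of [subsample_genealogy()]), `matrix`,
#'   `truth` (params, S, age, seed) and `files` (paths, when written).
#' @export
make_single_cell_dataset <- function(params, S = 89, age = 59, seed = 1,
                                     dir = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (S > params$NM) stop("'S' cannot exceed the mature population size")
  set.seed(seed)
  g <- simulate_population(params, age)
  sub <- subsample_genealogy(g, S)
  mat <- cell_variant_matrix(g, sub$cells)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(burdens = file.path(dir, "burdens.tsv"),
                  matrix = file.path(dir, "cell_variant_matrix.tsv"),
                  vaf = file.path(dir, "vaf_sample.tsv"),
                  manifest = file.path(dir, "manifest.json"))
    write_burdens(sub$burdens, files$burdens)
    write_cell_variant_matrix(mat, files$matrix)
    write_vaf_table(sub$spectrum, files$vaf)
    write_manifest(files$manifest, params, seed,
                   list(kind = "single-cell", S = S, age = age, N = g$N))
  }
  structure(list(kind = "single-cell", genealogy = g, sample = sub,
                 matrix = mat,
                 truth = list(params = params, S = S, age = age,
                              seed = seed),
                 files = files),
            class = "synthetic_dataset")
}

#' Synthetic bulk-sequenced cohort
#'
#' Generates a cohort of donors of different ages, emulating bulk
#' sequencing of a tissue whose stem cell population grew early in life and
#' is maintained by turnover (the design under which young donors' VAF
#' spectra sit near the growing-population shape and old donors' near the
#' constant-population shape).  Per donor, the expected VAF spectrum is
#' evolved to the donor age, a realized variant set is drawn Poisson around
#' the expectation per abundance class (independent-sites approximation;
#' genealogical correlations require the simulator route), and binomial
#' read-depth noise is applied to each variant's frequency.
#'
#' @param ages Donor ages (years), all positive.
#' @param params A [model_params] object shared by the cohort.
#' @param depth Sequencing depth for the binomial frequency noise.
#' @param seed Integer seed.
#' @param dir Output directory; `NULL` skips file output.
#' @param n PDE grid points.
#' @return A `synthetic_dataset` of kind `"bulk-cohort"`: `donors` is a
#'   list (one per age) with the expected spectrum (`expected`), realized
#'   per-class counts (`counts`) and the observed variant table
#'   (`variants`: `f_true`, `f_obs`).
#' @export
make_bulk_cohort <- function(ages, params, depth = 100, seed = 1,
                             dir = NULL, n = 400) {
  stopifnot(inherits(params, "model_params"), all(ages > 0), depth >= 1)
  set.seed(seed)
  sols <- evolve_expected_vaf(params, sort(unique(ages)), n = n)
  if (inherits(sols, "vaf_solution")) sols <- list(sols)
  names(sols) <- as.character(vapply(sols, `[[`, 0, "t_obs"))
  donors <- lapply(seq_along(ages), function(di) {
    sol <- sols[[as.character(ages[di])]]
    N <- floor(sol$N_obs)
    Vk <- expected_spectrum(sol)
    counts <- rpois(N, Vk)
    f_true <- rep(seq_len(N) / N, counts)
    variants <- read_depth_noise(f_true, depth)
    list(age = ages[di], expected = Vk, counts = counts,
         variants = variants)
  })
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vf <- vapply(seq_along(donors), function(di) {
      path <- file.path(dir, sprintf("donor%02d_vaf.tsv", di))
      write.table(donors[[di]]$variants, path, sep = "\t",
                  row.names = FALSE, quote = FALSE)
      path
    }, character(1))
    files <- list(vaf = vf, manifest = file.path(dir, "manifest.json"))
    write_manifest(files$manifest, params, seed,
                   list(kind = "bulk-cohort", ages = ages, depth = depth))
  }
  structure(list(kind = "bulk-cohort", donors = donors,
                 truth = list(params = params, ages = ages, depth = depth,
                              seed = seed),
                 files = files),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset (%s)%s\n", x$kind,
              if (is.null(x$files)) "" else
                paste0(", written to ", dirname(x$files$manifest))))
  invisible(x)
}

#' Bin observed variant frequencies into a VAF spectrum
#'
#' Histogram of observed variant frequencies on a fixed binning, the common
#' grid on which cohort spectra are averaged and compared against reference
#' shapes.
#'
#' @param f Observed variant frequencies.
#' @param breaks Bin edges (default: 25 equal bins on `(0, 0.5]`).
#' @param drop_zero Drop variants with observed frequency 0 (undetected).
#' @return Data frame with columns `f` (bin midpoints) and `count`.
#' @export
bin_vaf_counts <- function(f, breaks = seq(0, 0.5, length.out = 26),
                           drop_zero = TRUE) {
  if (drop_zero) f <- f[f > 0]
  f <- f[f > min(breaks) & f <= max(breaks)]
  idx <- cut(f, breaks, labels = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  data.frame(f = mids, count = counts)
}
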