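test_that("simulation is seed-deterministic and mutation-free when mu = 0", {
  par0 <- model_params(NM = 50, tM = 2, NH = 5, lam = 2, p = 0.3, mu = 0)
  g <- simulate_population(par0, 10, seed = 1)
  expect_equal(cell_burdens(g)$burdens, rep(0L, g$N))
  expect_equal(sum(vaf_spectrum(g)$count), 0)

  par <- desk_params(NM = 200)
  g1 <- simulate_population(par, 15, seed = 7)
  g2 <- simulate_population(par, 15, seed = 7)
  expect_identical(g1$parent, g2$parent)
  expect_identical(g1$nmut, g2$nmut)
  expect_identical(g1$alive, g2$alive)
  g3 <- simulate_population(par, 15, seed = 8)
  expect_false(identical(g1$nmut, g3$nmut))
})

test_that("population matures at NM and stays exactly constant", {
  par <- desk_params(NM = 300)
  g <- simulate_population(par, 30, seed = 2)
  expect_equal(g$N, 300)
  g_late <- simulate_population(par, 60, seed = 2)
  expect_equal(g_late$N, 300)
})

test_that("the event cap truncates with a warning", {
  par <- desk_params(NM = 500)
  expect_warning(simulate_population(par, 59, seed = 1, max_events = 100),
                 "event cap")
  expect_error(simulate_population(par, -1), "t_end")
})

test_that("burden equals the branch-count sum along the root path", {
  # chain founder -> a -> b -> c -> d with branch counts 3, 1, 0, 2
  g <- manual_genealogy(parent = c(0, 1, 2, 3, 4), nmut = c(0, 3, 1, 0, 2),
                        alive = 5)
  expect_equal(cell_burdens(g)$burdens, 6L)
  expect_equal(lineage_divisions(g), 4L)
  founder <- manual_genealogy(parent = 0, nmut = 0, alive = 1)
  expect_equal(cell_burdens(founder)$burdens, 0L)
})

test_that("variant incidences are conserved between tree and spectrum", {
  par <- desk_params(NM = 150)
  g <- simulate_population(par, 20, seed = 3)
  sp <- vaf_spectrum(g)
  expect_equal(sum(seq_len(sp$size) * sp$count),
               sum(cell_burdens(g)$burdens))
  # and within a subsample
  sub <- subsample_genealogy(g, 40, seed = 4)
  expect_equal(sum(seq_len(40) * sub$spectrum$count),
               sum(sub$burdens$burdens))
})

test_that("growth-only ensemble mean spectrum matches the pure-birth recursion", {
  par <- model_params(NM = 30, tM = 2, NH = 30, lam = 0, p = 0, mu = 1)
  reps <- 500
  set.seed(11)
  acc <- matrix(0, reps, 30)
  for (r in seq_len(reps)) {
    g <- simulate_population(par, 10)
    expect_equal(g$N, 30)
    acc[r, ] <- vaf_spectrum(g)$count
  }
  mv <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(reps)
  rec <- pure_birth_recursion(29, 1)$V
  for (k in 1:8)
    expect_lt(abs(mv[k] - rec[k]), 3 * se[k] + 1e-9)
})

test_that("constant-size ensemble mean reaches the Moran equilibrium level", {
  # discrete equilibrium with two mutated daughters per Moran event (one
  # when the divider replaces itself): V_k = (2 - 1/N) mu N / k
  N <- 30
  par <- model_params(NM = N, tM = 0.5, NH = 1, lam = 2, p = 0, mu = 1)
  reps <- 250
  set.seed(13)
  acc <- matrix(0, reps, 3)
  for (r in seq_len(reps)) {
    g <- simulate_population(par, 120)
    acc[r, ] <- vaf_spectrum(g)$count[1:3]
  }
  ref <- (2 - 1 / N) * N / (1:3)
  mv <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(reps)
  for (k in 1:3)
    expect_lt(abs(mv[k] - ref[k]), 3 * se[k])
})

test_that("subsampling matches exact subset enumeration on a 4-cell tree", {
  # founder -> (a carries 1 variant, b none); a -> (c, d); b -> (e, f):
  # one variant at abundance 2 among 4 alive cells
  g <- manual_genealogy(parent = c(0, 1, 1, 2, 2, 3, 3),
                        nmut = c(0, 1, 0, 0, 0, 0, 0),
                        alive = c(4, 5, 6, 7))
  expect_equal(vaf_spectrum(g)$count, c(0, 1, 0, 0))
  # exact expectation over all C(4,2) subsets: V~(1) = 2/3, V~(2) = 1/6
  enum <- enumerate_sampled(4, 2, 2)
  expect_equal(enum[2:3], c(2 / 3, 1 / 6))
  set.seed(5)
  draws <- replicate(1200, subsample_genealogy(g, 2)$spectrum$count)
  m <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_lt(abs(m[1] - 2 / 3), 3 * se[1])
  expect_lt(abs(m[2] - 1 / 6), 3 * se[2])
  # S = N reproduces the population spectrum exactly
  expect_equal(subsample_genealogy(g, 4)$spectrum$count,
               vaf_spectrum(g)$count)
  expect_error(subsample_genealogy(g, 5), "S")
})

test_that("a fixed variant appears at abundance S in every sample", {
  g <- manual_genealogy(parent = c(0, 1, 1, 2, 2),
                        nmut = c(0, 2, 0, 0, 0),
                        alive = c(3, 4, 5))
  # variant pair on branch 2 is carried by cells 4 and 5; make one fixed:
  g2 <- manual_genealogy(parent = c(0, 1, 1), nmut = c(1, 0, 0),
                         alive = c(2, 3))
  for (s in 1:2)
    expect_equal(subsample_genealogy(g2, s, seed = s)$spectrum$count[s], 1)
})

test_that("burden-only dynamics have the expected moments and dispersion", {
  m0 <- simulate_burdens(50, 0.5, 0, 3, 10, reps = 5, seed = 1)
  expect_true(all(m0 == 0))

  # all-asymmetric: burden is a compound Poisson over own divisions,
  # mean = lam * t * mu
  N <- 400; lam <- 4; tt <- 10; mu <- 1.5
  m <- simulate_burdens(N, 1, mu, lam, tt, reps = 8, seed = 2)
  mm <- colMeans(m)
  expect_lt(abs(mean(mm) - lam * tt * mu), 3 * sd(mm) / sqrt(length(mm)))

  # dispersion probabilities: mu = 1.3 cannot reach the observed 3 < theta
  # < 5 band while mu = 3 often does
  p13 <- dispersion_probability(300, 0.9, 1.3, 5, 59, reps = 50, seed = 21)
  p30 <- dispersion_probability(300, 0.9, 3.0, 5, 59, reps = 50, seed = 22)
  expect_gt(p30, p13)
  expect_lt(p13, 0.25)
  th <- apply(simulate_burdens(300, 0.9, 1.3, 5, 59, reps = 50, seed = 23),
              2, function(x) var(x) / mean(x))
  expect_lt(mean(th), 3)

  expect_equal(dispersion_probability(100, 0.5, 0, 3, 5, reps = 5,
                                      seed = 3), 0)
  expect_equal(dispersion_probability(100, 0.5, 2, 3, 5,
                                      interval = c(4, 4), reps = 5,
                                      seed = 4), 0)
})

test_that("cell-variant matrix row sums equal the burdens", {
  par <- desk_params(NM = 120)
  g <- simulate_population(par, 12, seed = 6)
  sub <- subsample_genealogy(g, 15, seed = 7)
  mat <- cell_variant_matrix(g, sub$cells)
  expect_equal(unname(rowSums(mat)), as.numeric(sub$burdens$burdens))
  expect_true(all(mat %in% 0:1))
  # column sums reproduce the sample spectrum
  occ <- tabulate(colSums(mat), nbins = 15)
  expect_equal(occ, as.integer(sub$spectrum$count))
})
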