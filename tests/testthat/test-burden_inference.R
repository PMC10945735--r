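test_that("burden moments are the plain sample moments", {
  m <- burden_moments(c(2, 2, 2))
  expect_equal(m$mean, 2)
  expect_equal(m$var, 0)
  expect_equal(m$theta, 0)
  m2 <- burden_moments(burden_sample(c(0, 4)))
  expect_equal(m2$var, 8)                      # unbiased variance
  expect_equal(m2$se_mean, sqrt(8 / 2))
  expect_error(burden_moments(5), "2 cells")
})

test_that("division and mutation-rate estimators follow the moment identities", {
  expect_equal(estimate_divisions(1000, 1.2), 833 + 1 / 3)
  expect_equal(estimate_divisions(0, 2), 0)
  expect_error(estimate_divisions(10, 0), "mu")

  expect_equal(estimate_mu(500, 500), 0)       # pure Poisson burden
  # the published single-cell blood case: theta = 5.3 gives 4.3 /division
  expect_equal(estimate_mu(1000, 5300), 4.3)
  expect_equal(estimate_mu(1000, 5300, dispersion = 2), 2.15)
  expect_warning(mu_neg <- estimate_mu(100, 50), "under-dispersed")
  expect_lt(mu_neg, 0)
})

test_that("compound Poisson pmf has the right mass, mean and variance", {
  Ey <- 40; mu <- 1.2
  tab <- compound_poisson_pmf(Ey, mu)
  expect_equal(sum(tab$prob), 1, tolerance = 1e-8)
  expect_equal(tab$prob[tab$m == 0], exp(Ey * (exp(-mu) - 1)),
               tolerance = 1e-10)
  expect_equal(sum(tab$m * tab$prob), Ey * mu, tolerance = 1e-6)
  expect_equal(sum(tab$m^2 * tab$prob) - sum(tab$m * tab$prob)^2,
               Ey * mu * (1 + mu), tolerance = 1e-5)
})

test_that("independently evolved lineages draw burdens from the CPD", {
  # one cell per replicate of the burden-only dynamics gives iid compound
  # Poisson draws with Ey = (2 rho (1 - 1/(2N)) + phi) t
  N <- 5; p <- 0.4; lam <- 5; tt <- 10; mu <- 1.2
  rho <- (1 - p) * lam; phi <- p * lam
  Ey <- (2 * rho * (1 - 1 / (2 * N)) + phi) * tt
  m <- simulate_burdens(N, p, mu, lam, tt, reps = 400, seed = 17)[1, ]
  tab <- compound_poisson_pmf(Ey, mu)
  # chi-square goodness of fit on bins with expected count >= 8
  qs <- stats::quantile(m, probs = seq(0, 1, length.out = 11))
  br <- unique(round(qs)); br[1] <- -Inf; br[length(br)] <- Inf
  obs <- table(cut(m, br))
  expected <- vapply(seq_len(length(br) - 1), function(i)
    sum(tab$prob[tab$m > br[i] & tab$m <= br[i + 1]]), numeric(1)) * 400
  keep <- expected >= 8
  stat <- sum((as.numeric(obs[keep]) - expected[keep])^2 / expected[keep])
  expect_lt(stat, stats::qchisq(0.95, sum(keep) - 1))
})

test_that("estimate_mu is unbiased on iid compound Poisson samples", {
  set.seed(19)
  mu <- 1.2; Ey <- 500; S <- 1e4
  est <- replicate(200, {
    y <- rpois(S, Ey)
    m <- rpois(S, y * mu)
    estimate_mu(mean(m), var(m))
  })
  expect_lt(abs(mean(est) - mu), 3 * sd(est) / sqrt(200))
  # and the burden mean matches Ey * mu
  y <- rpois(S, Ey); m <- rpois(S, y * mu)
  expect_lt(abs(mean(m) - 600), 3 * sd(m) / sqrt(S))
})

test_that("shared ancestry biases the population mutation-rate estimate down", {
  set.seed(23)
  par <- desk_params(NM = 400)
  est <- replicate(25, {
    g <- simulate_population(par, 40)
    b <- cell_burdens(g)
    (b$var / b$mean - 1)
  })
  expect_lt(mean(est), par$mu)       # Var(m) shrinks within one genealogy
})

test_that("the division integral matches rate limits and the simulator", {
  par <- desk_params()
  # mature-phase slope: dy/dt = 2 rho (1 - 1/(2 NM)) + phi
  slope <- (expected_divisions(par, 40) - expected_divisions(par, 30)) / 10
  expect_equal(slope, 2 * par$rho * (1 - 1 / (2 * par$NM)) + par$phi,
               tolerance = 1e-8)
  # all-asymmetric homeostasis accrues lam divisions per lineage-year
  p1 <- model_params(NM = 1000, tM = 5, NH = 50, lam = 5, p = 1, mu = 1)
  slope1 <- (expected_divisions(p1, 40) - expected_divisions(p1, 30)) / 10
  expect_equal(slope1, 5, tolerance = 1e-8)
  # against the simulator's true division counts
  set.seed(29)
  dv <- replicate(8, {
    g <- simulate_population(desk_params(NM = 500), 25)
    mean(lineage_divisions(g))
  })
  y_theory <- expected_divisions(desk_params(NM = 500), 25)
  expect_lt(abs(mean(dv) - y_theory), 3 * sd(dv) / sqrt(8))
})

test_that("solve_lambda inverts the division integral", {
  y59 <- expected_divisions(desk_params(), 59)
  lam <- solve_lambda(y59, NM = 1000, NH = 50, tM = 5, p = 0.4, t = 59)
  expect_equal(lam, 5, tolerance = 1e-6)
  # mature-dominated limit: lam ~ (R - growth part) / ((2 - p)(t - tH))
  R <- 500
  lam2 <- solve_lambda(R, NM = 1e5, NH = 1e5 - 1, tM = 5, p = 0, t = 59)
  par2 <- model_params(NM = 1e5, tM = 5, NH = 1e5 - 1, lam = 0, p = 0)
  G <- expected_divisions(par2, 59)
  tH <- par2$tH
  expect_equal(lam2, (R - G) / (2 * (1 - 1 / (2e5)) * (59 - tH)),
               tolerance = 1e-3)
  expect_error(solve_lambda(5, NM = 1e5, NH = 50, tM = 5, p = 0, t = 59),
               "no root")
})

test_that("the lambda sweep brackets the central value and grows with p", {
  sw <- sweep_lambda(800, 59, tM = c(2, 5, 8), NH = c(1, 100),
                     NM = c(2e4, 2e5), p = c(0, 0.5, 1))
  expect_true(sw$central >= sw$range[1] && sw$central <= sw$range[2])
  byp <- tapply(sw$grid$lam, sw$grid$p, median)
  expect_true(all(diff(byp) > 0))      # asymmetric divisions count singly
  sw2 <- sweep_lambda(800, 59, tM = 5, NH = 50, NM = 1e5, p = 0.5,
                      R_se = 20)
  expect_true(sw2$se_range[1] < sw2$central + 1 &&
                length(sw2$se_range) == 2)
})
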