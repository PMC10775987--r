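test_that("circular summaries: mean direction, resultant length, deviation", {
  s <- circ_summary(c(10, 10))
  expect_equal(s$mu, 10)
  expect_equal(s$R, 1)
  expect_equal(s$ad, 0)

  # mean vector of {0, 90} is (0.5, 0.5)
  s <- circ_summary(c(0, 90))
  expect_equal(s$mu, 45)
  expect_equal(s$R, sqrt(0.5), tolerance = 1e-12)
  expect_equal(s$ad, sqrt(2 * (1 - sqrt(0.5))) * 180 / pi, tolerance = 1e-9)

  # antipodal sample: resultant vanishes, mean undefined, AD still returned
  s <- circ_summary(c(0, 180))
  expect_lt(s$R, 1e-12)
  expect_false(s$mu_defined)
  expect_true(is.finite(s$ad))

  # summaries rotate with the data; spread statistics do not change
  set.seed(9)
  ang <- rvonmises(50, 40, 3)
  for (rot in c(17, 123, 301)) {
    s0 <- circ_summary(ang); s1 <- circ_summary(ang + rot)
    expect_equal(wrap180(s1$mu - s0$mu - rot), 0, tolerance = 1e-9)
    expect_equal(s1$R, s0$R, tolerance = 1e-12)
    expect_equal(s1$ad, s0$ad, tolerance = 1e-9)
  }
})

test_that("Rayleigh statistic is n R^2 with the series p-value", {
  # identical angles: R = 1, z = n
  expect_equal(rayleigh_test(rep(33, 7))$statistic, 7)
  expect_equal(rayleigh_test(c(0, 90))$statistic, 1, tolerance = 1e-12)

  # uniform grid: no preferred direction
  r <- rayleigh_test(seq(0, 359, by = 1))
  expect_lt(r$statistic, 1e-12)
  expect_gt(r$p_value, 0.99)

  # z = n R^2 cross-checked against a direct complex-sum implementation
  set.seed(10)
  for (i in 1:10) {
    ang <- runif(sample(5:40, 1), 0, 360)
    R_direct <- Mod(mean(exp(1i * ang * pi / 180)))
    expect_equal(rayleigh_test(ang)$statistic, length(ang) * R_direct^2,
                 tolerance = 1e-12)
  }
})

test_that("Watson-Williams matches its design and a permutation oracle", {
  # identical groups cannot differ
  g <- c(10, 25, 40)
  expect_lt(watson_williams(list(g, g))$statistic, 1e-10)

  # two groups of 10 give df = (1, 18)
  set.seed(11)
  g1 <- rvonmises(10, 0, 8); g2 <- rvonmises(10, 20, 8)
  ww <- watson_williams(list(g1, g2))
  expect_equal(ww$df, c(1L, 18L))
  expect_true(ww$p_value >= 0 && ww$p_value <= 1)

  # p agrees with a label-permutation oracle within Monte-Carlo error
  set.seed(12)
  a <- rvonmises(12, 0, 5); b <- rvonmises(12, 25, 5)
  p_ww <- watson_williams(list(a, b))$p_value
  pool <- c(a, b)
  stat <- function(x, y) abs(wrap180(circ_summary(x)$mu - circ_summary(y)$mu))
  obs <- stat(a, b)
  B <- 4000
  exceed <- 0
  for (i in seq_len(B)) {
    idx <- sample.int(24, 12)
    if (stat(pool[idx], pool[-idx]) >= obs) exceed <- exceed + 1
  }
  p_perm <- (exceed + 1) / (B + 1)
  expect_lt(abs(p_ww - p_perm), 0.06)

  # diffuse samples trigger the validity warning
  set.seed(13)
  expect_warning(watson_williams(list(runif(20, 0, 360), runif(20, 0, 360))),
                 "unreliable")
  expect_error(watson_williams(list(c(0, 180), c(10, 20))), "zero resultant")
})

test_that("circular Cohen's d is the mean gap over the pooled deviation", {
  x <- c(5, 15, 25)
  expect_equal(cohens_d_circular(x, x), 0)

  # symmetric pairs +-a around 0 and around 10, with a chosen so the
  # angular deviation is exactly 10 degrees: d = 10 / 10 = 1
  a <- acos(1 - (10 * pi / 180)^2 / 2) * 180 / pi
  e1 <- c(-a, a); e2 <- c(10 - a, 10 + a)
  expect_equal(cohens_d_circular(e1, e2), 1, tolerance = 1e-9)
  expect_equal(cohens_d_circular(e2, e1), cohens_d_circular(e1, e2))

  # zero pooled deviation with distinct means: flagged infinite effect
  expect_warning(d <- cohens_d_circular(c(0, 0), c(10, 10)), "zero")
  expect_true(is.infinite(d))
})

test_that("von Mises fitting recovers mean and concentration", {
  # coincident angles hit the concentration cap
  expect_equal(fit_von_mises(rep(12, 5))$kappa, 1e4)

  # uniform sample: concentration near zero
  expect_lt(fit_von_mises(seq(0, 359.9, by = 0.5))$kappa, 1e-6)

  # simulation recovery at kappa = 4
  set.seed(14)
  draws <- rvonmises(2000, 130, 4)
  fit <- fit_von_mises(draws)
  expect_lt(abs(fit$kappa - 4) / 4, 0.1)
  expect_lt(abs(wrap180(fit$mu - 130)), 3)

  # the noiseless limit returns the mean exactly
  expect_equal(rvonmises(3, 77, Inf), rep(77, 3))
})

test_that("von Mises log-likelihood integrates the density it claims", {
  # kappa = 0 is the circular uniform: log density -log(2 pi) per angle
  expect_equal(vm_loglik(c(10, 250, 33), 0, 0), -3 * log(2 * pi))
  # density integrates to one at moderate concentration
  f <- function(th) exp(vapply(th, function(t)
    vm_loglik(t * 180 / pi, 40, 3.5), 0))
  expect_equal(stats::integrate(f, -pi, pi)$value, 1, tolerance = 1e-6)
  # large kappa does not overflow
  expect_true(is.finite(vm_loglik(c(0.01, -0.01) * 180 / pi, 0, 1e4)))
})

test_that("BIC arithmetic and parameter counts", {
  expect_equal(bic_score(0, 10, 0)$bic, 0)
  expect_equal(bic_score(2, 100, -50)$bic, 2 * log(100) + 100)
  # equal likelihoods: the criterion difference is the parameter penalty
  expect_equal(bic_score(162, 264, -10)$bic - bic_score(82, 264, -10)$bic,
               80 * log(264))
  # strictly increasing in k at fixed likelihood
  bics <- vapply(0:5, function(k) bic_score(k, 3, -1)$bic, 0)
  expect_true(all(diff(bics) > 0))

  g <- build_graph(make_wormhole_replica(), "wormhole")
  expect_equal(count_parameters("embedded", g), 82L)
  # three-vertex corridor: 2 * 3 + 2
  expect_equal(count_parameters("embedded", build_graph(corridor_maze())), 8L)
  # an empty graph still has its noise term
  empty <- labeled_graph(integer(), data.frame(from = integer(),
    to = integer(), d = numeric()), data.frame())
  expect_equal(count_parameters("embedded", empty), 2L)
  # nonmetric: one distance per edge and angles per the chosen convention
  gc <- build_graph(corridor_maze())
  expect_equal(count_parameters("nonmetric", gc), 2L + 2L + 2L)
  expect_equal(count_parameters("nonmetric", gc,
                                angle_convention = "unordered"), 2L + 1L + 2L)
})

test_that("tests are invariant under a common rotation of all angles", {
  set.seed(15)
  g1 <- rvonmises(15, 10, 6); g2 <- rvonmises(15, 40, 6)
  for (rot in c(45, 210)) {
    expect_equal(watson_williams(list(g1 + rot, g2 + rot))$statistic,
                 watson_williams(list(g1, g2))$statistic, tolerance = 1e-9)
    expect_equal(rayleigh_test(g1 + rot)$statistic,
                 rayleigh_test(g1)$statistic, tolerance = 1e-9)
    expect_equal(cohens_d_circular(g1 + rot, g2 + rot),
                 cohens_d_circular(g1, g2), tolerance = 1e-9)
  }
})
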