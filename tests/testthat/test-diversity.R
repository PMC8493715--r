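test_that("coverage estimates reproduce hand-evaluated values", {
  # single clonotype: no singletons, complete coverage
  expect_equal(coverage_estimate(5), 1)
  # Good-Turing on [1,1,2]: 1 - (2/4) * (3*2 / (3*2 + 2)) = 0.625
  expect_equal(coverage_estimate(c(1, 1, 2)), 0.625)
  # interpolation on [2,2] at m = 2: 2/3
  expect_equal(coverage_estimate(c(2, 2), m = 2), 2 / 3)
  expect_error(coverage_estimate(c(2, 2), m = 0),
               class = "gammarep_invalid_input")
  expect_error(coverage_estimate(integer(0)), class = "gammarep_invalid_input")
})

test_that("coverage is monotone non-decreasing in m", {
  set.seed(51)
  for (i in 1:5) {
    x <- as.integer(rmultinom(1, 60, prob = runif(12))[, 1])
    x <- x[x > 0]
    n <- sum(x)
    covs <- vapply(1:n, function(m) coverage_estimate(x, m), numeric(1))
    expect_true(all(diff(covs) >= -1e-12))
  }
})

test_that("observed Hill numbers hit the closed forms", {
  expect_equal(hill_observed(c(4, 4, 4, 4), 0), 4)
  expect_equal(hill_observed(c(4, 4, 4, 4), 1), 4)
  expect_equal(hill_observed(c(4, 4, 4, 4), 2), 4)
  expect_equal(hill_observed(c(8, 2), 1),
               exp(-0.8 * log(0.8) - 0.2 * log(0.2)), tolerance = 1e-10)
  expect_equal(hill_observed(c(8, 2), 2), 1 / (0.64 + 0.04), tolerance = 1e-10)
})

test_that("rarefied Hill numbers match hand-derived small cases", {
  expect_equal(hill_at_size(c(2, 2), 2, 0)$estimate, 5 / 3)
  expect_equal(hill_at_size(c(2, 2), 2, 1)$estimate, exp((4 / 6) * log(2)),
               tolerance = 1e-10)
  expect_equal(hill_at_size(c(2, 2), 2, 2)$estimate, 1.5)
})

test_that("interpolation equals exhaustive subsample enumeration", {
  set.seed(53)
  cases <- list(c(2, 2), c(1, 1, 2), c(3, 2, 1), c(4, 2, 2), c(1, 1, 1, 2))
  for (x in cases) {
    n <- sum(x)
    for (m in 1:(n - 1)) {
      bf <- bf_subsample_diversity(x, m)
      expect_equal(hill_at_size(x, m, 0)$estimate, bf$mean_richness,
                   tolerance = 1e-9)
      expect_equal(hill_at_size(x, m, 1)$estimate, exp(bf$mean_entropy),
                   tolerance = 1e-9)
    }
  }
})

test_that("rarefaction and extrapolation are continuous at the sample size", {
  set.seed(55)
  x <- c(5, 3, 2, 1, 1, 1)
  for (q in 0:2) {
    at_n <- hill_at_size(x, sum(x), q)
    expect_equal(at_n$estimate, hill_observed(x, q))
    expect_equal(at_n$method, "observed")
    just_below <- hill_at_size(x, sum(x) - 1, q)$estimate
    just_above <- hill_at_size(x, sum(x) + 1, q)$estimate
    expect_lt(abs(just_above - at_n$estimate),
              abs(at_n$estimate - just_below) + 1)
  }
})

test_that("richness extrapolation is monotone and bounded by the asymptote", {
  x <- c(4, 3, 2, 2, 1, 1, 1)
  ms <- sum(x) + c(1, 5, 20, 100, 1000)
  est <- vapply(ms, function(m) hill_at_size(x, m, 0)$estimate, numeric(1))
  expect_true(all(diff(est) > 0))
  f1 <- sum(x == 1); f2 <- sum(x == 2); n <- sum(x)
  chao1 <- length(x) + ((n - 1) / n) * f1^2 / (2 * f2)
  expect_true(all(est <= chao1 + 1e-9))
})

test_that("estimates are non-increasing in diversity order q", {
  set.seed(57)
  for (i in 1:10) {
    x <- as.integer(rmultinom(1, 80, prob = runif(15)^2)[, 1])
    x <- x[x > 0]
    m <- sample(c(5, 20, sum(x), sum(x) + 30), 1)
    est <- vapply(c(0, 1, 2), function(q) hill_at_size(x, m, q)$estimate,
                  numeric(1))
    expect_true(all(diff(est) <= 1e-9))
  }
})

test_that("coverage standardisation picks the smallest adequate sample size", {
  x <- c(2, 2)
  out <- hill_at_coverage(x, target_coverage = 0.6, q = 0)
  covs <- vapply(1:4, function(m) coverage_estimate(x, m), numeric(1))
  m_expected <- min(which(covs >= 0.6))
  expect_equal(out$m, m_expected)
  # a very low target is met by a single draw, worth exactly one clonotype
  low <- hill_at_coverage(c(50, 50), target_coverage = 1e-6, q = c(0, 1, 2))
  expect_equal(low$m, rep(1L, 3))
  expect_equal(low$estimate, rep(1, 3), tolerance = 1e-9)
})

test_that("coverage standardisation is stable across sampling depths", {
  # two samples of one community at different depths agree at equal coverage
  set.seed(59)
  p <- c(rep(0.002, 300), rep(0.004, 100))
  draw <- function(n) {
    x <- as.integer(rmultinom(1, n, p)[, 1])
    x[x > 0]
  }
  shallow <- draw(1000)
  deep <- draw(4000)
  for (q in 0:2) {
    a <- hill_at_coverage(shallow, 0.1, q)$estimate
    b <- hill_at_coverage(deep, 0.1, q)$estimate
    expect_lt(abs(a - b) / b, 0.15)
  }
})

test_that("uniform communities sampled deeply converge to true richness", {
  set.seed(61)
  S <- 12
  x <- as.integer(rmultinom(1, 4000, rep(1 / S, S))[, 1])
  for (q in 0:2) {
    expect_equal(hill_at_size(x, sum(x), q)$estimate, S, tolerance = 0.05)
  }
})

test_that("repertoire diversity pools within bird and attaches intervals", {
  cfg <- simulation_config(seed = 63, lines = list(L = 2), tissues = "thymus",
                           reads_per_sample = 400, clones_per_bird = 60,
                           error_rate = 0)
  rep <- simulate_repertoire(cfg)
  div <- repertoire_diversity(rep$clonotypes, replicates = 50, seed = 1)
  expect_equal(nrow(div), 2 * 3)   # 2 birds x 3 orders
  expect_true(all(div$estimate >= 1))
  expect_true(all(div$lower <= div$upper))
  # ordering across q holds per unit
  for (b in unique(div$bird_id)) {
    e <- div$estimate[div$bird_id == b][order(div$q[div$bird_id == b])]
    expect_true(all(diff(e) <= 1e-9))
  }
})
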