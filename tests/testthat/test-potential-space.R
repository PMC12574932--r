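test_that("slope maps stay in [0, 90] and are seed-deterministic", {
  a <- generate_perlin_slope(64, 64, perlin_params(seed = 42))
  b <- generate_perlin_slope(64, 64, perlin_params(seed = 42))
  c <- generate_perlin_slope(64, 64, perlin_params(seed = 43))
  expect_gte(min(a$values), 0)
  expect_lte(max(a$values), 90)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("slope maps are spatially autocorrelated", {
  s <- generate_perlin_slope(64, 64, perlin_params(octaves = 1, seed = 42))
  expect_gt(oracle_morans_i(s$values), 0)
})

test_that("threshold categorisation marks gentle terrain as available", {
  s <- generate_perlin_slope(20, 20, perlin_params(seed = 11))
  expect_true(all(categorize_by_threshold(s, 90)$mask$values == 1))
  ps0 <- categorize_by_threshold(s, 0)
  expect_equal(sum(ps0$mask$values), sum(s$values == 0))
  ps45 <- categorize_by_threshold(s, 45)
  expect_equal(ps45$mask$values, matrix(as.numeric(s$values <= 45), 20, 20))
  expect_error(categorize_by_threshold(s, 91), "\\[0, 90\\]")
})

test_that("share categorisation takes the lowest cells, within one cell", {
  s <- generate_perlin_slope(10, 10, perlin_params(seed = 13))
  expect_true(all(categorize_by_share(s, 1)$mask$values == 1))
  expect_equal(sum(categorize_by_share(s, 0.5)$mask$values), 50)
  # sort-based oracle at 70%
  ps <- categorize_by_share(s, 0.7)
  cut <- sort(s$values)[70]
  expect_true(all(s$values[ps$mask$values == 1] <= cut))
  expect_equal(sum(ps$mask$values), 70)
  expect_error(categorize_by_share(s, 0), "\\(0, 1\\]")
  # one-cell tolerance holds for any map, ties included
  tied <- ag_grid(matrix(rep(1:5, each = 20), 10, 10))
  for (sh in c(0.13, 0.5, 0.77)) {
    got <- sum(categorize_by_share(tied, sh)$mask$values)
    expect_lte(abs(got - sh * 100), 1)
  }
})

test_that("external masks must be binary", {
  expect_s3_class(load_external(ag_grid(matrix(1, 4, 4))), "ag_potential_space")
  expect_error(load_external(ag_grid(matrix(c(1, 2), 2, 2))), "2")
  m <- matrix(c(0, 1, NA, 1), 2, 2)
  expect_equal(load_external(ag_grid(m))$mask$values, m)
})

test_that("intercept-only hybrid model fits the arable mean", {
  set.seed(3)
  arable <- ag_grid(matrix(rbinom(400, 1, 0.3), 20, 20))
  hp <- fit_hybrid(arable, list())
  expect_equal(plogis(hp$coefficients[1]), mean(arable$values),
               tolerance = 1e-6)
})

test_that("hybrid fit recovers a strong covariate and matches an ML oracle", {
  set.seed(17)
  truth <- matrix(rbinom(2500, 1, 0.4), 50, 50)
  cov1 <- ag_grid(truth + matrix(rnorm(2500, 0, 0.05), 50, 50))
  hp <- fit_hybrid(ag_grid(truth), list(cov1))
  expect_gt(hp$coefficients[2], 2)
  # holdout accuracy on a fresh realisation of the same signal
  truth2 <- matrix(rbinom(2500, 1, 0.4), 50, 50)
  x2 <- truth2 + matrix(rnorm(2500, 0, 0.05), 50, 50)
  pred <- plogis(hp$coefficients[1] + hp$coefficients[2] * x2) > 0.5
  expect_gt(mean(pred == (truth2 == 1)), 0.95)
})

test_that("hybrid fit matches an independent ML oracle on a well-posed model", {
  set.seed(19)
  x <- matrix(rnorm(2500), 50, 50)
  y <- matrix(rbinom(2500, 1, plogis(-0.5 + 1.5 * x)), 50, 50)
  hp <- fit_hybrid(ag_grid(y), list(ag_grid(x)))
  nll <- function(b) {
    eta <- b[1] + b[2] * as.vector(x)
    -sum(as.vector(y) * eta - log1p(exp(eta)))
  }
  ml <- optim(c(0, 1), nll, method = "BFGS")
  expect_equal(unname(hp$coefficients), ml$par, tolerance = 1e-3)
  expect_true(hp$converged)
})

test_that("independent noise yields no significant covariate", {
  set.seed(29)
  n_sig <- 0
  for (r in 1:100) {
    y <- matrix(rbinom(900, 1, 0.5), 30, 30)
    x <- matrix(rnorm(900), 30, 30)
    h1 <- fit_hybrid(ag_grid(y), list(ag_grid(x)))
    # likelihood-ratio test against intercept-only
    d1 <- suppressWarnings(stats::glm(as.vector(y) ~ as.vector(x),
                                      family = binomial())$deviance)
    d0 <- suppressWarnings(stats::glm(as.vector(y) ~ 1,
                                      family = binomial())$deviance)
    if (stats::pchisq(d0 - d1, 1, lower.tail = FALSE) < 0.05) n_sig <- n_sig + 1
    if (r <= 10) expect_lt(abs(h1$coefficients[2]), 0.5)
  }
  expect_lte(n_sig, 10)
})

test_that("apply_hybrid honours probabilities, seeds and smoothing", {
  ext <- ag_grid(matrix(0, 20, 20))
  sure <- structure(list(coefficients = 20, converged = TRUE,
                         smoothing_iterations = 2L,
                         smoothing_connectivity = 8L),
                    class = "hybrid_params")
  expect_true(all(apply_hybrid(sure, extent = ext, seed = 1)$mask$values == 1))
  # zero smoothing reproduces the raw Bernoulli field deterministically
  coin <- structure(list(coefficients = 0, converged = TRUE,
                         smoothing_iterations = 0L,
                         smoothing_connectivity = 8L),
                    class = "hybrid_params")
  a <- apply_hybrid(coin, extent = ext, seed = 5)
  b <- apply_hybrid(coin, extent = ext, seed = 5)
  expect_identical(a$mask$values, b$mask$values)
  expect_gt(sd(a$mask$values), 0)
})

test_that("majority smoothing clusters the mask spatially", {
  # smoothing exists to induce spatial autocorrelation: the share of
  # same-state rook adjacencies must rise on noisy fields, every time
  same_adj <- function(m) {
    h <- m[, -1] == m[, -ncol(m)]
    v <- m[-1, ] == m[-nrow(m), ]
    mean(c(h, v))
  }
  set.seed(31)
  for (r in 1:100) {
    m <- matrix(rbinom(2500, 1, runif(1, 0.4, 0.6)), 50, 50)
    sm <- agriscape:::majority_smooth(m, 2L, 8L)
    expect_gt(same_adj(sm), same_adj(m))
    expect_true(all(sm %in% c(0, 1)))
  }
  # smoothing is idempotent on homogeneous regions
  flat <- matrix(1, 20, 20)
  expect_identical(agriscape:::majority_smooth(flat, 3L, 8L), flat)
})
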