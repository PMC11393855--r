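test_that("firefly distance and attractiveness follow their closed forms", {
  expect_equal(firefly_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(firefly_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(firefly_distance(c(1, 2), c(3, 4)),
               firefly_distance(c(3, 4), c(1, 2)))
  expect_equal(firefly_attractiveness(0, 1.3, 2), 1.3)
  expect_equal(firefly_attractiveness(5, 1.3, 0), 1.3)
  expect_equal(firefly_attractiveness(1, 1, 1), exp(-1))
  r <- seq(0, 3, by = 0.5)
  expect_true(all(diff(firefly_attractiveness(r, 1, 1)) < 0))
})

test_that("firefly moves attract fully at gamma = 0 and have centered noise", {
  set.seed(61)
  a <- c(0.2, 0.8); b <- c(1, -1)
  expect_equal(firefly_move(a, b, beta0 = 1, gamma = 0, alpha = 0), b)
  expect_equal(firefly_move(a, a, beta0 = 1, gamma = 1, alpha = 0), a)
  steps <- replicate(10000, firefly_move(c(0, 0), c(0, 0), 1, 1, 0.5))
  expect_lt(max(abs(rowMeans(steps))), 0.01 * 0.5 * 3)
})

test_that("both swarm optimizers minimize the 5-D sphere within budget", {
  sphere <- function(v) sum(v^2)
  for (s in 1:3) {
    fa <- fa_optimize(sphere, 5, pop = 20, iters = 100, seed = s)
    expect_lt(fa$fitness, 1e-2)
    expect_true(all(diff(fa$trace) <= 1e-15))
    cs <- csa_optimize(sphere, 5, pop = 45, iters = 100, seed = s)
    expect_lt(cs$fitness, 1e-2)
    expect_true(all(diff(cs$trace) <= 1e-15))
  }
})

test_that("optimizers are seed-reproducible and flat on constant objectives", {
  const <- function(v) 1
  fa1 <- fa_optimize(const, 3, pop = 8, iters = 10, seed = 4)
  expect_true(all(fa1$trace == 1))
  fa2 <- fa_optimize(function(v) sum(abs(v)), 3, pop = 8, iters = 10, seed = 9)
  fa3 <- fa_optimize(function(v) sum(abs(v)), 3, pop = 8, iters = 10, seed = 9)
  expect_identical(fa2$best, fa3$best)
  cs1 <- csa_optimize(const, 3, pop = 8, iters = 10, seed = 4)
  expect_true(all(cs1$trace == 1))
  # zero-iteration budget returns the best of the initial population
  fa0 <- fa_optimize(function(v) sum(v^2), 3, pop = 8, iters = 0, seed = 5)
  expect_true(is.finite(fa0$fitness))
})

test_that("capuchin decay factor, angle and velocity follow their definitions", {
  expect_identical(csa_tau(0, 100), 2)
  expect_equal(csa_tau(100, 100), 2 * exp(-21))
  set.seed(62)
  th <- replicate(1000, csa_theta())
  expect_true(all(th >= 0 & th <= 1.5))
  v <- csa_velocity(c(0, 0), c(1, 1), c(1, 1), c(1, 1), rho = 0.7,
                    z1 = 2, z2 = 2, tau = 1)
  expect_equal(v, c(0, 0))                    # fixed point at the optimum
  v2 <- csa_velocity(c(1, 1), c(0, 0), c(1, 1), c(1, 1), rho = 0,
                     z1 = 0, z2 = 0, tau = 1)
  expect_equal(v2, c(0, 0))
})

test_that("capuchin positions remain inside the bounds throughout", {
  set.seed(63)
  # objective records every visited point
  seen <- new.env(); seen$bad <- 0
  obj <- function(v) {
    if (any(v < -1 - 1e-12) || any(v > 1 + 1e-12)) seen$bad <- seen$bad + 1
    sum(v^2)
  }
  invisible(csa_optimize(obj, 4, lower = -1, upper = 1, pop = 12, iters = 30,
                         seed = 7))
  expect_equal(seen$bad, 0)
})

test_that("swarm-tuned weighted ELMs beat the median random initialization", {
  set.seed(64)
  sp <- synth_spec(n_per_class = 15, duration_s = 0.4, seed = 9)
  # work directly in feature space with a small planted table for speed
  pt <- make_planted_table(n_samples = 80, n_informative = 6, n_noise = 6,
                           class_sep = 1.0, seed = 13)
  X <- pt$table$values; y <- pt$table$labels
  tr <- seq_along(y) %% 2 == 0
  for (s in 1:3) {
    tuned <- optimize_welm(X[tr, ], y[tr], X[!tr, ], y[!tr], optimizer = "fa",
                           D = 30, pop = 8, iters = 10, seed = s)
    err_tuned <- 1 - uar(y[!tr], elm_predict(tuned, X[!tr, ])$labels)
    rand_errs <- vapply(1:20, function(k) {
      m <- welm_train(X[tr, ], y[tr], D = 30, seed = 1000 + k)
      1 - uar(y[!tr], elm_predict(m, X[!tr, ])$labels)
    }, numeric(1))
    expect_lte(err_tuned, stats::median(rand_errs))
  }
  expect_equal(dim(tuned$input_weights), c(30L, ncol(X)))
  expect_length(tuned$biases, 30L)
})
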