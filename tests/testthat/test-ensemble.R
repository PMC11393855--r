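test_that("initial boosting weights equalize class mass", {
  expect_equal(init_boost_weights(c("A", "A", "B", "B")), rep(0.25, 4))
  w <- init_boost_weights(c("A", "A", "A", "B"))
  expect_equal(w, c(1/6, 1/6, 1/6, 1/2))
  expect_equal(sum(w[1:3]), sum(w[4]))
  expect_error(init_boost_weights(rep("A", 4)), "2 classes")
})

test_that("weighted error and vote weight follow their closed forms", {
  y <- c("a", "b", "a", "b")
  expect_equal(weak_error(y, y, rep(0.25, 4)), 0)
  expect_equal(weak_error(c("b", "a", "b", "a"), y, rep(0.25, 4)), 1)
  expect_equal(weak_error(c("a", "b", "a", "a"), y, rep(0.25, 4)), 0.25)

  expect_equal(learner_alpha(0.25, 4), 2 * log(3))
  expect_equal(learner_alpha(0.75, 4), 0)      # (C-1)/C boundary
  expect_equal(learner_alpha(0.5, 2), 0)       # two-class random guessing
  expect_gt(learner_alpha(0, 4), 20)           # capped, finite, large
})

test_that("the distribution update boosts misclassified mass and stays simplex", {
  dist <- rep(0.25, 4)
  y <- c("a", "a", "a", "b")
  pred <- c("a", "a", "a", "a")                # one of four wrong
  d0 <- update_boost_weights(dist, y, y, 0)
  expect_equal(d0, dist)
  d1 <- update_boost_weights(dist, pred, y, log(3))
  expect_equal(sum(d1), 1, tolerance = 1e-12)
  expect_equal(d1[4], 0.5)                     # hand arithmetic: 1 vs 3*(1/3)
  expect_gt(d1[4], dist[4])
})

test_that("boosting over weighted ELMs improves or matches a single learner", {
  # three-ring data: classes at increasing radius with angular noise
  set.seed(51)
  n <- 45
  r <- rep(c(1, 2, 3), each = n) + rnorm(3 * n, sd = 0.3)
  th <- runif(3 * n, 0, 2 * pi)
  X <- cbind(r * cos(th), r * sin(th))
  y <- rep(c("inner", "mid", "outer"), each = n)

  wins <- 0
  for (s in 1:5) {
    single <- welm_train(X, y, D = 30, lambda = 0.1, seed = s)
    uar_single <- uar(y, elm_predict(single, X)$labels)
    ens <- adaboost_welm_train(X, y, M = 10, D = 30, lambda = 0.1, seed = s)
    uar_ens <- uar(y, adaboost_predict(ens, X))
    if (uar_ens >= uar_single) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("single-round ensembles reduce to their base learner and stop early when perfect", {
  bd <- blob_data(15, sep = 5)
  ens1 <- adaboost_welm_train(bd$X, bd$y, M = 1, D = 30, seed = 2)
  base <- ens1$learners[[1]]
  expect_equal(adaboost_predict(ens1, bd$X), elm_predict(base, bd$X)$labels)
  ens <- adaboost_welm_train(bd$X, bd$y, M = 10, D = 40, lambda = 0.01, seed = 2)
  expect_equal(ens$rounds_run, 1)             # perfect learner ends boosting
  expect_true(all(ens$alphas > 0))
})

test_that("weighted voting follows the alpha totals with scale invariance", {
  classes <- c("a", "b")
  fake_model <- function(lab) {
    structure(list(input_weights = matrix(0, 1, 2), biases = 0,
                   activation = "identity", classes = classes, kernel = NULL,
                   beta = matrix(if (lab == "a") c(1, -1) else c(-1, 1), 1, 2),
                   lambda = 1), class = "elm_model")
  }
  X <- matrix(1, 1, 2)
  ens <- structure(list(learners = list(fake_model("a"), fake_model("a"),
                                        fake_model("b")),
                        alphas = c(1, 1, 1.5), classes = classes),
                   class = "boosted_ensemble")
  expect_equal(adaboost_predict(ens, X), "a")   # 2.0 beats 1.5
  ens$alphas <- ens$alphas * 10
  expect_equal(adaboost_predict(ens, X), "a")
})

test_that("the error-weighted combiner normalizes weights and passes through one predictor", {
  bd <- blob_data(15, sep = 4)
  m1 <- welm_train(bd$X, bd$y, D = 25, lambda = 0.1, seed = 1)
  m2 <- welm_train(bd$X, bd$y, D = 25, lambda = 0.1, seed = 2)
  combo1 <- regressor_combine(list(m1), bd$X, bd$y)
  expect_equal(combo1$weights, 1)
  expect_equal(combined_predict(combo1, bd$X)$labels,
               elm_predict(m1, bd$X)$labels)
  combo <- regressor_combine(list(m1, m2), bd$X, bd$y)
  expect_equal(sum(combo$weights), 1, tolerance = 1e-12)
  expect_true(all(combo$weights > 0))
})
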