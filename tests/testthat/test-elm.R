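test_that("hidden activations follow the activation contract", {
  m <- structure(list(input_weights = matrix(0, 5, 3), biases = rep(0, 5),
                      activation = "sigmoid"), class = "elm_model")
  H <- hidden_activations(matrix(rnorm(12), 4, 3), m)
  expect_true(all(H == 0.5))
  m2 <- structure(list(input_weights = diag(3), biases = rep(0, 3),
                       activation = "identity"), class = "elm_model")
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(hidden_activations(X, m2), X)
  expect_error(hidden_activations(matrix(0, 2, 5), m), "mismatch")
})

test_that("both ridge-solution branches agree on random instances", {
  set.seed(20)
  for (i in 1:20) {
    X <- matrix(rnorm(20 * 4), 20, 4)
    y <- rep(c("a", "b"), 10)
    m1 <- elm_train(X, y, D = 30, lambda = 0.1, seed = i, force_branch = "kernel")
    m2 <- elm_train(X, y, D = 30, lambda = 0.1, seed = i, force_branch = "primal")
    expect_lt(max(abs(elm_predict(m1, X)$decision - elm_predict(m2, X)$decision)),
              1e-8)
  }
})

test_that("ELM separates blobs, shrinks with ridge, and predicts deterministically", {
  bd <- blob_data(20, sep = 4)
  m <- elm_train(bd$X, bd$y, D = 40, lambda = 0.01, seed = 3)
  expect_equal(mean(elm_predict(m, bd$X)$labels == bd$y), 1)
  norms <- vapply(c(1e-2, 1, 1e2, 1e4, 1e6), function(l) {
    sum(elm_train(bd$X, bd$y, D = 40, lambda = l, seed = 3)$beta^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  p1 <- elm_predict(elm_train(bd$X, bd$y, D = 40, seed = 7), bd$X)$decision
  p2 <- elm_predict(elm_train(bd$X, bd$y, D = 40, seed = 7), bd$X)$decision
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(40L, 2L))
})

test_that("class-inverse weights give each class unit mass", {
  w <- class_weights(c("A", "A", "B"))
  expect_equal(w, c(0.5, 0.5, 1.0))
  expect_equal(as.numeric(tapply(w, c("A", "A", "B"), sum)), c(1, 1))
  wb <- class_weights(rep(c("A", "B"), each = 5))
  expect_true(all(wb == wb[1]))
})

test_that("weighted ELM reduces to ELM at unit weights and helps minority recall", {
  bd <- blob_data(20, sep = 4)
  me <- elm_train(bd$X, bd$y, D = 40, lambda = 0.1, seed = 5)
  mw <- welm_train(bd$X, bd$y, D = 40, lambda = 0.1,
                   weights = rep(1, length(bd$y)), seed = 5)
  expect_lt(max(abs(elm_predict(me, bd$X)$decision -
                    elm_predict(mw, bd$X)$decision)), 1e-10)

  # 95:5 imbalance: class-weighted training should not hurt minority recall
  wins <- 0
  for (s in 1:5) {
    set.seed(s)
    y <- rep(c("maj", "min"), c(95, 5))
    X <- rbind(matrix(rnorm(95 * 2, 0), 95, 2), matrix(rnorm(5 * 2, 2.0), 5, 2))
    m_plain <- elm_train(X, y, D = 50, lambda = 0.1, seed = s)
    m_wt <- welm_train(X, y, D = 50, lambda = 0.1, seed = s)
    rec <- function(m) mean(elm_predict(m, X)$labels[y == "min"] == "min")
    if (rec(m_wt) >= rec(m_plain)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("uniformly scaled weights with matched ridge leave beta unchanged", {
  bd <- blob_data(10, sep = 3)
  w <- class_weights(bd$y)
  m1 <- welm_train(bd$X, bd$y, D = 25, lambda = 0.1, weights = w, seed = 2)
  m2 <- welm_train(bd$X, bd$y, D = 25, lambda = 0.2, weights = 2 * w, seed = 2)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-9)
})

test_that("kernel matrices are symmetric, PSD, and hit closed-form values", {
  set.seed(8)
  X <- matrix(rnorm(10 * 3), 10, 3)
  K <- kernel_matrix(X, X, kernel_spec("rbf", gamma = 0.7))
  expect_true(all(abs(diag(K) - 1) < 1e-12))
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  z <- matrix(0, 1, 3)
  expect_equal(as.numeric(kernel_matrix(z, z, kernel_spec("polynomial", degree = 1))), 1)
})

test_that("the composited kernel interpolates its two view kernels", {
  set.seed(9)
  X <- matrix(rnorm(6 * 4), 6, 4)
  sp <- kernel_spec("composited", gamma = 0.5, degree = 2, mu = 0.5,
                    view1 = 1:2, view2 = 3:4)
  Ks <- kernel_matrix(X[, 1:2], X[, 1:2], kernel_spec("rbf", gamma = 0.5))
  Kw <- kernel_matrix(X[, 3:4], X[, 3:4], kernel_spec("polynomial", degree = 2))
  Kc <- kernel_matrix(X, X, sp)
  expect_equal(Kc, 0.5 * Ks + 0.5 * Kw, tolerance = 1e-12)
  sp1 <- sp; sp1$mu <- 1
  expect_equal(kernel_matrix(X, X, sp1), Ks, tolerance = 1e-12)
  sp0 <- sp; sp0$mu <- 0
  expect_equal(kernel_matrix(X, X, sp0), Kw, tolerance = 1e-12)
  spbad <- sp; spbad$view1 <- integer(0)
  expect_error(kernel_matrix(X, X, spbad), "non-empty")
})

test_that("kernel ELM with the explicit linear kernel matches the explicit-feature ELM", {
  bd <- blob_data(15, sep = 3, d = 3)
  # build an explicit hidden layer, then compare decision values of the
  # weighted ELM against a kernel machine on k(x, y) = h(x) . h(y)
  hid <- snoreforge:::new_elm_hidden(3, 30, seed = 11)
  model0 <- structure(c(hid, list(lambda = 0.1, classes = c("a", "b"),
                                  kernel = NULL)), class = "elm_model")
  H <- hidden_activations(bd$X, model0)
  w <- class_weights(bd$y)
  mw <- welm_train(bd$X, bd$y, D = 30, lambda = 0.1, weights = w, seed = 11)
  dec_welm <- elm_predict(mw, bd$X)$decision

  Om <- tcrossprod(H)
  a <- sqrt(w)
  Tm <- snoreforge:::one_hot_pm(bd$y, c("a", "b"))
  beta <- a * solve((Om * a) * rep(a, each = nrow(Om)) + diag(0.1, nrow(Om)),
                    Tm * a)
  dec_kernel <- Om %*% beta
  expect_lt(max(abs(dec_welm - dec_kernel)), 1e-6)
})

test_that("weighted kernel ELM fits the separable fixture and reduces at U = I", {
  bd <- blob_data(15, sep = 4)
  spec <- kernel_spec("rbf", gamma = 0.5)
  mk <- wkelm_train(bd$X, bd$y, spec, lambda = 0.01)
  expect_equal(mean(elm_predict(mk, bd$X)$labels == bd$y), 1)
  m_unit <- wkelm_train(bd$X, bd$y, spec, lambda = 0.01,
                        weights = rep(1, length(bd$y)))
  m_bal <- wkelm_train(bd$X, bd$y, spec, lambda = 0.01,
                       weights = rep(2, length(bd$y)))
  expect_false(identical(m_unit$beta, m_bal$beta))  # scaling interacts with ridge
  expect_equal(elm_predict(m_unit, bd$X)$labels, bd$y)
})

test_that("label predictions are invariant to class encoding order", {
  bd <- blob_data(12, sep = 4)
  m <- elm_train(bd$X, bd$y, D = 30, seed = 4)
  swapped <- c(a = "b2", b = "a1")[bd$y]  # reverse lexical order
  m2 <- elm_train(bd$X, swapped, D = 30, seed = 4)
  map_back <- c(b2 = "a", a1 = "b")
  expect_equal(unname(map_back[elm_predict(m2, bd$X)$labels]),
               elm_predict(m, bd$X)$labels)
})
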