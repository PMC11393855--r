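# one-hot targets in {-1, +1}: T[i, c] = 1 if sample i is in class c
one_hot_pm <- function(y, classes) {
  T <- matrix(-1, length(y), length(classes))
  T[cbind(seq_along(y), match(y, classes))] <- 1
  T
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Hidden-layer activations of an ELM
#'
#' H\[i, k\] = s(v_k . x_i + b_k) for random input weights v and biases
#' b; sigmoid activation by default.
#'
#' @param X numeric matrix N x d.
#' @param model an `elm_model` (explicit hidden-layer form).
#' @return N x D activation matrix.
#' @export
hidden_activations <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$input_weights))
    stop("feature count mismatch", call. = FALSE)
  Z <- X %*% t(model$input_weights) +
    matrix(model$biases, nrow(X), length(model$biases), byrow = TRUE)
  switch(model$activation,
         sigmoid = sigmoid(Z),
         identity = Z,
         stop("unknown activation"))
}

new_elm_hidden <- function(d, D, seed, activation = "sigmoid") {
  with_seed(seed, {
    W <- matrix(stats::runif(D * d, -1, 1), D, d)
    b <- stats::runif(D, 0, 1)
    list(input_weights = W, biases = b, activation = activation)
  })
}

# ridge solve of the ELM output weights, optionally sample-weighted.
# Symmetric weighted form: with A = U^{1/2},
#   N <= D: beta = H' A (lambda I + A H H' A)^{-1} A T
#   N >  D: beta = (lambda I + H' U H)^{-1} H' U T
# (equal to the asymmetric textbook expressions by a similarity identity).
solve_beta <- function(H, T, lambda, w = NULL, force_branch = NULL) {
  N <- nrow(H); D <- ncol(H)
  if (is.null(w)) w <- rep(1, N)
  branch <- if (!is.null(force_branch)) force_branch else
    if (N <= D) "kernel" else "primal"
  if (branch == "kernel") {
    a <- sqrt(w)
    Ha <- H * a
    G <- tcrossprod(Ha)               # A H H' A
    M <- G + diag(lambda, N)
    t(Ha) %*% solve(M, T * a)
  } else {
    HtUH <- crossprod(H * sqrt(w))
    M <- HtUH + diag(lambda, D)
    solve(M, crossprod(H, T * w))
  }
}

#' Train an extreme learning machine
#'
#' Single hidden layer with random input weights in \[-1, 1\] and biases
#' in \[0, 1\]; output weights from the ridge-regularized least-squares
#' solution (the kernel-form expression for N <= D and the primal form
#' for N > D; the two agree algebraically).
#'
#' @param X N x d feature matrix.
#' @param y class labels, length N (>= 2 classes).
#' @param D hidden-layer size (default 100).
#' @param lambda ridge coefficient (> 0, default 0.1).
#' @param seed RNG seed for the hidden parameters.
#' @param force_branch internal: force "kernel" or "primal" solve.
#' @return object of class `elm_model`.
#' @export
elm_train <- function(X, y, D = 100L, lambda = 0.1, seed = 1L,
                      force_branch = NULL) {
  welm_train(X, y, D = D, lambda = lambda, weights = rep(1, length(y)),
             seed = seed, force_branch = force_branch)
}

#' Per-sample class-balancing weights
#'
#' w_i = 1 / (number of training samples in the class of sample i), so
#' each class carries equal total weight.
#'
#' @param y class labels.
#' @return positive numeric vector, one weight per sample.
#' @export
class_weights <- function(y) {
  cnt <- table(y)
  as.numeric(1 / cnt[as.character(y)])
}

#' Train a weighted ELM
#'
#' ELM with a diagonal sample-weight matrix U in the ridge solution;
#' with unit weights it reduces exactly to [elm_train]. Class-inverse
#' weights ([class_weights]) counteract class imbalance.
#'
#' @inheritParams elm_train
#' @param weights positive per-sample weights (diagonal of U).
#' @return object of class `elm_model`.
#' @export
welm_train <- function(X, y, D = 100L, lambda = 0.1, weights = NULL,
                       seed = 1L, force_branch = NULL) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(weights)) weights <- class_weights(y)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  hid <- new_elm_hidden(ncol(X), D, seed)
  model <- structure(c(hid, list(lambda = lambda, classes = classes,
                                 kernel = NULL)), class = "elm_model")
  H <- hidden_activations(X, model)
  Tm <- one_hot_pm(as.character(y), classes)
  model$beta <- solve_beta(H, Tm, lambda, weights, force_branch)
  model
}

#' Predict with an ELM / weighted ELM
#'
#' @param model an `elm_model`.
#' @param X feature matrix.
#' @return list with `labels` (argmax class, ties to the lowest class
#'   index) and `decision` (N x C decision-value matrix).
#' @export
elm_predict <- function(model, X) {
  f <- if (is.null(model$kernel)) {
    hidden_activations(as.matrix(X), model) %*% model$beta
  } else {
    K <- kernel_matrix(as.matrix(X), model$train_anchors, model$kernel)
    K %*% model$beta
  }
  colnames(f) <- model$classes
  list(labels = model$classes[max.col(f, ties.method = "first")],
       decision = f)
}

#' Kernel matrix between two sample sets
#'
#' RBF: exp(-gamma ||x - y||^2). Polynomial: (<x, y> + 1)^degree.
#' Composited: mu * RBF on one column view + (1 - mu) * polynomial on
#' the other (see [kernel_spec]).
#'
#' @param Xa,Xb numeric matrices with matching column count.
#' @param spec a [kernel_spec].
#' @return |Xa| x |Xb| kernel matrix.
#' @export
kernel_matrix <- function(Xa, Xb, spec) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  switch(spec$kind,
    rbf = {
      d2 <- outer(rowSums(Xa^2), rowSums(Xb^2), `+`) - 2 * tcrossprod(Xa, Xb)
      exp(-spec$gamma * pmax(d2, 0))
    },
    polynomial = (tcrossprod(Xa, Xb) + 1)^spec$degree,
    composited = {
      v1 <- spec$view1; v2 <- spec$view2
      if (length(v1) == 0L || length(v2) == 0L)
        stop("composited kernel requires two non-empty views", call. = FALSE)
      Ks <- kernel_matrix(Xa[, v1, drop = FALSE], Xb[, v1, drop = FALSE],
                          list(kind = "rbf", gamma = spec$gamma))
      Kw <- kernel_matrix(Xa[, v2, drop = FALSE], Xb[, v2, drop = FALSE],
                          list(kind = "polynomial", degree = spec$degree))
      spec$mu * Ks + (1 - spec$mu) * Kw
    },
    stop("unknown kernel kind", call. = FALSE))
}

#' Kernel specification
#'
#' @param kind "rbf", "polynomial" or "composited".
#' @param gamma RBF width parameter (> 0).
#' @param degree polynomial degree (positive integer).
#' @param mu composited balance coefficient in \[0, 1\].
#' @param view1,view2 column indices (or names) of the two feature views
#'   for the composited kernel; view1 feeds the RBF part, view2 the
#'   polynomial part.
#' @return list of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "polynomial", "composited"),
                        gamma = 1, degree = 2L, mu = 0.5,
                        view1 = NULL, view2 = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, gamma = gamma, degree = as.integer(degree),
                 mu = mu, view1 = view1, view2 = view2),
            class = "kernel_spec")
}

#' Train a (weighted) kernel ELM
#'
#' Kernel form of the weighted ELM: with Gram matrix Omega and diagonal
#' sample weights U, the output weights solve the symmetric system
#' beta = U^{1/2} (lambda I + U^{1/2} Omega U^{1/2})^{-1} U^{1/2} T, and
#' prediction for p is the kernel row \[k(p, p_1) ... k(p, p_N)\] times
#' beta. With U = I this is the plain kernel ELM.
#'
#' @param X N x d training features.
#' @param y class labels.
#' @param spec a [kernel_spec].
#' @param lambda ridge coefficient.
#' @param weights per-sample weights; NULL for [class_weights].
#' @return object of class `elm_model` (kernel form; training features
#'   stored as anchors).
#' @export
wkelm_train <- function(X, y, spec, lambda = 0.1, weights = NULL) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(weights)) weights <- class_weights(y)
  Om <- kernel_matrix(X, X, spec)
  a <- sqrt(weights)
  M <- (Om * a) * rep(a, each = nrow(Om))   # A Omega A
  Tm <- one_hot_pm(as.character(y), classes)
  beta <- a * solve(M + diag(lambda, nrow(Om)), Tm * a)
  structure(list(input_weights = NULL, biases = NULL, activation = "kernel",
                 lambda = lambda, classes = classes, kernel = spec,
                 train_anchors = X, beta = beta),
            class = "elm_model")
}
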