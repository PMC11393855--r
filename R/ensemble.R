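#' Initial boosting distribution
#'
#' Sample weights proportional to the inverse class size, normalized to
#' sum one, so every class carries equal total mass regardless of
#' imbalance.
#'
#' @param y class labels (>= 2 classes).
#' @return numeric weights summing to 1.
#' @export
init_boost_weights <- function(y) {
  if (length(unique(y)) < 2L) stop("need at least 2 classes", call. = FALSE)
  w <- class_weights(y)
  w / sum(w)
}

#' Distribution-weighted error of a weak learner
#'
#' epsilon = sum_i dist_i * \[pred_i != y_i\], in \[0, 1\].
#'
#' @param pred,y predicted and true labels.
#' @param dist weight distribution (sums to 1).
#' @return scalar error.
#' @export
weak_error <- function(pred, y, dist) {
  stopifnot(length(pred) == length(y), length(dist) == length(y))
  sum(dist * (as.character(pred) != as.character(y)))
}

#' Multiclass learner vote weight
#'
#' alpha = ln((1 - epsilon) / epsilon) + ln(C - 1); positive exactly
#' when the weak learner beats C-class random guessing
#' (epsilon < (C - 1) / C). epsilon = 0 is capped at 1e-10.
#'
#' @param epsilon weighted error in \[0, 1).
#' @param C number of classes.
#' @return vote weight alpha.
#' @export
learner_alpha <- function(epsilon, C) {
  epsilon <- max(epsilon, 1e-10)
  log((1 - epsilon) / epsilon) + log(C - 1)
}

#' Boosting distribution update
#'
#' w_i <- w_i * exp(-alpha * \[pred_i == y_i\]) followed by
#' normalization: correctly classified samples are scaled down, so after
#' normalization misclassified samples gain relative weight whenever
#' alpha > 0 (the stagewise multiclass exponential-loss update).
#'
#' @param dist current distribution.
#' @param pred,y predicted and true labels.
#' @param alpha learner vote weight.
#' @return updated distribution summing to 1.
#' @export
update_boost_weights <- function(dist, pred, y, alpha) {
  correct <- as.character(pred) == as.character(y)
  w <- dist * exp(-alpha * as.numeric(correct))
  s <- sum(w)
  if (s < EPS) stop("degenerate boosting weights", call. = FALSE)
  w / s
}

#' Adaboost over weighted ELM / kernel ELM weak learners
#'
#' Multiclass boosting: each round trains a weak learner with the
#' current distribution folded into its sample weights
#' (U = diag(dist * N)), computes the distribution-weighted error,
#' derives the vote weight alpha, and reweights the samples. Rounds
#' stop early on a perfect learner or one no better than random
#' guessing; if no usable round is found a single unboosted learner is
#' returned with a warning.
#'
#' @param X N x d features.
#' @param y class labels.
#' @param M maximum boosting rounds (default 10).
#' @param learner "welm" or "wkelm".
#' @param D hidden size for the ELM weak learner.
#' @param lambda ridge coefficient.
#' @param spec [kernel_spec] when `learner = "wkelm"`.
#' @param seed base RNG seed; round t uses seed + t.
#' @param train_fn optional custom weak trainer
#'   `function(X, y, weights, round)` returning an `elm_model`.
#' @return object of class `boosted_ensemble` with `learners`, `alphas`,
#'   `history` (per-round errors) and `classes`.
#' @export
adaboost_welm_train <- function(X, y, M = 10L, learner = c("welm", "wkelm"),
                                D = 100L, lambda = 0.1, spec = NULL,
                                seed = 1L, train_fn = NULL) {
  learner <- match.arg(learner)
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  C <- length(classes)
  N <- length(y)
  if (is.null(train_fn)) {
    train_fn <- function(X, y, weights, round) {
      if (learner == "welm")
        welm_train(X, y, D = D, lambda = lambda, weights = weights,
                   seed = seed + round)
      else
        wkelm_train(X, y, spec = spec, lambda = lambda, weights = weights)
    }
  }
  dist <- init_boost_weights(y)
  learners <- list(); alphas <- numeric(0); history <- numeric(0)
  for (t in seq_len(M)) {
    m <- train_fn(X, y, dist * N, t)
    pred <- elm_predict(m, X)$labels
    eps <- weak_error(pred, y, dist)
    if (eps >= (C - 1) / C) break
    a <- learner_alpha(eps, C)
    learners <- c(learners, list(m)); alphas <- c(alphas, a)
    history <- c(history, eps)
    if (eps <= 1e-10) break
    dist <- update_boost_weights(dist, pred, y, a)
  }
  if (length(learners) == 0L) {
    warning("no weak learner beat random guessing; returning unboosted model")
    m <- train_fn(X, y, class_weights(y), 1L)
    learners <- list(m); alphas <- 1; history <- NA_real_
  }
  structure(list(learners = learners, alphas = alphas,
                 rounds_run = length(learners), history = history,
                 classes = classes),
            class = "boosted_ensemble")
}

#' Predict with a boosted ensemble
#'
#' Weighted vote: argmax_c sum_t alpha_t * \[label_t(x) = c\], ties to
#' the lowest class index.
#'
#' @param ensemble a `boosted_ensemble`.
#' @param X feature matrix.
#' @return character labels.
#' @export
adaboost_predict <- function(ensemble, X) {
  votes <- matrix(0, nrow(as.matrix(X)), length(ensemble$classes))
  for (t in seq_along(ensemble$learners)) {
    lab <- elm_predict(ensemble$learners[[t]], X)$labels
    idx <- match(lab, ensemble$classes)
    votes[cbind(seq_along(idx), idx)] <-
      votes[cbind(seq_along(idx), idx)] + ensemble$alphas[t]
  }
  ensemble$classes[max.col(votes, ties.method = "first")]
}

#' Error-weighted combination of fitted predictors
#'
#' Adaboost-regressor-style combiner applied to class decision scores.
#' For each predictor k: per-sample normalized error
#' e_k(i) = |h_k(x_i) - q_i| / R with R the largest absolute deviation,
#' total error eps_k = sum_i T_i e_k(i) under the (uniform) training
#' distribution, beta_k = eps_k / (1 - eps_k) and coefficient
#' c_k = log(1 / beta_k) / 2. Predictors with eps_k >= 0.5 are dropped;
#' final combination weights are c_k / sum c_k. Targets q are the
#' +/- 1 one-vs-all encoding per class, and errors are averaged over
#' classes.
#'
#' @param predictors list of fitted `elm_model`s (decision values used).
#' @param X_train,y_train training data the errors are measured on.
#' @return list of class `combined_predictor` with `predictors`,
#'   `weights` (sum to 1), `classes`.
#' @export
regressor_combine <- function(predictors, X_train, y_train) {
  stopifnot(length(predictors) >= 1L)
  y_train <- as.character(y_train)
  classes <- sort(unique(y_train))
  Q <- one_hot_pm(y_train, classes)
  n <- length(y_train)
  dist <- rep(1 / n, n)
  cs <- numeric(length(predictors))
  for (k in seq_along(predictors)) {
    Hk <- elm_predict(predictors[[k]], X_train)$decision
    err <- abs(Hk - Q)
    R <- max(err)
    if (R < EPS) { cs[k] <- 0.5 * log(1 / EPS); next }  # perfect predictor
    e_i <- rowMeans(err / R)                 # averaged over classes
    eps_k <- sum(dist * e_i)
    if (eps_k >= 0.5) { cs[k] <- NA_real_; next }
    beta <- max(eps_k / (1 - eps_k), EPS)
    cs[k] <- 0.5 * log(1 / beta)
    # reweight toward badly predicted samples before the next predictor
    dist <- dist * beta^(1 - e_i)
    dist <- dist / sum(dist)
  }
  keep <- which(is.finite(cs) & cs > 0)
  if (length(keep) == 0L) stop("all predictors dropped (error >= 0.5)", call. = FALSE)
  w <- cs[keep] / sum(cs[keep])
  structure(list(predictors = predictors[keep], weights = w,
                 classes = classes),
            class = "combined_predictor")
}

#' Predict with a combined predictor
#'
#' Weighted sum of the member decision matrices, then argmax.
#'
#' @param combo a `combined_predictor`.
#' @param X feature matrix.
#' @return list with `labels` and `decision`.
#' @export
combined_predict <- function(combo, X) {
  dec <- 0
  for (k in seq_along(combo$predictors)) {
    dec <- dec + combo$weights[k] *
      elm_predict(combo$predictors[[k]], X)$decision
  }
  list(labels = combo$classes[max.col(dec, ties.method = "first")],
       decision = dec)
}
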