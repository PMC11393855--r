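#' Unweighted average recall
#'
#' Mean over the true classes of the per-class recall; the standard
#' imbalance-robust metric of computational paralinguistics. Classes
#' that occur only among the predictions are ignored; a true class must
#' have at least one sample.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @return scalar in \[0, 1\].
#' @export
uar <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  classes <- unique(y_true)
  recalls <- vapply(classes, function(cl) {
    idx <- y_true == cl
    if (sum(idx) == 0L) stop("true class without samples", call. = FALSE)
    mean(y_pred[idx] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Confusion matrix with stable class order
#' @param y_true,y_pred label vectors.
#' @return table with true classes as rows.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  classes <- sort(unique(c(y_true, y_pred)))
  table(factor(y_true, classes), factor(y_pred, classes),
        dnn = c("true", "pred"))
}

#' Stratified k-fold assignment
#'
#' Assigns each sample a fold in 1..k such that per-class proportions
#' are preserved within one sample per fold; the assignment is a
#' function of the current RNG state (wrap in a seed for
#' reproducibility).
#'
#' @param labels class labels.
#' @param k number of folds; every class must have >= k samples.
#' @return integer fold id per sample.
#' @export
stratified_folds <- function(labels, k) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop(sprintf("class '%s' has fewer samples than folds", cl), call. = FALSE)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# z-score scaling fit on the training rows only
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  sc[sc < EPS] <- 1
  list(mu = mu, sc = sc)
}
apply_scaler <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sc, "/")

# train the configured classifier on a (scaled) training split
train_classifier <- function(classifier, Xtr, ytr, cfg, seed) {
  switch(classifier,
    elm = elm_train(Xtr, ytr, D = cfg$hidden, lambda = cfg$lambda, seed = seed),
    welm = welm_train(Xtr, ytr, D = cfg$hidden, lambda = cfg$lambda, seed = seed),
    wkelm = wkelm_train(Xtr, ytr, spec = kernel_spec("rbf", gamma = cfg$gamma),
                        lambda = cfg$lambda),
    ckelm = {
      p <- ncol(Xtr)
      spec <- kernel_spec("composited", gamma = cfg$gamma, degree = 2L,
                          mu = cfg$mu, view1 = seq_len(p %/% 2),
                          view2 = (p %/% 2 + 1L):p)
      wkelm_train(Xtr, ytr, spec = spec, lambda = cfg$lambda)
    },
    adaboost_welm = adaboost_welm_train(Xtr, ytr, M = cfg$boost_rounds,
                                        D = cfg$hidden, lambda = cfg$lambda,
                                        seed = seed),
    fa_welm_adaboost = ,
    csa_welm_adaboost = {
      optname <- if (classifier == "fa_welm_adaboost") "fa" else "csa"
      boosted_tuned_welm(Xtr, ytr, optimizer = optname, cfg = cfg, seed = seed)
    },
    stop(sprintf("unknown classifier '%s'", classifier), call. = FALSE))
}

predict_classifier <- function(model, X) {
  if (inherits(model, "boosted_ensemble")) adaboost_predict(model, X)
  else elm_predict(model, X)$labels
}

# Adaboost whose weak learners are swarm-tuned weighted ELMs: each
# round carves an inner stratified validation split, tunes the hidden
# layer with FA or CSA against validation UAR, then lets the boosting
# distribution reweight the samples
boosted_tuned_welm <- function(X, y, optimizer, cfg, seed) {
  train_fn <- function(Xr, yr, weights, round) {
    inner <- with_seed(seed + 1000L + round,
                       stratified_folds(yr, max(3L, 3L)))
    val <- inner == 1L
    m <- optimize_welm(Xr[!val, , drop = FALSE], yr[!val],
                       Xr[val, , drop = FALSE], yr[val],
                       optimizer = optimizer, D = cfg$hidden,
                       lambda = cfg$lambda, pop = cfg$opt_pop,
                       iters = cfg$opt_iters, seed = seed + round)
    # refit the tuned hidden layer on the full round data with the
    # boosting weights folded in
    H <- hidden_activations(Xr, m)
    Tm <- one_hot_pm(as.character(yr), m$classes)
    m$beta <- solve_beta(H, Tm, cfg$lambda, weights)
    m
  }
  adaboost_welm_train(X, y, M = cfg$boost_rounds, seed = seed,
                      train_fn = train_fn)
}

#' Pipeline run configuration
#'
#' @param domains feature domains to extract (ignored when the run
#'   starts from a feature table).
#' @param selector NULL (no selection) or "geo" / "ssa" / "rssa".
#' @param selector_pop,selector_iters selector budget per fold.
#' @param classifier one of "elm", "welm", "wkelm", "ckelm",
#'   "adaboost_welm", "fa_welm_adaboost", "csa_welm_adaboost".
#' @param cv_folds stratified folds (default 10).
#' @param hidden,lambda,gamma,mu,boost_rounds classifier parameters.
#' @param alpha,beta wrapper-fitness weights (see [fitness_config]).
#' @param opt_pop,opt_iters swarm budget for the tuned classifiers.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(domains = c("time", "ceps"), selector = "rssa",
                       selector_pop = 10L, selector_iters = 30L,
                       classifier = "fa_welm_adaboost", cv_folds = 10L,
                       hidden = 100L, lambda = 0.1, gamma = 0.01, mu = 0.5,
                       boost_rounds = 5L, alpha = 0.8, beta = 0.01,
                       opt_pop = 10L, opt_iters = 10L, seed = 1L) {
  if (!is.null(selector) &&
      !selector %in% c("geo", "ssa", "rssa"))
    stop(sprintf("unknown selector '%s'", selector), call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full classification pipeline under cross-validation
#'
#' Stratified k-fold evaluation with a leakage guard: for every fold,
#' feature scaling, feature selection and classifier training see only
#' that fold's training split. Reports per-fold UAR, mean UAR, the
#' pooled confusion matrix and the per-fold selected masks.
#'
#' @param input a list of [audio_clip]s or a [feature_table].
#' @param config a [run_config].
#' @return list of class `eval_report`: `fold_uar`, `mean_uar`,
#'   `confusion`, `masks`, `config`.
#' @export
run_pipeline <- function(input, config = run_config()) {
  table <- if (inherits(input, "feature_table")) input
           else extract_domains(input, config$domains)
  y <- table$labels
  folds <- with_seed(config$seed, stratified_folds(y, config$cv_folds))
  pred <- character(length(y))
  masks <- vector("list", config$cv_folds)
  fold_uar <- numeric(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    tab_tr <- subset_table(table, which(tr))
    scaler <- fit_scaler(tab_tr$values)
    Xtr <- apply_scaler(tab_tr$values, scaler)
    Xte <- apply_scaler(table$values[!tr, , drop = FALSE], scaler)
    if (!is.null(config$selector)) {
      cfg_fit <- fitness_config(alpha = config$alpha, beta = config$beta,
                                seed = config$seed + 77L)
      tab_scaled <- feature_table(Xtr, tab_tr$labels, tab_tr$clip_ids)
      mask <- select_features(config$selector, tab_scaled, cfg_fit,
                              pop = config$selector_pop,
                              iters = config$selector_iters,
                              seed = config$seed + f)
      masks[[f]] <- mask
      keep <- which(mask$bits == 1)
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    }
    model <- train_classifier(config$classifier, Xtr, tab_tr$labels,
                              config, seed = config$seed + 100L + f)
    pf <- predict_classifier(model, Xte)
    pred[!tr] <- pf
    fold_uar[f] <- uar(y[!tr], pf)
  }
  structure(list(fold_uar = fold_uar, mean_uar = mean(fold_uar),
                 confusion = confusion_matrix(y, pred),
                 masks = masks, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: mean UAR %.4f over %d folds>\n",
              x$mean_uar, length(x$fold_uar)))
  cat("fold UAR:", paste(sprintf("%.3f", x$fold_uar), collapse = " "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(mean_uar = report$mean_uar, fold_uar = report$fold_uar,
         confusion = as.data.frame(report$confusion),
         seed = report$config$seed,
         classifier = report$config$classifier,
         selector = report$config$selector),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
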