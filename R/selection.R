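#' Wrapper-fitness configuration
#'
#' Controls the subset-scoring objective
#' f = alpha * error + beta * |subset| / N, where the error is the
#' balanced error (1 - unweighted average recall) of the internal
#' wrapper classifier under stratified cross-validation on the masked
#' features. Defaults alpha = 0.8, beta = 0.01 follow the experimental
#' settings this package reproduces; beta = 1 - alpha is the documented
#' alternative.
#'
#' @param alpha weight on the classification error, in \[0, 1\].
#' @param beta weight on the relative subset size.
#' @param wrapper_folds stratified CV folds for the wrapper classifier.
#' @param hidden hidden-layer size of the wrapper's weighted ELM.
#' @param lambda ridge coefficient of the wrapper's weighted ELM.
#' @param seed seed controlling the wrapper CV split and ELM hidden
#'   parameters (kept fixed so fitness is a deterministic function of
#'   the mask).
#' @return list of class `fitness_config`.
#' @export
fitness_config <- function(alpha = 0.8, beta = 0.01, wrapper_folds = 3L,
                           hidden = 50L, lambda = 0.01, seed = 42L) {
  if (alpha + beta <= 0) stop("alpha + beta must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, wrapper_folds = wrapper_folds,
                 hidden = hidden, lambda = lambda, seed = seed),
            class = "fitness_config")
}

#' Wrapper fitness of a feature mask
#'
#' f = alpha * gamma + beta * |p| / N with gamma the stratified-CV
#' balanced error (1 - UAR) of a weighted ELM trained on the selected
#' columns. Deterministic for a fixed config seed.
#'
#' @param bits binary vector over feature columns (>= 1 selected).
#' @param table a [feature_table].
#' @param cfg a [fitness_config].
#' @return scalar fitness (lower is better).
#' @export
wrapper_fitness <- function(bits, table, cfg) {
  if (sum(bits) < 1L) stop("mask must select at least one feature", call. = FALSE)
  if (length(unique(table$labels)) < 2L)
    stop("fitness undefined for a single-class table", call. = FALSE)
  # the CV error is only needed when it carries weight
  gamma <- if (cfg$alpha == 0) 0 else
    wrapper_cv_error(mask_table(table, bits), cfg)
  cfg$alpha * gamma + cfg$beta * sum(bits > 0) / length(bits)
}

# balanced error (1 - UAR) of the wrapper WELM under stratified k-fold CV
wrapper_cv_error <- function(table, cfg) {
  with_seed(cfg$seed, {
    folds <- stratified_folds(table$labels, cfg$wrapper_folds)
    pred <- character(length(table$labels))
    mu <- colMeans(table$values); sc <- apply(table$values, 2, stats::sd)
    sc[sc < EPS] <- 1
    Xs <- sweep(sweep(table$values, 2, mu), 2, sc, "/")
    for (f in seq_len(cfg$wrapper_folds)) {
      tr <- folds != f
      m <- welm_train(Xs[tr, , drop = FALSE], table$labels[tr],
                      D = cfg$hidden, lambda = cfg$lambda, seed = cfg$seed)
      pred[!tr] <- elm_predict(m, Xs[!tr, , drop = FALSE])$labels
    }
    1 - uar(table$labels, pred)
  })
}

#' Binarize a continuous position into a feature mask
#'
#' Two discretization dialects: the golden-eagle rule sets bit = 1 when
#' the updated position is at or below the threshold theta; the
#' salp-swarm rule sets bit = 1 when the position exceeds 0.5. An empty
#' mask is repaired by switching on the single coordinate nearest its
#' threshold.
#'
#' @param position real vector.
#' @param method "geo" or "ssa".
#' @param theta threshold for the geo dialect, in (0, 1).
#' @return integer vector of 0/1 bits with at least one 1.
#' @export
binarize <- function(position, method = c("ssa", "geo"), theta = 0.5) {
  method <- match.arg(method)
  bits <- if (method == "geo") as.integer(position <= theta)
          else as.integer(position > 0.5)
  if (sum(bits) == 0L) {
    thr <- if (method == "geo") theta else 0.5
    bits[which.min(abs(position - thr))] <- 1L
  }
  bits
}

#' Golden-eagle attack vector
#'
#' Points from the eagle's current position to the remembered best
#' position of the selected prey.
#'
#' @param prey_best,current numeric vectors of equal length.
#' @return attack vector prey_best - current.
#' @export
geo_attack_vector <- function(prey_best, current) {
  if (length(prey_best) != length(current))
    stop("dimension mismatch", call. = FALSE)
  prey_best - current
}

#' Golden-eagle cruise vector
#'
#' A random vector exactly orthogonal to the attack vector: all
#' components but one are drawn uniform in \[-1, 1\]; a fixed index q
#' (chosen among coordinates with non-zero attack component) is solved
#' from the orthogonality constraint sum_k v_k w_k = 0.
#'
#' @param attack non-zero attack vector.
#' @return cruise vector with `sum(attack * cruise) == 0` (to machine
#'   precision).
#' @export
geo_cruise_vector <- function(attack) {
  d <- length(attack)
  if (sqrt(sum(attack^2)) < EPS) stop("zero attack vector", call. = FALSE)
  if (d == 1L) return(0)
  nz <- which(abs(attack) > EPS)
  q <- if (length(nz) == 1L) nz else sample(nz, 1L)
  w <- stats::runif(d, -1, 1)
  w[q] <- -sum(attack[-q] * w[-q]) / attack[q]
  w
}

#' Golden-eagle step vector
#'
#' Delta = r1 * (cv * V / ||V||) + r2 * (cw * W / ||W||) with r1, r2
#' uniform per coordinate; a zero cruise vector drops its term.
#'
#' @param attack,cruise attack and cruise vectors.
#' @param cv,cw attack and cruise weights at the current iteration.
#' @return step vector.
#' @export
geo_step <- function(attack, cruise, cv, cw) {
  d <- length(attack)
  nv <- sqrt(sum(attack^2)); nw <- sqrt(sum(cruise^2))
  s <- numeric(d)
  if (nv > EPS) s <- s + stats::runif(d) * cv * attack / nv
  if (nw > EPS) s <- s + stats::runif(d) * cw * cruise / nw
  s
}

#' Linear attack / cruise weight schedule
#'
#' c(i) = c0 + (i / I) * (cI - c0): the attack weight typically grows
#' (exploitation) while the cruise weight decays (exploration).
#'
#' @param i current iteration; `I` maximum iteration.
#' @param c0,cI start and end values.
#' @return interpolated coefficient.
#' @export
geo_coefficient <- function(i, I, c0, cI) c0 + (i / I) * (cI - c0)

#' Binary golden-eagle feature selection
#'
#' Population of eagles with continuous positions in \[0, 1\]^N and a
#' per-eagle memory of the best binarized solution found. Each
#' iteration: prey are assigned by a random one-to-one mapping over the
#' memory, positions move along attack + cruise steps, get binarized
#' (bit = 1 when position <= theta), and memory is updated only on
#' fitness improvement.
#'
#' @param table a [feature_table].
#' @param cfg a [fitness_config].
#' @param pop number of eagles (default 15).
#' @param iters iterations (default 200).
#' @param theta binarization threshold (default 0.5).
#' @param cv0,cvI,cw0,cwI attack / cruise weight schedule endpoints.
#' @param seed RNG seed.
#' @param fitness_fn optional custom fitness `function(bits)`; defaults
#'   to [wrapper_fitness] on `table`.
#' @return list of class `feature_mask`: `bits`, `fitness`, `trace`
#'   (best fitness per iteration, non-increasing), `names`, `seed`.
#' @export
geo_select <- function(table, cfg = fitness_config(), pop = 15L, iters = 200L,
                       theta = 0.5, cv0 = 0.5, cvI = 2, cw0 = 1, cwI = 0.5,
                       seed = 1L, fitness_fn = NULL) {
  d <- ncol(table$values)
  if (is.null(fitness_fn))
    fitness_fn <- function(bits) wrapper_fitness(bits, table, cfg)
  with_seed(seed, {
    pos <- matrix(stats::runif(pop * d), pop, d)
    mem_pos <- pos
    mem_fit <- apply(pos, 1, function(p) fitness_fn(binarize(p, "geo", theta)))
    trace <- numeric(iters)
    for (i in seq_len(iters)) {
      cv <- geo_coefficient(i, iters, cv0, cvI)
      cw <- geo_coefficient(i, iters, cw0, cwI)
      prey <- sample(pop)
      for (g in seq_len(pop)) {
        V <- geo_attack_vector(mem_pos[prey[g], ], pos[g, ])
        if (sqrt(sum(V^2)) < EPS) next
        W <- geo_cruise_vector(V)
        step <- geo_step(V, W, cv, cw)
        pos[g, ] <- pos[g, ] + step
        bits <- binarize(pos[g, ], "geo", theta)
        f <- fitness_fn(bits)
        if (f < mem_fit[g]) {
          mem_fit[g] <- f
          mem_pos[g, ] <- pmin(pmax(pos[g, ], 0), 1)
        }
      }
      trace[i] <- min(mem_fit)
    }
    best <- which.min(mem_fit)
    bits <- binarize(mem_pos[best, ], "geo", theta)
    structure(list(bits = bits, fitness = mem_fit[best],
                   trace = if (iters > 0) trace else min(mem_fit),
                   names = colnames(table$values)[bits == 1],
                   method = "geo", seed = seed),
              class = "feature_mask")
  })
}

#' Salp-swarm leader update
#'
#' Per coordinate the leader moves around the food source:
#' food +/- r1 * ((ub - lb) * r2 + lb), the sign chosen by a per-
#' coordinate uniform draw (plus with probability 1/2), with
#' r1 = 2 * exp(-(4 i / Imax)^2) shrinking the step over iterations.
#' The result is clamped to the bounds.
#'
#' @param food current best (food) position.
#' @param i,Imax current and maximum iteration.
#' @param lb,ub scalar bounds (defaults 0, 1).
#' @return updated leader position.
#' @export
ssa_leader_update <- function(food, i, Imax, lb = 0, ub = 1) {
  d <- length(food)
  r1 <- ssa_r1(i, Imax)
  r2 <- stats::runif(d)
  plus <- stats::runif(d) >= 0.5
  step <- r1 * ((ub - lb) * r2 + lb)
  pmin(pmax(ifelse(plus, food + step, food - step), lb), ub)
}

#' Salp-swarm adaptive factor r1 = 2 exp(-(4 i / Imax)^2)
#' @param i,Imax current and maximum iteration.
#' @return scalar factor (2 at i = 0, 2 exp(-16) at i = Imax).
#' @export
ssa_r1 <- function(i, Imax) 2 * exp(-(4 * i / Imax)^2)

#' Salp-swarm follower update: midpoint of own and preceding positions
#' @param pos_i,pos_prev follower's own and preceding positions.
#' @return updated position.
#' @export
ssa_follower_update <- function(pos_i, pos_prev) 0.5 * (pos_i + pos_prev)

#' Tent / Bernoulli-shift chaotic sequence
#'
#' Iterates d <- 2 d mod 1 (the Bernoulli-shift form of the tent map)
#' from a seed value in (0, 1); degenerate seeds (0, 0.5, 1) are
#' perturbed by 1e-6 with a warning. All iterates lie in \[0, 1).
#'
#' @param seed_value starting value in (0, 1).
#' @param n number of iterates to return.
#' @return numeric vector of length n.
#' @export
tent_map_sequence <- function(seed_value, n) {
  if (seed_value %in% c(0, 0.5, 1)) {
    warning("degenerate tent-map seed perturbed by 1e-6")
    seed_value <- seed_value + 1e-6
  }
  out <- numeric(n)
  d <- seed_value
  for (i in seq_len(n)) {
    d <- (2 * d) %% 1
    # double-precision orbits of the doubling map collapse to 0; kick
    # with a tiny irrational offset to keep the sequence non-degenerate
    if (d < 1e-12) d <- d + pi * 1e-7
    out[i] <- d
  }
  out
}

#' Stepped inertia weight
#'
#' w = wmax while t / tmax <= lambda (inclusive), wmin afterwards.
#'
#' @param t,tmax current and maximum iteration.
#' @param lambda switch point in (0, 1).
#' @param wmin,wmax the two inertia levels.
#' @return scalar weight.
#' @export
stepped_inertia <- function(t, tmax, lambda, wmin, wmax) {
  if (t / tmax <= lambda) wmax else wmin
}

#' Simulated-annealing acceptance rule
#'
#' Accept an update with probability 1 when it improves the fitness and
#' with probability exp(-(f_new - f_old) / temperature) otherwise.
#'
#' @param f_new,f_old candidate and incumbent fitness (minimization).
#' @param temperature positive temperature.
#' @return logical: accept the candidate.
#' @export
sa_accept <- function(f_new, f_old, temperature) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (f_new < f_old) return(TRUE)
  stats::runif(1) < exp(-(f_new - f_old) / temperature)
}

# shared engine for the plain and refined salp-swarm selectors
ssa_engine <- function(table, cfg, pop, iters, seed, refined,
                       wmin = 0.6, wmax = 0.8, lambda = 0.2,
                       cooling = 0.95, fitness_fn = NULL) {
  d <- ncol(table$values)
  if (is.null(fitness_fn))
    fitness_fn <- function(bits) wrapper_fitness(bits, table, cfg)
  with_seed(seed, {
    if (refined) {
      seq0 <- tent_map_sequence(stats::runif(1, 0.1, 0.9), pop * d)
      pos <- matrix(seq0, pop, d)
    } else {
      pos <- matrix(stats::runif(pop * d), pop, d)
    }
    fit <- apply(pos, 1, function(p) fitness_fn(binarize(p, "ssa")))
    best <- which.min(fit)
    food <- pos[best, ]; food_fit <- fit[best]
    best_bits <- binarize(food, "ssa"); best_fit <- food_fit
    temp <- max(max(fit) - min(fit), 1e-3)
    trace <- numeric(iters)
    for (t in seq_len(iters)) {
      w_l <- if (refined) stepped_inertia(t, iters, lambda, wmin, wmax) else 1
      pos[1, ] <- ssa_leader_update(food, t, iters)
      if (pop > 1) for (s in 2:pop) {
        pos[s, ] <- 0.5 * (pos[s, ] + w_l * pos[s - 1, ])
        pos[s, ] <- pmin(pmax(pos[s, ], 0), 1)
      }
      fit <- apply(pos, 1, function(p) fitness_fn(binarize(p, "ssa")))
      cand <- which.min(fit)
      accept <- if (refined) sa_accept(fit[cand], food_fit, temp)
                else fit[cand] < food_fit
      if (accept) {
        food <- pos[cand, ]; food_fit <- fit[cand]
      }
      if (fit[cand] < best_fit) {
        best_fit <- fit[cand]; best_bits <- binarize(pos[cand, ], "ssa")
      }
      temp <- temp * cooling
      trace[t] <- best_fit
    }
    structure(list(bits = best_bits, fitness = best_fit, trace = trace,
                   names = colnames(table$values)[best_bits == 1],
                   method = if (refined) "rssa" else "ssa", seed = seed),
              class = "feature_mask")
  })
}

#' Salp-swarm feature selection
#'
#' Plain salp-swarm wrapper selection: a leader salp tracks the food
#' source (best solution) while followers average along the chain;
#' positions are binarized with the strict > 0.5 rule before each
#' fitness evaluation.
#'
#' @inheritParams geo_select
#' @param pop chain length (default 15).
#' @return a `feature_mask` (see [geo_select]).
#' @export
ssa_select <- function(table, cfg = fitness_config(), pop = 15L, iters = 200L,
                       seed = 1L, fitness_fn = NULL) {
  ssa_engine(table, cfg, pop, iters, seed, refined = FALSE,
             fitness_fn = fitness_fn)
}

#' Refined salp-swarm feature selection
#'
#' Salp-swarm selection with three refinements aimed at convergence
#' speed and local-optimum escape: tent-chaotic-map population
#' initialization, a stepped inertia weight in the follower update
#' (wmax early, wmin after the fraction lambda of the run), and
#' simulated-annealing acceptance of food-source updates with geometric
#' cooling (initial temperature = fitness spread of the initial
#' population).
#'
#' @inheritParams ssa_select
#' @param wmin,wmax stepped inertia levels (defaults 0.6, 0.8).
#' @param lambda inertia switch point (default 0.2).
#' @param cooling geometric cooling factor per iteration (default 0.95).
#' @return a `feature_mask` (see [geo_select]).
#' @export
refined_ssa_select <- function(table, cfg = fitness_config(), pop = 15L,
                               iters = 200L, seed = 1L, wmin = 0.6, wmax = 0.8,
                               lambda = 0.2, cooling = 0.95, fitness_fn = NULL) {
  ssa_engine(table, cfg, pop, iters, seed, refined = TRUE,
             wmin = wmin, wmax = wmax, lambda = lambda, cooling = cooling,
             fitness_fn = fitness_fn)
}

#' Run a named selector
#'
#' @param method "geo", "ssa" or "rssa".
#' @param table a [feature_table].
#' @param cfg a [fitness_config].
#' @param ... passed to the selector.
#' @return a `feature_mask`.
#' @export
select_features <- function(method = c("geo", "ssa", "rssa"), table,
                            cfg = fitness_config(), ...) {
  method <- match.arg(method)
  switch(method,
         geo = geo_select(table, cfg, ...),
         ssa = ssa_select(table, cfg, ...),
         rssa = refined_ssa_select(table, cfg, ...))
}

#' Write a feature mask as JSON
#' @param mask a `feature_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_json <- function(mask, path) {
  jsonlite::write_json(
    list(names = mask$names, bits = mask$bits, fitness = mask$fitness,
         trace = mask$trace, method = mask$method, seed = mask$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
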